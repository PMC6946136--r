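#' Full (dimensional) model parameters
#'
#' Bundles the physical parameters of the resource-explicit growth model:
#' bacterial and resource diffusion constants, per-genotype maximum growth
#' rates, the Monod half-saturation constant, the yield coefficient, and the
#' initial resource per lattice box. Internal units are fixed as cm and
#' hours; constants given in cm^2/s are converted on ingest (a common source
#' of 3600-fold errors).
#'
#' @param D_B bacterial diffusion constant (cm^2 per hour unless `units`
#'   says otherwise).
#' @param D_R resource diffusion constant (same units as `D_B`).
#' @param mu numeric vector of per-genotype maximum growth rates (1/h),
#'   fastest first: `mu[1]` must equal `max(mu)` because the scaling divides
#'   by the fastest rate.
#' @param k Monod half-saturation constant (resource units).
#' @param lam yield coefficient \eqn{\lambda}: resources consumed per cell
#'   produced.
#' @param R0 initial resource per lattice box (resource units).
#' @param units units of the diffusion constants, `"cm2_per_h"` (default)
#'   or `"cm2_per_s"`.
#' @return An object of class `full_params`.
#' @examples
#' # the benchmark parameterization: D_R typical of a small sugar in agar
#' p <- full_params(D_B = 5e-9, D_R = 5e-6, mu = c(0.11, 0.10),
#'                  k = 1, lam = 1, R0 = 100, units = "cm2_per_s")
#' p$D_R  # 0.018 cm^2/h
#' @export
full_params <- function(D_B, D_R, mu, k, lam, R0,
                        units = c("cm2_per_h", "cm2_per_s")) {
  units <- match.arg(units)
  if (units == "cm2_per_s") {
    D_B <- D_B * 3600
    D_R <- D_R * 3600
  }
  vals <- c(D_B = D_B, D_R = D_R, k = k, lam = lam, R0 = R0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all parameters must be finite and strictly positive")
  if (length(mu) < 1L || any(!is.finite(mu)) || any(mu <= 0))
    stop("'mu' must contain finite, strictly positive rates")
  if (mu[1] != max(mu))
    stop("'mu' must be ordered fastest-first: mu[1] must equal max(mu)")
  structure(list(D_B = D_B, D_R = D_R, mu = as.numeric(mu),
                 k = k, lam = lam, R0 = R0),
            class = "full_params")
}

#' Scaled (dimensionless) model parameters
#'
#' The nondimensionalized parameterization: relative bacterial diffusion
#' `D_c = D_B/D_R`, relative growth rates `mu_rel = mu/mu[1]` (so
#' `mu_rel[1] = 1`), and scaled initial resource `R0_hat = R0/k`. In the
#' scaled model the resource diffuses with constant 1 and the half-saturation
#' constant is 1.
#'
#' @param D_c relative bacterial diffusion constant (dimensionless, in
#'   `(0, 1]` for all settings of interest).
#' @param mu_rel per-genotype relative growth rates; `mu_rel[1]` must be 1.
#' @param R0_hat initial scaled resource per box.
#' @return An object of class `scaled_params`.
#' @export
scaled_params <- function(D_c, mu_rel, R0_hat) {
  if (!is.finite(D_c) || D_c <= 0) stop("'D_c' must be positive")
  if (!is.finite(R0_hat) || R0_hat <= 0) stop("'R0_hat' must be positive")
  if (any(!is.finite(mu_rel)) || any(mu_rel <= 0))
    stop("'mu_rel' must be strictly positive")
  if (abs(mu_rel[1] - 1) > 1e-12)
    stop("'mu_rel[1]' must equal 1 (rates are relative to the fastest)")
  if (mu_rel[1] != max(mu_rel))
    stop("'mu_rel' must be ordered fastest-first")
  structure(list(D_c = D_c, mu_rel = as.numeric(mu_rel), R0_hat = R0_hat),
            class = "scaled_params")
}

#' Characteristic quantities of the nondimensionalization
#'
#' The characteristic resource, biomass, time, and length used to make the
#' model dimensionless: `R_c = k`, `B_c = k/lambda`, `t_c = 1/mu1`,
#' `x_c = sqrt(D_R/mu1)`. `x_c` is the natural length scale: the distance
#' the resource diffuses in one characteristic growth time.
#'
#' @param D_R resource diffusion constant (cm^2/h).
#' @param mu1 fastest maximum growth rate (1/h).
#' @param k Monod half-saturation constant.
#' @param lam yield coefficient.
#' @return An object of class `scaling_transform` with fields `R_c`, `B_c`,
#'   `t_c`, `x_c`.
#' @export
scaling_transform <- function(D_R, mu1, k = 1, lam = 1) {
  if (any(c(D_R, mu1, k, lam) <= 0)) stop("all arguments must be positive")
  structure(list(R_c = k, B_c = k / lam, t_c = 1 / mu1,
                 x_c = sqrt(D_R / mu1)),
            class = "scaling_transform")
}

#' Natural length scale of resource competition
#'
#' `sqrt(D_R/mu1)`: the distance over which the resource diffuses within one
#' characteristic doubling time of the fastest genotype. Faster growth
#' shrinks it (localizing competition); faster resource diffusion enlarges
#' it. Strictly increasing in `D_R` and strictly decreasing in `mu1`;
#' quadrupling `mu1` halves it.
#'
#' @param D_R resource diffusion constant (cm^2/h).
#' @param mu1 fastest maximum growth rate (1/h).
#' @return Length in cm.
#' @examples
#' natural_length_scale(0.018, 0.15)  # 0.3464 cm
#' @export
natural_length_scale <- function(D_R, mu1) {
  if (!all(is.finite(D_R)) || !all(is.finite(mu1)) ||
      any(D_R <= 0) || any(mu1 <= 0))
    stop("'D_R' and 'mu1' must be finite and strictly positive")
  sqrt(D_R / mu1)
}

#' Convert full-model parameters to the scaled model
#'
#' @param p a [full_params()] object.
#' @return A list with components `scaled` (a [scaled_params()] object) and
#'   `transform` (a [scaling_transform()] object). The pair round-trips
#'   through [from_scaled()] to relative error below 1e-12.
#' @examples
#' p <- full_params(1.8e-5, 1.8e-2, c(0.11, 0.10), 1, 1, 100)
#' to_scaled(p)$scaled$D_c      # 0.001
#' to_scaled(p)$scaled$mu_rel   # 1, 1/1.1
#' @export
to_scaled <- function(p) {
  stopifnot(inherits(p, "full_params"))
  list(scaled = scaled_params(D_c = p$D_B / p$D_R,
                              mu_rel = p$mu / p$mu[1],
                              R0_hat = p$R0 / p$k),
       transform = scaling_transform(p$D_R, p$mu[1], p$k, p$lam))
}

#' Recover full-model parameters from the scaled model
#'
#' Exact algebraic inverse of [to_scaled()]: `mu1 = 1/t_c`,
#' `D_R = x_c^2/t_c`, `D_B = D_c * D_R`, `k = R_c`, `lam = R_c/B_c`,
#' `R0 = R0_hat * k`.
#'
#' @param s a [scaled_params()] object.
#' @param transform a [scaling_transform()] object.
#' @return A [full_params()] object.
#' @export
from_scaled <- function(s, transform) {
  stopifnot(inherits(s, "scaled_params"),
            inherits(transform, "scaling_transform"))
  mu1 <- 1 / transform$t_c
  D_R <- transform$x_c^2 / transform$t_c
  full_params(D_B = s$D_c * D_R, D_R = D_R, mu = s$mu_rel * mu1,
              k = transform$R_c, lam = transform$R_c / transform$B_c,
              R0 = s$R0_hat * transform$R_c)
}

#' Scaled mean intercolony distance zeta
#'
#' `zeta = ic_bar / sqrt(D_R/mu1)`: the mean nearest-neighbor intercolony
#' distance expressed in units of the natural length scale. It is the single
#' dimensionless knob coupling growth rate, founder spacing, and resource
#' diffusion: multiplying `ic_bar` by c has exactly the same effect as
#' multiplying `mu1` by c^2 (or dividing `D_R` by c^2).
#'
#' @param ic_bar mean minimum center-to-center intercolony distance (cm).
#' @param D_R resource diffusion constant (cm^2/h).
#' @param mu1 fastest maximum growth rate (1/h).
#' @return Dimensionless zeta.
#' @examples
#' compute_zeta(0.45, 0.018, 0.15)            # 1.299
#' compute_zeta(0.9, 0.018, 0.15)             # equals the next line
#' compute_zeta(0.45, 0.018, 4 * 0.15)        # doubling distance == 4x rate
#' @export
compute_zeta <- function(ic_bar, D_R, mu1) {
  if (!all(is.finite(ic_bar)) || any(ic_bar <= 0))
    stop("'ic_bar' must be finite and strictly positive")
  ic_bar / natural_length_scale(D_R, mu1)
}

#' @export
print.full_params <- function(x, ...) {
  cat("Full-model parameters (cm, h):\n")
  cat(sprintf("  D_B = %g cm^2/h, D_R = %g cm^2/h\n", x$D_B, x$D_R))
  cat(sprintf("  mu  = %s 1/h (fastest first)\n",
              paste(signif(x$mu, 6), collapse = ", ")))
  cat(sprintf("  k = %g, lambda = %g, R0 = %g per box\n", x$k, x$lam, x$R0))
  cat(sprintf("  natural length scale sqrt(D_R/mu1) = %.6g cm\n",
              natural_length_scale(x$D_R, x$mu[1])))
  invisible(x)
}

#' @export
print.scaled_params <- function(x, ...) {
  cat("Scaled (dimensionless) model parameters:\n")
  cat(sprintf("  D_c = %g, R0_hat = %g per box\n", x$D_c, x$R0_hat))
  cat(sprintf("  mu_rel = %s\n", paste(signif(x$mu_rel, 6), collapse = ", ")))
  invisible(x)
}

#' @export
print.scaling_transform <- function(x, ...) {
  cat("Characteristic quantities:\n")
  cat(sprintf("  R_c = %g, B_c = %g, t_c = %g h, x_c = %.6g cm\n",
              x$R_c, x$B_c, x$t_c, x$x_c))
  invisible(x)
}
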