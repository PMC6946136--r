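#' Engine parameterization
#'
#' The stepping engine is parameterization-agnostic: it needs diffusion
#' constants for biomass and resource, per-genotype rates, `k`, and
#' `lambda`. A [full_params()] object supplies its physical values; a
#' [scaled_params()] object supplies the dimensionless equivalents
#' (resource diffusion 1, `k` 1, `lambda` 1).
#'
#' @param p a [full_params()] or [scaled_params()] object.
#' @return A plain list with fields `D_B`, `D_R`, `mu`, `k`, `lam`, `R0`.
#' @export
engine_params <- function(p) UseMethod("engine_params")

#' @export
engine_params.full_params <- function(p) {
  list(D_B = p$D_B, D_R = p$D_R, mu = p$mu, k = p$k, lam = p$lam, R0 = p$R0)
}

#' @export
engine_params.scaled_params <- function(p) {
  list(D_B = p$D_c, D_R = 1, mu = p$mu_rel, k = 1, lam = 1, R0 = p$R0_hat)
}

#' @export
engine_params.list <- function(p) p

#' Time-step control
#'
#' @param dt time step; `NULL` selects the stability bound
#'   `0.1 * dx^2 / D_max` exactly (the largest admissible step for the
#'   explicit diffusion scheme at the accuracy margin used throughout).
#' @param consumed_frac_stop stop batch runs once this fraction of the
#'   initial resource has been consumed (default 0.99).
#' @param max_steps non-termination guard for [run_until_consumed()].
#' @return An object of class `step_control`.
#' @export
step_control <- function(dt = NULL, consumed_frac_stop = 0.99,
                         max_steps = 1e8) {
  if (!is.null(dt) && dt <= 0) stop("'dt' must be positive")
  if (consumed_frac_stop <= 0 || consumed_frac_stop > 1)
    stop("'consumed_frac_stop' must be in (0, 1]")
  structure(list(dt = dt, consumed_frac_stop = consumed_frac_stop,
                 max_steps = max_steps),
            class = "step_control")
}

#' Default stable time step
#'
#' `0.1 * dx^2 / D_max`, where `D_max` is the largest diffusion constant in
#' play (the resource dominates since bacteria diffuse ~1000x slower).
#'
#' @param params engine parameters (see [engine_params()]).
#' @param domain an [rd_domain()].
#' @return Time step.
#' @export
default_dt <- function(params, domain) {
  ep <- engine_params(params)
  0.1 * domain$dx^2 / max(ep$D_B, ep$D_R)
}

.check_dt <- function(dt, D, dx) {
  bound <- 0.1 * dx^2 / D
  if (dt > bound * (1 + 1e-9))
    stop(sprintf("dt = %g violates the stability bound 0.1*dx^2/D = %g",
                 dt, bound), call. = FALSE)
  invisible(dt)
}

.resolve_dt <- function(ctrl, params, domain) {
  dt <- if (is.null(ctrl$dt)) default_dt(params, domain) else ctrl$dt
  ep <- engine_params(params)
  .check_dt(dt, max(ep$D_B, ep$D_R), domain$dx)
  dt
}

#' Simulation state
#'
#' @param map a [founder_map()] whose founders seed the biomass fields.
#' @param params engine parameters (full or scaled).
#' @param domain an [rd_domain()].
#' @param tracking `"genotype"` (one field per genotype) or `"lineage"`
#'   (one field per founder, as used by the drift and localization assays).
#' @param founder_biomass biomass deposited in each founder's box (one unit
#'   per location by default).
#' @param R0 initial resource per box; defaults to the parameter set's.
#' @return An object of class `sim_state`: list with `R_field` (nx x ny
#'   matrix), `B` (nx x ny x n_lineages array), `lineage_genotype`, `t`.
#' @export
init_state <- function(map, params, domain = attr(map, "domain"),
                       tracking = c("genotype", "lineage"),
                       founder_biomass = 1, R0 = NULL) {
  tracking <- match.arg(tracking)
  ep <- engine_params(params)
  if (is.null(R0)) R0 <- ep$R0
  if (any(map$genotype < 1L) || any(map$genotype > length(ep$mu)))
    stop("founder genotype index outside the parameter set's mu vector")
  nx <- domain$nx; ny <- domain$ny
  if (tracking == "lineage") {
    nl <- nrow(map)
    lineage_genotype <- map$genotype
    lin <- seq_len(nl)
  } else {
    nl <- length(ep$mu)
    lineage_genotype <- seq_len(nl)
    lin <- map$genotype
  }
  B <- array(0, dim = c(nx, ny, nl))
  idx <- cbind(map$i + 1L, map$j + 1L, lin)
  B[idx] <- B[idx] + founder_biomass
  structure(list(R_field = matrix(R0, nx, ny), B = B,
                 lineage_genotype = as.integer(lineage_genotype), t = 0),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("Simulation state: %d x %d lattice, %d lineage field(s), t = %g\n",
              dim(x$B)[1], dim(x$B)[2], dim(x$B)[3], x$t))
  cat(sprintf("  total resource %.6g, total biomass %.6g\n",
              sum(x$R_field), sum(x$B)))
  invisible(x)
}

#' Field totals
#'
#' @param state a `sim_state`.
#' @param by `"lineage"` or `"genotype"` (sums lineage fields by genotype).
#' @return Named numeric vector of per-lineage (or per-genotype) biomass
#'   totals, or the total resource.
#' @export
total_biomass <- function(state, by = c("lineage", "genotype")) {
  by <- match.arg(by)
  tot <- apply(state$B, 3, sum)
  if (by == "genotype")
    tot <- as.numeric(tapply(tot, factor(state$lineage_genotype,
                                         levels = sort(unique(state$lineage_genotype))),
                             sum))
  tot
}

#' @rdname total_biomass
#' @export
total_resource <- function(state) sum(state$R_field)

#' One explicit diffusion step
#'
#' Forward-Euler five-point-stencil update
#' `f + D*dt/dx^2 * (sum of 4 neighbors - 4f)`. On a torus neighbors wrap;
#' with no-flux boundaries the missing neighbor takes the edge value
#' (zero gradient), so total mass is conserved exactly either way. The
#' stability bound `dt <= 0.1 * dx^2 / D` is enforced, never silently
#' sub-stepped.
#'
#' @param field nonnegative matrix.
#' @param D diffusion constant.
#' @param dt time step.
#' @param domain an [rd_domain()].
#' @return Updated matrix.
#' @export
diffuse_step <- function(field, D, dt, domain) {
  .check_dt(dt, D, domain$dx)
  if (D == 0) return(field)
  nx <- domain$nx; ny <- domain$ny
  alpha <- D * dt / domain$dx^2
  if (domain$boundary == "torus") {
    im <- c(nx, seq_len(nx - 1)); ip <- c(seq_len(nx - 1) + 1L, 1L)
    jm <- c(ny, seq_len(ny - 1)); jp <- c(seq_len(ny - 1) + 1L, 1L)
  } else {
    im <- c(1L, seq_len(nx - 1)); ip <- c(seq_len(nx - 1) + 1L, nx)
    jm <- c(1L, seq_len(ny - 1)); jp <- c(seq_len(ny - 1) + 1L, ny)
  }
  field + alpha * (field[im, ] + field[ip, ] +
                   field[, jm] + field[, jp] - 4 * field)
}

#' One Monod growth step (reaction substep)
#'
#' Integrates, within each box over `dt`,
#' `dB_l/dt = mu_l B_l R/(R+k)` and `dR/dt = -lambda * sum_l mu_l B_l R/(R+k)`.
#' The system reduces exactly to a scalar ODE for the cumulative Monod
#' integral G (then `B_l' = B_l exp(mu_l G)`), which is advanced with one
#' classical RK4 step. Resource bookkeeping is exact by construction:
#' `R' = R - lambda * sum(B' - B)`, clipped at zero with the biomass gain
#' capped proportionally if the step would overshoot exhaustion.
#'
#' @param B biomass: a `n_box x n_lineage` matrix (or a vector, one box).
#' @param R resource: vector of length `n_box` (or a scalar).
#' @param mu per-lineage maximum growth rates.
#' @param k half-saturation constant.
#' @param lam yield coefficient.
#' @param dt time step.
#' @return List with updated `B` and `R`.
#' @export
growth_step <- function(B, R, mu, k, lam, dt) {
  single <- is.null(dim(B))
  if (single) B <- matrix(B, nrow = length(R))
  if (any(B < 0) || any(R < 0)) stop("negative biomass or resource")
  if (dt <= 0) stop("'dt' must be positive")
  g <- function(G) {
    consumed <- rowSums(B * expm1(outer(G, mu)))
    Rof <- pmax(R - lam * consumed, 0)
    Rof / (Rof + k)
  }
  k1 <- g(numeric(length(R)))
  k2 <- g(0.5 * dt * k1)
  k3 <- g(0.5 * dt * k2)
  k4 <- g(dt * k3)
  G <- dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  E <- expm1(outer(G, mu))
  dB <- rowSums(B * E)
  Rp <- R - lam * dB
  over <- which(Rp < 0 & dB > 0)
  if (length(over)) {
    scale <- R[over] / (lam * dB[over])
    E[over, ] <- E[over, , drop = FALSE] * scale
    Rp[over] <- 0
  }
  Bp <- B + B * E
  if (single) Bp <- drop(Bp)
  list(B = Bp, R = Rp)
}

#' One full operator-split step
#'
#' Growth then diffusion: applies [growth_step()] to every box, then
#' [diffuse_step()] to each biomass field (with `D_B`) and to the resource
#' field (with `D_R`); advances `t` by `dt`.
#'
#' @param state a `sim_state`.
#' @param params engine parameters (full or scaled).
#' @param ctrl a [step_control()].
#' @param domain an [rd_domain()].
#' @return Updated `sim_state`.
#' @export
step <- function(state, params, ctrl = step_control(), domain) {
  ep <- engine_params(params)
  dt <- .resolve_dt(ctrl, params, domain)
  nx <- domain$nx; ny <- domain$ny
  nl <- dim(state$B)[3]
  mu_lineage <- ep$mu[state$lineage_genotype]
  Bmat <- state$B
  dim(Bmat) <- c(nx * ny, nl)
  gr <- growth_step(Bmat, as.vector(state$R_field), mu_lineage,
                    ep$k, ep$lam, dt)
  B <- gr$B
  dim(B) <- c(nx, ny, nl)
  for (l in seq_len(nl))
    B[, , l] <- diffuse_step(B[, , l], ep$D_B, dt, domain)
  R_field <- diffuse_step(matrix(gr$R, nx, ny), ep$D_R, dt, domain)
  state$B <- B
  state$R_field <- R_field
  state$t <- state$t + dt
  state
}

.kernel_run <- function(state, params, ctrl, domain, stop_mode,
                        max_steps = ctrl$max_steps,
                        chemo_delta = 0, chemo_reservoir = 0,
                        is_mutant = NULL, freq_threshold = 1,
                        washout_total = 0) {
  ep <- engine_params(params)
  dt <- .resolve_dt(ctrl, params, domain)
  nl <- dim(state$B)[3]
  if (is.null(is_mutant)) is_mutant <- rep(FALSE, nl)
  res <- rd_run_cpp(as.vector(state$B), as.vector(state$R_field),
                    domain$nx, domain$ny, nl,
                    ep$mu[state$lineage_genotype], ep$k, ep$lam,
                    ep$D_B, ep$D_R, domain$dx, dt,
                    domain$boundary == "torus",
                    ctrl$consumed_frac_stop, state$t, max_steps,
                    chemo_delta, chemo_reservoir,
                    is_mutant, freq_threshold, washout_total, stop_mode)
  state$B <- array(res$B, dim = dim(state$B))
  state$R_field <- matrix(res$R, domain$nx, domain$ny)
  state$t <- res$t
  attr(state, "steps") <- res$steps
  attr(state, "stop") <- res$stop
  state
}

#' Run a batch simulation to resource exhaustion
#'
#' Iterates [step()] until the total resource drops to
#' `(1 - consumed_frac_stop)` of its initial total (default: until more
#' than 99% is consumed). Uses a compiled stepping loop implementing the
#' identical update; set `compiled = FALSE` for the pure-R path.
#'
#' @inheritParams step
#' @param compiled use the compiled stepping loop (default).
#' @return Final `sim_state`, with attributes `"steps"` and `"stop"`.
#' @export
run_until_consumed <- function(state, params, ctrl = step_control(), domain,
                               compiled = TRUE) {
  if (total_resource(state) <= 0) stop("initial total resource must be positive")
  if (sum(state$B) == 0)
    stop("all-zero biomass cannot consume the resource (non-termination)")
  if (compiled)
    return(.kernel_run(state, params, ctrl, domain, stop_mode = 0L))
  stop_at <- (1 - ctrl$consumed_frac_stop) * total_resource(state)
  steps <- 0
  while (total_resource(state) > stop_at) {
    if (steps >= ctrl$max_steps)
      stop(sprintf("stop condition not reached within %g steps", ctrl$max_steps))
    state <- step(state, params, ctrl, domain)
    steps <- steps + 1
  }
  attr(state, "steps") <- steps
  attr(state, "stop") <- "consumed"
  state
}

#' Run a fixed number of steps
#'
#' @inheritParams step
#' @param n number of steps.
#' @param compiled use the compiled stepping loop.
#' @return Final `sim_state`.
#' @export
run_steps <- function(state, params, n, ctrl = step_control(), domain,
                      compiled = TRUE) {
  if (compiled)
    return(.kernel_run(state, params, ctrl, domain, stop_mode = 2L,
                       max_steps = n))
  for (s in seq_len(n)) state <- step(state, params, ctrl, domain)
  attr(state, "steps") <- n
  state
}

#' Well-mixed (mass-action) batch growth
#'
#' Integrates the spaceless analogue of the model,
#' `dB_i/dt = mu_i B_i R/(R+k)`, `dR/dt = -lambda sum_i mu_i B_i R/(R+k)`,
#' stopping when the consumed fraction reaches `consumed_frac_stop`. Because
#' every genotype shares the same Monod factor, the exact invariant
#' `log(B_i(T)/B_i(0)) / log(B_j(T)/B_j(0)) = mu_i/mu_j` holds at any
#' stopping time.
#'
#' @param B0 per-genotype initial biomass.
#' @param R0_total total initial resource.
#' @param mu per-genotype maximum growth rates.
#' @param k half-saturation constant.
#' @param lam yield coefficient.
#' @param consumed_frac_stop stop once this resource fraction is consumed.
#' @return List with `B` (per-genotype final biomass), `R`, `t`.
#' @export
run_well_mixed <- function(B0, R0_total, mu, k, lam,
                           consumed_frac_stop = 0.99) {
  if (sum(B0) <= 0 || R0_total <= 0) stop("totals must be positive")
  if (length(B0) != length(mu)) stop("'B0' and 'mu' lengths differ")
  n <- length(B0)
  rhs <- function(t, y, parms) {
    B <- y[seq_len(n)]
    R <- max(y[n + 1], 0)
    f <- R / (R + k)
    dB <- mu * B * f
    list(c(dB, -lam * sum(dB)))
  }
  rootf <- function(t, y, parms) y[n + 1] - (1 - consumed_frac_stop) * R0_total
  tmax <- 50 * (1 + log1p(R0_total / (lam * sum(B0)))) / min(mu)
  sol <- deSolve::lsodar(y = c(B0, R0_total), times = c(0, tmax),
                         func = rhs, parms = NULL, rootfunc = rootf,
                         rtol = 1e-10, atol = 1e-10 * (R0_total + sum(B0)))
  last <- sol[nrow(sol), ]
  list(B = unname(last[1 + seq_len(n)]), R = unname(last[n + 2]),
       t = unname(last[1]))
}

#' Convert a state between full and scaled representations
#'
#' Biomass scales by `lambda/k`, resource by `1/k`, time by `mu1`, and the
#' box width by the natural length scale (handled by the paired domain).
#'
#' @param state a `sim_state` in full (physical) units.
#' @param transform a [scaling_transform()].
#' @return The state in the other representation.
#' @export
state_to_scaled <- function(state, transform) {
  state$R_field <- state$R_field / transform$R_c
  state$B <- state$B / transform$B_c
  state$t <- state$t / transform$t_c
  state
}

#' @rdname state_to_scaled
#' @export
state_from_scaled <- function(state, transform) {
  state$R_field <- state$R_field * transform$R_c
  state$B <- state$B * transform$B_c
  state$t <- state$t * transform$t_c
  state
}

#' Write or read a state snapshot as plain text
#'
#' One whitespace-separated matrix file per field plus a small YAML metadata
#' header (time, lattice shape, lineage genotypes).
#'
#' @param state a `sim_state`.
#' @param dir directory for the snapshot files.
#' @param prefix file-name prefix.
#' @return `write_state` returns the metadata path invisibly; `read_state`
#'   returns a `sim_state`.
#' @export
write_state <- function(state, dir, prefix = "state") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- list(t = state$t, nx = dim(state$B)[1], ny = dim(state$B)[2],
               n_lineages = dim(state$B)[3],
               lineage_genotype = as.integer(state$lineage_genotype))
  yaml::write_yaml(meta, file.path(dir, paste0(prefix, "_meta.yaml")))
  write.table(state$R_field, file.path(dir, paste0(prefix, "_R.txt")),
              row.names = FALSE, col.names = FALSE)
  for (l in seq_len(dim(state$B)[3]))
    write.table(state$B[, , l],
                file.path(dir, sprintf("%s_B%d.txt", prefix, l)),
                row.names = FALSE, col.names = FALSE)
  invisible(file.path(dir, paste0(prefix, "_meta.yaml")))
}

#' @rdname write_state
#' @export
read_state <- function(dir, prefix = "state") {
  meta <- yaml::read_yaml(file.path(dir, paste0(prefix, "_meta.yaml")))
  R_field <- as.matrix(read.table(file.path(dir, paste0(prefix, "_R.txt"))))
  dimnames(R_field) <- NULL
  B <- array(0, dim = c(meta$nx, meta$ny, meta$n_lineages))
  for (l in seq_len(meta$n_lineages)) {
    m <- as.matrix(read.table(file.path(dir, sprintf("%s_B%d.txt", prefix, l))))
    dimnames(m) <- NULL
    B[, , l] <- m
  }
  structure(list(R_field = R_field, B = B,
                 lineage_genotype = as.integer(meta$lineage_genotype),
                 t = meta$t),
            class = "sim_state")
}
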