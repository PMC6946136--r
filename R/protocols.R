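#' Deterministic serial-transfer bottleneck
#'
#' Apportions a fixed number of founder cells among genotypes in proportion
#' to their final biomass fractions, using largest-remainder rounding
#' (ties broken toward the faster genotype, i.e. the lower index). This is
#' the deterministic dilution of the serial-transfer protocol: each count
#' deviates from `freq * n_founders` by less than one founder, and counts
#' always sum exactly to `n_founders`.
#'
#' @param freqs per-genotype biomass fractions (must sum to 1 within 1e-9).
#' @param n_founders number of founders to seed the next transfer.
#' @return Integer vector of per-genotype founder counts.
#' @examples
#' bottleneck(c(0.9, 0.1), 49)  # 44, 5
#' @export
bottleneck <- function(freqs, n_founders) {
  if (abs(sum(freqs) - 1) > 1e-9) stop("'freqs' must sum to 1")
  if (any(freqs < 0)) stop("'freqs' must be nonnegative")
  quota <- freqs * n_founders
  counts <- floor(quota)
  short <- n_founders - sum(counts)
  if (short > 0) {
    pick <- order(-(quota - counts), seq_along(freqs))[seq_len(short)]
    counts[pick] <- counts[pick] + 1
  }
  as.integer(counts)
}

.transfer_series <- function(freqs, threshold, outcome, seed = NA_integer_,
                             mu1 = NA_real_) {
  hit <- which(freqs >= threshold)
  structure(list(freqs = freqs,
                 transfers_to_threshold = if (length(hit)) hit[1] else NA_integer_,
                 threshold = threshold, outcome = outcome,
                 seed = seed, mu1 = mu1),
            class = "transfer_series")
}

#' @export
print.transfer_series <- function(x, ...) {
  cat(sprintf("Serial-transfer invasion: %d transfer(s), outcome '%s'\n",
              length(x$freqs), x$outcome))
  if (!is.na(x$transfers_to_threshold))
    cat(sprintf("  mutant reached frequency %g at transfer %d\n",
                x$threshold, x$transfers_to_threshold))
  invisible(x)
}

#' @export
plot.transfer_series <- function(x, ...) {
  plot(seq_along(x$freqs), x$freqs, type = "b", pch = 16,
       xlab = "transfer", ylab = "mutant frequency",
       ylim = c(0, 1), ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

# derive a per-replicate / per-transfer seed from a base seed (counter
# scheme; keeps results reproducible and independent across transfers)
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 1009) %% 2147483647)
}

#' Spatial serial-transfer invasion of a faster-growing mutant
#'
#' Starts with one mutant founder (genotype 1, the fastest) among
#' `n_founders - 1` ancestors. Each transfer: founders are placed at fresh
#' random positions on a fresh resource field, the batch is run until >99%
#' of the resource is consumed, the mutant's biomass fraction is recorded,
#' and the deterministic [bottleneck()] seeds the next transfer. Stops when
#' the mutant frequency reaches `threshold` (or at extinction, if rounding
#' ever drives the mutant to zero founders).
#'
#' @param params a [full_params()] (or scaled) parameter set with the mutant
#'   rate first.
#' @param domain an [rd_domain()] (torus in the benchmark design).
#' @param n_founders founders per transfer (default 49).
#' @param threshold mutant frequency declaring invasion complete
#'   (default 0.9).
#' @param seed integer seed; each transfer derives its own placement seed.
#' @param ctrl a [step_control()].
#' @param max_transfers guard on the transfer loop.
#' @return A `transfer_series`.
#' @export
run_invasion_spatial <- function(params, domain, n_founders = 49,
                                 threshold = 0.9, seed = 1,
                                 ctrl = step_control(),
                                 max_transfers = 500) {
  ep <- engine_params(params)
  counts <- c(1L, n_founders - 1L)
  freq0 <- counts[1] / n_founders
  if (freq0 >= threshold)
    return(.transfer_series(numeric(0), threshold, "threshold", seed, ep$mu[1]))
  freqs <- numeric(0)
  for (tr in seq_len(max_transfers)) {
    map <- seed_random_founders(n_founders, domain,
                                genotype = rep(1:2, counts),
                                seed = derive_seed(seed, tr))
    st <- init_state(map, params, domain, tracking = "genotype")
    st <- run_until_consumed(st, params, ctrl, domain)
    tot <- total_biomass(st, by = "lineage")
    freq <- tot[1] / sum(tot)
    freqs <- c(freqs, freq)
    if (freq >= threshold)
      return(.transfer_series(freqs, threshold, "threshold", seed, ep$mu[1]))
    counts <- bottleneck(c(freq, 1 - freq), n_founders)
    if (counts[1] == 0L)
      return(.transfer_series(freqs, threshold, "extinction", seed, ep$mu[1]))
  }
  .transfer_series(freqs, threshold, "max_transfers", seed, ep$mu[1])
}

#' Well-mixed serial-transfer invasion
#'
#' The mass-action control: each transfer integrates the spaceless batch
#' ODEs to 99% consumption, records the mutant fraction, and bottlenecks
#' back to `n_founders` cells. Fully deterministic. Because the per-transfer
#' growth factor depends only on totals and the growth-rate *ratio*, the
#' number of transfers to threshold is identical for any `mu1` at a fixed
#' ratio and resource total.
#'
#' @param params parameter set (mutant first).
#' @param n_boxes number of lattice boxes of the matched spatial run; the
#'   resource total is `R0 * n_boxes`.
#' @param n_founders founders per transfer.
#' @param threshold mutant frequency declaring invasion complete.
#' @param consumed_frac_stop per-transfer consumption stop.
#' @param max_transfers guard on the transfer loop.
#' @return A `transfer_series`.
#' @export
run_invasion_well_mixed <- function(params, n_boxes, n_founders = 49,
                                    threshold = 0.9,
                                    consumed_frac_stop = 0.99,
                                    max_transfers = 500) {
  ep <- engine_params(params)
  R_total <- ep$R0 * n_boxes
  counts <- c(1L, n_founders - 1L)
  if (counts[1] / n_founders >= threshold)
    return(.transfer_series(numeric(0), threshold, "threshold", NA, ep$mu[1]))
  freqs <- numeric(0)
  for (tr in seq_len(max_transfers)) {
    wm <- run_well_mixed(counts, R_total, ep$mu[1:2], ep$k, ep$lam,
                         consumed_frac_stop)
    freq <- wm$B[1] / sum(wm$B)
    freqs <- c(freqs, freq)
    if (freq >= threshold)
      return(.transfer_series(freqs, threshold, "threshold", NA, ep$mu[1]))
    counts <- bottleneck(c(freq, 1 - freq), n_founders)
    if (counts[1] == 0L)
      return(.transfer_series(freqs, threshold, "extinction", NA, ep$mu[1]))
  }
  .transfer_series(freqs, threshold, "max_transfers", NA, ep$mu[1])
}

#' Chemostat parameters
#'
#' @param dilution_rate dilution rate delta (1/h): the rate at which cells
#'   and resource are washed out and resource is replenished from the
#'   reservoir.
#' @param reservoir_R reservoir resource concentration per box
#'   (default 100).
#' @return An object of class `chemostat_params`.
#' @export
chemostat_params <- function(dilution_rate, reservoir_R = 100) {
  if (dilution_rate <= 0) stop("'dilution_rate' must be positive")
  if (reservoir_R <= 0) stop("'reservoir_R' must be positive")
  structure(list(dilution_rate = dilution_rate, reservoir_R = reservoir_R),
            class = "chemostat_params")
}

#' Continuous-culture (chemostat) invasion
#'
#' No transfers: every box is continuously replenished from a reservoir
#' (`dR/dt += delta (reservoir_R - R)`) while cells and resource are diluted
#' (`dB/dt -= delta B`). The run ends when the mutant biomass fraction
#' reaches `threshold`, when the total biomass falls below one founder unit
#' (washout: all growth rates below the dilution rate), or at `max_hours`.
#'
#' @param params parameter set (mutant first).
#' @param chemo a [chemostat_params()].
#' @param domain an [rd_domain()] (torus by default in the benchmark).
#' @param n_founders founders seeded at random positions at t = 0.
#' @param threshold mutant frequency stop.
#' @param seed placement seed.
#' @param ctrl a [step_control()].
#' @param max_hours guard on simulated time.
#' @return List with `outcome` (`"threshold"`, `"washout"`, or
#'   `"max_hours"`), `time` (h, or `NA` on washout), `mutant_freq`.
#' @export
run_chemostat <- function(params, chemo, domain, n_founders = 49,
                          threshold = 0.9, seed = 1,
                          ctrl = step_control(), max_hours = 1e5) {
  stopifnot(inherits(chemo, "chemostat_params"))
  ep <- engine_params(params)
  map <- seed_random_founders(n_founders, domain,
                              genotype = c(1L, rep(2L, n_founders - 1L)),
                              seed = seed)
  st <- init_state(map, params, domain, tracking = "genotype")
  dt <- .resolve_dt(ctrl, params, domain)
  st <- .kernel_run(st, params, ctrl, domain, stop_mode = 1L,
                    max_steps = ceiling(max_hours / dt),
                    chemo_delta = chemo$dilution_rate,
                    chemo_reservoir = chemo$reservoir_R,
                    is_mutant = c(TRUE, FALSE),
                    freq_threshold = threshold, washout_total = 1)
  tot <- total_biomass(st, by = "lineage")
  stop <- attr(st, "stop")
  outcome <- switch(stop, threshold = "threshold", washout = "washout",
                    "max_hours")
  list(outcome = outcome,
       time = if (outcome == "threshold") st$t else NA_real_,
       mutant_freq = if (sum(tot) > 0) tot[1] / sum(tot) else 0,
       state = st)
}
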