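#' Experiment configuration
#'
#' Builds a validated configuration list for one of the packaged experiment
#' drivers. Two presets are provided: `"paper"` mirrors the benchmark design
#' (101 x 101 or 105 x 105 lattices, full sweeps, 20 replicates) and
#' `"desk"` is a reduced single-CPU design (51 x 51 or 45 x 45 lattices,
#' 3-point sweeps) that preserves every qualitative contrast. Unknown keys
#' are rejected.
#'
#' @param experiment one of `"invasion"`, `"localization"`, `"selection"`,
#'   `"chemostat"`.
#' @param preset `"desk"` (default) or `"paper"`.
#' @param ... overrides for individual keys (must already exist in the
#'   preset).
#' @return A named list with class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("invasion", "localization",
                                             "selection", "chemostat"),
                              preset = c("desk", "paper"), ...) {
  experiment <- match.arg(experiment)
  preset <- match.arg(preset)
  base <- list(experiment = experiment, preset = preset, seed = 1L,
               out_dir = NULL)
  cfg <- switch(experiment,
    invasion = c(base, list(
      environments = c("spatial", "well_mixed"),
      mu1_values = if (preset == "paper") c(0.01, 0.05, 0.1, 0.2, 0.4)
                   else c(0.05, 0.15, 0.4),
      replicates = if (preset == "paper") 20L else 10L,
      nx = if (preset == "paper") 101L else 51L,
      side_cm = 5, n_founders = 49L, threshold = 0.9, benefit = 1.1,
      D_B = 1.8e-5, D_R = 1.8e-2, k = 1, lam = 1, R0 = 100,
      units = "cm2_per_h")),
    localization = c(base, list(
      founder_counts = if (preset == "paper") c(15L, 49L) else 15L,
      n_maps = if (preset == "paper") 10L else 3L,
      length_scales = if (preset == "paper")
        exp(seq(log(0.03), log(3), length.out = 11))
      else c(0.05, 0.4, 3.2),
      nx = if (preset == "paper") 101L else 51L,
      D_c = 0.001, R0_hat = 100)),
    selection = c(base, list(
      length_scales = if (preset == "paper")
        exp(seq(log(0.02), log(1.3), length.out = 11))
      else c(0.05, 0.2, 0.8),
      nx = if (preset == "paper") 105L else 45L,
      n_founders = if (preset == "paper") 49L else 9L,
      benefit = 1.1, D_c = 0.001, R0_hat = 100)),
    chemostat = c(base, list(
      mu1_values = if (preset == "paper") c(0.05, 0.15, 0.25, 0.4)
                   else c(0.05, 0.15, 0.4),
      replicates = if (preset == "paper") 20L else 3L,
      dilution_rate = 0.1, reservoir_R = 100,
      nx = if (preset == "paper") 105L else 51L,
      side_cm = 5, n_founders = 49L, threshold = 0.9, benefit = 1.1,
      D_B = 1.8e-5, D_R = 1.8e-2, k = 1, lam = 1, R0 = 100,
      units = "cm2_per_h")))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "experiment_config"
  cfg
}

#' Read or write an experiment configuration (YAML)
#'
#' @param config an [experiment_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   validated [experiment_config()] (unknown keys rejected).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$out_dir <- if (is.null(x$out_dir)) "" else x$out_dir
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$experiment)) stop("config lacks an 'experiment' key")
  if (!is.null(x$out_dir) && identical(x$out_dir, "")) x$out_dir <- NULL
  args <- x[setdiff(names(x), c("experiment", "preset"))]
  do.call(experiment_config,
          c(list(experiment = x$experiment, preset = x$preset), args))
}

.invasion_params <- function(cfg, mu_ancestor) {
  full_params(D_B = cfg$D_B, D_R = cfg$D_R,
              mu = c(cfg$benefit * mu_ancestor, mu_ancestor),
              k = cfg$k, lam = cfg$lam, R0 = cfg$R0, units = cfg$units)
}

.write_output <- function(df, cfg, filename) {
  if (!is.null(cfg$out_dir)) {
    if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
    write.csv(df, file.path(cfg$out_dir, filename), row.names = FALSE)
  }
  df
}

#' Serial-transfer invasion experiment
#'
#' Sweeps the ancestor growth rate over `mu1_values` (the mutant always
#' grows `benefit` times faster), running the spatial protocol for
#' `replicates` seeds and the deterministic well-mixed control once per
#' rate. Writes `invasion.csv` when `out_dir` is set.
#'
#' @param config an [experiment_config()] for `"invasion"`.
#' @return Data frame with columns `replicate`, `mu1` (ancestor maximum
#'   growth rate, 1/h), `environment`, `transfer`, `mutant_freq`,
#'   `transfers_to_threshold`, `rng_seed`.
#' @export
run_invasion_experiment <- function(config = experiment_config("invasion")) {
  cfg <- config
  dom <- rd_domain(cfg$nx, cfg$nx, dx = cfg$side_cm / cfg$nx,
                   boundary = "torus")
  rows <- list()
  for (mu_a in cfg$mu1_values) {
    params <- .invasion_params(cfg, mu_a)
    if ("well_mixed" %in% cfg$environments) {
      ts <- run_invasion_well_mixed(params, n_boxes = cfg$nx^2,
                                    n_founders = cfg$n_founders,
                                    threshold = cfg$threshold)
      rows[[length(rows) + 1L]] <-
        data.frame(replicate = 1L, mu1 = mu_a, environment = "well_mixed",
                   transfer = seq_along(ts$freqs), mutant_freq = ts$freqs,
                   transfers_to_threshold = ts$transfers_to_threshold,
                   rng_seed = NA_integer_)
    }
    if ("spatial" %in% cfg$environments) {
      for (rep in seq_len(cfg$replicates)) {
        rs <- derive_seed(cfg$seed, 100000L * match(mu_a, cfg$mu1_values) + rep)
        ts <- run_invasion_spatial(params, dom, n_founders = cfg$n_founders,
                                   threshold = cfg$threshold, seed = rs)
        rows[[length(rows) + 1L]] <-
          data.frame(replicate = rep, mu1 = mu_a, environment = "spatial",
                     transfer = seq_along(ts$freqs), mutant_freq = ts$freqs,
                     transfers_to_threshold = ts$transfers_to_threshold,
                     rng_seed = rs)
      }
    }
  }
  df <- do.call(rbind, rows)
  .write_output(df, cfg, "invasion.csv")
}

#' Localization and drift experiment
#'
#' One pass of [localization_sweep()] feeds both statistics (the drift
#' analysis reuses the neutral localization runs). Writes
#' `localization.csv` and `drift.csv` when `out_dir` is set.
#'
#' @param config an [experiment_config()] for `"localization"`.
#' @return List with `localization` (per-run table), `drift`
#'   (per-length-scale [drift_statistic()] table), and the full `sweep`.
#' @export
run_localization_experiment <- function(config = experiment_config("localization")) {
  cfg <- config
  sweep <- localization_sweep(founder_counts = cfg$founder_counts,
                              n_maps = cfg$n_maps,
                              length_scales = cfg$length_scales,
                              nx = cfg$nx, D_c = cfg$D_c,
                              R0_hat = cfg$R0_hat, seed = cfg$seed)
  drift <- drift_statistic(sweep)
  .write_output(sweep$table, cfg, "localization.csv")
  .write_output(as.data.frame(drift), cfg, "drift.csv")
  list(localization = sweep$table, drift = drift, sweep = sweep)
}

#' Drift-free grid selection experiment
#'
#' Deterministic: no RNG is consumed; identical reruns give identical
#' output. Writes `selection.csv` when `out_dir` is set.
#'
#' @param config an [experiment_config()] for `"selection"`.
#' @return The [selection_assay()] data frame.
#' @export
run_selection_experiment <- function(config = experiment_config("selection")) {
  cfg <- config
  out <- selection_assay(length_scales = cfg$length_scales, nx = cfg$nx,
                         n_founders = cfg$n_founders, benefit = cfg$benefit,
                         D_c = cfg$D_c, R0_hat = cfg$R0_hat)
  .write_output(as.data.frame(out), cfg, "selection.csv")
  out
}

#' Chemostat experiment
#'
#' Continuous-culture invasion across ancestor growth rates, at a fixed
#' dilution rate. Rates below the dilution rate wash out. Writes
#' `chemostat.csv` when `out_dir` is set.
#'
#' @param config an [experiment_config()] for `"chemostat"`.
#' @return Data frame with columns `replicate`, `mu1`, `outcome`,
#'   `hours_to_threshold`, `rng_seed`.
#' @export
run_chemostat_experiment <- function(config = experiment_config("chemostat")) {
  cfg <- config
  dom <- rd_domain(cfg$nx, cfg$nx, dx = cfg$side_cm / cfg$nx,
                   boundary = "torus")
  chemo <- chemostat_params(cfg$dilution_rate, cfg$reservoir_R)
  rows <- list()
  for (mu_a in cfg$mu1_values) {
    params <- .invasion_params(cfg, mu_a)
    for (rep in seq_len(cfg$replicates)) {
      rs <- derive_seed(cfg$seed, 200000L * match(mu_a, cfg$mu1_values) + rep)
      res <- run_chemostat(params, chemo, dom, n_founders = cfg$n_founders,
                           threshold = cfg$threshold, seed = rs)
      rows[[length(rows) + 1L]] <-
        data.frame(replicate = rep, mu1 = mu_a, outcome = res$outcome,
                   hours_to_threshold = res$time, rng_seed = rs)
    }
  }
  df <- do.call(rbind, rows)
  .write_output(df, cfg, "chemostat.csv")
  df
}

#' Robustness variants of the invasion experiment
#'
#' Re-runs the invasion design across alternative settings: lower mutant
#' benefit, higher half-saturation constant, different founder numbers, and
#' higher resource concentrations. Each variant changes one knob relative to
#' the base configuration.
#'
#' @param config base invasion [experiment_config()].
#' @param benefits mutant benefits to test (default `c(1.1, 1.05)`).
#' @param k_values half-saturation constants (default `c(1, 50)`).
#' @param founder_numbers founder counts (default `c(25, 49, 98)`).
#' @param R0_values resources per box (default `c(100, 1e4, 1e6)`).
#' @return Data frame: one row per (variant, value, mu1, replicate) with the
#'   transfers to threshold.
#' @export
run_robustness_experiment <- function(config = experiment_config("invasion"),
                                      benefits = c(1.1, 1.05),
                                      k_values = c(1, 50),
                                      founder_numbers = c(25L, 49L, 98L),
                                      R0_values = c(100, 1e4, 1e6)) {
  cfg <- config
  variants <- rbind(
    data.frame(variant = "benefit", value = benefits),
    data.frame(variant = "k", value = k_values),
    data.frame(variant = "n_founders", value = founder_numbers),
    data.frame(variant = "R0", value = R0_values))
  rows <- list()
  for (v in seq_len(nrow(variants))) {
    vcfg <- cfg
    vcfg[[variants$variant[v]]] <- variants$value[v]
    dom <- rd_domain(vcfg$nx, vcfg$nx, dx = vcfg$side_cm / vcfg$nx,
                     boundary = "torus")
    for (mu_a in vcfg$mu1_values) {
      params <- .invasion_params(vcfg, mu_a)
      for (rep in seq_len(vcfg$replicates)) {
        rs <- derive_seed(vcfg$seed, 300000L * v + 1000L * match(mu_a, vcfg$mu1_values) + rep)
        ts <- run_invasion_spatial(params, dom, n_founders = vcfg$n_founders,
                                   threshold = vcfg$threshold, seed = rs)
        rows[[length(rows) + 1L]] <-
          data.frame(variant = variants$variant[v], value = variants$value[v],
                     replicate = rep, mu1 = mu_a, outcome = ts$outcome,
                     transfers_to_threshold = ts$transfers_to_threshold,
                     rng_seed = rs)
      }
    }
  }
  df <- do.call(rbind, rows)
  .write_output(df, cfg, "robustness.csv")
  df
}

# 31-bit polynomial rolling hash of a string, for config fingerprints
.confighash <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a run manifest
#'
#' Plain-JSON record of a driver run: configuration fingerprint, package
#' version, seed, and stop bookkeeping, so every output row is traceable.
#'
#' @param config the [experiment_config()] used.
#' @param path output path (e.g. `manifest.json`).
#' @param extra optional named list of additional fields (per-run seeds,
#'   step counts, stop conditions).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, extra = list()) {
  cfgyaml <- yaml::as.yaml(unclass(config))
  manifest <- c(list(
    experiment = config$experiment,
    preset = config$preset,
    seed = config$seed,
    config_hash = .confighash(cfgyaml),
    package_version = as.character(utils::packageVersion("zetasim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Deterministic small fixtures for tests and examples
#'
#' @param kind `"map"` (random 9-founder map on 21 x 21), `"state"`
#'   (a 9 x 9 two-genotype state stepped 10 times), or `"csv"` (a tiny
#'   well-mixed invasion series).
#' @param dir output directory.
#' @param seed integer seed.
#' @return Character vector of files written.
#' @export
make_fixture <- function(kind = c("map", "state", "csv"), dir, seed = 1) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (kind == "map") {
    dom <- rd_domain(21, 21, dx = 1, boundary = "no_flux")
    map <- seed_random_founders(9, dom, genotype = 1L, seed = seed)
    f <- file.path(dir, "fixture_map.txt")
    write_founder_map(map, f)
    return(f)
  }
  if (kind == "state") {
    dom <- rd_domain(9, 9, dx = 1, boundary = "torus")
    params <- list(D_B = 0.001, D_R = 1, mu = c(1, 1 / 1.1), k = 1, lam = 1,
                   R0 = 10)
    map <- founder_map(i = c(2L, 6L), j = c(2L, 6L), genotype = c(1L, 2L),
                       domain = dom)
    st <- init_state(map, params, dom)
    st <- run_steps(st, params, 10, domain = dom)
    return(write_state(st, dir, prefix = "fixture_state"))
  }
  params <- full_params(1.8e-5, 1.8e-2, c(0.11, 0.1), 1, 1, 100)
  ts <- run_invasion_well_mixed(params, n_boxes = 25, n_founders = 9,
                                threshold = 0.9)
  f <- file.path(dir, "fixture_invasion.csv")
  write.csv(data.frame(transfer = seq_along(ts$freqs),
                       mutant_freq = ts$freqs), f, row.names = FALSE)
  f
}
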