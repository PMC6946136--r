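test_that("bottleneck apportionment respects quotas deterministically", {
  expect_identical(bottleneck(c(0.9, 0.1), 49), c(44L, 5L))
  expect_identical(bottleneck(c(1 / 49, 48 / 49), 49), c(1L, 48L))
  # ties go to the faster (lower-index) genotype
  expect_identical(bottleneck(c(0.5, 0.5), 49), c(25L, 24L))
  expect_error(bottleneck(c(0.8, 0.1), 49), "sum to 1")

  set.seed(31)
  for (rep in 1:50) {
    n_g <- sample(2:6, 1)
    f <- runif(n_g); f <- f / sum(f)
    n <- sample(c(25, 49, 98), 1)
    cnt <- bottleneck(f, n)
    expect_identical(sum(cnt), as.integer(n))
    expect_true(all(abs(cnt - f * n) < 1))          # quota property
    expect_identical(cnt, oracle_apportion(f, n))
  }
})

test_that("well-mixed invasion matches the closed-form recursion oracle", {
  n_boxes <- 101^2
  oracle <- oracle_well_mixed_transfers(1.1, 49, 100 * n_boxes)
  for (mu_a in c(0.01, 0.1, 0.4)) {
    ts <- run_invasion_well_mixed(bench_params(mu_a), n_boxes = n_boxes)
    expect_identical(ts$transfers_to_threshold, oracle$transfers)
    expect_equal(ts$freqs, oracle$freqs, tolerance = 1e-6)
  }
  # degenerate threshold: already above it at transfer zero
  ts0 <- run_invasion_well_mixed(bench_params(0.1), n_boxes = 25,
                                 n_founders = 49, threshold = 1 / 49)
  expect_equal(length(ts0$freqs), 0)
  expect_identical(ts0$outcome, "threshold")
})

test_that("spatial invasion is neutral under equal growth rates", {
  dom <- rd_domain(16, 16, dx = 0.1, boundary = "torus")
  params <- list(D_B = 1e-3 * 0.018, D_R = 0.018, mu = c(0.2, 0.2),
                 k = 1, lam = 1, R0 = 20)
  map <- founder_map(i = c(3L, 11L), j = c(3L, 11L), genotype = c(1L, 2L),
                     domain = dom)
  fin <- run_until_consumed(init_state(map, params, dom), params,
                            step_control(), dom)
  tot <- total_biomass(fin)
  expect_equal(tot[1] / sum(tot), 0.5, tolerance = 1e-10)
})

test_that("mutant frequency rises across transfers in expectation", {
  dom <- rd_domain(21, 21, dx = 0.1, boundary = "torus")
  params <- full_params(1.8e-5, 1.8e-2, c(0.33, 0.30), 1, 1, 400)
  n_tr <- 4
  freq_mat <- vapply(1:20, function(rep) {
    ts <- run_invasion_spatial(params, dom, n_founders = 16, threshold = 0.9,
                               seed = 100 + rep, max_transfers = n_tr)
    out <- ts$freqs
    length(out) <- n_tr
    out[is.na(out)] <- 1          # reached threshold early: saturated
    out
  }, numeric(n_tr))
  means <- rowMeans(freq_mat)
  expect_true(all(diff(means) > 0))
})

test_that("invasion runs are reproducible and guard their loops", {
  dom <- rd_domain(16, 16, dx = 0.1, boundary = "torus")
  params <- full_params(1.8e-5, 1.8e-2, c(0.22, 0.20), 1, 1, 20)
  a <- run_invasion_spatial(params, dom, n_founders = 4, seed = 5,
                            max_transfers = 3)
  b <- run_invasion_spatial(params, dom, n_founders = 4, seed = 5,
                            max_transfers = 3)
  expect_identical(a$freqs, b$freqs)
  expect_identical(a$outcome, "max_transfers")
})

test_that("lineage and genotype tracking agree when lineages are summed", {
  dom <- rd_domain(15, 15, dx = 0.4, boundary = "torus")
  params <- list(D_B = 0.001, D_R = 1, mu = c(1, 1 / 1.1), k = 1, lam = 1,
                 R0 = 30)
  map <- seed_random_founders(6, dom, genotype = c(1L, 2L, 2L, 1L, 2L, 2L),
                              seed = 13)
  by_gen <- run_steps(init_state(map, params, dom, tracking = "genotype"),
                      params, 300, domain = dom)
  by_lin <- run_steps(init_state(map, params, dom, tracking = "lineage"),
                      params, 300, domain = dom)
  summed <- vapply(1:2, function(g)
    apply(by_lin$B[, , by_lin$lineage_genotype == g, drop = FALSE], c(1, 2), sum),
    matrix(0, 15, 15))
  expect_equal(by_gen$B[, , 1], summed[, , 1], tolerance = 1e-12)
  expect_equal(by_gen$B[, , 2], summed[, , 2], tolerance = 1e-12)
  expect_equal(by_gen$R_field, by_lin$R_field, tolerance = 1e-12)
})

test_that("chemostat reaches its analytic steady state and washes out", {
  chemo <- chemostat_params(dilution_rate = 0.1, reservoir_R = 100)

  # growth balances dilution at R* = k*delta/(mu - delta) = 1; a tiny
  # fast-equilibrating lattice approximates the well-mixed limit
  dom_wm <- rd_domain(5, 5, dx = 0.02, boundary = "torus")
  params <- list(D_B = 1.8e-5, D_R = 0.018, mu = c(0.2, 0.2), k = 1,
                 lam = 1, R0 = 100)
  res <- run_chemostat(params, chemo, dom_wm, n_founders = 9, threshold = 1.1,
                       seed = 2, max_hours = 400)
  expect_identical(res$outcome, "max_hours")
  expect_equal(mean(res$state$R_field), 1, tolerance = 0.05)

  # all growth rates below the dilution rate: washout
  dom <- rd_domain(9, 9, dx = 0.1, boundary = "torus")
  params_slow <- list(D_B = 1.8e-5, D_R = 0.018, mu = c(0.055, 0.05),
                      k = 1, lam = 1, R0 = 100)
  res2 <- run_chemostat(params_slow, chemo, dom, n_founders = 9,
                        threshold = 0.9, seed = 2, max_hours = 5000)
  expect_identical(res2$outcome, "washout")
  expect_true(is.na(res2$time))

  # a faster mutant above the dilution rate eventually takes over
  params_mut <- list(D_B = 1.8e-5, D_R = 0.018, mu = c(0.22, 0.2), k = 1,
                     lam = 1, R0 = 100)
  res3 <- run_chemostat(params_mut, chemo, dom, n_founders = 9,
                        threshold = 0.3, seed = 2, max_hours = 2e4)
  expect_identical(res3$outcome, "threshold")
  expect_gt(res3$mutant_freq, 0.3 - 1e-9)
})

test_that("vanishing dilution reduces the chemostat to batch dynamics", {
  dom <- rd_domain(11, 11, dx = 0.1, boundary = "torus")
  params <- list(D_B = 1.8e-5, D_R = 0.018, mu = c(0.22, 0.2), k = 1,
                 lam = 1, R0 = 10)
  chemo <- chemostat_params(dilution_rate = 1e-12, reservoir_R = 100)
  horizon <- 20
  dt <- default_dt(params, dom)
  res <- run_chemostat(params, chemo, dom, n_founders = 5, threshold = 2,
                       seed = 8, max_hours = horizon)
  map <- seed_random_founders(5, dom, genotype = c(1L, rep(2L, 4L)), seed = 8)
  batch <- run_steps(init_state(map, params, dom, tracking = "genotype"),
                     params, ceiling(horizon / dt), domain = dom)
  expect_equal(res$state$B, batch$B, tolerance = 1e-6)
  expect_equal(res$state$R_field, batch$R_field, tolerance = 1e-6)
})
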