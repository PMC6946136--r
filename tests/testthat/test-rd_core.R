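test_that("diffusion implements the conservative 5-point stencil", {
  dom <- rd_domain(7, 7, dx = 1, boundary = "torus")
  u <- matrix(3.5, 7, 7)
  expect_equal(diffuse_step(u, D = 1, dt = 0.1, dom), u)  # zero Laplacian

  # single box of mass m: center keeps m(1 - 4 a), each neighbor gets m a
  f <- matrix(0, 7, 7); f[4, 4] <- 2
  out <- diffuse_step(f, D = 0.5, dt = 0.1, dom)
  a <- 0.5 * 0.1 / 1
  expect_equal(out[4, 4], 2 * (1 - 4 * a))
  expect_equal(out[3, 4], 2 * a); expect_equal(out[5, 4], 2 * a)
  expect_equal(out[4, 3], 2 * a); expect_equal(out[4, 5], 2 * a)
  expect_equal(sum(out), 2)

  # stability bound enforced, never silently sub-stepped
  expect_error(diffuse_step(f, D = 1, dt = 0.11, dom), "stability")
})

test_that("diffusion conserves mass on both boundary types", {
  set.seed(23)
  for (bnd in c("torus", "no_flux")) {
    dom <- rd_domain(15, 12, dx = 0.3, boundary = bnd)
    f <- matrix(runif(15 * 12), 15, 12)
    m0 <- sum(f)
    for (s in 1:200) f <- diffuse_step(f, D = 0.4, dt = 0.1 * 0.09 / 0.4, dom)
    expect_lt(abs(sum(f) - m0) / m0, 1e-12)
    expect_true(all(f >= 0))
  }
})

test_that("a point release matches the analytic heat kernel", {
  dom <- rd_domain(61, 61, dx = 1, boundary = "torus")
  f <- matrix(0, 61, 61); f[31, 31] <- 1
  for (s in 1:150) f <- diffuse_step(f, D = 1, dt = 0.1, dom)
  tt <- 15
  xs <- (1:61) - 31
  K <- outer(xs, xs, function(a, b) exp(-(a^2 + b^2) / (4 * tt)) / (4 * pi * tt))
  expect_lt(sqrt(sum((f - K)^2) / sum(K^2)), 0.02)
})

test_that("growth integrates Monod kinetics with exact resource bookkeeping", {
  # no growth without resource
  g0 <- growth_step(B = c(1, 2), R = 0, mu = c(0.11, 0.1), k = 1, lam = 1,
                    dt = 0.5)
  expect_equal(g0$B, c(1, 2)); expect_equal(g0$R, 0)

  # dB/dt -> mu * B * R/(R+k) as dt -> 0
  g1 <- growth_step(B = 1, R = 100, mu = 0.1, k = 1, lam = 1, dt = 1e-6)
  expect_equal((g1$B - 1) / 1e-6, 0.1 * 100 / 101, tolerance = 1e-6)

  # conservation with lam = 1 over a large step
  g2 <- growth_step(B = c(5, 3), R = 50, mu = c(0.3, 0.2), k = 1, lam = 1,
                    dt = 2)
  expect_lt(abs((sum(g2$B) + g2$R) - (8 + 50)) / 58, 1e-10)

  # overshoot is clipped at zero resource, still conservative
  g3 <- growth_step(B = 1000, R = 1, mu = 1, k = 0.01, lam = 1, dt = 1)
  expect_equal(g3$R, 0)
  expect_equal(sum(g3$B) - 1000, 1, tolerance = 1e-12)

  expect_error(growth_step(B = -1, R = 1, mu = 0.1, k = 1, lam = 1, dt = 1),
               "negative")
})

test_that("one step equals growth-then-diffusion composed by hand", {
  dom <- rd_domain(3, 3, dx = 0.2, boundary = "torus")
  params <- list(D_B = 0.01, D_R = 0.1, mu = c(0.6, 0.5), k = 1, lam = 2,
                 R0 = 10)
  map <- founder_map(i = c(0L, 2L), j = c(1L, 2L), genotype = c(1L, 2L),
                     domain = dom)
  st <- init_state(map, params, dom)
  st$R_field <- matrix(seq(1, 9), 3, 3)   # non-uniform resource
  dt <- default_dt(params, dom)

  out <- step(st, params, step_control(), dom)

  Bm <- st$B; dim(Bm) <- c(9, 2)
  man <- growth_step(Bm, as.vector(st$R_field), c(0.6, 0.5), 1, 2, dt)
  B1 <- matrix(man$B[, 1], 3, 3); B2 <- matrix(man$B[, 2], 3, 3)
  expect_equal(out$B[, , 1], diffuse_step(B1, 0.01, dt, dom), tolerance = 1e-14)
  expect_equal(out$B[, , 2], diffuse_step(B2, 0.01, dt, dom), tolerance = 1e-14)
  expect_equal(out$R_field, diffuse_step(matrix(man$R, 3, 3), 0.1, dt, dom),
               tolerance = 1e-14)
  expect_equal(out$t, dt)

  # the compiled kernel performs the identical update
  cmp <- run_steps(st, params, 1, domain = dom)
  expect_equal(cmp$B, out$B, tolerance = 1e-12)
  expect_equal(cmp$R_field, out$R_field, tolerance = 1e-12)

  # exhausted resource and uniform biomass: only t advances
  st0 <- st; st0$R_field[] <- 0; st0$B[] <- 2.5
  out0 <- step(st0, params, step_control(), dom)
  expect_equal(out0$B, st0$B)
  expect_equal(out0$R_field, st0$R_field)

  # batch monotonicity
  expect_gte(sum(out$B), sum(st$B))
  expect_lte(sum(out$R_field), sum(st$R_field))
})

test_that("run_until_consumed stops at the consumption threshold and conserves", {
  dom <- rd_domain(15, 15, dx = 0.5, boundary = "torus")
  params <- list(D_B = 0.001, D_R = 1, mu = 1, k = 1, lam = 1, R0 = 20)
  map <- founder_map(i = 7L, j = 7L, genotype = 1L, domain = dom)
  st <- init_state(map, params, dom)
  R0 <- total_resource(st)
  fin <- run_until_consumed(st, params, step_control(), dom)
  expect_lte(total_resource(fin), 0.01 * R0)
  # lam = 1: biomass gain accounts for all consumed resource
  expect_gte(sum(fin$B), sum(st$B) + 0.99 * R0 - 1e-8 * R0)
  expect_lt(abs((sum(fin$B) - sum(st$B)) - (R0 - total_resource(fin))) / R0,
            1e-8)
  # single central founder on a torus: final field keeps lattice symmetry
  f <- fin$B[, , 1]
  expect_equal(f, f[15:1, ], tolerance = 1e-9)
  expect_equal(f, t(f), tolerance = 1e-9)

  # compiled and pure-R loops agree
  st_small <- init_state(map, params, rd_domain(15, 15, dx = 0.5), R0 = 2)
  a <- run_until_consumed(st_small, params, step_control(), dom, compiled = TRUE)
  b <- run_until_consumed(st_small, params, step_control(), dom, compiled = FALSE)
  expect_equal(attr(a, "steps"), attr(b, "steps"))
  expect_equal(a$B, b$B, tolerance = 1e-11)

  expect_error(run_until_consumed(init_state(map, params, dom,
                                             founder_biomass = 0),
                                  params, step_control(), dom),
               "all-zero biomass")
})

test_that("full and scaled simulations are the same dynamics", {
  p <- full_params(1.8e-5, 1.8e-2, c(0.11, 0.10), 1, 1, 100)
  dom <- rd_domain(21, 21, dx = 0.05, boundary = "torus")
  map <- founder_map(i = c(3L, 15L, 10L), j = c(4L, 12L, 18L),
                     genotype = c(1L, 2L, 2L), domain = dom)
  st <- init_state(map, p, dom)
  full <- run_steps(st, p, 400, domain = dom)

  sc <- to_scaled(p)
  domS <- rd_domain(21, 21, dx = 0.05 / sc$transform$x_c, boundary = "torus")
  scaledrun <- run_steps(state_to_scaled(st, sc$transform), sc$scaled, 400,
                         domain = domS)
  back <- state_from_scaled(scaledrun, sc$transform)
  expect_lt(max(abs(back$B - full$B)) / max(full$B), 1e-6)
  expect_lt(max(abs(back$R_field - full$R_field)) / max(full$R_field), 1e-6)
  expect_equal(back$t, full$t, tolerance = 1e-9)
})

test_that("halving the box width leaves genotype frequencies within 1%", {
  run_freq <- function(nx, h) {
    dom <- rd_domain(nx, nx, dx = h, boundary = "torus")
    sc <- nx / 21
    map <- founder_map(i = as.integer(c(5, 14) * sc), j = as.integer(c(5, 12) * sc),
                       genotype = c(1L, 2L), domain = dom)
    params <- list(D_B = 0.001, D_R = 1, mu = c(1, 1 / 1.1), k = 1, lam = 1,
                   R0 = 50)
    st <- init_state(map, params, dom)
    fin <- run_until_consumed(st, params, step_control(), dom)
    tot <- total_biomass(fin)
    tot[1] / sum(tot)
  }
  f1 <- run_freq(21, 0.6)
  f2 <- run_freq(42, 0.3)
  expect_lt(abs(f2 - f1), 0.01)
})

test_that("well-mixed growth satisfies the shared-Monod-factor identity", {
  # symmetric genotypes end symmetric
  eq <- run_well_mixed(c(2, 2), 500, c(0.2, 0.2), 1, 1)
  expect_equal(eq$B[1], eq$B[2], tolerance = 1e-9)

  wm <- run_well_mixed(c(1, 48), 100 * 2601, c(0.11, 0.10), 1, 1)
  expect_equal(log(wm$B[1] / 1) / log(wm$B[2] / 48), 1.1, tolerance = 1e-6)
  # conservation + stop rule
  expect_equal(sum(wm$B), 49 + 0.99 * 100 * 2601, tolerance = 1e-6)
})

test_that("states round-trip through plain-text snapshots", {
  dom <- rd_domain(5, 5, dx = 0.3, boundary = "no_flux")
  params <- list(D_B = 0.01, D_R = 1, mu = c(1, 0.9), k = 1, lam = 1, R0 = 10)
  map <- founder_map(i = c(1L, 3L), j = c(1L, 3L), genotype = c(1L, 2L),
                     domain = dom)
  st <- run_steps(init_state(map, params, dom), params, 25, domain = dom)
  d <- tempfile(); dir.create(d)
  write_state(st, d)
  back <- read_state(d)
  expect_equal(back$R_field, st$R_field, tolerance = 1e-12)
  expect_equal(back$B, st$B, tolerance = 1e-12)
  expect_equal(back$t, st$t, tolerance = 1e-12)
  expect_identical(back$lineage_genotype, st$lineage_genotype)
})
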