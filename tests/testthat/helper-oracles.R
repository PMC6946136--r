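# Independent oracles, kept deliberately naive (explicit loops, closed
# forms) so they share no code path with the package implementations.

# O(n^2) nearest-neighbor distances with explicit loops
brute_nn_ic <- function(map, domain) {
  d <- domain
  x <- (map$i + 0.5) * d$dx
  y <- (map$j + 0.5) * d$dx
  n <- length(x)
  Lx <- d$nx * d$dx
  Ly <- d$ny * d$dx
  ic <- numeric(n)
  for (a in seq_len(n)) {
    best <- Inf
    for (b in seq_len(n)) {
      if (a == b) next
      ddx <- abs(x[a] - x[b]); ddy <- abs(y[a] - y[b])
      if (d$boundary == "torus") {
        ddx <- min(ddx, Lx - ddx); ddy <- min(ddy, Ly - ddy)
      }
      best <- min(best, sqrt(ddx^2 + ddy^2))
    }
    ic[a] <- best
  }
  ic
}

# nearest-site assignment over all boxes, explicit loops
brute_voronoi_areas <- function(map, domain) {
  d <- domain
  fx <- (map$i + 0.5) * d$dx
  fy <- (map$j + 0.5) * d$dx
  counts <- integer(nrow(map))
  for (jj in seq_len(d$ny)) {
    for (ii in seq_len(d$nx)) {
      bx <- (ii - 0.5) * d$dx; by <- (jj - 0.5) * d$dx
      best <- Inf; who <- 0L
      for (f in seq_len(nrow(map))) {
        d2 <- (bx - fx[f])^2 + (by - fy[f])^2
        if (d2 < best) { best <- d2; who <- f }
      }
      counts[who] <- counts[who] + 1L
    }
  }
  counts * d$dx^2
}

# largest-remainder apportionment, reimplemented here so the protocol's
# rounding rule is checked against an independent copy
oracle_apportion <- function(freqs, n) {
  q <- freqs * n
  cnt <- floor(q)
  rem <- q - cnt
  while (sum(cnt) < n) {
    pick <- which(rem == max(rem))[1]
    cnt[pick] <- cnt[pick] + 1
    rem[pick] <- -1
  }
  as.integer(cnt)
}

# Closed-form per-transfer recursion for the well-mixed serial-transfer
# protocol. Each transfer, the shared Monod factor implies final biomasses
# B_m * x^ratio and B_a * x where x is the ancestor growth factor solving
# B_m x^ratio + B_a x = B_m + B_a + consumed resource (lambda = 1).
oracle_well_mixed_transfers <- function(ratio, n_founders, R_total,
                                        threshold = 0.9,
                                        consumed_frac = 0.99,
                                        max_transfers = 500) {
  cnt <- c(1, n_founders - 1)
  freqs <- numeric(0)
  for (tr in seq_len(max_transfers)) {
    target <- sum(cnt) + consumed_frac * R_total
    f <- function(x) cnt[1] * x^ratio + cnt[2] * x - target
    x <- uniroot(f, c(1, target), tol = 1e-13)$root
    Bm <- cnt[1] * x^ratio
    Ba <- cnt[2] * x
    freqs <- c(freqs, Bm / (Bm + Ba))
    if (freqs[tr] >= threshold)
      return(list(transfers = tr, freqs = freqs))
    cnt <- oracle_apportion(c(freqs[tr], 1 - freqs[tr]), n_founders)
    if (cnt[1] == 0) return(list(transfers = NA_integer_, freqs = freqs))
  }
  list(transfers = NA_integer_, freqs = freqs)
}

# benchmark physical parameter set (small-sugar resource diffusion in agar)
bench_params <- function(mu_ancestor = 0.10, benefit = 1.1) {
  full_params(D_B = 1.8e-5, D_R = 1.8e-2,
              mu = c(benefit * mu_ancestor, mu_ancestor),
              k = 1, lam = 1, R0 = 100)
}
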