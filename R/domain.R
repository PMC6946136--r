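#' Lattice domain
#'
#' Rectangular lattice of `nx` by `ny` boxes of width `dx`, with either
#' toroidal (wrap-around) or no-flux (zero-gradient, reflecting) boundaries.
#' `dx` is in cm for the full model and in natural-length-scale units for
#' the scaled model.
#'
#' @param nx,ny box counts (at least 3).
#' @param dx box width.
#' @param boundary `"torus"` or `"no_flux"`.
#' @return An object of class `rd_domain`.
#' @export
rd_domain <- function(nx, ny = nx, dx = 1, boundary = c("torus", "no_flux")) {
  boundary <- match.arg(boundary)
  if (nx < 3 || ny < 3) stop("'nx' and 'ny' must be at least 3")
  if (dx <= 0) stop("'dx' must be positive")
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
                 boundary = boundary),
            class = "rd_domain")
}

#' @export
print.rd_domain <- function(x, ...) {
  cat(sprintf("%d x %d lattice, dx = %g (%s boundary), area = %g\n",
              x$nx, x$ny, x$dx, x$boundary, domain_area(x)))
  invisible(x)
}

#' Total domain area
#' @param domain an [rd_domain()] object.
#' @return `nx * ny * dx^2`.
#' @export
domain_area <- function(domain) domain$nx * domain$ny * domain$dx^2

#' Founder map
#'
#' Founder cells occupying distinct lattice boxes. Box indices `i`, `j` are
#' 0-based; founder centers sit at `((i + 0.5) dx, (j + 0.5) dx)`. Each
#' founder carries a genotype index into the parameter set's growth-rate
#' vector.
#'
#' @param i,j integer vectors of 0-based box indices.
#' @param genotype integer vector of genotype indices (1-based), recycled.
#' @param domain an [rd_domain()] object the map lives on.
#' @return An object of class `founder_map` (a data.frame with columns
#'   `i`, `j`, `genotype` and the domain as an attribute).
#' @export
founder_map <- function(i, j, genotype = 1L, domain) {
  stopifnot(inherits(domain, "rd_domain"))
  i <- as.integer(i); j <- as.integer(j)
  if (length(i) != length(j)) stop("'i' and 'j' must have equal length")
  if (any(i < 0 | i >= domain$nx | j < 0 | j >= domain$ny))
    stop("founder indices outside the lattice")
  if (anyDuplicated(i + domain$nx * j))
    stop("duplicate founder positions (maximum 1 founder per box)")
  genotype <- as.integer(rep_len(genotype, length(i)))
  out <- data.frame(i = i, j = j, genotype = genotype)
  attr(out, "domain") <- domain
  class(out) <- c("founder_map", "data.frame")
  out
}

#' @export
print.founder_map <- function(x, ...) {
  d <- attr(x, "domain")
  cat(sprintf("Founder map: %d founders (%d genotype(s)) on a %d x %d %s lattice\n",
              nrow(x), length(unique(x$genotype)), d$nx, d$ny, d$boundary))
  invisible(x)
}

#' Founder center coordinates
#' @param map a [founder_map()].
#' @return Two-column matrix of (x, y) box-center coordinates.
#' @export
founder_coords <- function(map) {
  d <- attr(map, "domain")
  cbind(x = (map$i + 0.5) * d$dx, y = (map$j + 0.5) * d$dx)
}

#' Seed founders at random lattice positions
#'
#' Draws `n` distinct boxes uniformly without replacement. Deterministic for
#' a given `seed`.
#'
#' @param n number of founders (at most `nx * ny`).
#' @param domain an [rd_domain()].
#' @param genotype genotype index per founder (recycled).
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @return A [founder_map()].
#' @export
seed_random_founders <- function(n, domain, genotype = 1L, seed = NULL) {
  nb <- domain$nx * domain$ny
  if (n > nb) stop("more founders than lattice boxes")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  cells <- sample.int(nb, n) - 1L
  founder_map(i = cells %% domain$nx, j = cells %/% domain$nx,
              genotype = genotype, domain = domain)
}

#' Seed founders on a regular grid
#'
#' Places a perfect square number of founders at equidistant positions; the
#' pattern is translation-symmetric on a torus (every founder sees the same
#' neighborhood). The founder closest to the domain center is flagged via
#' the `"center"` attribute so a single mutant can be planted there.
#'
#' @param n number of founders; must be a perfect square whose root divides
#'   `nx` and `ny` exactly (e.g. 49 on a 105 x 105 lattice gives spacing 15).
#' @param domain an [rd_domain()].
#' @param genotype genotype per founder (recycled); the center founder can be
#'   relabeled afterwards.
#' @return A [founder_map()] with attribute `"center"` (row index of the
#'   central founder) and `"spacing"` (in boxes).
#' @export
seed_grid_founders <- function(n, domain, genotype = 1L) {
  m <- round(sqrt(n))
  if (m * m != n) stop("'n' must be a perfect square")
  if (domain$nx %% m != 0 || domain$ny %% m != 0)
    stop("sqrt(n) must divide nx and ny for equal grid spacing")
  sx <- domain$nx %/% m
  sy <- domain$ny %/% m
  off_x <- sx %/% 2L
  off_y <- sy %/% 2L
  g <- expand.grid(i = seq_len(m) - 1L, j = seq_len(m) - 1L)
  map <- founder_map(i = g$i * sx + off_x, j = g$j * sy + off_y,
                     genotype = genotype, domain = domain)
  cx <- (domain$nx - 1) / 2
  cy <- (domain$ny - 1) / 2
  attr(map, "center") <- which.min((map$i - cx)^2 + (map$j - cy)^2)
  attr(map, "spacing") <- sx
  map
}

#' Mean nearest-neighbor intercolony distance
#'
#' For each founder, the minimum center-to-center distance to any other
#' founder (`ic`), and their arithmetic mean `ic_bar`. On toroidal domains
#' distances use the minimum-image convention; on square domains plain
#' Euclidean distance.
#'
#' @param map a [founder_map()] with at least 2 founders.
#' @param domain an [rd_domain()]; defaults to the map's own domain.
#' @return An object of class `spatial_summary`: list with `ic` (per-founder
#'   minimum distances), `ic_bar`, and `n`.
#' @export
mean_nn_distance <- function(map, domain = attr(map, "domain")) {
  n <- nrow(map)
  if (n < 2) stop("at least 2 founders are required")
  xy <- founder_coords(map)
  dxm <- abs(outer(xy[, 1], xy[, 1], "-"))
  dym <- abs(outer(xy[, 2], xy[, 2], "-"))
  if (domain$boundary == "torus") {
    Lx <- domain$nx * domain$dx
    Ly <- domain$ny * domain$dx
    dxm <- pmin(dxm, Lx - dxm)
    dym <- pmin(dym, Ly - dym)
  }
  dm <- sqrt(dxm^2 + dym^2)
  diag(dm) <- Inf
  ic <- apply(dm, 1, min)
  structure(list(ic = ic, ic_bar = mean(ic), n = n),
            class = "spatial_summary")
}

#' @export
print.spatial_summary <- function(x, ...) {
  cat(sprintf("Intercolony distances: n = %d, ic_bar = %.6g\n", x$n, x$ic_bar))
  invisible(x)
}

#' Read or write a founder map as plain text
#'
#' Three whitespace-separated columns: `box_i`, `box_j`, `genotype`
#' (0-based box indices, 1-based genotype index), with a `#` header line.
#'
#' @param map a [founder_map()].
#' @param path file path.
#' @param domain an [rd_domain()] to attach when reading.
#' @return `write_founder_map` returns `path` invisibly; `read_founder_map`
#'   returns a [founder_map()].
#' @export
write_founder_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# box_i box_j genotype", con)
  write.table(as.data.frame(map)[c("i", "j", "genotype")], con,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_founder_map
#' @export
read_founder_map <- function(path, domain) {
  tab <- read.table(path, comment.char = "#",
                    col.names = c("i", "j", "genotype"))
  founder_map(tab$i, tab$j, tab$genotype, domain)
}
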