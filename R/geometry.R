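#' Geometry configuration for the granular-layer volume
#'
#' Defines the simulated tissue volume (a periodic cube) and the density and
#' exclusion radius of each cell population. Default densities are calibrated
#' so that a 100 micron cube holds approximately 300 glomeruli (one per mossy
#' fiber), 3700 granule cells and 8 Golgi cells.
#'
#' @param cube_side Side of the cubic volume in microns.
#' @param density Named vector of cell densities (cells per cubic micron) for
#'   `glomerulus`, `grc` and `goc`.
#' @param exclusion_radius Named vector of per-population exclusion radii in
#'   microns: two somata of the same population are never placed closer than
#'   the sum of their radii.
#' @param periodic Logical; the cube boundaries are treated as continuous
#'   (toroidal topology). Only `TRUE` is supported.
#' @return An object of class `grc_geometry`.
#' @export
geometry_config <- function(cube_side = 100,
                            density = c(glomerulus = 3.0e-4,
                                        grc = 3.7e-3,
                                        goc = 8e-6),
                            exclusion_radius = c(glomerulus = 1.5,
                                                 grc = 2.5,
                                                 goc = 8),
                            periodic = TRUE) {
  stopifnot(is.numeric(cube_side), length(cube_side) == 1, cube_side > 0)
  pops <- c("glomerulus", "grc", "goc")
  if (!all(pops %in% names(density)))
    stop("`density` must be named with: ", paste(pops, collapse = ", "))
  if (any(density < 0)) stop("densities must be >= 0")
  if (!all(pops %in% names(exclusion_radius)))
    stop("`exclusion_radius` must be named with: ", paste(pops, collapse = ", "))
  if (any(exclusion_radius < 0)) stop("exclusion radii must be >= 0")
  if (!isTRUE(periodic)) stop("only periodic (toroidal) volumes are supported")
  structure(list(cube_side = cube_side,
                 density = density[pops],
                 exclusion_radius = exclusion_radius[pops],
                 periodic = TRUE),
            class = "grc_geometry")
}

#' @export
print.grc_geometry <- function(x, ...) {
  cat("Granular-layer geometry: periodic cube, side", x$cube_side, "um\n")
  v <- x$cube_side^3
  for (p in names(x$density))
    cat(sprintf("  %-10s density %.3g um^-3 (expected n = %.1f), exclusion %.1f um\n",
                p, x$density[[p]], x$density[[p]] * v, x$exclusion_radius[[p]]))
  invisible(x)
}

#' Toroidal (periodic) Euclidean distance
#'
#' Distance between points in a cube whose opposite faces are identified, so
#' the per-axis displacement is never larger than half the cube side.
#'
#' @param a,b Numeric vectors of length 3, or matrices with 3 columns
#'   (rows are points). If both are matrices they must have the same number
#'   of rows and distances are computed row-wise.
#' @param cube_side Side of the cube in microns.
#' @return Numeric vector of distances.
#' @export
toroidal_distance <- function(a, b, cube_side) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3, byrow = TRUE)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3, byrow = TRUE)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  d <- abs(a - b)
  d <- pmin(d, cube_side - d)
  sqrt(rowSums(d^2))
}

# Full cross-distance matrix (nrow(a) x nrow(b)) on the torus; optionally
# restricted to a subset of axes (for lateral / parallel-fiber wiring rules).
toroidal_cross_distance <- function(a, b, cube_side, axes = 1:3) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (ax in axes) {
    dd <- abs(outer(a[, ax], b[, ax], "-"))
    dd <- pmin(dd, cube_side - dd)
    d2 <- d2 + dd^2
  }
  sqrt(d2)
}

#' Place cell somata inside the periodic cube
#'
#' Sequential random placement with per-population exclusion radii and
#' bounded rejection retries. Counts are Poisson draws around
#' `density * cube_side^3`, so realized censuses vary slightly with the seed,
#' while positions are uniform over the volume subject to the minimum
#' inter-soma distance.
#'
#' @param geometry A [geometry_config()].
#' @param seed Integer seed for counts and positions.
#' @param max_tries Rejection retries allowed per cell before the
#'   configuration is declared unplaceable.
#' @return Named list of position matrices (n x 3, microns, in
#'   `[0, cube_side)`), one per population.
#' @export
place_cells <- function(geometry, seed, max_tries = 5000L) {
  stopifnot(inherits(geometry, "grc_geometry"))
  set.seed(derive_seed(seed, "place"))
  side <- geometry$cube_side
  vol <- side^3
  out <- list()
  for (p in names(geometry$density)) {
    n <- rpois(1, geometry$density[[p]] * vol)
    minsep <- 2 * geometry$exclusion_radius[[p]]
    pos <- matrix(NA_real_, n, 3)
    i <- 1L
    while (i <= n) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- runif(3, 0, side)
        if (i == 1L ||
            min(toroidal_distance(pos[seq_len(i - 1L), , drop = FALSE],
                                  cand, side)) >= minsep) {
          pos[i, ] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("unplaceable configuration for population '", p,
             "': exclusion radius too large for density (cell ", i,
             " of ", n, ")")
      i <- i + 1L
    }
    colnames(pos) <- c("x", "y", "z")
    attr(pos, "cube_side") <- side
    out[[p]] <- pos
  }
  attr(out, "cube_side") <- side
  out
}
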