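#' Configuration of spatially correlated MF pattern generation
#'
#' @param f Target average fraction of active mossy fibers, in `[0, 1]`.
#' @param sigma Correlation radius (um) of the Gaussian distance kernel
#'   `c(d) = exp(-d^2 / (2 sigma^2))` on the latent field.
#' @param n_patterns Number of patterns to draw.
#' @param seed Integer seed.
#' @param ridge Maximal diagonal ridge applied to a numerically
#'   non-positive-definite latent covariance before falling back to
#'   eigenvalue clamping.
#' @return Object of class `grc_pattern_config`.
#' @export
pattern_config <- function(f, sigma, n_patterns, seed = 1L, ridge = 1e-6) {
  stopifnot(f >= 0, f <= 1, sigma >= 0, n_patterns >= 1, ridge >= 0)
  structure(list(f = f, sigma = sigma, n_patterns = as.integer(n_patterns),
                 seed = as.integer(seed), ridge = ridge),
            class = "grc_pattern_config")
}

# square-root factor of the latent covariance: Cholesky when PD, Cholesky of
# the ridged matrix when a ridge <= cap repairs it, otherwise eigenvalue
# clamping with rescaling back to unit marginal variances
latent_factor <- function(C, ridge_cap) {
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (!is.null(R)) return(R)
  R <- tryCatch(chol(C + diag(ridge_cap, nrow(C))), error = function(e) NULL)
  if (!is.null(R)) return(R)
  e <- eigen(C, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  L <- e$vectors %*% diag(sqrt(lam))
  v <- rowSums(L^2)
  L <- L / sqrt(pmax(v, .Machine$double.eps))
  t(L)
}

#' Generate spatially correlated binary MF activity patterns
#'
#' Dichotomized-Gaussian construction: each pattern is an independent draw
#' from a zero-mean, unit-variance multivariate normal whose correlation
#' between fibers i and j is `exp(-d_ij^2 / (2 sigma^2))` (d toroidal),
#' thresholded at the upper-`f` standard-normal quantile so each fiber is
#' active with marginal probability `f`. For `sigma -> 0` the fibers become
#' independent coin flips; for large `sigma` patterns approach all-active /
#' all-silent draws.
#'
#' @param mf_positions Matrix of MF/glomerulus positions (n x 3, um), e.g.
#'   `place_cells(...)$glomerulus`.
#' @param config A [pattern_config()].
#' @param cube_side Cube side (um); defaults to the attribute carried by
#'   [place_cells()] output.
#' @return Object of class `grc_patterns` with `activity`
#'   (n_patterns x n_mf binary matrix), `config` and `labels` (NULL until
#'   [assign_classes()]).
#' @export
generate_patterns <- function(mf_positions, config,
                              cube_side = attr(mf_positions, "cube_side")) {
  stopifnot(inherits(config, "grc_pattern_config"))
  if (is.null(cube_side)) stop("cube_side is required")
  n_mf <- nrow(mf_positions)
  set.seed(derive_seed(config$seed, "pattern"))
  if (config$sigma < 1e-9) {
    act <- matrix(rbinom(config$n_patterns * n_mf, 1, config$f),
                  config$n_patterns, n_mf)
  } else {
    D <- toroidal_cross_distance(mf_positions, mf_positions, cube_side)
    C <- exp(-D^2 / (2 * config$sigma^2))
    R <- latent_factor(C, config$ridge)
    Z <- matrix(rnorm(config$n_patterns * n_mf), config$n_patterns, n_mf)
    X <- Z %*% R
    thr <- qnorm(1 - config$f)
    act <- (X > thr) + 0L
  }
  structure(list(activity = act, config = config, labels = NULL),
            class = "grc_patterns")
}

#' @export
print.grc_patterns <- function(x, ...) {
  cat(sprintf(
    "MF pattern set: %d patterns x %d fibers (f = %.2f, sigma = %g um)\n",
    nrow(x$activity), ncol(x$activity), x$config$f, x$config$sigma))
  cat(sprintf("  realized mean active fraction: %.3f\n", mean(x$activity)))
  if (!is.null(x$labels))
    cat("  classes:", length(unique(x$labels)), "\n")
  invisible(x)
}

#' Activity-preserving pattern noise
#'
#' Resamples the state of exactly `round(noise_frac * n_mf)` distinct,
#' uniformly chosen fibers: each reselected fiber becomes active with
#' probability `f` independently; untouched fibers keep their state. Averaged
#' over presentations this preserves the set-average active fraction.
#'
#' @param pattern Binary vector over MFs.
#' @param noise_frac Fraction of fibers to resample, in `[0, 1]`.
#' @param f Reactivation probability (the set's average active fraction).
#' @param seed Integer seed; within one R session, pass distinct seeds per
#'   presentation.
#' @return Binary vector of the same length.
#' @export
apply_noise <- function(pattern, noise_frac, f, seed) {
  stopifnot(noise_frac >= 0, noise_frac <= 1, all(pattern %in% c(0, 1)))
  if (noise_frac == 0) return(pattern)
  set.seed(derive_seed(seed, "noise"))
  n <- length(pattern)
  k <- round(noise_frac * n)
  if (k == 0) return(pattern)
  idx <- sample.int(n, k)
  pattern[idx] <- rbinom(k, 1, f)
  pattern
}

#' Assign random class labels to a pattern set
#'
#' Labels are drawn uniformly at random (maximal class overlap by design),
#' covering `0 .. n_classes - 1`.
#'
#' @param pattern_set A `grc_patterns` object.
#' @param n_classes Number of classes.
#' @param seed Integer seed.
#' @return The pattern set with `labels` filled in.
#' @export
assign_classes <- function(pattern_set, n_classes = 10L, seed = 1L) {
  stopifnot(inherits(pattern_set, "grc_patterns"))
  n <- nrow(pattern_set$activity)
  if (n_classes > n) stop("more classes (", n_classes,
                          ") than patterns (", n, ")")
  set.seed(derive_seed(seed, "labels"))
  pattern_set$labels <- sample.int(n_classes, n, replace = TRUE) - 1L
  pattern_set
}
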