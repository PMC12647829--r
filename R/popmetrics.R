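# Population coding metrics on spike-count matrices (patterns/presentations
# are rows = observations, neurons are columns = variables), and the small
# statistical helpers used to summarize repeated-seed runs.

#' Population sparseness
#'
#' For a single activity vector x over N neurons:
#' `(N - (sum x)^2 / sum x^2) / (N - 1)`, which is 0 for uniform activity and
#' 1 when a single neuron is active. Averaged over all patterns; all-zero
#' patterns contribute 0 (documented convention for the 0/0 case).
#'
#' @param counts Matrix (patterns x neurons) of non-negative counts.
#' @return Value in `[0, 1]`.
#' @export
population_sparseness <- function(counts) {
  counts <- as.matrix(counts)
  N <- ncol(counts)
  stopifnot(N >= 2, all(counts >= 0))
  s1 <- rowSums(counts)
  s2 <- rowSums(counts^2)
  per <- ifelse(s2 > 0, (N - s1^2 / s2) / (N - 1), 0)
  mean(pmin(pmax(per, 0), 1))
}

#' Total variance (expansion of the coding space)
#'
#' Sum over neurons of the across-pattern variance of the spike count; equal
#' to the trace of the covariance matrix of the activity patterns.
#'
#' @param counts Matrix (patterns x neurons), >= 2 rows.
#' @return Non-negative value (spikes squared).
#' @export
total_variance <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) >= 2)
  sum(apply(counts, 2, var))
}

#' Population correlation
#'
#' `N/(N-1) * (max(sqrt(lambda)) / sum(sqrt(lambda)) - 1/N)` where lambda are
#' the eigenvalues of the across-pattern covariance matrix: 0 when all
#' eigenvalues are equal (independent, equal-variance limit) and 1 when the
#' covariance is rank one (perfect correlation). Tiny negative eigenvalues
#' from finite-sample covariance estimation are clamped to zero
#' (tolerance `1e-10 * max(lambda)`); a covariance with no variance at all
#' returns 0.
#'
#' @param counts Matrix (patterns x neurons), >= 2 rows.
#' @return Value in `[0, 1]`.
#' @export
population_correlation <- function(counts) {
  counts <- as.matrix(counts)
  N <- ncol(counts)
  n <- nrow(counts)
  stopifnot(N >= 2, n >= 2)
  # nonzero covariance eigenvalues via the smaller Gram matrix; the zero
  # eigenvalues of the larger side contribute nothing to max or sum
  if (N <= n) {
    M <- cov(counts)
  } else {
    Xc <- scale(counts, center = TRUE, scale = FALSE)
    M <- tcrossprod(Xc) / (n - 1)
  }
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (max(lam) <= 0) return(0)
  lam[lam < 1e-10 * max(lam)] <- 0
  r <- sqrt(lam)
  val <- N / (N - 1) * (max(r) / sum(r) - 1 / N)
  min(max(val, 0), 1)
}

#' Mean pairwise overlap of active cell sets
#'
#' A cell is active in a pattern when its count is positive. Overlap between
#' two patterns is the Jaccard index |A intersect B| / |A union B| by
#' default, or |A intersect B| / min(|A|, |B|); two empty sets are identical
#' and overlap 1.
#'
#' @param counts Matrix (patterns x neurons) of counts, or a binary matrix.
#' @param method `"jaccard"` or `"min"`.
#' @return Mean over all pattern pairs, in `[0, 1]`.
#' @export
pattern_overlap <- function(counts, method = c("jaccard", "min")) {
  method <- match.arg(method)
  A <- (as.matrix(counts) > 0) + 0
  n <- nrow(A)
  stopifnot(n >= 2)
  inter <- tcrossprod(A)
  sz <- rowSums(A)
  denom <- if (method == "jaccard") outer(sz, sz, "+") - inter
           else outer(sz, sz, pmin)
  ov <- ifelse(denom > 0, inter / denom, 1)
  mean(ov[upper.tri(ov)])
}

#' Correlation matrix between coding metrics and accuracy
#'
#' @param df Data frame of paired observations (columns are metrics and
#'   accuracy across configurations), >= 3 rows.
#' @param method Correlation type (`"pearson"` or `"spearman"`).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
metric_accuracy_correlation <- function(df, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(nrow(df) >= 3)
  cor(as.matrix(df), method = method)
}

#' Mean, SD and 95 percent confidence interval of repeated-seed values
#'
#' @param x Numeric vector (one value per seed).
#' @param level Confidence level.
#' @return One-row data frame with mean, sd, ci_lo, ci_hi, n.
#' @export
summary_stats <- function(x, level = 0.95) {
  n <- length(x)
  m <- mean(x)
  s <- if (n > 1) sd(x) else NA_real_
  half <- if (n > 1) qt(1 - (1 - level) / 2, n - 1) * s / sqrt(n) else NA_real_
  data.frame(mean = m, sd = s, ci_lo = m - half, ci_hi = m + half, n = n)
}

#' Paired t-test with the identical-samples convention
#'
#' Two-sided paired t-test of zero mean difference; identical paired samples
#' (all differences zero) return p = 1 and a mean difference of 0 rather than
#' a degenerate test.
#'
#' @param x,y Paired numeric vectors.
#' @return List with `mean_diff`, `t`, `df`, `p`.
#' @export
paired_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (all(d == 0))
    return(list(mean_diff = 0, t = 0, df = length(d) - 1, p = 1))
  if (sd(d) == 0) # constant nonzero difference: certain shift
    return(list(mean_diff = mean(d), t = sign(mean(d)) * Inf,
                df = length(d) - 1, p = 0))
  tt <- t.test(x, y, paired = TRUE)
  list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}
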