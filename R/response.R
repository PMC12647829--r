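# Rate-based response measures: a dF/F analog (windowed rate change divided
# by the pre-stimulus baseline rate), per-cell response probabilities,
# significance of stimulus responses across trials, multisensory response
# categories and stimulus-preference analysis.

baseline_rate <- function(spikes, population, baseline_window) {
  dur_s <- (baseline_window[2] - baseline_window[1]) / 1000
  cnt <- window_counts(spikes, population, baseline_window[1],
                      baseline_window[2] - baseline_window[1], 1L)
  cnt[, 1] / dur_s
}

#' dF/F-analog response trace
#'
#' For each cell, the firing-rate change in contiguous 50 ms stimulus windows
#' divided by the mean pre-stimulus baseline rate:
#' `trace_w = (rate_w - baseline) / max(baseline, floor)`. The floor is one
#' spike per baseline duration, which keeps silent-baseline cells finite and
#' monotone in their stimulus rate.
#'
#' @param spikes A `grc_spikes` object (single trial).
#' @param baseline_window,stim_window `c(start, end)` in ms.
#' @param win Window width (ms).
#' @param population Population to analyze.
#' @return Object of class `grc_response`: `baseline` (Hz), `trace`
#'   (cells x windows), `amplitude` (per-cell mean over stimulus windows),
#'   `peak` (per-cell max over stimulus windows), `win`.
#' @export
dff_trace <- function(spikes, baseline_window, stim_window, win = 50,
                      population = "grc") {
  stim_dur <- stim_window[2] - stim_window[1]
  if (stim_dur < win) stop("stimulus window shorter than the analysis window")
  n_win <- floor(stim_dur / win)
  base <- baseline_rate(spikes, population, baseline_window)
  floor_rate <- 1000 / (baseline_window[2] - baseline_window[1]) # 1 spike / baseline
  cnt <- window_counts(spikes, population, stim_window[1], win, n_win)
  rates <- cnt / (win / 1000)
  trace <- (rates - base) / pmax(base, floor_rate)
  structure(list(baseline = base, trace = trace,
                 amplitude = rowMeans(trace),
                 peak = apply(trace, 1, max), win = win),
            class = "grc_response")
}

#' Per-cell firing probability during stimulation
#'
#' Fraction of fixed-width stimulus windows, pooled over trials, in which a
#' cell fires at least one spike.
#'
#' @param trials List of `grc_spikes` (one per trial).
#' @param stim_window `c(start, end)` ms.
#' @param win Window width (ms).
#' @param population Population to analyze.
#' @return Numeric vector in `[0, 1]`, one value per cell.
#' @export
response_probability <- function(trials, stim_window, win = 50,
                                 population = "grc") {
  stopifnot(length(trials) >= 1)
  n_win <- floor((stim_window[2] - stim_window[1]) / win)
  hit <- 0
  for (tr in trials) {
    cnt <- window_counts(tr, population, stim_window[1], win, n_win)
    hit <- hit + rowSums(cnt > 0)
  }
  hit / (n_win * length(trials))
}

#' Cells with significant stimulus responses
#'
#' Per-cell paired comparison (t-test across trials) of the stimulus-window
#' firing rate against the baseline-window rate; a cell is a significant
#' responder when p < alpha and its mean rate change is positive. Cells with
#' zero across-trial variance are significant iff their (constant) rate
#' change is positive.
#'
#' @param trials List of `grc_spikes` (>= 2 trials).
#' @param baseline_window,stim_window `c(start, end)` ms.
#' @param alpha Significance level.
#' @param population Population to analyze.
#' @return List with `mask` (logical per cell), `fraction`, `p` (per-cell
#'   p-values) and `mean_diff` (Hz).
#' @export
significant_responders <- function(trials, baseline_window, stim_window,
                                   alpha = 0.05, population = "grc") {
  n_tr <- length(trials)
  if (n_tr < 2) stop("need at least 2 trials")
  diffs <- vapply(trials, function(tr) {
    b <- baseline_rate(tr, population, baseline_window)
    sdur <- (stim_window[2] - stim_window[1]) / 1000
    s <- window_counts(tr, population, stim_window[1],
                       stim_window[2] - stim_window[1], 1L)[, 1] / sdur
    s - b
  }, numeric(trials[[1]]$n[[population]]))
  m <- rowMeans(diffs)
  sdv <- apply(diffs, 1, sd)
  tval <- m / (sdv / sqrt(n_tr))
  p <- 2 * pt(-abs(tval), df = n_tr - 1)
  p[sdv == 0 & m != 0] <- 0   # constant nonzero change
  p[sdv == 0 & m == 0] <- 1   # no change at all
  mask <- p < alpha & m > 0
  list(mask = mask, fraction = mean(mask), p = p, mean_diff = m)
}

#' Multisensory response categories
#'
#' Classifies each cell from its responses to two individual patterns and
#' their combination. The threshold T is the larger of the two individual
#' mean responses and M is the largest per-trial peak response over both
#' individual patterns. Comparisons at T use >=, with the convention that a
#' non-positive response never counts as above threshold (so cells silent for
#' both individual stimuli but driven by the combination are emergent).
#' Decision list: all below T -> unchanged; both individuals below and
#' combined above -> emergent; an individual above and combined below ->
#' suppressed; combined above T and above M -> facilitated; otherwise
#' unchanged. Categories partition the cell set.
#'
#' @param mean1,mean2,mean_comb Per-cell mean responses (e.g. dF/F
#'   amplitudes averaged over trials) to pattern 1, pattern 2 and their
#'   combination.
#' @param peak_max Per-cell maximum per-trial response over both individual
#'   patterns (M).
#' @param band Per-cell tolerance around T for the combined-response
#'   comparison (default 0 = exact tie rule): the combination counts as above
#'   threshold only beyond `T + band` and as below only under `T - band`.
#'   Protocol-level analyses pass the across-trial confidence half-width here
#'   so that chance-level fluctuations of the combined response do not create
#'   spurious suppressed or facilitated calls.
#' @return Factor with levels facilitated, unchanged, suppressed, emergent.
#' @export
categorize_multisensory <- function(mean1, mean2, mean_comb, peak_max,
                                    band = 0) {
  n <- length(mean1)
  stopifnot(length(mean2) == n, length(mean_comb) == n,
            length(peak_max) == n, all(band >= 0))
  T <- pmax(mean1, mean2)
  a1 <- mean1 >= T & mean1 > 0
  a2 <- mean2 >= T & mean2 > 0
  comb_above <- mean_comb >= T + band & mean_comb > 0
  comb_below <- mean_comb < T - band
  cat <- rep("unchanged", n)
  cat[!a1 & !a2 & comb_above] <- "emergent"
  cat[(a1 | a2) & comb_below] <- "suppressed"
  cat[(a1 | a2) & comb_above & mean_comb > peak_max] <- "facilitated"
  factor(cat, levels = c("facilitated", "unchanged", "suppressed", "emergent"))
}

#' Stimulus preference across a set of patterns
#'
#' For matched per-cell responses to several patterns, identifies the
#' preferred pattern (argmax response, ties to the lowest index) and the
#' responses normalized by each cell's maximum (cells with no response at all
#' normalize to zero).
#'
#' @param responses Matrix (cells x patterns) of mean responses.
#' @return List with `preferred` (integer per cell), `normalized`
#'   (cells x patterns) and `group_means` (patterns x patterns matrix: mean
#'   normalized response to each pattern within each preference group).
#' @export
preference_analysis <- function(responses) {
  stopifnot(is.matrix(responses), ncol(responses) >= 2)
  pref <- apply(responses, 1, which.max)
  mx <- apply(responses, 1, max)
  norm <- responses / ifelse(mx > 0, mx, 1)
  k <- ncol(responses)
  gm <- matrix(NA_real_, k, k)
  for (g in seq_len(k)) {
    sel <- pref == g
    if (any(sel)) gm[g, ] <- colMeans(norm[sel, , drop = FALSE])
  }
  list(preferred = pref, normalized = norm, group_means = gm)
}
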