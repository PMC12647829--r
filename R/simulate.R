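#' Stimulation schedule
#'
#' Ordered, contiguous segments of mossy-fiber drive. Each segment holds a
#' binary MF pattern and the Poisson rate of its active fibers; inactive
#' fibers are silent.
#'
#' @param segments List of lists with elements `start`, `end` (ms),
#'   `pattern` (binary vector over MFs) and `rate` (Hz).
#' @return Object of class `grc_schedule`.
#' @export
stimulus_schedule <- function(segments) {
  stopifnot(length(segments) >= 1)
  t_prev <- 0
  for (s in segments) {
    stopifnot(all(c("start", "end", "pattern", "rate") %in% names(s)))
    if (s$rate < 0) stop("rates must be >= 0")
    if (s$end <= s$start) stop("segments must have positive length")
    if (abs(s$start - t_prev) > 1e-9)
      stop("segments must be contiguous from t = 0")
    if (!all(s$pattern %in% c(0, 1))) stop("patterns must be binary")
    t_prev <- s$end
  }
  structure(list(segments = segments, t_end = t_prev,
                 n_mf = length(segments[[1]]$pattern)),
            class = "grc_schedule")
}

#' Poisson mossy-fiber drive
#'
#' Draws homogeneous Poisson spike trains for every active MF in every
#' schedule segment; inactive MFs emit nothing.
#'
#' @param schedule A [stimulus_schedule()].
#' @param seed Integer seed.
#' @return Data frame with columns `id` (MF index) and `time` (ms), sorted
#'   by time.
#' @export
poisson_drive <- function(schedule, seed) {
  stopifnot(inherits(schedule, "grc_schedule"))
  set.seed(derive_seed(seed, "poisson"))
  ids <- integer(0); times <- numeric(0)
  for (s in schedule$segments) {
    active <- which(s$pattern == 1)
    if (length(active) == 0 || s$rate == 0) next
    dur_s <- (s$end - s$start) / 1000
    counts <- rpois(length(active), s$rate * dur_s)
    tot <- sum(counts)
    if (tot == 0) next
    ids <- c(ids, rep.int(active, counts))
    times <- c(times, s$start + runif(tot) * (s$end - s$start))
  }
  ord <- order(times)
  data.frame(id = ids[ord], time = times[ord])
}

# flatten per-population params into per-neuron arrays (GrCs first, GoCs after)
expand_params <- function(params, n_grc, n_goc, dt) {
  fld <- function(name) c(rep(params$grc[[name]], n_grc),
                          rep(params$goc[[name]], n_goc))
  list(Cm = fld("Cm"), grest = fld("g_rest"), Erest = fld("E_rest"),
       Eampa = fld("E_ampa"), Egaba = fld("E_gaba"), Vth = fld("V_th"),
       Vreset = fld("V_reset"),
       decayA = exp(-dt / fld("tau_ampa")),
       decayG = exp(-dt / fld("tau_gaba")),
       refSteps = as.integer(round(fld("t_ref") / dt)))
}

# CSR (0-based) over n_src sources from parallel edge vectors
build_csr <- function(pre, target0, receptor, delay_steps, weight, n_src) {
  ord <- order(pre)
  counts <- tabulate(pre, nbins = n_src)
  list(ptr = as.integer(c(0L, cumsum(counts))),
       target = as.integer(target0[ord]),
       receptor = as.integer(receptor[ord]),
       delay = as.integer(delay_steps[ord]),
       weight = as.numeric(weight[ord]))
}

#' Simulate the spiking network
#'
#' Time-driven integration of all granule and Golgi cells under Poisson
#' mossy-fiber drive. Conductances decay exponentially between spikes; the
#' membrane advances by the exponential-Euler closed form within each step;
#' threshold crossing emits a spike, resets the membrane and starts the
#' absolute refractory period. Synaptic increments are applied before the
#' membrane update of the step in which they are due.
#'
#' @param net A `grc_network`.
#' @param schedule A [stimulus_schedule()].
#' @param params Per-population neuron parameters
#'   (default [default_neuron_params()]).
#' @param weights Optional [weight_config()] overriding the per-class weights
#'   stored in the network, so conditions can be toggled without rewiring.
#' @param dt Integration step (ms).
#' @param seed Integer seed for the Poisson drive (ignored when `mf_spikes`
#'   is supplied).
#' @param mf_spikes Optional pre-generated MF drive from [poisson_drive()].
#' @param record Optional list(population, ids) of neurons whose membrane
#'   potential to record.
#' @return Object of class `grc_spikes`: `events` (data frame id, population,
#'   time), `mf_spikes`, `t_end`, `dt`, counts of each population, optional
#'   voltage traces `V` (matrix steps x recorded), and metadata.
#' @export
simulate_network <- function(net, schedule, params = default_neuron_params(),
                             weights = NULL, dt = 0.1, seed = 1L,
                             mf_spikes = NULL, record = NULL) {
  stopifnot(inherits(net, "grc_network"), inherits(schedule, "grc_schedule"))
  taus <- c(params$grc$tau_ampa, params$grc$tau_gaba,
            params$goc$tau_ampa, params$goc$tau_gaba)
  if (dt > min(taus) / 5)
    stop("dt must be <= min(tau)/5 = ", min(taus) / 5, " ms")
  n_grc <- nrow(net$positions$grc)
  n_goc <- nrow(net$positions$goc)
  n_mf <- nrow(net$positions$glomerulus)
  if (schedule$n_mf != n_mf)
    stop("schedule pattern length (", schedule$n_mf,
         ") does not match MF count (", n_mf, ")")
  if (is.null(weights)) weights <- net$weights
  n_steps <- as.integer(ceiling(schedule$t_end / dt))
  pp <- expand_params(params, n_grc, n_goc, dt)

  dstep <- function(ms) pmax(1L, as.integer(round(ms / dt)))
  class_weight <- function(cl) switch(cl,
    mf_grc = weights$w_mf_grc_total / net$config$grc_dendrites,
    mf_goc = weights$w_mf_goc,
    aa_goc = weights$w_grc_goc,
    pf_goc = weights$w_grc_goc,
    goc_grc = weights$w_goc_grc)

  # recurrent edges: GrC (1..n_grc) and GoC (n_grc+1..) in global 0-based ids
  syn <- net$synapses
  rec_pre <- c(syn$aa_goc$pre, syn$pf_goc$pre, syn$goc_grc$pre + n_grc)
  rec_tgt <- c(syn$aa_goc$post + n_grc, syn$pf_goc$post + n_grc,
               syn$goc_grc$post) - 1L
  rec_rcp <- c(rep(0L, nrow(syn$aa_goc) + nrow(syn$pf_goc)),
               rep(1L, nrow(syn$goc_grc)))
  rec_dly <- c(rep(dstep(net$config$delay[["aa_goc"]]), nrow(syn$aa_goc)),
               rep(dstep(net$config$delay[["pf_goc"]]), nrow(syn$pf_goc)),
               rep(dstep(net$config$delay[["goc_grc"]]), nrow(syn$goc_grc)))
  rec_w <- c(rep(class_weight("aa_goc"), nrow(syn$aa_goc)),
             rep(class_weight("pf_goc"), nrow(syn$pf_goc)),
             rep(class_weight("goc_grc"), nrow(syn$goc_grc)))
  rec <- build_csr(rec_pre, rec_tgt, rec_rcp, rec_dly, rec_w, n_grc + n_goc)

  # external (MF) fanout
  ext_pre <- c(syn$mf_grc$pre, syn$mf_goc$pre)
  ext_tgt <- c(syn$mf_grc$post, syn$mf_goc$post + n_grc) - 1L
  ext_rcp <- rep(0L, length(ext_pre))
  ext_dly <- c(rep(dstep(net$config$delay[["mf_grc"]]), nrow(syn$mf_grc)),
               rep(dstep(net$config$delay[["mf_goc"]]), nrow(syn$mf_goc)))
  ext_w <- c(rep(class_weight("mf_grc"), nrow(syn$mf_grc)),
             rep(class_weight("mf_goc"), nrow(syn$mf_goc)))
  ext <- build_csr(ext_pre, ext_tgt, ext_rcp, ext_dly, ext_w, max(n_mf, 1L))

  if (is.null(mf_spikes)) mf_spikes <- poisson_drive(schedule, seed)
  sp_step <- as.integer(floor(mf_spikes$time / dt))
  keep <- sp_step >= 0L & sp_step < n_steps
  sp_src <- as.integer(mf_spikes$id[keep]) - 1L
  sp_step <- sp_step[keep]
  ord <- order(sp_step)

  rec_ids <- integer(0)
  if (!is.null(record)) {
    off <- if (record$population == "goc") n_grc else 0L
    rec_ids <- as.integer(record$ids + off - 1L)
  }

  res <- lif_simulate_cpp(pp$Cm, pp$grest, pp$Erest, pp$Eampa, pp$Egaba,
                          pp$Vth, pp$Vreset, pp$decayA, pp$decayG,
                          pp$refSteps,
                          rec$ptr, rec$target, rec$receptor, rec$delay,
                          rec$weight,
                          sp_src[ord], sp_step[ord],
                          ext$ptr, ext$target, ext$receptor, ext$delay,
                          ext$weight,
                          n_steps, dt, rec_ids)

  gid <- res$id + 1L
  pop <- ifelse(gid <= n_grc, "grc", "goc")
  id <- ifelse(gid <= n_grc, gid, gid - n_grc)
  events <- data.frame(id = id, population = pop, time = res$time)
  structure(list(events = events, mf_spikes = mf_spikes,
                 t_end = schedule$t_end, dt = dt,
                 n = c(mf = n_mf, grc = n_grc, goc = n_goc),
                 V = if (length(rec_ids)) res$V else NULL,
                 weights_label = weights$label, seed = seed),
            class = "grc_spikes")
}

#' @export
print.grc_spikes <- function(x, ...) {
  cat("Spike data:", x$t_end, "ms simulated,",
      nrow(x$events), "GrC/GoC spikes,", nrow(x$mf_spikes), "MF spikes\n")
  for (p in c("grc", "goc")) {
    ev <- x$events$population == p
    cat(sprintf("  %s: mean rate %.2f Hz over %d cells\n", p,
                sum(ev) / x$n[[p]] / (x$t_end / 1000), x$n[[p]]))
  }
  invisible(x)
}

#' Mean firing rate of a population
#' @param spikes A `grc_spikes` object.
#' @param population `"grc"` or `"goc"`.
#' @param window Optional `c(start, end)` ms restriction.
#' @return Mean rate in Hz across all cells of the population.
#' @export
mean_rate <- function(spikes, population = "grc", window = NULL) {
  ev <- spikes$events[spikes$events$population == population, ]
  dur <- spikes$t_end
  if (!is.null(window)) {
    ev <- ev[ev$time > window[1] & ev$time <= window[2], ]
    dur <- window[2] - window[1]
  }
  nrow(ev) / spikes$n[[population]] / (dur / 1000)
}

#' Sweep the inhibitory drive weights
#'
#' Runs the same network, schedule and seeds over a grid of
#' (feedforward, feedback) excitatory drives onto Golgi cells and summarizes
#' the resulting firing rates; used to calibrate inhibition levels against a
#' target granule-cell rate.
#'
#' @param net A `grc_network`.
#' @param schedule A [stimulus_schedule()].
#' @param grid Data frame with columns `w_mf_goc`, `w_grc_goc`.
#' @param params,dt,seed Passed to [simulate_network()].
#' @return `grid` with appended `grc_rate` and `goc_rate` columns (Hz).
#' @export
weight_sweep <- function(net, schedule, grid,
                         params = default_neuron_params(), dt = 0.1,
                         seed = 1L) {
  stopifnot(nrow(grid) >= 1, all(c("w_mf_goc", "w_grc_goc") %in% names(grid)))
  mf_spikes <- poisson_drive(schedule, seed)
  grid$grc_rate <- NA_real_
  grid$goc_rate <- NA_real_
  for (i in seq_len(nrow(grid))) {
    w <- weight_config(w_mf_goc = grid$w_mf_goc[i],
                       w_grc_goc = grid$w_grc_goc[i],
                       label = sprintf("sweep_%d", i))
    sim <- simulate_network(net, schedule, params, weights = w, dt = dt,
                            seed = seed, mf_spikes = mf_spikes)
    grid$grc_rate[i] <- mean_rate(sim, "grc")
    grid$goc_rate[i] <- mean_rate(sim, "goc")
  }
  grid
}

#' Spike counts per neuron in fixed windows
#'
#' @param spikes A `grc_spikes` object or a data frame of events.
#' @param population Population to count.
#' @param t0 Window origin (ms).
#' @param win Window width (ms).
#' @param n_windows Number of contiguous windows.
#' @return Integer matrix (cells x windows).
#' @export
window_counts <- function(spikes, population = "grc", t0, win, n_windows) {
  if (inherits(spikes, "grc_spikes")) {
    n <- spikes$n[[population]]
    ev <- spikes$events[spikes$events$population == population, ]
  } else {
    ev <- spikes
    n <- attr(spikes, "n_cells")
  }
  window_counts_cpp(as.integer(ev$id) - 1L, as.numeric(ev$time),
                    as.integer(n), t0, win, as.integer(n_windows))
}
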