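# Shared lazily-built fixtures, cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

small_net <- function() cached("small_net", function() {
  make_fixture("small", seed = 3L)
})

tiny_net <- function() cached("tiny_net", function() {
  make_fixture("tiny", seed = 1L)
})

# Synthetic spike container for analysis-level tests: events built directly
# from per-cell spike-time lists.
synthetic_spikes <- function(times_by_cell, n_cells, t_end) {
  id <- rep(seq_along(times_by_cell),
            vapply(times_by_cell, length, 0L))
  times <- as.numeric(unlist(times_by_cell))
  structure(list(events = data.frame(id = id,
                                     population = rep("grc", length(id)),
                                     time = times),
                 mf_spikes = data.frame(id = integer(0), time = numeric(0)),
                 t_end = t_end, dt = 0.1,
                 n = c(mf = 0L, grc = as.integer(n_cells), goc = 0L)),
            class = "grc_spikes")
}

# Poisson trial: each cell fires at rate_hz[i] over [0, t_end]
poisson_trial <- function(rate_hz, t_end) {
  times <- lapply(rate_hz, function(r) {
    k <- rpois(1, r * t_end / 1000)
    sort(runif(k, 0, t_end))
  })
  synthetic_spikes(times, length(rate_hz), t_end)
}

# Independent single-neuron reference integration of the membrane equation
# with exponentially decaying conductances: plain forward Euler at a fine
# step, with synaptic increments applied at prescribed absolute times.
# Events: data.frame(time, receptor (0 ampa / 1 gaba), weight).
reference_lif <- function(params, events, t_end, dt_fine = 0.001,
                          report_dt = 0.1) {
  n_fine <- round(t_end / dt_fine)
  ev_step <- round(events$time / dt_fine)
  V <- params$E_rest
  gA <- 0; gG <- 0
  decayA <- exp(-dt_fine / params$tau_ampa)
  decayG <- exp(-dt_fine / params$tau_gaba)
  report_every <- round(report_dt / dt_fine)
  out_V <- numeric(n_fine / report_every)
  out_t <- numeric(length(out_V))
  spikes <- numeric(0)
  ref_until <- -1
  k <- 0
  for (s in seq_len(n_fine)) {
    gA <- gA * decayA
    gG <- gG * decayG
    hit <- which(ev_step == s - 1)
    for (h in hit) {
      if (events$receptor[h] == 0) gA <- gA + events$weight[h]
      else gG <- gG + events$weight[h]
    }
    if (s * dt_fine <= ref_until) {
      V <- params$V_reset
    } else {
      dV <- (gA * (params$E_ampa - V) + gG * (params$E_gaba - V) +
               params$g_rest * (params$E_rest - V)) / params$Cm
      V <- V + dt_fine * dV
      if (V >= params$V_th) {
        spikes <- c(spikes, s * dt_fine)
        V <- params$V_reset
        ref_until <- s * dt_fine + params$t_ref
      }
    }
    if (s %% report_every == 0) {
      k <- k + 1
      out_V[k] <- V
      out_t[k] <- s * dt_fine
    }
  }
  list(t = out_t, V = out_V, spikes = spikes)
}
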