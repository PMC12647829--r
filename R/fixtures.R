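# Miniature test substrates: a hand-wired few-cell motif with scripted input
# spikes (membrane responses verifiable against an independent reference
# integration) and a small 25 um cube network for fast end-to-end runs.

#' Build a miniature fixture
#'
#' `tiny`: a hand-wired motif of 4 mossy fibers converging on one granule
#' cell plus one Golgi cell fed by the same fibers and inhibiting the granule
#' cell, with a scripted (deterministic) input spike list. `small`: a 25 um
#' cube network built by the standard placement and wiring rules, with the
#' Golgi density raised so the cube holds a couple of Golgi cells, and a
#' small spatially correlated pattern set.
#'
#' @param scale `"tiny"` or `"small"`.
#' @param seed Integer seed.
#' @return List with `net`, and for tiny `input_spikes` + `schedule`, for
#'   small `patterns`.
#' @export
make_fixture <- function(scale = c("tiny", "small"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "tiny") return(tiny_fixture(seed))
  small_fixture(seed)
}

tiny_fixture <- function(seed) {
  side <- 50
  positions <- list(
    glomerulus = cbind(x = c(10, 20, 30, 40), y = rep(25, 4), z = rep(25, 4)),
    grc = cbind(x = 25, y = 20, z = 25),
    goc = cbind(x = 25, y = 35, z = 25))
  attr(positions, "cube_side") <- side
  w <- weight_config()
  syn <- list(
    mf_grc = data.frame(pre = 1:4, post = 1L,
                        weight = w$w_mf_grc_total / 4, delay = 1),
    mf_goc = data.frame(pre = 1:4, post = 1L, weight = w$w_mf_goc, delay = 1),
    aa_goc = data.frame(pre = 1L, post = 1L, weight = w$w_grc_goc, delay = 1),
    pf_goc = empty_synapses(),
    goc_grc = data.frame(pre = 1L, post = 1L, weight = w$w_goc_grc,
                         delay = 1))
  net <- structure(list(positions = positions, cube_side = side,
                        synapses = syn, config = connectivity_config(),
                        weights = w, seed = seed),
                   class = "grc_network")
  # scripted input: a triple near-coincidence at 20 ms, a lone spike at
  # 60 ms, a full quadruple volley at 100 ms
  input_spikes <- data.frame(
    id = c(1L, 2L, 3L, 1L, 1L, 2L, 3L, 4L),
    time = c(20, 20.5, 21, 60, 100, 100.2, 100.4, 100.6))
  sched <- stimulus_schedule(list(
    list(start = 0, end = 150, pattern = rep(1, 4), rate = 0)))
  list(net = net, input_spikes = input_spikes, schedule = sched)
}

small_fixture <- function(seed) {
  geom <- geometry_config(cube_side = 25,
                          density = c(glomerulus = 8.0e-4, grc = 3.7e-3,
                                      goc = 1.5e-4),
                          exclusion_radius = c(glomerulus = 1.5, grc = 2.5,
                                               goc = 4))
  # dendritic reach spans the whole 25 um torus (max distance 21.7 um) so
  # every granule cell always finds its four afferents
  cfg <- connectivity_config(grc_dendrite_length = 22, goc_basal_radius = 12,
                             goc_apical_radius = 12, goc_axon_radius = 25)
  pos <- place_cells(geom, seed)
  net <- build_connectome(pos, cfg, weight_config(), seed)
  pats <- generate_patterns(pos$glomerulus,
                            pattern_config(0.45, 10, 20, seed = seed))
  list(net = net, patterns = pats)
}
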