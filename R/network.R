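#' Connectivity configuration
#'
#' Geometric reaches, convergence targets and synaptic delays of the five
#' synapse classes: MF->GrC, MF->GoC, GrC->GoC via ascending axon (AA),
#' GrC->GoC via parallel fiber (PF) and GoC->GrC. Granule cell ascending
#' axons run along z; parallel fibers run along the `pf_axis` for the full
#' (wrapped) cube length. Convergence targets beyond the geometric candidate
#' pool are capped at the pool size.
#'
#' @param grc_dendrite_length Maximal glomerulus-to-GrC dendrite length (um).
#' @param goc_basal_radius GoC basal-dendrite field radius for MF input (um).
#' @param goc_apical_radius GoC apical-dendrite field radius for AA/PF input (um).
#' @param goc_axon_radius GoC axonal field radius for glomerular inhibition
#'   (um); must be at least as large as the dendritic radii (Golgi axonal
#'   fields are wider than their dendritic fields).
#' @param pf_axis Axis ("x" or "y") along which parallel fibers run.
#' @param grc_dendrites Number of dendrites (distinct glomerular afferents)
#'   per granule cell.
#' @param conv_mf_goc,conv_aa_goc,conv_pf_goc Target convergences (afferents
#'   per GoC) for the MF, ascending-axon and parallel-fiber inputs.
#' @param delay Named vector of synaptic delays in ms per class.
#' @return An object of class `grc_connectivity`.
#' @export
connectivity_config <- function(grc_dendrite_length = 40,
                                goc_basal_radius = 50,
                                goc_apical_radius = 50,
                                goc_axon_radius = 100,
                                pf_axis = c("x", "y"),
                                grc_dendrites = 4L,
                                conv_mf_goc = 100L,
                                conv_aa_goc = 400L,
                                conv_pf_goc = 1200L,
                                delay = c(mf_grc = 1, mf_goc = 1, aa_goc = 1,
                                          pf_goc = 1, goc_grc = 1)) {
  pf_axis <- match.arg(pf_axis)
  reaches <- c(grc_dendrite_length, goc_basal_radius, goc_apical_radius,
               goc_axon_radius)
  if (any(reaches < 0)) stop("all reaches must be >= 0")
  if (goc_axon_radius < max(goc_basal_radius, goc_apical_radius))
    stop("GoC axon radius must be >= GoC dendritic radii")
  classes <- c("mf_grc", "mf_goc", "aa_goc", "pf_goc", "goc_grc")
  if (!all(classes %in% names(delay))) stop("`delay` must name all 5 classes")
  if (any(delay < 0)) stop("delays must be >= 0")
  structure(list(grc_dendrite_length = grc_dendrite_length,
                 goc_basal_radius = goc_basal_radius,
                 goc_apical_radius = goc_apical_radius,
                 goc_axon_radius = goc_axon_radius,
                 pf_axis = pf_axis,
                 grc_dendrites = as.integer(grc_dendrites),
                 conv_mf_goc = as.integer(conv_mf_goc),
                 conv_aa_goc = as.integer(conv_aa_goc),
                 conv_pf_goc = as.integer(conv_pf_goc),
                 delay = delay[classes]),
            class = "grc_connectivity")
}

synapse_classes <- function() c("mf_grc", "mf_goc", "aa_goc", "pf_goc", "goc_grc")

empty_synapses <- function() {
  data.frame(pre = integer(0), post = integer(0),
             weight = numeric(0), delay = numeric(0))
}

# uniform subsample of candidate ids down to a target convergence
subsample_afferents <- function(ids, target) {
  if (length(ids) <= target) return(ids)
  sample(ids, target)
}

#' Wire the five synapse classes of the granular-layer network
#'
#' Applies the geometric wiring rules on the periodic cube: each granule cell
#' contacts its `grc_dendrites` nearest glomeruli within dendritic reach
#' (random tie-breaking); each Golgi cell samples glomeruli within its basal
#' field and granule cells within its apical field (directly for ascending
#' axons, via the full-length parallel-fiber line for PF synapses), each
#' subsampled to the class convergence target; and a GoC inhibits a GrC when
#' its axonal field covers at least one glomerulus contacted by that GrC
#' (one synapse per GoC-GrC pair).
#'
#' @param positions Output of [place_cells()].
#' @param config A [connectivity_config()].
#' @param weights A [weight_config()]; peak conductances assigned uniformly
#'   per class (the MF->GrC total is split across the dendrites).
#' @param seed Integer seed for subsampling and tie-breaking.
#' @return An object of class `grc_network` with elements `positions`,
#'   `synapses` (one data frame per class with columns pre, post, weight,
#'   delay), `config`, `weights`, `seed`.
#' @export
build_connectome <- function(positions, config, weights = weight_config(),
                             seed = 1L) {
  stopifnot(inherits(config, "grc_connectivity"),
            inherits(weights, "grc_weights"))
  glo <- positions$glomerulus
  grc <- positions$grc
  goc <- positions$goc
  side <- attr(positions, "cube_side")
  if (is.null(side)) {
    side <- max(1e-9, vapply(positions, function(m)
      if (nrow(m)) max(m) else 0, 0))
    side <- ceiling(side) # fallback; place_cells output should carry the side
  }
  set.seed(derive_seed(seed, "wire"))
  syn <- list()
  n_glo <- nrow(glo); n_grc <- nrow(grc); n_goc <- nrow(goc)
  dly <- config$delay

  # MF -> GrC: nearest-first among glomeruli within dendritic reach
  if (n_grc > 0 && n_glo > 0) {
    D <- toroidal_cross_distance(grc, glo, side)
    w_dend <- weights$w_mf_grc_total / config$grc_dendrites
    pre <- post <- vector("list", n_grc)
    for (i in seq_len(n_grc)) {
      cand <- which(D[i, ] <= config$grc_dendrite_length)
      if (length(cand) < config$grc_dendrites)
        stop("granule cell ", i, " has only ", length(cand),
             " reachable glomeruli (needs ", config$grc_dendrites, ")")
      ord <- cand[order(D[i, cand], runif(length(cand)))]
      pre[[i]] <- ord[seq_len(config$grc_dendrites)]
      post[[i]] <- rep.int(i, config$grc_dendrites)
    }
    syn$mf_grc <- data.frame(pre = unlist(pre), post = unlist(post),
                             weight = w_dend, delay = dly[["mf_grc"]])
  } else syn$mf_grc <- empty_synapses()

  # MF -> GoC: glomeruli within basal field, subsampled to convergence
  if (n_goc > 0 && n_glo > 0) {
    D <- toroidal_cross_distance(goc, glo, side)
    pre <- post <- vector("list", n_goc)
    for (j in seq_len(n_goc)) {
      cand <- which(D[j, ] <= config$goc_basal_radius)
      keep <- subsample_afferents(cand, config$conv_mf_goc)
      pre[[j]] <- keep
      post[[j]] <- rep.int(j, length(keep))
    }
    syn$mf_goc <- data.frame(pre = unlist(pre), post = unlist(post),
                             weight = weights$w_mf_goc, delay = dly[["mf_goc"]])
  } else syn$mf_goc <- empty_synapses()

  # GrC -> GoC via ascending axon: lateral (x, y) proximity to apical field
  lateral_axes <- c(1L, 2L)
  if (n_goc > 0 && n_grc > 0) {
    Dlat <- toroidal_cross_distance(goc, grc, side, axes = lateral_axes)
    pre <- post <- vector("list", n_goc)
    for (j in seq_len(n_goc)) {
      cand <- which(Dlat[j, ] <= config$goc_apical_radius)
      keep <- subsample_afferents(cand, config$conv_aa_goc)
      pre[[j]] <- keep
      post[[j]] <- rep.int(j, length(keep))
    }
    syn$aa_goc <- data.frame(pre = unlist(pre), post = unlist(post),
                             weight = weights$w_grc_goc, delay = dly[["aa_goc"]])

    # GrC -> GoC via parallel fiber: the PF line (full cube length along
    # pf_axis) passes within apical reach iff distance in the two remaining
    # axes is within reach
    pf_ax <- if (config$pf_axis == "x") 1L else 2L
    pf_axes <- setdiff(1:3, pf_ax)
    Dpf <- toroidal_cross_distance(goc, grc, side, axes = pf_axes)
    pre <- post <- vector("list", n_goc)
    for (j in seq_len(n_goc)) {
      cand <- which(Dpf[j, ] <= config$goc_apical_radius)
      keep <- subsample_afferents(cand, config$conv_pf_goc)
      pre[[j]] <- keep
      post[[j]] <- rep.int(j, length(keep))
    }
    syn$pf_goc <- data.frame(pre = unlist(pre), post = unlist(post),
                             weight = weights$w_grc_goc, delay = dly[["pf_goc"]])
  } else {
    syn$aa_goc <- empty_synapses()
    syn$pf_goc <- empty_synapses()
  }

  # GoC -> GrC: edge iff the GoC axon field covers a glomerulus contacted by
  # the GrC; one synapse per (GoC, GrC) pair
  if (n_goc > 0 && n_grc > 0 && n_glo > 0) {
    Dax <- toroidal_cross_distance(goc, glo, side) # n_goc x n_glo
    covered <- Dax <= config$goc_axon_radius
    # glomeruli afferent to each GrC
    aff <- split(syn$mf_grc$pre, syn$mf_grc$post)
    pre <- post <- vector("list", n_goc)
    for (j in seq_len(n_goc)) {
      cov_glo <- which(covered[j, ])
      if (length(cov_glo) == 0) { pre[[j]] <- integer(0); post[[j]] <- integer(0); next }
      hit <- vapply(aff, function(g) any(g %in% cov_glo), logical(1))
      tgt <- as.integer(names(aff))[hit]
      pre[[j]] <- rep.int(j, length(tgt))
      post[[j]] <- tgt
    }
    syn$goc_grc <- data.frame(pre = unlist(pre), post = unlist(post),
                              weight = weights$w_goc_grc, delay = dly[["goc_grc"]])
  } else syn$goc_grc <- empty_synapses()

  structure(list(positions = positions,
                 cube_side = side,
                 synapses = syn,
                 config = config,
                 weights = weights,
                 seed = seed),
            class = "grc_network")
}

#' @export
print.grc_network <- function(x, ...) {
  n <- vapply(x$positions, nrow, 0L)
  cat("Granular-layer network (cube side", x$cube_side, "um):\n")
  cat(sprintf("  %d glomeruli/MFs, %d GrCs, %d GoCs\n",
              n[["glomerulus"]], n[["grc"]], n[["goc"]]))
  for (cl in names(x$synapses))
    cat(sprintf("  %-8s %6d synapses\n", cl, nrow(x$synapses[[cl]])))
  invisible(x)
}

#' Per-class convergence and divergence summary
#'
#' In-degree (convergence onto postsynaptic cells) and out-degree (divergence
#' from presynaptic cells) distributions for every synapse class, including
#' cells with zero degree.
#'
#' @param net A `grc_network`.
#' @return Data frame with one row per synapse class.
#' @export
connectivity_stats <- function(net) {
  stopifnot(inherits(net, "grc_network"))
  pops <- list(mf_grc = c("glomerulus", "grc"),
               mf_goc = c("glomerulus", "goc"),
               aa_goc = c("grc", "goc"),
               pf_goc = c("grc", "goc"),
               goc_grc = c("goc", "grc"))
  rows <- lapply(names(net$synapses), function(cl) {
    s <- net$synapses[[cl]]
    n_pre <- nrow(net$positions[[pops[[cl]][1]]])
    n_post <- nrow(net$positions[[pops[[cl]][2]]])
    indeg <- tabulate(s$post, nbins = max(n_post, 1L))
    outdeg <- tabulate(s$pre, nbins = max(n_pre, 1L))
    if (n_post == 0) indeg <- 0L
    if (n_pre == 0) outdeg <- 0L
    data.frame(class = cl, n_edges = nrow(s),
               conv_mean = mean(indeg), conv_min = min(indeg),
               conv_max = max(indeg),
               div_mean = mean(outdeg), div_min = min(outdeg),
               div_max = max(outdeg))
  })
  do.call(rbind, rows)
}
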