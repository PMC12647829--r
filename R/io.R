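# Delimited-text serialization of networks, pattern sets and spike data,
# plus structured-config loading and run manifests. Every artifact directory
# carries a manifest recording the configuration snapshot, all seeds and a
# content hash, sufficient to reproduce deterministic stages bit-identically.

config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = 12, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(dir, config, seeds, extra = list()) {
  man <- c(list(tool = "grclayer",
                version = as.character(utils::packageVersion("grclayer")),
                timestamp = format(Sys.time(), tz = "UTC"),
                config = config, seeds = seeds,
                config_hash = config_hash(config)),
           extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 12, force = TRUE, pretty = TRUE)
  invisible(man)
}

#' Serialize a network to delimited text files
#'
#' One tab-delimited file per population (id, x, y, z) and per synapse class
#' (pre, post, weight_nS, delay_ms), plus a JSON manifest with the
#' configuration snapshot and seed.
#'
#' @param net A `grc_network`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in names(net$positions)) {
    df <- data.frame(id = seq_len(nrow(net$positions[[p]])),
                     net$positions[[p]])
    write.table(df, file.path(dir, paste0("positions_", p, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (cl in names(net$synapses)) {
    s <- net$synapses[[cl]]
    names(s) <- c("pre", "post", "weight_nS", "delay_ms")
    write.table(s, file.path(dir, paste0("synapses_", cl, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  cc <- unclass(net$config)
  cc$delay <- as.list(cc$delay) # keep names through JSON
  write_manifest(dir,
                 config = list(cube_side = net$cube_side,
                               connectivity = cc,
                               weights = unclass(net$weights)),
                 seeds = list(topology = net$seed))
  invisible(dir)
}

#' Read a network written by [write_network()]
#' @param dir Directory holding the serialized network.
#' @return A `grc_network`.
#' @export
read_network <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  pops <- c("glomerulus", "grc", "goc")
  positions <- lapply(pops, function(p) {
    df <- read.delim(file.path(dir, paste0("positions_", p, ".tsv")))
    as.matrix(df[, c("x", "y", "z")])
  })
  names(positions) <- pops
  attr(positions, "cube_side") <- man$config$cube_side
  syn <- lapply(synapse_classes(), function(cl) {
    s <- read.delim(file.path(dir, paste0("synapses_", cl, ".tsv")))
    names(s) <- c("pre", "post", "weight", "delay")
    s
  })
  names(syn) <- synapse_classes()
  cc <- man$config$connectivity
  cfg <- connectivity_config(cc$grc_dendrite_length, cc$goc_basal_radius,
                             cc$goc_apical_radius, cc$goc_axon_radius,
                             cc$pf_axis, cc$grc_dendrites, cc$conv_mf_goc,
                             cc$conv_aa_goc, cc$conv_pf_goc,
                             unlist(cc$delay))
  w <- man$config$weights
  weights <- weight_config(w$w_mf_grc_total, w$w_goc_grc, w$w_mf_goc,
                           w$w_grc_goc, w$label)
  structure(list(positions = positions, cube_side = man$config$cube_side,
                 synapses = syn, config = cfg, weights = weights,
                 seed = man$seeds$topology),
            class = "grc_network")
}

#' Write a pattern set as a delimited binary matrix with a config sidecar
#' @param patterns A `grc_patterns`.
#' @param path Output file (.tsv); the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_patterns <- function(patterns, path) {
  m <- patterns$activity
  colnames(m) <- paste0("mf", seq_len(ncol(m)))
  write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- c(unclass(patterns$config),
            list(labels = patterns$labels))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = 12, null = "null")
  invisible(path)
}

#' Read a pattern set written by [write_patterns()]
#' @param path Pattern file path.
#' @return A `grc_patterns`.
#' @export
read_patterns <- function(path) {
  m <- as.matrix(read.delim(path))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- pattern_config(side$f, side$sigma, side$n_patterns, side$seed,
                        side$ridge)
  labels <- side$labels
  if (length(labels) == 0) labels <- NULL
  structure(list(activity = unname(m), config = cfg, labels = labels),
            class = "grc_patterns")
}

#' Write spike events as a delimited file
#' @param spikes A `grc_spikes`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  ev <- spikes$events[, c("time", "population", "id")]
  names(ev) <- c("time_ms", "population", "neuron_id")
  write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# schema of user-facing configuration files
config_defaults <- function() {
  list(
    geometry = list(cube_side = 100,
                    density = list(glomerulus = 3.0e-4, grc = 3.7e-3,
                                   goc = 8e-6),
                    exclusion_radius = list(glomerulus = 1.5, grc = 2.5,
                                            goc = 8)),
    connectivity = list(grc_dendrite_length = 40, goc_basal_radius = 50,
                        goc_apical_radius = 50, goc_axon_radius = 100,
                        pf_axis = "x", grc_dendrites = 4,
                        conv_mf_goc = 100, conv_aa_goc = 400,
                        conv_pf_goc = 1200),
    weights = list(w_mf_grc_total = 4.0, w_goc_grc = 0.5, w_mf_goc = 0.1,
                   w_grc_goc = 0.015, label = "control"),
    patterns = list(f = 0.45, sigma = 40, n_patterns = 640, ridge = 1e-6),
    simulation = list(dt = 0.1),
    decoder = list(lr = 0.001, batch = 32, epochs = 2000, patience = 5,
                   mode = "early")
  )
}

check_keys <- function(x, ref, path = "") {
  bad <- setdiff(names(x), names(ref))
  if (length(bad))
    stop("unknown configuration key(s): ",
         paste0(path, bad, collapse = ", "))
  for (k in names(x))
    if (is.list(ref[[k]]) && is.list(x[[k]]))
      check_keys(x[[k]], ref[[k]], paste0(path, k, "."))
}

#' Load and validate a structured (YAML) configuration file
#'
#' Unknown keys are rejected with their full path; missing keys are filled
#' with the package defaults. Basic range checks are applied to the pattern
#' parameters.
#'
#' @param path YAML file.
#' @return Nested configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  ref <- config_defaults()
  check_keys(user, ref)
  cfg <- modifyList(ref, user)
  if (cfg$patterns$f < 0 || cfg$patterns$f > 1)
    stop("patterns.f must be in [0, 1], got ", cfg$patterns$f)
  if (cfg$patterns$sigma < 0) stop("patterns.sigma must be >= 0")
  if (cfg$simulation$dt <= 0) stop("simulation.dt must be > 0")
  cfg
}

#' Save a configuration tree to YAML
#' @param config Nested configuration list.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
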