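# End-to-end experiment recipes: each named experiment wires
# patterns -> simulation -> analysis/decoding with the protocol parameters,
# at full scale or a scaled-down substitute for quick runs.

default_network <- function(seed = 1L, cube_side = 100) {
  geom <- geometry_config(cube_side = cube_side)
  pos <- place_cells(geom, seed)
  build_connectome(pos, connectivity_config(), weight_config(), seed)
}

experiment_scale <- function(scale) {
  switch(scale,
    tiny = list(cube_side = 40, trials = 2, n_patterns = 40,
                presentations = 1, seeds = 2, epochs = 20),
    small = list(cube_side = 60, trials = 5, n_patterns = 160,
                 presentations = 2, seeds = 2, epochs = 50),
    full = list(cube_side = 100, trials = 10, n_patterns = 640,
                presentations = 10, seeds = 6, epochs = 500),
    stop("unknown scale: ", scale))
}

#' Run a named experiment recipe
#'
#' Orchestrates the full pipeline for each figure-level experiment of the
#' study: sensory validation (`sensory`), selectivity (`selectivity`),
#' multisensory combination (`combined`), noise-free classification
#' (`classification`), noisy classification with inhibition levels
#' (`noisy_classification`), the inhibition-level metric sweep (`metrics`),
#' the timing protocol (`timing`) and the train-with / test-without
#' inhibition transfer (`transfer`).
#'
#' @param name Experiment name (see Description).
#' @param scale `"tiny"`, `"small"` or `"full"`.
#' @param seed Integer seed.
#' @param ... Extra arguments forwarded to the underlying protocol.
#' @return A result bundle (list), experiment-specific.
#' @export
run_experiment <- function(name = c("sensory", "selectivity", "combined",
                                    "classification", "noisy_classification",
                                    "metrics", "timing", "transfer"),
                           scale = "small", seed = 1L, ...) {
  name <- match.arg(name)
  sc <- experiment_scale(scale)
  net <- default_network(seed, sc$cube_side)
  switch(name,
    sensory = {
      out <- list()
      for (kind in c("auditory", "somatosensory"))
        for (cond in c("control", "DART")) {
          run <- run_sensory(net, kind, cond, trials = sc$trials,
                             seed = seed, ...)
          out[[paste(kind, cond, sep = "_")]] <- sensory_summary(run)
        }
      out
    },
    selectivity = {
      lapply(c(control = "control", DART = "DART"), function(cond) {
        sel <- run_selectivity(net, cond, trials = sc$trials, seed = seed, ...)
        c(sel["responses"], preference_analysis(sel$responses))
      })
    },
    combined = {
      lapply(c(control = "control", DART = "DART"), function(cond)
        combined_categories(run_combined(net, cond, trials = sc$trials,
                                         seed = seed, ...)))
    },
    classification = {
      ps <- assign_classes(
        generate_patterns(net$positions$glomerulus,
                          pattern_config(0.35, 40, sc$n_patterns,
                                         seed = seed)),
        n_classes = 10, seed = seed)
      run <- run_classification(net, ps, presentations = sc$presentations,
                                condition = "control", seed = seed, ...)
      cfg <- decoder_config(mode = "fixed", epochs = min(50, sc$epochs),
                            seed = seed)
      list(grc = train_slp(run$counts$grc, run$labels, cfg)$accuracy,
           mf = train_slp(run$counts$mf, run$labels, cfg)$accuracy)
    },
    noisy_classification = {
      ps <- assign_classes(
        generate_patterns(net$positions$glomerulus,
                          pattern_config(0.55, 40, sc$n_patterns,
                                         seed = seed)),
        n_classes = 10, seed = seed)
      arms <- c("DART", "Inh+", "Inh++")
      datasets <- list()
      for (arm in arms) {
        run <- run_classification(net, ps, presentations = sc$presentations,
                                  condition = arm, noise_frac = 0.2,
                                  seed = seed, ...)
        datasets[[paste0("grc_", arm)]] <- list(X = run$counts$grc,
                                                y = run$labels)
        if (arm == arms[[1]])
          datasets$mf <- list(X = run$counts$mf, y = run$labels)
      }
      accuracy_over_seeds(datasets,
                          decoder_config(mode = "fixed", epochs = sc$epochs),
                          seeds = seq_len(sc$seeds))
    },
    metrics = {
      ps <- assign_classes(
        generate_patterns(net$positions$glomerulus,
                          pattern_config(0.55, 40, sc$n_patterns,
                                         seed = seed)),
        n_classes = 10, seed = seed)
      presets <- weight_presets()[c("DART", "Feedforward+", "Feedback+",
                                    "Combined+", "Feedforward++",
                                    "Feedback++", "Combined++")]
      rows <- lapply(names(presets), function(nm) {
        run <- run_classification(net, ps, presentations = sc$presentations,
                                  condition = presets[[nm]], noise_frac = 0.2,
                                  seed = seed, ...)
        X <- run$counts$grc
        cfg <- decoder_config(mode = "fixed", epochs = sc$epochs, seed = seed)
        data.frame(config = nm,
                   sparseness = population_sparseness(X),
                   total_variance = total_variance(X),
                   correlation = population_correlation(X),
                   overlap = pattern_overlap(X),
                   active_fraction = mean(X > 0),
                   accuracy = train_slp(X, run$labels,
                                        cfg)$accuracy[["test"]])
      })
      tab <- do.call(rbind, rows)
      list(table = tab,
           correlation_matrix = metric_accuracy_correlation(
             tab[, c("sparseness", "total_variance", "correlation",
                     "accuracy")]))
    },
    timing = {
      lapply(c(control = "Combined++", DART = "DART"), function(cond)
        run_timing(net, cond, trials = sc$trials, seed = seed, ...))
    },
    transfer = {
      ps <- assign_classes(
        generate_patterns(net$positions$glomerulus,
                          pattern_config(0.55, 40, sc$n_patterns,
                                         seed = seed)),
        n_classes = 10, seed = seed)
      ctrl <- run_classification(net, ps, presentations = sc$presentations,
                                 condition = "control", noise_frac = 0.2,
                                 seed = seed, ...)
      dart <- run_classification(net, ps, presentations = sc$presentations,
                                 condition = "DART", noise_frac = 0.2,
                                 seed = seed, ...)
      cfg <- decoder_config(mode = "fixed", epochs = sc$epochs, seed = seed)
      model <- train_slp(ctrl$counts$grc, ctrl$labels, cfg)
      list(within = model$accuracy[["test"]],
           cross = evaluate_cross_condition(model, dart$counts$grc,
                                            dart$labels, model$split$test))
    })
}
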