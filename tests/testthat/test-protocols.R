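# Protocol composition on the small fixture network: structure, windows,
# matched-trial semantics and count-matrix bookkeeping.

test_that("sensory protocols compose noise and stimulus phases correctly", {
  net <- small_net()$net
  run <- run_sensory(net, "somatosensory", "control", trials = 2, seed = 5)
  expect_s3_class(run, "grc_sensory_run")
  expect_length(run$trials, 2)
  expect_equal(run$stim_window, c(1000, 1500)) # 500 ms stimulus
  expect_equal(run$trials[[1]]$t_end, 1500)
  n_mf <- nrow(net$positions$glomerulus)
  expect_lt(abs(mean(run$pattern) - 0.35),
            max(0.005, 0.5 / n_mf) + 1e-9) # matched fraction
  aud <- run_sensory(net, "auditory", "DART", trials = 1, seed = 5)
  expect_equal(aud$stim_window, c(1000, 4000))
  # same seed, different condition: identical stimulus pattern
  aud2 <- run_sensory(net, "auditory", "control", trials = 1, seed = 5)
  expect_identical(aud$pattern, aud2$pattern)
  sm <- sensory_summary(run)
  expect_true(sm$probability_mean >= 0 && sm$probability_mean <= 1)
  expect_length(sm$probability, net$positions$grc |> nrow())
})

test_that("combined stimulation presents p1, p2 and their union", {
  net <- small_net()$net
  run <- run_combined(net, "control", trials = 2, seed = 9)
  expect_named(run$stimuli, c("p1", "p2", "comb"))
  expect_identical(run$patterns$comb,
                   pmax(run$patterns$p1, run$patterns$p2))
  # disjoint components would add their fractions exactly
  a <- c(1, 1, 0, 0, 0); b <- c(0, 0, 1, 0, 0)
  expect_equal(mean(pmax(a, b)), mean(a) + mean(b))
  cc <- combined_categories(run)
  expect_equal(sum(cc$fractions), 1)
  expect_length(cc$category, nrow(net$positions$grc))
})

test_that("selectivity runs three matched patterns through one network", {
  net <- small_net()$net
  sel <- run_selectivity(net, "DART", trials = 2, seed = 4)
  expect_equal(dim(sel$responses), c(nrow(net$positions$grc), 3))
  pats <- vapply(sel$runs, function(r) list(r$pattern), list(1))
  expect_false(identical(pats[[1]], pats[[2]]))
  pa <- preference_analysis(sel$responses)
  expect_true(all(pa$preferred %in% 1:3))
})

test_that("classification counts index samples and windows correctly", {
  fx <- small_net()
  ps <- assign_classes(fx$patterns, n_classes = 4, seed = 2)
  run <- run_classification(fx$net, ps, presentations = 2,
                            condition = "DART", seed = 6)
  n_pat <- nrow(ps$activity)
  expect_equal(nrow(run$counts$grc), 2 * n_pat)
  expect_equal(ncol(run$counts$grc), nrow(fx$net$positions$grc))
  expect_equal(ncol(run$counts$mf), nrow(fx$net$positions$glomerulus))
  expect_true(all(run$counts$grc >= 0))
  expect_equal(run$labels, ps$labels[run$pattern_index])
  expect_equal(run$window_ms, 70)
  # MF counts track the Poisson expectation over the counted window
  f_real <- mean(ps$activity)
  expected <- f_real * 50 * 0.070 # per fiber per presentation
  expect_lt(abs(mean(run$counts$mf) - expected), 4 * sqrt(expected /
    length(run$counts$mf)) + 0.01)
  # identical seeds reproduce the full count matrix
  run2 <- run_classification(fx$net, ps, presentations = 2,
                             condition = "DART", seed = 6)
  expect_identical(run$counts, run2$counts)
})

test_that("per-presentation noise keeps sample bookkeeping intact", {
  fx <- small_net()
  ps <- assign_classes(fx$patterns, n_classes = 4, seed = 2)
  run <- run_classification(fx$net, ps, presentations = 2,
                            condition = "DART", noise_frac = 0.2, seed = 6)
  expect_equal(nrow(run$counts$grc), 2 * nrow(ps$activity))
  # noise changes the drive relative to the noise-free run
  clean <- run_classification(fx$net, ps, presentations = 2,
                              condition = "DART", seed = 6)
  expect_false(identical(run$counts$mf, clean$counts$mf))
})

test_that("the timing protocol yields per-round first-spike profiles", {
  net <- small_net()$net
  tm <- run_timing(net, "Combined++", rounds = 1, trials = 2, seed = 3)
  expect_length(tm$rounds, 1)
  expect_length(tm$rounds[[1]]$first_spike, 50) # 500 ms / 10 ms bins
  expect_true(all(tm$rounds[[1]]$spike_prob >= 0 &
                    tm$rounds[[1]]$spike_prob <= 1))
  expect_lte(sum(tm$rounds[[1]]$first_spike), 1 + 1e-9)
})
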