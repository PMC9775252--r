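# Synthetic cohort generator: band limitation, coupling recovery,
# determinism.

test_that("make_narrowband_signal is band-limited with a truthful phase", {
  s <- make_narrowband_signal(500, 10, canonical_bands()$alpha, seed = 1)
  spec <- stats::spec.pgram(stats::ts(s$signal, frequency = 500),
                            taper = 0, plot = FALSE, detrend = FALSE)
  inband <- spec$freq >= 8 & spec$freq <= 13
  expect_gt(sum(spec$spec[inband]) / sum(spec$spec), 0.9)
  peak <- spec$freq[which.max(spec$spec)]
  expect_gt(peak, 8); expect_lt(peak, 13)

  # Hilbert phase of the output vs the generator's stored ground truth
  s2 <- make_narrowband_signal(500, 2, canonical_bands()$delta, seed = 7)
  rec <- eeg_recording(rbind(s2$signal), 500, "x")
  got <- instantaneous_phase(rec, edge_exclusion = 0)$phases[1, ]
  idx <- 101:900                       # exclude the edge 10% per side
  err <- Arg(exp(1i * (got[idx] - s2$phase[idx])))
  expect_lt(sqrt(mean(err^2)), 0.2)
})

test_that("make_narrowband_signal validates its inputs", {
  expect_error(make_narrowband_signal(500, 0.01, canonical_bands()$alpha),
               class = "plvnet_invalid_input")
  bad <- band_definition("hf", 100, 400)
  expect_error(make_narrowband_signal(500, 2, bad),
               class = "plvnet_invalid_band")
  s1 <- make_narrowband_signal(500, 2, canonical_bands()$theta, seed = 5)
  s2 <- make_narrowband_signal(500, 2, canonical_bands()$theta, seed = 5)
  expect_identical(s1$signal, s2$signal)
})

test_that("full coupling with no jitter or noise gives PLV 1", {
  cfg <- closure_config(kappa = 1, n_channels = 5, duration = 10)
  m <- closure_plv(cfg, subject_seed = 3)
  expect_true(all(abs(offdiag(m) - 1) < 1e-2))
})

test_that("zero coupling gives near-null PLV over 60 s", {
  for (seed in 1:3) {
    cfg <- closure_config(kappa = 0, n_channels = 5, duration = 60)
    m <- closure_plv(cfg, subject_seed = 100 + seed)
    expect_lt(max(offdiag(m)), 0.2)
  }
})

test_that("median recovered PLV increases with kappa (reduced grid)", {
  meds <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(kap) {
    vals <- unlist(lapply(1:3, function(r) {
      cfg <- closure_config(kappa = kap, n_channels = 5, duration = 60)
      offdiag(closure_plv(cfg, subject_seed = 1000 * r))
    }))
    median(vals)
  })
  expect_true(all(diff(meds) > 0))
})

test_that("coupling in delta only separates delta from alpha PLV", {
  labels <- retained_channels()[1:5]
  mk <- function(kap) {
    coupling <- list()
    for (b in c("delta", "alpha"))
      coupling[[paste("MDD", "pre", b, sep = ".")]] <-
        list(coupling_spec(if (b == "delta") kap else 0,
                           phase_jitter_sd = 0))
    simulation_config(n_per_group = 1, segment_layout = c(pre = 60),
                      channel_labels = labels,
                      bands = canonical_bands(c("delta", "alpha")),
                      band_coupling = coupling,
                      band_amplitudes = c(delta = 1, alpha = 1),
                      noise_sd = 0, seed = 2)
  }
  lr <- generate_coupled_recording(mk(0.9), "MDD", "pre", 42)
  bands <- decompose_bands(lr$recording, canonical_bands(c("delta", "alpha")))
  pd <- mean(offdiag(plv_matrix(instantaneous_phase(bands$delta, 1))$values))
  pa <- mean(offdiag(plv_matrix(instantaneous_phase(bands$alpha, 1))$values))
  expect_gte(pd - pa, 0.2)
})

test_that("generate_cohort counts, ids and determinism", {
  cfg <- tiny_cohort_config(n_per_group = 2, seed = 7,
                            layout = c(pre = 12, music = 12, post = 12),
                            n_channels = 4)
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 2 * 2 * 3)
  ids <- vapply(cohort, function(x) paste(x$subject_id, x$condition), "")
  expect_false(anyDuplicated(ids) > 0)
  expect_setequal(unique(vapply(cohort, `[[`, "", "group")), c("MDD", "HC"))

  cohort2 <- generate_cohort(cfg)
  expect_identical(cohort[["mdd01.pre"]]$recording$data,
                   cohort2[["mdd01.pre"]]$recording$data)
  expect_identical(cohort[["hc02.post"]]$recording$data,
                   cohort2[["hc02.post"]]$recording$data)

  # different subjects get different signals
  expect_false(identical(cohort[["mdd01.pre"]]$recording$data,
                         cohort[["mdd02.pre"]]$recording$data))
})

test_that("configuration validation rejects bad inputs", {
  expect_error(coupling_spec(1.2), class = "plvnet_config")
  expect_error(coupling_spec(0.5, phase_jitter_sd = -1),
               class = "plvnet_config")
  expect_error(simulation_config(n_per_group = 0), class = "plvnet_config")
  expect_error(simulation_config(sampling_rate = 50), class = "plvnet_config")
  expect_error(
    simulation_config(band_coupling = list(
      "MDD.pre.delta" = list(coupling_spec(0.5, channels = "NOPE")))),
    class = "plvnet_config")
  cfg <- closure_config(0.5)
  expect_error(generate_coupled_recording(cfg, "MDD", "post", 1),
               class = "plvnet_config")  # condition not in layout
  cfg$segment_layout <- c(pre = 60, post = 60)
  expect_error(generate_coupled_recording(cfg, "MDD", "post", 1),
               class = "plvnet_config")  # no coupling key for post
})

test_that("default coupling map covers the full grid with valid strengths", {
  bc <- default_band_coupling()
  expect_length(bc, 2 * 3 * 4)
  for (key in names(bc)) for (sp in bc[[key]]) {
    expect_s3_class(sp, "coupling_spec")
    expect_gte(sp$strength, 0); expect_lte(sp$strength, 1)
  }
  # built-in effect directions, delta: MDD pre > MDD post > HC; beta: reverse
  k <- function(key) bc[[key]][[2]]$strength   # secondary community
  expect_gt(k("MDD.pre.delta"), k("MDD.post.delta"))
  expect_gt(k("MDD.post.delta"), k("HC.pre.delta"))
  expect_lt(k("MDD.pre.beta"), k("MDD.post.beta"))
  expect_lt(k("MDD.post.beta"), k("HC.pre.beta"))
})
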