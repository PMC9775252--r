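# Hilbert phase extraction and PLV.

test_that("instantaneous phase of a cosine advances at the carrier rate", {
  fs <- 500
  t <- seq_len(10 * fs) / fs
  rec <- eeg_recording(rbind(cos(2 * pi * 10 * t)), fs, "Cz")
  ph <- instantaneous_phase(rec, edge_exclusion = 1)
  expect_s3_class(ph, "phase_series")
  expect_identical(sum(!ph$valid_mask), as.integer(2 * fs))
  step <- diff(ph$phases[1, ph$valid_mask])
  step <- Arg(exp(1i * step))          # wrap to (-pi, pi]
  err <- step - 2 * pi * 10 / fs
  expect_lt(sqrt(mean(err^2)), 0.05)
  expect_true(all(ph$phases >= -pi & ph$phases <= pi))
})

test_that("sine lags cosine by pi/2", {
  fs <- 500
  t <- seq_len(5 * fs) / fs
  rec <- eeg_recording(rbind(cos(2 * pi * 8 * t), sin(2 * pi * 8 * t)),
                       fs, c("a", "b"))
  ph <- instantaneous_phase(rec, 0.5)
  d <- Arg(exp(1i * (ph$phases[1, ] - ph$phases[2, ])))[ph$valid_mask]
  expect_lt(max(abs(d - pi / 2)), 0.05)
})

test_that("degenerate inputs are rejected", {
  rec <- eeg_recording(matrix(1, 1, 1000), 500, "a")
  expect_error(instantaneous_phase(rec, 0.1), class = "plvnet_invalid_input")
  short <- sine_recording(10, duration = 1)
  expect_error(instantaneous_phase(short, edge_exclusion = 1),
               class = "plvnet_too_short")
})

test_that("PLV anchors: synchrony, antiphase, quadrature mixture", {
  ramp <- (1:1000) * 0.01
  expect_equal(plv_from_phase_pair(ramp, ramp), 1, tolerance = 1e-12)

  alternating <- rep(c(0, pi), 500)
  expect_equal(plv_from_phase_pair(alternating, rep(0, 1000)), 0,
               tolerance = 1e-12)

  # half the samples at phase difference 0, half at pi/2:
  # |(1 + i)/2| = sqrt(2)/2, computed from the complex mean directly
  d <- rep(c(0, pi / 2), 500)
  oracle <- Mod(mean(exp(1i * d)))
  expect_equal(plv_from_phase_pair(d, rep(0, 1000)), oracle,
               tolerance = 1e-12)
  expect_equal(oracle, sqrt(2) / 2, tolerance = 1e-12)
})

test_that("PLV input validation", {
  expect_error(plv_from_phase_pair(1:5, 1:4), class = "plvnet_invalid_input")
  expect_error(plv_from_phase_pair(1:5, 1:5, mask = c(TRUE, rep(FALSE, 4))),
               class = "plvnet_invalid_input")
})

test_that("PLV is symmetric, bounded, and invariant to global phase shifts", {
  set.seed(11)
  for (r in 1:20) {
    x <- runif(200, -pi, pi)
    y <- runif(200, -pi, pi)
    v <- plv_from_phase_pair(x, y)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(plv_from_phase_pair(y, x), v, tolerance = 1e-12)
    expect_equal(plv_from_phase_pair(x + 1.234, y + 1.234), v,
                 tolerance = 1e-12)
    expect_equal(plv_from_phase_pair(x, x), 1, tolerance = 1e-12)
    # modulus of the complex-mean adjacency entry equals the PLV formula
    w <- Mod(mean(exp(1i * (x - y))))
    expect_equal(v, w, tolerance = 1e-12)
  }
})

test_that("plv_matrix has unit diagonal, symmetry and respects duplicates", {
  set.seed(12)
  p <- runif(500, -pi, pi)
  ps <- structure(list(phases = rbind(a = p, b = p, c = p),
                       valid_mask = rep(TRUE, 500),
                       channel_labels = c("a", "b", "c"),
                       sampling_rate = 100),
                  class = "phase_series")
  m <- plv_matrix(ps)
  expect_true(all(abs(m$values - 1) < 1e-12))

  q <- rbind(a = runif(500, -pi, pi), b = runif(500, -pi, pi),
             c = runif(500, -pi, pi))
  ps2 <- structure(list(phases = q, valid_mask = rep(TRUE, 500),
                        channel_labels = rownames(q), sampling_rate = 100),
                   class = "phase_series")
  m2 <- plv_matrix(ps2)
  expect_identical(diag(m2$values), c(a = 1, b = 1, c = 1))
  expect_identical(m2$values, t(m2$values))
  expect_identical(m2$n_samples, 500L)

  # permutation equivariance
  perm <- c(3, 1, 2)
  ps3 <- structure(list(phases = q[perm, ], valid_mask = rep(TRUE, 500),
                        channel_labels = rownames(q)[perm],
                        sampling_rate = 100), class = "phase_series")
  m3 <- plv_matrix(ps3)
  expect_equal(m3$values, m2$values[perm, perm], tolerance = 1e-12)
})

test_that("independent uniform phases give near-zero PLV at S = 30000", {
  set.seed(13)
  q <- matrix(runif(5 * 30000, -pi, pi), 5)
  rownames(q) <- paste0("c", 1:5)
  ps <- structure(list(phases = q, valid_mask = rep(TRUE, 30000),
                       channel_labels = rownames(q), sampling_rate = 500),
                  class = "phase_series")
  m <- plv_matrix(ps)
  expect_lt(max(offdiag(m$values)), 0.05)
})

test_that("null PLV shrinks like 1/sqrt(S)", {
  set.seed(14)
  mean_null <- function(S, reps = 200)
    mean(replicate(reps,
      plv_from_phase_pair(runif(S, -pi, pi), runif(S, -pi, pi))))
  ratio <- mean_null(500) / mean_null(1000)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 1.5)
})

test_that("cohort_connectivity yields one matrix per subject/condition/band", {
  cfg <- tiny_cohort_config(n_per_group = 1, seed = 3)
  cohort <- generate_cohort(cfg)
  mats <- cohort_connectivity(cohort)
  expect_length(mats, 1 * 2 * 2 * 4)     # subjects x groups x conds x bands
  m <- mats[[1]]
  expect_s3_class(m, "connectivity_matrix")
  expect_identical(m$channel_labels, retained_channels())
  expect_true(all(m$values >= 0 & m$values <= 1))
  # group averages: one per (group, condition, band)
  avg <- average_connectivity(mats)
  expect_length(avg, 2 * 2 * 4)
  expect_true(all(vapply(avg, function(a) is.matrix(a) && nrow(a) == 19,
                         logical(1))))
})
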