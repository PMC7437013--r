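test_that("ring-lattice construction and rewiring respect their invariants", {
  ws0 <- watts_strogatz_adjacency(12, 4, 0)
  expect_true(all(rowSums(ws0) == 4))
  expect_equal(ws0[1, 2], 1L)
  expect_equal(ws0[1, 3], 1L)
  expect_equal(ws0[1, 4], 0L)
  for (b in c(0.2, 0.8, 1)) {
    ws <- watts_strogatz_adjacency(20, 6, b, seed = round(100 * b))
    expect_equal(sum(ws) / 2, 60)                 # edge count preserved
    expect_identical(ws, t(ws))
    expect_true(all(diag(ws) == 0))
  }
  expect_error(watts_strogatz_adjacency(10, 3, 0.1), "even")
  expect_error(watts_strogatz_adjacency(10, 10, 0.1), "< n - 1")
})

test_that("generated recordings are finite, zero-mean, and reproducible", {
  adj <- watts_strogatz_adjacency(8, 4, 0.2, seed = 1)
  rec <- generate_coupled_alpha(8, 1024, 200, adj, coupling_gain = 0.8,
                                coupling_lag = 5, mixing_strength = 0.2,
                                noise_sd = 0.1, seed = 42)
  expect_true(all(is.finite(rec$data)))
  expect_lt(max(abs(colMeans(rec$data))), 1e-12)
  rec2 <- generate_coupled_alpha(8, 1024, 200, adj, coupling_gain = 0.8,
                                 coupling_lag = 5, mixing_strength = 0.2,
                                 noise_sd = 0.1, seed = 42)
  expect_identical(rec$data, rec2$data)           # bit-identical under one seed

  bad <- adj; bad[1, 2] <- 1L; bad[2, 1] <- 0L
  expect_error(generate_coupled_alpha(8, 1024, 200, bad), "symmetric")
  expect_error(generate_coupled_alpha(8, 1024, 200, adj, coupling_lag = 1024),
               "lag")
})

test_that("generated signals are band-limited to the alpha range", {
  rec <- generate_coupled_alpha(4, 4096, 200,
                                watts_strogatz_adjacency(4, 2, 0, seed = 1),
                                coupling_gain = 0.6, coupling_lag = 5,
                                seed = 7)
  sp <- welch_spectra(rec$data, 200)
  pow <- Re(sp$S[, 1, 1])
  inband <- sp$freq >= 6 & sp$freq <= 14
  expect_lt(sum(pow[!inband]) / sum(pow), 0.05)
})

test_that("uncoupled channels sit at chance coherence; duplicates at 1", {
  rec <- generate_coupled_alpha(4, 4096, 200, seed = 8)
  m <- msc(welch_spectra(rec$data, 200))
  expect_lt(max(m[upper.tri(m)]), 0.2)
  dup <- cbind(rec$data, rec$data[, 1])
  m2 <- msc(welch_spectra(dup, 200))
  expect_equal(m2[1, 5], 1, tolerance = 1e-9)
})

test_that("lagged coupling is visible to imaginary coherency on coupled pairs", {
  adj <- matrix(0L, 4, 4)
  adj[1, 2] <- adj[2, 1] <- adj[3, 4] <- adj[4, 3] <- 1L
  rec <- generate_coupled_alpha(4, 4096, 200, adj, coupling_gain = 1.5,
                                coupling_lag = 5, mixing_strength = 0,
                                noise_sd = 0, seed = 9)
  # brute-force cross-spectrum estimate on the realization
  ic <- icoh(welch_spectra(rec$data, 200))
  coupled <- c(ic[1, 2], ic[3, 4])
  uncoupled <- c(ic[1, 3], ic[1, 4], ic[2, 3], ic[2, 4])
  expect_gt(min(coupled), max(uncoupled))
})

test_that("the common rhythm raises coherence uniformly without touching power", {
  adj <- watts_strogatz_adjacency(8, 4, 0.2, seed = 2)
  r0 <- generate_coupled_alpha(8, 4096, 200, adj, coupling_gain = 0.9,
                               coupling_lag = 5, zero_lag_gain = 0.5,
                               common_frac = 0, seed = 11)
  r1 <- generate_coupled_alpha(8, 4096, 200, adj, coupling_gain = 0.9,
                               coupling_lag = 5, zero_lag_gain = 0.5,
                               common_frac = 0.5, seed = 11)
  m0 <- msc(welch_spectra(r0$data, 200))
  m1 <- msc(welch_spectra(r1$data, 200))
  expect_gt(mean_fc(m1), mean_fc(m0))
  pow0 <- mean(r0$data^2); pow1 <- mean(r1$data^2)
  expect_lt(abs(pow1 - pow0) / pow0, 0.15)        # variance-neutral swap
})

test_that("cohort generation honours counts, modes, and the seed contract", {
  spec <- cohort_spec(n_subjects = 3, n_channels = 8, n_segments = 2,
                      segment_len = 512, k = 4, mode = "linked", seed = 5)
  coh <- generate_study_cohort(spec)
  expect_length(coh$subjects, 3)
  s1 <- coh$subjects[[1]]
  expect_length(s1$segments$segments, 2)
  expect_equal(dim(s1$segments$segments[[1]]), c(512, 8))
  # linked mode ties the driver to the topology draw
  betas <- sapply(coh$subjects, `[[`, "beta")
  drivers <- sapply(coh$subjects, `[[`, "driver")
  expect_equal(cor(betas, drivers, method = "spearman"), 1, tolerance = 1e-12)

  coh2 <- generate_study_cohort(spec)
  expect_identical(coh$subjects[[2]]$segments$segments[[1]],
                   coh2$subjects[[2]]$segments$segments[[1]])
  expect_error(cohort_spec(n_channels = 8, k = 8), "k must be")
})

test_that("null mode decouples the connectivity driver from topology", {
  spec <- cohort_spec(n_subjects = 80, n_channels = 4, n_segments = 1,
                      segment_len = 64, k = 2, mode = "null",
                      lag_range = c(2L, 1L), seed = 6)
  coh <- generate_study_cohort(spec)
  betas <- sapply(coh$subjects, `[[`, "beta")
  drivers <- sapply(coh$subjects, `[[`, "driver")
  expect_lt(abs(cor(betas, drivers)), 0.3)
})

test_that("uniform-weight reference cohorts have the right moments and shape", {
  expect_length(generate_er_weight_cohort(0, 10), 0)
  cohort <- generate_er_weight_cohort(80, 30, seed = 12)
  expect_length(cohort, 80)
  for (m in cohort[1:5]) {
    expect_identical(unclass(m), t(unclass(m)))
    expect_true(all(diag(m) == 0))
  }
  w <- unlist(lapply(cohort, function(m) m[upper.tri(m)]))
  se <- sqrt(1 / 12) / sqrt(length(w))
  expect_lt(abs(mean(w) - 0.5), 3 * se)
  # reproducible
  cohort2 <- generate_er_weight_cohort(80, 30, seed = 12)
  expect_identical(unclass(cohort[[7]]), unclass(cohort2[[7]]))
})
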