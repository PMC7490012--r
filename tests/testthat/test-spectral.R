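test_that("frequency grid and cycle schedule match the analysis convention", {
  f <- morlet_freqs()
  expect_length(f, 80L)
  expect_equal(f[1], 1)
  expect_equal(f[80], 100)
  expect_true(all(diff(f) > 0))
  cyc <- morlet_cycles()
  expect_equal(cyc[1], 3)
  expect_equal(cyc[80], 10)
})

test_that("Morlet power peaks at the driving frequency and recovers amplitude", {
  fs <- 1000
  t <- (0:19999) / fs
  x <- 2 * sin(2 * pi * 10 * t)
  tf <- morlet_tf(x, fs, bin_s = 0.01)
  mean_p <- rowMeans(tf$power[, 50:1950])
  pk <- which.max(mean_p)
  expect_lt(abs(log(tf$freqs[pk] / 10)), log(morlet_freqs()[2] / morlet_freqs()[1]) * 1.5)
  expect_lt(abs(sqrt(max(tf$power)) - 2), 0.1)       # unit-gain amplitude
  expect_true(all(morlet_tf(numeric(20000), fs, bin_s = 0.01)$power == 0))
  expect_error(morlet_tf(rnorm(500), fs), class = "lfpged_validation_error")
})

test_that("binned power is an exact decimation of full-resolution power", {
  set.seed(20)
  x <- rnorm(30000)
  tf_full <- morlet_tf(x, 1000, nfft = 40960)
  tf_bin <- morlet_tf(x, 1000, bin_s = 0.01, nfft = 40960)
  samp <- tf_full$power[, seq(1, 30000, by = 10)][, seq_len(ncol(tf_bin$power))]
  expect_equal(tf_bin$power, samp, tolerance = 1e-10)
})

test_that("total Morlet power of unit white noise is stable across seeds", {
  totals <- vapply(1:8, function(s) {
    set.seed(s)
    sum(rowMeans(morlet_tf(rnorm(20000), 1000, bin_s = 0.01)$power))
  }, 0)
  expect_lt((max(totals) - min(totals)) / mean(totals), 0.10)
})

test_that("condition difference reflects stimulus-locked power changes", {
  cfg <- quick_cfg(n_trials = 6, seed = 21)
  up <- gained_component_series(cfg, 4.5, gain = 2)
  tf <- morlet_tf(up$series, up$fs, bin_s = 0.01)
  d <- tf_condition_difference(tf, up$events)
  band <- abs(log(d$freqs / 4.5)) < 0.2
  expect_gt(mean(d$diff[band, ]), 0)
  expect_gt(mean(d$diff[band, ]), 5 * abs(mean(d$diff[d$freqs > 20, ])))
  down <- gained_component_series(cfg, 4.5, gain = 0.4)
  tfd <- morlet_tf(down$series, down$fs, bin_s = 0.01)
  dd <- tf_condition_difference(tfd, down$events)
  expect_lt(mean(dd$diff[band, ]), 0)
  expect_error(tf_condition_difference(tf, up$events, modality = "gustatory"),
               class = "lfpged_validation_error")
})

test_that("shuffle z-scoring is seeded, scale invariant, and roughly N(0,1) under null", {
  cfg <- quick_cfg(n_trials = 4, seed = 22)
  nc <- generate_null_component_series(cfg)
  tf <- morlet_tf(nc$series, nc$sampling_rate_hz, bin_s = 0.01)
  z1 <- shuffle_zscore(tf, nc$events, n_shuffle = 300, seed = 5)
  z2 <- shuffle_zscore(tf, nc$events, n_shuffle = 300, seed = 5)
  expect_identical(z1$z, z2$z)
  # cells are heavily correlated (wavelet smoothing), so the across-cell
  # moments of a single session fluctuate; bands are deliberately loose
  expect_lt(abs(mean(z1$z)), 0.6)
  expect_lt(abs(sd(z1$z) - 1), 0.35)
  # multiplying the raw series by a constant leaves z untouched
  tf_scaled <- morlet_tf(5 * nc$series, nc$sampling_rate_hz, bin_s = 0.01)
  z3 <- shuffle_zscore(tf_scaled, nc$events, n_shuffle = 300, seed = 5)
  expect_equal(z3$z, z1$z, tolerance = 1e-8)
  # constant power surface: degenerate shuffles give z = 0, not NaN
  tf0 <- tf; tf0$power[] <- 1
  z0 <- shuffle_zscore(tf0, nc$events, n_shuffle = 50, seed = 5)
  expect_true(all(z0$z == 0))
})

test_that("cluster labelling matches a recursive flood-fill oracle", {
  set.seed(23)
  for (rep in 1:20) {
    mask <- matrix(runif(30 * 40) < 0.35, 30, 40)
    expect_true(same_partition(label_clusters(mask), oracle_flood_fill(mask)))
  }
})

test_that("cluster mass bookkeeping: thresholds, singletons, signs", {
  z <- matrix(0, 10, 10)
  m0 <- cluster_mass_test(fake_tf_map(z, runif(100, 1, 2)))
  expect_equal(nrow(m0$clusters), 0L)
  expect_false(m0$any_significant)
  z[4, 5] <- 3.0
  z[8, 1:3] <- -4
  m1 <- cluster_mass_test(fake_tf_map(z, runif(100, 1, 2)))
  expect_equal(sort(m1$clusters$mass), c(-12, 3))
  expect_equal(m1$clusters$n_cells[order(m1$clusters$mass)], c(3L, 1L))
  expect_true(all(m1$clusters$significant))          # null max ~2 < |mass|
  # sub-threshold cells never join a cluster
  expect_equal(sum(m1$cluster_labels > 0), 4L)
  expect_error(cluster_mass_test(fake_tf_map(z, numeric(0))),
               class = "lfpged_validation_error")
})

test_that("selectivity profiles aggregate per-frequency cluster z-values", {
  z <- matrix(0, 6, 8)
  z[2:3, 4:6] <- 3
  tfm <- cluster_mass_test(fake_tf_map(z, runif(50, 1, 2)))
  prof <- modality_selectivity_profile(list(tfm, tfm))
  expect_equal(prof$n_components, c(0, 2, 2, 0, 0, 0))
  expect_equal(prof$mean_z[2], 3)
  expect_true(all(is.na(prof$mean_z[c(1, 4:6)])))
  # no significant clusters anywhere: empty (all-NA) profile allowed
  tfn <- cluster_mass_test(fake_tf_map(matrix(0, 6, 8), runif(50, 1, 2)))
  expect_true(all(modality_selectivity_profile(list(tfn))$n_components == 0))
})

test_that("modality comparison honors alpha under the null and finds separations", {
  set.seed(24)
  freqs <- 1:6
  a <- matrix(rnorm(40 * 6), 40)
  b <- matrix(rnorm(40 * 6), 40)
  nullcmp <- compare_modalities(a, b, freqs)
  expect_true(all(nullcmp$p > 1e-4, na.rm = TRUE))
  b2 <- b; b2[, 3] <- b2[, 3] + 3
  cmp <- compare_modalities(a, b2, freqs)
  expect_true(cmp$significant[3])
  expect_false(any(cmp$significant[-3]))
  # frequencies with < 2 contributing components are skipped
  a_na <- a; a_na[2:40, 5] <- NA
  expect_true(is.na(compare_modalities(a_na, b, freqs)$p[5]))
})

test_that("spectral profiles expose planted rhythms and PCA degeneracy", {
  fs <- 1000
  t <- (0:29999) / fs
  set.seed(25)
  mk <- function(f) cos(2 * pi * f * t) + 0.5 * rnorm(30000)
  out <- spectral_profiles_and_pca(
    list(list(mk(7), mk(7), mk(7)), list(mk(38), mk(38))), fs)
  expect_equal(length(out$groups), 2L)
  sp1 <- colMeans(out$groups[[1]]$spectra)
  sp2 <- colMeans(out$groups[[2]]$spectra)
  expect_lt(abs(log(out$freqs[which.max(sp1)] / 7)), 0.1)
  expect_lt(abs(log(out$freqs[which.max(sp2)] / 38)), 0.1)
  expect_equal(sum(out$groups[[1]]$spectra[1, ]), 1, tolerance = 1e-10)
  ev <- out$groups[[1]]$explained_variance
  expect_true(all(diff(ev) <= 1e-12))
  expect_true(all(ev >= 0 & ev <= 1))
  # duplicated component: first PC explains everything
  x <- mk(10)
  dup <- spectral_profiles_and_pca(list(list(x, x, x)), fs)
  expect_equal(dup$groups[[1]]$explained_variance[1], 1)
  expect_warning(spectral_profiles_and_pca(list(list(x)), fs), "skipped")
})
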