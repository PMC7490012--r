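test_that("trial covariance matches direct computation and handles edge cases", {
  set.seed(1)
  seg <- matrix(rnorm(12), 3, 4)
  expect_equal(trial_covariance(seg), cov(t(seg)))   # independent route
  expect_true(all(trial_covariance(matrix(5, 3, 10)) == 0))
  s <- rnorm(100); s <- s - mean(s)
  cc <- trial_covariance(rbind(s, s))
  expect_equal(cc, matrix(var(s), 2, 2), ignore_attr = TRUE)
  expect_error(trial_covariance(matrix(1, 2, 1)), class = "lfpged_validation_error")
  # explicit centering vector
  ctr <- c(1, 2, 3)
  expect_equal(trial_covariance(seg, ctr),
               tcrossprod(seg - ctr) / 3)
  expect_error(trial_covariance(seg, 1:2), class = "lfpged_validation_error")
})

test_that("covariance pair averages per-trial matrices and keeps the stacks", {
  seg <- matrix(rnorm(2 * 40), 2)
  ep <- list(stimulus = list(seg, seg, seg), baseline = list(seg, seg, seg),
             trial_means = NULL)
  p <- build_cov_pair(ep)
  expect_equal(p$S, trial_covariance(seg))
  expect_equal(p$S, p$R)
  expect_equal(dim(p$S_trials), c(2L, 2L, 3L))
  expect_error(build_cov_pair(list(stimulus = list(seg), baseline = list(seg))),
               class = "lfpged_validation_error")
  expect_error(build_cov_pair(list(stimulus = list(seg, seg),
                                   baseline = list(seg))),
               class = "lfpged_validation_error")
})

test_that("GED identities: S = R gives lambda 1; diagonal case; S = 2R", {
  set.seed(2)
  S <- random_spd(6)
  g <- compute_ged(S, S)
  expect_lt(max(abs(g$values - 1)), 1e-8)
  g2 <- compute_ged(diag(c(4, 1)), diag(2))
  expect_equal(g2$values, c(4, 1))
  expect_equal(abs(g2$vectors), diag(2), tolerance = 1e-10)
  g3 <- compute_ged(2 * S, S)
  expect_lt(max(abs(g3$values - 2)), 1e-8)
})

test_that("GED agrees with an independent eigensolver on random SPD pairs", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(2:16, 1)
    S <- random_spd(n); R <- random_spd(n)
    g <- compute_ged(S, R)
    o <- oracle_ged(S, R)
    expect_equal(g$values, o$values, tolerance = 1e-8)
    # eigenvectors match up to the shared sign convention
    for (k in seq_len(n)) {
      expect_gt(abs(sum(g$vectors[, k] * o$vectors[, k])), 1 - 1e-6)
    }
    # Rayleigh identity at 1e-8 relative tolerance
    rq <- vapply(seq_len(n), function(k) {
      w <- g$vectors[, k]
      drop(w %*% S %*% w) / drop(w %*% R %*% w)
    }, 0)
    expect_equal(rq, g$values, tolerance = 1e-8)
  }
})

test_that("GED is scale invariant and validates its inputs", {
  set.seed(4)
  S <- random_spd(5); R <- random_spd(5)
  a <- compute_ged(S, R); b <- compute_ged(7 * S, 7 * R)
  expect_equal(a$values, b$values, tolerance = 1e-10)
  expect_equal(a$vectors, b$vectors, tolerance = 1e-8)
  Sx <- S; Sx[1, 2] <- Sx[1, 2] + 1
  expect_error(compute_ged(Sx, R), class = "lfpged_validation_error")
  expect_error(compute_ged(S, R[1:4, 1:4]), class = "lfpged_validation_error")
  # singular R without shrinkage errors with guidance; shrinkage rescues
  Rsing <- tcrossprod(matrix(rnorm(10), 5, 2))
  expect_error(compute_ged(S, Rsing), class = "lfpged_numeric_error")
  expect_s3_class(compute_ged(S, Rsing, shrinkage = 1e-4), "ged_result")
})

test_that("permutation test finds nothing in permutation-invariant data", {
  set.seed(5)
  segs <- lapply(1:8, function(i) matrix(rnorm(4 * 60), 4))
  ep <- list(stimulus = segs, baseline = segs, trial_means = NULL)
  p <- build_cov_pair(ep)
  r <- permutation_significance(p, n_perm = 200, seed = 1, shrinkage = 1e-6)
  expect_false(any(r$significant))
  expect_lt(max(abs(r$values - 1)), 1e-6)
  expect_warning(permutation_significance(p, n_perm = 50, seed = 1),
                 "unstable")
})

test_that("permutation test is deterministic given a seed and detects a gain", {
  cfg <- sim_config(n_trials_per_modality = 10, seed = 6)
  gt <- default_ground_truth(cfg, n_sources = 1, gains = matrix(3, 1, 3))
  sim <- generate_session(cfg, gt)
  p <- build_cov_pair(epoch_trials(common_average_reference(sim$session)))
  r1 <- permutation_significance(p, seed = 99)
  r2 <- permutation_significance(p, seed = 99)
  expect_identical(r1$null_eigenvalues, r2$null_eigenvalues)
  expect_true(r1$significant[1])
  # max-statistic mode uses the permuted top eigenvalue as every rank's null
  rmax <- permutation_significance(p, seed = 99, mode = "max")
  expect_true(all(rmax$null_threshold == rmax$null_threshold[1]))
  expect_true(rmax$significant[1])
})

test_that("component maps and time series follow the linear algebra", {
  set.seed(7)
  S <- diag(c(3, 2, 1))
  expect_equal(component_map(S, c(1, 0, 0)), c(3, 0, 0))
  expect_error(component_map(S, c(1, 0)), class = "lfpged_validation_error")
  X <- matrix(rnorm(3 * 50), 3)
  w <- c(0.2, -0.5, 1)
  expect_equal(component_timeseries(w, X), drop(w %*% X))
  W <- cbind(w, c(1, 0, 0))
  expect_equal(dim(component_timeseries(W, X)), c(2L, 50L))
  expect_error(component_timeseries(c(1, 2), X), class = "lfpged_validation_error")
  # variance ratio of component time series computed from the averaged
  # covariances equals the eigenvalue
  Sp <- random_spd(4); Rp <- random_spd(4)
  g <- compute_ged(Sp, Rp)
  for (k in 1:4) {
    w <- g$vectors[, k]
    expect_equal(drop(w %*% Sp %*% w) / drop(w %*% Rp %*% w), g$values[k],
                 tolerance = 1e-8)
  }
})

test_that("contact-subset runs bound the component count and drop lost sources", {
  cfg <- sim_config(n_trials_per_modality = 8, seed = 8)
  # source confined to the last four contacts
  mixing <- matrix(0, 16, 1); mixing[13:16, 1] <- 1
  gt <- ground_truth(mixing, 7, matrix(3, 1, 3,
                                       dimnames = list(NULL, c("visual", "tactile", "auditory"))),
                     contact_labels = rep("basal", 16),
                     boundary_flags = rep(FALSE, 16))
  sim <- generate_session(cfg, gt)
  # raw (unreferenced) session: the common average would leak a fraction of
  # the planted source into every contact and defeat the masking
  raw <- sim$session
  full <- run_ged_on_subset(raw, seed = 11)
  expect_true(full$significant[1])
  masked <- run_ged_on_subset(raw, contact_mask = rep(c(TRUE, FALSE), c(12, 4)),
                              seed = 11)
  expect_lte(length(masked$values), 12L)
  expect_false(any(masked$significant))
  expect_error(run_ged_on_subset(ref, contact_mask = rep(c(TRUE, FALSE), c(1, 15))),
               class = "lfpged_validation_error")
})
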