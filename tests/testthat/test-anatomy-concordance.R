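test_that("changepoint detection localizes noiseless steps and constants", {
  cp <- detect_changepoints(c(0, 0, 0, 5, 5, 5))
  expect_equal(cp$changepoints, 3L)
  expect_equal(cp$segment_means, c(0, 5))
  expect_equal(cp$segments, rep(1:2, each = 3))
  expect_length(detect_changepoints(rep(2.5, 10))$changepoints, 0L)
  expect_error(detect_changepoints(c(1, NA, 2)), class = "lfpged_validation_error")
  expect_error(detect_changepoints(1), class = "lfpged_validation_error")
})

test_that("penalized segmentation equals exhaustive enumeration", {
  set.seed(10)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    x <- rnorm(n, sd = sample(c(0.05, 0.2, 1), 1))
    pen <- sample(c(0.01, 0.05, 0.3), 1)
    got <- detect_changepoints(x, pen)
    want <- oracle_segment(x, pen)
    expect_equal(got$changepoints, want$changepoints)
    expect_equal(got$cost, want$cost, tolerance = 1e-10)
  }
})

test_that("raising the penalty never adds changepoints", {
  set.seed(11)
  for (rep in 1:15) {
    x <- rnorm(12)
    ns <- vapply(c(0.01, 0.05, 0.2, 1), function(p)
      length(detect_changepoints(x, p)$changepoints), 0L)
    expect_true(all(diff(ns) <= 0L))
  }
})

test_that("matching rules reproduce the worked 4/3 split example", {
  # seven same-nucleus contacts split into groups of 4 and 3: only the
  # 4-contact group counts as matching
  ann <- flat_annotations(rep("basal", 7))
  m <- count_matching_contacts(c(1, 1, 1, 1, 2, 2, 2), ann)
  expect_equal(m$n_matching, 4L)
  expect_equal(m$n_evaluated, 7L)
})

test_that("perfect boundary alignment gives 100% overlap; exclusions drop out", {
  ann <- flat_annotations(rep(c("lateral", "basal", "central"), c(4, 5, 3)))
  seg <- rep(1:3, c(4, 5, 3))
  m <- count_matching_contacts(seg, ann)
  expect_equal(m$percent, 100)
  # boundary-flagged and out-of-structure contacts count in neither total
  ann$boundary[4:5] <- TRUE
  ann$in_structure[12] <- FALSE
  m2 <- count_matching_contacts(seg, ann)
  expect_equal(m2$n_evaluated, 9L)
  expect_equal(m2$n_matching, 9L)
  expect_true(all(is.na(m2$matching[c(4, 5, 12)])))
})

test_that("matching count is invariant to nucleus relabeling", {
  set.seed(12)
  for (rep in 1:10) {
    nuc <- sample(c("a", "b", "c"), 10, replace = TRUE)
    seg <- cumsum(c(1, sample(c(0, 1), 9, replace = TRUE)))
    ann <- flat_annotations(nuc)
    relab <- c(a = "x", b = "y", c = "z")[nuc]
    expect_equal(count_matching_contacts(seg, ann)$n_matching,
                 count_matching_contacts(seg, flat_annotations(relab))$n_matching)
  }
})

test_that("matching rules agree with an independent segment-first oracle", {
  set.seed(13)
  for (rep in 1:100) {
    n <- 10L
    nuc <- rep(letters[1:4], times = c(rmultinom(1, n - 4, rep(1, 4)) + 1))[1:n]
    seg <- cumsum(c(1, sample(c(0, 1), n - 1, replace = TRUE, prob = c(.6, .4))))
    ann <- flat_annotations(nuc)
    ann$boundary[sample(n, sample(0:2, 1))] <- TRUE
    m <- count_matching_contacts(seg, ann)
    expect_equal(m$n_matching, oracle_match_count(seg, ann))
  }
})

test_that("cut-and-shift null is degenerate for structureless maps", {
  ann <- flat_annotations(rep(c("a", "b"), c(4, 4)))
  counts <- cut_and_shift_null(rep(1, 8), ann, n = 50, seed = 1)
  obs <- count_matching_contacts(detect_changepoints(rep(1, 8))$segments, ann)
  expect_true(all(counts == obs$n_matching))
})

test_that("Monte-Carlo cut-and-shift mean matches exhaustive enumeration", {
  set.seed(14)
  map <- rnorm(8, sd = 1)
  ann <- flat_annotations(rep(c("a", "b", "c"), c(3, 3, 2)))
  exhaustive <- vapply(1:7, function(s) {
    shifted <- c(map[(s + 1):8], map[1:s])
    count_matching_contacts(detect_changepoints(shifted)$segments, ann)$n_matching
  }, 0L)
  mc <- cut_and_shift_null(map, ann, n = 2000, seed = 2)
  se <- sd(exhaustive) / sqrt(2000) * 3 + 0.05
  expect_lt(abs(mean(mc) - mean(exhaustive)), max(3 * sd(mc) / sqrt(2000), 0.08))
  expect_true(all(mc %in% exhaustive))   # value multiset preserved per shift
})

test_that("rank-group test behaves under null, offset, and degenerate input", {
  obs <- list(c(5, 6, 7, 8))
  nul <- list(c(5, 6, 7, 8))
  r <- rank_group_test(obs, nul, n_comparisons = 5)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$alpha_adjusted, 0.01)
  # near-constant positive offset: t > 0 and p shrinks with group size
  set.seed(15)
  base <- rnorm(12, 5)
  jit <- rnorm(12, 0, 0.05)
  small <- rank_group_test(list(base[1:4] + 1 + jit[1:4]), list(base[1:4]))
  big <- rank_group_test(list(base + 1 + jit), list(base))
  expect_gt(small$t, 0)
  expect_lt(big$p, small$p)
  # exactly constant offset: degenerate paired test reports p = 0
  const <- rank_group_test(list(base[1:4] + 1), list(base[1:4] + 0))
  expect_equal(const$p, 0)
  expect_warning(rank_group_test(list(1), list(1)), "fewer than 2")
  expect_error(rank_group_test(list(1:3), list(1:2)),
               class = "lfpged_validation_error")
})

test_that("anatomy-aligned components beat the cut-and-shift null (positive control)", {
  # scaled-down concordance power study: a planted source whose projection
  # steps at every nucleus boundary, so the rank-1 map mirrors the anatomy
  run_once <- function(seed) {
    cfg <- sim_config(n_trials_per_modality = 5, seed = seed)
    mixing <- matrix(0, 16, 1)
    mixing[3:6] <- 3; mixing[7:10] <- 2; mixing[11:13] <- 1
    gt <- ground_truth(mixing, 7,
                       matrix(3, 1, 3, dimnames = list(NULL, c("visual", "tactile", "auditory"))),
                       contact_labels = rep(c("outside", "lateral", "basal",
                                              "accessory basal", "central"), c(2, 4, 4, 3, 3)),
                       boundary_flags = rep(c(FALSE, TRUE, TRUE, FALSE), c(5, 1, 1, 9)))
    sim <- generate_session(cfg, gt)
    ref <- common_average_reference(sim$session)
    p <- build_cov_pair(epoch_trials(ref))
    g <- compute_ged(p$S, p$R, shrinkage = 1e-6)
    m <- drop(p$S %*% g$vectors[, 1])
    m <- m / sd(m)            # the pipeline's pre-segmentation normalization
    cc <- component_concordance(m, sim$session$annotations, n_perm = 200,
                                seed = seed + 1)
    c(cc$match$n_matching, cc$null_mean)
  }
  res <- vapply(1:6, run_once, numeric(2))
  test <- rank_group_test(list(res[1, ]), list(res[2, ]), n_comparisons = 5)
  expect_gt(test$t, 0)
  expect_lt(test$p, 0.01)
})
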