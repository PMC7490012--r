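#' Analysis configuration for the full session pipeline
#'
#' One versioned document holding every statistical parameter of the
#' pipeline, echoed into each report so thresholds stay auditable.
#'
#' @param n_perm GED permutations (default 500).
#' @param percentile GED null percentile (default 99).
#' @param null_mode `"rank"` or `"max"` eigenvalue null (see
#'   [permutation_significance()]).
#' @param shrinkage covariance shrinkage gamma (default 1e-6; needed for
#'   rank-deficient common-average-referenced data).
#' @param screen_alpha family-wise alpha of the per-contact responsiveness
#'   screen before Bonferroni division (default 0.01).
#' @param changepoint_penalty additive per-changepoint penalty (default 0.05).
#' @param concordance_n_perm cut-and-shift permutations (default 1000).
#' @param tf_n_shuffle time-frequency shuffles (default 1000).
#' @param tf_jitter_s window-start jitter (default 0.5 s).
#' @param tf_threshold cluster-forming |z| threshold (default 2.33).
#' @param tf_bin_s time-bin width for TF statistics (default 0.01 s).
#' @param cluster_percentile max-cluster-mass percentile (default 99).
#' @param baseline_window,stimulus_window epoch windows, seconds.
#' @param run_tf,run_concordance,run_spectra stage switches.
#' @param seed master seed; stage seeds are derived deterministically.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_perm = 500L, percentile = 99,
                            null_mode = "rank", shrinkage = 1e-6,
                            screen_alpha = 0.01,
                            changepoint_penalty = 0.05,
                            concordance_n_perm = 1000L,
                            tf_n_shuffle = 1000L, tf_jitter_s = 0.5,
                            tf_threshold = 2.33, tf_bin_s = 0.01,
                            cluster_percentile = 99,
                            baseline_window = c(-1.5, -1.0),
                            stimulus_window = c(0, 1.0),
                            run_tf = TRUE, run_concordance = TRUE,
                            run_spectra = TRUE, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

stage_seed <- function(config, offset) {
  (as.integer(config$seed) + offset) %% .Machine$integer.max
}

#' Run the full analysis pipeline on one session
#'
#' Executes reference -> epoch -> responsiveness screen -> covariance pair ->
#' GED -> permutation significance -> component maps and time series ->
#' anatomical concordance -> time-frequency cluster statistics -> spectral
#' profiles, for the full probe and again for the in-structure contact
#' subset. Deterministic given `config$seed`.
#'
#' @param session an `lfp_session`.
#' @param config a [pipeline_config()].
#' @param session_id label stored in the report.
#' @return an object of class `session_report`; see details. Key fields:
#'   `screen` (per-contact responsiveness), `ged` / `ged_in_structure`
#'   (ged_results with maps), `n_significant`, `n_significant_in_structure`,
#'   `concordance` (per significant component), `tf` (per significant
#'   component, per modality, cluster-tested), `spectra` (unit-power spectra
#'   per significant component), `config`.
#' @export
run_session <- function(session, config = pipeline_config(), session_id = "session") {
  validate_session(session)
  ref <- common_average_reference(session)
  epochs <- epoch_trials(ref, config$baseline_window, config$stimulus_window)
  screen <- screen_contact_responsiveness(epochs, alpha = config$screen_alpha)

  ged <- run_ged_on_subset(ref, NULL, n_perm = config$n_perm,
                           percentile = config$percentile,
                           seed = stage_seed(config, 1L),
                           mode = config$null_mode, shrinkage = config$shrinkage,
                           baseline_window = config$baseline_window,
                           stimulus_window = config$stimulus_window)
  in_mask <- session$annotations$in_structure
  ged_in <- if (sum(in_mask) >= 2L && any(!in_mask)) {
    run_ged_on_subset(ref, in_mask, n_perm = config$n_perm,
                      percentile = config$percentile,
                      seed = stage_seed(config, 2L),
                      mode = config$null_mode, shrinkage = config$shrinkage,
                      baseline_window = config$baseline_window,
                      stimulus_window = config$stimulus_window)
  } else ged

  sig <- which(ged$significant)
  concordance <- NULL
  if (config$run_concordance && length(sig) > 0L) {
    concordance <- lapply(seq_along(sig), function(j) {
      k <- sig[j]
      # unit-variance map: the fixed penalty then rejects steps below ~0.2 SD
      # regardless of the covariance scale
      m <- ged$maps[, k]; m <- m / sd(m)
      cc <- component_concordance(m, session$annotations,
                                  penalty = config$changepoint_penalty,
                                  n_perm = config$concordance_n_perm,
                                  seed = stage_seed(config, 100L + k))
      cc$rank <- j
      cc
    })
  }

  tf_results <- NULL
  spectra <- NULL
  if ((config$run_tf || config$run_spectra) && length(sig) > 0L) {
    series <- component_timeseries(ged$vectors[, sig, drop = FALSE], ref$lfp)
    series <- matrix(series, nrow = length(sig))
    if (config$run_tf) {
      tf_results <- lapply(seq_along(sig), function(j) {
        tfp <- morlet_tf(series[j, ], ref$sampling_rate_hz,
                         bin_s = config$tf_bin_s)
        per_mod <- lapply(MODALITIES, function(m) {
          if (sum(ref$events$modality == m) == 0L) return(NULL)
          zm <- shuffle_zscore(tfp, ref$events, modality = m,
                               n_shuffle = config$tf_n_shuffle,
                               jitter_s = config$tf_jitter_s,
                               threshold = config$tf_threshold,
                               baseline_window = config$baseline_window,
                               stimulus_window = config$stimulus_window,
                               seed = stage_seed(config, 1000L + 10L * sig[j] +
                                                   match(m, MODALITIES)))
          cluster_mass_test(zm, percentile = config$cluster_percentile)
        })
        names(per_mod) <- MODALITIES
        per_mod
      })
    }
    if (config$run_spectra) {
      spectra <- t(apply(series, 1L, function(x) {
        p <- rowMeans(morlet_tf(x, ref$sampling_rate_hz)$power)
        p / sum(p)
      }))
    }
  }

  structure(list(
    session_id = session_id,
    n_contacts = nrow(session$lfp),
    n_trials = nrow(epochs$events),
    screen = screen,
    ged = ged,
    ged_in_structure = ged_in,
    n_significant = sum(ged$significant),
    n_significant_in_structure = sum(ged_in$significant),
    significant_ranks = sig,
    concordance = concordance,
    tf = tf_results,
    spectra = spectra,
    freqs = morlet_freqs(),
    config = config
  ), class = "session_report")
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %s: %d contacts, %d trials\n", x$session_id,
              x$n_contacts, x$n_trials))
  cat(sprintf("  responsive contacts: %d/%d\n", sum(x$screen$significant),
              nrow(x$screen)))
  cat(sprintf("  significant components: %d (all contacts), %d (in structure)\n",
              x$n_significant, x$n_significant_in_structure))
  invisible(x)
}

#' Modality-specific GED reruns
#'
#' Subsets the trials of each sensory modality and reruns the identical
#' covariance -> GED -> permutation chain on each subset.
#'
#' @param session an `lfp_session` (re-referenced internally).
#' @param config a [pipeline_config()].
#' @return named list (visual/tactile/auditory) of `ged_result`s; modalities
#'   with fewer than 2 trials are skipped with a warning (NULL entry).
#' @export
run_modality_specific <- function(session, config = pipeline_config()) {
  validate_session(session)
  ref <- common_average_reference(session)
  out <- lapply(MODALITIES, function(m) {
    sub <- ref
    sub$events <- ref$events[ref$events$modality == m, , drop = FALSE]
    if (nrow(sub$events) < 2L) {
      warning("modality '", m, "' has fewer than 2 trials; skipped")
      return(NULL)
    }
    run_ged_on_subset(sub, NULL, n_perm = config$n_perm,
                      percentile = config$percentile,
                      seed = stage_seed(config, 10L + match(m, MODALITIES)),
                      mode = config$null_mode, shrinkage = config$shrinkage,
                      baseline_window = config$baseline_window,
                      stimulus_window = config$stimulus_window)
  })
  names(out) <- MODALITIES
  out
}

#' Correlate all-trials component maps with modality-specific maps
#'
#' Pearson correlation over contact weights for every (all-trials component,
#' modality-specific component) pair, after the shared sign convention.
#'
#' @param all_maps contacts x components matrix of all-trials maps.
#' @param modality_maps contacts x components matrix from one
#'   modality-specific rerun.
#' @return long-format data.frame: `all_component`, `modality_component`,
#'   `r`.
#' @export
correlate_maps <- function(all_maps, modality_maps) {
  all_maps <- as.matrix(all_maps); modality_maps <- as.matrix(modality_maps)
  if (nrow(all_maps) != nrow(modality_maps))
    stop_validation("maps computed over different contact sets")
  r <- cor(all_maps, modality_maps)
  data.frame(
    all_component = rep(seq_len(ncol(all_maps)), times = ncol(modality_maps)),
    modality_component = rep(seq_len(ncol(modality_maps)), each = ncol(all_maps)),
    r = as.vector(r)
  )
}

#' Chi-square comparison of per-modality component counts
#'
#' Goodness-of-fit of the significant-component counts per modality against
#' equal expected counts: chi2 = sum (O - E)^2 / E with E the mean count and
#' df = k - 1.
#'
#' @param counts named or unnamed non-negative integer vector (one entry per
#'   modality).
#' @return list with `chi2`, `df`, `p`.
#' @export
compare_component_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop_validation("need counts for >= 2 categories")
  if (any(counts < 0)) stop_validation("counts must be non-negative")
  if (sum(counts) == 0) stop_validation("all counts are zero")
  e <- mean(counts)
  chi2 <- sum((counts - e)^2 / e)
  df <- length(counts) - 1L
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Aggregate session reports
#'
#' Cross-session summary: histograms of significant-component counts (full
#' probe and in-structure-only), the pooled rank-wise concordance t-tests,
#' and the pooled spectral-profile PCA per rank group.
#'
#' @param reports list of `session_report`s.
#' @param max_rank deepest component rank pooled (default 5, matching the
#'   five rank comparisons of the concordance test).
#' @return list: `component_count_histogram`,
#'   `component_count_histogram_in_structure` (tables),
#'   `concordance_tests` (data.frame from [rank_group_test()], NULL if no
#'   session ran concordance), `spectral_pca` (per rank group, NULL without
#'   spectra).
#' @export
aggregate_sessions <- function(reports, max_rank = 5L) {
  if (length(reports) == 0L) stop_validation("no reports to aggregate")
  n_sig <- vapply(reports, function(r) r$n_significant, 0L)
  n_sig_in <- vapply(reports, function(r) r$n_significant_in_structure, 0L)

  obs_by_rank <- vector("list", max_rank)
  null_by_rank <- vector("list", max_rank)
  for (r in reports) {
    for (cc in r$concordance %||% list()) {
      if (cc$rank > max_rank) next
      obs_by_rank[[cc$rank]] <- c(obs_by_rank[[cc$rank]], cc$match$n_matching)
      null_by_rank[[cc$rank]] <- c(null_by_rank[[cc$rank]], cc$null_mean)
    }
  }
  ranks_present <- which(lengths(obs_by_rank) >= 2L)
  conc_tests <- if (length(ranks_present)) {
    tests <- suppressWarnings(
      rank_group_test(obs_by_rank, null_by_rank))
    tests
  } else NULL

  spectra_by_rank <- vector("list", max_rank)
  for (r in reports) {
    if (is.null(r$spectra)) next
    for (j in seq_len(min(nrow(r$spectra), max_rank))) {
      spectra_by_rank[[j]] <- rbind(spectra_by_rank[[j]], r$spectra[j, ])
    }
  }
  spectral_pca <- lapply(spectra_by_rank, function(m) {
    if (is.null(m) || nrow(m) < 2L) return(NULL)
    pca <- prcomp(m, center = TRUE, scale. = FALSE)
    list(loadings = pca$rotation,
         explained_variance = pca$sdev^2 / sum(pca$sdev^2))
  })

  list(component_count_histogram = table(factor(n_sig, levels = 0:max(n_sig, 1))),
       component_count_histogram_in_structure =
         table(factor(n_sig_in, levels = 0:max(n_sig_in, 1))),
       concordance_tests = conc_tests,
       spectral_pca = spectral_pca,
       n_sessions = length(reports))
}
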