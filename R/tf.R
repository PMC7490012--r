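#' Morlet frequency grid and cycle schedule
#'
#' The analysis grid is 80 logarithmically spaced frequencies from 1 to
#' 100 Hz. The number of wavelet cycles rises logarithmically from 3 at the
#' lowest to 10 at the highest frequency, trading temporal for spectral
#' resolution in the usual way.
#'
#' @param n number of frequencies.
#' @param fmin,fmax grid endpoints, Hz.
#' @return numeric vector of frequencies (Hz) / cycle counts.
#' @export
morlet_freqs <- function(n = 80L, fmin = 1, fmax = 100) {
  exp(seq(log(fmin), log(fmax), length.out = n))
}

#' @rdname morlet_freqs
#' @param cmin,cmax cycle counts at `fmin` and `fmax`.
#' @export
morlet_cycles <- function(n = 80L, cmin = 3, cmax = 10) {
  exp(seq(log(cmin), log(cmax), length.out = n))
}

#' Morlet wavelet time-frequency power
#'
#' Convolves a (component) time series with complex Morlet wavelets via the
#' FFT: the analytic wavelet at frequency f has a Gaussian spectrum of width
#' set by `n_cycles`, with peak gain 2 so a pure sinusoid's amplitude is
#' recovered in the magnitude. Power is the squared magnitude. Optionally the
#' power is averaged within consecutive time bins (`bin_s`), which is how the
#' cluster statistics consume it. Samples within one wavelet half-width
#' (3 temporal SDs) of either edge are counted in `edge_bins` per frequency.
#'
#' @param series numeric vector.
#' @param fs sampling rate, Hz.
#' @param freqs frequency grid (default [morlet_freqs()]).
#' @param n_cycles per-frequency cycle counts (default [morlet_cycles()]).
#' @param bin_s bin width in seconds for time-decimated power, or `NULL` for
#'   full resolution. Binned power is the squared magnitude of the analytic
#'   wavelet signal sampled once per bin, computed exactly by folding the
#'   product spectrum and taking a short inverse FFT (decimating a signal in
#'   time aliases its spectrum; the magnitude is untouched because the
#'   wavelet output is analytic and narrowband).
#' @return object of class `tf_power`: `power` (frequencies x time bins),
#'   `freqs`, `fs`, `bin_s`, `bin_hz` (bins per second), `edge_bins`
#'   (per-frequency count of edge-contaminated bins at each end).
#' @export
morlet_tf <- function(series, fs, freqs = morlet_freqs(),
                      n_cycles = morlet_cycles(length(freqs)), bin_s = NULL,
                      nfft = NULL) {
  n <- length(series)
  if (length(n_cycles) != length(freqs))
    stop_validation("n_cycles must have one entry per frequency")
  sigma_t <- n_cycles / (2 * pi * freqs)
  widest <- max(6 * sigma_t) * fs
  if (n <= widest)
    stop_validation("series (", n, " samples) shorter than the widest wavelet (",
                    ceiling(widest), " samples)")
  bin_n <- if (is.null(bin_s)) 1L else max(1L, round(bin_s * fs))
  # FFT length: a multiple of the decimation factor with power-of-2 quotient
  if (is.null(nfft))
    nfft <- bin_n * 2^ceiling(log2((n + ceiling(widest)) / bin_n))
  nfft <- as.integer(nfft)
  if (nfft < n || nfft %% bin_n != 0L)
    stop_validation("nfft must be >= series length and a multiple of the bin size")
  m <- nfft %/% bin_n
  X <- fft(c(series, numeric(nfft - n)))
  n_bins <- n %/% bin_n
  half <- nfft %/% 2L
  omega_pos <- 2 * pi * fs * (0:half) / nfft           # rad/s, >= 0 bins only
  power <- matrix(0, length(freqs), n_bins)
  for (i in seq_along(freqs)) {
    w0 <- 2 * pi * freqs[i]
    # Gaussian support truncation: the wavelet spectrum is negligible
    # outside +/- 7 sigma_omega of the center frequency
    s_om <- 1 / sigma_t[i]
    kband <- which(abs(omega_pos - w0) <= 7 * s_om)    # 1-based bin indices
    vals <- X[kband] * (2 * exp(-0.5 * sigma_t[i]^2 * (omega_pos[kband] - w0)^2))
    # fold the band into the decimated spectrum: r = (k-1) mod m; within any
    # m consecutive bins the fold targets are distinct, so chunk the band
    folded <- complex(length.out = m)
    kk <- kband - 1L
    start <- 1L
    while (start <= length(kk)) {
      end <- min(length(kk), start + m - 1L)
      idx <- (kk[start:end] %% m) + 1L
      folded[idx] <- folded[idx] + vals[start:end]
      start <- end + 1L
    }
    y <- fft(folded, inverse = TRUE)[seq_len(n_bins)] / nfft
    power[i, ] <- Mod(y)^2
  }
  edge <- ceiling(3 * sigma_t * fs / bin_n)
  structure(list(power = power, freqs = freqs, fs = fs,
                 bin_s = bin_n / fs,
                 bin_hz = fs / bin_n, edge_bins = edge,
                 n_cycles = n_cycles),
            class = "tf_power")
}

window_bins <- function(tf, onset_s, window) {
  start <- floor((onset_s + window[1]) * tf$bin_hz)      # 0-based bin index
  len <- round((window[2] - window[1]) * tf$bin_hz)
  list(start = as.integer(start), len = as.integer(len))
}

select_trials <- function(events, modality) {
  if (is.null(modality)) return(events)
  ev <- events[events$modality == modality, , drop = FALSE]
  if (nrow(ev) == 0L) stop_validation("no trials for modality '", modality, "'")
  ev
}

#' Raw stimulus-minus-baseline time-frequency difference
#'
#' Averages the time-frequency power over the stimulus windows of the
#' selected trials (time-resolved) and subtracts the per-frequency power
#' averaged over the baseline windows (time-averaged, since the baseline
#' window is half the length of the stimulus window).
#'
#' @param tf a `tf_power` object for a whole-session component series.
#' @param events event table (columns `fixspot_onset_s`, `stimulus_onset_s`,
#'   `modality`).
#' @param modality restrict to one modality, or `NULL` for all trials.
#' @param baseline_window seconds relative to fixspot onset.
#' @param stimulus_window seconds relative to stimulus onset.
#' @return list: `diff` (frequencies x stimulus-window bins), `time_s` (bin
#'   centers relative to stimulus onset), `freqs`.
#' @export
tf_condition_difference <- function(tf, events, modality = NULL,
                                    baseline_window = c(-1.5, -1.0),
                                    stimulus_window = c(0, 1.0)) {
  ev <- select_trials(events, modality)
  sw <- window_bins(tf, ev$stimulus_onset_s, stimulus_window)
  bw <- window_bins(tf, ev$fixspot_onset_s, baseline_window)
  n_bins <- ncol(tf$power)
  if (any(sw$start < 0L) || any(sw$start + sw$len > n_bins) ||
      any(bw$start < 0L) || any(bw$start + bw$len > n_bins))
    stop_validation("a trial's analysis window falls outside the recording")
  stim_acc <- matrix(0, nrow(tf$power), sw$len)
  base_acc <- numeric(nrow(tf$power))
  for (k in seq_len(nrow(ev))) {
    stim_acc <- stim_acc + tf$power[, (sw$start[k] + 1L):(sw$start[k] + sw$len)]
    base_acc <- base_acc +
      rowMeans(tf$power[, (bw$start[k] + 1L):(bw$start[k] + bw$len), drop = FALSE])
  }
  diff <- stim_acc / nrow(ev) - base_acc / nrow(ev)
  time_s <- stimulus_window[1] + (seq_len(sw$len) - 0.5) / tf$bin_hz
  list(diff = diff, time_s = time_s, freqs = tf$freqs)
}

#' Shuffle-based z-scoring of the time-frequency difference map
#'
#' Builds a null ensemble of difference maps by, for every trial
#' independently, swapping which of the two window anchors (baseline vs
#' stimulus) plays the stimulus role with probability 1/2 and jittering each
#' window start uniformly within +/- `jitter_s` of its anchor (draws pushing
#' a window outside the recording are redrawn). The observed map is z-scored
#' cell-wise by the shuffle mean and SD, and every shuffled map is z-scored
#' with those same parameters; the per-shuffle maximum absolute cluster mass
#' (at the cluster-forming threshold) provides the null for the cluster test.
#'
#' @inheritParams tf_condition_difference
#' @param n_shuffle number of shuffles (default 1000).
#' @param jitter_s window-start jitter half-range, seconds (default 0.5).
#' @param threshold cluster-forming |z| threshold (default 2.33,
#'   corresponding to one-sided alpha 0.01).
#' @param seed integer seed (`NULL` = current RNG state).
#' @return object of class `tf_map`: `z` (frequencies x stimulus bins),
#'   `diff`, `mu`, `sd` (shuffle statistics), `null_max_mass` (length
#'   `n_shuffle`), `time_s`, `freqs`, `threshold`, plus the call parameters.
#' @export
shuffle_zscore <- function(tf, events, modality = NULL, n_shuffle = 1000L,
                           jitter_s = 0.5, threshold = 2.33,
                           baseline_window = c(-1.5, -1.0),
                           stimulus_window = c(0, 1.0), seed = NULL) {
  if (n_shuffle < 1L) stop_validation("need at least one shuffle")
  ev <- select_trials(events, modality)
  sw <- window_bins(tf, ev$stimulus_onset_s, stimulus_window)
  bw <- window_bins(tf, ev$fixspot_onset_s, baseline_window)
  jitter_bins <- round(jitter_s * tf$bin_hz)
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_shuffle_zscore(tf$power, sw$start, bw$start, sw$len[1L], bw$len[1L],
                            as.integer(jitter_bins), as.integer(n_shuffle),
                            threshold)
  time_s <- stimulus_window[1] + (seq_len(sw$len[1L]) - 0.5) / tf$bin_hz
  structure(list(z = out$z, diff = out$diff, mu = out$mu, sd = out$sd,
                 null_max_mass = as.numeric(out$null_max_mass),
                 time_s = time_s, freqs = tf$freqs, threshold = threshold,
                 n_shuffle = as.integer(n_shuffle), jitter_s = jitter_s,
                 modality = modality),
            class = "tf_map")
}

#' Label 4-connected clusters in a boolean grid
#'
#' Connected-component labelling with 4-neighbour (time and frequency, no
#' diagonal) adjacency. Exposed mainly so the compiled labeller used inside
#' the permutation loop can be validated against independent oracles.
#'
#' @param mask logical matrix.
#' @return integer matrix of cluster labels (0 = background), labelled in
#'   first-encounter (column-major) order.
#' @export
label_clusters <- function(mask) {
  storage.mode(mask) <- "logical"
  cpp_label_clusters(mask)
}

#' Cluster-mass significance test on a z-scored time-frequency map
#'
#' Forms clusters of 4-connected cells with |z| above the cluster-forming
#' threshold (positive and negative clusters kept separate), sums the z
#' values within each cluster into a cluster mass, and declares a cluster
#' significant when its absolute mass exceeds the chosen percentile
#' (default 99th) of the per-shuffle maximum absolute cluster masses.
#'
#' @param tf_map a `tf_map` from [shuffle_zscore()].
#' @param threshold cluster-forming threshold (defaults to the map's own).
#' @param percentile percentile of the max-mass null (default 99).
#' @return the `tf_map` with added fields: `clusters` (data.frame: id, sign,
#'   mass, n_cells, significant), `cluster_labels` (integer matrix, 0 =
#'   background; positive and negative clusters share the id space),
#'   `mass_threshold`, `any_significant`.
#' @export
cluster_mass_test <- function(tf_map, threshold = NULL, percentile = 99) {
  if (is.null(tf_map$null_max_mass) || length(tf_map$null_max_mass) == 0L)
    stop_validation("tf_map carries no shuffle null; run shuffle_zscore first")
  thr <- threshold %||% tf_map$threshold
  z <- tf_map$z
  labels <- matrix(0L, nrow(z), ncol(z))
  rows <- list(); next_id <- 1L
  for (sgn in c(1, -1)) {
    lab <- cpp_label_clusters(sgn * z > thr)
    if (max(lab) == 0L) next
    for (id in seq_len(max(lab))) {
      cells <- lab == id
      rows[[next_id]] <- data.frame(id = next_id, sign = sgn,
                                    mass = sum(z[cells]), n_cells = sum(cells))
      labels[cells] <- next_id
      next_id <- next_id + 1L
    }
  }
  mass_thr <- unname(quantile(tf_map$null_max_mass, percentile / 100))
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), sign = numeric(), mass = numeric(),
               n_cells = integer())
  clusters$significant <- abs(clusters$mass) > mass_thr
  tf_map$clusters <- clusters
  tf_map$cluster_labels <- labels
  tf_map$mass_threshold <- mass_thr
  tf_map$any_significant <- any(clusters$significant)
  tf_map
}

#' Per-frequency mean z within significant clusters, per component
#'
#' For each component's cluster-tested map, averages z over the time bins
#' belonging to significant clusters at each frequency (NA where a frequency
#' has no significant cells). Stacking components gives the input for the
#' modality-selectivity profile and its comparisons.
#'
#' @param tf_maps list of cluster-tested `tf_map` objects (one per
#'   component), all sharing a frequency grid.
#' @return matrix, components x frequencies, of per-component mean z values
#'   within significant clusters (NA where absent).
#' @export
component_profile_matrix <- function(tf_maps) {
  freqs <- tf_maps[[1L]]$freqs
  out <- t(vapply(tf_maps, function(m) {
    if (is.null(m$cluster_labels)) stop_validation("run cluster_mass_test first")
    sig_ids <- m$clusters$id[m$clusters$significant]
    sig <- matrix(m$cluster_labels %in% sig_ids, nrow(m$z))
    vapply(seq_along(freqs), function(i) {
      cells <- sig[i, ]
      if (!any(cells)) NA_real_ else mean(m$z[i, cells])
    }, 0)
  }, numeric(length(freqs))))
  out
}

#' Modality-selectivity profile
#'
#' Mean (and SEM) across components of the per-component mean z within
#' significant clusters, per frequency, for one modality. Components without
#' significant cells at a frequency contribute nothing there.
#'
#' @param tf_maps list of cluster-tested `tf_map`s for one modality.
#' @return data.frame: `freq_hz`, `mean_z`, `sem`, `n_components` (rows with
#'   `n_components = 0` have NA mean/sem; an all-NA profile is allowed).
#' @export
modality_selectivity_profile <- function(tf_maps) {
  prof <- component_profile_matrix(tf_maps)
  n <- colSums(!is.na(prof))
  mean_z <- ifelse(n > 0L, colMeans(prof, na.rm = TRUE), NA_real_)
  sem <- ifelse(n > 1L, apply(prof, 2L, sd, na.rm = TRUE) / sqrt(pmax(n, 1L)),
                NA_real_)
  data.frame(freq_hz = tf_maps[[1L]]$freqs, mean_z = mean_z, sem = sem,
             n_components = n)
}

#' Per-frequency rank-sum comparison between two modalities
#'
#' At each frequency, compares the per-component mean-z values of two
#' modalities with a Wilcoxon rank-sum test at alpha = 0.01. Frequencies with
#' fewer than two contributing components on either side are skipped (NA p).
#'
#' @param profile_a,profile_b component x frequency matrices from
#'   [component_profile_matrix()] for the two modalities.
#' @param freqs frequency grid (Hz).
#' @param alpha significance level (default 0.01).
#' @return data.frame: `freq_hz`, `n_a`, `n_b`, `p`, `significant`.
#' @export
compare_modalities <- function(profile_a, profile_b, freqs, alpha = 0.01) {
  if (ncol(profile_a) != ncol(profile_b) || ncol(profile_a) != length(freqs))
    stop_validation("profile matrices and frequency grid must align")
  rows <- lapply(seq_along(freqs), function(i) {
    a <- profile_a[, i]; a <- a[!is.na(a)]
    b <- profile_b[, i]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(freq_hz = freqs[i], n_a = length(a), n_b = length(b),
                        p = NA_real_, significant = FALSE))
    p <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    data.frame(freq_hz = freqs[i], n_a = length(a), n_b = length(b),
               p = p, significant = p < alpha)
  })
  do.call(rbind, rows)
}

#' Spectral profiles of components and their rank-group PCA
#'
#' Estimates each component's power spectrum as its time-averaged Morlet
#' power on the standard 1-100 Hz grid, normalized to unit total power, and
#' then runs a principal component analysis across the components of each
#' rank group (1st, 2nd, ... strongest per session) with frequencies as
#' variables, extracting the dominant spectral shapes and their
#' explained-variance (scree) fractions.
#'
#' @param series_by_rank list (one element per rank group) of lists of
#'   component time series (numeric vectors).
#' @param fs sampling rate, Hz.
#' @param freqs,n_cycles Morlet parameters.
#' @return object of class `spectral_profile_set`: list per rank group with
#'   `spectra` (components x frequencies, unit total power), `loadings`
#'   (frequencies x PCs), `explained_variance` (non-increasing fractions in
#'   \[0,1\]), plus `freqs`. Rank groups with fewer than two components are
#'   skipped with a warning.
#' @export
spectral_profiles_and_pca <- function(series_by_rank, fs,
                                      freqs = morlet_freqs(),
                                      n_cycles = morlet_cycles(length(freqs))) {
  groups <- lapply(seq_along(series_by_rank), function(r) {
    series <- series_by_rank[[r]]
    if (length(series) < 2L) {
      warning("rank group ", r, " has fewer than 2 components; skipped")
      return(NULL)
    }
    spectra <- t(vapply(series, function(x) {
      p <- rowMeans(morlet_tf(x, fs, freqs, n_cycles)$power)
      p / sum(p)
    }, numeric(length(freqs))))
    pca <- prcomp(spectra, center = TRUE, scale. = FALSE)
    tot <- sum(pca$sdev^2)
    # identical spectra leave zero variance: all structure is in the mean,
    # so the first direction carries everything by convention
    ev <- if (tot < 1e-24) c(1, rep(0, length(pca$sdev) - 1L)) else
      pca$sdev^2 / tot
    list(spectra = spectra, loadings = pca$rotation,
         explained_variance = ev)
  })
  structure(list(groups = groups, freqs = freqs),
            class = "spectral_profile_set")
}
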