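#' Simulation configuration for synthetic LFP sessions
#'
#' Bundles the parameters of the synthetic recording world: probe geometry,
#' sampling, trial schedule, and noise model. Defaults follow the recording
#' protocol the analysis was designed for: 16 equidistant contacts, 1 kHz
#' sampling, 1 s stimulus delivery, 3-4 s inter-trial intervals, and three
#' sensory modalities (visual, tactile, auditory) with eight stimuli each
#' presented 12-20 times.
#'
#' @param n_contacts number of probe contacts (>= 2).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param n_trials_per_modality trials per modality. `NULL` (default) draws
#'   12-20 repetitions for each of `n_stimuli` stimuli per modality, matching
#'   the experimental schedule; an integer gives exactly that many trials with
#'   stimulus ids cycling through `1:n_stimuli`.
#' @param n_stimuli distinct stimulus ids per modality.
#' @param stimulus_duration_s stimulus delivery window length, seconds.
#' @param fixspot_to_stimulus_delay_s delay from fixation-cue onset to
#'   stimulus onset, seconds (0.2 s default; 0 in one of the two animals).
#' @param iti_range_s length-2 numeric, uniform inter-trial interval range.
#' @param noise_exponent exponent beta of the 1/f^beta background noise.
#' @param noise_sd per-contact background noise standard deviation (uV).
#' @param shared_noise_sd standard deviation of the noise component common to
#'   all contacts (removed by common-average referencing).
#' @param line_noise_amplitude amplitude of additive 60 Hz line noise (uV).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_contacts = 16L,
                       sampling_rate_hz = 1000,
                       n_trials_per_modality = NULL,
                       n_stimuli = 8L,
                       stimulus_duration_s = 1.0,
                       fixspot_to_stimulus_delay_s = 0.2,
                       iti_range_s = c(3, 4),
                       noise_exponent = 1.0,
                       noise_sd = 1.0,
                       shared_noise_sd = 0.5,
                       line_noise_amplitude = 0,
                       seed = NULL) {
  cfg <- structure(list(
    n_contacts = as.integer(n_contacts),
    sampling_rate_hz = sampling_rate_hz,
    n_trials_per_modality = if (is.null(n_trials_per_modality)) NULL else as.integer(n_trials_per_modality),
    n_stimuli = as.integer(n_stimuli),
    stimulus_duration_s = stimulus_duration_s,
    fixspot_to_stimulus_delay_s = fixspot_to_stimulus_delay_s,
    iti_range_s = as.numeric(iti_range_s),
    noise_exponent = noise_exponent,
    noise_sd = noise_sd,
    shared_noise_sd = shared_noise_sd,
    line_noise_amplitude = line_noise_amplitude,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop_config("not a sim_config object")
  if (cfg$n_contacts < 2L) stop_config("n_contacts must be >= 2")
  if (cfg$sampling_rate_hz <= 0) stop_config("sampling_rate_hz must be positive")
  if (!is.null(cfg$n_trials_per_modality) && cfg$n_trials_per_modality < 0L)
    stop_config("n_trials_per_modality must be non-negative")
  if (cfg$stimulus_duration_s <= 0) stop_config("stimulus_duration_s must be positive")
  if (cfg$fixspot_to_stimulus_delay_s < 0) stop_config("delay must be non-negative")
  if (length(cfg$iti_range_s) != 2L || any(cfg$iti_range_s <= 0) ||
      cfg$iti_range_s[1] > cfg$iti_range_s[2])
    stop_config("iti_range_s must be an increasing positive pair")
  if (cfg$noise_sd < 0 || cfg$shared_noise_sd < 0)
    stop_config("noise standard deviations must be non-negative")
  invisible(cfg)
}

#' Ground truth for a synthetic session
#'
#' Describes the planted subnetworks: how each band-limited oscillatory source
#' projects onto the contacts (mixing vectors), its center frequency, its
#' per-modality multiplicative amplitude gain during stimulus delivery, and
#' the anatomical annotation of each contact (nucleus label, near-boundary
#' flag). Sources project linearly and instantaneously onto the contacts,
#' which is the generative assumption GED inverts.
#'
#' @param mixing_vectors numeric matrix, contacts x sources; each column is a
#'   source's projection weights onto the probe.
#' @param source_center_freqs numeric vector of source center frequencies, Hz.
#' @param modality_gains numeric matrix, sources x modalities, with column
#'   names `visual`, `tactile`, `auditory`: multiplicative amplitude gain of
#'   each source during the stimulus window of a trial of that modality
#'   (1 = no stimulus-locked change).
#' @param contact_labels character vector of nucleus labels per contact;
#'   `"outside"` marks contacts outside the target structure.
#' @param boundary_flags logical vector; `TRUE` if a contact lies within
#'   200 um of a nucleus boundary (excluded from concordance counting).
#' @param source_amplitudes baseline oscillation amplitude per source (uV).
#'
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(mixing_vectors, source_center_freqs, modality_gains,
                         contact_labels, boundary_flags,
                         source_amplitudes = NULL) {
  mixing_vectors <- as.matrix(mixing_vectors)
  n_src <- ncol(mixing_vectors)
  if (is.null(source_amplitudes)) source_amplitudes <- rep(1, n_src)
  gt <- structure(list(
    mixing_vectors = mixing_vectors,
    source_center_freqs = as.numeric(source_center_freqs),
    modality_gains = as.matrix(modality_gains),
    contact_labels = as.character(contact_labels),
    boundary_flags = as.logical(boundary_flags),
    source_amplitudes = as.numeric(source_amplitudes)
  ), class = "ground_truth")
  validate_ground_truth(gt)
  gt
}

validate_ground_truth <- function(gt) {
  n_contacts <- nrow(gt$mixing_vectors)
  n_src <- ncol(gt$mixing_vectors)
  if (length(gt$contact_labels) != n_contacts || length(gt$boundary_flags) != n_contacts)
    stop_validation("contact annotations must have one entry per contact")
  if (length(gt$source_center_freqs) != n_src || length(gt$source_amplitudes) != n_src)
    stop_validation("per-source fields must have one entry per source")
  if (any(colSums(abs(gt$mixing_vectors)) == 0))
    stop_validation("every mixing vector needs at least one nonzero entry")
  if (nrow(gt$modality_gains) != n_src)
    stop_validation("modality_gains must have one row per source")
  if (is.null(colnames(gt$modality_gains)) ||
      !all(MODALITIES %in% colnames(gt$modality_gains)))
    stop_validation("modality_gains must have columns visual, tactile, auditory")
  if (any(!is.finite(gt$modality_gains)) || any(gt$modality_gains < 0))
    stop_validation("gains must be finite and non-negative")
  invisible(gt)
}

#' Default planted ground truth
#'
#' Builds a ground truth with `n_sources` oscillatory subnetworks at the
#' spectral peaks characteristic of amygdala LFP (4, 7, 38, 70 Hz), each
#' projecting as a piecewise-constant block onto the contiguous contacts of
#' one nucleus. The probe emulates a track entering the structure after two
#' contacts: labels are `outside`, `lateral`, `basal`, `accessory basal`,
#' `central`, and the two contacts flanking one internal boundary carry the
#' near-boundary flag. Default gains order visual > tactile > auditory.
#'
#' @param config a [sim_config()].
#' @param n_sources number of planted sources (1-4 with default frequencies).
#' @param gains optional sources x 3 gain matrix (columns visual, tactile,
#'   auditory); default `rbind` of (2, 1.5, 1.2) rows.
#' @param freqs optional per-source center frequencies, Hz.
#' @param smooth if `TRUE`, mixing blocks get Gaussian-tapered edges instead
#'   of hard steps.
#' @return a [ground_truth()] object.
#' @export
default_ground_truth <- function(config, n_sources = 4L, gains = NULL,
                                 freqs = NULL, smooth = FALSE) {
  n <- config$n_contacts
  freqs <- freqs %||% c(4, 7, 38, 70)[seq_len(n_sources)]
  if (length(freqs) != n_sources) stop_config("need one frequency per source")
  # contact blocks: outside (2), then nuclei tiling the rest of the probe
  n_out <- if (n >= 8L) 2L else 0L
  nuclei <- c("lateral", "basal", "accessory basal", "central")
  n_in <- n - n_out
  sizes <- rep(n_in %/% 4L, 4L)
  sizes[seq_len(n_in %% 4L)] <- sizes[seq_len(n_in %% 4L)] + 1L
  labels <- c(rep("outside", n_out), rep(nuclei, times = sizes))
  blocks <- split(seq_len(n), factor(labels, levels = unique(labels)))
  in_blocks <- blocks[names(blocks) != "outside"]
  mixing <- matrix(0, n, n_sources)
  for (s in seq_len(n_sources)) {
    idx <- in_blocks[[((s - 1L) %% length(in_blocks)) + 1L]]
    mixing[idx, s] <- 1
    if (smooth) {
      center <- mean(idx)
      width <- max(1, length(idx) / 2)
      mixing[, s] <- exp(-0.5 * ((seq_len(n) - center) / width)^2)
    }
  }
  if (is.null(gains)) {
    gains <- matrix(rep(c(2.0, 1.5, 1.2), each = n_sources), n_sources, 3)
  }
  colnames(gains) <- MODALITIES
  boundary <- rep(FALSE, n)
  if (length(in_blocks) >= 2L) {
    # flag the two contacts flanking the first internal nucleus boundary
    b <- max(in_blocks[[1L]])
    boundary[c(b, b + 1L)] <- TRUE
  }
  ground_truth(mixing, freqs, gains, labels, boundary)
}

# Smallest even FFT-friendly length >= n (k * 2^j for small odd k).
fft_length_even <- function(n) {
  best <- 2^ceiling(log2(n))
  for (k in c(3L, 5L, 9L, 15L, 25L, 27L)) {
    cand <- k * 2^max(1, ceiling(log2(n / k)))
    if (cand >= n && cand < best) best <- cand
  }
  as.integer(best)
}

# 1/f^beta noise synthesized in the frequency domain: Hermitian complex
# Gaussian spectrum shaped by f^(-beta/2), inverse FFT, scaled analytically
# to the requested standard deviation. Two independent real series are packed
# into each complex FFT (one as the real, one as the imaginary part).
pink_noise <- function(n_samples, fs, beta, sd_target, n_series = 1L) {
  nfft <- fft_length_even(max(n_samples, 16L))
  half <- nfft %/% 2L
  amp <- (seq_len(half - 1L) * (fs / nfft))^(-beta / 2)
  n_pair <- ceiling(n_series / 2)
  Z <- cpp_noise_spectrum(nfft, amp, n_pair)
  y <- stats::mvfft(Z, inverse = TRUE)[seq_len(n_samples), , drop = FALSE] / nfft
  x <- matrix(0, n_samples, 2L * n_pair)
  x[, seq(1L, 2L * n_pair, by = 2L)] <- Re(y)
  x[, seq(2L, 2L * n_pair, by = 2L)] <- Im(y)
  # Var(x_t) = (4 / nfft^2) * sum(amp^2) exactly, by construction
  scale <- sd_target / sqrt(4 * sum(amp^2) / nfft^2)
  x[, seq_len(n_series), drop = FALSE] * scale
}

# Smooth positive amplitude envelope: 1 + 0.5 * (white noise smoothed with a
# `width_s` Gaussian kernel, unit variance), floored at 0.1. The envelope is
# band-limited to a few Hz, so it is synthesized on a decimated 50 Hz grid
# and linearly interpolated up to the sampling rate.
slow_envelope <- function(n_samples, fs, width_s = 0.2, env_fs = 50) {
  n_env <- ceiling(n_samples / fs * env_fs) + 2L
  half <- ceiling(3 * width_s * env_fs)
  k <- exp(-0.5 * ((-half:half) / (width_s * env_fs))^2)
  k <- k / sum(k)
  z <- rnorm(n_env + 2L * half)
  sm <- stats::filter(z, k, sides = 2)[(half + 1L):(half + n_env)]
  sm <- as.numeric(sm) / sd(sm)
  t_env <- (seq_len(n_env) - 1L) / env_fs
  t_out <- (seq_len(n_samples) - 1L) / fs
  env <- stats::approx(t_env, sm, xout = t_out, rule = 2)$y
  pmax(0.1, 1 + 0.5 * env)
}

# Randomized trial schedule. Returns the event table plus total duration.
make_schedule <- function(config) {
  reps <- if (is.null(config$n_trials_per_modality)) {
    lapply(MODALITIES, function(m) {
      rep(seq_len(config$n_stimuli),
          times = sample(12:20, config$n_stimuli, replace = TRUE))
    })
  } else {
    k <- config$n_trials_per_modality
    lapply(MODALITIES, function(m) {
      rep_len(seq_len(config$n_stimuli), k)
    })
  }
  modality <- rep(MODALITIES, times = lengths(reps))
  stimulus_id <- unlist(reps, use.names = FALSE)
  n_trials <- length(modality)
  if (n_trials == 0L) stop_validation("trial schedule is empty (n_trials = 0)")
  ord <- sample.int(n_trials)
  modality <- modality[ord]
  stimulus_id <- stimulus_id[ord]
  iti <- runif(n_trials, config$iti_range_s[1], config$iti_range_s[2])
  # 2.5 s lead-in: room for the -1.5..-1.0 s baseline window plus 0.5 s of
  # shuffle jitter; same margin after the last stimulus.
  lead_in <- 2.5
  fixspot <- numeric(n_trials)
  fixspot[1] <- lead_in
  trial_len <- config$fixspot_to_stimulus_delay_s + config$stimulus_duration_s
  if (n_trials > 1L) {
    for (k in 2:n_trials) fixspot[k] <- fixspot[k - 1L] + trial_len + iti[k - 1L]
  }
  stim_on <- fixspot + config$fixspot_to_stimulus_delay_s
  duration <- stim_on[n_trials] + config$stimulus_duration_s + 2.5
  list(events = data.frame(trial_id = seq_len(n_trials),
                           fixspot_onset_s = fixspot,
                           stimulus_onset_s = stim_on,
                           modality = modality,
                           stimulus_id = stimulus_id,
                           stringsAsFactors = FALSE),
       duration_s = duration)
}

# Band-limited source signals with per-trial stimulus gains applied.
# Returns a sources x samples matrix.
source_signals <- function(config, truth, events, n_samples) {
  fs <- config$sampling_rate_hz
  t <- (seq_len(n_samples) - 1L) / fs
  n_src <- ncol(truth$mixing_vectors)
  out <- matrix(0, n_src, n_samples)
  for (s in seq_len(n_src)) {
    f0 <- truth$source_center_freqs[s]
    if (f0 < 1 || f0 >= fs / 2)
      stop_config("source frequency ", f0, " Hz outside [1, fs/2)")
    phase <- runif(1, 0, 2 * pi)
    env <- slow_envelope(n_samples, fs)
    gain <- rep(1, n_samples)
    for (k in seq_len(nrow(events))) {
      g <- truth$modality_gains[s, events$modality[k]]
      i0 <- floor(events$stimulus_onset_s[k] * fs) + 1L
      i1 <- min(n_samples, i0 + round(config$stimulus_duration_s * fs) - 1L)
      gain[i0:i1] <- g
    }
    out[s, ] <- truth$source_amplitudes[s] * env * gain * cos(2 * pi * f0 * t + phase)
  }
  out
}

#' Generate a synthetic LFP session with known ground truth
#'
#' Simulates a continuous multichannel recording as a linear instantaneous
#' mixture of amplitude-modulated narrowband oscillatory sources plus 1/f
#' background noise (independent per contact and one component shared across
#' the probe), with a randomized trial schedule. During each trial's stimulus
#' window the amplitude of every source is multiplied by its gain for that
#' trial's modality, so stimulus-locked covariance changes have a known
#' spatial signature (the mixing vectors).
#'
#' @param config a [sim_config()].
#' @param truth a [ground_truth()]; default [default_ground_truth()].
#' @return a list with elements `session` (an `lfp_session`) and `truth`
#'   (the ground truth, unchanged).
#' @examples
#' cfg <- sim_config(n_trials_per_modality = 4, seed = 1)
#' sim <- generate_session(cfg)
#' dim(sim$session$lfp)
#' @export
generate_session <- function(config, truth = NULL) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  truth <- truth %||% default_ground_truth(config)
  validate_ground_truth(truth)
  if (nrow(truth$mixing_vectors) != config$n_contacts)
    stop_validation("mixing vectors sized for ", nrow(truth$mixing_vectors),
                    " contacts, config has ", config$n_contacts)
  if (any(truth$source_center_freqs >= config$sampling_rate_hz / 2))
    stop_config("sampling rate must exceed twice the highest source frequency")

  sched <- make_schedule(config)
  fs <- config$sampling_rate_hz
  n_samples <- ceiling(sched$duration_s * fs)

  src <- source_signals(config, truth, sched$events, n_samples)
  lfp <- truth$mixing_vectors %*% src
  lfp <- lfp + t(pink_noise(n_samples, fs, config$noise_exponent,
                            config$noise_sd, n_series = config$n_contacts))
  if (config$shared_noise_sd > 0) {
    shared <- pink_noise(n_samples, fs, config$noise_exponent,
                         config$shared_noise_sd)[, 1]
    lfp <- sweep(lfp, 2L, shared, "+")
  }
  if (config$line_noise_amplitude > 0) {
    t <- (seq_len(n_samples) - 1L) / fs
    lfp <- sweep(lfp, 2L, config$line_noise_amplitude * sin(2 * pi * 60 * t), "+")
  }

  session <- lfp_session(
    lfp = lfp,
    sampling_rate_hz = fs,
    events = sched$events,
    annotations = data.frame(
      contact = seq_len(config$n_contacts),
      nucleus = truth$contact_labels,
      boundary = truth$boundary_flags,
      in_structure = truth$contact_labels != "outside",
      excluded = FALSE,
      stringsAsFactors = FALSE
    )
  )
  list(session = session, truth = truth)
}

#' Generate a null session (no stimulus-locked change)
#'
#' Same generative model as [generate_session()] but with every modality gain
#' fixed at 1, so baseline and stimulus windows are draws from the same
#' stationary process. Used for calibration of the permutation tests: under
#' this null the stimulus/baseline covariance ratio has generalized
#' eigenvalues near 1.
#'
#' @inheritParams generate_session
#' @return an `lfp_session`.
#' @export
generate_null_session <- function(config, truth = NULL) {
  validate_sim_config(config)
  truth <- truth %||% default_ground_truth(config)
  truth$modality_gains[] <- 1
  generate_session(config, truth)$session
}

#' Generate a null single-channel component time series
#'
#' Produces what a GED component time series looks like under the null:
#' 1/f background plus stationary narrowband oscillations, with a full trial
#' event table but no stimulus-locked amplitude change. This is the input for
#' calibrating the time-frequency cluster-mass test without simulating and
#' decomposing a full multichannel session.
#'
#' @param config a [sim_config()] (only schedule/noise fields are used).
#' @param freqs center frequencies of the stationary oscillations, Hz.
#' @param amplitudes amplitudes of those oscillations.
#' @return list with `series` (numeric vector), `sampling_rate_hz`, `events`.
#' @export
generate_null_component_series <- function(config, freqs = c(7, 38),
                                           amplitudes = rep(0.5, length(freqs))) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  sched <- make_schedule(config)
  fs <- config$sampling_rate_hz
  n_samples <- ceiling(sched$duration_s * fs)
  x <- pink_noise(n_samples, fs, config$noise_exponent, config$noise_sd)[, 1]
  t <- (seq_len(n_samples) - 1L) / fs
  for (j in seq_along(freqs)) {
    env <- slow_envelope(n_samples, fs)
    x <- x + amplitudes[j] * env * cos(2 * pi * freqs[j] * t + runif(1, 0, 2 * pi))
  }
  list(series = x, sampling_rate_hz = fs, events = sched$events)
}

#' Write ground truth to a JSON file
#'
#' @param truth a [ground_truth()].
#' @param path output file path.
#' @export
save_ground_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, digits = NA, pretty = TRUE)
  invisible(path)
}
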