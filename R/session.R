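#' Multichannel LFP session container
#'
#' Holds a contacts x samples LFP matrix together with its sampling rate,
#' a per-trial event table, and per-contact anatomical annotations. Contacts
#' are ordered by probe position (index 1..n along the array).
#'
#' @param lfp numeric matrix, contacts x samples (uV).
#' @param sampling_rate_hz sampling rate, Hz.
#' @param events data.frame with columns `trial_id`, `fixspot_onset_s`,
#'   `stimulus_onset_s`, `modality`, `stimulus_id`.
#' @param annotations data.frame with columns `contact`, `nucleus`,
#'   `boundary`, `in_structure`, `excluded` (one row per contact).
#' @return an object of class `lfp_session`.
#' @export
lfp_session <- function(lfp, sampling_rate_hz, events, annotations) {
  s <- structure(list(
    lfp = as.matrix(lfp),
    sampling_rate_hz = sampling_rate_hz,
    events = as.data.frame(events),
    annotations = as.data.frame(annotations)
  ), class = "lfp_session")
  validate_session(s)
  s
}

validate_session <- function(s) {
  if (!is.numeric(s$lfp) || !is.matrix(s$lfp))
    stop_format("lfp must be a numeric matrix (contacts x samples)")
  n <- nrow(s$lfp)
  req_ev <- c("trial_id", "fixspot_onset_s", "stimulus_onset_s", "modality", "stimulus_id")
  if (!all(req_ev %in% names(s$events)))
    stop_validation("event table missing columns: ",
                    paste(setdiff(req_ev, names(s$events)), collapse = ", "))
  req_an <- c("contact", "nucleus", "boundary", "in_structure", "excluded")
  if (!all(req_an %in% names(s$annotations)))
    stop_validation("annotations missing columns: ",
                    paste(setdiff(req_an, names(s$annotations)), collapse = ", "))
  if (nrow(s$annotations) != n)
    stop_format("annotations have ", nrow(s$annotations), " rows for ", n, " contacts")
  if (anyDuplicated(s$events$trial_id))
    stop_validation("duplicate trial ids in event table")
  dur <- ncol(s$lfp) / s$sampling_rate_hz
  if (nrow(s$events) > 0L) {
    if (any(s$events$stimulus_onset_s < 0) || any(s$events$stimulus_onset_s > dur) ||
        any(s$events$fixspot_onset_s < 0) || any(s$events$fixspot_onset_s > dur))
      stop_validation("event times fall outside the recording duration")
    if (is.unsorted(s$events$stimulus_onset_s))
      stop_validation("event table must be time-ordered")
  }
  invisible(s)
}

#' @export
print.lfp_session <- function(x, ...) {
  cat(sprintf("<lfp_session> %d contacts x %d samples @ %g Hz (%.1f s), %d trials\n",
              nrow(x$lfp), ncol(x$lfp), x$sampling_rate_hz,
              ncol(x$lfp) / x$sampling_rate_hz, nrow(x$events)))
  invisible(x)
}

#' Save / load a session
#'
#' The on-disk format is deliberately simple and fully portable: the LFP
#' matrix as little-endian float64 binary (column-major, samples varying
#' fastest within a contact row... stored as contacts x samples in column
#' order), a JSON sidecar carrying shape, dtype, sampling rate and contact
#' annotations, and a CSV event table. Round trips are lossless.
#'
#' @param session an `lfp_session`.
#' @param path directory to write into (created if missing).
#' @return `save_session` returns `path` invisibly; `load_session` returns
#'   the reconstructed `lfp_session`.
#' @export
save_session <- function(session, path) {
  validate_session(session)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "lfp.f64"), "wb")
  on.exit(close(con))
  writeBin(as.vector(session$lfp), con, size = 8L, endian = "little")
  jsonlite::write_json(list(
    n_contacts = nrow(session$lfp),
    n_samples = ncol(session$lfp),
    dtype = "float64",
    byte_order = "little",
    sampling_rate_hz = session$sampling_rate_hz,
    annotations = session$annotations
  ), file.path(path, "session.json"), digits = NA, auto_unbox = TRUE)
  write.csv(session$events, file.path(path, "events.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "session.json"), simplifyVector = TRUE)
  n <- meta$n_contacts * meta$n_samples
  con <- file(file.path(path, "lfp.f64"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n + 1L, size = 8L, endian = "little")
  if (length(x) != n)
    stop_format("binary payload has ", length(x), " doubles, sidecar declares ", n)
  lfp <- matrix(x, nrow = meta$n_contacts, ncol = meta$n_samples)
  events <- read.csv(file.path(path, "events.csv"), stringsAsFactors = FALSE)
  lfp_session(lfp, as.numeric(meta$sampling_rate_hz), events, meta$annotations)
}

#' Common-average re-referencing
#'
#' Subtracts, at every sample, the mean over all retained (non-excluded)
#' contacts from every retained contact, suppressing signals common to the
#' whole probe. Excluded contacts do not enter the average and are passed
#' through unchanged.
#'
#' @param session an `lfp_session`.
#' @return a re-referenced `lfp_session`.
#' @export
common_average_reference <- function(session) {
  validate_session(session)
  keep <- !session$annotations$excluded
  if (sum(keep) < 2L)
    stop_validation("common average reference needs >= 2 retained contacts")
  avg <- colMeans(session$lfp[keep, , drop = FALSE])
  session$lfp[keep, ] <- sweep(session$lfp[keep, , drop = FALSE], 2L, avg, "-")
  session
}

# Windowed-sinc FIR low-pass (Hamming window), linear phase, applied by
# centered convolution so event times in seconds stay aligned.
fir_lowpass <- function(x, fs, cutoff_hz, n_taps = 129L) {
  m <- (n_taps - 1L) / 2L
  k <- -m:m
  h <- 2 * cutoff_hz / fs * sinc(2 * cutoff_hz / fs * k)
  h <- h * (0.54 + 0.46 * cos(pi * k / m))
  h <- h / sum(h)
  pad <- c(rep(x[1], m), x, rep(x[length(x)], m))
  stats::convolve(pad, h, type = "filter")
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Downsample a session
#'
#' Anti-alias filters (windowed-sinc FIR low-pass at 80% of the target
#' Nyquist) and decimates each contact. Event times are stored in seconds and
#' are unchanged. A no-op when the session is already at the target rate.
#'
#' @param session an `lfp_session`.
#' @param target_hz target sampling rate; must divide into and not exceed the
#'   current rate.
#' @return the downsampled `lfp_session`.
#' @export
downsample <- function(session, target_hz = 1000) {
  validate_session(session)
  fs <- session$sampling_rate_hz
  if (target_hz > fs) stop_validation("target rate exceeds current rate")
  if (target_hz == fs) return(session)
  factor <- fs / target_hz
  if (abs(factor - round(factor)) > 1e-9)
    stop_validation("target rate must divide the current rate")
  factor <- round(factor)
  cutoff <- 0.8 * target_hz / 2
  n_taps <- 2L * ceiling(2 * fs / cutoff) + 1L
  idx <- seq(1L, ncol(session$lfp), by = factor)
  out <- t(apply(session$lfp, 1L, function(row) {
    fir_lowpass(row, fs, cutoff, n_taps)[idx]
  }))
  session$lfp <- out
  session$sampling_rate_hz <- target_hz
  session
}

#' Epoch a session into baseline and stimulus segments
#'
#' Extracts, per trial, a baseline segment over \[-1.5, -1.0) s relative to
#' fixation-cue onset and a stimulus segment over \[0, +1.0) s relative to
#' stimulus onset (half-open sample windows: 500 and 1000 samples at 1 kHz).
#' Trials whose windows do not fit inside the recording are dropped with a
#' warning.
#'
#' @param session an `lfp_session`.
#' @param baseline_window length-2 numeric, seconds relative to fixspot onset.
#' @param stimulus_window length-2 numeric, seconds relative to stimulus onset.
#' @return an object of class `lfp_epochs`: list with `baseline` and
#'   `stimulus` (lists of contacts x samples matrices), `trial_means`
#'   (per-trial per-contact mean LFP over the span from baseline start to
#'   stimulus end, used to center both windows of a trial on the same
#'   vector), `events` (metadata of retained trials), `sampling_rate_hz`,
#'   `annotations`.
#' @export
epoch_trials <- function(session, baseline_window = c(-1.5, -1.0),
                         stimulus_window = c(0, 1.0)) {
  validate_session(session)
  if (nrow(session$events) == 0L) stop_validation("no events to epoch")
  fs <- session$sampling_rate_hz
  n_samp <- ncol(session$lfp)
  slice <- function(onset_s, window) {
    i0 <- floor(onset_s * fs + window[1] * fs) + 1L
    i1 <- i0 + round((window[2] - window[1]) * fs) - 1L
    if (i0 < 1L || i1 > n_samp) return(NULL)
    session$lfp[, i0:i1, drop = FALSE]
  }
  base <- list(); stim <- list(); tmeans <- list()
  keep <- logical(nrow(session$events))
  for (k in seq_len(nrow(session$events))) {
    b <- slice(session$events$fixspot_onset_s[k], baseline_window)
    s <- slice(session$events$stimulus_onset_s[k], stimulus_window)
    if (is.null(b) || is.null(s)) next
    # trial-wide mean over the span from baseline start to stimulus end
    t0 <- session$events$fixspot_onset_s[k] + baseline_window[1]
    t1 <- session$events$stimulus_onset_s[k] + stimulus_window[2]
    i0 <- floor(t0 * fs) + 1L; i1 <- floor(t1 * fs)
    keep[k] <- TRUE
    base[[length(base) + 1L]] <- b
    stim[[length(stim) + 1L]] <- s
    tmeans[[length(tmeans) + 1L]] <- rowMeans(session$lfp[, i0:i1, drop = FALSE])
  }
  if (any(!keep))
    warning(sum(!keep), " trial(s) dropped: epoch window outside recording")
  if (!any(keep)) stop_validation("no usable trials after windowing")
  structure(list(
    baseline = base,
    stimulus = stim,
    trial_means = tmeans,
    events = session$events[keep, , drop = FALSE],
    sampling_rate_hz = fs,
    annotations = session$annotations
  ), class = "lfp_epochs")
}

#' Per-contact responsiveness screen
#'
#' For each contact, pools the LFP sample values of all baseline segments and
#' all stimulus segments across trials and compares the two distributions
#' with a Wilcoxon rank-sum test (normal approximation with tie correction).
#' Significance uses a Bonferroni-adjusted level `alpha / n_contacts`
#' (0.01/16 = 0.000625 for a 16-contact probe).
#'
#' @param epochs an `lfp_epochs` object.
#' @param alpha family-wise alpha before Bonferroni division (default 0.01).
#' @return data.frame with one row per contact: `contact`, `statistic`
#'   (rank-sum W), `p`, `significant`, and the `alpha_adjusted` used.
#' @export
screen_contact_responsiveness <- function(epochs, alpha = 0.01) {
  if (length(epochs$baseline) < 2L)
    stop_validation("responsiveness screen needs >= 2 trials")
  n_contacts <- nrow(epochs$baseline[[1L]])
  alpha_adj <- alpha / n_contacts
  base_mat <- do.call(cbind, epochs$baseline)
  stim_mat <- do.call(cbind, epochs$stimulus)
  res <- lapply(seq_len(n_contacts), function(i) {
    b <- base_mat[i, ]; s <- stim_mat[i, ]
    if (var(b) == 0 && var(s) == 0 && b[1] == s[1]) {
      return(c(statistic = NA_real_, p = 1))
    }
    w <- suppressWarnings(wilcox.test(s, b, exact = FALSE, correct = TRUE))
    c(statistic = unname(w$statistic), p = w$p.value)
  })
  res <- do.call(rbind, res)
  data.frame(contact = seq_len(n_contacts),
             statistic = res[, "statistic"],
             p = res[, "p"],
             significant = res[, "p"] < alpha_adj,
             alpha_adjusted = alpha_adj)
}
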