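#' Single-trial covariance matrix
#'
#' Centers each contact's segment over time and forms the cross-product
#' divided by (n_samples - 1). Normalizing by the sample count makes the
#' stimulus (1.0 s) and baseline (0.5 s) covariances directly comparable, so
#' that under stationarity the generalized eigenvalues of the pair sit at 1.
#'
#' The centering vector is the mean LFP across time on the trial: by default
#' the segment's own mean, but when a whole-trial mean (spanning baseline
#' through stimulus) is supplied, both windows are centered on the same
#' vector. Trial-wide centering matters for 1/f signals: per-window
#' centering high-passes each window at ~1/length, which differs between the
#' 0.5 s and 1.0 s windows and would bias the stimulus/baseline ratio away
#' from 1 under stationarity.
#'
#' @param segment numeric matrix, contacts x samples.
#' @param center numeric vector (one value per contact) to subtract;
#'   defaults to the segment's own per-contact time average.
#' @return contacts x contacts covariance matrix.
#' @export
trial_covariance <- function(segment, center = NULL) {
  segment <- as.matrix(segment)
  if (ncol(segment) < 2L) stop_validation("segment needs >= 2 samples")
  center <- center %||% rowMeans(segment)
  if (length(center) != nrow(segment))
    stop_validation("centering vector length does not match contact count")
  centered <- segment - center
  tcrossprod(centered) / (ncol(segment) - 1L)
}

#' Build the stimulus/baseline covariance pair
#'
#' Computes one covariance matrix per trial for the stimulus and baseline
#' windows, averages each set into the S (stimulus) and R (reference) matrix,
#' and retains the per-trial stacks for permutation testing. Both windows of
#' a trial are centered on the trial-wide mean (see [trial_covariance()])
#' when the epochs carry one.
#'
#' @param epochs an `lfp_epochs` object (see [epoch_trials()]).
#' @return object of class `cov_pair`: list with `S`, `R` (averages),
#'   `S_trials`, `R_trials` (contacts x contacts x trials arrays), `n_trials`,
#'   `events`.
#' @export
build_cov_pair <- function(epochs) {
  n_trials <- length(epochs$stimulus)
  if (n_trials != length(epochs$baseline))
    stop_validation("mismatched trial counts between stimulus and baseline windows")
  if (n_trials < 2L) stop_validation("covariance pair needs >= 2 trials")
  n <- nrow(epochs$stimulus[[1L]])
  centers <- epochs$trial_means %||% vector("list", n_trials)
  S_trials <- vapply(seq_len(n_trials), function(k)
    trial_covariance(epochs$stimulus[[k]], centers[[k]]), matrix(0, n, n))
  R_trials <- vapply(seq_len(n_trials), function(k)
    trial_covariance(epochs$baseline[[k]], centers[[k]]), matrix(0, n, n))
  structure(list(
    S = apply(S_trials, c(1L, 2L), mean),
    R = apply(R_trials, c(1L, 2L), mean),
    S_trials = S_trials,
    R_trials = R_trials,
    n_trials = n_trials,
    events = epochs$events
  ), class = "cov_pair")
}

apply_shrinkage <- function(R, gamma) {
  if (gamma <= 0) return(R)
  (1 - gamma) * R + gamma * mean(diag(R)) * diag(nrow(R))
}

#' Generalized eigendecomposition of a covariance pair
#'
#' Solves the symmetric-definite pencil `S w = lambda R w` (equivalently
#' `R W Lambda = S W`): each eigenvector w is a spatial filter maximizing the
#' Rayleigh quotient `(w'Sw)/(w'Rw)`, the multichannel stimulus-to-baseline
#' variance ratio, and its eigenvalue is that ratio. Solved by Cholesky
#' whitening of R followed by a symmetric eigendecomposition. Eigenvalues are
#' returned in descending order; eigenvectors have unit Euclidean norm with
#' the sign fixed so the largest-magnitude element is positive.
#'
#' Optional shrinkage regularizes R as `(1-gamma) R + gamma mean(diag(R)) I`;
#' common-average-referenced covariances are rank-deficient by one and need
#' `gamma > 0` (the pipeline default is 1e-6). The core default is 0 so that
#' S = R yields eigenvalues exactly 1 to numerical precision.
#'
#' @param S,R symmetric covariance matrices of identical size.
#' @param shrinkage shrinkage weight gamma in \[0, 1).
#' @return object of class `ged_result`: `values` (descending eigenvalues),
#'   `vectors` (columns are eigenvectors), `shrinkage`.
#' @export
compute_ged <- function(S, R, shrinkage = 0) {
  S <- as.matrix(S); R <- as.matrix(R)
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)) ||
      !isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    stop_validation("S and R must be symmetric")
  if (!all(dim(S) == dim(R))) stop_validation("S and R must have identical dimensions")
  S <- (S + t(S)) / 2
  R <- apply_shrinkage((R + t(R)) / 2, shrinkage)
  U <- tryCatch(chol(R), error = function(e)
    stop_numeric("R is singular (not positive-definite); raise the shrinkage ",
                 "parameter (e.g. 1e-6) to regularize"))
  Uinv <- backsolve(U, diag(nrow(R)))
  C <- crossprod(Uinv, S %*% Uinv)
  C <- (C + t(C)) / 2
  eig <- eigen(C, symmetric = TRUE)
  W <- Uinv %*% eig$vectors
  W <- apply(W, 2L, function(w) {
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) -w else w
  })
  structure(list(values = eig$values, vectors = W, shrinkage = shrinkage),
            class = "ged_result")
}

#' @export
print.ged_result <- function(x, ...) {
  cat(sprintf("<ged_result> %d components, top eigenvalues: %s\n",
              length(x$values),
              paste(signif(head(x$values, 5), 4), collapse = ", ")))
  if (!is.null(x$significant))
    cat(sprintf("  significant components: %d (ranks %s)\n",
                sum(x$significant),
                paste(which(x$significant), collapse = ", ")))
  invisible(x)
}

#' Permutation significance test for GED eigenvalues
#'
#' Builds a null distribution of eigenvalues by randomly swapping, for each
#' trial independently with probability 1/2, which of its two windows counts
#' as stimulus and which as baseline, re-averaging, and re-running the GED;
#' this is repeated `n_perm` times (500 in the reference procedure). In the
#' default rank-matched mode the observed k-th eigenvalue is compared with
#' the 99th percentile of the permuted k-th eigenvalues; `mode = "max"`
#' instead compares every observed eigenvalue to the null of the permuted
#' largest eigenvalue (a max-statistic correction).
#'
#' @param cov_pair a `cov_pair` from [build_cov_pair()].
#' @param n_perm number of permutations (default 500).
#' @param percentile null percentile defining significance (default 99).
#' @param seed integer seed for the permutation RNG (required for
#'   reproducibility; `NULL` uses the current RNG state).
#' @param mode `"rank"` (rank-matched null, default) or `"max"`.
#' @param shrinkage shrinkage passed to every GED solve.
#' @return a `ged_result` with extra fields: `significant` (logical mask),
#'   `null_eigenvalues` (components x n_perm matrix), `null_threshold`
#'   (per-component percentile of its null), `n_perm`, `percentile`, `mode`.
#' @export
permutation_significance <- function(cov_pair, n_perm = 500L, percentile = 99,
                                     seed = NULL, mode = c("rank", "max"),
                                     shrinkage = 1e-6) {
  mode <- match.arg(mode)
  if (!inherits(cov_pair, "cov_pair")) stop_validation("need a cov_pair object")
  if (cov_pair$n_trials < 1L) stop_validation("no trials available")
  if (n_perm < 100L) warning("n_perm < 100: percentile threshold will be unstable")
  if (!is.null(seed)) set.seed(seed)
  ged <- compute_ged(cov_pair$S, cov_pair$R, shrinkage = shrinkage)
  n <- nrow(cov_pair$S)
  Ms <- matrix(cov_pair$S_trials, nrow = n * n)  # columns are trials
  Mr <- matrix(cov_pair$R_trials, nrow = n * n)
  null_eig <- cpp_perm_ged_eigs(Ms, Mr, n, as.integer(n_perm), shrinkage)
  null_ref <- if (mode == "rank") null_eig else
    matrix(rep(null_eig[1L, ], each = n), nrow = n)
  thr <- apply(null_ref, 1L, quantile, probs = percentile / 100)
  # tiny relative epsilon: the observed and permuted eigenvalues come from
  # different solvers, so permutation-invariant data must not flip the strict
  # inequality on rounding noise
  ged$significant <- ged$values > thr + 1e-9 * pmax(abs(thr), 1)
  ged$null_eigenvalues <- null_eig
  ged$null_threshold <- thr
  ged$n_perm <- as.integer(n_perm)
  ged$percentile <- percentile
  ged$mode <- mode
  ged
}

#' Component forward-model map
#'
#' The eigenvector itself both boosts signal and suppresses noise, so it is
#' hard to read spatially; multiplying the stimulus covariance by the
#' eigenvector (`S w`) gives the forward model: each contact's contribution
#' to the component.
#'
#' @param S stimulus covariance matrix.
#' @param w eigenvector (spatial filter).
#' @return numeric vector, one value per contact.
#' @export
component_map <- function(S, w) {
  S <- as.matrix(S)
  if (length(w) != ncol(S)) stop_validation("filter length does not match S")
  drop(S %*% w)
}

#' Component time series
#'
#' Projects the contacts x timepoints data matrix through a spatial filter:
#' `w' X`, a weighted average over contacts.
#'
#' @param w eigenvector (spatial filter), or a matrix whose columns are
#'   filters.
#' @param X contacts x timepoints LFP matrix.
#' @return numeric vector (or components x timepoints matrix).
#' @export
component_timeseries <- function(w, X) {
  w <- as.matrix(w)
  if (nrow(w) != nrow(X)) stop_validation("filter length does not match X")
  out <- crossprod(w, X)
  if (ncol(w) == 1L) drop(out) else out
}

#' Full covariance -> GED -> significance chain on a contact subset
#'
#' Used both for complete probes and for in-structure-only reruns (e.g.
#' restricting to contacts inside the amygdala): the session is subset to the
#' retained contacts, epoched, covariance pairs built, GED computed and
#' permutation-tested with identical parameters.
#'
#' @param session an `lfp_session` (typically already re-referenced).
#' @param contact_mask logical vector selecting retained contacts
#'   (default all).
#' @inheritParams permutation_significance
#' @param baseline_window,stimulus_window passed to [epoch_trials()].
#' @return a `ged_result` (with `contact_mask`, `maps` and `cov_pair`
#'   attached; maps are columns of `S %*% W`).
#' @export
run_ged_on_subset <- function(session, contact_mask = NULL, n_perm = 500L,
                              percentile = 99, seed = NULL,
                              mode = c("rank", "max"), shrinkage = 1e-6,
                              baseline_window = c(-1.5, -1.0),
                              stimulus_window = c(0, 1.0)) {
  mode <- match.arg(mode)
  contact_mask <- contact_mask %||% rep(TRUE, nrow(session$lfp))
  if (sum(contact_mask) < 2L) stop_validation("need >= 2 retained contacts")
  sub <- session
  sub$lfp <- session$lfp[contact_mask, , drop = FALSE]
  sub$annotations <- session$annotations[contact_mask, , drop = FALSE]
  epochs <- epoch_trials(sub, baseline_window, stimulus_window)
  pair <- build_cov_pair(epochs)
  res <- permutation_significance(pair, n_perm = n_perm, percentile = percentile,
                                  seed = seed, mode = mode, shrinkage = shrinkage)
  res$contact_mask <- contact_mask
  res$maps <- pair$S %*% res$vectors
  res$cov_pair <- pair
  res
}
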