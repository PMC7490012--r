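# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results through different algorithms than the
# package (enumeration, nonsymmetric eigensolvers, recursive flood fill) so
# agreement is evidence, not tautology.

quick_cfg <- function(n_trials = 4L, seed = 1L, ...) {
  sim_config(n_trials_per_modality = n_trials, seed = seed, ...)
}

flat_annotations <- function(nuclei, boundary = NULL, in_structure = NULL) {
  n <- length(nuclei)
  data.frame(
    contact = seq_len(n),
    nucleus = nuclei,
    boundary = boundary %||% rep(FALSE, n),
    in_structure = in_structure %||% (nuclei != "outside"),
    excluded = FALSE,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_spd <- function(n) {
  A <- matrix(rnorm(n * (n + 2L)), n + 2L, n)
  crossprod(A) / (n + 2L)
}

# GED oracle via the nonsymmetric route: eigen of solve(R) %*% S.
oracle_ged <- function(S, R) {
  e <- eigen(solve(R) %*% S)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values)[ord]
  vecs <- Re(e$vectors)[, ord, drop = FALSE]
  vecs <- apply(vecs, 2L, function(w) {
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) -w else w
  })
  list(values = vals, vectors = vecs)
}

# Exhaustive penalized change-in-mean segmentation: tries all 2^(n-1)
# segmentations of the vector and returns the minimum-cost one.
oracle_segment <- function(x, penalty = 0.05) {
  n <- length(x)
  best_cost <- Inf; best_bounds <- integer(0)
  for (mask in 0:(2^(n - 1L) - 1L)) {
    bounds <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0L)  # changepoint after i
    seg <- cumsum(seq_len(n) %in% (bounds + 1L)) + 1L
    cost <- sum(tapply(x, seg, function(v) sum((v - mean(v))^2))) +
      penalty * length(bounds)
    if (cost < best_cost - 1e-12) {
      best_cost <- cost; best_bounds <- bounds
    }
  }
  list(changepoints = best_bounds, cost = best_cost)
}

# Independent application of the matching rules, organized segment-first
# (the package iterates contacts): for every segment find its dominant
# nucleus among evaluated contacts; for every nucleus find its largest
# group; count contacts satisfying both.
oracle_match_count <- function(seg, ann) {
  eval_idx <- which(ann$in_structure & !ann$boundary)
  if (length(eval_idx) == 0L) return(0L)
  n_match <- 0L
  for (i in eval_idx) {
    g <- seg[i]; v <- ann$nucleus[i]
    in_g <- eval_idx[seg[eval_idx] == g]
    # dominant nucleus in segment g (first-along-probe tie break)
    nucs <- ann$nucleus[in_g]
    counts <- sapply(unique(nucs), function(u) sum(nucs == u))
    dom <- unique(nucs)[which.max(counts)]
    # largest segment-group of nucleus v (lowest segment id tie break)
    in_v <- eval_idx[ann$nucleus[eval_idx] == v]
    segs_v <- sort(unique(seg[in_v]))
    sizes <- sapply(segs_v, function(s) sum(seg[in_v] == s))
    best_seg <- segs_v[which.max(sizes)]
    if (dom == v && g == best_seg) n_match <- n_match + 1L
  }
  n_match
}

# Recursive flood fill with 4-connectivity, depth-first in R.
oracle_flood_fill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || labels[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j))
    labels[i, j] <- nxt
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- cur[1] + d[1]; c2 <- cur[2] + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (mask[r2, c2] && labels[r2, c2] == 0L) {
          labels[r2, c2] <- nxt
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  labels
}

# Label matrices are equivalent if they induce the same partition of cells.
same_partition <- function(a, b) {
  ua <- unique(as.vector(a[a > 0]))
  for (la in ua) {
    cells <- a == la
    lb <- unique(as.vector(b[cells]))
    if (length(lb) != 1L || lb == 0L) return(FALSE)
    if (!all(b[cells] == lb) || sum(b == lb) != sum(cells)) return(FALSE)
  }
  sum(a > 0) == sum(b > 0)
}

# Synthetic component time series with a stimulus-locked amplitude gain on
# one oscillator, for TF tests. Returns list(series, events, fs).
gained_component_series <- function(cfg, freq, gain, noise_sd = 0.3) {
  stopifnot(!is.null(cfg$seed))
  set.seed(cfg$seed)
  sched <- lfpged:::make_schedule(cfg)
  fs <- cfg$sampling_rate_hz
  n <- ceiling(sched$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  amp <- rep(1, n)
  for (k in seq_len(nrow(sched$events))) {
    i0 <- floor(sched$events$stimulus_onset_s[k] * fs) + 1L
    i1 <- min(n, i0 + round(cfg$stimulus_duration_s * fs) - 1L)
    amp[i0:i1] <- gain
  }
  x <- amp * cos(2 * pi * freq * t + runif(1, 0, 2 * pi)) +
    lfpged:::pink_noise(n, fs, 1, noise_sd)[, 1]
  list(series = x, events = sched$events, fs = fs)
}

# Minimal hand-built tf_map for cluster bookkeeping tests.
fake_tf_map <- function(z, null_max_mass, threshold = 2.33, freqs = NULL) {
  structure(list(
    z = z, diff = z, mu = z * 0, sd = z * 0 + 1,
    null_max_mass = null_max_mass,
    time_s = seq_len(ncol(z)), freqs = freqs %||% seq_len(nrow(z)),
    threshold = threshold, n_shuffle = length(null_max_mass),
    jitter_s = 0.5, modality = NULL
  ), class = "tf_map")
}
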