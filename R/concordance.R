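#' Penalized change-in-mean segmentation of a component map
#'
#' Finds the changepoints that minimize the total within-segment sum of
#' squared deviations from segment means, paying a fixed additive penalty per
#' changepoint: a candidate changepoint that does not reduce the residual
#' error by at least `penalty` is rejected. Solved exactly by dynamic
#' programming (O(n^2), trivial for 16-contact probes), so results agree with
#' exhaustive enumeration over all segmentations.
#'
#' @param map numeric vector of per-contact component-map values.
#' @param penalty additive penalty per changepoint (default 0.05).
#' @return object of class `changepoint_result`: `changepoints` (indices i
#'   meaning a mean shift between positions i and i+1; empty if none),
#'   `segments` (integer segment id per position), `segment_means`, `cost`
#'   (penalized residual), `penalty`.
#' @export
detect_changepoints <- function(map, penalty = 0.05) {
  map <- as.numeric(map)
  n <- length(map)
  if (n < 2L) stop_validation("map must have length >= 2")
  if (any(!is.finite(map))) stop_validation("map contains non-finite values")
  cs <- cumsum(map); cs2 <- cumsum(map^2)
  sse <- function(i, j) { # segment cost for positions i..j
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  best <- numeric(n + 1L)   # best[j+1] = optimal cost of segmenting 1..j
  back <- integer(n + 1L)
  best[1L] <- 0
  for (j in seq_len(n)) {
    costs <- vapply(seq_len(j), function(i) {
      best[i] + sse(i, j) + if (i > 1L) penalty else 0
    }, 0)
    k <- which.min(costs)
    best[j + 1L] <- costs[k]
    back[j + 1L] <- k
  }
  bounds <- integer(0)
  j <- n
  while (j > 0L) {
    i <- back[j + 1L]
    if (i > 1L) bounds <- c(i - 1L, bounds)
    j <- i - 1L
  }
  seg <- cumsum(seq_len(n) %in% (bounds + 1L)) + 1L
  structure(list(
    changepoints = bounds,
    segments = seg,
    segment_means = as.numeric(tapply(map, seg, mean)),
    cost = best[n + 1L],
    penalty = penalty
  ), class = "changepoint_result")
}

#' Count contacts whose statistical grouping matches their anatomy
#'
#' Applies the matching rules comparing a changepoint segmentation of a
#' component map with the anatomical (nucleus) grouping of the same contacts:
#' a contact counts as matching iff (a) it lies in the segment that captures
#' the most contacts of its nucleus (a nucleus split across segments
#' contributes only its largest group), and (b) its nucleus is the
#' best-represented nucleus within that segment (a segment spanning several
#' nuclei credits only the dominant one). Contacts flagged as near a nucleus
#' boundary (within 200 um) and contacts outside the structure are excluded:
#' they count as neither matching nor non-matching and do not enter the
#' representation counts. Ties (equally represented nuclei, equally sized
#' groups) are broken toward the lower contact index.
#'
#' @param segmentation a `changepoint_result` (or integer vector of segment
#'   ids per position).
#' @param annotations data.frame with columns `nucleus`, `boundary`,
#'   `in_structure`, one row per map position.
#' @return object of class `match_result`: `n_matching`, `n_evaluated`,
#'   `percent` (100 * n_matching / n_evaluated), `matching` (logical per
#'   position, NA for excluded contacts).
#' @export
count_matching_contacts <- function(segmentation, annotations) {
  seg <- if (inherits(segmentation, "changepoint_result"))
    segmentation$segments else as.integer(segmentation)
  if (nrow(annotations) != length(seg))
    stop_validation("annotations and segmentation cover different numbers of contacts")
  evaluated <- annotations$in_structure & !annotations$boundary
  nuc <- as.character(annotations$nucleus)
  matching <- rep(NA, length(seg))
  idx_eval <- which(evaluated)
  if (length(idx_eval) == 0L)
    return(structure(list(n_matching = 0L, n_evaluated = 0L, percent = NA_real_,
                          matching = matching), class = "match_result"))
  # majority segment of each nucleus (over evaluated contacts)
  maj_seg <- vapply(unique(nuc[idx_eval]), function(v) {
    segs <- seg[idx_eval][nuc[idx_eval] == v]
    cand <- sort(unique(segs))
    counts <- vapply(cand, function(g) sum(segs == g), 0L)
    cand[which.max(counts)]  # first max = lower segment id on ties
  }, 0L)
  # dominant nucleus of each segment (over evaluated contacts); ties broken
  # toward the nucleus appearing first along the probe
  dom_nuc <- vapply(unique(seg[idx_eval]), function(g) {
    v <- nuc[idx_eval][seg[idx_eval] == g]
    tab <- table(factor(v, levels = unique(v)))  # unique() preserves probe order
    names(tab)[which.max(tab)]
  }, "")
  names(dom_nuc) <- unique(seg[idx_eval])
  for (i in idx_eval) {
    matching[i] <- (seg[i] == maj_seg[[nuc[i]]]) &&
      (dom_nuc[[as.character(seg[i])]] == nuc[i])
  }
  n_eval <- length(idx_eval)
  n_match <- sum(matching[idx_eval])
  structure(list(n_matching = n_match, n_evaluated = n_eval,
                 percent = 100 * n_match / n_eval, matching = matching),
            class = "match_result")
}

#' Cut-and-shift permutation null for anatomical concordance
#'
#' Builds the chance distribution of matching-contact counts for one
#' component map: the in-structure subvector of the map is cut at a random
#' point and the values before the cut are moved to the end (a circular
#' shift, drawn uniformly from the len-1 non-identity shifts), the
#' changepoint segmentation is recomputed on the shifted values, and the
#' matching count is re-evaluated against the unchanged anatomical
#' annotations. Shifting permutes values while preserving their multiset and
#' most of their local ordering, so it is a spatial null.
#'
#' @param map numeric component map over all probe contacts.
#' @param annotations per-contact annotation data.frame (see
#'   [count_matching_contacts()]).
#' @param n number of permutations (default 1000).
#' @param penalty changepoint penalty (default 0.05).
#' @param seed integer seed (`NULL` = current RNG state).
#' @return integer vector of `n` null matching counts.
#' @export
cut_and_shift_null <- function(map, annotations, n = 1000L, penalty = 0.05,
                               seed = NULL) {
  in_idx <- which(annotations$in_structure)
  sub <- map[in_idx]
  len <- length(sub)
  if (len < 3L) stop_validation("need >= 3 in-structure contacts for cut-and-shift")
  if (!is.null(seed)) set.seed(seed)
  ann_sub <- annotations[in_idx, , drop = FALSE]
  shifts <- sample.int(len - 1L, n, replace = TRUE)
  vapply(shifts, function(s) {
    shifted <- c(sub[(s + 1L):len], sub[1:s])
    cp <- detect_changepoints(shifted, penalty)
    count_matching_contacts(cp, ann_sub)$n_matching
  }, 0L)
}

#' Concordance analysis of one component map
#'
#' Convenience wrapper running the observed segmentation, the matching count,
#' and the cut-and-shift null on the in-structure contacts of one component.
#' The map is segmented on its in-structure subvector so that observed and
#' null counts are computed identically.
#'
#' @inheritParams cut_and_shift_null
#' @param n_perm cut-and-shift permutations.
#' @return list: `changepoints` (on the in-structure subvector), `match`
#'   (a `match_result`), `null_counts`, `null_mean`, `null_sd`.
#' @export
component_concordance <- function(map, annotations, penalty = 0.05,
                                  n_perm = 1000L, seed = NULL) {
  in_idx <- which(annotations$in_structure)
  if (length(in_idx) < 3L) stop_validation("need >= 3 in-structure contacts")
  cp <- detect_changepoints(map[in_idx], penalty)
  match <- count_matching_contacts(cp, annotations[in_idx, , drop = FALSE])
  null_counts <- cut_and_shift_null(map, annotations, n = n_perm,
                                    penalty = penalty, seed = seed)
  list(changepoints = cp, match = match, null_counts = null_counts,
       null_mean = mean(null_counts), null_sd = sd(null_counts))
}

#' Rank-wise paired t-tests of concordance against the permutation null
#'
#' For each component rank group (1st, 2nd, ... strongest components across
#' sessions), pairs every component's observed matching count with the mean
#' of its own cut-and-shift null and runs a paired t-test across the group,
#' Bonferroni-corrected for the five rank comparisons (alpha = 0.05/5 =
#' 0.01).
#'
#' @param observed_by_rank list (one element per rank) of numeric vectors of
#'   observed matching counts, one entry per component.
#' @param null_means_by_rank list of the matching null means, same shapes.
#' @param alpha family-wise alpha before Bonferroni division (default 0.05).
#' @param n_comparisons Bonferroni divisor (default 5).
#' @return data.frame with one row per rank: `rank`, `n`, `t`, `df`, `p`,
#'   `ci_lo`, `ci_hi`, `significant`, `alpha_adjusted`. Ranks with fewer than
#'   two components are skipped with a warning.
#' @export
rank_group_test <- function(observed_by_rank, null_means_by_rank,
                            alpha = 0.05, n_comparisons = 5L) {
  if (length(observed_by_rank) != length(null_means_by_rank))
    stop_validation("rank lists must align")
  alpha_adj <- alpha / n_comparisons
  rows <- lapply(seq_along(observed_by_rank), function(r) {
    obs <- observed_by_rank[[r]]; nul <- null_means_by_rank[[r]]
    if (length(obs) != length(nul))
      stop_validation("rank ", r, ": observed and null lengths differ")
    if (length(obs) < 2L) {
      warning("rank ", r, " has fewer than 2 components; skipped")
      return(NULL)
    }
    d <- obs - nul
    if (sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
      # degenerate paired test: all differences identical
      t_val <- if (all(d == 0)) 0 else Inf * sign(d[1])
      p <- if (all(d == 0)) 1 else 0
      return(data.frame(rank = r, n = length(obs), t = t_val,
                        df = length(obs) - 1L, p = p,
                        ci_lo = mean(d), ci_hi = mean(d),
                        significant = p < alpha_adj, alpha_adjusted = alpha_adj))
    }
    tt <- t.test(obs, nul, paired = TRUE, conf.level = 0.95)
    data.frame(rank = r, n = length(obs), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               significant = tt$p.value < alpha_adj, alpha_adjusted = alpha_adj)
  })
  do.call(rbind, rows)
}
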