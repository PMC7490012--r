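// Shuffle engine for the time-frequency cluster-mass test: builds the
// label-swapped, jittered difference maps, z-scores, and extracts the
// per-shuffle maximum absolute cluster mass (4-connectivity flood fill).

#include <RcppArmadillo.h>
#include <stack>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// 4-connected labelling of mask (freq x time). 0 = background; clusters
// numbered in column-major first-encounter order.
static int flood_label(const arma::umat& mask, arma::imat& labels) {
  const int nr = mask.n_rows, nc = mask.n_cols;
  labels.zeros(nr, nc);
  int next = 0;
  std::stack<std::pair<int, int> > st;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++next;
      st.push(std::make_pair(r, c));
      labels(r, c) = next;
      while (!st.empty()) {
        std::pair<int, int> cur = st.top();
        st.pop();
        int rr = cur.first, cc = cur.second;
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int r2 = rr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && labels(r2, c2) == 0) {
            labels(r2, c2) = next;
            st.push(std::make_pair(r2, c2));
          }
        }
      }
    }
  }
  return next;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label_clusters(const LogicalMatrix& mask) {
  arma::umat m(mask.nrow(), mask.ncol());
  for (int i = 0; i < mask.nrow(); ++i)
    for (int j = 0; j < mask.ncol(); ++j)
      m(i, j) = mask(i, j) ? 1 : 0;
  arma::imat labels;
  flood_label(m, labels);
  IntegerMatrix out(mask.nrow(), mask.ncol());
  for (int i = 0; i < mask.nrow(); ++i)
    for (int j = 0; j < mask.ncol(); ++j)
      out(i, j) = (int)labels(i, j);
  return out;
}

// Max |cluster mass| over positive (z > thr) and negative (z < -thr)
// clusters, kept separate.
static double max_abs_cluster_mass(const arma::mat& z, double thr) {
  double best = 0.0;
  arma::imat labels;
  for (int sgn = 0; sgn < 2; ++sgn) {
    arma::umat mask;
    if (sgn == 0) mask = z > thr; else mask = z < -thr;
    int n = flood_label(mask, labels);
    if (n == 0) continue;
    arma::vec mass(n, arma::fill::zeros);
    for (arma::uword j = 0; j < z.n_cols; ++j)
      for (arma::uword i = 0; i < z.n_rows; ++i)
        if (labels(i, j) > 0) mass(labels(i, j) - 1) += z(i, j);
    double m = arma::abs(mass).max();
    if (m > best) best = m;
  }
  return best;
}

static int draw_jitter(int jitter_bins) {
  if (jitter_bins <= 0) return 0;
  // uniform integer in [-jitter_bins, jitter_bins]
  return (int)std::floor(unif_rand() * (2 * jitter_bins + 1)) - jitter_bins;
}

// power: freq x bins. stim_anchor/base_anchor: per-trial 0-based start bins
// of the stimulus and baseline windows. A shuffle swaps each trial's window
// roles with probability 1/2 and jitters each window start by a uniform
// integer in [-jitter_bins, jitter_bins], redrawing if the window leaves the
// recording. The difference map is the trial-mean time-resolved stimulus
// window minus the trial- and time-mean baseline power per frequency.
// Returns observed diff, shuffle mean/sd, observed z, and the per-shuffle
// max |cluster mass| of the z-scored shuffle maps at `threshold`.
// [[Rcpp::export]]
List cpp_shuffle_zscore(const arma::mat& power,
                        const arma::ivec& stim_anchor,
                        const arma::ivec& base_anchor,
                        int stim_len, int base_len,
                        int jitter_bins, int n_shuffle, double threshold) {
  const int nf = power.n_rows;
  const int nb = power.n_cols;
  const int nt = stim_anchor.n_elem;
  if (base_anchor.n_elem != (unsigned)nt) stop("anchor vectors differ in length");
  if (nt < 1) stop("no trials");

  // observed difference map
  arma::mat diff(nf, stim_len, arma::fill::zeros);
  arma::vec base(nf, arma::fill::zeros);
  for (int t = 0; t < nt; ++t) {
    if (stim_anchor(t) < 0 || stim_anchor(t) + stim_len > nb ||
        base_anchor(t) < 0 || base_anchor(t) + base_len > nb)
      stop("a trial's analysis window falls outside the recording");
    diff += power.cols(stim_anchor(t), stim_anchor(t) + stim_len - 1);
    base += arma::mean(power.cols(base_anchor(t), base_anchor(t) + base_len - 1), 1);
  }
  diff /= nt;
  base /= nt;
  diff.each_col() -= base;

  // cumulative sum over time per frequency: baseline (time-averaged) window
  // means come from two column reads instead of base_len
  arma::mat csum(nf, nb + 1, arma::fill::zeros);
  for (int c = 0; c < nb; ++c)
    csum.col(c + 1) = csum.col(c) + power.col(c);

  // shuffled maps
  arma::cube maps(nf, stim_len, n_shuffle);
  const double* P = power.memptr();
  for (int s = 0; s < n_shuffle; ++s) {
    arma::mat d(nf, stim_len, arma::fill::zeros);
    arma::vec b(nf, arma::fill::zeros);
    double* D = d.memptr();
    for (int t = 0; t < nt; ++t) {
      bool swap = unif_rand() < 0.5;
      int s_anchor = swap ? base_anchor(t) : stim_anchor(t);
      int b_anchor = swap ? stim_anchor(t) : base_anchor(t);
      int s_start, b_start;
      do {
        s_start = s_anchor + draw_jitter(jitter_bins);
      } while (s_start < 0 || s_start + stim_len > nb);
      do {
        b_start = b_anchor + draw_jitter(jitter_bins);
      } while (b_start < 0 || b_start + base_len > nb);
      const double* src = P + (size_t)s_start * nf;
      for (int j = 0; j < stim_len * nf; ++j) D[j] += src[j];
      b += (csum.col(b_start + base_len) - csum.col(b_start)) / base_len;
    }
    d /= nt;
    b /= nt;
    d.each_col() -= b;
    maps.slice(s) = d;
  }

  arma::mat mu(nf, stim_len, arma::fill::zeros);
  for (int s = 0; s < n_shuffle; ++s) mu += maps.slice(s);
  mu /= n_shuffle;
  arma::mat var(nf, stim_len, arma::fill::zeros);
  for (int s = 0; s < n_shuffle; ++s)
    var += arma::square(maps.slice(s) - mu);
  var /= std::max(n_shuffle - 1, 1);        // n-1 normalization
  arma::mat sdm = arma::sqrt(var);
  const double eps = 1e-12;
  arma::mat sd_safe = sdm;
  sd_safe.transform([eps](double v) { return v < eps ? 1.0 : v; });
  arma::mat z = (diff - mu) / sd_safe;
  z.elem(arma::find(sdm < eps)).zeros();

  arma::vec null_max(n_shuffle);
  for (int s = 0; s < n_shuffle; ++s) {
    arma::mat zs = (maps.slice(s) - mu) / sd_safe;
    zs.elem(arma::find(sdm < eps)).zeros();
    null_max(s) = max_abs_cluster_mass(zs, threshold);
  }

  return List::create(_["diff"] = diff, _["mu"] = mu, _["sd"] = sdm,
                      _["z"] = z, _["null_max_mass"] = null_max);
}
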