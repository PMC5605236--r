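#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Dynamic-programming alignment of an ordered molecule label pattern to an
// ordered reference nick-site list.  Scores are log-likelihood ratios of the
// placement hypothesis against a random-genome label process of density
// `lambda` (labels per bp).  See align_molecule() for the model description.
//
// u:  oriented molecule label positions (ascending, bp)
// L:  molecule length (bp)
// v:  reference site positions (ascending, bp)
// R:  reference length (bp)
// tel_at_start: TRUE if the telomeric end of the reference is at coordinate 0
//   (p-arm convention); FALSE for q-arm (telomere at coordinate R).
// rel_sd, sd_floor: sizing error model, sd(y) = sqrt((rel_sd*y)^2 + sd_floor^2)
// lambda: random-genome label density (per bp)
// clean_per_bp: lambda * (1 - extra_rate); per-bp reward for molecule extent
//   explained by the placement (both hypotheses' Poisson integrals folded in)
// miss_pen: -log(miss rate), cost of a spanned-but-unlabeled reference site
// extra_pen: -log(extra rate), cost of an unexplained molecule label
// match_logp: log(1 - miss rate), per matched pair
// max_skip: max consecutive skipped sites/labels between matched pairs
// sv_cap: cap on the half-squared sizing z-score per interval (outlier/SV
//   tolerance); pass R_PosInf to disable.
// max_tract: molecule overhang beyond the telomeric reference end is
//   treated as unlabeled (TTAGGG)n tract (clean-extent credit, spurious
//   labels charged) only up to this many bp; beyond it — and beyond the
//   centromeric end — the reference cannot evaluate the molecule, so
//   extent and labels there are neutral.
//
// Returns best total score, matched pairs (1-based oriented indices), and the
// full endpoint-total matrix (NA where no valid >=2-pair path ends there),
// used by the caller for confidence computation.

static const double NEG = -1e30;
static const double HALF_LOG_2PI = 0.9189385332046727;

// [[Rcpp::export(name = ".dp_align_cpp")]]
List dp_align_cpp(NumericVector u, double L, NumericVector v, double R,
                  bool tel_at_start, double rel_sd, double sd_floor,
                  double lambda, double clean_per_bp, double miss_pen,
                  double extra_pen, double match_logp, int max_skip,
                  double sv_cap, double max_tract) {
  const int n = u.size(), m = v.size();
  const double log_lambda = std::log(lambda);
  NumericMatrix S(n, m);        // best score of a path ending at pair (i,j)
  IntegerMatrix NP(n, m);       // pairs on that path
  IntegerMatrix Pi(n, m), Pj(n, m);   // parent pointers (0-based; -1 = none)
  IntegerMatrix Src(n, m);            // 1 = parent is a path start
  NumericMatrix head(n, m), tail(n, m);

  // head/tail adjustments for a path starting or ending at (i,j)
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double off = v[j] - u[i];
      // --- head: molecule [0, u[i]) maps to reference [off, v[j])
      double h = 0.0;
      double lo = std::max(0.0, off);
      // spanned reference sites distal of the first matched site
      int nmiss = (int)(std::lower_bound(v.begin(), v.end(), v[j]) -
                        std::lower_bound(v.begin(), v.end(), lo));
      h -= miss_pen * nmiss;
      for (int k = 0; k < i; ++k) {
        double w = u[k] + off;
        if (w >= 0.0) h -= extra_pen;
        else if (tel_at_start && w >= -max_tract) h -= extra_pen;
        // labels beyond the tract window (or over a centromeric start)
        // are expected genomic labels: neutral
      }
      if (off < 0.0) {
        double beyond = tel_at_start ? std::max(0.0, -off - max_tract)
                                     : -off;
        h -= clean_per_bp * beyond;
      }
      head(i, j) = h;

      // --- tail: molecule [u[i], L) maps to reference (v[j], L + off]
      double t = 0.0;
      double hi = std::min(R, L + off);
      int nmiss2 = (int)(std::upper_bound(v.begin(), v.end(), hi) -
                         std::upper_bound(v.begin(), v.end(), v[j]));
      t -= miss_pen * nmiss2;
      for (int k = i + 1; k < n; ++k) {
        double w = u[k] + off;
        if (w <= R) t -= extra_pen;
        else if (!tel_at_start && w <= R + max_tract) t -= extra_pen;
      }
      if (L + off > R) {
        double over = L + off - R;
        double beyond = tel_at_start ? over
                                     : std::max(0.0, over - max_tract);
        t -= clean_per_bp * beyond;
      }
      tail(i, j) = t;
    }
  }

  // two layers: a path of exactly one pair (its score is head(i,j)) and
  // the best path of >= 2 pairs ending at (i,j).  Keeping them separate
  // matters: a high single-pair start must not shadow a lower-scoring
  // multi-pair path, because only >= 2-pair paths are valid alignments.
  const double eps = 1e-9;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double best = NEG;
      int bnp = 0, bpi = -1, bpj = -1, bsrc = 0;
      int i0 = std::max(0, i - 1 - max_skip);
      int j0 = std::max(0, j - 1 - max_skip);
      for (int ip = i0; ip < i; ++ip) {
        for (int jp = j0; jp < j; ++jp) {
          double prev = head(ip, jp);   // start a path at (ip, jp)
          int pnp = 1;
          if (S(ip, jp) > prev + eps ||
              (S(ip, jp) > prev - eps && NP(ip, jp) > pnp)) {
            prev = S(ip, jp); pnp = NP(ip, jp);
          }
          if (prev <= NEG) continue;
          double x = u[i] - u[ip];
          double y = v[j] - v[jp];
          double sd = std::sqrt(rel_sd * rel_sd * y * y + sd_floor * sd_floor);
          double z = (x - y) / sd;
          double gauss = -std::log(sd) - HALF_LOG_2PI -
                         std::min(0.5 * z * z, sv_cap);
          double I = match_logp + gauss - log_lambda -
                     miss_pen * (j - jp - 1) - extra_pen * (i - ip - 1);
          double cand = prev + I;
          int cnp = pnp + 1;
          if (cand > best + eps ||
              (cand > best - eps && cnp > bnp)) {
            best = cand; bnp = cnp; bpi = ip; bpj = jp;
            bsrc = (pnp == 1) ? 1 : 0;
          }
        }
      }
      S(i, j) = best; NP(i, j) = bnp; Pi(i, j) = bpi; Pj(i, j) = bpj;
      Src(i, j) = bsrc;
    }
  }

  const double G0 = clean_per_bp * L;
  NumericMatrix totals(n, m);
  double best_total = NA_REAL;
  int bi = -1, bj = -1, bnp = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (NP(i, j) >= 2) {
        double tot = S(i, j) + tail(i, j) + G0;
        totals(i, j) = tot;
        if (bi < 0 || tot > best_total + eps ||
            (tot > best_total - eps && NP(i, j) > bnp)) {
          best_total = tot; bi = i; bj = j; bnp = NP(i, j);
        }
      } else {
        totals(i, j) = NA_REAL;
      }
    }
  }

  IntegerMatrix pairs(0, 2);
  if (bi >= 0) {
    std::vector<int> pi_, pj_;
    int ci = bi, cj = bj;
    pi_.push_back(ci); pj_.push_back(cj);
    while (Pi(ci, cj) >= 0) {
      int ni = Pi(ci, cj), nj = Pj(ci, cj);
      bool parent_is_start = Src(ci, cj) == 1;
      pi_.push_back(ni); pj_.push_back(nj);
      if (parent_is_start) break;
      ci = ni; cj = nj;
    }
    int k = pi_.size();
    pairs = IntegerMatrix(k, 2);
    for (int t = 0; t < k; ++t) {
      pairs(t, 0) = pi_[k - 1 - t] + 1;  // 1-based
      pairs(t, 1) = pj_[k - 1 - t] + 1;
    }
  }

  return List::create(_["score"] = best_total, _["pairs"] = pairs,
                      _["totals"] = totals, _["npairs"] = bnp);
}
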