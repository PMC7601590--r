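// Ensemble co-occurrence scoring engine.
//
// For every fungus x bacterium pair this computes, for each of the four
// association measures (Spearman, Kendall tau-b, Bray-Curtis, symmetrized
// Kullback-Leibler): the observed score, the mean/sd of a ReBoot-style
// permutation null (independent shuffling of the two taxa with per-sample
// re-closure of the composition for the correlation measures), and the
// mean/sd/percentile-CI of a bootstrap distribution over samples.
//
// All randomness comes from R's RNG (unif_rand), so set.seed() in R makes
// every scan reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;


static void midrank(const std::vector<double>& x, std::vector<int>& idx,
                    std::vector<double>& r) {
  const int n = (int)x.size();
  idx.resize(n); r.resize(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
    const double rr = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) r[idx[k]] = rr;
    i = j + 1;
  }
}

static double pearson(const std::vector<double>& a,
                      const std::vector<double>& b) {
  const int n = (int)a.size();
  double ma = 0, mb = 0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0, sa = 0, sb = 0;
  for (int i = 0; i < n; ++i) {
    const double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; sa += da * da; sb += db * db;
  }
  if (sa <= 0 || sb <= 0) return NA_REAL;
  return sab / std::sqrt(sa * sb);
}

struct ScoreWork {                 // scratch buffers reused across calls
  std::vector<int> idx;
  std::vector<double> rx, ry;
};

static double spearman_stat(const std::vector<double>& x,
                            const std::vector<double>& y, ScoreWork& w) {
  midrank(x, w.idx, w.rx);
  std::vector<double> rx = w.rx;   // midrank reuses buffers
  midrank(y, w.idx, w.ry);
  return pearson(rx, w.ry);
}

static double kendall_taub(const std::vector<double>& x,
                           const std::vector<double>& y) {
  const int n = (int)x.size();
  double num = 0, dx = 0, dy = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double sx = (x[i] < x[j]) ? -1.0 : ((x[i] > x[j]) ? 1.0 : 0.0);
      const double sy = (y[i] < y[j]) ? -1.0 : ((y[i] > y[j]) ? 1.0 : 0.0);
      num += sx * sy; dx += sx * sx; dy += sy * sy;
    }
  if (dx <= 0 || dy <= 0) return NA_REAL;
  return num / std::sqrt(dx * dy);
}

static double bray_stat(const std::vector<double>& x,
                        const std::vector<double>& y) {
  double num = 0, den = 0;
  for (size_t i = 0; i < x.size(); ++i) {
    num += std::fabs(x[i] - y[i]);
    den += x[i] + y[i];
  }
  if (den <= 0) return NA_REAL;
  return num / den;
}

// symmetrized KL divergence on the across-sample-normalized profiles.
// The pseudocount is 1% of each profile's mean so that a zero cell is a
// bounded log-ratio away from typical values (scale-invariant; an
// absolute pseudocount would let one co-zero sample dominate the
// divergence).
static double kld_stat(const std::vector<double>& x,
                       const std::vector<double>& y) {
  const int n = (int)x.size();
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  if (mx <= 0 || my <= 0) return NA_REAL;
  const double ex = 0.01 * mx / n, ey = 0.01 * my / n;
  double sx = mx + n * ex, sy = my + n * ey;
  double d = 0;
  for (int i = 0; i < n; ++i) {
    const double xi = (x[i] + ex) / sx, yi = (y[i] + ey) / sy;
    d += 0.5 * (xi - yi) * std::log(xi / yi);
  }
  return d;
}

static double score_one(int measure, const std::vector<double>& x,
                        const std::vector<double>& y, ScoreWork& w) {
  switch (measure) {
  case 0: return spearman_stat(x, y, w);
  case 1: return kendall_taub(x, y);
  case 2: return bray_stat(x, y);
  default: return kld_stat(x, y);
  }
}

// [[Rcpp::export]]
double pair_score_cpp(NumericVector x, NumericVector y, int measure) {
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  ScoreWork w;
  return score_one(measure, xv, yv, w);
}

static void shuffle_into(const std::vector<double>& src,
                         std::vector<double>& dst) {
  const int n = (int)src.size();
  dst = src;
  for (int k = n - 1; k > 0; --k) {
    int j = (int)(unif_rand() * (k + 1));
    if (j > k) j = k;
    std::swap(dst[k], dst[j]);
  }
}

static double quantile7(std::vector<double>& v, double q) {
  if (v.empty()) return NA_REAL;
  std::sort(v.begin(), v.end());
  const double h = ((double)v.size() - 1.0) * q;
  const int lo = (int)std::floor(h);
  const int hi = std::min(lo + 1, (int)v.size() - 1);
  return v[lo] + (h - lo) * (v[hi] - v[lo]);
}

// F, B: samples x taxa relative-abundance slices of one closed composition;
// tot: per-sample total over ALL taxa of the composition (so the "other"
// mass for a pair is tot - x - y).
// Returns, per measure, matrices (nf x nb) of observed score, null mean/sd,
// bootstrap mean/sd and percentile CI bounds, plus the count of skipped
// degenerate bootstrap iterations.
// [[Rcpp::export]]
List ensemble_scan_cpp(NumericMatrix F, NumericMatrix B, NumericVector tot,
                       int b_perm, int b_boot, double ci_level,
                       bool renorm_corr) {
  const int n = F.nrow(), nf = F.ncol(), nb = B.ncol();
  if (B.nrow() != n || tot.size() != n)
    stop("sample dimension mismatch in ensemble scan");
  const double qlo = (1.0 - ci_level) / 2.0, qhi = 1.0 - qlo;

  std::vector<NumericMatrix> obs(4), nmean(4), nsd(4), bmean(4), bsd(4),
      lo(4), hi(4), skipped(4);
  for (int m = 0; m < 4; ++m) {
    obs[m] = NumericMatrix(nf, nb); nmean[m] = NumericMatrix(nf, nb);
    nsd[m] = NumericMatrix(nf, nb); bmean[m] = NumericMatrix(nf, nb);
    bsd[m] = NumericMatrix(nf, nb); lo[m] = NumericMatrix(nf, nb);
    hi[m] = NumericMatrix(nf, nb); skipped[m] = NumericMatrix(nf, nb);
  }

  ScoreWork w;
  std::vector<double> x(n), y(n), o(n), xp(n), yp(n), xr(n), yr(n),
      xb(n), yb(n);
  std::vector<std::vector<double> > boots(4);

  for (int fi = 0; fi < nf; ++fi) {
    for (int bi = 0; bi < nb; ++bi) {
      for (int s = 0; s < n; ++s) {
        x[s] = F(s, fi); y[s] = B(s, bi);
        o[s] = tot[s] - x[s] - y[s];
      }
      for (int m = 0; m < 4; ++m) obs[m](fi, bi) = score_one(m, x, y, w);

      // ReBoot permutation null
      double nsum[4] = {0, 0, 0, 0}, nsq[4] = {0, 0, 0, 0};
      int ncnt[4] = {0, 0, 0, 0};
      for (int it = 0; it < b_perm; ++it) {
        shuffle_into(x, xp);
        shuffle_into(y, yp);
        for (int m = 0; m < 4; ++m) {
          double sc;
          if (m <= 1 && renorm_corr) {
            for (int s = 0; s < n; ++s) {
              const double t = o[s] + xp[s] + yp[s];
              xr[s] = (t > 0) ? xp[s] / t : 0.0;
              yr[s] = (t > 0) ? yp[s] / t : 0.0;
            }
            sc = score_one(m, xr, yr, w);
          } else {
            sc = score_one(m, xp, yp, w);
          }
          if (!ISNAN(sc)) { nsum[m] += sc; nsq[m] += sc * sc; ++ncnt[m]; }
        }
      }
      for (int m = 0; m < 4; ++m) {
        if (ncnt[m] > 1) {
          const double mu = nsum[m] / ncnt[m];
          double v = (nsq[m] - ncnt[m] * mu * mu) / (ncnt[m] - 1);
          if (v < 0) v = 0;
          nmean[m](fi, bi) = mu;
          nsd[m](fi, bi) = std::sqrt(v);
        } else {
          nmean[m](fi, bi) = NA_REAL; nsd[m](fi, bi) = NA_REAL;
        }
      }

      // bootstrap over samples (shared resample across measures)
      for (int m = 0; m < 4; ++m) { boots[m].clear(); skipped[m](fi, bi) = 0; }
      for (int it = 0; it < b_boot; ++it) {
        for (int s = 0; s < n; ++s) {
          int j = (int)(unif_rand() * n);
          if (j >= n) j = n - 1;
          xb[s] = x[j]; yb[s] = y[j];
        }
        for (int m = 0; m < 4; ++m) {
          const double sc = score_one(m, xb, yb, w);
          if (ISNAN(sc)) skipped[m](fi, bi) += 1;
          else boots[m].push_back(sc);
        }
      }
      for (int m = 0; m < 4; ++m) {
        const int cnt = (int)boots[m].size();
        if (cnt > 1) {
          double mu = 0;
          for (double v : boots[m]) mu += v;
          mu /= cnt;
          double v2 = 0;
          for (double v : boots[m]) v2 += (v - mu) * (v - mu);
          bmean[m](fi, bi) = mu;
          bsd[m](fi, bi) = std::sqrt(v2 / (cnt - 1));
          lo[m](fi, bi) = quantile7(boots[m], qlo);
          hi[m](fi, bi) = quantile7(boots[m], qhi);
        } else {
          bmean[m](fi, bi) = NA_REAL; bsd[m](fi, bi) = NA_REAL;
          lo[m](fi, bi) = NA_REAL; hi[m](fi, bi) = NA_REAL;
        }
      }
    }
  }

  CharacterVector nm = CharacterVector::create("spearman", "kendall",
                                               "bray_curtis", "kld");
  List out(4);
  for (int m = 0; m < 4; ++m)
    out[m] = List::create(_["observed"] = obs[m], _["null_mean"] = nmean[m],
                          _["null_sd"] = nsd[m], _["boot_mean"] = bmean[m],
                          _["boot_sd"] = bsd[m], _["ci_lo"] = lo[m],
                          _["ci_hi"] = hi[m], _["skipped_boot"] = skipped[m]);
  out.names() = nm;
  return out;
}

// Exact two-sided permutation p-value for Spearman's rho (small n): the
// proportion of distinct arrangements of y whose |rho| reaches the observed.
// [[Rcpp::export]]
double spearman_exact_p_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  ScoreWork w;
  const double rho = spearman_stat(xv, yv, w);
  if (ISNAN(rho)) return NA_REAL;
  std::vector<int> idx;
  std::vector<double> rx, ry;
  midrank(xv, idx, rx);
  std::vector<double> rxx = rx;
  midrank(yv, idx, ry);
  std::sort(ry.begin(), ry.end());
  long total = 0, extreme = 0;
  const double target = std::fabs(rho) - 1e-12;
  do {
    const double r = pearson(rxx, ry);
    ++total;
    if (!ISNAN(r) && std::fabs(r) >= target) ++extreme;
  } while (std::next_permutation(ry.begin(), ry.end()));
  if (n > 0 && total > 0) return (double)extreme / (double)total;
  return NA_REAL;
}
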