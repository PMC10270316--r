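#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Soft-margin linear SVM trained by simplified SMO. Training sets here are
// tiny (the 2*(n_folds-1) fold-averaged class exemplars), so a dense pairwise
// SMO converges in a handful of sweeps.
// ---------------------------------------------------------------------------
struct SvmFit {
  std::vector<double> w;
  double b;
};

static SvmFit smo_linear(const std::vector<double>& X, int m, int d,
                         const std::vector<double>& y, double C = 1.0,
                         double tol = 1e-5, int max_passes = 3) {
  std::vector<double> K(m * m);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j <= i; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) s += X[i * d + k] * X[j * d + k];
      K[i * m + j] = s;
      K[j * m + i] = s;
    }
  std::vector<double> alpha(m, 0.0);
  double b = 0.0;
  auto fx = [&](int i) {
    double s = 0.0;
    for (int j = 0; j < m; ++j) s += alpha[j] * y[j] * K[j * m + i];
    return s + b;
  };
  int passes = 0, iter = 0, max_iter = 2000;
  while (passes < max_passes && iter < max_iter) {
    int changed = 0;
    for (int i = 0; i < m; ++i) {
      double Ei = fx(i) - y[i];
      if ((y[i] * Ei < -tol && alpha[i] < C) || (y[i] * Ei > tol && alpha[i] > 0)) {
        int j = (int)std::floor(unif_rand() * (m - 1));
        if (j >= i) ++j;
        double Ej = fx(j) - y[j];
        double ai_old = alpha[i], aj_old = alpha[j];
        double L, H;
        if (y[i] != y[j]) {
          L = std::max(0.0, aj_old - ai_old);
          H = std::min(C, C + aj_old - ai_old);
        } else {
          L = std::max(0.0, ai_old + aj_old - C);
          H = std::min(C, ai_old + aj_old);
        }
        if (L >= H) continue;
        double eta = 2.0 * K[i * m + j] - K[i * m + i] - K[j * m + j];
        if (eta >= 0) continue;
        double aj = aj_old - y[j] * (Ei - Ej) / eta;
        if (aj > H) aj = H;
        if (aj < L) aj = L;
        if (std::fabs(aj - aj_old) < 1e-12) continue;
        double ai = ai_old + y[i] * y[j] * (aj_old - aj);
        alpha[i] = ai;
        alpha[j] = aj;
        double b1 = b - Ei - y[i] * (ai - ai_old) * K[i * m + i] -
                    y[j] * (aj - aj_old) * K[i * m + j];
        double b2 = b - Ej - y[i] * (ai - ai_old) * K[i * m + j] -
                    y[j] * (aj - aj_old) * K[j * m + j];
        if (ai > 0 && ai < C) b = b1;
        else if (aj > 0 && aj < C) b = b2;
        else b = 0.5 * (b1 + b2);
        ++changed;
      }
      ++iter;
    }
    passes = (changed == 0) ? passes + 1 : 0;
  }
  SvmFit fit;
  fit.w.assign(d, 0.0);
  for (int i = 0; i < m; ++i)
    for (int k = 0; k < d; ++k) fit.w[k] += alpha[i] * y[i] * X[i * d + k];
  fit.b = b;
  return fit;
}

// Fisher-Yates shuffle driven by R's RNG so set.seed() controls everything.
static void shuffle_idx(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// ---------------------------------------------------------------------------
// Fold-averaged per-timepoint decoding core.
//
// cube: features in channel-fastest layout (k + d*trial + d*nt*tp),
// idx0/idx1 the trial indices of the two classes. For each timepoint and
// iteration: stratified shuffled fold assignment (remainder trials
// dropped), class exemplars averaged within each fold, train on the
// exemplars of n_folds-1 folds (standardized by training-fold statistics),
// test the held-out fold's two exemplars; a test exemplar exactly on the
// boundary counts as incorrect. Writes mean accuracy per timepoint; NA
// where features are not finite.
// ---------------------------------------------------------------------------
static void decode_core(const double* cube, int nt, int d, int ntp,
                        std::vector<int>& idx0, std::vector<int>& idx1,
                        int n_folds, int n_iter, double* acc,
                        const std::vector<bool>& tp_valid) {
  int n0 = (int)idx0.size(), n1 = (int)idx1.size();
  if (n0 < n_folds || n1 < n_folds)
    stop("each class needs at least n_folds trials");
  int m_train = 2 * (n_folds - 1);
  std::vector<double> Xtr(m_train * d), ytr(m_train), mu(d), sd(d);
  std::vector<double> ex(2 * n_folds * d);
  // class lookup + canonical pooled ordering: the stratified partition is
  // derived from one shuffle of the pooled trials, so it consumes the RNG
  // identically whichever class is coded 0 or 1 (label-swap invariance)
  std::vector<int> cls(nt, -1), pool;
  for (int i : idx0) cls[i] = 0;
  for (int i : idx1) cls[i] = 1;
  pool.reserve(idx0.size() + idx1.size());
  for (int i = 0; i < nt; ++i) if (cls[i] >= 0) pool.push_back(i);

  for (int tp = 0; tp < ntp; ++tp) {
    if (!tp_valid[tp]) { acc[tp] = NA_REAL; continue; }
    const double* slab = cube + (size_t)nt * d * tp;
    double correct = 0.0, total = 0.0;
    for (int it = 0; it < n_iter; ++it) {
      shuffle_idx(pool);
      {
        int c0 = 0, c1 = 0;
        for (int i : pool) {
          if (cls[i] == 0) idx0[c0++] = i; else idx1[c1++] = i;
        }
      }
      int per0 = n0 / n_folds, per1 = n1 / n_folds;
      for (int f = 0; f < n_folds; ++f) {
        for (int c = 0; c < 2; ++c) {
          double* e = &ex[(f * 2 + c) * d];
          for (int k = 0; k < d; ++k) e[k] = 0.0;
          const std::vector<int>& src = (c == 0) ? idx0 : idx1;
          int per = (c == 0) ? per0 : per1;
          for (int t = 0; t < per; ++t) {
            const double* row = slab + (size_t)d * src[f * per + t];
            for (int k = 0; k < d; ++k) e[k] += row[k];
          }
          for (int k = 0; k < d; ++k) e[k] /= per;
        }
      }
      for (int f = 0; f < n_folds; ++f) {
        int r = 0;
        for (int g = 0; g < n_folds; ++g) {
          if (g == f) continue;
          for (int c = 0; c < 2; ++c, ++r) {
            for (int k = 0; k < d; ++k) Xtr[r * d + k] = ex[(g * 2 + c) * d + k];
            ytr[r] = (c == 0) ? -1.0 : 1.0;
          }
        }
        for (int k = 0; k < d; ++k) {
          double s = 0.0;
          for (int i = 0; i < m_train; ++i) s += Xtr[i * d + k];
          mu[k] = s / m_train;
          double ss = 0.0;
          for (int i = 0; i < m_train; ++i) {
            double dv = Xtr[i * d + k] - mu[k];
            ss += dv * dv;
          }
          sd[k] = std::sqrt(ss / (m_train - 1));
          if (!(sd[k] > 1e-12)) sd[k] = 1.0;
          for (int i = 0; i < m_train; ++i)
            Xtr[i * d + k] = (Xtr[i * d + k] - mu[k]) / sd[k];
        }
        SvmFit fit = smo_linear(Xtr, m_train, d, ytr);
        for (int c = 0; c < 2; ++c) {
          double dec = fit.b;
          for (int k = 0; k < d; ++k)
            dec += fit.w[k] * ((ex[(f * 2 + c) * d + k] - mu[k]) / sd[k]);
          double yv = (c == 0) ? -1.0 : 1.0;
          if (yv * dec > 0) correct += 1.0;  // boundary (==0) counts incorrect
          total += 1.0;
        }
      }
    }
    acc[tp] = correct / total;
  }
}

static std::vector<bool> valid_timepoints(const double* cube, int nt, int d,
                                          int ntp) {
  std::vector<bool> ok(ntp, true);
  for (int tp = 0; tp < ntp; ++tp) {
    const double* slab = cube + (size_t)nt * d * tp;
    for (size_t i = 0; i < (size_t)nt * d; ++i) {
      if (!R_finite(slab[i])) { ok[tp] = false; break; }
    }
  }
  return ok;
}

// Repack an R trials x channels x timepoints array into channel-fastest
// layout (k + d*trial + d*nt*tp) for cache-friendly exemplar averaging.
static std::vector<double> repack_cube(const double* cube, int nt, int d,
                                       int ntp) {
  std::vector<double> out((size_t)nt * d * ntp);
  for (int tp = 0; tp < ntp; ++tp) {
    const double* slab = cube + (size_t)nt * d * tp;
    double* oslab = out.data() + (size_t)nt * d * tp;
    for (int k = 0; k < d; ++k)
      for (int t = 0; t < nt; ++t)
        oslab[k + (size_t)d * t] = slab[t + (size_t)nt * k];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector decode_cube_cpp(NumericVector cube, IntegerVector y01,
                              int n_folds, int n_iter) {
  IntegerVector dims = cube.attr("dim");
  if (dims.size() != 3) stop("features must be a trials x channels x timepoints array");
  int nt = dims[0], d = dims[1], ntp = dims[2];
  if (y01.size() != nt) stop("label length must match trial count");
  std::vector<int> idx0, idx1;
  for (int i = 0; i < nt; ++i) (y01[i] == 0 ? idx0 : idx1).push_back(i);
  NumericVector acc(ntp);
  std::vector<bool> ok = valid_timepoints(REAL(cube), nt, d, ntp);
  std::vector<double> packed = repack_cube(REAL(cube), nt, d, ntp);
  decode_core(packed.data(), nt, d, ntp, idx0, idx1, n_folds, n_iter,
              REAL(acc), ok);
  return acc;
}

// ---------------------------------------------------------------------------
// Monte-Carlo null distribution of the maximum cluster mass.
//
// cubes: list of per-subject trials x channels x timepoints arrays.
// Each permutation draws i.i.d. uniform class labels per subject, equalizes
// the class counts by subsampling the larger class, decodes the full curve,
// computes the across-subject one-sample t against 0.5 at every timepoint,
// and records the largest summed-t cluster above tcrit (0 when none).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector mc_null_max_mass_cpp(List cubes, int n_perm, int n_folds,
                                   int n_iter, double tcrit, double chance,
                                   double t_cap) {
  int S = cubes.size();
  if (S < 3) stop("need at least 3 subjects");
  std::vector<std::vector<double>> cv;
  std::vector<int> nts, ds;
  int ntp = -1;
  std::vector<std::vector<bool>> valid(S);
  for (int s = 0; s < S; ++s) {
    NumericVector c = cubes[s];
    IntegerVector dims = c.attr("dim");
    if (dims.size() != 3) stop("each cube must be 3-dimensional");
    if (ntp < 0) ntp = dims[2];
    if (dims[2] != ntp) stop("subjects must share a common time grid");
    cv.push_back(repack_cube(REAL(c), dims[0], dims[1], dims[2]));
    nts.push_back(dims[0]);
    ds.push_back(dims[1]);
    valid[s] = valid_timepoints(REAL(c), dims[0], dims[1], dims[2]);
  }
  std::vector<bool> tp_ok(ntp, true);
  for (int tp = 0; tp < ntp; ++tp)
    for (int s = 0; s < S; ++s)
      if (!valid[s][tp]) { tp_ok[tp] = false; break; }

  NumericVector out(n_perm);
  std::vector<std::vector<double>> accs(S, std::vector<double>(ntp));
  for (int p = 0; p < n_perm; ++p) {
    for (int s = 0; s < S; ++s) {
      int nt = nts[s];
      std::vector<int> idx0, idx1;
      for (int i = 0; i < nt; ++i)
        (unif_rand() < 0.5 ? idx0 : idx1).push_back(i);
      // guard: force minimal class sizes on pathological draws
      while ((int)idx0.size() < n_folds && !idx1.empty()) {
        idx0.push_back(idx1.back());
        idx1.pop_back();
      }
      while ((int)idx1.size() < n_folds && !idx0.empty()) {
        idx1.push_back(idx0.back());
        idx0.pop_back();
      }
      // equalize: subsample the larger class
      size_t m = std::min(idx0.size(), idx1.size());
      if (idx0.size() > m) { shuffle_idx(idx0); idx0.resize(m); }
      if (idx1.size() > m) { shuffle_idx(idx1); idx1.resize(m); }
      decode_core(cv[s].data(), nt, ds[s], ntp, idx0, idx1, n_folds, n_iter,
                  accs[s].data(), valid[s]);
    }
    double max_mass = 0.0, run = 0.0;
    for (int tp = 0; tp < ntp; ++tp) {
      double tval;
      if (!tp_ok[tp]) {
        tval = R_NegInf;
      } else {
        double mn = 0.0;
        for (int s = 0; s < S; ++s) mn += accs[s][tp];
        mn /= S;
        double ss = 0.0;
        for (int s = 0; s < S; ++s) {
          double dv = accs[s][tp] - mn;
          ss += dv * dv;
        }
        double sdv = std::sqrt(ss / (S - 1));
        if (sdv > 0) {
          tval = (mn - chance) / (sdv / std::sqrt((double)S));
        } else {
          tval = (mn > chance) ? R_PosInf : ((mn < chance) ? R_NegInf : 0.0);
        }
        if (tval > t_cap) tval = t_cap;
      }
      if (tval > tcrit) {
        run += tval;
        if (run > max_mass) max_mass = run;
      } else {
        run = 0.0;
      }
    }
    out[p] = max_mass;
  }
  return out;
}

// Train one linear SVM on given exemplars (rows) without standardization;
// used by the weight-map extraction, which handles scaling itself.
// [[Rcpp::export]]
List svm_weights_cpp(NumericMatrix X, NumericVector y) {
  int m = X.nrow(), d = X.ncol();
  std::vector<double> Xv(m * d), yv(m);
  for (int i = 0; i < m; ++i) {
    yv[i] = y[i];
    for (int k = 0; k < d; ++k) Xv[i * d + k] = X(i, k);
  }
  SvmFit fit = smo_linear(Xv, m, d, yv, 1.0, 1e-8, 10);
  return List::create(_["w"] = NumericVector(fit.w.begin(), fit.w.end()),
                      _["b"] = fit.b);
}

// ---------------------------------------------------------------------------
// Moving-window peak-to-peak artifact scan.
// data: trials x channels x samples; ch_idx 1-based channel subset;
// windows of length w placed every s samples, with a final window flushed
// to the epoch end. A trial is flagged when any channel in the subset has
// max - min > threshold inside any window.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
LogicalVector p2p_flag_cpp(NumericVector data, IntegerVector ch_idx,
                           int w, int s, double threshold) {
  IntegerVector dims = data.attr("dim");
  int nt = dims[0], nc = dims[1], ns = dims[2];
  if (w > ns) w = ns;
  std::vector<int> starts;
  for (int p = 0; p + w <= ns; p += s) starts.push_back(p);
  if (starts.empty() || starts.back() != ns - w) starts.push_back(ns - w);
  LogicalVector flagged(nt);
  const double* d0 = REAL(data);
  std::vector<double> buf(ns);
  for (int t = 0; t < nt; ++t) {
    bool hit = false;
    for (int ci = 0; ci < ch_idx.size() && !hit; ++ci) {
      int c = ch_idx[ci] - 1;
      if (c < 0 || c >= nc) stop("channel index out of range");
      // gather the strided series once, then scan windows contiguously
      const double* base = d0 + t + (size_t)nt * c;
      for (int k = 0; k < ns; ++k) buf[k] = base[(size_t)nt * nc * k];
      for (size_t pi = 0; pi < starts.size() && !hit; ++pi) {
        int p = starts[pi];
        double mx = buf[p], mn = buf[p];
        for (int k = 1; k < w; ++k) {
          double v = buf[p + k];
          if (v > mx) mx = v;
          if (v < mn) mn = v;
        }
        if (mx - mn > threshold) hit = true;
      }
    }
    flagged[t] = hit;
  }
  return flagged;
}

// ---------------------------------------------------------------------------
// Zero-phase IIR/FIR filtering of a channels x time matrix: odd-reflection
// padding at both ends, forward pass, backward pass (filtfilt).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix filtfilt_matrix_cpp(NumericMatrix X, NumericVector b,
                                  NumericVector a) {
  int nch = X.nrow(), n = X.ncol();
  int nb = b.size(), na = a.size();
  int nfilt = std::max(nb, na);
  int pad = 3 * (nfilt - 1);
  if (pad >= n) stop("signal too short for filter padding");
  std::vector<double> bb(nfilt, 0.0), aa(nfilt, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i] / a[0];
  for (int i = 0; i < na; ++i) aa[i] = a[i] / a[0];
  int m = n + 2 * pad;
  std::vector<double> x(m), y(m);
  NumericMatrix out(nch, n);
  for (int c = 0; c < nch; ++c) {
    for (int i = 0; i < pad; ++i) x[i] = 2.0 * X(c, 0) - X(c, pad - i);
    for (int i = 0; i < n; ++i) x[pad + i] = X(c, i);
    for (int i = 0; i < pad; ++i)
      x[pad + n + i] = 2.0 * X(c, n - 1) - X(c, n - 2 - i);
    for (int i = 0; i < m; ++i) {
      double acc = 0.0;
      for (int k = 0; k < nfilt && k <= i; ++k) acc += bb[k] * x[i - k];
      for (int k = 1; k < nfilt && k <= i; ++k) acc -= aa[k] * y[i - k];
      y[i] = acc;
    }
    for (int i = m - 1; i >= 0; --i) {
      double acc = 0.0;
      for (int k = 0; k < nfilt && i + k < m; ++k) acc += bb[k] * y[i + k];
      for (int k = 1; k < nfilt && i + k < m; ++k) acc -= aa[k] * x[i + k];
      x[i] = acc;
    }
    for (int i = 0; i < n; ++i) out(c, i) = x[pad + i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Hann-tapered single-frequency power at a set of window centers.
// data: trials x channels x samples; centers 1-based sample indices (all
// with a full window inside the epoch); vre/vim the normalized tapered
// carrier (length 2*h+1). Returns trials x channels x length(centers).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericVector tf_band_power_cpp(NumericVector data, IntegerVector centers,
                                int h, NumericVector vre, NumericVector vim) {
  IntegerVector dims = data.attr("dim");
  int nt = dims[0], nc = dims[1], ns = dims[2];
  int L = 2 * h + 1;
  if (vre.size() != L || vim.size() != L) stop("taper length mismatch");
  int ng = centers.size();
  NumericVector out(Dimension(nt, nc, ng));
  const double* d0 = REAL(data);
  double* o0 = REAL(out);
  for (int g = 0; g < ng; ++g) {
    int c0 = centers[g] - 1;
    if (c0 - h < 0 || c0 + h >= ns) stop("window exceeds the epoch");
    for (int c = 0; c < nc; ++c) {
      const double* base = d0 + (size_t)nt * c + (size_t)nt * nc * (c0 - h);
      double* obase = o0 + (size_t)nt * c + (size_t)nt * nc * g;
      for (int t = 0; t < nt; ++t) {
        double re = 0.0, im = 0.0;
        const double* p = base + t;
        for (int k = 0; k < L; ++k) {
          double v = p[(size_t)nt * nc * k];
          re += v * vre[k];
          im += v * vim[k];
        }
        obase[t] = re * re + im * im;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fused preprocessing: subtract the (TP9+TP10)/2 reference row, then apply
// the zero-phase high-pass and low-pass cascades, all on one buffer.
// ref1/ref2 are 1-based row indices of the reference channels.
// ---------------------------------------------------------------------------
static void filtfilt_row(double* row, int n, const std::vector<double>& bb,
                         const std::vector<double>& aa, int nfilt,
                         std::vector<double>& x, std::vector<double>& y) {
  int pad = 3 * (nfilt - 1);
  int m = n + 2 * pad;
  for (int i = 0; i < pad; ++i) x[i] = 2.0 * row[0] - row[pad - i];
  for (int i = 0; i < n; ++i) x[pad + i] = row[i];
  for (int i = 0; i < pad; ++i) x[pad + n + i] = 2.0 * row[n - 1] - row[n - 2 - i];
  for (int i = 0; i < m; ++i) {
    double acc = 0.0;
    for (int k = 0; k < nfilt && k <= i; ++k) acc += bb[k] * x[i - k];
    for (int k = 1; k < nfilt && k <= i; ++k) acc -= aa[k] * y[i - k];
    y[i] = acc;
  }
  for (int i = m - 1; i >= 0; --i) {
    double acc = 0.0;
    for (int k = 0; k < nfilt && i + k < m; ++k) acc += bb[k] * y[i + k];
    for (int k = 1; k < nfilt && i + k < m; ++k) acc -= aa[k] * x[i + k];
    x[i] = acc;
  }
  for (int i = 0; i < n; ++i) row[i] = x[pad + i];
}

// [[Rcpp::export]]
NumericMatrix preprocess_matrix_cpp(NumericMatrix X, int ref1, int ref2,
                                    NumericVector bh, NumericVector ah,
                                    NumericVector bl, NumericVector al) {
  int nch = X.nrow(), n = X.ncol();
  NumericMatrix out(nch, n);
  // re-reference
  for (int j = 0; j < n; ++j) {
    double ref = 0.5 * (X(ref1 - 1, j) + X(ref2 - 1, j));
    for (int c = 0; c < nch; ++c) out(c, j) = X(c, j) - ref;
  }
  int nh = std::max(bh.size(), ah.size());
  int nl = std::max(bl.size(), al.size());
  std::vector<double> bbh(nh, 0.0), aah(nh, 0.0), bbl(nl, 0.0), aal(nl, 0.0);
  for (int i = 0; i < bh.size(); ++i) bbh[i] = bh[i] / ah[0];
  for (int i = 0; i < ah.size(); ++i) aah[i] = ah[i] / ah[0];
  for (int i = 0; i < bl.size(); ++i) bbl[i] = bl[i] / al[0];
  for (int i = 0; i < al.size(); ++i) aal[i] = al[i] / al[0];
  int maxpad = 3 * (std::max(nh, nl) - 1);
  if (maxpad >= n) stop("signal too short for filter padding");
  std::vector<double> xbuf(n + 2 * maxpad), ybuf(n + 2 * maxpad), row(n);
  for (int c = 0; c < nch; ++c) {
    for (int j = 0; j < n; ++j) row[j] = out(c, j);
    filtfilt_row(row.data(), n, bbh, aah, nh, xbuf, ybuf);
    filtfilt_row(row.data(), n, bbl, aal, nl, xbuf, ybuf);
    for (int j = 0; j < n; ++j) out(c, j) = row[j];
  }
  return out;
}
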