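#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Kernelised ordered-subsets EM inner loop.
//
// The system matrix is supplied per subset in compressed-sparse-column form
// (columns = voxels), with attenuation already folded into the entries, so
// forward projection is a column scatter and back projection a column
// gather from the same arrays — the operator pair is an exact transpose by
// construction.
//
// The kernel is a voxel-neighbourhood table: nb (V x N, 1-based neighbour
// voxel index, 0 = outside the grid) and the anatomical weight table wm.
// For the hybrid kernel the PET component is recomputed from the current
// activity estimate: the estimate is standardised over fmask and the
// combined weight is wm * exp(-dz^2 / (2 sigma_p^2)) * distp[f].

static void csc_forward(const IntegerVector &p, const IntegerVector &idx,
                        const NumericVector &x, const std::vector<double> &v,
                        std::vector<double> &out) {
  const int V = p.size() - 1;
  for (int j = 0; j < V; ++j) {
    const double a = v[j];
    if (a == 0.0) continue;
    for (int k = p[j]; k < p[j + 1]; ++k) out[idx[k]] += x[k] * a;
  }
}

static void csc_back(const IntegerVector &p, const IntegerVector &idx,
                     const NumericVector &x, const std::vector<double> &r,
                     std::vector<double> &out) {
  const int V = p.size() - 1;
  for (int j = 0; j < V; ++j) {
    double acc = 0.0;
    for (int k = p[j]; k < p[j + 1]; ++k) acc += x[k] * r[idx[k]];
    out[j] = acc;
  }
}

static void kernel_apply_w(const IntegerMatrix &nb, const NumericMatrix &w,
                           const std::vector<double> &x,
                           std::vector<double> &out) {
  const int V = nb.nrow(), N = nb.ncol();
  std::fill(out.begin(), out.end(), 0.0);
  for (int f = 0; f < N; ++f)
    for (int j = 0; j < V; ++j) {
      const int t = nb(j, f);
      if (t > 0) out[j] += w(j, f) * x[t - 1];
    }
}

static void kernel_apply_wt(const IntegerMatrix &nb, const NumericMatrix &w,
                            const std::vector<double> &x,
                            std::vector<double> &out) {
  const int V = nb.nrow(), N = nb.ncol();
  std::fill(out.begin(), out.end(), 0.0);
  for (int f = 0; f < N; ++f)
    for (int j = 0; j < V; ++j) {
      const int t = nb(j, f);
      if (t > 0) out[t - 1] += w(j, f) * x[j];
    }
}

// standardise v over mask into z; all-zero when (near-)constant
static void standardise(const std::vector<double> &v,
                        const LogicalVector &mask, std::vector<double> &z) {
  const int V = v.size();
  double sum = 0.0, sum2 = 0.0, amax = 1.0;
  int n = 0;
  for (int j = 0; j < V; ++j)
    if (mask[j]) {
      sum += v[j];
      ++n;
      if (std::fabs(v[j]) > amax) amax = std::fabs(v[j]);
    }
  const double mu = (n > 0) ? sum / n : 0.0;
  for (int j = 0; j < V; ++j)
    if (mask[j]) { const double d = v[j] - mu; sum2 += d * d; }
  const double sd = (n > 0) ? std::sqrt(sum2 / n) : 0.0;  // population SD
  if (sd < 1e-12 * amax || n < 2) {
    std::fill(z.begin(), z.end(), 0.0);
  } else {
    for (int j = 0; j < V; ++j) z[j] = (v[j] - mu) / sd;
  }
}

// [[Rcpp::export]]
List em_run_cpp(List sub_p, List sub_i, List sub_x, List y_list, List s_list,
                NumericMatrix backones, IntegerMatrix nb, NumericMatrix wm,
                NumericVector distp, double sigma_p, LogicalVector fmask,
                NumericVector alpha0, int n_iter, double eps,
                bool use_kernel, bool use_pet, bool update_every_subiter,
                bool normalise_rows) {
  const int S = sub_p.size();
  const int V = alpha0.size();
  const int N = use_kernel ? nb.ncol() : 0;

  std::vector<double> alpha(alpha0.begin(), alpha0.end());
  std::vector<double> lam(V), bp(V), corr(V), sens(V), z(V, 0.0);
  NumericMatrix wk;
  if (use_kernel) wk = clone(wm);

  auto rebuild_pet = [&](void) {
    // lam holds the current activity estimate
    standardise(lam, fmask, z);
    const double t2 = 2.0 * sigma_p * sigma_p;
    for (int f = 0; f < N; ++f) {
      const double dw = distp[f];
      for (int j = 0; j < V; ++j) {
        const int t = nb(j, f);
        if (t > 0) {
          const double dz = z[t - 1] - z[j];
          wk(j, f) = wm(j, f) * std::exp(-dz * dz / t2) * dw;
        } else {
          wk(j, f) = 0.0;
        }
      }
    }
    if (normalise_rows) {
      for (int j = 0; j < V; ++j) {
        double rs = 0.0;
        for (int f = 0; f < N; ++f) rs += wk(j, f);
        if (rs > 0) for (int f = 0; f < N; ++f) wk(j, f) /= rs;
      }
    }
  };

  // current activity estimate: lambda = K alpha (identity kernel for OSEM)
  if (use_kernel) {
    if (use_pet) rebuild_pet();       // uniform start => pure distance factor
    kernel_apply_w(nb, wk, alpha, lam);
  } else {
    lam = alpha;
  }

  for (int it = 0; it < n_iter; ++it) {
    for (int s = 0; s < S; ++s) {
      if (use_kernel && use_pet &&
          (update_every_subiter || s == 0) && !(it == 0 && s == 0)) {
        rebuild_pet();
      }
      IntegerVector p = sub_p[s], ridx = sub_i[s];
      NumericVector x = sub_x[s], y = y_list[s], sadd = s_list[s];
      const int M = y.size();
      std::vector<double> yb(M), ratio(M);

      if (use_kernel) kernel_apply_w(nb, wk, alpha, lam);
      else lam = alpha;

      for (int i = 0; i < M; ++i) yb[i] = sadd[i];
      csc_forward(p, ridx, x, lam, yb);
      for (int i = 0; i < M; ++i)
        ratio[i] = y[i] / std::max(yb[i], eps);
      csc_back(p, ridx, x, ratio, bp);

      if (use_kernel) {
        kernel_apply_wt(nb, wk, bp, corr);
        std::vector<double> b1(backones.column(s).begin(),
                               backones.column(s).end());
        kernel_apply_wt(nb, wk, b1, sens);
      } else {
        corr = bp;
        for (int j = 0; j < V; ++j) sens[j] = backones(j, s);
      }
      for (int j = 0; j < V; ++j)
        alpha[j] = (sens[j] > 0.0) ? alpha[j] * corr[j] / sens[j] : 0.0;
      // keep the activity estimate current: the next PET-kernel rebuild
      // must see the post-update image
      if (use_kernel && use_pet) kernel_apply_w(nb, wk, alpha, lam);
    }
  }
  if (use_kernel) kernel_apply_w(nb, wk, alpha, lam);
  else lam = alpha;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["lambda"] = NumericVector(lam.begin(), lam.end()));
}
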