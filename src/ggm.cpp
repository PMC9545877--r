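// Gaussian graphical model engine: graphical-lasso coordinate descent along
// a penalty path, constrained (fixed edge set) maximum-likelihood refits, and
// greedy stepwise BIC edge search. All matrices are correlation-scale.
//
// The kernels run thousands of times inside bootstrap loops, so they are
// written allocation-free on plain column-major arrays with small in-place
// Cholesky solves; p is a few dozen at most in this domain.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

typedef std::vector<double> dvec;
typedef std::vector<int> ivec;

// in-place Cholesky factorization of the leading m x m block (column-major,
// leading dimension ld); returns false if not positive definite
static bool chol_ip(double *A, int m, int ld) {
  for (int j = 0; j < m; ++j) {
    double d = A[j * ld + j];
    for (int k = 0; k < j; ++k) d -= A[k * ld + j] * A[k * ld + j];
    if (d <= 0.0) return false;
    d = std::sqrt(d);
    A[j * ld + j] = d;
    for (int i = j + 1; i < m; ++i) {
      double s = A[j * ld + i];
      for (int k = 0; k < j; ++k) s -= A[k * ld + i] * A[k * ld + j];
      A[j * ld + i] = s / d;
    }
  }
  return true;
}

// solve A x = b given the Cholesky factor from chol_ip (lower, in A)
static void chol_solve_ip(const double *A, double *b, int m, int ld) {
  for (int i = 0; i < m; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= A[k * ld + i] * b[k];
    b[i] = s / A[i * ld + i];
  }
  for (int i = m - 1; i >= 0; --i) {
    double s = b[i];
    for (int k = i + 1; k < m; ++k) s -= A[i * ld + k] * b[k];
    b[i] = s / A[i * ld + i];
  }
}

// scratch buffers shared by the kernels (sized for p nodes)
struct Work {
  int p;
  dvec A, b, w12, Wc;
  ivec ne;
  Work(int p_) : p(p_), A((size_t)p_ * p_), b(p_), w12(p_), Wc((size_t)p_ * p_),
                 ne(p_) {}
};

// One cyclic-update pass set for the constrained MLE: regression updates on
// the working covariance W (Hastie-Tibshirani style). At convergence
// (W^-1)_ij = 0 off the edge set and W_ij = S_ij on edges and diagonal.
static bool mle_core(const double *S, const int *adj, double *W, int p,
                     double tol, int maxit, int &iters, Work &wk) {
  iters = 0;
  for (int it = 0; it < maxit; ++it) {
    double dw = 0.0;
    for (int j = 0; j < p; ++j) {
      int m = 0;
      for (int i = 0; i < p; ++i)
        if (adj[j * p + i] && i != j) wk.ne[m++] = i;
      if (m == 0) {
        for (int i = 0; i < p; ++i) wk.w12[i] = 0.0;
      } else {
        // A = W[ne, ne], b = S[ne, j]
        for (int c = 0; c < m; ++c) {
          const double *Wcol = W + (size_t)wk.ne[c] * p;
          for (int r = 0; r < m; ++r) wk.A[c * m + r] = Wcol[wk.ne[r]];
          wk.b[c] = S[j * p + wk.ne[c]];
        }
        if (!chol_ip(wk.A.data(), m, m)) return false;
        chol_solve_ip(wk.A.data(), wk.b.data(), m, m);
        for (int i = 0; i < p; ++i) wk.w12[i] = 0.0;
        for (int c = 0; c < m; ++c) {
          const double bc = wk.b[c];
          const double *Wcol = W + (size_t)wk.ne[c] * p;
          for (int i = 0; i < p; ++i) wk.w12[i] += Wcol[i] * bc;
        }
      }
      for (int i = 0; i < p; ++i) {
        if (i == j) continue;
        double d = std::fabs(wk.w12[i] - W[j * p + i]);
        if (d > dw) dw = d;
        W[j * p + i] = wk.w12[i];
        W[i * p + j] = wk.w12[i];
      }
    }
    iters = it + 1;
    if (dw < tol) return true;
  }
  return false;
}

// log det of the p x p SPD matrix W (copy + Cholesky); NaN if not PD
static double logdet_spd(const double *W, int p, Work &wk) {
  std::copy(W, W + (size_t)p * p, wk.Wc.begin());
  if (!chol_ip(wk.Wc.data(), p, p)) return R_NaN;
  double ld = 0.0;
  for (int j = 0; j < p; ++j) ld += std::log(wk.Wc[(size_t)j * p + j]);
  return 2.0 * ld;
}

// precision matrix K from converged W given the edge set (partitioned
// inverse per column; exact zeros off the edge set)
static void precision_from_W(const double *S, const int *adj, const double *W,
                             double *K, int p, Work &wk) {
  std::fill(K, K + (size_t)p * p, 0.0);
  for (int j = 0; j < p; ++j) {
    int m = 0;
    for (int i = 0; i < p; ++i)
      if (adj[j * p + i] && i != j) wk.ne[m++] = i;
    if (m == 0) {
      K[j * p + j] = 1.0 / W[j * p + j];
      continue;
    }
    for (int c = 0; c < m; ++c) {
      const double *Wcol = W + (size_t)wk.ne[c] * p;
      for (int r = 0; r < m; ++r) wk.A[c * m + r] = Wcol[wk.ne[r]];
      wk.b[c] = S[j * p + wk.ne[c]];
    }
    chol_ip(wk.A.data(), m, m);
    chol_solve_ip(wk.A.data(), wk.b.data(), m, m);
    double q = W[j * p + j];
    for (int c = 0; c < m; ++c) q -= W[j * p + wk.ne[c]] * wk.b[c];
    double kjj = 1.0 / q;
    K[j * p + j] = kjj;
    for (int c = 0; c < m; ++c) K[j * p + wk.ne[c]] = -wk.b[c] * kjj;
  }
  // symmetrize (the two per-column estimates agree to solver precision)
  for (int j = 0; j < p; ++j)
    for (int i = j + 1; i < p; ++i) {
      double v = 0.5 * (K[j * p + i] + K[i * p + j]);
      K[j * p + i] = v;
      K[i * p + j] = v;
    }
}

static double loglik_SK(const double *S, const double *K, int p, double n,
                        Work &wk) {
  double ld = logdet_spd(K, p, wk);
  if (!R_FINITE(ld)) return R_NaN;
  double tr = 0.0;
  for (size_t q = 0; q < (size_t)p * p; ++q) tr += S[q] * K[q];
  return 0.5 * n * (ld - tr);
}

static int edge_count_adj(const int *adj, int p) {
  int e = 0;
  for (int j = 0; j < p; ++j)
    for (int i = j + 1; i < p; ++i)
      if (adj[j * p + i]) ++e;
  return e;
}

// [[Rcpp::export]]
List cpp_ggm_mle(NumericMatrix S_, IntegerMatrix A_, double n, double tol,
                 int maxit, Nullable<NumericMatrix> W_init = R_NilValue) {
  int p = S_.nrow();
  const double *S = S_.begin();
  std::vector<int> adj(A_.begin(), A_.end());
  dvec W(S, S + (size_t)p * p);
  if (W_init.isNotNull()) {
    NumericMatrix Wi(W_init.get());
    std::copy(Wi.begin(), Wi.end(), W.begin());
  }
  Work wk(p);
  int iters = 0;
  bool conv = mle_core(S, adj.data(), W.data(), p, tol, maxit, iters, wk);
  NumericMatrix K_(p, p);
  precision_from_W(S, adj.data(), W.data(), K_.begin(), p, wk);
  double ll = loglik_SK(S, K_.begin(), p, n, wk);
  int E = edge_count_adj(adj.data(), p);
  double bic = -2.0 * ll + E * std::log(n);
  double resid = 0.0;
  for (int j = 0; j < p; ++j)
    for (int i = 0; i <= j; ++i)
      if (i == j || adj[j * p + i]) {
        double d = std::fabs(W[(size_t)j * p + i] - S[(size_t)j * p + i]);
        if (d > resid) resid = d;
      }
  NumericMatrix W_(p, p);
  std::copy(W.begin(), W.end(), W_.begin());
  return List::create(Named("W") = W_, Named("K") = K_,
                      Named("loglik") = ll, Named("bic") = bic,
                      Named("edges") = E, Named("converged") = conv,
                      Named("iters") = iters, Named("resid") = resid);
}

// ---------------------------------------------------------------------------
// Greedy stepwise BIC search: evaluate every single-edge addition/removal
// (each via a warm-started constrained MLE), apply the best strictly
// improving move, stop at a local optimum. Ties (within tie_tol) prefer
// removal, then the lexicographically smallest pair. Candidate BICs use
// log det W: at the constrained MLE, tr(S K) = p and log det K = -log det W.
// [[Rcpp::export]]
List cpp_stepwise(NumericMatrix S_, double n, IntegerMatrix A0_, double tol,
                  int maxit, int max_moves, double tie_tol = 1e-10,
                  double screen_tol = 1e-4) {
  if (screen_tol < tol) screen_tol = tol;
  int p = S_.nrow();
  const double *S = S_.begin();
  std::vector<int> adj(A0_.begin(), A0_.end());
  dvec W(S, S + (size_t)p * p);
  Work wk(p);
  int iters = 0;
  mle_core(S, adj.data(), W.data(), p, tol, maxit, iters, wk);
  int E = edge_count_adj(adj.data(), p);
  const double logn = std::log(n);
  double bic = n * (logdet_spd(W.data(), p, wk) + p) + E * logn;

  dvec Wcand((size_t)p * p), Wbest((size_t)p * p);
  // per-candidate warm-start cache: the MLE is the unique optimum of a
  // convex problem, so warm starts change speed, never the selected model
  std::vector<dvec> cache((size_t)p * (p - 1) / 2);
  std::vector<double> mv_i, mv_j, mv_type, mv_bic;
  int moves = 0;
  while (moves < max_moves) {
    double best_bic = bic;
    bool have = false, best_rm = false;
    int bi = -1, bj = -1;
    int ci = -1;
    for (int i = 0; i < p - 1; ++i) {
      for (int j = i + 1; j < p; ++j) {
        ++ci;
        bool removing = adj[j * p + i] != 0;
        adj[j * p + i] = adj[i * p + j] = removing ? 0 : 1;
        if (cache[ci].empty())
          std::copy(W.begin(), W.end(), Wcand.begin());
        else
          std::copy(cache[ci].begin(), cache[ci].end(), Wcand.begin());
        int it2 = 0;
        bool ok =
            mle_core(S, adj.data(), Wcand.data(), p, screen_tol, maxit, it2, wk);
        if (ok) cache[ci].assign(Wcand.begin(), Wcand.end());
        else cache[ci].clear();
        double bic2 = R_PosInf;
        if (ok) {
          double ld = logdet_spd(Wcand.data(), p, wk);
          if (R_FINITE(ld))
            bic2 = n * (ld + p) + (E + (removing ? -1 : 1)) * logn;
        }
        adj[j * p + i] = adj[i * p + j] = removing ? 1 : 0;  // restore
        bool better = false;
        if (R_FINITE(bic2)) {
          if (bic2 < best_bic - tie_tol) {
            better = true;
          } else if (have && std::fabs(bic2 - best_bic) <= tie_tol) {
            better = (removing && !best_rm);
          }
        }
        if (better) {
          have = true;
          best_bic = bic2;
          best_rm = removing;
          bi = i; bj = j;
          std::copy(Wcand.begin(), Wcand.end(), Wbest.begin());
        }
      }
    }
    if (!have) break;
    bool removing = adj[bj * p + bi] != 0;
    adj[bj * p + bi] = adj[bi * p + bj] = removing ? 0 : 1;
    std::copy(Wbest.begin(), Wbest.end(), W.begin());
    E += removing ? -1 : 1;
    // polish the applied move at full tolerance before the next pass
    int itp = 0;
    mle_core(S, adj.data(), W.data(), p, tol, maxit, itp, wk);
    bic = n * (logdet_spd(W.data(), p, wk) + p) + E * logn;
    mv_i.push_back(bi + 1);
    mv_j.push_back(bj + 1);
    mv_type.push_back(removing ? -1 : 1);
    mv_bic.push_back(bic);
    ++moves;
  }
  // final refit at full precision + exact likelihood bookkeeping
  int itf = 0;
  mle_core(S, adj.data(), W.data(), p, tol, maxit, itf, wk);
  NumericMatrix K_(p, p), W_(p, p);
  precision_from_W(S, adj.data(), W.data(), K_.begin(), p, wk);
  std::copy(W.begin(), W.end(), W_.begin());
  double ll = loglik_SK(S, K_.begin(), p, n, wk);
  double bic_final = -2.0 * ll + E * logn;
  IntegerMatrix Aout(p, p);
  std::copy(adj.begin(), adj.end(), Aout.begin());
  NumericMatrix mv(moves, 4);
  for (int m = 0; m < moves; ++m) {
    mv(m, 0) = mv_i[m];
    mv(m, 1) = mv_j[m];
    mv(m, 2) = mv_type[m];
    mv(m, 3) = mv_bic[m];
  }
  colnames(mv) = CharacterVector::create("i", "j", "type", "bic");
  return List::create(Named("adj") = Aout, Named("W") = W_, Named("K") = K_,
                      Named("loglik") = ll, Named("bic") = bic_final,
                      Named("edges") = (double)E, Named("moves") = mv,
                      Named("hit_cap") = moves >= max_moves);
}

// ---------------------------------------------------------------------------
// graphical lasso: block coordinate descent with an inner lasso solved by
// coordinate descent on a maintained residual vector r = W11 * beta.
static void glasso_one(const double *S, double lam, double *W, double *B,
                       int p, double tol, int maxit, Work &wk) {
  for (int j = 0; j < p; ++j) W[(size_t)j * p + j] = S[(size_t)j * p + j] + lam;
  double sbar = 0.0;
  int np = 0;
  for (int j = 0; j < p; ++j)
    for (int i = j + 1; i < p; ++i) { sbar += std::fabs(S[j * p + i]); ++np; }
  sbar = np ? sbar / np : 1.0;
  double thr = tol * (sbar > 0 ? sbar : 1.0);
  double thr_in = 0.1 * thr;

  dvec &r = wk.w12;  // reuse buffer: r_k = sum_{l != j} W(k,l) beta_l
  for (int it = 0; it < maxit; ++it) {
    double dw = 0.0;
    for (int j = 0; j < p; ++j) {
      double *Bj = B + (size_t)j * p;
      // r = sum_l W(:,l) Bj[l], l != j (Bj[j] stays 0)
      for (int k = 0; k < p; ++k) r[k] = 0.0;
      for (int l = 0; l < p; ++l) {
        double bl = Bj[l];
        if (bl == 0.0 || l == j) continue;
        const double *Wl = W + (size_t)l * p;
        for (int k = 0; k < p; ++k) r[k] += Wl[k] * bl;
      }
      for (int in = 0; in < 500; ++in) {
        double dlx = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double wkk = W[(size_t)k * p + k];
          double bk = Bj[k];
          double gk = S[(size_t)j * p + k] - (r[k] - wkk * bk);
          double b = 0.0;
          if (std::fabs(gk) > lam) b = (gk > 0 ? gk - lam : gk + lam) / wkk;
          if (b != bk) {
            double d = b - bk;
            const double *Wk = W + (size_t)k * p;
            for (int t = 0; t < p; ++t) r[t] += Wk[t] * d;
            Bj[k] = b;
            double ad = std::fabs(d);
            if (ad > dlx) dlx = ad;
          }
        }
        if (dlx < thr_in) break;
      }
      for (int i = 0; i < p; ++i) {
        if (i == j) continue;
        double d = std::fabs(r[i] - W[(size_t)j * p + i]);
        if (d > dw) dw = d;
        W[(size_t)j * p + i] = r[i];
        W[(size_t)i * p + j] = r[i];
      }
    }
    if (dw < thr) break;
  }
}

// [[Rcpp::export]]
List cpp_glasso_path(NumericMatrix S_, NumericVector lambdas, double tol,
                     int maxit) {
  int p = S_.nrow();
  const double *S = S_.begin();
  dvec W(S, S + (size_t)p * p), B((size_t)p * p, 0.0);
  Work wk(p);
  List supports(lambdas.size());
  for (int l = 0; l < lambdas.size(); ++l) {
    glasso_one(S, lambdas[l], W.data(), B.data(), p, tol, maxit, wk);
    IntegerMatrix A(p, p);
    for (int j = 0; j < p; ++j)
      for (int i = 0; i < p; ++i)
        A(i, j) = (i != j &&
                   (B[(size_t)j * p + i] != 0.0 || B[(size_t)i * p + j] != 0.0))
                      ? 1 : 0;
    supports[l] = A;
  }
  return supports;
}
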