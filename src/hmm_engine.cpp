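#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Log-space recursions over a compiled HMM. States are 0-based here; the
// only silent states are START/END, which are carried as per-state entry
// (startlogp) and exit (endlogp) log-probability vectors rather than as
// nodes of the inner edge list. Inner edges connect emitting states only.
//
// Edge layout (built in R, see hmm_compile):
//   efrom/eto/elogp : parallel arrays, sorted by (to, tie-break priority)
//   tptr            : CSR offsets into the arrays by target state (n+1)
//   fidx/fptr       : permutation + CSR offsets giving edges by source state
// Tie-break for Viterbi is "first maximum wins" while scanning a target's
// incoming edges in their stored order, so R controls determinism by the
// sort it applies.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// [[Rcpp::export]]
List hmm_forward_cpp(const NumericMatrix& logemit, const IntegerVector& obs,
                     const IntegerVector& efrom, const NumericVector& elogp,
                     const IntegerVector& tptr,
                     const NumericVector& startlogp, const NumericVector& endlogp,
                     bool want_alpha) {
  const int n = logemit.nrow();
  const int T = obs.size();
  NumericMatrix alpha(T, n);
  std::fill(alpha.begin(), alpha.end(), NEG_INF);

  for (int j = 0; j < n; ++j) {
    if (startlogp[j] > NEG_INF)
      alpha(0, j) = startlogp[j] + logemit(j, obs[0]);
  }
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < n; ++j) {
      double acc = NEG_INF;
      for (int e = tptr[j]; e < tptr[j + 1]; ++e) {
        double a = alpha(t - 1, efrom[e]);
        if (a > NEG_INF) acc = lse2(acc, a + elogp[e]);
      }
      if (acc > NEG_INF) alpha(t, j) = acc + logemit(j, obs[t]);
    }
  }
  double ll = NEG_INF;
  for (int j = 0; j < n; ++j) {
    if (endlogp[j] > NEG_INF && alpha(T - 1, j) > NEG_INF)
      ll = lse2(ll, alpha(T - 1, j) + endlogp[j]);
  }
  if (want_alpha) return List::create(_["loglik"] = ll, _["alpha"] = alpha);
  return List::create(_["loglik"] = ll);
}

// [[Rcpp::export]]
List hmm_backward_cpp(const NumericMatrix& logemit, const IntegerVector& obs,
                      const IntegerVector& eto, const NumericVector& elogp,
                      const IntegerVector& fidx, const IntegerVector& fptr,
                      const NumericVector& startlogp, const NumericVector& endlogp,
                      bool want_beta) {
  const int n = logemit.nrow();
  const int T = obs.size();
  NumericMatrix beta(T, n);
  std::fill(beta.begin(), beta.end(), NEG_INF);

  for (int j = 0; j < n; ++j) beta(T - 1, j) = endlogp[j];
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < n; ++i) {
      double acc = NEG_INF;
      for (int k = fptr[i]; k < fptr[i + 1]; ++k) {
        int e = fidx[k];
        int j = eto[e];
        double b = beta(t + 1, j);
        if (b > NEG_INF) {
          double em = logemit(j, obs[t + 1]);
          if (em > NEG_INF) acc = lse2(acc, elogp[e] + em + b);
        }
      }
      beta(t, i) = acc;
    }
  }
  double ll = NEG_INF;
  for (int j = 0; j < n; ++j) {
    if (startlogp[j] > NEG_INF && beta(0, j) > NEG_INF) {
      double em = logemit(j, obs[0]);
      if (em > NEG_INF) ll = lse2(ll, startlogp[j] + em + beta(0, j));
    }
  }
  if (want_beta) return List::create(_["loglik"] = ll, _["beta"] = beta);
  return List::create(_["loglik"] = ll);
}

// init_order: states in tie-break order for the initial and final argmax
// scans (strict > keeps the earliest, i.e. highest-priority, candidate).
// [[Rcpp::export]]
List hmm_viterbi_cpp(const NumericMatrix& logemit, const IntegerVector& obs,
                     const IntegerVector& efrom, const NumericVector& elogp,
                     const IntegerVector& tptr,
                     const NumericVector& startlogp, const NumericVector& endlogp,
                     const IntegerVector& init_order) {
  const int n = logemit.nrow();
  const int T = obs.size();
  NumericMatrix delta(T, n);
  IntegerMatrix from(T, n);
  std::fill(delta.begin(), delta.end(), NEG_INF);
  std::fill(from.begin(), from.end(), -1);

  for (int j = 0; j < n; ++j) {
    if (startlogp[j] > NEG_INF)
      delta(0, j) = startlogp[j] + logemit(j, obs[0]);
  }
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < n; ++j) {
      double best = NEG_INF;
      int arg = -1;
      for (int e = tptr[j]; e < tptr[j + 1]; ++e) {
        double a = delta(t - 1, efrom[e]);
        if (a > NEG_INF) {
          double cand = a + elogp[e];
          if (cand > best) { best = cand; arg = efrom[e]; }
        }
      }
      if (best > NEG_INF) {
        delta(t, j) = best + logemit(j, obs[t]);
        from(t, j) = arg;
      }
    }
  }
  double best = NEG_INF;
  int last = -1;
  for (int k = 0; k < n; ++k) {
    int j = init_order[k];
    if (endlogp[j] > NEG_INF && delta(T - 1, j) > NEG_INF) {
      double cand = delta(T - 1, j) + endlogp[j];
      if (cand > best) { best = cand; last = j; }
    }
  }
  if (last < 0)
    return List::create(_["logprob"] = NEG_INF, _["path"] = IntegerVector(0));
  IntegerVector path(T);
  path[T - 1] = last;
  for (int t = T - 1; t > 0; --t) path[t - 1] = from(t, path[t]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // back to 1-based for R
  return List::create(_["logprob"] = best, _["path"] = path);
}

// Expected counts for one sequence (E-step). Returns the sequence
// log-likelihood, per-state emission counts, per-inner-edge transition
// counts, and expected uses of the START->j / j->END transitions.
// [[Rcpp::export]]
List hmm_counts_cpp(const NumericMatrix& logemit, const IntegerVector& obs,
                    const IntegerVector& efrom, const IntegerVector& eto,
                    const NumericVector& elogp,
                    const IntegerVector& tptr,
                    const IntegerVector& fidx, const IntegerVector& fptr,
                    const NumericVector& startlogp, const NumericVector& endlogp) {
  const int n = logemit.nrow();
  const int T = obs.size();
  const int ne = efrom.size();

  List fw = hmm_forward_cpp(logemit, obs, efrom, elogp, tptr, startlogp, endlogp, true);
  double ll = fw["loglik"];
  NumericMatrix emitc(n, logemit.ncol());
  NumericVector edgec(ne), startc(n), endc(n);
  if (ll == NEG_INF)
    return List::create(_["loglik"] = ll, _["emit"] = emitc, _["edge"] = edgec,
                        _["start"] = startc, _["end"] = endc);
  NumericMatrix alpha = fw["alpha"];
  List bw = hmm_backward_cpp(logemit, obs, eto, elogp, fidx, fptr, startlogp, endlogp, true);
  NumericMatrix beta = bw["beta"];

  for (int t = 0; t < T; ++t) {
    for (int j = 0; j < n; ++j) {
      double a = alpha(t, j), b = beta(t, j);
      if (a > NEG_INF && b > NEG_INF)
        emitc(j, obs[t]) += std::exp(a + b - ll);
    }
  }
  for (int t = 0; t + 1 < T; ++t) {
    for (int e = 0; e < ne; ++e) {
      double a = alpha(t, efrom[e]);
      if (a == NEG_INF) continue;
      double b = beta(t + 1, eto[e]);
      if (b == NEG_INF) continue;
      double em = logemit(eto[e], obs[t + 1]);
      if (em == NEG_INF) continue;
      edgec[e] += std::exp(a + elogp[e] + em + b - ll);
    }
  }
  for (int j = 0; j < n; ++j) {
    if (startlogp[j] > NEG_INF && beta(0, j) > NEG_INF) {
      double em = logemit(j, obs[0]);
      if (em > NEG_INF) startc[j] = std::exp(startlogp[j] + em + beta(0, j) - ll);
    }
    if (endlogp[j] > NEG_INF && alpha(T - 1, j) > NEG_INF)
      endc[j] = std::exp(alpha(T - 1, j) + endlogp[j] - ll);
  }
  return List::create(_["loglik"] = ll, _["emit"] = emitc, _["edge"] = edgec,
                      _["start"] = startc, _["end"] = endc);
}
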