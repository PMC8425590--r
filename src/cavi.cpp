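#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

// One full sequential coordinate-ascent sweep over the categorical label
// posteriors q (n x K, modified in place). The network enters in CSR form
// (adj: 0-based neighbour indices, ptr: length n+1 offsets). ann holds the
// per-protein annotation log-likelihood terms E[log theta] + E[log beta]
// already contracted with the protein's annotation counts (n x K).
// S (colSums of q) and Aq (A %*% q) are maintained incrementally so each
// node update is O(K^2 + K * degree).
// [[Rcpp::export]]
void cavi_sweep(NumericMatrix q, IntegerVector adj, IntegerVector ptr,
                NumericMatrix ann, NumericVector elog_alpha,
                NumericMatrix elog_eps, NumericMatrix elog_1meps,
                NumericVector S, NumericMatrix Aq) {
  const int n = q.nrow(), K = q.ncol();
  std::vector<double> logp(K), qnew(K), delta(K);

  for (int i = 0; i < n; ++i) {
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double acc = elog_alpha[k] + ann(i, k);
      for (int l = 0; l < K; ++l) {
        double e = Aq(i, l);
        double ne = S[l] - q(i, l) - e;  // non-neighbours in block l
        acc += e * elog_eps(k, l) + ne * elog_1meps(k, l);
      }
      logp[k] = acc;
      if (acc > mx) mx = acc;
    }
    double z = 0.0;
    for (int k = 0; k < K; ++k) { qnew[k] = std::exp(logp[k] - mx); z += qnew[k]; }
    for (int k = 0; k < K; ++k) {
      qnew[k] /= z;
      delta[k] = qnew[k] - q(i, k);
      q(i, k) = qnew[k];
      S[k] += delta[k];
    }
    for (int p = ptr[i]; p < ptr[i + 1]; ++p) {
      int j = adj[p];
      for (int k = 0; k < K; ++k) Aq(j, k) += delta[k];
    }
  }
}

// All simple paths from src to dst with 1..max_interior interior nodes,
// lexicographic by node sequence (assumes neighbour lists sorted ascending).
// Returns a list of integer vectors of interior nodes (1-based).
// [[Rcpp::export]]
List enumerate_paths_cpp(IntegerVector adj, IntegerVector ptr,
                         int src, int dst, int max_interior) {
  std::vector<SEXP> out;
  std::vector<int> interior;
  const int n = ptr.size() - 1;
  std::vector<char> visited(n, 0);
  visited[src] = 1;
  visited[dst] = 1;

  std::function<void(int)> dfs = [&](int node) {
    for (int p = ptr[node]; p < ptr[node + 1]; ++p) {
      int nb = adj[p];
      if (nb == dst) {
        if (!interior.empty()) {
          IntegerVector path(interior.size());
          for (size_t t = 0; t < interior.size(); ++t) path[t] = interior[t] + 1;
          out.push_back(path);
        }
        continue;
      }
      if (visited[nb] || (int)interior.size() >= max_interior) continue;
      visited[nb] = 1;
      interior.push_back(nb);
      dfs(nb);
      interior.pop_back();
      visited[nb] = 0;
    }
  };
  dfs(src);
  return List(out.begin(), out.end());
}

// Batch pair scoring: sum over simple paths (1..max_interior interiors) of
// weight/decay, weight = product of memb(interior, k) with k fixed per pair.
// lw_total adds the endpoints to both the weight product and the path size.
// Returns a 2-column matrix (score, n_paths).
// [[Rcpp::export]]
NumericMatrix score_pairs_cpp(IntegerVector adj, IntegerVector ptr,
                              NumericMatrix memb, IntegerMatrix pairs,
                              IntegerVector mod, double phi,
                              int max_interior, bool decay_exp,
                              bool lw_total) {
  const int n = ptr.size() - 1, np = pairs.nrow();
  NumericMatrix out(np, 2);
  std::vector<char> visited(n, 0);

  for (int r = 0; r < np; ++r) {
    int src = pairs(r, 0), dst = pairs(r, 1), k = mod[r];
    double total = 0.0;
    long n_paths = 0;
    std::fill(visited.begin(), visited.end(), 0);
    visited[src] = visited[dst] = 1;
    double w0 = lw_total ? memb(src, k) * memb(dst, k) : 1.0;

    std::function<void(int, int, double)> dfs =
        [&](int node, int depth, double w) {
      for (int p = ptr[node]; p < ptr[node + 1]; ++p) {
        int nb = adj[p];
        if (nb == dst) {
          if (depth >= 1) {
            int lw = lw_total ? depth + 2 : depth;
            double decay = decay_exp ? std::pow(phi, lw) : phi * lw;
            total += w / decay;
            ++n_paths;
          }
          continue;
        }
        if (visited[nb] || depth >= max_interior) continue;
        visited[nb] = 1;
        dfs(nb, depth + 1, w * memb(nb, k));
        visited[nb] = 0;
      }
    };
    dfs(src, 0, w0);
    out(r, 0) = total;
    out(r, 1) = (double)n_paths;
  }
  return out;
}
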