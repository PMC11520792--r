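// Uniform-weight Laplacian smoothing steps over mesh vertex neighbourhoods.
// A positive factor moves each vertex toward its one-ring centroid; Taubin
// smoothing alternates a positive and a negative factor to limit shrinkage.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_laplacian_smooth")]]
NumericMatrix cpp_laplacian_smooth(NumericMatrix V, IntegerMatrix F,
                                   NumericVector factors, int iterations) {
  int nv = V.nrow(), nt = F.nrow();
  // vertex adjacency from triangle edges
  std::vector<std::vector<int> > adj(nv);
  for (int t = 0; t < nt; ++t) {
    int a = F(t, 0) - 1, b = F(t, 1) - 1, c = F(t, 2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int i = 0; i < nv; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
  }
  NumericMatrix X = clone(V);
  NumericMatrix Y(nv, 3);
  int nf = factors.size();
  for (int it = 0; it < iterations; ++it) {
    for (int s = 0; s < nf; ++s) {
      double lam = factors[s];
      for (int i = 0; i < nv; ++i) {
        if (adj[i].empty()) {
          Y(i, 0) = X(i, 0); Y(i, 1) = X(i, 1); Y(i, 2) = X(i, 2);
          continue;
        }
        double cx = 0, cy = 0, cz = 0;
        for (size_t m = 0; m < adj[i].size(); ++m) {
          int j = adj[i][m];
          cx += X(j, 0); cy += X(j, 1); cz += X(j, 2);
        }
        double inv = 1.0 / adj[i].size();
        Y(i, 0) = X(i, 0) + lam * (cx * inv - X(i, 0));
        Y(i, 1) = X(i, 1) + lam * (cy * inv - X(i, 1));
        Y(i, 2) = X(i, 2) + lam * (cz * inv - X(i, 2));
      }
      std::swap(X, Y);
    }
  }
  return X;
}
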