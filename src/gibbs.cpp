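#include <Rcpp.h>
using namespace Rcpp;

// No-admixture Gibbs sampler over multi-allelic markers.
// a1, a2: n x m integer haplotype codes (0-based; -1 = missing marker).
// nhap:   haplotype alphabet size per marker.
// Alternates (1) cluster haplotype frequencies | assignments ~
// Dirichlet(lambda + counts) per marker and cluster, and (2) each sample's
// cluster | frequencies ~ categorical with HWE genotype weights. Kept
// iterations accumulate assignment posteriors after greedy label alignment
// to the first kept iteration. Uses R's RNG, so set.seed() on the R side
// makes runs reproducible.
// [[Rcpp::export]]
List gibbs_no_admixture_cpp(IntegerMatrix a1, IntegerMatrix a2,
                            IntegerVector nhap, int K, double lambda,
                            int burn_in, int kept) {
  const int n = a1.nrow();
  const int m = a1.ncol();
  if (K < 1) stop("K must be >= 1");
  if (K > n) stop("K exceeds the number of samples");

  // flat storage: logp[k][m] is a block of nhap[m] doubles
  std::vector<int> off(m + 1, 0);
  for (int j = 0; j < m; ++j) off[j + 1] = off[j] + nhap[j];
  const int Htot = off[m];
  std::vector<double> logp(K * Htot), counts(K * Htot);
  std::vector<int> z(n), ref_z(n);
  std::vector<double> ll(K), post_counts((size_t)n * K, 0.0);
  NumericVector trace(kept);
  const double log2v = std::log(2.0);

  for (int i = 0; i < n; ++i)
    z[i] = (int)std::floor(unif_rand() * K);

  bool have_ref = false;
  std::vector<int> perm(K);

  for (int it = 0; it < burn_in + kept; ++it) {
    // (1) frequencies | assignments
    std::fill(counts.begin(), counts.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const int base = z[i] * Htot;
      for (int j = 0; j < m; ++j) {
        if (a1(i, j) < 0) continue;
        counts[base + off[j] + a1(i, j)] += 1.0;
        counts[base + off[j] + a2(i, j)] += 1.0;
      }
    }
    for (int k = 0; k < K; ++k) {
      const int base = k * Htot;
      for (int j = 0; j < m; ++j) {
        double tot = 0.0;
        for (int h = 0; h < nhap[j]; ++h) {
          double g = R::rgamma(lambda + counts[base + off[j] + h], 1.0);
          if (g <= 0) g = 1e-300;
          logp[base + off[j] + h] = g;
          tot += g;
        }
        const double lt = std::log(tot);
        for (int h = 0; h < nhap[j]; ++h) {
          double &v = logp[base + off[j] + h];
          v = std::log(v) - lt;
        }
      }
    }
    // (2) assignments | frequencies
    for (int i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        const int base = k * Htot;
        double s = 0.0;
        for (int j = 0; j < m; ++j) {
          const int h1 = a1(i, j), h2 = a2(i, j);
          if (h1 < 0) continue;
          const double lp1 = logp[base + off[j] + h1];
          if (h1 == h2) s += 2.0 * lp1;
          else s += log2v + lp1 + logp[base + off[j] + h2];
        }
        ll[k] = s;
        if (s > mx) mx = s;
      }
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        ll[k] = std::exp(ll[k] - mx);
        tot += ll[k];
      }
      double u = unif_rand() * tot, acc = 0.0;
      int pick = K - 1;
      for (int k = 0; k < K; ++k) {
        acc += ll[k];
        if (u <= acc) { pick = k; break; }
      }
      z[i] = pick;
    }
    // data log-likelihood at the current state: P(X | z, frequencies)
    double logL = 0.0;
    for (int i = 0; i < n; ++i) {
      const int base = z[i] * Htot;
      for (int j = 0; j < m; ++j) {
        const int h1 = a1(i, j), h2 = a2(i, j);
        if (h1 < 0) continue;
        const double lp1 = logp[base + off[j] + h1];
        if (h1 == h2) logL += 2.0 * lp1;
        else logL += log2v + lp1 + logp[base + off[j] + h2];
      }
    }

    if (it >= burn_in) {
      const int t = it - burn_in;
      if (!have_ref) { ref_z = z; have_ref = true; }
      // greedy max-overlap permutation current -> reference labels
      std::vector<std::vector<int>> ov(K, std::vector<int>(K, 0));
      for (int i = 0; i < n; ++i) ov[z[i]][ref_z[i]]++;
      std::vector<bool> rowdone(K, false), coldone(K, false);
      for (int step = 0; step < K; ++step) {
        int bi = -1, bj = -1, best = -1;
        for (int a = 0; a < K; ++a) {
          if (rowdone[a]) continue;
          for (int b = 0; b < K; ++b) {
            if (coldone[b]) continue;
            if (ov[a][b] > best) { best = ov[a][b]; bi = a; bj = b; }
          }
        }
        perm[bi] = bj;
        rowdone[bi] = true;
        coldone[bj] = true;
      }
      for (int i = 0; i < n; ++i)
        post_counts[(size_t)i * K + perm[z[i]]] += 1.0;
      trace[t] = logL;
    }
  }

  NumericMatrix posterior(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k)
      posterior(i, k) = post_counts[(size_t)i * K + k] / kept;
  IntegerVector zfin(n);
  for (int i = 0; i < n; ++i) zfin[i] = z[i] + 1;
  return List::create(_["posterior"] = posterior, _["trace"] = trace,
                      _["z_last"] = zfin);
}
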