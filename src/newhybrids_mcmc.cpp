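#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler over six hybrid genotype-frequency classes.
//
// Each class c fixes the probabilities phi_c over the origins of a locus's
// two gene copies, (WW, WD, DD). Conditional on an individual's class, copy
// origins are sampled per locus and the two source allele-frequency vectors
// are updated from the allocated copies under Dirichlet priors; class
// membership is sampled from pi_c times the genotype likelihood and pi has
// a flat Dirichlet prior. Reference individuals can be pinned to a class.
// Uses R's RNG (reproducible via set.seed()).

static void rdirichlet_vec(std::vector<double>& out,
                           const std::vector<double>& shape) {
  double tot = 0.0;
  for (size_t j = 0; j < shape.size(); ++j) {
    double g = R::rgamma(shape[j], 1.0);
    if (g < 1e-300) g = 1e-300;
    out[j] = g;
    tot += g;
  }
  for (size_t j = 0; j < shape.size(); ++j) out[j] /= tot;
}

// genotype probability under origin o (0=WW,1=WD,2=DD)
static inline double geno_prob(int a, int b, int o,
                               const std::vector<double>& pW,
                               const std::vector<double>& pD) {
  if (o == 0) return (a == b) ? pW[a] * pW[a] : 2.0 * pW[a] * pW[b];
  if (o == 2) return (a == b) ? pD[a] * pD[a] : 2.0 * pD[a] * pD[b];
  return (a == b) ? pW[a] * pD[a] : pW[a] * pD[b] + pW[b] * pD[a];
}

// [[Rcpp::export(name = ".newhybrids_gibbs_cpp")]]
List newhybrids_gibbs_cpp(IntegerMatrix a1, IntegerMatrix a2,
                          IntegerVector nAlleles,
                          NumericMatrix phi,          // 6 x 3
                          IntegerVector fixedClass,   // 0 free, else 1..6
                          double freqPrior,
                          int burnin, int niter) {
  const int N = a1.nrow(), L = a1.ncol(), C = phi.nrow();
  const int nsweep = burnin + niter;

  // state: source frequencies, mixing proportions, classes
  std::vector<std::vector<double> > pW(L), pD(L);
  for (int l = 0; l < L; ++l) {
    pW[l].assign(nAlleles[l], 1.0 / nAlleles[l]);
    pD[l].assign(nAlleles[l], 1.0 / nAlleles[l]);
  }
  std::vector<double> pi(C, 1.0 / C);
  std::vector<int> z(N, 0);
  for (int i = 0; i < N; ++i) if (fixedClass[i] > 0) z[i] = fixedClass[i] - 1;

  NumericMatrix postSum(N, C);
  NumericVector lnLtrace(niter);
  std::vector<double> logp(C);

  for (int sweep = 0; sweep < nsweep; ++sweep) {
    double lnLdata = 0.0;
    // class update (Rao-Blackwellised accumulation after burn-in)
    for (int i = 0; i < N; ++i) {
      for (int c = 0; c < C; ++c) logp[c] = std::log(std::max(pi[c], 1e-300));
      for (int l = 0; l < L; ++l) {
        int a = a1(i, l), b = a2(i, l);
        if (a == NA_INTEGER || a == 0) continue;
        --a; --b;
        for (int c = 0; c < C; ++c) {
          double lik = 0.0;
          for (int o = 0; o < 3; ++o) {
            const double w = phi(c, o);
            if (w > 0.0) lik += w * geno_prob(a, b, o, pW[l], pD[l]);
          }
          logp[c] += std::log(std::max(lik, 1e-300));
        }
      }
      double m = logp[0];
      for (int c = 1; c < C; ++c) if (logp[c] > m) m = logp[c];
      double tot = 0.0;
      std::vector<double> pr(C);
      for (int c = 0; c < C; ++c) { pr[c] = std::exp(logp[c] - m); tot += pr[c]; }
      lnLdata += m + std::log(tot);
      if (fixedClass[i] > 0) {
        z[i] = fixedClass[i] - 1;
      } else {
        double u = R::unif_rand() * tot, acc = 0.0;
        z[i] = C - 1;
        for (int c = 0; c < C; ++c) { acc += pr[c]; if (u <= acc) { z[i] = c; break; } }
      }
      if (sweep >= burnin)
        for (int c = 0; c < C; ++c) postSum(i, c) += pr[c] / tot;
    }

    // origin allocation and source frequency update
    std::vector<std::vector<double> > cW(L), cD(L);
    for (int l = 0; l < L; ++l) {
      cW[l].assign(nAlleles[l], 0.0);
      cD[l].assign(nAlleles[l], 0.0);
    }
    for (int i = 0; i < N; ++i) {
      const int c = z[i];
      for (int l = 0; l < L; ++l) {
        int a = a1(i, l), b = a2(i, l);
        if (a == NA_INTEGER || a == 0) continue;
        --a; --b;
        double po[3], tot = 0.0;
        for (int o = 0; o < 3; ++o) {
          po[o] = phi(c, o) > 0.0 ? phi(c, o) * geno_prob(a, b, o, pW[l], pD[l]) : 0.0;
          tot += po[o];
        }
        if (tot <= 0.0) continue;
        double u = R::unif_rand() * tot, acc = 0.0;
        int o = 2;
        for (int oo = 0; oo < 3; ++oo) { acc += po[oo]; if (u <= acc) { o = oo; break; } }
        if (o == 0) { cW[l][a] += 1.0; cW[l][b] += 1.0; }
        else if (o == 2) { cD[l][a] += 1.0; cD[l][b] += 1.0; }
        else {
          if (a == b) { cW[l][a] += 1.0; cD[l][a] += 1.0; }
          else {
            // which copy came from W
            double w1 = pW[l][a] * pD[l][b], w2 = pW[l][b] * pD[l][a];
            if (R::unif_rand() * (w1 + w2) <= w1) { cW[l][a] += 1.0; cD[l][b] += 1.0; }
            else { cW[l][b] += 1.0; cD[l][a] += 1.0; }
          }
        }
      }
    }
    for (int l = 0; l < L; ++l) {
      const int A = nAlleles[l];
      std::vector<double> sh(A), out(A);
      for (int a = 0; a < A; ++a) sh[a] = freqPrior + cW[l][a];
      rdirichlet_vec(out, sh);
      pW[l] = out;
      for (int a = 0; a < A; ++a) sh[a] = freqPrior + cD[l][a];
      rdirichlet_vec(out, sh);
      pD[l] = out;
    }

    // mixing proportions
    {
      std::vector<double> sh(C, 1.0), out(C);
      for (int i = 0; i < N; ++i) sh[z[i]] += 1.0;
      rdirichlet_vec(out, sh);
      pi = out;
    }

    if (sweep >= burnin) lnLtrace[sweep - burnin] = lnLdata;
  }

  for (int i = 0; i < N; ++i)
    for (int c = 0; c < C; ++c) postSum(i, c) /= niter;
  return List::create(_["posterior"] = postSum, _["lnL"] = lnLtrace);
}
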