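#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model with independent allele frequencies.
//
// Latent allele-copy origins are integrated over each sweep by resampling:
//   z ~ Categorical(q_i[k] * p[k][l][a])
//   p[k][l] ~ Dirichlet(lambda + allele counts assigned to k)
//   q_i ~ Dirichlet(alpha + per-cluster copy counts)  (unflagged individuals)
//   alpha: Metropolis random walk under a Uniform(0, alphaMax] prior.
// Flagged individuals (popflagCluster > 0) keep q fixed to their declared
// cluster; with updateFlaggedOnly only their copies update p.
// Uses R's RNG so results are reproducible via set.seed().

static void rdirichlet_inplace(std::vector<double>& out,
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

// [[Rcpp::export(name = ".admixture_gibbs_cpp")]]
List admixture_gibbs_cpp(IntegerMatrix a1, IntegerMatrix a2,
                         IntegerVector nAlleles, int K,
                         int burnin, int niter, int thin,
                         double lambda, double alphaInit, double alphaMax,
                         double alphaPropSd,
                         IntegerVector popflagCluster,
                         bool updateFlaggedOnly) {
  const int N = a1.nrow(), L = a1.ncol();
  const int maxA = max(nAlleles);
  const int nsweep = burnin + niter;

  // state
  std::vector<std::vector<std::vector<double> > > P(K);
  for (int k = 0; k < K; ++k) {
    P[k].resize(L);
    for (int l = 0; l < L; ++l) {
      P[k][l].assign(nAlleles[l], 1.0 / nAlleles[l]);
    }
  }
  NumericMatrix Q(N, K);
  bool anyFlag = false;
  for (int i = 0; i < N; ++i) {
    if (popflagCluster[i] > 0) {
      anyFlag = true;
      for (int k = 0; k < K; ++k) Q(i, k) = (k == popflagCluster[i] - 1) ? 1.0 : 0.0;
    } else {
      for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;
    }
  }
  if (!anyFlag) updateFlaggedOnly = false;
  double alpha = alphaInit;

  // accumulators
  NumericMatrix Qsum(N, K);
  const int nkept = niter / thin;
  NumericVector Qkeep(nkept * N * K);   // [rep, i, k] flattened
  NumericVector lnLtrace(niter), alphaTrace(niter);
  NumericVector Psum(K * L * maxA);
  int kept = 0, alphaAcc = 0;

  // scratch
  std::vector<std::vector<std::vector<double> > > cnt(K,
      std::vector<std::vector<double> >(L));
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) cnt[k][l].assign(nAlleles[l], 0.0);
  std::vector<std::vector<double> > nik(N, std::vector<double>(K, 0.0));
  std::vector<double> pz(K), shape(maxA), tmp(maxA);

  for (int sweep = 0; sweep < nsweep; ++sweep) {
    // reset counts
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        std::fill(cnt[k][l].begin(), cnt[k][l].end(), 0.0);
    for (int i = 0; i < N; ++i) std::fill(nik[i].begin(), nik[i].end(), 0.0);

    double lnL = 0.0;
    // sample copy origins
    for (int i = 0; i < N; ++i) {
      const bool flagged = popflagCluster[i] > 0;
      const int fk = flagged ? popflagCluster[i] - 1 : -1;
      const bool contributes = !updateFlaggedOnly || flagged;
      for (int l = 0; l < L; ++l) {
        int al[2] = { a1(i, l), a2(i, l) };
        if (al[0] == NA_INTEGER || al[0] == 0) continue;
        for (int c = 0; c < 2; ++c) {
          const int a = al[c] - 1;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            pz[k] = Q(i, k) * P[k][l][a];
            tot += pz[k];
          }
          lnL += std::log(tot);
          int zk;
          if (flagged) {
            zk = fk;  // declared origin: deterministic contribution
          } else {
            double u = R::unif_rand() * tot, acc = 0.0;
            zk = K - 1;
            for (int k = 0; k < K; ++k) { acc += pz[k]; if (u <= acc) { zk = k; break; } }
          }
          nik[i][zk] += 1.0;
          if (contributes) cnt[zk][l][a] += 1.0;
        }
      }
    }

    // update P
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < L; ++l) {
        const int A = nAlleles[l];
        for (int a = 0; a < A; ++a) shape[a] = lambda + cnt[k][l][a];
        std::vector<double> sh(shape.begin(), shape.begin() + A);
        std::vector<double> out(A);
        rdirichlet_inplace(out, sh);
        for (int a = 0; a < A; ++a) P[k][l][a] = out[a];
      }
    }

    // update Q for unflagged individuals
    for (int i = 0; i < N; ++i) {
      if (popflagCluster[i] > 0) continue;
      std::vector<double> sh(K), out(K);
      for (int k = 0; k < K; ++k) sh[k] = alpha + nik[i][k];
      rdirichlet_inplace(out, sh);
      for (int k = 0; k < K; ++k) Q(i, k) = out[k];
    }

    // Metropolis update of alpha (uniform prior on (0, alphaMax])
    if (K > 1) {
      double prop = alpha + R::norm_rand() * alphaPropSd;
      if (prop > 0.0 && prop <= alphaMax) {
        double logr = 0.0;
        int nfree = 0;
        for (int i = 0; i < N; ++i) {
          if (popflagCluster[i] > 0) continue;
          ++nfree;
          for (int k = 0; k < K; ++k)
            logr += (prop - alpha) * std::log(std::max(Q(i, k), 1e-300));
        }
        logr += nfree * (R::lgammafn(K * prop) - K * R::lgammafn(prop)
                         - R::lgammafn(K * alpha) + K * R::lgammafn(alpha));
        if (std::log(R::unif_rand()) < logr) { alpha = prop; ++alphaAcc; }
      }
    }

    if (sweep >= burnin) {
      const int it = sweep - burnin;
      lnLtrace[it] = lnL;
      alphaTrace[it] = alpha;
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      if (it % thin == 0 && kept < nkept) {
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < K; ++k)
            Qkeep[kept + nkept * (i + N * k)] = Q(i, k);
        ++kept;
      }
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l)
          for (int a = 0; a < nAlleles[l]; ++a)
            Psum[k + K * (l + L * a)] += P[k][l][a];
    }
  }

  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= niter;
  for (int j = 0; j < Psum.size(); ++j) Psum[j] /= niter;

  Qkeep.attr("dim") = IntegerVector::create(nkept, N, K);
  Psum.attr("dim") = IntegerVector::create(K, L, maxA);
  return List::create(_["Q"] = Qsum, _["Qsamples"] = Qkeep,
                      _["lnL"] = lnLtrace, _["alpha"] = alphaTrace,
                      _["Pmean"] = Psum,
                      _["alpha_accept"] = (double)alphaAcc / nsweep);
}
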