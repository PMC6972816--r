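// Gibbs sampler for the standard admixture model on codominant multilocus
// genotypes: latent cluster of origin for each allele copy, per-individual
// ancestry with symmetric Dirichlet(alpha) prior (alpha updated by a
// Metropolis step), per-cluster allele frequencies with either a flat
// Dirichlet(lambda) prior (independent model) or a correlated F-model prior
// centred on fixed ancestral frequencies with per-cluster drift updated by
// Metropolis. Missing genotypes are skipped in the likelihood.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static double rgamma1(double shape) {
  // R::rgamma with very small shapes can return 0; floor to keep Dirichlet valid
  double x = R::rgamma(shape, 1.0);
  return (x > 0) ? x : 1e-300;
}

// [[Rcpp::export]]
List admix_gibbs_cpp(IntegerMatrix A, IntegerMatrix B, IntegerVector nAll,
                     int K, int burnin, int iters, int thin,
                     bool correlated, double alpha_init, double lambda,
                     List ancestral, double alpha_prop_sd, double f_prop_sd) {
  const int N = A.nrow(), L = A.ncol();
  const int total = burnin + iters;

  // allele frequencies p[l] : K x nAll[l], row-major by cluster
  std::vector<std::vector<double> > p(L);
  std::vector<std::vector<double> > anc(L);
  for (int l = 0; l < L; ++l) {
    p[l].assign(K * nAll[l], 1.0 / nAll[l]);
    NumericVector av = ancestral[l];
    anc[l].assign(av.begin(), av.end());
  }
  NumericMatrix q(N, K);
  std::fill(q.begin(), q.end(), 1.0 / K);
  std::vector<double> Fk(K, 0.15);  // drift parameters (correlated model)
  double alpha = alpha_init;

  // accumulators
  std::vector<double> indCount(N * K);
  std::vector<std::vector<double> > allCount(L);
  for (int l = 0; l < L; ++l) allCount[l].assign(K * nAll[l], 0.0);

  const int ndraws = (thin > 0) ? iters / thin : 0;
  NumericVector qdraws(std::max(1, ndraws) * N * K);
  NumericVector loglik(total), alphaTrace(total);
  NumericMatrix qmean(N, K);
  std::vector<double> pmean; // filled at end from accumulated sums
  std::vector<std::vector<double> > psum(L);
  for (int l = 0; l < L; ++l) psum[l].assign(K * nAll[l], 0.0);

  std::vector<double> prob(K);
  int drawIdx = 0;

  for (int it = 0; it < total; ++it) {
    std::fill(indCount.begin(), indCount.end(), 0.0);
    for (int l = 0; l < L; ++l)
      std::fill(allCount[l].begin(), allCount[l].end(), 0.0);
    double ll = 0.0;

    // --- latent origins z, counts, and data log-likelihood ---
    for (int i = 0; i < N; ++i) {
      for (int l = 0; l < L; ++l) {
        int x1 = A(i, l);
        if (x1 < 0) continue;
        int x2 = B(i, l);
        const std::vector<double>& pl = p[l];
        const int m = nAll[l];
        for (int c = 0; c < 2; ++c) {
          int x = c == 0 ? x1 : x2;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = q(i, k) * pl[k * m + x];
            s += prob[k];
          }
          ll += std::log(s);
          double u = R::unif_rand() * s, acc = 0.0;
          int k = K - 1;
          for (int kk = 0; kk < K; ++kk) {
            acc += prob[kk];
            if (u <= acc) { k = kk; break; }
          }
          indCount[i * K + k] += 1.0;
          allCount[l][k * m + x] += 1.0;
        }
      }
    }
    loglik[it] = ll;

    // --- q | z ~ Dirichlet(alpha + counts) ---
    for (int i = 0; i < N; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = rgamma1(alpha + indCount[i * K + k]);
        q(i, k) = g; s += g;
      }
      for (int k = 0; k < K; ++k) q(i, k) /= s;
    }

    // --- p | z ~ Dirichlet(prior + counts) ---
    for (int l = 0; l < L; ++l) {
      const int m = nAll[l];
      for (int k = 0; k < K; ++k) {
        double conc = correlated ? (1.0 - Fk[k]) / Fk[k] : 0.0;
        double s = 0.0;
        for (int a = 0; a < m; ++a) {
          double prior = correlated ? conc * anc[l][a] : lambda;
          double g = rgamma1(prior + allCount[l][k * m + a]);
          p[l][k * m + a] = g; s += g;
        }
        for (int a = 0; a < m; ++a) p[l][k * m + a] /= s;
      }
    }

    // --- alpha Metropolis (uniform prior on (0, 10]) ---
    {
      double cand = alpha + R::norm_rand() * alpha_prop_sd;
      if (cand > 0 && cand <= 10.0) {
        double sumlogq = 0.0;
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < K; ++k) sumlogq += std::log(q(i, k));
        double lpCur = N * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
                       (alpha - 1.0) * sumlogq;
        double lpCand = N * (R::lgammafn(K * cand) - K * R::lgammafn(cand)) +
                        (cand - 1.0) * sumlogq;
        if (std::log(R::unif_rand()) < lpCand - lpCur) alpha = cand;
      }
      alphaTrace[it] = alpha;
    }

    // --- drift Fk Metropolis (correlated model only) ---
    if (correlated) {
      for (int k = 0; k < K; ++k) {
        double cand = Fk[k] + R::norm_rand() * f_prop_sd;
        if (cand <= 1e-4 || cand >= 1 - 1e-4) continue;
        double lpCur = 0.0, lpCand = 0.0;
        double cCur = (1.0 - Fk[k]) / Fk[k], cCand = (1.0 - cand) / cand;
        for (int l = 0; l < L; ++l) {
          const int m = nAll[l];
          double sCur = 0.0, sCand = 0.0;
          for (int a = 0; a < m; ++a) {
            double lg = std::log(p[l][k * m + a]);
            sCur  += (cCur  * anc[l][a] - 1.0) * lg - R::lgammafn(cCur  * anc[l][a]);
            sCand += (cCand * anc[l][a] - 1.0) * lg - R::lgammafn(cCand * anc[l][a]);
          }
          lpCur  += R::lgammafn(cCur)  + sCur;
          lpCand += R::lgammafn(cCand) + sCand;
        }
        if (std::log(R::unif_rand()) < lpCand - lpCur) Fk[k] = cand;
      }
    }

    // --- retention ---
    if (it >= burnin) {
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) qmean(i, k) += q(i, k) / iters;
      for (int l = 0; l < L; ++l)
        for (size_t j = 0; j < psum[l].size(); ++j)
          psum[l][j] += p[l][j] / iters;
      if (thin > 0 && (it - burnin) % thin == thin - 1 && drawIdx < ndraws) {
        for (int i = 0; i < N; ++i)
          for (int k = 0; k < K; ++k)
            qdraws[(size_t)drawIdx * N * K + (size_t)k * N + i] = q(i, k);
        ++drawIdx;
      }
    }
  }

  List pout(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix pm(K, nAll[l]);
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < nAll[l]; ++a) pm(k, a) = psum[l][k * nAll[l] + a];
    pout[l] = pm;
  }
  qdraws.attr("dim") = IntegerVector::create(N, K, std::max(1, ndraws));
  return List::create(_["qmean"] = qmean, _["qdraws"] = qdraws,
                      _["ndraws"] = drawIdx, _["loglik"] = loglik,
                      _["alpha"] = alphaTrace, _["cluster_freqs"] = pout,
                      _["drift"] = NumericVector(Fk.begin(), Fk.end()));
}
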