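#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model with independent Beta(1,1)
// cluster-locus allele frequencies. Genotypes are B-allele dosages
// (0/1/2, -1 = missing) for diploid biallelic loci. Latent variables are
// the cluster origins of the two allele copies per (individual, locus).
// alpha (symmetric Dirichlet parameter of the ancestry prior) is updated
// by a Metropolis step with a normal proposal, as in the reference
// implementation. Uses R's RNG: seed with set.seed() before calling.
// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix geno, int K, int burnin, int iters,
                         double alpha_init) {
  int N = geno.nrow(), L = geno.ncol();
  RNGScope scope;

  // copy-level allele data (0 = A, 1 = B; -1 = missing call)
  std::vector<signed char> a1(N * L), a2(N * L);
  for (int i = 0; i < N; i++) for (int l = 0; l < L; l++) {
    int g = geno(i, l);
    if (g < 0) { a1[i * L + l] = -1; a2[i * L + l] = -1; }
    else { a1[i * L + l] = (g >= 1); a2[i * L + l] = (g == 2); }
  }

  std::vector<signed char> z1(N * L), z2(N * L);
  // sufficient statistics of Z, maintained incrementally
  std::vector<double> nB(K * L, 0.0), nTot(K * L, 0.0), m(N * K, 0.0);
  for (int i = 0; i < N; i++) for (int l = 0; l < L; l++) {
    int idx = i * L + l;
    z1[idx] = (signed char)(unif_rand() * K);
    z2[idx] = (signed char)(unif_rand() * K);
    if (a1[idx] < 0) continue;
    nB[z1[idx] + K * l] += a1[idx]; nTot[z1[idx] + K * l] += 1.0;
    nB[z2[idx] + K * l] += a2[idx]; nTot[z2[idx] + K * l] += 1.0;
    m[i * K + z1[idx]] += 1.0;
    m[i * K + z2[idx]] += 1.0;
  }

  std::vector<double> P(K * L), q(N * K), probs(K);
  std::vector<double> Qsum(N * K, 0.0), Psum(K * L, 0.0);
  NumericVector lltrace(iters);
  double alpha = alpha_init, alpha_sum = 0.0;

  int total = burnin + iters;
  for (int sweep = 0; sweep < total; sweep++) {
    // P | Z: Beta(1 + nB, 1 + nA), element (k,l) at k + K*l
    for (int v = 0; v < K * L; v++)
      P[v] = R::rbeta(1.0 + nB[v], 1.0 + (nTot[v] - nB[v]));

    // Q | Z: Dirichlet(alpha + m_ik), row-major q[i*K + k]
    for (int i = 0; i < N; i++) {
      double s = 0.0;
      for (int k = 0; k < K; k++) {
        double g = R::rgamma(alpha + m[i * K + k], 1.0);
        q[i * K + k] = g; s += g;
      }
      for (int k = 0; k < K; k++) q[i * K + k] /= s;
    }

    // alpha | Q (Metropolis, uniform prior on (0, 10))
    if (K > 1) {
      double prop = alpha + norm_rand() * 0.05;
      if (prop > 0.0 && prop < 10.0) {
        double logr = N * (R::lgammafn(K * prop) - K * R::lgammafn(prop)
                         - R::lgammafn(K * alpha) + K * R::lgammafn(alpha));
        for (int v = 0; v < N * K; v++)
          logr += (prop - alpha) * std::log(q[v] + 1e-300);
        if (std::log(unif_rand() + 1e-300) < logr) alpha = prop;
      }
    }

    // Z | Q, P per allele copy, updating the sufficient statistics in place
    for (int i = 0; i < N; i++) {
      const double *qi = &q[i * K];
      for (int l = 0; l < L; l++) {
        int idx = i * L + l;
        if (a1[idx] < 0) continue;
        const double *pl = &P[K * l];
        for (int copy = 0; copy < 2; copy++) {
          signed char *z = copy == 0 ? &z1[idx] : &z2[idx];
          int al = copy == 0 ? a1[idx] : a2[idx];
          double s = 0.0;
          for (int k = 0; k < K; k++) {
            double pk = al ? pl[k] : 1.0 - pl[k];
            probs[k] = qi[k] * pk;
            s += probs[k];
          }
          double u = unif_rand() * s, c = 0.0;
          int zk = K - 1;
          for (int k = 0; k < K; k++) { c += probs[k]; if (u <= c) { zk = k; break; } }
          int old = *z;
          if (old != zk) {
            nB[old + K * l] -= al;  nTot[old + K * l] -= 1.0;
            nB[zk + K * l]  += al;  nTot[zk + K * l]  += 1.0;
            m[i * K + old] -= 1.0;  m[i * K + zk] += 1.0;
            *z = (signed char)zk;
          }
        }
      }
    }

    // log-likelihood of the data given (Q, P)
    if (sweep >= burnin) {
      double ll = 0.0;
      for (int i = 0; i < N; i++) {
        const double *qi = &q[i * K];
        for (int l = 0; l < L; l++) {
          int idx = i * L + l;
          if (a1[idx] < 0) continue;
          const double *pl = &P[K * l];
          double pi = 0.0;
          for (int k = 0; k < K; k++) pi += qi[k] * pl[k];
          int g = a1[idx] + a2[idx];
          double pg = g == 0 ? (1 - pi) * (1 - pi)
                    : g == 1 ? 2 * pi * (1 - pi) : pi * pi;
          ll += std::log(pg + 1e-300);
        }
      }
      lltrace[sweep - burnin] = ll;
      alpha_sum += alpha;
      for (int v = 0; v < N * K; v++) Qsum[v] += q[v];
      for (int v = 0; v < K * L; v++) Psum[v] += P[v];
    }
  }

  NumericMatrix Qout(N, K), Pout(K, L);
  for (int i = 0; i < N; i++) for (int k = 0; k < K; k++)
    Qout(i, k) = Qsum[i * K + k] / iters;
  for (int k = 0; k < K; k++) for (int l = 0; l < L; l++)
    Pout(k, l) = Psum[k + K * l] / iters;
  return List::create(_["Q"] = Qout, _["P"] = Pout,
                      _["loglik_trace"] = lltrace,
                      _["alpha_mean"] = alpha_sum / iters);
}
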