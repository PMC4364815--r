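#include <Rcpp.h>
using namespace Rcpp;

// Markov chain for the Hardy-Weinberg exact test on a multi-allelic
// genotype array, conditional on the observed allele counts.
//
// The chain works on the space of gene-slot assignments: the 2n genes of
// the sample occupy 2n labelled slots (two per individual). For a fixed
// multiset of alleles, a uniformly random assignment of genes to slots
// induces exactly the Levene conditional distribution of genotype arrays,
//   P(array) = n! 2^H prod_k a_k! / ( (2n)! prod_{i<=j} g_ij! ),
// because an array corresponds to n!/prod(g!) * 2^H slot states. Swapping
// the contents of two uniformly chosen slots is a symmetric proposal with
// a uniform target, so every swap is accepted; no Metropolis ratio is
// needed and the stationary array distribution is exact.
//
// The p-value is the long-run fraction of visited arrays whose conditional
// probability does not exceed the observed array's (ties included), with a
// Monte Carlo standard error from batch means. Uses R's RNG so results are
// reproducible under set.seed().

static inline int cell(int i, int j, int k) {
  // lower-triangle index with i >= j
  return (i >= j) ? i * k + j : j * k + i;
}

// [[Rcpp::export]]
List hwe_chain_cpp(IntegerMatrix geno, int dememorization, int batches,
                   int iterations) {
  int k = geno.nrow();
  if (geno.ncol() != k) stop("genotype count matrix must be square");

  // gene slots: 2 per individual; counts for the statistic
  std::vector<int> slot;
  std::vector<double> counts(k * k, 0.0);
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j <= i; ++j) {
      int c = geno(i, j) + ((i == j) ? 0 : geno(j, i));
      if (c < 0) stop("negative genotype count");
      counts[cell(i, j, k)] = c;
      for (int r = 0; r < c; ++r) { slot.push_back(i); slot.push_back(j); }
    }
  }
  int n2 = (int)slot.size();
  int n = n2 / 2;
  if (n < 2) stop("need at least 2 individuals");

  // statistic T = H log 2 - sum lgamma(g_ij + 1); P(array) proportional to
  // exp(T), so T orders arrays by conditional probability
  double T = 0.0;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j <= i; ++j) {
      double g = counts[cell(i, j, k)];
      T -= lgamma(g + 1.0);
      if (i != j) T += g * M_LN2;
    }
  const double T0 = T;
  const double tol = 1e-9 * (1.0 + fabs(T0));

  GetRNGstate();
  long total_steps = (long)dememorization + (long)batches * (long)iterations;
  NumericVector batch_means(batches);
  int cur_batch = -1;
  double batch_acc = 0.0;

  for (long step = 0; step < total_steps; ++step) {
    // two distinct slots, uniformly
    int s1 = (int)(unif_rand() * n2); if (s1 == n2) s1 = n2 - 1;
    int s2 = (int)(unif_rand() * (n2 - 1)); if (s2 == n2 - 1) s2 = n2 - 2;
    if (s2 >= s1) s2 += 1;
    int i1 = s1 / 2, i2 = s2 / 2;
    if (i1 != i2 && slot[s1] != slot[s2]) {
      // genotypes change: update counts and the statistic
      int a1 = slot[2 * i1], b1 = slot[2 * i1 + 1];
      int a2 = slot[2 * i2], b2 = slot[2 * i2 + 1];
      int v1 = slot[s1], v2 = slot[s2];
      // remove old cells, add new cells; dT = dH*log2 + log(removed counts)
      // - log(added counts), accumulated sequentially so coincident cells
      // are handled exactly
      double dT = 0.0;
      int c_old1 = cell(a1, b1, k), c_old2 = cell(a2, b2, k);
      dT += log(counts[c_old1]); counts[c_old1] -= 1.0;
      dT += log(counts[c_old2]); counts[c_old2] -= 1.0;
      slot[s1] = v2; slot[s2] = v1;
      int na1 = slot[2 * i1], nb1 = slot[2 * i1 + 1];
      int na2 = slot[2 * i2], nb2 = slot[2 * i2 + 1];
      int c_new1 = cell(na1, nb1, k), c_new2 = cell(na2, nb2, k);
      counts[c_new1] += 1.0; dT -= log(counts[c_new1]);
      counts[c_new2] += 1.0; dT -= log(counts[c_new2]);
      int dh = (na1 != nb1) + (na2 != nb2) - (a1 != b1) - (a2 != b2);
      T += dT + dh * M_LN2;
    }
    // (same-individual or equal-allele swaps leave the array unchanged)

    if (step >= dememorization) {
      long s = step - dememorization;
      int b = (int)(s / iterations);
      if (b != cur_batch) {
        if (cur_batch >= 0) batch_means[cur_batch] = batch_acc / iterations;
        cur_batch = b; batch_acc = 0.0;
      }
      if (T <= T0 + tol) batch_acc += 1.0;
    }
  }
  if (cur_batch >= 0) batch_means[cur_batch] = batch_acc / iterations;
  PutRNGstate();

  double p_hat = mean(batch_means);
  double se = batches > 1 ? sd(batch_means) / sqrt((double)batches) : NA_REAL;
  return List::create(_["p_value"] = p_hat, _["mc_se"] = se,
                      _["batch_means"] = batch_means);
}
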