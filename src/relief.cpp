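#include <Rcpp.h>
using namespace Rcpp;

// Genotype mismatch distance between samples: count of differing
// non-missing genotypes divided by the count of jointly non-missing SNPs.
// NA_REAL when a pair shares no non-missing SNP.
// Works on a transposed (p x n) copy so each sample is contiguous.
static NumericMatrix mismatch_dist(const std::vector<int>& gt, int n, int p) {
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    const int* gi = gt.data() + (size_t)i * p;
    for (int j = i + 1; j < n; ++j) {
      const int* gj = gt.data() + (size_t)j * p;
      int diff = 0, obs = 0;
      for (int a = 0; a < p; ++a) {
        if (gi[a] == NA_INTEGER || gj[a] == NA_INTEGER) continue;
        ++obs;
        diff += gi[a] != gj[a];
      }
      double v = obs > 0 ? (double)diff / obs : NA_REAL;
      d(i, j) = v;
      d(j, i) = v;
    }
  }
  return d;
}

static std::vector<int> transpose_geno(const IntegerMatrix& g) {
  const int n = g.nrow(), p = g.ncol();
  std::vector<int> gt((size_t)n * p);
  for (int a = 0; a < p; ++a)
    for (int i = 0; i < n; ++i) gt[(size_t)i * p + a] = g(i, a);
  return gt;
}

// [[Rcpp::export]]
NumericMatrix cpp_pairwise_dist(IntegerMatrix g) {
  return mismatch_dist(transpose_geno(g), g.nrow(), g.ncol());
}

// Accumulate per-feature value differences between target gi and every
// member of `grp`, into `acc`. Missing values contribute 0 (no evidence).
static void group_sums(const std::vector<int>& gt, const int* gi, int p,
                       const std::vector<int>& grp, bool continuous,
                       std::vector<double>& acc) {
  std::fill(acc.begin(), acc.end(), 0.0);
  for (int j : grp) {
    const int* gj = gt.data() + (size_t)j * p;
    if (continuous) {
      for (int a = 0; a < p; ++a) {
        if (gi[a] == NA_INTEGER || gj[a] == NA_INTEGER) continue;
        acc[a] += std::abs(gi[a] - gj[a]) / 2.0;
      }
    } else {
      for (int a = 0; a < p; ++a) {
        if (gi[a] == NA_INTEGER || gj[a] == NA_INTEGER) continue;
        acc[a] += gi[a] != gj[a];
      }
    }
  }
}

// MultiSURF / MultiSURF* feature scoring. Per target instance i the
// distance distribution to all other instances defines adaptive
// thresholds: near if d < mu_i - sd_i/2, far if d > mu_i + sd_i/2
// (population sd). Near misses increment and near hits decrement a
// feature's score when its values differ; with star=true far pairs also
// contribute with inverted sign (far hits increment, far misses
// decrement). Each group's contribution is averaged within the group,
// summed over targets, and divided by n (MultiSURF) or 2n (MultiSURF*),
// bounding scores to [-1, 1].
// Mean with long-double accumulation and a correction pass, mirroring R's
// mean() so that threshold comparisons agree bitwise with an R reference.
static double r_mean(const std::vector<double>& x) {
  long double s = 0.0L;
  for (double v : x) s += v;
  s /= (long double)x.size();
  long double t = 0.0L;
  for (double v : x) t += (v - s);
  return (double)(s + t / (long double)x.size());
}

// [[Rcpp::export]]
NumericVector cpp_relief_scores(IntegerMatrix g, IntegerVector y, bool star,
                                bool continuous) {
  const int n = g.nrow(), p = g.ncol();
  std::vector<int> gt = transpose_geno(g);
  NumericMatrix d = mismatch_dist(gt, n, p);
  std::vector<double> total(p, 0.0), acc(p), dv, dev2;
  std::vector<int> nearH, nearM, farH, farM;

  for (int i = 0; i < n; ++i) {
    dv.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i || NumericVector::is_na(d(i, j))) continue;
      dv.push_back(d(i, j));
    }
    if (dv.empty()) continue;
    double mu = r_mean(dv);
    dev2.clear();
    for (double v : dv) dev2.push_back((v - mu) * (v - mu));
    double sd = std::sqrt(r_mean(dev2));
    double lo = mu - sd / 2.0, hi = mu + sd / 2.0;

    nearH.clear(); nearM.clear(); farH.clear(); farM.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i || NumericVector::is_na(d(i, j))) continue;
      bool hit = y[j] == y[i];
      if (d(i, j) < lo) (hit ? nearH : nearM).push_back(j);
      else if (star && d(i, j) > hi) (hit ? farH : farM).push_back(j);
    }

    const int* gi = gt.data() + (size_t)i * p;
    if (!nearM.empty()) {
      group_sums(gt, gi, p, nearM, continuous, acc);
      for (int a = 0; a < p; ++a) total[a] += acc[a] / nearM.size();
    }
    if (!nearH.empty()) {
      group_sums(gt, gi, p, nearH, continuous, acc);
      for (int a = 0; a < p; ++a) total[a] -= acc[a] / nearH.size();
    }
    if (star) {
      if (!farH.empty()) {
        group_sums(gt, gi, p, farH, continuous, acc);
        for (int a = 0; a < p; ++a) total[a] += acc[a] / farH.size();
      }
      if (!farM.empty()) {
        group_sums(gt, gi, p, farM, continuous, acc);
        for (int a = 0; a < p; ++a) total[a] -= acc[a] / farM.size();
      }
    }
  }
  double denom = star ? 2.0 * n : (double)n;
  NumericVector out(p);
  for (int a = 0; a < p; ++a) out[a] = total[a] / denom;
  return out;
}
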