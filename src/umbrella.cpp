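#include <Rcpp.h>
using namespace Rcpp;

// Mann-Whitney concordance counts for the k cyclically adjacent phase-group
// pairs.  For adjacent pair j (groups j and (j+1) mod k):
//   ufwd[j] = #{(a in g_j, b in g_j+1) : b > a}, ties[j] = #{b == a}.
static void adjacent_counts(const std::vector<std::vector<double> > &groups,
                            std::vector<double> &ufwd,
                            std::vector<double> &ties,
                            std::vector<double> &npair) {
  const int k = groups.size();
  for (int j = 0; j < k; ++j) {
    const std::vector<double> &g1 = groups[j];
    const std::vector<double> &g2 = groups[(j + 1) % k];
    double u = 0.0, t = 0.0;
    for (size_t a = 0; a < g1.size(); ++a)
      for (size_t b = 0; b < g2.size(); ++b) {
        if (g2[b] > g1[a]) u += 1.0;
        else if (g2[b] == g1[a]) t += 1.0;
      }
    ufwd[j] = u; ties[j] = t;
    npair[j] = (double)(g1.size() * g2.size());
  }
}

// Umbrella statistic for one candidate peak given the adjacency counts.
// dir(j) = +1 when the later group of adjacent pair j is expected larger
// (rising limb), -1 when smaller (falling limb), 0 when the two phases are
// equidistant from the peak (pair contributes half its pair count).
static double stat_for_dir(const std::vector<double> &ufwd,
                           const std::vector<double> &ties,
                           const std::vector<double> &npair,
                           const IntegerVector &dir) {
  double s = 0.0;
  for (int j = 0; j < (int)ufwd.size(); ++j) {
    if (dir[j] > 0)      s += ufwd[j] + 0.5 * ties[j];
    else if (dir[j] < 0) s += (npair[j] - ufwd[j] - ties[j]) + 0.5 * ties[j];
    else                 s += 0.5 * npair[j];
  }
  return s;
}

// [[Rcpp::export]]
NumericVector umbrella_stats_cpp(NumericVector value, IntegerVector group,
                                 int k, IntegerMatrix dirs) {
  std::vector<std::vector<double> > groups(k);
  for (int i = 0; i < value.size(); ++i) groups[group[i]].push_back(value[i]);
  std::vector<double> ufwd(k), ties(k), npair(k);
  adjacent_counts(groups, ufwd, ties, npair);
  const int P = dirs.nrow();
  NumericVector out(P);
  for (int p = 0; p < P; ++p) {
    IntegerVector dir = dirs(p, _);
    out[p] = stat_for_dir(ufwd, ties, npair, dir);
  }
  return out;
}

// Permutation test: blocks (timepoints with their replicates) are reassigned
// to time-of-day slots; the max-over-peak-phases statistic is recomputed for
// each permutation.  Uses R's RNG so results respect set.seed().
//
// value: observations; block: 0-based block index per observation;
// tod_of_block: 0-based phase group of each block (in original order);
// dirs: candidate-peaks x k orientation matrix.
// [[Rcpp::export]]
List umbrella_perm_test(NumericVector value, IntegerVector block,
                        IntegerVector tod_of_block, int k,
                        IntegerMatrix dirs, int n_perm) {
  const int n = value.size();
  const int B = tod_of_block.size();
  const int P = dirs.nrow();

  std::vector<std::vector<double> > groups(k);
  std::vector<double> ufwd(k), ties(k), npair(k);

  // observed
  for (int i = 0; i < n; ++i) groups[tod_of_block[block[i]]].push_back(value[i]);
  adjacent_counts(groups, ufwd, ties, npair);
  NumericVector obs(P);
  double obs_max = R_NegInf;
  int best_phase = 0;
  for (int p = 0; p < P; ++p) {
    obs[p] = stat_for_dir(ufwd, ties, npair, dirs(p, _));
    if (obs[p] > obs_max) { obs_max = obs[p]; best_phase = p; }
  }

  int n_ge = 0;
  IntegerVector perm(B);
  for (int it = 0; it < n_perm; ++it) {
    // random permutation of blocks via R RNG
    IntegerVector idx = sample(B, B, false); // 1..B
    for (int b = 0; b < B; ++b) perm[b] = tod_of_block[idx[b] - 1];
    for (int g = 0; g < k; ++g) groups[g].clear();
    for (int i = 0; i < n; ++i) groups[perm[block[i]]].push_back(value[i]);
    adjacent_counts(groups, ufwd, ties, npair);
    double mx = R_NegInf;
    for (int p = 0; p < P; ++p) {
      double s = stat_for_dir(ufwd, ties, npair, dirs(p, _));
      if (s > mx) mx = s;
    }
    if (mx >= obs_max) ++n_ge;
  }

  double pval = (1.0 + n_ge) / (double)(n_perm + 1);
  double max_stat = 0.0;
  for (int j = 0; j < k; ++j) max_stat += npair[j];
  return List::create(_["statistic"] = obs_max, _["per_phase"] = obs,
                      _["best_phase_index"] = best_phase + 1,
                      _["p_value"] = pval, _["n_ge"] = n_ge,
                      _["max_statistic"] = max_stat);
}
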