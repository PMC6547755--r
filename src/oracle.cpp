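// Monte Carlo oracle for the well-mixed expected payoffs.
//
// Deliberately naive: it builds the explicit population, samples the
// N - 1 co-members of a focal individual without replacement, simulates
// every exclusion attempt (including, asynchronously, a random excluder
// ordering with attempt-by-attempt costs), and realizes the focal payoff.
// It shares no code with the analytic hypergeometric expectations and
// serves as their independent cross-check.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_mc_payoff(int X, int Y, int Z, int W, int focal, int N,
                   double r, double sigma, double beta, double cE,
                   bool async, int nsim) {
  // focal: 0 = C, 1 = D, 2 = L, 3 = E; focal strategy must be present
  int counts[4] = {X, Y, Z, W};
  if (counts[focal] < 1) stop("focal strategy absent from the state");
  int M = X + Y + Z + W;
  if (N < 2 || N > M) stop("need 2 <= N <= M");

  // population array with one focal individual removed
  std::vector<int> pop;
  pop.reserve(M - 1);
  for (int s = 0; s < 4; ++s) {
    int c = counts[s] - (s == focal ? 1 : 0);
    for (int i = 0; i < c; ++i) pop.push_back(s);
  }

  double sum = 0.0, sumsq = 0.0;
  std::vector<int> member(N - 1);
  for (int it = 0; it < nsim; ++it) {
    // partial Fisher-Yates draw of N - 1 co-members without replacement
    for (int d = 0; d < N - 1; ++d) {
      int t = d + (int)(unif_rand() * (pop.size() - d));
      if (t >= (int)pop.size()) t = pop.size() - 1;
      std::swap(pop[d], pop[t]);
      member[d] = pop[d];
    }
    int k = 0, j = 0, l = 0, i_coop = 0;
    for (int d = 0; d < N - 1; ++d) {
      switch (member[d]) {
        case 0: ++i_coop; break;
        case 1: ++j; break;
        case 2: ++k; break;
        default: ++l; break;
      }
    }
    double pay;
    if (focal == 2) {
      pay = sigma;                       // loner
    } else if (k == N - 1) {
      pay = sigma;                       // every co-member is a loner
    } else {
      int nExcl = l + (focal == 3 ? 1 : 0);
      int nDef = j + (focal == 1 ? 1 : 0);
      int contributors = i_coop + l + (focal == 0 || focal == 3 ? 1 : 0);
      // exclusion: focal position 0 (if excluder/defector), others 1..
      double myCost = 0.0;
      int survivors = 0;
      bool focalExcluded = false;
      if (nExcl > 0 && nDef > 0) {
        if (!async) {
          for (int d = 0; d < nDef; ++d) {
            bool out = false;
            for (int e = 0; e < nExcl; ++e) {
              if (focal == 3 && e == 0) myCost += cE;
              if (unif_rand() < beta) out = true;
            }
            if (out) { if (focal == 1 && d == 0) focalExcluded = true; }
            else ++survivors;
          }
        } else {
          // random order of all excluders; focal (if excluder) is slot 0
          std::vector<int> ord(nExcl);
          for (int e = 0; e < nExcl; ++e) ord[e] = e;
          for (int e = nExcl - 1; e > 0; --e) {
            int t = (int)(unif_rand() * (e + 1));
            if (t > e) t = e;
            std::swap(ord[e], ord[t]);
          }
          for (int d = 0; d < nDef; ++d) {
            bool out = false;
            for (int e = 0; e < nExcl; ++e) {
              if (focal == 3 && ord[e] == 0) myCost += cE;
              if (unif_rand() < beta) { out = true; break; }
            }
            if (out) { if (focal == 1 && d == 0) focalExcluded = true; }
            else ++survivors;
          }
        }
      } else {
        survivors = nDef;
      }
      int pool = contributors + survivors;
      double share = (contributors > 0 && pool > 0)
                       ? r * contributors / pool : 0.0;
      switch (focal) {
        case 0: pay = share - 1.0; break;
        case 1: pay = focalExcluded ? 0.0 : share; break;
        default: pay = share - 1.0 - myCost; break;  // excluder
      }
    }
    sum += pay;
    sumsq += pay * pay;
  }
  double mean = sum / nsim;
  double var = (sumsq - nsim * mean * mean) / (nsim - 1.0);
  if (var < 0) var = 0;
  return List::create(_["mean"] = mean,
                      _["se"] = std::sqrt(var / nsim));
}
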