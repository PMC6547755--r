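// Agent-based optional PGG with exclusion on a periodic square lattice.
//
// Strategies are encoded 0 = C, 1 = D, 2 = L, 3 = E.  Every cell plays a
// five-member game in each of the five groups it belongs to (the group
// centred on itself and the four centred on its von Neumann neighbours).
// All randomness comes from R's RNG, so set.seed() in R makes every run
// bit-for-bit reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int SC = 0, SD = 1, SL = 2, SE = 3;

struct GameParams {
  double r, sigma, beta, cE, tau;
  bool async;       // exclusion mechanism
  bool expected;    // payoff_mode: expected instead of stochastic
};

// indices of a cell's von Neumann neighbourhood with periodic wraparound
static inline void group_members(int cell, int L, int *m) {
  int x = cell % L, y = cell / L;
  m[0] = cell;
  m[1] = x + L * ((y + L - 1) % L);  // up
  m[2] = x + L * ((y + 1) % L);      // down
  m[3] = (x + L - 1) % L + L * y;    // left
  m[4] = (x + 1) % L + L * y;        // right
}

static inline double binom_pmf(int s, int n, double p) {
  double out = R::dbinom((double)s, (double)n, p, 0);
  return out;
}

// expected sequential unit cost with l co-excluders (per defector)
static inline double cR(double beta, int l, double cE) {
  if (beta <= 0.0 || l == 0) return cE;
  return (1.0 - std::pow(1.0 - beta, l + 1)) / ((l + 1) * beta) * cE;
}

// Resolve one group game and write the five members' payoffs into pay[].
// strat[5] holds the members' strategies.  In stochastic mode the exclusion
// outcome (and, asynchronously, the excluder ordering) is freshly realized.
static void group_game(const int *strat, const GameParams &gp, double *pay) {
  int idxE[5], idxD[5];
  int nE = 0, nD = 0, nC = 0, nL = 0;
  for (int m = 0; m < 5; ++m) {
    switch (strat[m]) {
      case SC: ++nC; break;
      case SD: idxD[nD++] = m; break;
      case SL: ++nL; break;
      default: idxE[nE++] = m; break;
    }
  }
  int participants = 5 - nL;
  for (int m = 0; m < 5; ++m) pay[m] = 0.0;
  // loners always earn sigma; a lone participant cannot play and gets sigma
  if (participants <= 1) {
    for (int m = 0; m < 5; ++m) pay[m] = gp.sigma;
    return;
  }
  for (int m = 0; m < 5; ++m) if (strat[m] == SL) pay[m] = gp.sigma;

  int contributors = nC + nE;

  if (!gp.expected) {
    // realized exclusion
    double cost[5] = {0, 0, 0, 0, 0};
    bool excluded[5] = {false, false, false, false, false};
    if (nE > 0 && nD > 0) {
      if (!gp.async) {
        // simultaneous: every excluder attempts (and pays for) every defector
        for (int d = 0; d < nD; ++d)
          for (int e = 0; e < nE; ++e) {
            cost[idxE[e]] += gp.cE;
            if (unif_rand() < gp.beta) excluded[idxD[d]] = true;
          }
      } else {
        // sequential: random excluder order, stop paying once expelled
        int ord[5];
        for (int e = 0; e < nE; ++e) ord[e] = idxE[e];
        for (int e = nE - 1; e > 0; --e) {
          int t = (int)(unif_rand() * (e + 1));
          if (t > e) t = e;
          int tmp = ord[e]; ord[e] = ord[t]; ord[t] = tmp;
        }
        for (int d = 0; d < nD; ++d)
          for (int e = 0; e < nE; ++e) {
            cost[ord[e]] += gp.cE;
            if (unif_rand() < gp.beta) { excluded[idxD[d]] = true; break; }
          }
      }
    }
    int survivors = 0;
    for (int d = 0; d < nD; ++d) if (!excluded[idxD[d]]) ++survivors;
    int pool = contributors + survivors;
    double share = (pool > 0 && contributors > 0)
                     ? gp.r * contributors / pool : 0.0;
    for (int m = 0; m < 5; ++m) {
      switch (strat[m]) {
        case SC: pay[m] = share - 1.0; break;
        case SE: pay[m] = share - 1.0 - cost[m]; break;
        case SD: pay[m] = excluded[m] ? 0.0 : share; break;
        default: break;  // loner already paid
      }
    }
  } else {
    // expected-value accounting: exclusion outcomes replaced by their means
    double q = std::pow(1.0 - gp.beta, nE);  // defector survival probability
    // expected share of a contributor: E[r * nc / (nc + S)], S ~ Bin(nD, q)
    double shareC = 0.0;
    for (int s = 0; s <= nD; ++s)
      shareC += binom_pmf(s, nD, q) *
        (contributors > 0 ? gp.r * contributors / (contributors + s) : 0.0);
    double unit = gp.async ? cR(gp.beta, nE - 1, gp.cE) : gp.cE;
    // expected share of a surviving defector (its own survival factored in)
    double shareD = 0.0;
    for (int s = 0; s <= nD - 1; ++s)
      shareD += binom_pmf(s, nD - 1, q) *
        (contributors > 0 ? gp.r * contributors / (contributors + s + 1) : 0.0);
    shareD *= q;
    for (int m = 0; m < 5; ++m) {
      switch (strat[m]) {
        case SC: pay[m] = shareC - 1.0; break;
        case SE: pay[m] = shareC - 1.0 - unit * nD; break;
        case SD: pay[m] = shareD; break;
        default: break;
      }
    }
  }
}

// cumulative payoff of `cell` over the five groups it belongs to
static double accumulate(const IntegerVector &grid, int L, int cell,
                         const GameParams &gp) {
  int centers[5];
  group_members(cell, L, centers);
  double total = 0.0;
  int strat[5];
  double pay[5];
  int mem[5];
  for (int g = 0; g < 5; ++g) {
    group_members(centers[g], L, mem);
    int self = -1;
    for (int m = 0; m < 5; ++m) {
      strat[m] = grid[mem[m]];
      if (mem[m] == cell) self = m;
    }
    group_game(strat, gp, pay);
    total += pay[self];
  }
  return total;
}

static GameParams make_params(double r, double sigma, double beta, double cE,
                              double tau, bool async, bool expected) {
  GameParams gp;
  gp.r = r; gp.sigma = sigma; gp.beta = beta; gp.cE = cE; gp.tau = tau;
  gp.async = async; gp.expected = expected;
  return gp;
}

// [[Rcpp::export]]
NumericVector cpp_group_payoffs(IntegerVector grid, int L, int center,
                                double r, double sigma, double beta,
                                double cE, bool async, bool expected) {
  GameParams gp = make_params(r, sigma, beta, cE, 0.1, async, expected);
  int mem[5], strat[5];
  double pay[5];
  group_members(center - 1, L, mem);
  for (int m = 0; m < 5; ++m) strat[m] = grid[mem[m]];
  group_game(strat, gp, pay);
  NumericVector out(5);
  IntegerVector cells(5);
  for (int m = 0; m < 5; ++m) { out[m] = pay[m]; cells[m] = mem[m] + 1; }
  out.attr("cells") = cells;
  return out;
}

// [[Rcpp::export]]
List cpp_resolve_exclusion(int nExcluders, int nDefectors, double beta,
                           double cE, bool async) {
  NumericVector cost(nExcluders);
  LogicalVector excluded(nDefectors);
  if (nExcluders > 0 && nDefectors > 0) {
    if (!async) {
      for (int d = 0; d < nDefectors; ++d)
        for (int e = 0; e < nExcluders; ++e) {
          cost[e] += cE;
          if (unif_rand() < beta) excluded[d] = true;
        }
    } else {
      std::vector<int> ord(nExcluders);
      for (int e = 0; e < nExcluders; ++e) ord[e] = e;
      for (int e = nExcluders - 1; e > 0; --e) {
        int t = (int)(unif_rand() * (e + 1));
        if (t > e) t = e;
        std::swap(ord[e], ord[t]);
      }
      for (int d = 0; d < nDefectors; ++d)
        for (int e = 0; e < nExcluders; ++e) {
          cost[ord[e]] += cE;
          if (unif_rand() < beta) { excluded[d] = true; break; }
        }
    }
  }
  return List::create(_["excluded"] = excluded, _["costs"] = cost);
}

// [[Rcpp::export]]
double cpp_accumulate_payoff(IntegerVector grid, int L, int cell,
                             double r, double sigma, double beta, double cE,
                             bool async, bool expected) {
  GameParams gp = make_params(r, sigma, beta, cE, 0.1, async, expected);
  return accumulate(grid, L, cell - 1, gp);
}

// One elementary update: random cell i, random neighbour j; j adopts i's
// strategy with Fermi probability 1 / (1 + exp((pi_j - pi_i) / tau)).
// Returns the (1-based) index of the changed cell, or 0.
static int imitate_once(IntegerVector &grid, int L, const GameParams &gp) {
  int n = L * L;
  int i = (int)(unif_rand() * n); if (i >= n) i = n - 1;
  int mem[5];
  group_members(i, L, mem);
  int j = mem[1 + (int)(unif_rand() * 4)];
  // identical strategies: adoption is a no-op, skip the payoff evaluations
  if (grid[i] == grid[j]) return 0;
  double pi_i = accumulate(grid, L, i, gp);
  double pi_j = accumulate(grid, L, j, gp);
  double prob = 1.0 / (1.0 + std::exp((pi_j - pi_i) / gp.tau));
  if (unif_rand() < prob) { grid[j] = grid[i]; return j + 1; }
  return 0;
}

// [[Rcpp::export]]
List cpp_imitation_step(IntegerVector grid, int L, double r, double sigma,
                        double beta, double cE, double tau, bool async,
                        bool expected) {
  IntegerVector g = clone(grid);
  GameParams gp = make_params(r, sigma, beta, cE, tau, async, expected);
  int changed = imitate_once(g, L, gp);
  return List::create(_["grid"] = g, _["changed"] = changed);
}

// [[Rcpp::export]]
List cpp_run_lattice(IntegerVector grid0, int L, double r, double sigma,
                     double beta, double cE, double tau, bool async,
                     bool expected, int rounds, int updates_per_round,
                     IntegerVector snapshot_rounds) {
  IntegerVector grid = clone(grid0);
  GameParams gp = make_params(r, sigma, beta, cE, tau, async, expected);
  NumericMatrix freq(rounds, 4);
  int n = L * L;
  List snaps(snapshot_rounds.size());
  CharacterVector snap_names(snapshot_rounds.size());
  for (int t = 0; t < rounds; ++t) {
    for (int u = 0; u < updates_per_round; ++u) imitate_once(grid, L, gp);
    int cnt[4] = {0, 0, 0, 0};
    for (int c = 0; c < n; ++c) ++cnt[grid[c]];
    for (int s = 0; s < 4; ++s) freq(t, s) = (double)cnt[s] / n;
    for (int k = 0; k < snapshot_rounds.size(); ++k)
      if (snapshot_rounds[k] == t + 1) {
        IntegerMatrix snap(L, L);
        for (int c = 0; c < n; ++c) snap[c] = grid[c];
        snaps[k] = snap;
        snap_names[k] = std::to_string(t + 1);
      }
    if ((t & 63) == 0) Rcpp::checkUserInterrupt();
  }
  colnames(freq) = CharacterVector::create("C", "D", "L", "E");
  snaps.attr("names") = snap_names;
  return List::create(_["freq"] = freq, _["final_grid"] = grid,
                      _["snapshots"] = snaps);
}
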