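#' Lattice simulation parameters
#'
#' Settings of the agent-based Monte Carlo protocol: an `L x L` square
#' lattice with periodic boundaries and von Neumann neighbourhoods, Fermi
#' imitation with noise `tau`, a fixed budget of rounds (one round = one
#' Monte Carlo step = `updates_per_round` elementary updates), a terminal
#' averaging window and independent replicates.
#'
#' @param L Lattice side (default 100).
#' @param tau Fermi noise (selection temperature), default 0.1.
#' @param rounds Number of Monte Carlo steps (default 10000).
#' @param updates_per_round Elementary imitation updates per round
#'   (default `L^2`, so each cell updates once per round on average).
#' @param averaging_window Final rounds averaged for the stable frequencies
#'   (default 1000).
#' @param replicates Independent runs averaged in sweeps (default 20).
#' @param seed Master RNG seed.
#' @param payoff_mode `"stochastic"` (exclusion freshly realized at every
#'   payoff evaluation; the canonical mode) or `"expected"` (exclusion
#'   outcomes replaced by their means, for variance-reduction studies).
#' @return Object of class `lattice_params`.
#' @export
lattice_params <- function(L = 100, tau = 0.1, rounds = 10000,
                           updates_per_round = L^2,
                           averaging_window = 1000, replicates = 20,
                           seed = 1L,
                           payoff_mode = c("stochastic", "expected")) {
  payoff_mode <- match.arg(payoff_mode)
  stopifnot(L >= 4, L == round(L), tau > 0, rounds >= 1,
            updates_per_round >= 1, averaging_window >= 1,
            averaging_window <= rounds, replicates >= 1,
            is.numeric(seed) || is.integer(seed))
  structure(list(L = as.integer(L), tau = tau, rounds = as.integer(rounds),
                 updates_per_round = as.integer(updates_per_round),
                 averaging_window = as.integer(averaging_window),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), payoff_mode = payoff_mode),
            class = "lattice_params")
}

# replicate seeds derived from the master seed; documented splitting rule
replicate_seeds <- function(seed, replicates) {
  (as.integer(seed) + 7919L * (seq_len(replicates) - 1L)) %% .Machine$integer.max
}

#' Random initial lattice
#'
#' Each cell is assigned one of the four strategies independently and
#' uniformly at random.
#'
#' @param lp A [lattice_params()]; its `L` and `seed` are used.
#' @return Object of class `lattice_state`: integer `L x L` matrix with
#'   entries 0 = C, 1 = D, 2 = L, 3 = E.
#' @export
init_lattice <- function(lp) {
  set.seed(lp$seed)
  g <- matrix(sample.int(4L, lp$L^2, replace = TRUE) - 1L, lp$L, lp$L)
  structure(g, class = c("lattice_state", "matrix"))
}

lattice_codes <- c(C = 0L, D = 1L, L = 2L, E = 3L)

as_grid_vector <- function(grid) {
  g <- as.integer(grid)
  if (any(g < 0L | g > 3L)) stop("grid entries must be 0 (C), 1 (D), 2 (L) or 3 (E)")
  g
}

#' Payoffs of one five-member lattice group
#'
#' Resolves a single group game centred on `center`: loners take `sigma`, a
#' lone participant also takes `sigma`, contributors invest 1, exclusion is
#' realized under the chosen mechanism, and the pot `r *` (number of
#' contributors) is shared equally among the non-excluded participants.
#'
#' @param grid An `L x L` integer strategy matrix (0 = C, 1 = D, 2 = L,
#'   3 = E).
#' @param center Cell index (1-based, column-major) of the group centre.
#' @param params A [pgg_params()] (uses `r`, `sigma`, `beta`, `cE`,
#'   `mechanism`).
#' @param mode `"stochastic"` or `"expected"`.
#' @return Numeric vector of the five members' payoffs from this game, in
#'   order (centre, up, down, left, right), with attribute `cells` giving
#'   their indices.
#' @export
group_payoffs <- function(grid, center, params,
                          mode = c("stochastic", "expected")) {
  mode <- match.arg(mode)
  L <- nrow(grid)
  cpp_group_payoffs(as_grid_vector(grid), L, as.integer(center),
                    params$r, params$sigma, params$beta, params$cE,
                    params$mechanism == "asynchronous", mode == "expected")
}

#' Realize one exclusion round
#'
#' Simulates the exclusion attempts of `n_excluders` excluders against
#' `n_defectors` defectors.  Synchronously, every excluder attempts (and
#' pays the unit cost for) every defector; asynchronously, excluders act in
#' a uniformly random order and stop attempting a defector once it has been
#' expelled.
#'
#' @param n_excluders,n_defectors Nonnegative counts.
#' @param beta Per-attempt success probability.
#' @param cE Unit cost per attempt round.
#' @param mechanism `"synchronous"` or `"asynchronous"`.
#' @return List with `excluded` (logical per defector) and `costs` (numeric
#'   realized cost per excluder).
#' @export
resolve_exclusion <- function(n_excluders, n_defectors, beta, cE,
                              mechanism = c("synchronous", "asynchronous")) {
  mechanism <- match.arg(mechanism)
  stopifnot(n_excluders >= 0, n_defectors >= 0, beta >= 0, beta <= 1, cE >= 0)
  cpp_resolve_exclusion(as.integer(n_excluders), as.integer(n_defectors),
                        beta, cE, mechanism == "asynchronous")
}

#' Cumulative payoff of one lattice cell
#'
#' The sum of the cell's payoffs over the five groups it belongs to (the
#' group centred on itself and the four centred on its neighbours).  In
#' stochastic mode every group's exclusion is freshly realized.
#'
#' @inheritParams group_payoffs
#' @param cell Cell index (1-based, column-major).
#' @return Cumulative payoff.
#' @export
accumulate_payoff <- function(grid, cell, params,
                              mode = c("stochastic", "expected")) {
  mode <- match.arg(mode)
  cpp_accumulate_payoff(as_grid_vector(grid), nrow(grid), as.integer(cell),
                        params$r, params$sigma, params$beta, params$cE,
                        params$mechanism == "asynchronous", mode == "expected")
}

#' One Fermi imitation update
#'
#' Picks a uniformly random cell `i` and a uniformly random neighbour `j`;
#' `j` adopts `i`'s strategy with probability
#' `1 / (1 + exp((pi_j - pi_i) / tau))`, where the `pi` are freshly
#' evaluated cumulative payoffs.  At most one cell changes.
#'
#' @inheritParams group_payoffs
#' @param lp A [lattice_params()] (uses `tau` and `payoff_mode`).
#' @return List with the updated `grid` and `changed` (index of the changed
#'   cell, or 0).
#' @export
imitation_step <- function(grid, params, lp) {
  out <- cpp_imitation_step(as_grid_vector(grid), nrow(grid),
                            params$r, params$sigma, params$beta, params$cE,
                            lp$tau, params$mechanism == "asynchronous",
                            lp$payoff_mode == "expected")
  out$grid <- structure(matrix(out$grid, nrow(grid), ncol(grid)),
                        class = c("lattice_state", "matrix"))
  out
}

#' Run the lattice Monte Carlo simulation
#'
#' Initializes a random lattice and performs `rounds` Monte Carlo steps of
#' `updates_per_round` elementary Fermi updates each, recording the four
#' strategy frequencies after every round.  Stable frequencies are the
#' means over the final `averaging_window` rounds.  Fully reproducible from
#' the seed.
#'
#' @param params A [pgg_params()].
#' @param lp A [lattice_params()].
#' @param snapshot_at Integer vector of Monte Carlo steps at which to record
#'   the full grid (empty for none).
#' @param init Optional initial grid (a `lattice_state` or integer matrix);
#'   defaults to a fresh [init_lattice()] draw.
#' @return Object of class `lattice_trajectory`: list with `freq_series`
#'   (rounds x 4 matrix), `stable_freqs`, `snapshots`, `final_grid`, and the
#'   two parameter sets.
#' @export
run_simulation <- function(params, lp, snapshot_at = integer(0), init = NULL) {
  if (is.null(init)) {
    init <- init_lattice(lp)
  } else {
    stopifnot(nrow(init) == lp$L, ncol(init) == lp$L)
    set.seed(lp$seed)
  }
  res <- cpp_run_lattice(as_grid_vector(init), lp$L,
                         params$r, params$sigma, params$beta, params$cE,
                         lp$tau, params$mechanism == "asynchronous",
                         lp$payoff_mode == "expected",
                         lp$rounds, lp$updates_per_round,
                         as.integer(snapshot_at))
  win <- (lp$rounds - lp$averaging_window + 1L):lp$rounds
  stable <- colMeans(res$freq[win, , drop = FALSE])
  structure(list(freq_series = res$freq, stable_freqs = stable,
                 snapshots = res$snapshots,
                 final_grid = matrix(res$final_grid, lp$L, lp$L),
                 params = params, lattice_params = lp),
            class = "lattice_trajectory")
}

#' @export
print.lattice_trajectory <- function(x, ...) {
  lp <- x$lattice_params
  cat(sprintf("Lattice PGG run: %dx%d, %d rounds, %s exclusion\n",
              lp$L, lp$L, lp$rounds, x$params$mechanism))
  cat(sprintf("  stable frequencies (last %d rounds):\n", lp$averaging_window))
  print(round(x$stable_freqs, 4))
  invisible(x)
}

#' Replicated lattice runs
#'
#' Runs `lp$replicates` independent simulations with seeds derived from the
#' master seed by a fixed splitting rule (`seed + 7919 * (replicate - 1)`),
#' and averages the window-averaged stable frequencies.
#'
#' @inheritParams run_simulation
#' @return List with `stable` (replicate x 4 matrix), `mean`, `se` (standard
#'   error of the replicate mean) and the per-replicate seeds.
#' @export
run_replicates <- function(params, lp) {
  seeds <- replicate_seeds(lp$seed, lp$replicates)
  stable <- t(vapply(seeds, function(s) {
    lpr <- lp; lpr$seed <- s
    run_simulation(params, lpr)$stable_freqs
  }, numeric(4)))
  colnames(stable) <- c("C", "D", "L", "E")
  list(stable = stable,
       mean = colMeans(stable),
       se = apply(stable, 2, stats::sd) / sqrt(nrow(stable)),
       seeds = seeds)
}

#' Monte Carlo estimate of a well-mixed expected payoff
#'
#' Independent simulation oracle for the analytic payoff expectations:
#' samples the focal player's `N - 1` co-members without replacement from
#' the explicit population, simulates every exclusion attempt (with a
#' random excluder ordering and attempt-by-attempt costs in the
#' asynchronous mechanism), and realizes the focal payoff.
#'
#' @param state A [pgg_state()].
#' @param params A [pgg_params()].
#' @param strategy Focal strategy (must be present at `state`).
#' @param nsim Number of sampled groups.
#' @return List with `mean` and `se`.
#' @export
mc_payoff <- function(state, params, strategy, nsim = 1e6) {
  strategy <- match.arg(strategy, strategies)
  focal <- c(C = 0L, D = 1L, L = 2L, E = 3L)[[strategy]]
  cpp_mc_payoff(count_of(state, "C"), count_of(state, "D"),
                count_of(state, "L"), count_of(state, "E"),
                focal, params$N, params$r, params$sigma, params$beta,
                params$cE, params$mechanism == "asynchronous",
                as.integer(nsim))
}
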