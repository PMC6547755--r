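#' Game-level model parameters
#'
#' Bundles all constants of the optional public goods game (PGG) with
#' exclusion: the population size, the sampled group size, the investment
#' amplification factor, the loner payoff, the exclusion machinery and the
#' well-mixed dynamic's reaction/perturbation coefficients.
#'
#' The exclusion unit cost `cE` is derived once from `cost_fn(beta)` at
#' construction.  The default cost function, `0.2 * 10^beta`, is increasing
#' and convex in the exclusion success probability: more reliable exclusion
#' is disproportionately expensive.
#'
#' @param M Population size (integer >= 2).
#' @param N Group size sampled for one game (integer, 2 <= N <= M).
#' @param r Investment amplification factor; must satisfy 1 < r < N.
#' @param sigma Loner (non-participant) payoff, in payoff units.
#' @param beta Per-attempt exclusion success probability, in \[0, 1\].
#' @param kappa Reaction-speed coefficient of the transfer rate (>= 0).
#' @param epsilon Baseline transfer rate (> 0); keeps the well-mixed chain
#'   ergodic.
#' @param cost_fn Function mapping `beta` to the unit exclusion cost `cE`;
#'   must be nonnegative on \[0, 1\].
#' @param mechanism `"synchronous"` (all excluders pay the unit cost for
#'   every defector) or `"asynchronous"` (excluders act sequentially and
#'   stop paying for a defector once it has been expelled).
#' @param aggregation How per-capita transfer rates aggregate into
#'   state-level transition rates of the well-mixed chain.  `"type"` (the
#'   default): the rate of moving one individual from strategy `s1` to `s2`
#'   is the transfer rate itself whenever `s1` is present — the transfer
#'   rate acts at the level of strategy types, as a macroscopic transfer
#'   intensity.  `"count"`: the rate is multiplied by the number of `s1`
#'   individuals (density-dependent reading; individuals switch
#'   independently).  The two coincide up to time rescaling only on
#'   single-strategy boundaries; see the methods vignette for why `"type"`
#'   is the default.
#'
#' @return An object of class `pgg_params`: a list with fields `M`, `N`,
#'   `r`, `sigma`, `beta`, `kappa`, `epsilon`, `cE`, `cost_fn`,
#'   `mechanism`, `aggregation`.
#' @examples
#' p <- pgg_params(M = 20, N = 5, r = 3, sigma = 0.1, beta = 0.5)
#' p$cE  # 0.2 * 10^0.5
#' @export
pgg_params <- function(M = 20, N = 5, r = 3, sigma = 0.1, beta = 0.1,
                       kappa = 1, epsilon = 1e-3,
                       cost_fn = default_cost_fn,
                       mechanism = c("synchronous", "asynchronous"),
                       aggregation = c("type", "count")) {
  mechanism <- match.arg(mechanism)
  aggregation <- match.arg(aggregation)
  stopifnot(is.numeric(M), length(M) == 1L, M == round(M), M >= 2,
            is.numeric(N), length(N) == 1L, N == round(N), N >= 2, N <= M,
            is.numeric(r), length(r) == 1L,
            is.numeric(sigma), length(sigma) == 1L,
            is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1,
            is.numeric(kappa), length(kappa) == 1L, kappa >= 0,
            is.numeric(epsilon), length(epsilon) == 1L,
            is.function(cost_fn))
  if (!(r > 1 && r < N))
    stop("r must lie strictly between 1 and N (got r = ", r, ", N = ", N, ")")
  if (epsilon <= 0)
    stop("epsilon must be > 0: the baseline transfer rate keeps the chain ergodic")
  cE <- cost_fn(beta)
  if (!is.finite(cE) || cE < 0)
    stop("cost_fn(beta) must be finite and nonnegative, got ", cE)
  structure(
    list(M = as.integer(M), N = as.integer(N), r = r, sigma = sigma,
         beta = beta, kappa = kappa, epsilon = epsilon, cE = cE,
         cost_fn = cost_fn, mechanism = mechanism, aggregation = aggregation),
    class = "pgg_params")
}

#' Default exclusion cost function
#'
#' The unit exclusion cost as a function of the exclusion success
#' probability: `cE(beta) = 0.2 * 10^beta`.  Increasing and convex on
#' \[0, 1\], so reliable exclusion is disproportionately costly.
#'
#' @param beta Exclusion success probability.
#' @return Unit exclusion cost, in payoff units.
#' @export
default_cost_fn <- function(beta) 0.2 * 10^beta

#' @export
print.pgg_params <- function(x, ...) {
  cat("Optional PGG with exclusion - parameters\n")
  cat(sprintf("  M = %d, N = %d, r = %g, sigma = %g\n", x$M, x$N, x$r, x$sigma))
  cat(sprintf("  beta = %g, cE = %g, mechanism = %s\n", x$beta, x$cE, x$mechanism))
  cat(sprintf("  kappa = %g, epsilon = %g, aggregation = %s\n",
              x$kappa, x$epsilon, x$aggregation))
  invisible(x)
}

#' Well-mixed population state
#'
#' Counts of the four strategies in a finite well-mixed population:
#' cooperators `X`, defectors `Y`, loners `Z` and excluders `W`, with
#' `X + Y + Z + W = M`.
#'
#' @param X,Y,Z,W Nonnegative integer strategy counts.
#' @param M Population size the counts must sum to (defaults to their sum).
#' @return Named integer vector of class `pgg_state`.
#' @examples
#' pgg_state(5, 5, 5, 5)
#' @export
pgg_state <- function(X, Y, Z, W, M = X + Y + Z + W) {
  v <- c(X = X, Y = Y, Z = Z, W = W)
  if (any(v != round(v)) || any(v < 0))
    stop("strategy counts must be nonnegative integers")
  if (sum(v) != M)
    stop("strategy counts must sum to the population size M = ", M,
         " (got ", sum(v), ")")
  structure(as.integer(round(v)), names = names(v), class = "pgg_state")
}

strategies <- c("C", "D", "L", "E")

# map a strategy letter to the count slot of a pgg_state
count_of <- function(state, strategy) {
  slot <- c(C = 1L, D = 2L, L = 3L, E = 4L)[[strategy]]
  as.integer(state[[slot]])
}
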