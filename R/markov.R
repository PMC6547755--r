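# Ergodic Markov chain over well-mixed population states.
#
# Individuals switch strategies at per-capita rate
#   eps + kappa * max(payoff gain, 0);
# a state-level transition moves one individual from strategy s1 to s2, so
# its rate is count(s1) times the per-capita transfer rate.  With eps > 0
# every transition is possible and the chain is irreducible, hence has a
# unique stationary distribution; concentration of that distribution as
# eps shrinks identifies the stochastically stable states.

#' Per-capita transfer rate between two strategies
#'
#' `epsilon + kappa * max(pi_s2 - pi_s1, 0)`: strategies flow towards
#' higher-payoff alternatives at speed `kappa`, with a baseline exploration
#' rate `epsilon` keeping the chain ergodic.
#'
#' @param s1,s2 Source and target strategies (distinct, in `"C" "D" "L" "E"`).
#' @param profile Named payoff vector as returned by [payoff_profile()].
#' @param params A [pgg_params()].
#' @return Nonnegative rate, at least `epsilon`.
#' @export
transfer_rate <- function(s1, s2, profile, params) {
  s1 <- match.arg(s1, strategies); s2 <- match.arg(s2, strategies)
  if (s1 == s2) stop("transfer_rate needs two distinct strategies")
  params$epsilon + params$kappa * max(profile[[s2]] - profile[[s1]], 0)
}

#' Build the state-space generator matrix
#'
#' Enumerates all `choose(M + 3, 3)` population states and assembles the
#' sparse generator `Q`: for every ordered strategy pair `(s1, s2)` with
#' `count(s1) >= 1` there is a transition to the neighbouring state with
#' one individual moved.  Under the default `aggregation = "type"` the
#' transition rate is `transfer_rate(s1, s2)` itself (the transfer rate is
#' a macroscopic intensity between strategy types); under
#' `aggregation = "count"` it is `count(s1) * transfer_rate(s1, s2)`
#' (individuals switch independently).  Diagonal entries make rows sum to
#' zero.
#'
#' @param params A [pgg_params()].
#' @param basis Optional precomputed [payoff_basis()] (reused across sweeps).
#' @return Object of class `pgg_markov`: list with `states`, sparse `Q`,
#'   the payoff matrix and the parameter set.
#' @export
build_generator <- function(params, basis = NULL) {
  if (is.null(basis)) basis <- payoff_basis(params$M, params$N)
  S <- basis$states
  M <- params$M
  n <- nrow(S)
  P <- payoff_profiles_all(params, basis)
  index <- integer(max(basis$key) + 1L)
  index[basis$key + 1L] <- seq_len(n)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  cols <- c(C = 1L, D = 2L, L = 3L, E = 4L)
  for (a in 1:4) for (b in 1:4) {
    if (a == b) next
    from <- which(S[, a] >= 1L)
    if (!length(from)) next
    percap <- params$epsilon + params$kappa * pmax(P[from, b] - P[from, a], 0)
    rate <- if (identical(params$aggregation, "count"))
      S[from, a] * percap else percap
    Sn <- S[from, , drop = FALSE]
    Sn[, a] <- Sn[, a] - 1L
    Sn[, b] <- Sn[, b] + 1L
    to <- index[state_key(Sn[, 1], Sn[, 2], Sn[, 3], M) + 1L]
    ii <- c(ii, from); jj <- c(jj, to); xx <- c(xx, rate)
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::diag(Q) <- -Matrix::rowSums(Q)
  structure(list(states = S, Q = Q, payoffs = P, params = params),
            class = "pgg_markov")
}

#' @export
print.pgg_markov <- function(x, ...) {
  cat(sprintf("PGG well-mixed Markov chain: %d states (M = %d), %s exclusion\n",
              nrow(x$states), x$params$M, x$params$mechanism))
  invisible(x)
}

# membership masks for the stable-state classes
state_classes <- function(S) {
  M <- sum(S[1, ])
  allD <- S[, "Y"] == M
  allL <- (S[, "Z"] == M) |
    (S[, "Y"] == 1L & S[, "Z"] == M - 1L) |
    (S[, "W"] == 1L & S[, "Z"] == M - 1L)
  cpe <- S[, "Y"] == 0L & S[, "Z"] == 0L
  other <- !(allD | allL | cpe)
  cbind(AllD = allD, AllL = allL, CplusE = cpe, Other = other)
}

#' Stationary distribution of the population chain
#'
#' Solves `p' Q = 0`, `sum(p) = 1` by a sparse LU factorisation.  The
#' primary route pins one state's unnormalised probability to 1 and solves
#' the remaining `n - 1` equations (which preserves sparsity); if that
#' system is ill-conditioned the full system with one equation replaced by
#' the normalisation constraint is solved instead, and failing that, power
#' iteration on the uniformized transition matrix.  Also aggregates the
#' stationary mass into the
#' stable-state classes: `AllD` (all defectors), `AllL` (the three states
#' payoff-equivalent to all loners), `CplusE` (cooperators and excluders
#' only) and `Other`.
#'
#' @param model A `pgg_markov` from [build_generator()].
#' @return Object of class `pgg_stationary`: list with `probabilities`
#'   (per state, in [state_space()] order), `class_masses`, the residual
#'   `max |p'Q|` and the parameter set.
#' @export
stationary_distribution <- function(model) {
  stopifnot(inherits(model, "pgg_markov"))
  Q <- model$Q
  n <- nrow(Q)
  A <- Matrix::t(Q)
  check <- function(p) {
    if (is.null(p) || any(!is.finite(p)) || min(p) < -1e-8) return(NULL)
    p[p < 0] <- 0
    p / sum(p)
  }
  # reduced system: pin the last state's unnormalised mass to 1
  p <- tryCatch({
    x <- as.numeric(Matrix::solve(A[-n, -n], -A[-n, n]))
    c(x, 1)
  }, error = function(e) NULL)
  p <- check(p)
  if (!is.null(p)) {
    resid <- max(abs(as.numeric(Matrix::crossprod(Q, p))))
    if (resid > 1e-10) p <- NULL
  }
  if (is.null(p)) {
    # full system with the normalisation constraint in the last row
    A1 <- A
    A1[n, ] <- 1
    p <- tryCatch(as.numeric(Matrix::solve(A1, c(rep(0, n - 1L), 1))),
                  error = function(e) NULL)
    p <- check(p)
  }
  bad <- is.null(p)
  if (!bad) {
    resid <- max(abs(as.numeric(Matrix::crossprod(Q, p))))
    bad <- resid > 1e-8
  }
  if (bad) {
    # uniformization fallback: p P = p with P = I + Q / lambda
    lambda <- 1.05 * max(-Matrix::diag(Q))
    Pt <- Matrix::t(Matrix::Diagonal(n) + Q / lambda)
    p <- rep(1 / n, n)
    for (it in seq_len(200000L)) {
      p2 <- as.numeric(Pt %*% p)
      p2 <- p2 / sum(p2)
      if (max(abs(p2 - p)) < 1e-14) { p <- p2; break }
      p <- p2
    }
    resid <- max(abs(as.numeric(Matrix::crossprod(Q, p))))
    if (resid > 1e-8)
      stop(sprintf(
        "stationary solve failed (residual %.3e) for M=%d r=%g sigma=%g beta=%g eps=%g [%s]",
        resid, model$params$M, model$params$r, model$params$sigma,
        model$params$beta, model$params$epsilon, model$params$mechanism))
    p[p < 0] <- 0
    p <- p / sum(p)
  }
  cls <- state_classes(model$states)
  masses <- colSums(p * cls)
  structure(list(probabilities = p, class_masses = masses,
                 residual = resid, params = model$params),
            class = "pgg_stationary")
}

#' @export
print.pgg_stationary <- function(x, ...) {
  cat("Stationary distribution of the PGG population chain\n")
  cat(sprintf("  mechanism = %s, epsilon = %g, residual = %.2e\n",
              x$params$mechanism, x$params$epsilon, x$residual))
  print(round(x$class_masses, 4))
  invisible(x)
}

#' Operationally stochastically stable states
#'
#' Re-solves the chain along a strictly decreasing sequence of perturbation
#' rates `epsilon` and keeps the states whose stationary probability stays
#' above `threshold` throughout: as the exploration noise vanishes the
#' stationary mass concentrates on the stochastically stable states.  Class
#' masses are reported at the smallest `epsilon` ("limit probability").
#'
#' @param params A [pgg_params()]; its `epsilon` field is ignored here.
#' @param epsilons Strictly decreasing positive sequence.
#' @param threshold Probability floor for survival (default 1e-3).
#' @param basis Optional precomputed [payoff_basis()].
#' @return List with `states` (matrix of surviving states), their
#'   probabilities at the smallest epsilon, `class_masses`, and the epsilon
#'   sequence used.
#' @export
stable_states <- function(params, epsilons = c(1e-2, 1e-3, 1e-4),
                          threshold = 1e-3, basis = NULL) {
  stopifnot(all(epsilons > 0), all(diff(epsilons) < 0))
  if (is.null(basis)) basis <- payoff_basis(params$M, params$N)
  keep <- NULL
  last <- NULL
  prev_mass <- -Inf
  for (eps in epsilons) {
    pe <- params; pe$epsilon <- eps
    st <- stationary_distribution(build_generator(pe, basis))
    above <- st$probabilities > threshold
    keep <- if (is.null(keep)) above else keep & above
    mass <- sum(st$probabilities[above])
    if (mass < prev_mass - 1e-6)
      warning("stationary mass does not concentrate monotonically along the ",
              "epsilon sequence; reporting the smallest-epsilon result")
    prev_mass <- mass
    last <- st
  }
  list(states = basis$states[keep, , drop = FALSE],
       probabilities = last$probabilities[keep],
       class_masses = last$class_masses,
       epsilons = epsilons, threshold = threshold)
}

#' Cooperative-state probability gain of asynchronous exclusion
#'
#' The stationary probability mass on the cooperative `C + E` states
#' (compositions of cooperators and excluders only) under asynchronous
#' exclusion minus the same mass under synchronous exclusion, all other
#' parameters equal.  Positive values mean sequential exclusion promotes
#' cooperation more than simultaneous exclusion.
#'
#' @param params A [pgg_params()] (its `mechanism` field is overridden).
#' @param basis Optional precomputed [payoff_basis()].
#' @return Signed probability difference in \[-1, 1\].
#' @export
coop_probability_difference <- function(params, basis = NULL) {
  if (is.null(basis)) basis <- payoff_basis(params$M, params$N)
  mass <- function(mech) {
    p <- params; p$mechanism <- mech
    stationary_distribution(build_generator(p, basis))$class_masses[["CplusE"]]
  }
  mass("asynchronous") - mass("synchronous")
}
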