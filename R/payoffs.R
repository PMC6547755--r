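#' Defector survival probabilities under exclusion
#'
#' A defector facing `l` excluding co-members survives each independent
#' exclusion attempt with probability `1 - beta`.  `p1` is its survival
#' probability when the focal individual is not itself an excluder
#' (`(1 - beta)^l`); `p2` adds the focal excluder's own attempt
#' (`(1 - beta)^(l + 1)`).
#'
#' @param beta Per-attempt exclusion success probability in \[0, 1\].
#' @param l Number of excluding co-members (nonnegative integer).
#' @return Named numeric vector `c(p1, p2)`.
#' @examples
#' survival_probs(0.5, 2)  # c(p1 = 0.25, p2 = 0.125)
#' @export
survival_probs <- function(beta, l) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1,
            is.numeric(l), length(l) == 1L, l >= 0, l == round(l))
  c(p1 = (1 - beta)^l, p2 = (1 - beta)^(l + 1))
}

#' Expected unit exclusion cost under asynchronous (sequential) exclusion
#'
#' When excluders act in a uniformly random order and stop attempting a
#' defector once some excluder has expelled it, an excluder among `l + 1`
#' excluders in total pays, per defector, an expected cost
#' `cR = (1 - (1 - beta)^(l + 1)) / ((l + 1) * beta) * cE <= cE`.
#' At `beta = 0` the expression is 0/0; it is defined by its continuous
#' limit `cE` (no attempt ever succeeds, every excluder pays once per
#' defector).
#'
#' @param beta Per-attempt exclusion success probability in \[0, 1\].
#' @param l Number of co-excluders besides the focal one (so `l + 1`
#'   excluders act in total).
#' @param cE Unit exclusion cost of a single attempt round.
#' @return Expected unit cost `cR`, never exceeding `cE`.
#' @examples
#' async_unit_cost(0.5, 1, 1)  # 0.75
#' @export
async_unit_cost <- function(beta, l, cE) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1,
            is.numeric(l), length(l) == 1L, l >= 0, l == round(l),
            is.numeric(cE), length(cE) == 1L)
  if (cE < 0) stop("cE must be nonnegative")
  # beta = 0 by continuity; l = 0 reduces to cE algebraically -- return it
  # exactly rather than through the (numerically 1-ulp-off) quotient
  if (beta == 0 || l == 0) return(cE)
  (1 - (1 - beta)^(l + 1)) / ((l + 1) * beta) * cE
}

# log binomial coefficient that is exactly -Inf outside the support
# (R's lchoose() continues analytically for negative n, which we never want
# when counting group compositions)
lchoose0 <- function(n, k) {
  out <- lchoose(n, k)
  out[k < 0 | k > n] <- -Inf
  out
}

choose0 <- function(n, k) exp(lchoose0(n, k))

# binomial pmf over the number of surviving defectors
surv_pmf <- function(j, p) {
  if (j == 0) return(1)
  stats::dbinom(0:j, size = j, prob = p)
}

#' Expected payoff of a cooperator in the well-mixed population
#'
#' Exact expectation over hypergeometric sampling of the focal cooperator's
#' `N - 1` co-members from the remaining `M - 1` individuals and binomial
#' survival of each group defector against the group's excluders.  Three
#' terms: groups with at least one excluder, excluder-free groups, and the
#' all-loner group in which the focal player falls back to the loner payoff
#' `sigma`.  Identical under both exclusion mechanisms.
#'
#' @param state A [pgg_state()] with at least one cooperator.
#' @param params A [pgg_params()].
#' @return Expected payoff (payoff units).
#' @export
payoff_C <- function(state, params) {
  X <- count_of(state, "C"); Y <- count_of(state, "D")
  Z <- count_of(state, "L"); W <- count_of(state, "E")
  if (X < 1) stop("payoff_C needs X >= 1; use degenerate_payoff for absent strategies")
  M <- params$M; N <- params$N; r <- params$r; beta <- params$beta
  ldenom <- lchoose0(M - 1, N - 1)
  total <- 0
  # groups containing l >= 1 excluders
  for (l in seq_len(N - 1)) {
    p1 <- (1 - beta)^l
    for (k in 0:(N - 1 - l)) {
      for (j in 0:(N - 1 - l - k)) {
        lw <- lchoose0(W, l) + lchoose0(Z, k) + lchoose0(Y, j) +
          lchoose0(X - 1, N - 1 - l - k - j) - ldenom
        if (lw == -Inf) next
        pmf <- surv_pmf(j, p1)
        val <- sum(pmf * (r * (N - k - j) / (N - k - j + 0:j) - 1))
        total <- total + exp(lw) * val
      }
    }
  }
  # excluder-free groups with at least one non-loner co-member
  for (k in 0:(N - 2)) {
    for (j in 0:(N - 1 - k)) {
      lw <- lchoose0(Z, k) + lchoose0(Y, j) +
        lchoose0(X - 1, N - 1 - k - j) - ldenom
      if (lw == -Inf) next
      total <- total + exp(lw) * (r * (N - k - j) / (N - k) - 1)
    }
  }
  # all co-members are loners: game does not take place, focal gets sigma
  total + exp(lchoose0(Z, N - 1) - ldenom) * params$sigma
}

#' Expected payoff of a defector in the well-mixed population
#'
#' As [payoff_C()] but for a focal defector: it contributes nothing, earns a
#' share of the pot only if it survives all `l` excluders in its group
#' (probability `p1 = (1 - beta)^l`), and falls back to `sigma` when all
#' co-members are loners.  Identical under both exclusion mechanisms.
#'
#' @inheritParams payoff_C
#' @return Expected payoff (payoff units).
#' @export
payoff_D <- function(state, params) {
  X <- count_of(state, "C"); Y <- count_of(state, "D")
  Z <- count_of(state, "L"); W <- count_of(state, "E")
  if (Y < 1) stop("payoff_D needs Y >= 1; use degenerate_payoff for absent strategies")
  M <- params$M; N <- params$N; r <- params$r; beta <- params$beta
  ldenom <- lchoose0(M - 1, N - 1)
  total <- 0
  for (l in seq_len(N - 1)) {
    p1 <- (1 - beta)^l
    for (k in 0:(N - 1 - l)) {
      for (j in 0:(N - 1 - l - k)) {
        lw <- lchoose0(W, l) + lchoose0(Z, k) + lchoose0(Y - 1, j) +
          lchoose0(X, N - 1 - l - k - j) - ldenom
        if (lw == -Inf) next
        pmf <- surv_pmf(j, p1)
        val <- p1 * sum(pmf * (r * (N - k - j - 1) / (N - k - j + 0:j)))
        total <- total + exp(lw) * val
      }
    }
  }
  for (k in 0:(N - 2)) {
    for (j in 0:(N - 1 - k)) {
      lw <- lchoose0(Z, k) + lchoose0(Y - 1, j) +
        lchoose0(X, N - 1 - k - j) - ldenom
      if (lw == -Inf) next
      total <- total + exp(lw) * (r * (N - k - j - 1) / (N - k))
    }
  }
  total + exp(lchoose0(Z, N - 1) - ldenom) * params$sigma
}

#' Expected payoff of a loner
#'
#' Loners do not take part in the game and receive the fixed payoff
#' `sigma` whatever the population composition.
#'
#' @inheritParams payoff_C
#' @return `sigma`.
#' @export
payoff_L <- function(state, params) {
  if (count_of(state, "L") < 1)
    stop("payoff_L needs Z >= 1; use degenerate_payoff for absent strategies")
  params$sigma
}

#' Expected payoff of an excluder in the well-mixed population
#'
#' The focal excluder invests like a cooperator, and in addition attempts to
#' expel each defector in its group.  Each group defector survives the
#' `l + 1` excluders (the `l` sampled co-excluders plus the focal one) with
#' probability `p2 = (1 - beta)^(l + 1)`.  Under synchronous exclusion the
#' focal excluder pays the unit cost `cE` for every defector in the group;
#' under asynchronous exclusion it pays the expected sequential unit cost
#' `cR(beta, l, cE)` (see [async_unit_cost()]).  A correction term replaces
#' the all-loner group's nominal `r - 1` payoff by `sigma`: with no
#' participating co-members the game does not take place.
#'
#' @inheritParams payoff_C
#' @return Expected payoff (payoff units).
#' @export
payoff_E <- function(state, params) {
  X <- count_of(state, "C"); Y <- count_of(state, "D")
  Z <- count_of(state, "L"); W <- count_of(state, "E")
  if (W < 1) stop("payoff_E needs W >= 1; use degenerate_payoff for absent strategies")
  M <- params$M; N <- params$N; r <- params$r; beta <- params$beta
  ldenom <- lchoose0(M - 1, N - 1)
  total <- 0
  for (l in 0:(N - 1)) {
    p2 <- (1 - beta)^(l + 1)
    unit_cost <- if (params$mechanism == "synchronous") params$cE
                 else async_unit_cost(beta, l, params$cE)
    for (k in 0:(N - 1 - l)) {
      for (j in 0:(N - 1 - l - k)) {
        lw <- lchoose0(W - 1, l) + lchoose0(Z, k) + lchoose0(Y, j) +
          lchoose0(X, N - 1 - l - k - j) - ldenom
        if (lw == -Inf) next
        pmf <- surv_pmf(j, p2)
        val <- sum(pmf * (r * (N - k - j) / (N - k - j + 0:j) - 1 - unit_cost * j))
        total <- total + exp(lw) * val
      }
    }
  }
  # all-loner groups: the l = 0, k = N - 1 term above counted r - 1, but the
  # game does not take place; replace it by sigma
  ploner <- exp(lchoose0(Z, N - 1) - ldenom)
  total - ploner * (r - 1) + ploner * params$sigma
}

#' Payoff of an absent strategy: population-average fallback
#'
#' When a strategy has count zero its expected payoff is undefined; the
#' dynamic assigns it the count-weighted mean payoff of the strategies that
#' are present (each computed by its own payoff function).
#'
#' @inheritParams payoff_C
#' @param strategy One of `"C"`, `"D"`, `"L"`, `"E"`; must be absent at
#'   `state`.
#' @return The population-average payoff.
#' @export
degenerate_payoff <- function(state, params, strategy) {
  strategy <- match.arg(strategy, strategies)
  if (count_of(state, strategy) != 0)
    stop("degenerate_payoff is only defined for strategies absent at the state")
  counts <- as.integer(state)
  fns <- list(C = payoff_C, D = payoff_D, L = payoff_L, E = payoff_E)
  present <- which(counts > 0)
  vals <- vapply(present, function(i) fns[[i]](state, params), numeric(1))
  sum(counts[present] * vals) / sum(counts[present])
}

#' All four expected payoffs at a population state
#'
#' Computes `pi_C`, `pi_D`, `pi_L`, `pi_E` at `state`, substituting the
#' population-average [degenerate_payoff()] for strategies that are absent.
#' A pure function of `(state, params)`.
#'
#' @inheritParams payoff_C
#' @param state A valid [pgg_state()].
#' @return Named numeric vector `c(C =, D =, L =, E =)`.
#' @examples
#' p <- pgg_params(M = 20, N = 5, r = 3, sigma = 0.1, beta = 0.5)
#' payoff_profile(pgg_state(5, 5, 5, 5), p)
#' @export
payoff_profile <- function(state, params) {
  counts <- as.integer(state)
  fns <- list(C = payoff_C, D = payoff_D, L = payoff_L, E = payoff_E)
  out <- numeric(4)
  present <- counts > 0
  for (i in which(present)) out[i] <- fns[[i]](state, params)
  if (any(present)) {
    avg <- sum(counts[present] * out[present]) / sum(counts[present])
    out[!present] <- avg
  }
  names(out) <- strategies
  out
}
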