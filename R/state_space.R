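# State-space enumeration and vectorized payoff evaluation.
#
# The Markov chain lives on all compositions (X, Y, Z, W) of M individuals,
# C(M + 3, 3) states.  Building its generator needs all four expected
# payoffs at every state; the scalar functions in payoffs.R are exact but
# loop per state, so sweeps over (r, sigma) grids would redo the identical
# hypergeometric weights hundreds of times.  Here the weights -- which
# depend only on (M, N) and the state, never on (r, sigma, beta) -- are
# precomputed once as dense state-by-tuple matrices; each parameter set then
# costs four small matrix-vector products.

#' Enumerate the well-mixed state space
#'
#' All strategy-count states `(X, Y, Z, W)` with `X + Y + Z + W = M`,
#' ordered lexicographically by `(X, Y, Z)` (`W` is implied).  This ordering
#' is the on-disk contract of every state-indexed output.
#'
#' @param M Population size.
#' @return Integer matrix with columns `X`, `Y`, `Z`, `W`; one row per
#'   state, `choose(M + 3, 3)` rows.
#' @export
state_space <- function(M) {
  stopifnot(M >= 1, M == round(M))
  M <- as.integer(M)
  idx <- 1L
  out <- matrix(0L, nrow = choose(M + 3, 3), ncol = 4,
                dimnames = list(NULL, c("X", "Y", "Z", "W")))
  for (X in 0:M) for (Y in 0:(M - X)) {
    Z <- 0:(M - X - Y)
    n <- length(Z)
    out[idx:(idx + n - 1L), ] <- cbind(X, Y, Z, M - X - Y - Z)
    idx <- idx + n
  }
  out
}

# integer key for state lookup
state_key <- function(X, Y, Z, M) (X * (M + 1L) + Y) * (M + 1L) + Z

# tuple table for one payoff term: all (l, k, j) with l in lrange and
# l + k + j <= N - 1
tuple_grid <- function(lrange, N) {
  out <- expand.grid(l = lrange, k = 0:(N - 1), j = 0:(N - 1))
  out <- out[out$l + out$k + out$j <= N - 1, , drop = FALSE]
  out[order(out$l, out$k, out$j), , drop = FALSE]
}

#' Precomputed payoff basis for a state space
#'
#' Hypergeometric sampling weights of every group composition tuple at every
#' population state, for the four payoff expectations.  Depends only on
#' `(M, N)`; reusable across any `(r, sigma, beta, mechanism)` sweep.
#'
#' @param M Population size.
#' @param N Group size.
#' @return List with the state matrix, index key map, per-term tuple tables
#'   and weight matrices, and the all-loner group probability per state.
#' @keywords internal
payoff_basis <- function(M, N) {
  S <- state_space(M)
  X <- S[, "X"]; Y <- S[, "Y"]; Z <- S[, "Z"]; W <- S[, "W"]
  ldenom <- lchoose0(M - 1, N - 1)
  wmat <- function(tups, n1, n2, n3, n4) {
    # columns: one per tuple; lchoose0 weights, -Inf -> 0 after exp
    m <- vapply(seq_len(nrow(tups)), function(t) {
      l <- tups$l[t]; k <- tups$k[t]; j <- tups$j[t]
      exp(lchoose0(n1, l) + lchoose0(n2, k) + lchoose0(n3, j) +
            lchoose0(n4, N - 1 - l - k - j) - ldenom)
    }, numeric(nrow(S)))
    m
  }
  tC1 <- tuple_grid(1:(N - 1), N)
  tC2 <- tuple_grid(0L, N); tC2 <- tC2[tC2$k <= N - 2, , drop = FALSE]
  tD1 <- tC1
  tD2 <- tC2
  tE  <- tuple_grid(0:(N - 1), N)
  list(
    M = M, N = N, states = S,
    key = state_key(X, Y, Z, M),
    ploner = exp(lchoose0(Z, N - 1) - ldenom),
    tC1 = tC1, WC1 = wmat(tC1, W, Z, Y, X - 1L),
    tC2 = tC2, WC2 = wmat(tC2, W, Z, Y, X - 1L),  # l = 0 column uses choose(W,0)=1
    tD1 = tD1, WD1 = wmat(tD1, W, Z, Y - 1L, X),
    tD2 = tD2, WD2 = wmat(tD2, W, Z, Y - 1L, X),
    tE  = tE,  WE  = wmat(tE,  W - 1L, Z, Y, X))
}

# per-tuple expectation values (independent of the state)
term_values <- function(tups, kind, r, N, beta, cE = NULL, mechanism = NULL) {
  vapply(seq_len(nrow(tups)), function(t) {
    l <- tups$l[t]; k <- tups$k[t]; j <- tups$j[t]
    switch(kind,
      C1 = {
        p1 <- (1 - beta)^l
        sum(surv_pmf(j, p1) * (r * (N - k - j) / (N - k - j + 0:j) - 1))
      },
      C2 = r * (N - k - j) / (N - k) - 1,
      D1 = {
        p1 <- (1 - beta)^l
        p1 * sum(surv_pmf(j, p1) * (r * (N - k - j - 1) / (N - k - j + 0:j)))
      },
      D2 = r * (N - k - j - 1) / (N - k),
      E  = {
        p2 <- (1 - beta)^(l + 1)
        uc <- if (mechanism == "synchronous") cE else async_unit_cost(beta, l, cE)
        sum(surv_pmf(j, p2) * (r * (N - k - j) / (N - k - j + 0:j) - 1 - uc * j))
      })
  }, numeric(1))
}

#' Expected payoffs of all four strategies at every state
#'
#' Vectorized evaluation of the exact well-mixed payoff expectations over an
#' entire state space, with the population-average fallback applied at
#' states where a strategy is absent.  Agrees with the scalar
#' [payoff_profile()] state by state.
#'
#' @param params A [pgg_params()].
#' @param basis Optional precomputed [payoff_basis()]; rebuilt when missing.
#' @return Numeric matrix, one row per state of [state_space()]`(M)`,
#'   columns `C`, `D`, `L`, `E`.
#' @export
payoff_profiles_all <- function(params, basis = NULL) {
  if (is.null(basis)) basis <- payoff_basis(params$M, params$N)
  stopifnot(basis$M == params$M, basis$N == params$N)
  S <- basis$states
  r <- params$r; N <- params$N; beta <- params$beta
  sig <- params$sigma
  piC <- drop(basis$WC1 %*% term_values(basis$tC1, "C1", r, N, beta)) +
         drop(basis$WC2 %*% term_values(basis$tC2, "C2", r, N, beta)) +
         basis$ploner * sig
  piD <- drop(basis$WD1 %*% term_values(basis$tD1, "D1", r, N, beta)) +
         drop(basis$WD2 %*% term_values(basis$tD2, "D2", r, N, beta)) +
         basis$ploner * sig
  piE <- drop(basis$WE %*% term_values(basis$tE, "E", r, N, beta,
                                       params$cE, params$mechanism)) +
         basis$ploner * (sig - (r - 1))
  piL <- rep(sig, nrow(S))
  P <- cbind(C = piC, D = piD, L = piL, E = piE)
  # average-payoff fallback for absent strategies
  counts <- S
  pres <- counts > 0L
  num <- rowSums(ifelse(pres, counts * P, 0))
  den <- rowSums(counts * pres)
  avg <- num / den
  P[!pres] <- avg[row(P)[!pres]]
  P
}
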