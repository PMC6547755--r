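test_that("parameter construction enforces the model's admissible ranges", {
  expect_error(pgg_params(r = 6, N = 5), "strictly between 1 and N")
  expect_error(pgg_params(r = 1), "strictly between 1 and N")
  expect_error(pgg_params(epsilon = 0), "ergodic")
  expect_error(pgg_params(beta = 1.2))
  expect_error(pgg_params(cost_fn = function(b) -1), "nonnegative")
  p <- pgg_params(M = 20, N = 5, r = 3, beta = 0.5)
  expect_equal(p$cE, 0.2 * 10^0.5)
  expect_error(pgg_state(5, 5, 5, 6, M = 20), "sum")
  expect_error(pgg_state(-1, 21, 0, 0))
})

test_that("survival probabilities follow (1-beta)^l and (1-beta)^(l+1)", {
  expect_equal(survival_probs(0, 5), c(p1 = 1, p2 = 1))
  expect_equal(survival_probs(1, 0), c(p1 = 1, p2 = 0))
  expect_equal(survival_probs(0.5, 2), c(p1 = 0.25, p2 = 0.125))
  expect_error(survival_probs(1.5, 2))
  expect_error(survival_probs(0.5, -1))
})

test_that("asynchronous expected unit cost never exceeds cE and hits its limits", {
  expect_equal(async_unit_cost(0.7, 0, 1.3), 1.3)   # single excluder
  expect_equal(async_unit_cost(1, 3, 2), 0.5)       # certain success: cE/4
  expect_equal(async_unit_cost(0.5, 1, 1), 0.75)
  expect_error(async_unit_cost(0.5, 1, -1), "nonnegative")
  # continuous extension at beta = 0 and near-0 behaviour
  expect_equal(async_unit_cost(0, 4, 0.7), 0.7)
  for (l in 0:10)
    expect_lt(abs(async_unit_cost(1e-9, l, 1) - 1), 1e-6)
  # cR <= cE over a grid
  for (beta in seq(0.05, 1, by = 0.05)) for (l in 0:6)
    expect_lte(async_unit_cost(beta, l, 1.3), 1.3 + 1e-12)
})

test_that("homogeneous and degenerate states give the known closed forms", {
  p <- params_sync(M = 20, N = 5, r = 3, sigma = 0.1, beta = 0.5)
  expect_equal(payoff_C(pgg_state(20, 0, 0, 0), p), p$r - 1)
  expect_equal(payoff_D(pgg_state(0, 20, 0, 0), p), 0)
  expect_equal(payoff_L(pgg_state(0, 0, 20, 0), p), p$sigma)
  expect_equal(payoff_E(pgg_state(0, 0, 0, 20), p), p$r - 1)
  # single defector among cooperators, no excluders: closed-form share
  expect_equal(payoff_D(pgg_state(19, 1, 0, 0), p), p$r * 4 / 5)
  # degenerate fallbacks are the count-weighted population average
  expect_equal(degenerate_payoff(pgg_state(0, 0, 20, 0), p, "C"), p$sigma)
  expect_equal(degenerate_payoff(pgg_state(20, 0, 0, 0), p, "D"), p$r - 1)
  s <- pgg_state(10, 10, 0, 0)
  expect_equal(degenerate_payoff(s, p, "E"),
               (10 * payoff_C(s, p) + 10 * payoff_D(s, p)) / 20)
  expect_error(degenerate_payoff(s, p, "C"), "absent")
  # profile bundles payoffs with fallbacks
  expect_equal(unname(payoff_profile(pgg_state(20, 0, 0, 0), p)), rep(p$r - 1, 4))
  expect_equal(unname(payoff_profile(pgg_state(0, 0, 20, 0), p)), rep(p$sigma, 4))
})

test_that("pi_C, pi_D, pi_L are mechanism-independent; pi_E(async) >= pi_E(sync)", {
  for (i in seq_along(fx$states)) {
    s <- fx$states[[i]]
    pp <- fx$params[[(i - 1L) %% length(fx$params) + 1L]]
    ps <- pp; ps$mechanism <- "synchronous"
    pa <- pp; pa$mechanism <- "asynchronous"
    prof_s <- payoff_profile(s, ps)
    prof_a <- payoff_profile(s, pa)
    if (s[["Y"]] >= 1) expect_identical(payoff_D(s, ps), payoff_D(s, pa))
    if (s[["X"]] >= 1) expect_identical(payoff_C(s, ps), payoff_C(s, pa))
    if (s[["Z"]] >= 1) expect_identical(payoff_L(s, ps), payoff_L(s, pa))
    if (s[["W"]] >= 1)
      expect_gte(payoff_E(s, pa) - payoff_E(s, ps), -1e-12)
    expect_true(all(is.finite(prof_s)), info = paste(s, collapse = ","))
    if (s[[3]] >= 1) expect_equal(prof_s[["L"]], pp$sigma)
  }
})

test_that("hypergeometric and binomial weights are proper distributions", {
  # binomial survival weights sum to 1
  for (j in 0:4) for (p in c(0, 0.3, 1))
    expect_equal(sum(pggexclusion:::surv_pmf(j, p)), 1, tolerance = 1e-12)
  # hypergeometric weights over group compositions sum to 1 per focal type:
  # total probability of the three pi_C terms with value 1 each
  M <- 20; N <- 5
  for (s in fx$states[5:10]) {
    X <- s[["X"]]; Y <- s[["Y"]]; Z <- s[["Z"]]; W <- s[["W"]]
    if (X < 1) next
    tot <- 0
    for (l in 0:(N - 1)) for (k in 0:(N - 1 - l)) for (j in 0:(N - 1 - l - k))
      tot <- tot + exp(
        pggexclusion:::lchoose0(W, l) + pggexclusion:::lchoose0(Z, k) +
        pggexclusion:::lchoose0(Y, j) +
        pggexclusion:::lchoose0(X - 1, N - 1 - l - k - j) -
        pggexclusion:::lchoose0(M - 1, N - 1))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("vectorized state-space payoffs agree with the scalar functions", {
  basis <- pggexclusion:::payoff_basis(20, 5)
  S <- state_space(20)
  for (pp in fx$params[1:6]) {
    P <- payoff_profiles_all(pp, basis)
    idx <- vapply(fx$states[1:10], function(s)
      which(S[, 1] == s[[1]] & S[, 2] == s[[2]] & S[, 3] == s[[3]]),
      integer(1))
    for (q in seq_along(idx)) {
      expect_equal(unname(P[idx[q], ]),
                   unname(payoff_profile(fx$states[[q]], pp)),
                   tolerance = 1e-12)
    }
  }
})
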