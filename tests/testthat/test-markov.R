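test_that("transfer rates clip at the baseline and add the payoff gain", {
  p <- params_sync(epsilon = 0.01, kappa = 1)
  prof <- c(C = 1, D = 3, L = 1, E = -4)
  expect_equal(transfer_rate("C", "L", prof, p), 0.01)
  expect_equal(transfer_rate("C", "D", prof, p), 2.01)
  expect_equal(transfer_rate("C", "E", prof, p), 0.01)
  expect_error(transfer_rate("C", "C", prof, p), "distinct")
})

test_that("the generator is a proper CTMC generator on the full state space", {
  expect_equal(nrow(state_space(2)), 10)    # C(5,3)
  expect_equal(nrow(state_space(20)), 1771) # C(23,3)
  p <- params_sync(M = 6, N = 3, r = 2, sigma = 0.3, beta = 0.4,
                   epsilon = 1e-2)
  m <- build_generator(p)
  Q <- m$Q
  expect_lt(max(abs(Matrix::rowSums(Q))), 1e-10)
  offdiag <- Q - Matrix::Diagonal(x = Matrix::diag(Q))
  expect_gte(min(offdiag), 0)
  # strong connectivity via reachability from state 1 in both directions
  A <- Q
  Matrix::diag(A) <- 0
  A <- as(A > 0, "CsparseMatrix") * 1
  reach <- function(B) {
    v <- rep(0, nrow(B)); v[1] <- 1
    for (i in seq_len(nrow(B))) {
      v2 <- pmin(1, v + as.numeric(Matrix::crossprod(B, v)))
      if (all(v2 == v)) break
      v <- v2
    }
    v
  }
  expect_true(all(reach(A) == 1))
  expect_true(all(reach(Matrix::t(A)) == 1))
})

test_that("kappa = 0 collapses to the exact closed forms of both aggregation modes", {
  # count aggregation: edge rates count(s1) * epsilon, multinomial law
  p <- params_sync(M = 4, N = 3, r = 2, kappa = 0, epsilon = 0.05,
                   aggregation = "count")
  m <- build_generator(p)
  S <- m$states
  Q <- as.matrix(m$Q)
  for (i in seq_len(nrow(S))) {
    out <- Q[i, -i]
    expect_true(all(out[out > 0] %in% (0.05 * 1:4)))
  }
  st <- stationary_distribution(m)
  logm <- lgamma(5) - rowSums(lgamma(S + 1)) + 4 * log(0.25)
  expect_lt(0.5 * sum(abs(st$probabilities - exp(logm))), 1e-10)
  # type aggregation: every allowed edge has rate epsilon, uniform law
  pt <- params_sync(M = 4, N = 3, r = 2, kappa = 0, epsilon = 0.05,
                    aggregation = "type")
  mt <- build_generator(pt)
  Qt <- as.matrix(mt$Q)
  offd <- Qt[row(Qt) != col(Qt)]
  expect_true(all(abs(offd[offd > 0] - 0.05) < 1e-15))
  stt <- stationary_distribution(mt)
  expect_lt(0.5 * sum(abs(stt$probabilities - 1 / nrow(S))), 1e-10)
})

test_that("stationary solve matches eigenvector and trajectory occupancy at M = 5", {
  p <- params_async(M = 5, N = 3, r = 2.2, sigma = 0.4, beta = 0.6,
                    epsilon = 5e-2)
  m <- build_generator(p)
  st <- stationary_distribution(m)
  expect_lt(st$residual, 1e-10)
  expect_equal(sum(st$probabilities), 1, tolerance = 1e-12)
  # eigenvector of the uniformized transition matrix
  n <- nrow(m$Q)
  lambda <- 1.05 * max(-Matrix::diag(m$Q))
  P <- as.matrix(Matrix::Diagonal(n) + m$Q / lambda)
  ev <- eigen(t(P))
  i1 <- which.min(abs(ev$values - 1))
  v <- abs(Re(ev$vectors[, i1])); v <- v / sum(v)
  expect_lt(0.5 * sum(abs(v - st$probabilities)), 1e-8)
  # empirical occupancy of a simulated jump chain, weighting each visit by
  # the expected holding time 1/rate (variance-reduced trajectory estimate)
  set.seed(99)
  steps <- 3e5
  occ <- numeric(n)
  i <- 1L
  rates <- -Matrix::diag(m$Q)
  Pjump <- as.matrix(m$Q); diag(Pjump) <- 0
  Pjump <- Pjump / rowSums(Pjump)
  cum <- apply(Pjump, 1, cumsum)
  u <- stats::runif(steps)
  for (s in seq_len(steps)) {
    occ[i] <- occ[i] + 1 / rates[i]
    i <- findInterval(u[s], cum[, i]) + 1L
  }
  occ <- occ / sum(occ)
  expect_lt(0.5 * sum(abs(occ - st$probabilities)), 0.01)
})

test_that("class masses partition the stationary mass", {
  p <- params_sync(M = 20, N = 5, r = 3, sigma = 0.1, beta = 0.3)
  st <- stationary_distribution(build_generator(p))
  expect_equal(sum(st$class_masses), 1, tolerance = 1e-12)
  expect_true(all(st$class_masses >= 0))
  cls <- pggexclusion:::state_classes(state_space(20))
  expect_true(all(rowSums(cls) == 1))
  expect_equal(sum(cls[, "AllD"]), 1)
  expect_equal(sum(cls[, "AllL"]), 3)
  expect_equal(sum(cls[, "CplusE"]), 21)
})

test_that("synchronous and asynchronous chains coincide as beta -> 0", {
  base <- pgg_params(M = 20, N = 5, r = 2.5, sigma = 0.3, beta = 1e-9,
                     epsilon = 1e-3)
  basis <- pggexclusion:::payoff_basis(20, 5)
  ps <- base; ps$mechanism <- "synchronous"
  pa <- base; pa$mechanism <- "asynchronous"
  vs <- stationary_distribution(build_generator(ps, basis))$probabilities
  va <- stationary_distribution(build_generator(pa, basis))$probabilities
  expect_lt(0.5 * sum(abs(vs - va)), 1e-6)
})

test_that("stable states fall in the enumerated classes and AllD leads at large r, small sigma", {
  basis <- pggexclusion:::payoff_basis(20, 5)
  p <- params_async(M = 20, N = 5, r = 3.8, sigma = 0.1, beta = 0.1)
  # sharply selected regime: push the schedule low enough for the mass to
  # concentrate past the D-to-L transition ridge
  ss <- suppressWarnings(
    stable_states(p, epsilons = c(1e-4, 1e-5, 1e-6), basis = basis))
  cls <- pggexclusion:::state_classes(ss$states)
  expect_true(all(cls[, "AllD"] | cls[, "AllL"] | cls[, "CplusE"]))
  expect_equal(names(which.max(ss$class_masses)), "AllD")
  # kappa = 0, count aggregation: no concentration, multinomial aggregates
  p0 <- params_sync(M = 20, N = 5, r = 3, kappa = 0, aggregation = "count")
  ss0 <- stable_states(p0, epsilons = c(1e-2, 1e-3), basis = basis)
  S <- state_space(20)
  logm <- lgamma(21) - rowSums(lgamma(S + 1)) + 20 * log(0.25)
  cls0 <- pggexclusion:::state_classes(S)
  expected <- colSums(exp(logm) * cls0)
  expect_equal(unname(ss0$class_masses), unname(expected), tolerance = 1e-7)
})

test_that("cooperative-probability difference is a probability difference", {
  basis <- pggexclusion:::payoff_basis(20, 5)
  # beta ~ 0: the two mechanisms coincide
  p0 <- pgg_params(M = 20, N = 5, r = 2, sigma = 0.2, beta = 1e-6)
  expect_lt(abs(coop_probability_difference(p0, basis)), 1e-3)
  # Fig-3-type regime: small r, large beta favours asynchronous exclusion
  p1 <- pgg_params(M = 20, N = 5, r = 1.5, sigma = 0.1, beta = 0.8,
                   epsilon = 1e-3)
  expect_gt(coop_probability_difference(p1, basis), 0)
  # bounded in [-1, 1] for random draws
  set.seed(7)
  for (i in 1:6) {
    p <- pgg_params(M = 20, N = 5, r = runif(1, 1.1, 4.9),
                    sigma = runif(1), beta = runif(1), epsilon = 1e-2)
    d <- coop_probability_difference(p, basis)
    expect_gte(d, -1); expect_lte(d, 1)
  }
})
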