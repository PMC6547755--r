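test_that("initial lattices are uniform, reproducible and validated", {
  lp <- lattice_params(L = 100, rounds = 10, averaging_window = 5,
                       replicates = 1, seed = 31)
  g1 <- init_lattice(lp)
  g2 <- init_lattice(lp)
  expect_identical(unclass(g1), unclass(g2))
  freqs <- tabulate(as.integer(g1) + 1L, 4) / 1e4
  expect_true(all(abs(freqs - 0.25) < 0.013))  # 3 sigma of Binomial(1e4, 1/4)
  expect_error(lattice_params(L = 3), "L >= 4")
  expect_error(lattice_params(tau = 0), "tau > 0")
  expect_error(lattice_params(rounds = 10, averaging_window = 20))
})

test_that("a hand-resolved group fixture matches group_payoffs", {
  # group {E, D, D, L, C} with beta = 1, synchronous exclusion:
  # both defectors are excluded and get 0, E pays 2 cE, pot 2r shared by E, C
  p <- params_sync(M = 20, N = 5, r = 3, sigma = 0.1, beta = 1)
  g <- matrix(2L, 5, 5)  # loner background so other groups don't interfere
  # center (3,3) = E, its neighbours: up D, down D, left L, right C
  g[3, 3] <- 3L; g[2, 3] <- 1L; g[4, 3] <- 1L; g[3, 2] <- 2L; g[3, 4] <- 0L
  center <- 3L + 5L * 2L  # (row 3, col 3), 1-based column-major
  set.seed(1)
  pay <- group_payoffs(g, center, p, mode = "stochastic")
  cells <- attr(pay, "cells")
  by_cell <- setNames(as.numeric(pay), cells)
  idx <- function(row, col) row + 5L * (col - 1L)
  expect_equal(by_cell[[as.character(idx(3, 3))]], p$r - 1 - 2 * p$cE)  # E
  expect_equal(by_cell[[as.character(idx(2, 3))]], 0)                   # D
  expect_equal(by_cell[[as.character(idx(4, 3))]], 0)                   # D
  expect_equal(by_cell[[as.character(idx(3, 2))]], p$sigma)             # L
  expect_equal(by_cell[[as.character(idx(3, 4))]], p$r - 1)             # C
})

test_that("exclusion resolution realizes the two mechanisms' cost rules", {
  set.seed(2)
  out <- resolve_exclusion(2, 1, beta = 1, cE = 0.7, "synchronous")
  expect_equal(out$costs, c(0.7, 0.7))
  expect_true(out$excluded)
  out <- resolve_exclusion(2, 1, beta = 1, cE = 0.7, "asynchronous")
  expect_equal(sort(out$costs), c(0, 0.7))  # only the first in order pays
  expect_true(out$excluded)
  # no excluders or no defectors: nothing happens
  out <- resolve_exclusion(0, 3, 0.5, 1, "synchronous")
  expect_true(all(!out$excluded))
})

test_that("mean realized exclusion costs match the analytic expectations", {
  set.seed(3)
  nrep <- 4e4
  for (beta in c(0.2, 0.5, 0.9)) for (nE in 1:3) {
    nD <- 2L
    tot <- numeric(nrep)
    first <- numeric(nrep)
    for (i in seq_len(nrep)) {
      out <- resolve_exclusion(nE, nD, beta, 1, "asynchronous")
      tot[i] <- sum(out$costs)
      first[i] <- out$costs[1]
    }
    # per-defector total attempt cost is nE * cR(beta, nE - 1)
    expect_lt(abs(mean(tot) / nD - nE * async_unit_cost(beta, nE - 1, 1)),
              3 * stats::sd(tot / nD) / sqrt(nrep) + 1e-12)
    # marginal cost of any fixed excluder is cR (random ordering)
    expect_lt(abs(mean(first) / nD - async_unit_cost(beta, nE - 1, 1)),
              3 * stats::sd(first / nD) / sqrt(nrep) + 1e-12)
    # synchronous cost is exactly cE per defector per excluder
    outs <- resolve_exclusion(nE, nD, beta, 1, "synchronous")
    expect_equal(outs$costs, rep(nD, nE))
  }
})

test_that("homogeneous lattices give the closed-form cumulative payoffs", {
  p <- params_sync(M = 20, N = 5, r = 3, sigma = 0.1, beta = 0.5)
  allC <- matrix(0L, 6, 6); allL <- matrix(2L, 6, 6); allD <- matrix(1L, 6, 6)
  allE <- matrix(3L, 6, 6)
  for (mode in c("stochastic", "expected")) {
    set.seed(4)
    expect_equal(accumulate_payoff(allC, 10, p, mode), 5 * (p$r - 1))
    expect_equal(accumulate_payoff(allL, 10, p, mode), 5 * p$sigma)
    expect_equal(accumulate_payoff(allD, 10, p, mode), 0)
    expect_equal(accumulate_payoff(allE, 10, p, mode), 5 * (p$r - 1))
  }
})

test_that("expected-mode group payoffs equal the mean of stochastic realizations", {
  p <- params_async(M = 20, N = 5, r = 2.8, sigma = 0.1, beta = 0.6)
  g <- matrix(2L, 5, 5)
  g[3, 3] <- 3L; g[2, 3] <- 1L; g[4, 3] <- 1L; g[3, 2] <- 0L; g[3, 4] <- 3L
  center <- 3L + 5L * 2L  # group {E, D, D, C, E}
  exp_pay <- group_payoffs(g, center, p, mode = "expected")
  set.seed(5)
  nrep <- 3e4
  acc <- matrix(0, nrep, 5)
  for (i in seq_len(nrep)) acc[i, ] <- group_payoffs(g, center, p, "stochastic")
  se <- apply(acc, 2, stats::sd) / sqrt(nrep)
  expect_true(all(abs(colMeans(acc) - exp_pay) <= 3 * se + 1e-12))
})

test_that("imitation updates at most one cell and follows the Fermi rule", {
  # C sea with a single loner: deterministic payoffs in expected mode.
  # pi_L = 5 sigma = 2.4, pi_C = 5 (r - 1) = 2.5 -> adoption prob 1/(1+e^-1)
  p <- params_sync(M = 20, N = 5, r = 1.5, sigma = 0.48, beta = 0.1)
  lp <- lattice_params(L = 8, rounds = 10, averaging_window = 5,
                       replicates = 1, seed = 6, payoff_mode = "expected")
  g <- matrix(0L, 8, 8); g[4, 4] <- 2L
  lcell <- 4L + 8L * 3L
  set.seed(6)
  for (i in 1:20) expect_lte(sum(imitation_step(g, p, lp)$grid != g), 1)
  nstep <- 4e4
  flips <- 0L
  for (i in seq_len(nstep)) {
    out <- imitation_step(g, p, lp)
    if (out$changed == lcell && out$grid[4, 4] == 0L) flips <- flips + 1L
  }
  # P(the loner is the imitator) = 4/64 * 1/4 = 1/64
  pflip <- (1 / 64) * (1 / (1 + exp((5 * 0.48 - 5 * 0.5) / lp$tau)))
  expect_lt(abs(flips / nstep - pflip),
            3 * sqrt(pflip * (1 - pflip) / nstep))
})

test_that("simulations are reproducible and conserve frequencies", {
  p <- params_async(M = 20, N = 5, r = 3.2, sigma = 0.1, beta = 0.4)
  lp <- lattice_params(L = 10, rounds = 60, averaging_window = 20,
                       replicates = 1, seed = 77)
  t1 <- run_simulation(p, lp, snapshot_at = c(10, 50))
  t2 <- run_simulation(p, lp, snapshot_at = c(10, 50))
  expect_identical(t1$freq_series, t2$freq_series)
  expect_identical(t1$final_grid, t2$final_grid)
  expect_equal(unname(rowSums(t1$freq_series)), rep(1, 60))
  expect_named(t1$snapshots, c("10", "50"))
  expect_equal(dim(t1$snapshots[["10"]]), c(10, 10))
  expect_equal(sum(t1$stable_freqs), 1)
})

test_that("with beta = 0 and zero cost, excluders are payoff-equivalent to cooperators", {
  p <- pgg_params(M = 20, N = 5, r = 2.5, sigma = 0.1, beta = 0,
                  cost_fn = function(b) 0, mechanism = "synchronous")
  g <- fx$lattices[[6]]
  grel <- g; grel[grel == 3L] <- 0L  # relabel E -> C
  for (cell in c(1L, 9L, 33L, 64L)) {
    a <- accumulate_payoff(g, cell, p, mode = "expected")
    b <- accumulate_payoff(grel, cell, p, mode = "expected")
    expect_equal(a, b)
  }
})

test_that("replicate runs use the documented seed-splitting rule", {
  p <- params_sync(M = 20, N = 5, r = 2, sigma = 0.1, beta = 0.1)
  lp <- lattice_params(L = 8, rounds = 30, averaging_window = 10,
                       replicates = 3, seed = 123)
  rep1 <- run_replicates(p, lp)
  expect_equal(rep1$seeds, 123 + 7919 * (0:2))
  lp1 <- lp; lp1$seed <- rep1$seeds[2]; lp1$replicates <- 1L
  solo <- run_simulation(p, lp1)
  expect_equal(unname(rep1$stable[2, ]), unname(solo$stable_freqs))
})
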