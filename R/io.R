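# Flat key-value configuration, output writers and test-fixture generation.

config_keys <- c("M", "N", "r", "sigma", "beta", "kappa", "epsilon",
                 "mechanism", "aggregation", "L", "tau", "rounds", "updates_per_round",
                 "averaging_window", "replicates", "seed", "payoff_mode")

#' Load a run configuration from a flat key-value file
#'
#' The file holds one `key = value` pair per line; blank lines and lines
#' starting with `#` are ignored.  Recognised keys are the fields of
#' [pgg_params()] and [lattice_params()]; unknown keys are rejected by
#' name.  Missing keys take the documented defaults.
#'
#' @param path Path to the configuration file.
#' @return Object of class `run_config`: list with `params`
#'   (a [pgg_params()]), `lattice` (a [lattice_params()]) and the raw
#'   key-value list.
#' @export
load_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed configuration line (expected 'key = value'): ", ln)
    key <- trimws(sub("=.*", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[key]] <- val
  }
  unknown <- setdiff(names(kv), config_keys)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  num <- function(key, default) {
    if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  }
  chr <- function(key, default) {
    if (is.null(kv[[key]])) default else kv[[key]]
  }
  params <- pgg_params(
    M = num("M", 20), N = num("N", 5), r = num("r", 3),
    sigma = num("sigma", 0.1), beta = num("beta", 0.1),
    kappa = num("kappa", 1), epsilon = num("epsilon", 1e-3),
    mechanism = chr("mechanism", "synchronous"),
    aggregation = chr("aggregation", "type"))
  L <- num("L", 100)
  lattice <- lattice_params(
    L = L, tau = num("tau", 0.1), rounds = num("rounds", 10000),
    updates_per_round = num("updates_per_round", L^2),
    averaging_window = num("averaging_window", 1000),
    replicates = num("replicates", 20), seed = num("seed", 1),
    payoff_mode = chr("payoff_mode", "stochastic"))
  structure(list(params = params, lattice = lattice, raw = kv,
                 version = as.character(utils::packageVersion("pggexclusion"))),
            class = "run_config")
}

#' Write a run configuration to a flat key-value file
#'
#' Inverse of [load_config()]: [load_config()] of the written file
#' reproduces an equal configuration.
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  p <- config$params; l <- config$lattice
  lines <- c(
    sprintf("M = %d", p$M), sprintf("N = %d", p$N),
    sprintf("r = %.17g", p$r), sprintf("sigma = %.17g", p$sigma),
    sprintf("beta = %.17g", p$beta), sprintf("kappa = %.17g", p$kappa),
    sprintf("epsilon = %.17g", p$epsilon),
    sprintf("mechanism = %s", p$mechanism),
    sprintf("aggregation = %s", p$aggregation),
    sprintf("L = %d", l$L), sprintf("tau = %.17g", l$tau),
    sprintf("rounds = %d", l$rounds),
    sprintf("updates_per_round = %d", l$updates_per_round),
    sprintf("averaging_window = %d", l$averaging_window),
    sprintf("replicates = %d", l$replicates),
    sprintf("seed = %d", l$seed),
    sprintf("payoff_mode = %s", l$payoff_mode))
  writeLines(lines, path)
  invisible(path)
}

param_echo <- function(params) {
  sprintf("# M=%d N=%d r=%g sigma=%g beta=%g kappa=%g epsilon=%g cE=%g mechanism=%s aggregation=%s",
          params$M, params$N, params$r, params$sigma, params$beta,
          params$kappa, params$epsilon, params$cE, params$mechanism,
          params$aggregation)
}

#' Write analysis outputs to a directory
#'
#' Writes a stationary distribution as a state-indexed CSV plus a JSON
#' summary, a lattice trajectory as a frequency CSV plus plain-text
#' snapshot grids, or a sweep as a long-format CSV.  Every file embeds the
#' full parameter echo, and existing files are never overwritten unless
#' `force = TRUE`.
#'
#' @param result A `pgg_stationary`, `lattice_trajectory`,
#'   `wellmixed_sweep` or `lattice_sweep` object.
#' @param out_dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @param force Overwrite existing files?
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, out_dir, prefix = "run", force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  guard <- function(path) {
    if (file.exists(path) && !force)
      stop("refusing to overwrite ", path, " (use force = TRUE)")
    path
  }
  write_csv_echo <- function(df, path, echo) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(echo, con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  if (inherits(result, "pgg_stationary")) {
    S <- state_space(result$params$M)
    csv <- guard(file.path(out_dir, paste0(prefix, "_stationary.csv")))
    write_csv_echo(data.frame(S, probability = result$probabilities),
                   csv, param_echo(result$params))
    js <- guard(file.path(out_dir, paste0(prefix, "_summary.json")))
    p <- result$params
    jsonlite::write_json(list(
      class_masses = as.list(result$class_masses),
      epsilon = p$epsilon, residual = result$residual,
      params = list(M = p$M, N = p$N, r = p$r, sigma = p$sigma,
                    beta = p$beta, kappa = p$kappa, cE = p$cE,
                    mechanism = p$mechanism)),
      js, auto_unbox = TRUE, digits = NA)
    written <- c(csv, js)
  } else if (inherits(result, "lattice_trajectory")) {
    csv <- guard(file.path(out_dir, paste0(prefix, "_frequencies.csv")))
    df <- data.frame(round = seq_len(nrow(result$freq_series)),
                     result$freq_series)
    names(df) <- c("round", "freq_C", "freq_D", "freq_L", "freq_E")
    write_csv_echo(df, csv, param_echo(result$params))
    written <- csv
    for (nm in names(result$snapshots)) {
      snap <- result$snapshots[[nm]]
      if (is.null(snap)) next
      path <- guard(file.path(out_dir,
                              paste0(prefix, "_snapshot_mcs", nm, ".txt")))
      writeLines(apply(snap, 1, paste, collapse = " "), path)
      written <- c(written, path)
    }
  } else if (inherits(result, "wellmixed_sweep") ||
             inherits(result, "lattice_sweep")) {
    csv <- guard(file.path(out_dir, paste0(prefix, "_sweep.csv")))
    utils::write.csv(result, csv, row.names = FALSE)
    written <- c(written, csv)
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"))
  }
  invisible(written)
}

#' Random fixtures for tests and oracle checks
#'
#' Seeded draws of random population states (always including the four
#' single-strategy corners and states with each strategy absent at least
#' once), random parameter sets inside the model's admissible ranges, and
#' random small lattices (always including the four homogeneous grids).
#'
#' @param n_states Number of random states (in addition to the corners).
#' @param n_params Number of random parameter sets.
#' @param n_lattices Number of random lattices (in addition to the
#'   homogeneous ones).
#' @param M Population size of the states.
#' @param N Group size of the parameter sets.
#' @param L Lattice side of the lattice fixtures.
#' @param seed RNG seed.
#' @return List with `states`, `params` and `lattices`.
#' @export
generate_fixtures <- function(n_states = 20, n_params = 20, n_lattices = 4,
                              M = 20, N = 5, L = 8, seed = 42) {
  set.seed(seed)
  corner <- function(i) {
    v <- integer(4); v[i] <- M
    pgg_state(v[1], v[2], v[3], v[4])
  }
  states <- lapply(1:4, corner)
  # one state with each strategy absent but the others present
  for (i in 1:4) {
    v <- rep(M %/% 3, 4); v[i] <- 0L
    v[which.max(v)] <- v[which.max(v)] + (M - sum(v))
    states[[length(states) + 1L]] <- pgg_state(v[1], v[2], v[3], v[4])
  }
  for (i in seq_len(n_states)) {
    v <- as.integer(stats::rmultinom(1, M, rep(0.25, 4)))
    states[[length(states) + 1L]] <- pgg_state(v[1], v[2], v[3], v[4])
  }
  params <- lapply(seq_len(n_params), function(i) {
    pgg_params(M = M, N = N,
               r = stats::runif(1, 1 + 1e-3, N - 1e-3),
               sigma = stats::runif(1, 0, 1),
               beta = stats::runif(1, 0, 1),
               kappa = 1, epsilon = 1e-3,
               mechanism = sample(c("synchronous", "asynchronous"), 1))
  })
  lattices <- lapply(0:3, function(s)
    structure(matrix(s, L, L), class = c("lattice_state", "matrix")))
  for (i in seq_len(n_lattices)) {
    lattices[[length(lattices) + 1L]] <-
      structure(matrix(sample.int(4L, L^2, replace = TRUE) - 1L, L, L),
                class = c("lattice_state", "matrix"))
  }
  list(states = states, params = params, lattices = lattices)
}
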