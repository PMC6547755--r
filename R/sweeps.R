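# Parameter scans over the well-mixed chain and the lattice simulation.

#' Define a sweep grid
#'
#' One or two swept parameters, each as a `seq(start, stop, by = step)`
#' axis, evaluated under one or both exclusion mechanisms.
#'
#' @param ... Named axis specifications, each `c(start, stop, step)`, e.g.
#'   `r = c(1.5, 4.5, 0.2)`.  At most two axes.
#' @param mechanisms Character vector of mechanisms to run.
#' @return Object of class `sweep_grid`: list of axes (numeric vectors) and
#'   mechanisms.
#' @examples
#' sweep_grid(r = c(1.5, 4.5, 0.2), sigma = c(0, 1, 0.1))
#' @export
sweep_grid <- function(..., mechanisms = c("synchronous", "asynchronous")) {
  axes_spec <- list(...)
  if (length(axes_spec) < 1L || length(axes_spec) > 2L)
    stop("sweep_grid takes one or two named axes")
  if (is.null(names(axes_spec)) || any(names(axes_spec) == ""))
    stop("axes must be named after the swept parameter")
  mechanisms <- match.arg(mechanisms, several.ok = TRUE)
  axes <- lapply(axes_spec, function(a) {
    stopifnot(length(a) == 3L, a[3] > 0, a[2] >= a[1])
    seq(a[1], a[2], by = a[3])
  })
  structure(list(axes = axes, mechanisms = mechanisms), class = "sweep_grid")
}

grid_points <- function(grid) {
  pts <- do.call(expand.grid, c(grid$axes, list(KEEP.OUT.ATTRS = FALSE)))
  names(pts) <- names(grid$axes)
  pts
}

set_params <- function(params, point, mechanism) {
  for (nm in names(point)) params[[nm]] <- point[[nm]]
  params$mechanism <- mechanism
  # cE follows beta through the cost function
  params$cE <- params$cost_fn(params$beta)
  params
}

#' Well-mixed stationary-mass sweep
#'
#' Solves the stationary distribution at every grid point for every
#' requested mechanism and records the stable-state class masses.
#'
#' @param grid A [sweep_grid()] over any of `r`, `sigma`, `beta`,
#'   `epsilon`.
#' @param params Base [pgg_params()]; swept fields are overridden per
#'   point.
#' @return Data frame of class `wellmixed_sweep` with the swept parameters,
#'   `mechanism`, class-mass columns, `epsilon`, `residual` and an `ok`
#'   flag (FALSE where the solver failed; such points carry `NA` masses).
#' @export
wellmixed_sweep <- function(grid, params) {
  stopifnot(inherits(grid, "sweep_grid"))
  basis <- payoff_basis(params$M, params$N)
  pts <- grid_points(grid)
  rows <- list()
  for (mech in grid$mechanisms) {
    for (i in seq_len(nrow(pts))) {
      p <- set_params(params, pts[i, , drop = FALSE], mech)
      st <- tryCatch(stationary_distribution(build_generator(p, basis)),
                     error = function(e) e)
      if (inherits(st, "error")) {
        warning("solver failed at grid point ", i, " (", mech, "): ",
                conditionMessage(st))
        rows[[length(rows) + 1L]] <- data.frame(
          pts[i, , drop = FALSE], mechanism = mech, AllD = NA_real_,
          AllL = NA_real_, CplusE = NA_real_, Other = NA_real_,
          epsilon = p$epsilon, residual = NA_real_, ok = FALSE)
      } else {
        cm <- st$class_masses
        rows[[length(rows) + 1L]] <- data.frame(
          pts[i, , drop = FALSE], mechanism = mech, AllD = cm[["AllD"]],
          AllL = cm[["AllL"]], CplusE = cm[["CplusE"]],
          Other = cm[["Other"]], epsilon = p$epsilon,
          residual = st$residual, ok = TRUE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("wellmixed_sweep", "data.frame")
  out
}

#' Maximal cooperative-probability gain over a parameter grid
#'
#' Evaluates [coop_probability_difference()] (asynchronous minus synchronous
#' `C + E` stationary mass) at every point of a grid, typically over
#' `(r, sigma)`, and returns the maximum and its location.
#'
#' @param grid A [sweep_grid()]; mechanisms are ignored (both are always
#'   run).
#' @param params Base [pgg_params()].
#' @return List with `max` (the maximal difference), `argmax` (one-row data
#'   frame of swept parameters) and `differences` (data frame of all
#'   points).
#' @export
max_probability_difference <- function(grid, params) {
  sw <- wellmixed_sweep(
    structure(list(axes = grid$axes,
                   mechanisms = c("synchronous", "asynchronous")),
              class = "sweep_grid"),
    params)
  keys <- names(grid$axes)
  sync <- sw[sw$mechanism == "synchronous", , drop = FALSE]
  asyn <- sw[sw$mechanism == "asynchronous", , drop = FALSE]
  stopifnot(nrow(sync) == nrow(asyn),
            all(sync[keys] == asyn[keys]))
  d <- asyn$CplusE - sync$CplusE
  diffs <- cbind(sync[keys], difference = d)
  best <- which.max(d)
  list(max = d[best], argmax = diffs[best, keys, drop = FALSE],
       differences = diffs)
}

#' Lattice frequency sweep
#'
#' Runs replicated lattice simulations at every point of a one-dimensional
#' grid (over `r` or `beta`) for every requested mechanism and records the
#' window-averaged strategy frequencies with replicate standard errors.
#'
#' @param grid A one-axis [sweep_grid()].
#' @param params Base [pgg_params()].
#' @param lp A [lattice_params()]; each grid point reuses the same master
#'   seed so mechanisms are compared on matched replicate seeds.
#' @return Data frame of class `lattice_sweep` with the swept parameter,
#'   `mechanism`, mean frequencies `C`, `D`, `L`, `E`, their standard
#'   errors `se_C` ... `se_E`, and the replicate count.
#' @export
lattice_sweep <- function(grid, params, lp) {
  stopifnot(inherits(grid, "sweep_grid"))
  if (length(grid$axes) != 1L)
    stop("lattice_sweep needs a one-dimensional grid")
  if (lp$rounds < 1L) stop("zero-length run request")
  pts <- grid_points(grid)
  rows <- list()
  for (mech in grid$mechanisms) {
    for (i in seq_len(nrow(pts))) {
      p <- set_params(params, pts[i, , drop = FALSE], mech)
      rep <- run_replicates(p, lp)
      rows[[length(rows) + 1L]] <- data.frame(
        pts[i, , drop = FALSE], mechanism = mech,
        C = rep$mean[["C"]], D = rep$mean[["D"]],
        L = rep$mean[["L"]], E = rep$mean[["E"]],
        se_C = rep$se[["C"]], se_D = rep$se[["D"]],
        se_L = rep$se[["L"]], se_E = rep$se[["E"]],
        replicates = lp$replicates)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lattice_sweep", "data.frame")
  out
}

#' Peak of a swept frequency series
#'
#' Grid argmax of the mean frequency of one strategy along a
#' one-dimensional sweep, with its replicate standard error.  Ties break
#' towards the smaller parameter value; a monotone series returns its
#' endpoint with a warning; an all-zero series is reported as "no peak".
#'
#' @param result A `lattice_sweep` (or any data frame with the swept
#'   column, `mechanism`, and mean/SE columns).
#' @param strategy One of `"C"`, `"D"`, `"L"`, `"E"`.
#' @param mechanism Mechanism to inspect.
#' @return List with `location`, `height`, `se` and `no_peak` flag.
#' @export
detect_peak <- function(result, strategy, mechanism) {
  strategy <- match.arg(strategy, strategies)
  sub <- result[result$mechanism == mechanism, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for mechanism ", mechanism)
  key <- setdiff(names(sub), c("mechanism", "C", "D", "L", "E",
                               "se_C", "se_D", "se_L", "se_E",
                               "replicates"))[1]
  sub <- sub[order(sub[[key]]), , drop = FALSE]
  y <- sub[[strategy]]
  if (all(y == 0))
    return(list(location = NA_real_, height = 0, se = NA_real_,
                no_peak = TRUE))
  if (length(y) > 1 && (all(diff(y) > 0) || all(diff(y) < 0)))
    warning("frequency series is monotone over the grid; ",
            "returning the endpoint")
  best <- which(y == max(y))[1]  # ties: smaller parameter value
  se_col <- paste0("se_", strategy)
  list(location = sub[[key]][best], height = y[best],
       se = if (se_col %in% names(sub)) sub[[se_col]][best] else NA_real_,
       no_peak = FALSE)
}

#' Contiguous parameter interval where a strategy persists
#'
#' The maximal contiguous run of grid points at which the mean frequency of
#' `strategy` exceeds `threshold` (default 0.05).
#'
#' @inheritParams detect_peak
#' @param threshold Emergence threshold on the mean frequency.
#' @return Numeric `c(lower, upper)` grid values, or `NULL` when the
#'   strategy never exceeds the threshold.
#' @export
emergence_interval <- function(result, strategy, mechanism,
                               threshold = 0.05) {
  strategy <- match.arg(strategy, strategies)
  sub <- result[result$mechanism == mechanism, , drop = FALSE]
  key <- setdiff(names(sub), c("mechanism", "C", "D", "L", "E",
                               "se_C", "se_D", "se_L", "se_E",
                               "replicates"))[1]
  sub <- sub[order(sub[[key]]), , drop = FALSE]
  above <- sub[[strategy]] > threshold
  if (!any(above)) return(NULL)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  runs_true <- which(runs$values)
  longest <- runs_true[which.max(runs$lengths[runs_true])]
  c(lower = sub[[key]][starts[longest]], upper = sub[[key]][ends[longest]])
}
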