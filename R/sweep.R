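#' Sweep lifetime fitness along one life-history parameter
#'
#' Evaluates the analytic fitness chain at every point of a grid over one
#' baseline parameter (`d_E0`, `d_A0`, `r_0`, or `b`), for each requested
#' scenario, using that scenario's [default_allocation()] under the given
#' regime. Grids over the investment traits themselves are produced by
#' [investment_curve()].
#'
#' Default ranges are `[0.01, 0.99]` for the probability parameters (staying
#' off the exact bounds avoids degenerate zero-fitness points and log ties)
#' and `[1, 200]` for `b`, each on a 99-point grid.
#'
#' @param parameter One of `"d_E0"`, `"d_A0"`, `"r_0"`, `"b"`.
#' @param range Length-2 numeric, the sweep interval; `NULL` for the default.
#' @param grid_size Number of grid points (default 99).
#' @param scenarios Scenario ids or [scenario_spec()] list (default all four).
#' @param regime An [investment_regime()] or regime name.
#' @param params Fixed values for the non-swept parameters, a
#'   [life_history_params()].
#' @return A `sweep_table`: a data.frame with columns `parameter`, `value`,
#'   `scenario`, `regime`, `c`, `m`, `d_A`, `d_E`, `r`, `R`, `W`, `logW`,
#'   `rank` (rank 1 = highest `W` at that grid point; ties share the smallest
#'   rank). The grid, regime, and fixed parameters are carried as attributes.
#' @examples
#' sw <- sweep_fitness("d_E0", grid_size = 11)
#' head(sw)
#' @seealso [rank_scenarios()], [find_crossovers()]
#' @export
sweep_fitness <- function(parameter = c("d_E0", "d_A0", "r_0", "b"),
                          range = NULL, grid_size = 99,
                          scenarios = c("S1", "S2", "S3", "S4"),
                          regime = "unconstrained",
                          params = life_history_params()) {
  parameter <- match.arg(parameter)
  stopifnot(inherits(params, "life_history_params"))
  regime <- as_investment_regime(regime)
  scenarios <- as_scenario_list(scenarios)
  if (is.null(range)) {
    range <- if (parameter == "b") c(1, 200) else c(0.01, 0.99)
  }
  stopifnot(is.numeric(range), length(range) == 2L, range[1] < range[2])
  lo <- if (parameter == "b") 0 else 0
  hi <- if (parameter == "b") Inf else 1
  if (range[1] < lo || range[2] > hi) {
    stop("sweep range [", range[1], ", ", range[2], "] leaves the valid ",
         "domain of '", parameter, "'", call. = FALSE)
  }
  grid <- seq(range[1], range[2], length.out = grid_size)
  allocs <- lapply(scenarios, default_allocation, regime = regime)

  rows <- lapply(grid, function(v) {
    p <- set_param(params, parameter, v)
    do.call(rbind, lapply(names(scenarios), function(id) {
      bd <- evaluate_fitness(p, allocs[[id]], scenarios[[id]])
      cbind(data.frame(parameter = parameter, value = v,
                       stringsAsFactors = FALSE),
            as.data.frame(bd)[, c("scenario", "regime", "c", "m", "d_A",
                                  "d_E", "r", "R", "W", "logW")])
    }))
  })
  out <- do.call(rbind, rows)
  out$rank <- stats::ave(-out$W, out$value,
                         FUN = function(w) rank(w, ties.method = "min"))
  new_sweep_table(out, grid = grid, regime = regime, params = params,
                  scenarios = names(scenarios))
}

new_sweep_table <- function(df, grid, regime, params, scenarios) {
  rownames(df) <- NULL
  structure(df, grid = grid, regime = regime, fixed_params = params,
            scenarios = scenarios,
            class = c("sweep_table", "data.frame"))
}

set_param <- function(params, name, value) {
  args <- unclass(params)
  args[[name]] <- value
  do.call(life_history_params, args)
}

# Re-evaluate W for one scenario of a sweep at an arbitrary (off-grid) value
# of the swept parameter; used by bisection refinement.
sweep_fitness_fun <- function(sw, scenario_id) {
  parameter <- sw$parameter[1L]
  params <- attr(sw, "fixed_params")
  regime <- attr(sw, "regime")
  scen <- scenario_spec(scenario_id)
  alloc <- default_allocation(scen, regime)
  function(v) {
    evaluate_fitness(set_param(params, parameter, v), alloc, scen)$W
  }
}

#' Rank scenarios at every grid point of a sweep
#'
#' Produces the strict fitness ordering at each swept parameter value.
#' Fitness differences at or below `tie_tol` (absolute, default `1e-9`) are
#' reported as ties, joined with `"="` in the ordering string; within a tie
#' group scenarios are listed by id only for display.
#'
#' @param sweep A `sweep_table` from [sweep_fitness()] or
#'   [investment_curve()].
#' @param tie_tol Absolute fitness-difference tolerance below which two
#'   scenarios are tied.
#' @return A data.frame with one row per grid point: `value`, the `ordering`
#'   string (e.g. `"S4>S2>S3>S1"`), and one `rank_<id>` column per scenario.
#' @examples
#' rk <- rank_scenarios(sweep_fitness("d_E0", grid_size = 5))
#' rk$ordering
#' @export
rank_scenarios <- function(sweep, tie_tol = 1e-9) {
  stopifnot(inherits(sweep, "sweep_table"))
  ids <- attr(sweep, "scenarios")
  if (length(ids) < 2L) {
    stop("ranking needs at least two scenarios", call. = FALSE)
  }
  out <- lapply(split(sweep, sweep$value), function(pt) {
    w <- stats::setNames(pt$W, pt$scenario)[ids]
    ord <- order(-w, seq_along(ids)) # ties broken by scenario index
    sorted <- w[ord]
    sep <- vapply(seq_len(length(sorted) - 1L), function(k) {
      if (abs(sorted[k] - sorted[k + 1L]) <= tie_tol) "=" else ">"
    }, character(1))
    ordering <- paste0(names(sorted),
                       c(sep, ""), collapse = "")
    ranks <- rank(-w, ties.method = "min")
    row <- data.frame(value = pt$value[1L], ordering = ordering,
                      stringsAsFactors = FALSE)
    for (id in ids) row[[paste0("rank_", id)]] <- ranks[[id]]
    row
  })
  out <- do.call(rbind, out)
  out <- out[order(out$value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate scenario-ranking crossovers along a sweep
#'
#' For each pair of scenarios in the sweep, finds the parameter values where
#' their fitness difference changes sign between adjacent grid points, then
#' refines each sign change by bisection on the continuous difference function
#' (re-evaluating the analytic model off-grid) to a location tolerance of
#' `tol` (default `1e-6`). Returns an empty data.frame when no ordering
#' changes, e.g. for sweeps over `b`, in which fitness is exactly linear so
#' orderings never change.
#'
#' @param sweep A `sweep_table` over a continuous parameter.
#' @param tol Bisection half-interval at which refinement stops.
#' @return A data.frame of class `crossover_points` with columns `parameter`,
#'   `location`, `scenario_a`, `scenario_b`, `leader_before`, `leader_after`.
#' @examples
#' sw <- sweep_fitness("d_A0", grid_size = 33)
#' find_crossovers(sw)
#' @export
find_crossovers <- function(sweep, tol = 1e-6) {
  stopifnot(inherits(sweep, "sweep_table"))
  ids <- attr(sweep, "scenarios")
  grid <- attr(sweep, "grid")
  parameter <- sweep$parameter[1L]
  res <- list()
  for (a_i in seq_along(ids)) {
    for (b_i in seq_along(ids)) {
      if (b_i <= a_i) next
      a <- ids[a_i]; b <- ids[b_i]
      wa <- sweep$W[sweep$scenario == a]
      wb <- sweep$W[sweep$scenario == b]
      d <- wa - wb
      s <- sign(d)
      flips <- which(s[-1] * s[-length(s)] < 0)
      if (length(flips) == 0L) next
      fa <- sweep_fitness_fun(sweep, a)
      fb <- sweep_fitness_fun(sweep, b)
      diff_fun <- function(v) fa(v) - fb(v)
      for (k in flips) {
        loc <- bisect_root(diff_fun, grid[k], grid[k + 1L], tol = tol)
        res[[length(res) + 1L]] <- data.frame(
          parameter = parameter, location = loc,
          scenario_a = a, scenario_b = b,
          leader_before = if (d[k] > 0) a else b,
          leader_after = if (d[k] > 0) b else a,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(parameter = character(), location = numeric(),
               scenario_a = character(), scenario_b = character(),
               leader_before = character(), leader_after = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$location), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("crossover_points", "data.frame")
  out
}

# Plain bisection on [lo, hi] with f(lo), f(hi) of opposite sign.
bisect_root <- function(f, lo, hi, tol = 1e-6, max_iter = 200L) {
  flo <- f(lo); fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  stopifnot(sign(flo) != sign(fhi))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fmid <- f(mid)
    if (fmid == 0 || (hi - lo) / 2 < tol) {
      return(mid)
    }
    if (sign(fmid) == sign(flo)) {
      lo <- mid; flo <- fmid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Fitness along one investment trait
#'
#' Sweeps lifetime fitness over the additional-care level `c` or the
#' mating-trait level `m`, holding the other trait at a fixed value (0.5 by
#' default, the reference curve setting). Scenarios without a mating trait
#' always carry `m = 0` regardless of `other_level`.
#'
#' @param trait `"c"` or `"m"`.
#' @param range Trait interval within `[0, 1]`; default the full interval.
#' @param grid_size Number of grid points.
#' @param scenarios Scenario ids or specs; for `trait = "m"` defaults to the
#'   mating-trait scenarios S3 and S4.
#' @param other_level Fixed level of the non-swept trait.
#' @param params Fixed [life_history_params()].
#' @return A `sweep_table` with `parameter` equal to the trait name; the
#'   allocations carry the unconstrained regime since the traits vary freely.
#' @examples
#' investment_curve("c", grid_size = 11)
#' @export
investment_curve <- function(trait = c("c", "m"), range = c(0, 1),
                             grid_size = 101,
                             scenarios = NULL,
                             other_level = 0.5,
                             params = life_history_params()) {
  trait <- match.arg(trait)
  if (is.null(scenarios)) {
    scenarios <- if (trait == "m") c("S3", "S4") else c("S1", "S2", "S3", "S4")
  }
  scenarios <- as_scenario_list(scenarios)
  stopifnot(inherits(params, "life_history_params"),
            is.numeric(range), length(range) == 2L, range[1] <= range[2])
  if (range[1] < 0 || range[2] > 1) {
    stop("trait range must lie within [0, 1]", call. = FALSE)
  }
  check_unit_interval(other_level, "other_level")
  if (trait == "m") {
    no_trait <- !vapply(scenarios, `[[`, logical(1), "trait_present")
    if (any(no_trait)) {
      stop("cannot sweep 'm' for scenario(s) without a mating trait: ",
           paste(names(scenarios)[no_trait], collapse = ", "), call. = FALSE)
    }
  }
  grid <- if (range[1] == range[2]) range[1] else
    seq(range[1], range[2], length.out = grid_size)
  regime <- investment_regime("unconstrained")
  rows <- lapply(grid, function(v) {
    do.call(rbind, lapply(names(scenarios), function(id) {
      scen <- scenarios[[id]]
      cc <- if (trait == "c") v else other_level
      mm <- if (!scen$trait_present) 0 else if (trait == "m") v else other_level
      bd <- evaluate_fitness(params, trait_allocation(cc, mm, regime), scen)
      cbind(data.frame(parameter = trait, value = v, stringsAsFactors = FALSE),
            as.data.frame(bd)[, c("scenario", "regime", "c", "m", "d_A",
                                  "d_E", "r", "R", "W", "logW")])
    }))
  })
  out <- do.call(rbind, rows)
  out$rank <- stats::ave(-out$W, out$value,
                         FUN = function(w) rank(w, ties.method = "min"))
  new_sweep_table(out, grid = grid, regime = regime, params = params,
                  scenarios = names(scenarios))
}

#' Lifetime fitness over a (care, mating-trait) grid
#'
#' Evaluates `W` on the full Cartesian grid of additional-care and
#' mating-trait levels for one scenario, the surface view of how the two
#' investments jointly shape fitness.
#'
#' @param scenario A [scenario_spec()] or id (must exhibit the mating trait
#'   for the `m` axis to matter; S1/S2 are accepted and simply flat in `m`...
#'   the surface then collapses to the care curve).
#' @param params Fixed [life_history_params()].
#' @param c_grid,m_grid Ordered grids in `[0, 1]`.
#' @return A `fitness_surface`: a data.frame with columns `c`, `m`,
#'   `scenario`, `W`, plus a `W_matrix` attribute (rows index `c_grid`,
#'   columns `m_grid`).
#' @examples
#' fs <- fitness_surface("S4", c_grid = seq(0, 1, 0.5), m_grid = seq(0, 1, 0.5))
#' attr(fs, "W_matrix")
#' @export
fitness_surface <- function(scenario, params = life_history_params(),
                            c_grid = seq(0, 1, length.out = 21),
                            m_grid = seq(0, 1, length.out = 21)) {
  scenario <- as_scenario(scenario)
  stopifnot(inherits(params, "life_history_params"),
            all(c_grid >= 0 & c_grid <= 1), all(m_grid >= 0 & m_grid <= 1),
            !is.unsorted(c_grid), !is.unsorted(m_grid))
  W <- outer(c_grid, m_grid,
             Vectorize(function(cc, mm) fitness_at(params, scenario, cc, mm)))
  df <- expand.grid(c = c_grid, m = m_grid, KEEP.OUT.ATTRS = FALSE)
  df$scenario <- scenario$id
  df$W <- as.vector(W)
  structure(df, W_matrix = W, c_grid = c_grid, m_grid = m_grid,
            fixed_params = params,
            class = c("fitness_surface", "data.frame"))
}

#' Classify the monotonicity of fitness in an investment trait
#'
#' Answers the qualitative question behind the interaction analyses: holding
#' the life-history parameters fixed, does lifetime fitness increase,
#' decrease, stay flat, or change direction as the trait rises over `[0, 1]`?
#' The verdict comes from the sign pattern of finite differences of `W` on a
#' dense grid (1001 points by default); steps with `|dW| <= tol` count as
#' flat, and a verdict is `"non-monotone"` when both strictly positive and
#' strictly negative steps occur.
#'
#' @param trait `"c"` or `"m"`.
#' @param scenario A [scenario_spec()] or id.
#' @param params Fixed [life_history_params()].
#' @param other_level Fixed level of the non-swept trait (0.5 by default;
#'   forced to 0 for scenarios without a mating trait when `trait = "c"`).
#' @param grid_size Grid density on `[0, 1]`.
#' @param tol Absolute per-step tolerance below which a step counts as flat.
#' @return An object of class `monotonicity_verdict`: list with `trait`,
#'   `scenario`, `verdict` (one of `"increasing"`, `"decreasing"`,
#'   `"non-monotone"`, `"flat"`), `max_abs_slope`, and the fixed parameters.
#' @examples
#' classify_monotonicity("c", "S1",
#'                       params = life_history_params(d_E0 = 0.9))
#' @export
classify_monotonicity <- function(trait = c("c", "m"), scenario,
                                  params = life_history_params(),
                                  other_level = 0.5,
                                  grid_size = 1001, tol = 1e-9) {
  trait <- match.arg(trait)
  scenario <- as_scenario(scenario)
  curve <- investment_curve(trait, range = c(0, 1), grid_size = grid_size,
                            scenarios = list(scenario),
                            other_level = other_level, params = params)
  w <- curve$W
  grid <- attr(curve, "grid")
  dw <- diff(w)
  pos <- any(dw > tol)
  neg <- any(dw < -tol)
  verdict <- if (pos && neg) "non-monotone"
             else if (pos) "increasing"
             else if (neg) "decreasing"
             else "flat"
  structure(
    list(trait = trait, scenario = scenario$id, verdict = verdict,
         max_abs_slope = max(abs(dw / diff(grid))),
         fixed_params = params, other_level = other_level),
    class = "monotonicity_verdict"
  )
}

#' @export
print.monotonicity_verdict <- function(x, ...) {
  cat(sprintf("W is %s in %s for scenario %s (max |dW/d%s| = %.4g)\n",
              x$verdict, x$trait, x$scenario, x$trait, x$max_abs_slope))
  invisible(x)
}
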