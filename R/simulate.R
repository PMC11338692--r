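#' Simulate one male reproductive career
#'
#' Individual-based generative counterpart of the analytic lifetime fitness.
#' A male always reaches his first reproductive episode. His number of future
#' episodes `L` is drawn geometrically, `P(L = i) = d_A (1 - d_A)^i` for
#' `i = 0, 1, 2, ...`; matching the literal truncation of the analytic sum,
#' a draw with `L > n` contributes **zero** future episodes (or `n` under the
#' capped sensitivity variant). In each episode, of the `b` available gametes
#' each is independently fertilized with probability `r`, and each fertilized
#' egg survives the egg stage with probability `1 - d_E`.
#'
#' Uses the current R random-number stream; seed with `set.seed()` or call
#' through [estimate_fitness_mc()] for a self-seeding summary.
#'
#' @inheritParams adult_mortality
#' @param capped Count lifespans beyond `n` as `n` future episodes instead of
#'   zero (sensitivity variant)?
#' @return An object of class `male_life_record`: list with `scenario`, `c`,
#'   `m`, `L` (drawn future-episode count), `effective_episodes` (`L` if
#'   `L <= n`, else `0` or `n` when capped), `episodes` (total, including the
#'   guaranteed first), `offspring` (integer vector, survivors per episode),
#'   and `total_offspring`.
#' @examples
#' set.seed(1)
#' simulate_male(life_history_params(),
#'               default_allocation("S1", "unconstrained"), "S1")
#' @export
simulate_male <- function(params, alloc, scenario, capped = FALSE) {
  stopifnot(inherits(params, "life_history_params"),
            inherits(alloc, "trait_allocation"))
  scenario <- as_scenario(scenario)
  if (params$b != round(params$b)) {
    stop("simulation requires an integer gamete count 'b', got ", params$b,
         call. = FALSE)
  }
  d_A <- adult_mortality(params, alloc, scenario)
  d_E <- egg_mortality(params$d_E0, alloc$c)
  r <- fertilization_success(params$r_0, alloc, scenario)
  L <- draw_future_episodes(1L, d_A, params$n)
  eff <- effective_episodes(L, params$n, capped)
  episodes <- 1L + eff
  fert <- stats::rbinom(episodes, size = as.integer(params$b), prob = r)
  surv <- stats::rbinom(episodes, size = fert, prob = 1 - d_E)
  structure(
    list(scenario = scenario$id, c = alloc$c, m = alloc$m,
         L = L, effective_episodes = eff, episodes = episodes,
         offspring = surv, total_offspring = sum(surv)),
    class = "male_life_record"
  )
}

#' @export
print.male_life_record <- function(x, ...) {
  cat(sprintf("Male life record [%s, c = %g, m = %g]\n", x$scenario, x$c, x$m))
  cat(sprintf("  drawn future episodes L = %d -> %d effective (+1 first)\n",
              x$L, x$effective_episodes))
  cat("  surviving offspring per episode:", paste(x$offspring, collapse = " "),
      "\n")
  cat(sprintf("  total offspring = %d\n", x$total_offspring))
  invisible(x)
}

# Vectorized geometric draw of future-episode counts. rgeom(p) has
# P(X = i) = p (1-p)^i on 0, 1, 2, ..., exactly the lifespan distribution.
# d_A = 0 would make the draw almost surely exceed any finite horizon, which
# the truncation maps to zero future episodes; represented as n + 1.
draw_future_episodes <- function(n_draws, d_A, n) {
  if (d_A <= 0) {
    return(rep(n + 1L, n_draws))
  }
  stats::rgeom(n_draws, prob = d_A)
}

effective_episodes <- function(L, n, capped = FALSE) {
  over <- L > n
  if (capped) {
    ifelse(over, as.integer(n), as.integer(L))
  } else {
    ifelse(over, 0L, as.integer(L))
  }
}

#' Monte-Carlo estimate of lifetime fitness
#'
#' Simulates a cohort of independent male careers with [simulate_male()]'s
#' generative process (vectorized internally) and summarizes mean total
#' offspring against the analytic lifetime fitness `W`, including the
#' standard error and the z-score `(mean - W) / SE`. This is the package's
#' independent check that the closed-form fitness chain and its truncated
#' future-episode sum describe the process they claim to.
#'
#' @inheritParams simulate_male
#' @param n_replicates Number of simulated males (`>= 2`).
#' @param seed Integer seed; the cohort is fully reproducible given the seed.
#'   `NULL` continues the current RNG stream.
#' @return An object of class `cohort_summary`: list with `n_replicates`,
#'   `seed`, `mean_offspring`, `se`, `analytic_W`, `z`, and the scenario and
#'   allocation used.
#' @examples
#' estimate_fitness_mc(life_history_params(),
#'                     default_allocation("S1", "unconstrained"), "S1",
#'                     n_replicates = 2000, seed = 7)
#' @export
estimate_fitness_mc <- function(params, alloc, scenario,
                                n_replicates = 1e5, seed = NULL,
                                capped = FALSE) {
  stopifnot(inherits(params, "life_history_params"),
            inherits(alloc, "trait_allocation"))
  scenario <- as_scenario(scenario)
  if (n_replicates < 2) {
    stop("'n_replicates' must be at least 2", call. = FALSE)
  }
  if (params$b != round(params$b)) {
    stop("simulation requires an integer gamete count 'b'", call. = FALSE)
  }
  if (!is.null(seed)) {
    set.seed(seed, kind = "Mersenne-Twister")
  }
  totals <- simulate_cohort_totals(params, alloc, scenario, n_replicates,
                                   capped)
  mean_off <- mean(totals)
  se <- stats::sd(totals) / sqrt(n_replicates)
  W <- evaluate_fitness(params, alloc, scenario, capped = capped)$W
  structure(
    list(n_replicates = as.integer(n_replicates), seed = seed,
         scenario = scenario$id, c = alloc$c, m = alloc$m,
         regime = alloc$regime$kind,
         mean_offspring = mean_off, se = se, analytic_W = W,
         z = if (se > 0) (mean_off - W) / se else NA_real_),
    class = "cohort_summary"
  )
}

# One flat pass over all episodes of all males: draw every male's episode
# count, then a single vector of binomial fertilization and survival draws,
# summed back per male.
simulate_cohort_totals <- function(params, alloc, scenario, n_replicates,
                                   capped = FALSE) {
  d_A <- adult_mortality(params, alloc, scenario)
  d_E <- egg_mortality(params$d_E0, alloc$c)
  r <- fertilization_success(params$r_0, alloc, scenario)
  L <- draw_future_episodes(n_replicates, d_A, params$n)
  episodes <- 1L + effective_episodes(L, params$n, capped)
  total_ep <- sum(episodes)
  fert <- stats::rbinom(total_ep, size = as.integer(params$b), prob = r)
  surv <- stats::rbinom(total_ep, size = fert, prob = 1 - d_E)
  male <- rep.int(seq_len(n_replicates), episodes)
  as.vector(rowsum(surv, male, reorder = TRUE))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Monte-Carlo cohort [%s, %s regime, c = %g, m = %g]\n",
              x$scenario, x$regime, x$c, x$m))
  cat(sprintf("  replicates = %d%s\n", x$n_replicates,
              if (is.null(x$seed)) "" else sprintf(" (seed %d)", x$seed)))
  cat(sprintf("  mean total offspring = %.4f (SE %.4f)\n",
              x$mean_offspring, x$se))
  cat(sprintf("  analytic W = %.4f   z = %.3f\n", x$analytic_W, x$z))
  invisible(x)
}

#' Goodness of fit of simulated lifespans to the geometric law
#'
#' Draws future-episode counts and compares their empirical distribution on
#' `{0, ..., n, >n}` with the geometric probabilities
#' `P(L = i) = d_A (1 - d_A)^i` (tail mass pooled beyond `n`) by a chi-squared
#' test.
#'
#' @param d_A Adult mortality, a probability in `(0, 1]`.
#' @param n Episode horizon.
#' @param n_draws Number of simulated lifespans.
#' @param seed Optional integer seed.
#' @return The `htest` object from [stats::chisq.test()].
#' @examples
#' lifespan_gof(0.8, 5, n_draws = 5000, seed = 1)$p.value
#' @export
lifespan_gof <- function(d_A, n, n_draws = 1e5, seed = NULL) {
  check_probability(d_A, "d_A")
  if (d_A == 0) {
    stop("'d_A' must be positive for a geometric lifespan", call. = FALSE)
  }
  if (!is.null(seed)) {
    set.seed(seed, kind = "Mersenne-Twister")
  }
  L <- draw_future_episodes(n_draws, d_A, n)
  bins <- factor(pmin(L, n + 1L), levels = 0:(n + 1L))
  counts <- as.vector(table(bins))
  p <- d_A * (1 - d_A)^(0:n)
  p <- c(p, 1 - sum(p)) # pooled tail beyond n
  keep <- p > 0
  suppressWarnings(stats::chisq.test(counts[keep], p = p[keep] / sum(p[keep])))
}

#' Write a synthetic cohort table
#'
#' Simulates `n_per_scenario` male careers for each requested scenario at its
#' [default_allocation()] and writes one row per male to a CSV with a
#' `#`-prefixed metadata header recording the seed, parameters, regime, and
#' package version. Byte-for-byte reproducible given the seed.
#'
#' @param params A [life_history_params()] with integer `b`.
#' @param scenarios Scenario ids or specs.
#' @param regime An [investment_regime()] or name.
#' @param n_per_scenario Males per scenario.
#' @param seed Integer seed.
#' @param file Output path.
#' @param capped Passed to the simulator.
#' @return Invisibly, the cohort data.frame (columns `scenario`, `c`, `m`,
#'   `L`, `episodes`, `total_offspring`).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' generate_cohort_table(n_per_scenario = 5, seed = 1, file = f)
#' readLines(f, n = 8)
#' @export
generate_cohort_table <- function(params = life_history_params(),
                                  scenarios = c("S1", "S2", "S3", "S4"),
                                  regime = "unconstrained",
                                  n_per_scenario = 1000, seed = 1L,
                                  file, capped = FALSE) {
  stopifnot(inherits(params, "life_history_params"))
  regime <- as_investment_regime(regime)
  scenarios <- as_scenario_list(scenarios)
  set.seed(seed, kind = "Mersenne-Twister")
  rows <- lapply(names(scenarios), function(id) {
    scen <- scenarios[[id]]
    alloc <- default_allocation(scen, regime)
    if (n_per_scenario == 0) {
      return(data.frame(scenario = character(), c = numeric(), m = numeric(),
                        L = integer(), episodes = integer(),
                        total_offspring = integer(),
                        stringsAsFactors = FALSE))
    }
    d_A <- adult_mortality(params, alloc, scen)
    L <- draw_future_episodes(n_per_scenario, d_A, params$n)
    episodes <- 1L + effective_episodes(L, params$n, capped)
    totals <- vapply(episodes, function(ep) {
      fert <- stats::rbinom(ep, size = as.integer(params$b),
                            prob = fertilization_success(params$r_0, alloc,
                                                         scen))
      sum(stats::rbinom(ep, size = fert,
                        prob = 1 - egg_mortality(params$d_E0, alloc$c)))
    }, numeric(1))
    data.frame(scenario = id, c = alloc$c, m = alloc$m,
               L = as.integer(L), episodes = as.integer(episodes),
               total_offspring = as.integer(totals),
               stringsAsFactors = FALSE)
  })
  cohort <- do.call(rbind, rows)
  header <- c(
    sprintf("# carescape cohort table (package version %s)",
            as.character(utils::packageVersion("carescape"))),
    sprintf("# seed: %d  n_per_scenario: %d  regime: %s  capped: %s",
            seed, n_per_scenario, regime$kind, capped),
    sprintf("# params: d_E0=%g d_A0=%g r_0=%g b=%g n=%d",
            params$d_E0, params$d_A0, params$r_0, params$b, params$n)
  )
  con <- file(file, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(cohort, con, row.names = FALSE, quote = FALSE)
  invisible(cohort)
}
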