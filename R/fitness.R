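#' Realized adult male mortality
#'
#' Care is costly: adult mortality rises above the baseline `d_A0` with the
#' level of baseline care (proxied by low baseline egg mortality `d_E0`) and
#' with additional care `c`. In scenarios where the mating trait is exhibited
#' its investment `m` adds to the same survival cost:
#'
#' \deqn{d_A = 1 - (1 - d_{A0})\, e^{-\left((1 - d_{E0}) + c \,[+\, m]\right)}}
#'
#' The `m` term enters only when the scenario exhibits the mating trait; a
#' trait-less scenario is the same expression with `m = 0`. The result always
#' lies in `[d_A0, 1]`, is nondecreasing in `c`, `m`, and `d_A0`, and
#' nonincreasing in `d_E0` (lower baseline egg mortality means more baseline
#' care, hence more cost).
#'
#' @param params A [life_history_params()].
#' @param alloc A [trait_allocation()].
#' @param scenario A [scenario_spec()] or id; decides whether `m` is costly.
#' @return Realized adult mortality, a probability.
#' @examples
#' p <- life_history_params()
#' adult_mortality(p, trait_allocation(c = 0.5), "S1") # 1 - 0.5 exp(-1)
#' @export
adult_mortality <- function(params, alloc, scenario) {
  stopifnot(inherits(params, "life_history_params"),
            inherits(alloc, "trait_allocation"))
  scenario <- as_scenario(scenario)
  m_cost <- if (scenario$trait_present) alloc$m else 0
  exponent <- (1 - params$d_E0) + alloc$c + m_cost
  1 - (1 - params$d_A0) * exp(-exponent)
}

#' Realized egg mortality under additional care
#'
#' Additional care reduces egg mortality multiplicatively:
#' \deqn{d_E = d_{E0}\, e^{-c}}
#' strictly decreasing in `c` whenever `d_E0 > 0`, and bounded by
#' `[0, d_E0]`.
#'
#' @param d_E0 Baseline egg mortality, a probability.
#' @param c Additional-care level, nonnegative.
#' @return Realized egg mortality.
#' @examples
#' egg_mortality(0.5, 0.5) # 0.5 exp(-0.5)
#' @export
egg_mortality <- function(d_E0, c) {
  check_probability(d_E0, "d_E0")
  check_scalar_number(c, "c")
  if (c < 0) {
    stop("'c' must be nonnegative, got ", c, call. = FALSE)
  }
  d_E0 * exp(-c)
}

#' Realized fertilization success under female mate preferences
#'
#' Female preferences raise the focal male's fertilization success above the
#' baseline `r_0`. Preferred investments enter a shared saturating form
#' \deqn{r = 1 - (1 - r_0)\, e^{-x}}
#' where the exponent `x` collects whatever females prefer in that scenario:
#' nothing (S1, which leaves the baseline `r_0`), additional care `c` (S2),
#' the mating trait `m` (S3), or both `c + m` (S4). The result always lies in
#' `[r_0, 1]`.
#'
#' @param r_0 Baseline fertilization success, a probability.
#' @param alloc A [trait_allocation()].
#' @param scenario A [scenario_spec()] or id; decides which traits females
#'   prefer.
#' @return Realized fertilization success.
#' @examples
#' fertilization_success(0.5, trait_allocation(c = 0.5), "S2")
#' @export
fertilization_success <- function(r_0, alloc, scenario) {
  check_probability(r_0, "r_0")
  stopifnot(inherits(alloc, "trait_allocation"))
  scenario <- as_scenario(scenario)
  exponent <- (if (scenario$care_preferred) alloc$c else 0) +
    (if (scenario$trait_preferred) alloc$m else 0)
  1 - (1 - r_0) * exp(-exponent)
}

#' Per-episode reproductive success
#'
#' Expected surviving offspring in one reproductive episode: of the `b`
#' available female gametes, a fraction `r` is fertilized and a fraction
#' `(1 - d_E)` of those survives the egg stage,
#' \deqn{R = r \, b \, (1 - d_E).}
#'
#' @param r Realized fertilization success, a probability.
#' @param b Number of available female gametes, nonnegative.
#' @param d_E Realized egg mortality, a probability.
#' @return Expected surviving offspring, linear in `b`.
#' @examples
#' episode_reproductive_success(0.5, 100, egg_mortality(0.5, 0.5))
#' @export
episode_reproductive_success <- function(r, b, d_E) {
  check_probability(r, "r")
  check_scalar_number(b, "b")
  if (b < 0) {
    stop("'b' must be nonnegative, got ", b, call. = FALSE)
  }
  check_probability(d_E, "d_E")
  r * b * (1 - d_E)
}

#' Expected number of future reproductive episodes
#'
#' With per-episode adult mortality `d_A`, the number of future episodes a
#' male survives to is geometric, and the expectation truncated at horizon `n`
#' is
#' \deqn{\sum_{i=0}^{n} i \, d_A (1 - d_A)^i .}
#'
#' The truncation is literal: probability mass on lifespans beyond `n`
#' contributes nothing, and no renormalization is applied. Setting
#' `capped = TRUE` switches to a sensitivity variant in which lifespans beyond
#' `n` contribute `n` episodes (adding the tail term
#' \eqn{n (1-d_A)^{n+1}} plus the remaining mass re-weighted at `n`); the
#' capped variant is provided for sensitivity checks only and is never used in
#' the reference analyses.
#'
#' @param d_A Realized adult mortality, a probability.
#' @param n Episode horizon, a nonnegative integer.
#' @param capped Use the capped-lifespan variant instead of the literal
#'   truncation? Default `FALSE`.
#' @return Expected future episodes, in `[0, n]`.
#' @examples
#' expected_future_episodes(0.5, 5)
#' expected_future_episodes(0.5, 5, capped = TRUE)
#' @export
expected_future_episodes <- function(d_A, n, capped = FALSE) {
  check_probability(d_A, "d_A")
  check_scalar_number(n, "n")
  if (n < 0 || n != round(n)) {
    stop("'n' must be a nonnegative integer, got ", n, call. = FALSE)
  }
  i <- seq_len(n)          # i = 0 term contributes 0
  if (n == 0L) {
    return(0)
  }
  base <- sum(i * d_A * (1 - d_A)^i)
  if (!capped) {
    return(base)
  }
  # capped variant: lifespans longer than n count as n episodes
  base + n * (1 - d_A)^(n + 1)
}

#' Male lifetime fitness
#'
#' Males are assumed to survive to a guaranteed first reproductive episode;
#' lifetime fitness adds the expected future episodes, each worth the same
#' per-episode success `R`:
#' \deqn{W = R + R \sum_{i=0}^{n} i\, d_A (1 - d_A)^i .}
#'
#' @param R Per-episode reproductive success, nonnegative.
#' @param d_A Realized adult mortality, a probability.
#' @param n Episode horizon, a nonnegative integer.
#' @param capped Passed to [expected_future_episodes()].
#' @return Lifetime fitness `W >= R` (with equality at `d_A = 1`).
#' @examples
#' lifetime_fitness(R = 34.8367, d_A = 0.81606, n = 5)
#' @export
lifetime_fitness <- function(R, d_A, n, capped = FALSE) {
  check_scalar_number(R, "R")
  if (R < 0) {
    stop("'R' must be nonnegative, got ", R, call. = FALSE)
  }
  R * (1 + expected_future_episodes(d_A, n, capped = capped))
}

#' Evaluate the full fitness chain for one parameter set
#'
#' Composes the cost and benefit functions into a single record: realized
#' adult mortality, egg mortality, and fertilization success, per-episode
#' reproductive success `R`, lifetime fitness `W`, and `log(W)`. `log_W` is
#' `-Inf` when `W = 0` (the documented sentinel; no error is raised).
#'
#' @inheritParams adult_mortality
#' @param capped Use the capped-lifespan variant of the future-episode sum?
#' @return An object of class `fitness_breakdown`: a named list with fields
#'   `scenario`, `c`, `m`, `regime`, `d_A`, `d_E`, `r`, `R`, `W`, `log_W`.
#' @examples
#' p <- life_history_params()
#' evaluate_fitness(p, default_allocation("S4", "unconstrained"), "S4")
#' @export
evaluate_fitness <- function(params, alloc, scenario, capped = FALSE) {
  stopifnot(inherits(params, "life_history_params"),
            inherits(alloc, "trait_allocation"))
  scenario <- as_scenario(scenario)
  d_A <- adult_mortality(params, alloc, scenario)
  d_E <- egg_mortality(params$d_E0, alloc$c)
  r <- fertilization_success(params$r_0, alloc, scenario)
  R <- episode_reproductive_success(r, params$b, d_E)
  W <- lifetime_fitness(R, d_A, params$n, capped = capped)
  structure(
    list(
      scenario = scenario$id, c = alloc$c, m = alloc$m,
      regime = alloc$regime$kind,
      d_A = d_A, d_E = d_E, r = r, R = R, W = W,
      log_W = if (W > 0) log(W) else -Inf
    ),
    class = "fitness_breakdown"
  )
}

#' @export
print.fitness_breakdown <- function(x, ...) {
  cat(sprintf("Fitness breakdown [%s, %s regime, c = %g, m = %g]\n",
              x$scenario, x$regime, x$c, x$m))
  cat(sprintf("  d_A = %.6f  d_E = %.6f  r = %.6f\n", x$d_A, x$d_E, x$r))
  cat(sprintf("  R (per episode) = %.4f\n", x$R))
  cat(sprintf("  W (lifetime)    = %.4f   log W = %.4f\n", x$W, x$log_W))
  invisible(x)
}

#' @export
as.data.frame.fitness_breakdown <- function(x, ...) {
  data.frame(
    scenario = x$scenario, regime = x$regime, c = x$c, m = x$m,
    d_A = x$d_A, d_E = x$d_E, r = x$r, R = x$R, W = x$W, logW = x$log_W,
    stringsAsFactors = FALSE
  )
}

# Scalar fitness for one (params, scenario) pair at allocation (c, m):
# the workhorse behind sweeps, crossover bisection, and surfaces.
fitness_at <- function(params, scenario, c, m, regime = "unconstrained",
                       capped = FALSE) {
  alloc <- trait_allocation(c = c, m = m, regime = regime)
  evaluate_fitness(params, alloc, scenario, capped = capped)$W
}
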