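#' Life-history parameter set
#'
#' Bundles the baseline life-history rates of the paternal-care fitness model.
#' `d_E0` is the baseline egg mortality before any additional care is applied;
#' because eggs die less when males care more, it doubles as an (inverse) proxy
#' for the baseline level of male care. `d_A0` is the baseline adult male
#' mortality before the survival costs of care and the mating trait are paid,
#' `r_0` the baseline fertilization success before female mate preferences act,
#' `b` the number of reproductively available female gametes per episode, and
#' `n` the number of future reproductive episodes summed in the truncated
#' lifetime-fitness expression.
#'
#' Defaults are the reference parameter set used throughout the analyses
#' (`d_E0 = 0.5`, `d_A0 = 0.5`, `r_0 = 0.5`, `b = 100`, `n = 5`).
#'
#' @param d_E0 Baseline egg mortality, a probability in `[0, 1]`.
#' @param d_A0 Baseline adult male mortality, a probability in `[0, 1]`.
#' @param r_0 Baseline fertilization success, a probability in `[0, 1]`.
#' @param b Number of female gametes available per reproductive episode
#'   (`>= 0`; the analytic model accepts real `b`, the simulator requires an
#'   integer).
#' @param n Number of future reproductive episodes in the truncated lifetime
#'   sum; a nonnegative integer.
#' @return An object of class `life_history_params`: a named list with the
#'   five validated fields.
#' @examples
#' p <- life_history_params()
#' p
#' life_history_params(d_E0 = 0.9, b = 50)
#' @seealso [trait_allocation()], [scenario_spec()], [evaluate_fitness()]
#' @export
life_history_params <- function(d_E0 = 0.5, d_A0 = 0.5, r_0 = 0.5,
                                b = 100, n = 5L) {
  check_probability(d_E0, "d_E0")
  check_probability(d_A0, "d_A0")
  check_probability(r_0, "r_0")
  check_scalar_number(b, "b")
  if (b < 0) {
    stop("'b' must be nonnegative, got ", b, call. = FALSE)
  }
  check_scalar_number(n, "n")
  if (n < 0 || n != round(n)) {
    stop("'n' must be a nonnegative integer, got ", n, call. = FALSE)
  }
  structure(
    list(d_E0 = d_E0, d_A0 = d_A0, r_0 = r_0, b = b, n = as.integer(round(n))),
    class = "life_history_params"
  )
}

#' @export
print.life_history_params <- function(x, ...) {
  cat("Life-history parameters\n")
  cat(sprintf("  d_E0 (baseline egg mortality)    : %g\n", x$d_E0))
  cat(sprintf("  d_A0 (baseline adult mortality)  : %g\n", x$d_A0))
  cat(sprintf("  r_0  (baseline fertilization)    : %g\n", x$r_0))
  cat(sprintf("  b    (female gametes per episode): %g\n", x$b))
  cat(sprintf("  n    (future episodes summed)    : %d\n", x$n))
  invisible(x)
}

#' Trait investment allocation
#'
#' An investment pair: `c` is the level of additional paternal care beyond the
#' baseline, `m` the level of the non-care mating trait. Both vary on
#' `[0, 1]`. The `regime` records whether the pair was produced under the
#' free (`"unconstrained"`) regime, where each trait is set independently, or
#' the `"constrained"` regime, where total investment `c + m` may not exceed
#' a fixed budget (default 0.5), encoding a tradeoff between care and the
#' mating trait.
#'
#' @param c Additional-care level in `[0, 1]`.
#' @param m Mating-trait level in `[0, 1]`.
#' @param regime An [investment_regime()], or one of `"unconstrained"`,
#'   `"constrained"` (converted with default settings). Used by
#'   [validate_allocation()]; the analytic core itself only reads `c` and `m`.
#' @return An object of class `trait_allocation`.
#' @examples
#' trait_allocation(c = 0.5, m = 0.5)
#' trait_allocation(c = 0.25, m = 0.25, regime = "constrained")
#' @export
trait_allocation <- function(c = 0, m = 0, regime = "unconstrained") {
  check_unit_interval(c, "c")
  check_unit_interval(m, "m")
  regime <- as_investment_regime(regime)
  structure(list(c = c, m = m, regime = regime), class = "trait_allocation")
}

#' @export
print.trait_allocation <- function(x, ...) {
  cat(sprintf("Trait allocation: c = %g, m = %g [%s regime]\n",
              x$c, x$m, x$regime$kind))
  invisible(x)
}

#' Investment regime
#'
#' Describes how investment levels in additional care and the mating trait are
#' set. Under the unconstrained regime each expressed trait is invested at
#' `per_trait_level` (default 0.5) with no tradeoff between the two. Under the
#' constrained regime total investment `c + m` is capped at `budget` (default
#' 0.5), so a male with both traits splits the budget and a male with care
#' only devotes all of it to care.
#'
#' @param kind `"unconstrained"` or `"constrained"`.
#' @param per_trait_level Investment per expressed trait under the
#'   unconstrained regime, in `[0, 1]`.
#' @param budget Total investment cap under the constrained regime, in
#'   `[0, 1]`.
#' @return An object of class `investment_regime`.
#' @examples
#' investment_regime("constrained", budget = 0.5)
#' @export
investment_regime <- function(kind = c("unconstrained", "constrained"),
                              per_trait_level = 0.5, budget = 0.5) {
  kind <- match.arg(kind)
  check_unit_interval(per_trait_level, "per_trait_level")
  check_unit_interval(budget, "budget")
  structure(
    list(kind = kind, per_trait_level = per_trait_level, budget = budget),
    class = "investment_regime"
  )
}

#' @export
print.investment_regime <- function(x, ...) {
  if (x$kind == "unconstrained") {
    cat(sprintf("Unconstrained regime (per-trait level %g)\n",
                x$per_trait_level))
  } else {
    cat(sprintf("Constrained regime (budget c + m <= %g)\n", x$budget))
  }
  invisible(x)
}

as_investment_regime <- function(x) {
  if (inherits(x, "investment_regime")) {
    return(x)
  }
  if (is.character(x) && length(x) == 1L) {
    return(investment_regime(x))
  }
  stop("'regime' must be an investment_regime or one of ",
       "\"unconstrained\", \"constrained\"", call. = FALSE)
}

# -- validation helpers (shared across the package) ---------------------------

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  invisible(x)
}

check_probability <- function(x, name) {
  check_scalar_number(x, name)
  if (x < 0 || x > 1) {
    stop("'", name, "' must be a probability in [0, 1], got ", x,
         call. = FALSE)
  }
  invisible(x)
}

check_unit_interval <- function(x, name) {
  check_scalar_number(x, name)
  if (x < 0 || x > 1) {
    stop("'", name, "' must lie in [0, 1], got ", x, call. = FALSE)
  }
  invisible(x)
}
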