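#' Mate-preference scenarios
#'
#' The model contrasts four sexual-selection scenarios. In all of them males
#' provide (and can elaborate) paternal care; they differ in whether females
#' prefer additional care, whether a non-care mating trait is exhibited at
#' all, and whether that trait is preferred:
#'
#' * **S1** — no mate preferences; no mating trait.
#' * **S2** — females prefer additional care; no mating trait.
#' * **S3** — a mating trait is exhibited and preferred; care is not preferred.
#' * **S4** — females prefer both additional care and the mating trait.
#'
#' `scenario_spec()` builds one scenario, either canonically by id or from
#' explicit preference flags (non-canonical combinations are accepted and
#' flagged, so the analytic core can explore them, but reporting functions mark
#' them as custom).
#'
#' @param id Scenario id: one of `"S1"`–`"S4"` (case-insensitive, `"s1"` etc.
#'   accepted), or `NULL` when building a custom scenario from flags.
#' @param care_preferred Do females prefer additional care?
#' @param trait_present Do males exhibit the non-care mating trait?
#' @param trait_preferred Do females prefer the mating trait? Requires
#'   `trait_present`.
#' @return An object of class `scenario_spec` with fields `id`,
#'   `care_preferred`, `trait_present`, `trait_preferred`, `canonical`, and a
#'   one-line `description`.
#' @examples
#' scenario_spec("S4")
#' scenario_spec(care_preferred = TRUE, trait_present = TRUE,
#'               trait_preferred = FALSE) # custom, flagged non-canonical
#' @seealso [scenario_table()], [default_allocation()]
#' @export
scenario_spec <- function(id = NULL, care_preferred = FALSE,
                          trait_present = FALSE, trait_preferred = FALSE) {
  if (!is.null(id)) {
    id <- toupper(as.character(id))
    flags <- switch(id,
      S1 = c(FALSE, FALSE, FALSE),
      S2 = c(TRUE, FALSE, FALSE),
      S3 = c(FALSE, TRUE, TRUE),
      S4 = c(TRUE, TRUE, TRUE),
      stop("unknown scenario id '", id, "'; valid ids are S1, S2, S3, S4",
           call. = FALSE)
    )
    care_preferred <- flags[1L]
    trait_present <- flags[2L]
    trait_preferred <- flags[3L]
  }
  stopifnot(is.logical(care_preferred), is.logical(trait_present),
            is.logical(trait_preferred))
  if (trait_preferred && !trait_present) {
    stop("'trait_preferred' requires 'trait_present'", call. = FALSE)
  }
  canonical_id <- canonical_scenario_id(care_preferred, trait_present,
                                        trait_preferred)
  structure(
    list(
      id = if (is.na(canonical_id)) "custom" else canonical_id,
      care_preferred = care_preferred,
      trait_present = trait_present,
      trait_preferred = trait_preferred,
      canonical = !is.na(canonical_id),
      description = scenario_description(care_preferred, trait_present,
                                         trait_preferred)
    ),
    class = "scenario_spec"
  )
}

canonical_scenario_id <- function(care_preferred, trait_present,
                                  trait_preferred) {
  key <- paste(care_preferred, trait_present, trait_preferred)
  switch(key,
    "FALSE FALSE FALSE" = "S1",
    "TRUE FALSE FALSE" = "S2",
    "FALSE TRUE TRUE" = "S3",
    "TRUE TRUE TRUE" = "S4",
    NA_character_
  )
}

scenario_description <- function(care_preferred, trait_present,
                                 trait_preferred) {
  if (!care_preferred && !trait_present) {
    return("No mate preferences; additional care only")
  }
  if (care_preferred && !trait_present) {
    return("Females prefer additional care; no mating trait")
  }
  if (!care_preferred && trait_present && trait_preferred) {
    return("Females prefer the mating trait; care not preferred")
  }
  if (care_preferred && trait_present && trait_preferred) {
    return("Females prefer both additional care and the mating trait")
  }
  "Custom preference combination (non-canonical)"
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %s%s: %s\n", x$id,
              if (x$canonical) "" else " (non-canonical)", x$description))
  cat(sprintf("  care preferred: %s | trait present: %s | trait preferred: %s\n",
              x$care_preferred, x$trait_present, x$trait_preferred))
  invisible(x)
}

#' The four canonical scenarios
#'
#' @param ids Character vector of scenario ids to return, in order; defaults
#'   to all four.
#' @return A named list of [scenario_spec()] objects, in the order requested.
#' @examples
#' length(scenario_table())
#' scenario_table()$S3$trait_preferred
#' @export
scenario_table <- function(ids = c("S1", "S2", "S3", "S4")) {
  ids <- toupper(ids)
  out <- lapply(ids, scenario_spec)
  names(out) <- ids
  out
}

as_scenario_list <- function(scenarios) {
  if (inherits(scenarios, "scenario_spec")) {
    scenarios <- list(scenarios)
  } else if (is.character(scenarios)) {
    scenarios <- scenario_table(scenarios)
  }
  stopifnot(all(vapply(scenarios, inherits, logical(1), "scenario_spec")))
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, `[[`, character(1), "id")
  }
  scenarios
}

#' Default trait allocation for a scenario under a regime
#'
#' Reproduces the reference investment levels of the analyses: under the
#' unconstrained regime each expressed trait is invested at the per-trait
#' level (0.5 by default), so care-only scenarios get `(c, m) = (0.5, 0)` and
#' trait scenarios `(0.5, 0.5)`; under the constrained regime the budget
#' (0.5 by default) goes entirely to care when no mating trait is exhibited
#' and is split evenly otherwise, giving `(0.5, 0)` and `(0.25, 0.25)`.
#' `m` is zero whenever the scenario lacks the mating trait.
#'
#' @param scenario A [scenario_spec()] or scenario id.
#' @param regime An [investment_regime()] or regime name.
#' @return A [trait_allocation()] that passes [validate_allocation()].
#' @examples
#' default_allocation("S4", "unconstrained") # c = 0.5, m = 0.5
#' default_allocation("S4", "constrained")   # c = 0.25, m = 0.25
#' @export
default_allocation <- function(scenario, regime = "unconstrained") {
  scenario <- as_scenario(scenario)
  regime <- as_investment_regime(regime)
  if (regime$kind == "unconstrained") {
    alloc <- trait_allocation(
      c = regime$per_trait_level,
      m = if (scenario$trait_present) regime$per_trait_level else 0,
      regime = regime
    )
  } else {
    alloc <- if (scenario$trait_present) {
      trait_allocation(c = regime$budget / 2, m = regime$budget / 2,
                       regime = regime)
    } else {
      trait_allocation(c = regime$budget, m = 0, regime = regime)
    }
  }
  validate_allocation(alloc, scenario, regime)
}

as_scenario <- function(x) {
  if (inherits(x, "scenario_spec")) {
    return(x)
  }
  if (is.character(x) && length(x) == 1L) {
    return(scenario_spec(x))
  }
  stop("'scenario' must be a scenario_spec or an id S1..S4", call. = FALSE)
}

#' Validate a trait allocation against a scenario and regime
#'
#' Rejects investment in a mating trait the scenario does not exhibit, and
#' total investment exceeding the budget under the constrained regime.
#'
#' @inheritParams default_allocation
#' @param alloc A [trait_allocation()].
#' @return The allocation, unchanged, if valid; otherwise an error naming the
#'   violated rule.
#' @examples
#' a <- trait_allocation(c = 0.25, m = 0.25)
#' validate_allocation(a, "S4", "constrained")
#' @export
validate_allocation <- function(alloc, scenario, regime = alloc$regime) {
  stopifnot(inherits(alloc, "trait_allocation"))
  scenario <- as_scenario(scenario)
  regime <- as_investment_regime(regime)
  if (alloc$m > 0 && !scenario$trait_present) {
    stop("allocation invests m = ", alloc$m, " in a mating trait, but ",
         "scenario ", scenario$id, " has no mating trait", call. = FALSE)
  }
  if (regime$kind == "constrained" &&
      alloc$c + alloc$m > regime$budget + 1e-12) {
    stop("total investment c + m = ", alloc$c + alloc$m,
         " exceeds the constrained budget ", regime$budget, call. = FALSE)
  }
  alloc
}
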