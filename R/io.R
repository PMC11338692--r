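#' Write a sweep table to CSV
#'
#' Serializes a `sweep_table` with the canonical column set
#' `parameter,value,scenario,regime,c,m,d_A,d_E,r,R,W,logW,rank` and a
#' `#`-prefixed metadata header (package version, regime, fixed parameters)
#' so the file can be regenerated exactly. Round-trips losslessly through
#' [read_sweep_csv()].
#'
#' @param table A `sweep_table` from [sweep_fitness()] or
#'   [investment_curve()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @seealso [read_sweep_csv()], [write_surface_csv()]
#' @export
write_sweep_csv <- function(table, file) {
  stopifnot(inherits(table, "sweep_table"))
  params <- attr(table, "fixed_params")
  regime <- attr(table, "regime")
  cols <- c("parameter", "value", "scenario", "regime", "c", "m",
            "d_A", "d_E", "r", "R", "W", "logW", "rank")
  header <- c(
    sprintf("# carescape sweep table (package version %s)",
            as.character(utils::packageVersion("carescape"))),
    sprintf("# regime: %s (per_trait_level=%g, budget=%g)",
            regime$kind, regime$per_trait_level, regime$budget),
    sprintf("# fixed params: d_E0=%g d_A0=%g r_0=%g b=%g n=%d",
            params$d_E0, params$d_A0, params$r_0, params$b, params$n),
    sprintf("# scenarios: %s", paste(attr(table, "scenarios"),
                                     collapse = ","))
  )
  con <- file(file, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(as.data.frame(table)[, cols, drop = FALSE], con,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a sweep table written by [write_sweep_csv()]
#'
#' Restores the data and the metadata attributes (regime, fixed parameters,
#' scenario set, grid).
#'
#' @param file Path to a sweep CSV.
#' @return A `sweep_table`.
#' @export
read_sweep_csv <- function(file) {
  if (!file.exists(file)) {
    stop("sweep CSV not found: ", file, call. = FALSE)
  }
  lines <- readLines(file)
  meta <- lines[startsWith(lines, "#")]
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")],
                        stringsAsFactors = FALSE)
  regime_line <- grep("^# regime:", meta, value = TRUE)
  kind <- sub("^# regime: (\\w+).*$", "\\1", regime_line)
  level <- as.numeric(sub(".*per_trait_level=([0-9.eE+-]+).*", "\\1",
                          regime_line))
  budget <- as.numeric(sub(".*budget=([0-9.eE+-]+).*", "\\1", regime_line))
  pl <- grep("^# fixed params:", meta, value = TRUE)
  num <- function(key) {
    as.numeric(sub(paste0(".*", key, "=([0-9.eE+-]+).*"), "\\1", pl))
  }
  params <- life_history_params(d_E0 = num("d_E0"), d_A0 = num("d_A0"),
                                r_0 = num("r_0"), b = num("b"),
                                n = num("n"))
  scen_line <- grep("^# scenarios:", meta, value = TRUE)
  scenarios <- strsplit(sub("^# scenarios: ", "", scen_line), ",")[[1]]
  new_sweep_table(df, grid = sort(unique(df$value)),
                  regime = investment_regime(kind, per_trait_level = level,
                                             budget = budget),
                  params = params, scenarios = scenarios)
}

#' Write a fitness surface to CSV
#'
#' Columns `c,m,scenario,W`, with the same metadata header convention as
#' [write_sweep_csv()].
#'
#' @param surface A `fitness_surface` from [fitness_surface()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_surface_csv <- function(surface, file) {
  stopifnot(inherits(surface, "fitness_surface"))
  params <- attr(surface, "fixed_params")
  header <- c(
    sprintf("# carescape fitness surface (package version %s)",
            as.character(utils::packageVersion("carescape"))),
    sprintf("# fixed params: d_E0=%g d_A0=%g r_0=%g b=%g n=%d",
            params$d_E0, params$d_A0, params$r_0, params$b, params$n)
  )
  con <- file(file, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(as.data.frame(surface)[, c("c", "m", "scenario", "W")],
                   con, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a run configuration
#'
#' Reads a YAML configuration with optional sections `params` (fields of
#' [life_history_params()]), `regime` (fields of [investment_regime()]), and
#' `sweep` (`parameter`, `range`, `grid_size`, `scenarios`), plus top-level
#' `seed` and `outdir`. Unknown keys are rejected so typos fail loudly.
#' Values in `overrides` (e.g. parsed CLI flags) take precedence over the
#' file.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @param overrides Named list overriding config values; names use the same
#'   nesting, e.g. `list(params = list(d_E0 = 0.9))`.
#' @return A `run_config`: list with validated `params`, `regime`, `sweep`,
#'   `seed`, `outdir`.
#' @examples
#' cfg <- run_config()
#' cfg$params$b
#' @export
run_config <- function(path = NULL, overrides = list()) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("config file not found: ", path, call. = FALSE)
    }
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
  }
  known <- c("params", "regime", "sweep", "seed", "outdir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s) in ", if (is.null(path)) "config" else path,
         ": ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  raw <- modify_nested(raw, overrides)
  param_args <- as.list(raw$params)
  # YAML 1.1 reads a bare `n:` key as boolean FALSE; map it back
  names(param_args)[names(param_args) == "FALSE"] <- "n"
  params <- do.call(life_history_params, param_args)
  regime_args <- as.list(raw$regime)
  regime <- if (length(regime_args)) {
    do.call(investment_regime, regime_args)
  } else {
    investment_regime("unconstrained")
  }
  sweep <- as.list(raw$sweep)
  structure(
    list(params = params, regime = regime, sweep = sweep,
         seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
         outdir = if (is.null(raw$outdir)) "." else raw$outdir),
    class = "run_config"
  )
}

modify_nested <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_nested(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}
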