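#' Regenerate a reference figure panel
#'
#' Rebuilds the data behind one of the twelve reference panels and writes it
#' as CSV (always) and, when ggplot2 is available and `plot = TRUE`, a PNG.
#' Panel ids and their contents:
#'
#' | id | contents |
#' |----|----------|
#' | `1a`/`1b` | `d_E0` sweep, unconstrained / constrained (log-fitness axis) |
#' | `2a`/`2b` | `r_0` sweep, unconstrained / constrained |
#' | `3a`/`3b` | `b` sweep on `[1, 200]`, unconstrained / constrained |
#' | `4a`/`4b` | `d_A0` sweep, unconstrained / constrained |
#' | `5` | fitness vs additional care `c`, all scenarios, `m = 0.5` |
#' | `6` | fitness vs mating trait `m`, S3 and S4, `c = 0.5` |
#' | `7a`/`7b` | `(c, m)` fitness surface for S3 / S4 |
#'
#' All panels use the reference parameter set `d_E0 = d_A0 = r_0 = 0.5`,
#' `b = 100`, `n = 5` for whatever is not on an axis.
#'
#' @param figure_id One of `"1a"`, `"1b"`, `"2a"`, `"2b"`, `"3a"`, `"3b"`,
#'   `"4a"`, `"4b"`, `"5"`, `"6"`, `"7a"`, `"7b"`.
#' @param outdir Output directory (created if missing).
#' @param grid_size Grid resolution for sweeps and curves.
#' @param plot Also write a PNG plot? Requires ggplot2; silently skipped
#'   when the package is unavailable.
#' @return Invisibly, a list with the `table` and the paths written.
#' @examples
#' out <- reproduce_figure("1a", outdir = tempdir(), grid_size = 11,
#'                         plot = FALSE)
#' head(out$table)
#' @export
reproduce_figure <- function(figure_id, outdir = ".", grid_size = 99,
                             plot = TRUE) {
  valid <- c("1a", "1b", "2a", "2b", "3a", "3b", "4a", "4b", "5", "6",
             "7a", "7b")
  figure_id <- as.character(figure_id)
  if (!figure_id %in% valid) {
    stop("unknown figure id '", figure_id, "'; valid ids: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  params <- life_history_params()
  regime <- if (grepl("b$", figure_id)) "constrained" else "unconstrained"
  panel_param <- c(`1` = "d_E0", `2` = "r_0", `3` = "b", `4` = "d_A0")
  base <- substr(figure_id, 1, 1)

  is_surface <- base == "7"
  table <- if (base %in% names(panel_param)) {
    sweep_fitness(panel_param[[base]], grid_size = grid_size,
                  regime = regime, params = params)
  } else if (figure_id == "5") {
    investment_curve("c", grid_size = grid_size, other_level = 0.5,
                     params = params)
  } else if (figure_id == "6") {
    investment_curve("m", grid_size = grid_size, other_level = 0.5,
                     params = params)
  } else {
    fitness_surface(if (figure_id == "7a") "S3" else "S4", params = params)
  }

  csv <- file.path(outdir, paste0("figure_", figure_id, ".csv"))
  if (is_surface) {
    write_surface_csv(table, csv)
  } else {
    write_sweep_csv(table, csv)
  }

  png_path <- NULL
  if (plot && requireNamespace("ggplot2", quietly = TRUE)) {
    png_path <- file.path(outdir, paste0("figure_", figure_id, ".png"))
    p <- plot_panel(table, figure_id, is_surface)
    ggplot2::ggsave(png_path, p, width = 6, height = 4.5, dpi = 120)
  }
  invisible(list(table = table, csv = csv, png = png_path))
}

plot_panel <- function(table, figure_id, is_surface) {
  df <- as.data.frame(table)
  if (is_surface) {
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$c, y = .data$m,
                                       fill = .data$W)) +
        ggplot2::geom_raster() +
        ggplot2::labs(title = paste("Fitness surface,", df$scenario[1]),
                      x = "additional care (c)", y = "mating trait (m)",
                      fill = "W") +
        ggplot2::theme_minimal()
    )
  }
  log_axis <- figure_id %in% c("1a", "1b")
  df$y <- if (log_axis) df$logW else df$W
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$y,
                                   colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = df$parameter[1],
                  y = if (log_axis) "log lifetime fitness" else
                    "lifetime fitness (W)",
                  colour = "scenario",
                  title = sprintf("Panel %s (%s regime)", figure_id,
                                  df$regime[1])) +
    ggplot2::theme_minimal()
}

#' Run a configured analysis end to end
#'
#' Executes the sweep described by a [run_config()] — parameter, range, grid
#' size, scenarios, regime — writes the sweep CSV and its crossover table to
#' the configured output directory, and logs what was done to standard error.
#'
#' @param config A `run_config` from [run_config()], or a path to a YAML
#'   config file.
#' @param overrides Named list of overrides applied on top of the file (CLI
#'   flags win over config values).
#' @return Invisibly, a list with the sweep table, crossovers, and output
#'   paths.
#' @export
run_analysis <- function(config = run_config(), overrides = list()) {
  if (is.character(config)) {
    config <- run_config(config, overrides)
  }
  stopifnot(inherits(config, "run_config"))
  sw_args <- config$sweep
  parameter <- if (is.null(sw_args$parameter)) "d_E0" else sw_args$parameter
  sw <- sweep_fitness(
    parameter,
    range = sw_args$range,
    grid_size = if (is.null(sw_args$grid_size)) 99 else sw_args$grid_size,
    scenarios = if (is.null(sw_args$scenarios)) c("S1", "S2", "S3", "S4")
                else sw_args$scenarios,
    regime = config$regime, params = config$params
  )
  if (!dir.exists(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE)
  }
  sweep_path <- file.path(config$outdir, paste0("sweep_", parameter, ".csv"))
  write_sweep_csv(sw, sweep_path)
  cx <- find_crossovers(sw)
  cx_path <- file.path(config$outdir,
                       paste0("crossovers_", parameter, ".csv"))
  utils::write.csv(as.data.frame(cx), cx_path, row.names = FALSE)
  message(sprintf("[carescape] %s sweep (%d points, %s regime) -> %s; %d crossover(s) -> %s",
                  parameter, length(attr(sw, "grid")),
                  attr(sw, "regime")$kind, sweep_path, nrow(cx), cx_path))
  invisible(list(sweep = sw, crossovers = cx,
                 paths = c(sweep = sweep_path, crossovers = cx_path)))
}
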