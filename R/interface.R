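## Command-line front end and flat serialization of results.
##
## The CLI is a thin dispatcher over the package functions; a launcher
## script is installed under inst/cli/cvm2d.R.

#' Flatten configuration fractions (and optional thermodynamics) to a row
#'
#' Fixed field order: x1, x2, y1, y2, y3, w1, w2, w3, z1..z6, N, then the
#' thermodynamic fields when present.
#'
#' @param fr A `cvm_fractions` object.
#' @param thermo Optional `cvm_thermo` object.
#' @return A one-row data frame.
#' @export
fractions_record <- function(fr, thermo = NULL) {
  rec <- as.data.frame(fr)
  names(rec)[names(rec) == "n_units"] <- "N"
  if (!is.null(thermo)) rec <- cbind(rec, as.data.frame(thermo))
  rec
}

.cli_fail <- function(msg) {
  message("cvm2d: ", msg)
  1L
}

.parse_cli <- function(args) {
  opts <- list(); pos <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1L], "--"))
        stop(sprintf("option --%s needs a value", key), call. = FALSE)
      opts[[gsub("-", "_", key)]] <- args[i + 1L]
      i <- i + 2L
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(pos = pos, opts = opts)
}

.opt <- function(p, name, default = NULL, as = identity) {
  if (!is.null(p$opts[[name]])) as(p$opts[[name]]) else default
}

.write_table <- function(df, out, digits = 6) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = digits)
  if (is.null(out)) {
    write.csv(df, row.names = FALSE)
  } else if (grepl("\\.json$", out)) {
    jsonlite::write_json(df, out, auto_unbox = FALSE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  } else {
    write.csv(df, out, row.names = FALSE)
  }
  invisible(df)
}

#' Command-line entry point
#'
#' Dispatches one of the subcommands `generate`, `count`, `thermo`,
#' `analytic`, `minimize`, `sweep`, or `render`. Every stochastic
#' subcommand takes a `--seed` and records it in its output. User errors
#' produce a one-line diagnostic and a nonzero status, never a traceback.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments when run via the installed launcher script).
#' @return Integer exit status, invisibly (0 on success).
#' @examples
#' \dontrun{
#' cvm_cli(c("analytic", "--h-min", "0.8", "--h-max", "1.8",
#'           "--h-step", "0.1"))
#' }
#' @export
cvm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0L)
      stop("usage: cvm2d <generate|count|thermo|analytic|minimize|sweep|render> [options]",
           call. = FALSE)
    cmd <- args[1L]
    p <- .parse_cli(args[-1L])
    switch(cmd,
      generate = .cli_generate(p),
      count = .cli_count(p),
      thermo = .cli_thermo(p),
      analytic = .cli_analytic(p),
      minimize = .cli_minimize(p),
      sweep = .cli_sweep(p),
      render = .cli_render(p),
      stop(sprintf("unknown subcommand %s", dQuote(cmd)), call. = FALSE)
    )
    0L
  }, error = function(e) .cli_fail(conditionMessage(e)))
  invisible(status)
}

.cli_generate <- function(p) {
  kind <- .opt(p, "kind", "random")
  rows <- .opt(p, "rows", 16L, as.integer)
  cols <- .opt(p, "cols", 16L, as.integer)
  seed <- .opt(p, "seed", NULL, as.integer)
  x1 <- .opt(p, "x1", 0.5, as.numeric)
  g <- switch(kind,
    random = generate_random(rows, cols, x1, seed = seed),
    rich_club = generate_rich_club(rows, cols),
    scale_free = generate_scale_free(rows, cols, seed = seed),
    stop(sprintf("unknown pattern kind %s", dQuote(kind)), call. = FALSE))
  out <- .opt(p, "out")
  if (is.null(out)) stop("generate needs --out <gridfile>", call. = FALSE)
  write_grid(g, out)
  message(sprintf("wrote %s pattern (%d x %d, %d A-units, seed %s) to %s",
                  kind, rows, cols, a_count(g),
                  if (is.null(seed)) "none" else seed, out))
}

.cli_count <- function(p) {
  if (length(p$pos) != 1L) stop("count needs a grid file", call. = FALSE)
  g <- read_grid(p$pos)
  .write_table(fractions_record(grid_fractions(g)), .opt(p, "out"))
}

.cli_thermo <- function(p) {
  if (length(p$pos) != 1L) stop("thermo needs a grid file", call. = FALSE)
  g <- read_grid(p$pos)
  eps0 <- .opt(p, "eps0", 0, as.numeric)
  h <- .opt(p, "h", NULL, as.numeric)
  eps1 <- if (!is.null(h)) eps1_from_h(h) else .opt(p, "eps1", 0, as.numeric)
  variant <- .opt(p, "variant", "standard")
  fr <- grid_fractions(g)
  th <- free_energy(fr, eps0, eps1, variant)
  .write_table(fractions_record(fr, th), .opt(p, "out"))
}

.cli_analytic <- function(p) {
  h_min <- .opt(p, "h_min", 0.8, as.numeric)
  h_max <- .opt(p, "h_max", 1.8, as.numeric)
  h_step <- .opt(p, "h_step", 0.1, as.numeric)
  hs <- seq(h_min, h_max, by = h_step)
  rows <- lapply(hs, function(h) {
    eq <- analytic_equilibrium(h)
    th <- free_energy(eq$fractions, 0, eps1_from_h(h))
    cbind(data.frame(h = h, delta = eq$delta),
          fractions_record(eq$fractions, th))
  })
  .write_table(do.call(rbind, rows), .opt(p, "out"))
}

.cli_minimize <- function(p) {
  if (length(p$pos) != 1L) stop("minimize needs a grid file", call. = FALSE)
  g <- read_grid(p$pos)
  cfg <- minimization_config(
    h = .opt(p, "h", NULL, as.numeric) %||%
      h_from_eps1(.opt(p, "eps1", 0.25, as.numeric)),
    eps0 = .opt(p, "eps0", 0, as.numeric),
    max_accepted_swaps = .opt(p, "max_swaps", 100L, as.integer),
    max_attempts = .opt(p, "max_attempts", 10000L, as.integer),
    f_tolerance = .opt(p, "f_tolerance", 0, as.numeric),
    stall_attempts = .opt(p, "stall_attempts", 500L, as.integer),
    seed = .opt(p, "seed", NULL, as.integer),
    enthalpy_variant = .opt(p, "variant", "standard"))
  res <- minimize_free_energy(g, cfg)
  out_grid <- .opt(p, "out_grid")
  if (!is.null(out_grid)) write_grid(res$grid, out_grid)
  trace_path <- .opt(p, "trace")
  if (!is.null(trace_path)) write.csv(res$trace, trace_path, row.names = FALSE)
  summary_path <- .opt(p, "summary")
  summary <- list(
    config = cfg[c("h", "eps0", "max_accepted_swaps", "max_attempts",
                   "f_tolerance", "stall_attempts", "seed",
                   "enthalpy_variant")],
    attempts = nrow(res$trace), accepted = res$accepted,
    termination = res$termination,
    initial = unclass(res$initial), final = unclass(res$final),
    fractions = as.data.frame(res$fractions))
  if (!is.null(summary_path))
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  message(sprintf("%d/%d swaps accepted (%s); F %.6f -> %.6f",
                  res$accepted, nrow(res$trace), res$termination,
                  res$initial$fbar, res$final$fbar))
}

.cli_sweep <- function(p) {
  hs <- seq(.opt(p, "h_min", 0.8, as.numeric),
            .opt(p, "h_max", 1.8, as.numeric),
            by = .opt(p, "h_step", 0.1, as.numeric))
  tab <- sweep_h(hs,
                 n_trials = .opt(p, "trials", 10L, as.integer),
                 n_rows = .opt(p, "rows", 16L, as.integer),
                 n_cols = .opt(p, "cols", 16L, as.integer),
                 seed = .opt(p, "seed", NULL, as.integer),
                 summarize = !is.null(p$opts$summarize) &&
                   .opt(p, "summarize", "false") == "true")
  tab$seed <- .opt(p, "seed", NA_integer_, as.integer)
  .write_table(tab, .opt(p, "out"))
}

.cli_render <- function(p) {
  if (length(p$pos) != 1L) stop("render needs a grid file", call. = FALSE)
  g <- read_grid(p$pos)
  style <- .opt(p, "style", "text")
  if (style == "text") {
    cat(render_grid(g, "text"), sep = "\n")
  } else {
    out <- .opt(p, "out")
    if (is.null(out)) stop("render --style image needs --out <png>",
                           call. = FALSE)
    render_grid(g, "image", file = out,
                cell = .opt(p, "cell", 8L, as.integer))
    message("wrote ", out)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
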