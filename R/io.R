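# Readers and writers for the tabular plain-text formats used by the
# pipeline, plus the static control-vs-query fitness plot.

timecourse_columns <- c("barcode", "row", "col", "gene", "background",
                        "temperature", "expt_time_days", "density")

check_timecourse_columns <- function(data) {
  missing <- setdiff(timecourse_columns, names(data))
  if (length(missing) > 0) {
    abort(sprintf("missing required column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "qfascreen_error_schema")
  }
  invisible(TRUE)
}

#' Read a colony-density time-course table
#'
#' Reads the tab-separated time-course format produced downstream of colony
#' image analysis: one row per (culture, timepoint) with columns `barcode`,
#' `row`, `col`, `gene`, `background`, `temperature`, `expt_time_days`,
#' `density` (header required, UTF-8). Rows with non-numeric or negative
#' density, non-numeric or negative time, or missing fields are rejected;
#' their file line numbers are reported in a message and attached as
#' attribute `rejected_lines`. Observations are sorted by time within each
#' culture, so row order in the file does not matter.
#'
#' @param path Path to the TSV file.
#' @return A tibble in the time-course schema.
#' @export
read_timecourses <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_timecourse_columns(raw)
  num <- suppressWarnings(tibble(
    row = as.integer(raw$row),
    col = as.integer(raw$col),
    temperature = as.numeric(raw$temperature),
    expt_time_days = as.numeric(raw$expt_time_days),
    density = as.numeric(raw$density)
  ))
  bad <- !stats::complete.cases(num) | num$density < 0 | num$expt_time_days < 0 |
    is.na(raw$barcode) | is.na(raw$gene) | is.na(raw$background)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    lines <- which(bad) + 1L  # +1 for the header line
    inform(sprintf("rejected %d malformed row(s) at line(s): %s", sum(bad),
                   paste(utils::head(lines, 20), collapse = ", ")))
  }
  out <- tibble(
    barcode = raw$barcode, row = num$row, col = num$col, gene = raw$gene,
    background = raw$background, temperature = num$temperature,
    expt_time_days = num$expt_time_days, density = num$density
  )[!bad, ]
  out <- arrange(out, .data$barcode, .data$row, .data$col, .data$expt_time_days)
  attr(out, "rejected_lines") <- which(bad) + 1L
  out
}

#' Write a time-course table
#'
#' @param data A tibble in the time-course schema.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_timecourses <- function(data, path) {
  check_timecourse_columns(data)
  readr::write_tsv(data[timecourse_columns], path)
  invisible(path)
}

#' Write / read a per-culture fitness table
#'
#' Tab-separated, one row per culture: `culture_id`, `barcode`, `row`, `col`,
#' `gene`, `background`, `temperature`, `n_obs`, `r`, `K`, `nu`, `rss`,
#' `converged`, `never_doubles`, `mdr`, `mdp`, `fitness`.
#'
#' @param fitness A [fit_growth()] result.
#' @param path File path.
#' @return `write_fitness()` returns `path` invisibly; `read_fitness()`
#'   returns the fitness tibble.
#' @export
write_fitness <- function(fitness, path) {
  readr::write_tsv(as_tibble(fitness), path)
  invisible(path)
}

#' @rdname write_fitness
#' @export
read_fitness <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    barcode = readr::col_character(), gene = readr::col_character(),
    background = readr::col_character(), culture_id = readr::col_character(),
    converged = readr::col_logical(), never_doubles = readr::col_logical(),
    row = readr::col_integer(), col = readr::col_integer(),
    n_obs = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE)
}

#' Write / read a genetic interaction strength report
#'
#' Tab-separated `.gis.txt` dialect: columns `gene`, `n_control`, `n_query`,
#' `control_mean`, `query_mean_obs`, `query_mean_pred`, `gis`, `p`, `q`,
#' `call` — one file per (query screen, temperature).
#'
#' @param gis A [test_interactions()] result.
#' @param path File path (conventionally ending in `.gis.txt`).
#' @return `write_gis()` returns `path` invisibly; `read_gis()` the tibble.
#' @export
write_gis <- function(gis, path) {
  readr::write_tsv(as_tibble(gis), path)
  invisible(path)
}

#' @rdname write_gis
#' @export
read_gis <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), call = readr::col_character(),
    n_control = readr::col_integer(), n_query = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE)
}

#' Write / read a wide fitness-profile table
#'
#' @param profiles A [build_profiles()] result (gene x screens).
#' @param path File path.
#' @return `write_profiles()` returns `path` invisibly; `read_profiles()` the
#'   `qfa_profiles` tibble.
#' @export
write_profiles <- function(profiles, path) {
  readr::write_tsv(as_tibble(profiles), path)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  wide <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  structure(wide, class = c("qfa_profiles", class(wide)),
            screens = setdiff(names(wide), "gene"))
}

#' Read gene loci from a 4-column TSV or a GFF3 file
#'
#' The TSV dialect has columns `gene`, `chromosome`, `start`, `end`
#' (1-based inclusive bp). GFF3 input (extensions `.gff`/`.gff3`) is parsed
#' with \pkg{rtracklayer}, keeping `gene`-type records and using their `Name`
#' (falling back to `ID`) as the gene identifier.
#'
#' @param path File path.
#' @return A tibble `gene`, `chromosome`, `start`, `end`.
#' @export
read_gene_loci <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GFF3 requires the rtracklayer package",
            class = "qfascreen_error_io")
    }
    gr <- rtracklayer::import(path)
    df <- as.data.frame(gr[gr$type == "gene"])
    nm <- if ("Name" %in% names(df)) as.character(df$Name) else as.character(df$ID)
    if ("ID" %in% names(df)) nm[is.na(nm)] <- as.character(df$ID)[is.na(nm)]
    return(tibble(
      gene = nm,
      chromosome = as.character(df$seqnames),
      start = df$start,
      end = df$end
    ))
  }
  loci <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), chromosome = readr::col_character(),
    start = readr::col_double(), end = readr::col_double()
  ), progress = FALSE)
  if (!all(c("gene", "chromosome", "start", "end") %in% names(loci))) {
    abort("locus TSV needs columns gene, chromosome, start, end",
          class = "qfascreen_error_schema")
  }
  if (any(loci$start > loci$end)) {
    abort("locus intervals must satisfy start <= end",
          class = "qfascreen_error_schema")
  }
  loci
}

#' Read an exclusion list (one gene per line)
#'
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return A character vector of gene names.
#' @export
read_exclusions <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Control-vs-query fitness plot
#'
#' The classic screen summary: one point per gene at (mean control fitness,
#' mean query fitness), the solid grey through-origin regression line of the
#' multiplicative model, the dashed line of equal fitness, negative
#' interactors as red inverted triangles, positive as blue triangles, and the
#' class counts annotated across the top.
#'
#' @param object A [test_interactions()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qfa_gis <- function(object, ...) {
  m <- attr(object, "m")
  counts <- table(factor(object$call, levels = c("negative", "none", "positive")))
  pal <- c(negative = "red3", none = "grey55", positive = "blue3")
  shp <- c(negative = 25, none = 16, positive = 24)
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$control_mean, y = .data$query_mean_obs,
                               colour = .data$call, shape = .data$call,
                               fill = .data$call)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey30") +
    ggplot2::geom_abline(slope = m, intercept = 0, colour = "grey60",
                         linewidth = 0.8) +
    ggplot2::geom_point(size = 1.4, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = pal) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::scale_shape_manual(values = shp) +
    ggplot2::labs(
      x = "control fitness (mean)", y = "query fitness (mean)",
      subtitle = sprintf("n = %d   negative: %d   positive: %d   slope m = %.3f",
                         nrow(object), counts[["negative"]],
                         counts[["positive"]], m)
    ) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none")
}

#' Render the control-vs-query fitness plot to an image file
#'
#' @param gis A [test_interactions()] result.
#' @param path Output image path (`.png` or `.svg`).
#' @param width,height Plot size in inches.
#' @return Invisibly, `path` (or `NULL` for empty input, with a warning).
#' @export
render_fitness_plot <- function(gis, path, width = 6, height = 6) {
  if (nrow(gis) == 0) {
    warn("no genes to plot; nothing written")
    return(invisible(NULL))
  }
  p <- autoplot(gis)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}
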