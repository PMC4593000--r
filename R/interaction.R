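# Genetic interaction strength (GIS) estimation of a query screen against a
# control screen under Fisher's multiplicative model of genetic independence.
#
# The model: mean query fitness across the library is proportional to mean
# control fitness, query ~ m * control, with slope m estimated by
# through-origin least squares over all strains (assuming most strains do not
# interact). Per gene, predicted query replicate fitnesses are m times the
# observed control replicate fitnesses; an unpaired two-tailed Welch t-test
# compares observed and predicted, p-values are FDR-adjusted over the tested
# genes (Benjamini-Hochberg) and interactions with q below the threshold are
# called negative or positive by the sign of GIS = observed - predicted mean.

#' Summarise replicate fitnesses per strain
#'
#' Collapses a per-culture fitness table to one row per gene, keeping the
#' replicate fitness values (as a list-column) and their arithmetic mean.
#' Non-finite fitness values are dropped before averaging; genes left with no
#' finite replicate are excluded, with a warning.
#'
#' @param data A data frame with columns `gene` and `fitness` (e.g. a
#'   [fit_growth()] result). A `background` column, if present, is carried
#'   through (it must be constant within the table).
#' @return A tibble with columns `gene`, (`background`,) `n`, `fitnesses`
#'   (list-column of replicate fitness values) and `mean_fitness`.
#' @examples
#' summarize_screen(data.frame(gene = c("A", "A", "B"), fitness = c(1, 2, 7)))
#' @export
summarize_screen <- function(data) {
  if (!all(c("gene", "fitness") %in% names(data))) {
    abort("`data` must have columns `gene` and `fitness`",
          class = "qfascreen_error_schema")
  }
  genes_before <- unique(data$gene)
  n_bad <- sum(!is.finite(data$fitness))
  if (n_bad > 0) {
    warn(sprintf("dropping %d non-finite fitness value(s)", n_bad))
    data <- data[is.finite(data$fitness), , drop = FALSE]
  }
  emptied <- setdiff(genes_before, unique(data$gene))
  if (length(emptied) > 0) {
    warn(sprintf("excluding %d gene(s) with no finite replicate fitness",
                 length(emptied)))
  }
  bg <- if ("background" %in% names(data)) unique(data$background) else NULL
  if (length(bg) > 1) {
    abort("`background` must be constant within one screen",
          class = "qfascreen_error_schema")
  }
  out <- as_tibble(data) %>%
    group_by(.data$gene) %>%
    summarise(n = dplyr::n(), fitnesses = list(.data$fitness),
              mean_fitness = mean(.data$fitness), .groups = "drop")
  if (!is.null(bg)) out <- mutate(out, background = bg, .after = "gene")
  out
}

#' Through-origin slope of the multiplicative model
#'
#' Estimates the slope `m` of the no-intercept regression of mean query
#' fitness on mean control fitness across the library,
#' `m = sum(c_i q_i) / sum(c_i^2)` — the least-squares solution of
#' `query = m * control`. Valid under the assumption that most strains do
#' not interact with the query background.
#'
#' @param control,query Strain summaries from [summarize_screen()] for the
#'   control and query screens; matched by `gene`.
#' @return The slope `m` (a single number).
#' @examples
#' ctl <- summarize_screen(data.frame(gene = c("A", "B"), fitness = c(1, 2)))
#' qry <- summarize_screen(data.frame(gene = c("A", "B"), fitness = c(0.5, 1)))
#' estimate_slope(ctl, qry)
#' @export
estimate_slope <- function(control, query) {
  paired <- inner_join(
    select(control, "gene", control_mean = "mean_fitness"),
    select(query, "gene", query_mean = "mean_fitness"),
    by = "gene"
  )
  if (nrow(paired) < 2) {
    abort("need at least 2 genes shared between screens to estimate the slope",
          class = "qfascreen_error_params")
  }
  if (all(paired$control_mean == 0)) {
    abort("slope undefined: all control means are zero",
          class = "qfascreen_error_params")
  }
  sum(paired$control_mean * paired$query_mean) / sum(paired$control_mean^2)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a p-value vector: `q_(i) = min_(j>=i) p_(j) n/j`,
#' capped at 1 and mapped back to input order. `NA` entries are propagated and
#' do not count towards the adjustment denominator.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return The vector of q-values, same length and order as `p`.
#' @examples
#' adjust_fdr(c(0.001, 0.5))
#' @export
adjust_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1]", class = "qfascreen_error_params")
  }
  p.adjust(p, method = "BH")
}

welch_p <- function(x, y) {
  tryCatch(t.test(x, y, alternative = "two.sided", var.equal = FALSE)$p.value,
           error = function(e) NA_real_)
}

#' Test every gene for genetic interaction with the query background
#'
#' For each gene present in both screens, predicted query fitnesses are
#' `m` times each observed control replicate fitness, and an unpaired
#' two-tailed Welch t-test compares the observed query replicates with the
#' predictions. p-values are collected over all testable genes (at least two
#' replicates on each side) and Benjamini-Hochberg adjusted; genes with fewer
#' replicates are reported with `p = q = NA` and `call = "none"` and do not
#' enter the FDR denominator. Genetic interaction strength is
#' `GIS = mean(observed query) - mean(predicted query)` under the default sign
#' convention, so negative GIS means the strain grew more poorly than the
#' multiplicative model predicts.
#'
#' @param control,query Strain summaries from [summarize_screen()].
#' @param m Slope of the multiplicative model; `NULL` (default) estimates it
#'   from the supplied summaries via [estimate_slope()].
#' @param q_threshold Significance threshold on the FDR-adjusted q-value
#'   (default 0.05).
#' @param sign Sign convention for GIS: `"obs_minus_pred"` (default) or the
#'   reversed `"pred_minus_obs"`. Calls always label strains growing worse
#'   than predicted as `"negative"`, whichever convention is reported.
#' @return A tibble of class `qfa_gis` with one row per shared gene:
#'   `gene`, `n_control`, `n_query`, `control_mean`, `query_mean_obs`,
#'   `query_mean_pred`, `gis`, `p`, `q`, `call`. The slope, threshold and sign
#'   convention are attached as attributes.
#' @export
test_interactions <- function(control, query, m = NULL, q_threshold = 0.05,
                              sign = c("obs_minus_pred", "pred_minus_obs")) {
  sign <- match.arg(sign)
  stopifnot(q_threshold > 0, q_threshold < 1)
  if (is.null(m)) m <- estimate_slope(control, query)
  if (!is.finite(m)) {
    abort("`m` must be finite", class = "qfascreen_error_params")
  }

  paired <- inner_join(
    select(control, "gene", n_control = "n", control_reps = "fitnesses",
           control_mean = "mean_fitness"),
    select(query, "gene", n_query = "n", query_reps = "fitnesses",
           query_mean_obs = "mean_fitness"),
    by = "gene"
  )
  testable <- paired$n_control >= 2 & paired$n_query >= 2
  p <- rep(NA_real_, nrow(paired))
  p[testable] <- purrr::map2_dbl(
    paired$query_reps[testable], paired$control_reps[testable],
    function(obs, ctl) welch_p(obs, m * ctl)
  )
  q <- adjust_fdr(p)

  out <- paired %>%
    mutate(
      query_mean_pred = m * .data$control_mean,
      gis_obs = .data$query_mean_obs - .data$query_mean_pred,
      p = p, q = q,
      call = dplyr::case_when(
        !is.na(q) & q < q_threshold & .data$gis_obs < 0 ~ "negative",
        !is.na(q) & q < q_threshold & .data$gis_obs > 0 ~ "positive",
        TRUE ~ "none"
      ),
      gis = if (sign == "obs_minus_pred") .data$gis_obs else -.data$gis_obs
    ) %>%
    select("gene", "n_control", "n_query", "control_mean", "query_mean_obs",
           "query_mean_pred", "gis", "p", "q", "call")

  structure(out, class = c("qfa_gis", class(out)),
            m = m, q_threshold = q_threshold, sign = sign)
}

#' @export
tidy.qfa_gis <- function(x, ...) as_tibble(x)

#' @export
glance.qfa_gis <- function(x, ...) {
  tibble(
    m = attr(x, "m"),
    q_threshold = attr(x, "q_threshold"),
    n_genes = nrow(x),
    n_tested = sum(!is.na(x$p)),
    n_negative = sum(x$call == "negative"),
    n_positive = sum(x$call == "positive")
  )
}

#' Strip genes linked to the query locus or on an exclusion list
#'
#' Library genes genetically linked to a query mutation are over-represented
#' among apparent interactors because double mutants close to the query locus
#' are depleted after meiosis. Genes on the same chromosome as any query locus
#' whose interval lies within `window` base pairs (gap distance between
#' intervals, inclusive at exactly `window`) are removed, as are genes on the
#' explicit exclusion list (e.g. strains that failed the array procedure).
#' Genes absent from the locus table cannot be distance-checked and are
#' retained, with a message. The operation is idempotent.
#'
#' @param summaries A strain-summary tibble (any table with a `gene` column).
#' @param loci Gene coordinates: columns `gene`, `chromosome`, `start`, `end`
#'   (1-based inclusive bp); see [read_gene_loci()].
#' @param query_loci Coordinates of the query mutation(s), same columns
#'   (the `gene` column is optional).
#' @param window Linkage window in bp (default 20000).
#' @param exclusions Character vector of gene names to drop unconditionally.
#' @return `summaries` with linked and excluded genes removed; the numbers
#'   removed are attached as attribute `stripping` and reported via a message.
#' @export
strip_genes <- function(summaries, loci, query_loci, window = 20000,
                        exclusions = character()) {
  stopifnot(window >= 0)
  for (tb in list(loci, query_loci)) {
    if (!all(c("chromosome", "start", "end") %in% names(tb))) {
      abort("loci tables need columns `chromosome`, `start`, `end`",
            class = "qfascreen_error_schema")
    }
  }
  linked <- loci %>%
    filter(.data$gene %in% summaries$gene) %>%
    inner_join(select(query_loci, "chromosome", q_start = "start",
                      q_end = "end"),
               by = "chromosome", relationship = "many-to-many") %>%
    mutate(gap = pmax(pmax(.data$start, .data$q_start) -
                        pmin(.data$end, .data$q_end), 0)) %>%
    filter(.data$gap <= window) %>%
    pull("gene") %>%
    unique()

  missing_loci <- setdiff(setdiff(summaries$gene, loci$gene), exclusions)
  if (length(missing_loci) > 0) {
    inform(sprintf(
      "%d gene(s) missing from the locus table were retained (distance unknown)",
      length(missing_loci)))
  }
  drop <- union(linked, intersect(summaries$gene, exclusions))
  out <- filter(summaries, !(.data$gene %in% drop))
  inform(sprintf("stripped %d linked and %d excluded gene(s); %d retained",
                 length(linked), length(intersect(summaries$gene, exclusions)),
                 nrow(out)))
  attr(out, "stripping") <- list(linked = linked,
                                 excluded = intersect(summaries$gene, exclusions),
                                 missing_loci = missing_loci)
  out
}

#' Control-vs-query interaction analysis in one call
#'
#' Convenience wrapper chaining [summarize_screen()], optional
#' [strip_genes()], [estimate_slope()] and [test_interactions()]. The slope of
#' the multiplicative model is estimated after stripping (configurable), so
#' linked genes do not bias it.
#'
#' @param control_fitness,query_fitness Per-culture fitness tables
#'   ([fit_growth()] output, or any table with `gene` and `fitness`).
#' @param loci,query_loci,exclusions,window Passed to [strip_genes()];
#'   stripping is skipped when `loci` or `query_loci` is `NULL`.
#' @param slope_after_stripping Estimate `m` after stripping (default TRUE).
#' @inheritParams test_interactions
#' @return A `qfa_gis` tibble (see [test_interactions()]).
#' @export
screen_gis <- function(control_fitness, query_fitness,
                       loci = NULL, query_loci = NULL,
                       exclusions = character(), window = 20000,
                       q_threshold = 0.05,
                       sign = c("obs_minus_pred", "pred_minus_obs"),
                       slope_after_stripping = TRUE) {
  sign <- match.arg(sign)
  ctl <- summarize_screen(control_fitness)
  qry <- summarize_screen(query_fitness)
  m_pre <- if (!slope_after_stripping) estimate_slope(ctl, qry) else NULL
  if (!is.null(loci) && !is.null(query_loci)) {
    ctl <- strip_genes(ctl, loci, query_loci, window, exclusions)
    qry <- strip_genes(qry, loci, query_loci, window, exclusions)
  } else if (length(exclusions) > 0) {
    ctl <- filter(ctl, !(.data$gene %in% exclusions))
    qry <- filter(qry, !(.data$gene %in% exclusions))
  }
  m <- if (slope_after_stripping) estimate_slope(ctl, qry) else m_pre
  test_interactions(ctl, qry, m = m, q_threshold = q_threshold, sign = sign)
}
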