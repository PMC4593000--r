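# Fitness profiles across screens: per-gene vectors of summary fitness in
# several query backgrounds/conditions, Venn classification of significant
# interactors, and nearest-profile similarity search.

#' Build per-gene fitness profiles across screens
#'
#' Assembles one fitness profile per gene from several screens. Input is
#' either a named list of strain summaries (from [summarize_screen()]) or a
#' long tibble with columns `screen`, `gene`, `mean_fitness`. Genes absent
#' from a screen get `NA` in that screen.
#'
#' For distance computations the profiles are z-standardized per screen
#' (mean 0, unit variance across genes within each screen), making screens
#' with different overall fitness scales commensurable; the raw mean
#' fitnesses are what the profile table reports.
#'
#' @param x Named list of summary tibbles, or a long tibble
#'   (`screen`, `gene`, `mean_fitness`).
#' @return A wide tibble of class `qfa_profiles` (`gene` x screens), with the
#'   screen names in attribute `screens`.
#' @examples
#' ctl <- summarize_screen(data.frame(gene = c("A", "B"), fitness = c(1, 2)))
#' qry <- summarize_screen(data.frame(gene = c("A", "B"), fitness = c(2, 1)))
#' build_profiles(list(control = ctl, query = qry))
#' @export
build_profiles <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("screen", "gene", "mean_fitness") %in% names(x))) {
      abort("long input needs columns `screen`, `gene`, `mean_fitness`",
            class = "qfascreen_error_schema")
    }
    long <- as_tibble(x)[c("screen", "gene", "mean_fitness")]
  } else {
    if (is.null(names(x)) || any(names(x) == "") || anyDuplicated(names(x))) {
      abort("list input must have unique non-empty screen names",
            class = "qfascreen_error_schema")
    }
    long <- purrr::imap(x, function(tb, nm) {
      tibble(screen = nm, gene = tb$gene,
             mean_fitness = as.numeric(tb$mean_fitness))
    }) %>% bind_rows()
  }
  screens <- unique(long$screen)
  wide <- long %>%
    tidyr::pivot_wider(names_from = "screen", values_from = "mean_fitness") %>%
    arrange(.data$gene)
  structure(wide, class = c("qfa_profiles", class(wide)), screens = screens)
}

# per-screen z-scores (across genes); constant screens map to 0
profile_zscores <- function(profiles) {
  screens <- attr(profiles, "screens")
  z <- as_tibble(profiles)
  for (s in screens) {
    v <- z[[s]]
    mu <- mean(v, na.rm = TRUE)
    sig <- sd(v, na.rm = TRUE)
    z[[s]] <- if (!is.finite(sig) || sig == 0) ifelse(is.na(v), NA, 0) else (v - mu) / sig
  }
  z
}

#' Distance between two fitness profiles
#'
#' Euclidean distance over the per-screen z-standardized fitnesses of the two
#' genes, computed on the included screens where both genes have a value.
#' Symmetric; zero iff the genes agree on every included screen.
#'
#' @param profiles A [build_profiles()] result.
#' @param a,b Gene names.
#' @param screens Screens to include; `NULL` (default) uses all screens.
#' @return A single non-negative distance.
#' @export
profile_distance <- function(profiles, a, b, screens = NULL) {
  if (is.null(screens)) screens <- attr(profiles, "screens")
  bad <- setdiff(screens, attr(profiles, "screens"))
  if (length(bad) > 0) {
    abort(sprintf("unknown screen(s): %s", paste(bad, collapse = ", ")),
          class = "qfascreen_error_params")
  }
  z <- profile_zscores(profiles)
  za <- as.numeric(z[z$gene == a, screens])
  zb <- as.numeric(z[z$gene == b, screens])
  if (length(za) == 0 || length(zb) == 0) {
    abort("both genes must be present in the profile set",
          class = "qfascreen_error_params")
  }
  shared <- is.finite(za) & is.finite(zb)
  if (!any(shared)) {
    abort("distance undefined: the genes share no included screen",
          class = "qfascreen_error_params")
  }
  sqrt(sum((za[shared] - zb[shared])^2))
}

#' Rank genes by fitness-profile similarity to a query gene
#'
#' Finds the `k` genes whose z-standardized fitness profiles lie closest
#' (Euclidean distance) to the query gene's profile over the included screens.
#' Candidate genes with a missing value in any included screen are dropped
#' rather than imputed. Ties in distance are broken lexicographically by gene
#' name so the ranking is deterministic.
#'
#' @param profiles A [build_profiles()] result.
#' @param gene Query gene name (excluded from the ranking).
#' @param k Number of neighbours to return; if fewer candidates exist, all
#'   are returned with a message.
#' @param exclude_screens Screens to ignore when computing distances (e.g.
#'   the control screen).
#' @return A tibble `gene`, `distance`, `rank`, ascending by distance.
#' @export
nearest_profiles <- function(profiles, gene, k = 10, exclude_screens = NULL) {
  screens <- setdiff(attr(profiles, "screens"), exclude_screens)
  if (length(screens) == 0) {
    abort("no screens left after exclusion", class = "qfascreen_error_params")
  }
  z <- profile_zscores(profiles)
  if (!gene %in% z$gene) {
    abort(sprintf("query gene '%s' has no profile", gene),
          class = "qfascreen_error_params")
  }
  zq <- as.numeric(z[z$gene == gene, screens])
  if (any(!is.finite(zq))) {
    abort("query gene profile does not cover the included screens",
          class = "qfascreen_error_params")
  }
  zmat <- as.matrix(z[screens])
  complete <- rowSums(!is.finite(zmat)) == 0 & z$gene != gene
  cand <- z$gene[complete]
  d <- sqrt(colSums((t(zmat[complete, , drop = FALSE]) - zq)^2))
  ord <- order(d, cand)
  if (k > length(cand)) {
    inform(sprintf("only %d candidate gene(s) available; returning all",
                   length(cand)))
    k <- length(cand)
  }
  keep <- ord[seq_len(k)]
  tibble(gene = cand[keep], distance = unname(d[keep]), rank = seq_len(k))
}

#' Classify genes into Venn areas by screen membership
#'
#' Assigns every gene in the union of the supplied per-screen significant-gene
#' sets to exactly one Venn area defined by its exact membership pattern
#' (e.g. the three-way intersection, or "pol1-4 only"). Area counts therefore
#' sum to the size of the union.
#'
#' @param sets Named list of character vectors: the significant (e.g.
#'   negative) interactors of each screen.
#' @return A tibble with one row per gene in the union: `gene`,
#'   `member_screens` (list-column) and `area` (screen names joined
#'   with " & ").
#' @examples
#' venn_classify(list(A = c("g1", "g2"), B = "g2", C = c("g2", "g3")))
#' @export
venn_classify <- function(sets) {
  if (length(sets) < 1 || is.null(names(sets)) || any(names(sets) == "") ||
      anyDuplicated(names(sets))) {
    abort("`sets` must be a named list with unique non-empty names",
          class = "qfascreen_error_schema")
  }
  genes <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- lapply(genes, function(g) {
    names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
  })
  tibble(
    gene = genes,
    member_screens = member,
    area = vapply(member, paste, character(1), collapse = " & ")
  )
}

#' Count genes per Venn area
#'
#' @param assignments A [venn_classify()] result.
#' @return A tibble `area`, `n`, ordered by decreasing overlap order.
#' @export
venn_counts <- function(assignments) {
  assignments %>%
    mutate(n_screens = lengths(.data$member_screens)) %>%
    count(.data$area, .data$n_screens, name = "n") %>%
    arrange(-.data$n_screens, .data$area) %>%
    select("area", "n")
}

#' @export
autoplot.qfa_profiles <- function(object, genes = NULL, ...) {
  screens <- attr(object, "screens")
  long <- as_tibble(object) %>%
    tidyr::pivot_longer(dplyr::all_of(screens), names_to = "screen",
                        values_to = "mean_fitness")
  if (!is.null(genes)) long <- filter(long, .data$gene %in% genes)
  long <- mutate(long, screen = factor(.data$screen, levels = screens))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$screen, y = .data$mean_fitness,
                                     group = .data$gene, colour = .data$gene)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "mean fitness", colour = "gene") +
    ggplot2::theme_bw()
}
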