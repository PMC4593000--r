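# Synthetic paired control/query screens with known ground truth.
#
# The generator emulates the study design of a quantitative fitness analysis
# screen: a genome-wide library spotted in 384 format, typically eight
# replicate cultures per genotype, colony densities imaged every 4 h over a
# few days, generalized-logistic growth with strain-specific (r, K, nu) and a
# shared inoculum density, a multiplicative query-background fitness scaling
# m_true, a planted minority of interacting genes, and multiplicative
# log-normal measurement noise on density.

#' Configuration for the synthetic screen generator
#'
#' Defaults emulate a typical screen: eight replicates per genotype, 384-spot
#' plates (16 x 24), imaging every 4 h over 5 days, per-gene growth
#' parameters drawn log-normally around values typical of fitted yeast
#' colonies (`r` around 5/day, `K` around 0.12 density units with inoculum
#' `x0 = 0.001`, shape `nu` around 1), a query background that scales growth
#' rate — hence fitness — by `m_true = 0.5` (screens are run at temperatures
#' reducing query fitness to roughly half of the control), and 5%
#' multiplicative log-normal noise on observed density. Planted interacting
#' genes additionally scale the query growth rate by an effect multiplier
#' drawn uniformly from `effect_range` (below 1 = negative interaction).
#'
#' @param n_genes Number of library genes.
#' @param n_replicates Replicate cultures per genotype per screen (default 8).
#' @param plate_format Integer pair: rows, columns per plate (default 16 x 24).
#' @param n_plates Number of plates available per screen, or `NULL` to use as
#'   many as needed; a configuration whose cultures exceed the plate capacity
#'   is an error.
#' @param timepoints Imaging times in days (default every 4 h over 5 days).
#' @param x0 Shared inoculation density.
#' @param r_meanlog,r_sdlog,K_meanlog,K_sdlog,nu_meanlog,nu_sdlog Log-normal
#'   parameters of the per-gene control-growth parameter distributions.
#' @param m_true Multiplicative query-background fitness scaling.
#' @param planted_fraction Fraction of genes with a planted interaction.
#' @param effect_range Range of the uniform effect-multiplier distribution for
#'   planted genes.
#' @param noise_sd Standard deviation (log scale) of the multiplicative
#'   log-normal observation noise; 0.05 means roughly 5% noise.
#' @param temperature Nominal screen temperature (degrees C), metadata only.
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A validated list of class `qfa_sim_config`.
#' @export
sim_config <- function(n_genes = 100, n_replicates = 8,
                       plate_format = c(16, 24), n_plates = NULL,
                       timepoints = seq(0, 5, by = 1 / 6),
                       x0 = 1e-3,
                       r_meanlog = log(5), r_sdlog = 0.25,
                       K_meanlog = log(0.12), K_sdlog = 0.2,
                       nu_meanlog = 0, nu_sdlog = 0.3,
                       m_true = 0.5,
                       planted_fraction = 0, effect_range = c(0.1, 0.9),
                       noise_sd = 0.05, temperature = 30, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates),
              plate_format = as.integer(plate_format),
              n_plates = if (!is.null(n_plates)) as.integer(n_plates),
              timepoints = as.numeric(timepoints), x0 = x0,
              r_meanlog = r_meanlog, r_sdlog = r_sdlog,
              K_meanlog = K_meanlog, K_sdlog = K_sdlog,
              nu_meanlog = nu_meanlog, nu_sdlog = nu_sdlog,
              m_true = m_true, planted_fraction = planted_fraction,
              effect_range = as.numeric(effect_range),
              noise_sd = noise_sd, temperature = temperature,
              seed = as.integer(seed))
  if (cfg$n_genes < 1 || cfg$n_replicates < 1) {
    abort("need at least one gene and one replicate",
          class = "qfascreen_error_config")
  }
  if (length(cfg$plate_format) != 2 || any(cfg$plate_format < 1)) {
    abort("`plate_format` must be two positive integers (rows, columns)",
          class = "qfascreen_error_config")
  }
  if (cfg$planted_fraction < 0 || cfg$planted_fraction > 1) {
    abort("`planted_fraction` must lie in [0, 1]",
          class = "qfascreen_error_config")
  }
  if (cfg$x0 <= 0 || cfg$m_true <= 0 || cfg$noise_sd < 0 ||
      any(cfg$effect_range <= 0)) {
    abort("scale parameters must be positive (noise_sd may be 0)",
          class = "qfascreen_error_config")
  }
  if (length(cfg$timepoints) < 1 || any(cfg$timepoints < 0) ||
      is.unsorted(cfg$timepoints, strictly = TRUE)) {
    abort("`timepoints` must be strictly increasing and non-negative",
          class = "qfascreen_error_config")
  }
  capacity_needed <- ceiling(cfg$n_genes * cfg$n_replicates /
                               prod(cfg$plate_format))
  if (!is.null(cfg$n_plates) && cfg$n_plates < capacity_needed) {
    abort(sprintf(
      "geometry infeasible: %d cultures need %d plate(s) of %d, but n_plates = %d",
      cfg$n_genes * cfg$n_replicates, capacity_needed,
      prod(cfg$plate_format), cfg$n_plates),
      class = "qfascreen_error_config")
  }
  structure(cfg, class = "qfa_sim_config")
}

#' Read a simulation configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [sim_config()].
#' @return A `qfa_sim_config` list.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(sim_config)))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "qfascreen_error_config")
  }
  do.call(sim_config, vals)
}

# deterministic plate/row/col layout for culture i (1-based, in order)
plate_layout <- function(n, plate_format, prefix) {
  per_plate <- prod(plate_format)
  idx <- seq_len(n) - 1L
  plate <- idx %/% per_plate + 1L
  pos <- idx %% per_plate
  tibble(
    barcode = sprintf("%s_P%03d", prefix, plate),
    row = as.integer(pos %/% plate_format[2] + 1L),
    col = as.integer(pos %% plate_format[2] + 1L)
  )
}

simulate_one_screen <- function(truth, r_col, cfg, background, prefix) {
  n_cult <- nrow(truth) * cfg$n_replicates
  cultures <- truth[rep(seq_len(nrow(truth)), each = cfg$n_replicates), ]
  layout <- plate_layout(n_cult, cfg$plate_format, prefix)
  nt <- length(cfg$timepoints)
  obs <- tibble(
    barcode = rep(layout$barcode, each = nt),
    row = rep(layout$row, each = nt),
    col = rep(layout$col, each = nt),
    gene = rep(cultures$gene, each = nt),
    background = background,
    temperature = cfg$temperature,
    expt_time_days = rep(cfg$timepoints, times = n_cult),
    density = .glogistic_density(
      rep(cfg$timepoints, times = n_cult),
      cfg$x0,
      rep(cultures[[r_col]], each = nt),
      rep(cultures$K, each = nt),
      rep(cultures$nu, each = nt)
    )
  )
  if (cfg$noise_sd > 0) {
    noise <- exp(rnorm(nrow(obs), mean = -cfg$noise_sd^2 / 2, sd = cfg$noise_sd))
    obs$density <- obs$density * noise
  }
  obs
}

#' Generate a paired control/query screen with known ground truth
#'
#' Draws per-gene control growth parameters `(r, K, nu)`, scales the query
#' growth rate by `m_true` (times the planted effect multiplier for
#' interacting genes) — because MDR is exactly proportional to `r` at fixed
#' `(x0, K, nu)`, the expected query fitness is `m_true * effect` times the
#' control fitness — simulates replicate colony-density time courses from the
#' generalized logistic solution with multiplicative log-normal noise, and
#' assigns cultures to 384-format plate positions deterministically. The whole
#' simulation is reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()] configuration.
#' @return A list with elements `control` and `query` (time-course tibbles in
#'   the schema of [read_timecourses()]), `truth` (per-gene tibble: `gene`,
#'   `r`, `K`, `nu`, `r_query`, `effect`, `interacting`) and `config`.
#' @export
simulate_screen_pair <- function(cfg) {
  stopifnot(inherits(cfg, "qfa_sim_config"))
  withr::with_seed(cfg$seed, {
    genes <- sprintf("GENE%05d", seq_len(cfg$n_genes))
    n_planted <- round(cfg$planted_fraction * cfg$n_genes)
    planted <- sample(genes, n_planted)
    effect <- setNames(rep(1, cfg$n_genes), genes)
    effect[planted] <- runif(n_planted, cfg$effect_range[1], cfg$effect_range[2])
    truth <- tibble(
      gene = genes,
      r = exp(rnorm(cfg$n_genes, cfg$r_meanlog, cfg$r_sdlog)),
      K = pmax(exp(rnorm(cfg$n_genes, cfg$K_meanlog, cfg$K_sdlog)),
               2.001 * cfg$x0),
      nu = exp(rnorm(cfg$n_genes, cfg$nu_meanlog, cfg$nu_sdlog)),
      effect = unname(effect),
      interacting = genes %in% planted
    ) %>%
      mutate(r_query = .data$r * cfg$m_true * .data$effect)
    control <- simulate_one_screen(truth, "r", cfg, "control", "CTL")
    query <- simulate_one_screen(truth, "r_query", cfg, "query", "QRY")
    list(control = control, query = query,
         truth = select(truth, "gene", "r", "K", "nu", "r_query",
                        "effect", "interacting"),
         config = cfg)
  })
}

#' Simulate replicate fitnesses directly (no growth curves)
#'
#' A fast fitness-level counterpart of [simulate_screen_pair()] for
#' calibrating the interaction-testing stage at genome scale: per gene, a
#' control fitness is drawn log-normally; replicate fitnesses are that value
#' times mean-one multiplicative log-normal noise; query replicates are
#' additionally scaled by `m_true` and, for planted genes, by an effect
#' multiplier drawn uniformly from `effect_range`.
#'
#' @param n_genes,n_replicates Library size and replicates per genotype.
#' @param m_true Multiplicative query fitness scaling.
#' @param planted_fraction Fraction of genes with a planted interaction.
#' @param effect_range Uniform range for planted effect multipliers.
#' @param noise_sd Log-scale SD of the replicate noise (0.05 = ~5%).
#' @param fitness_meanlog,fitness_sdlog Log-normal parameters of the per-gene
#'   control fitness distribution.
#' @param seed Integer seed.
#' @return A list with `control` and `query` (tibbles `gene`, `background`,
#'   `fitness`, one row per replicate) and `truth` (`gene`, `fitness_control`,
#'   `effect`, `interacting`).
#' @export
simulate_fitness_screens <- function(n_genes = 2000, n_replicates = 8,
                                     m_true = 0.5, planted_fraction = 0,
                                     effect_range = c(0.1, 0.9),
                                     noise_sd = 0.05,
                                     fitness_meanlog = log(40),
                                     fitness_sdlog = 0.3, seed = 1) {
  stopifnot(n_genes >= 1, n_replicates >= 1, noise_sd >= 0,
            planted_fraction >= 0, planted_fraction <= 1)
  withr::with_seed(as.integer(seed), {
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    fit_ctl <- exp(rnorm(n_genes, fitness_meanlog, fitness_sdlog))
    n_planted <- round(planted_fraction * n_genes)
    planted <- sample(genes, n_planted)
    effect <- setNames(rep(1, n_genes), genes)
    effect[planted] <- runif(n_planted, effect_range[1], effect_range[2])
    noise <- function(n) exp(rnorm(n, -noise_sd^2 / 2, noise_sd))
    reps <- function(per_gene_mean, background) {
      tibble(
        gene = rep(genes, each = n_replicates),
        background = background,
        fitness = rep(per_gene_mean, each = n_replicates) *
          noise(n_genes * n_replicates)
      )
    }
    list(
      control = reps(fit_ctl, "control"),
      query = reps(fit_ctl * m_true * unname(effect), "query"),
      truth = tibble(gene = genes, fitness_control = fit_ctl,
                     effect = unname(effect),
                     interacting = genes %in% planted)
    )
  })
}

#' Write a simulated screen pair as raw time-course files
#'
#' Emits `control.tsv` and `query.tsv` in the exact tab-separated time-course
#' schema consumed by [read_timecourses()] / [fit_growth()], plus the ground
#' truth as `truth.tsv`.
#'
#' @param sim A [simulate_screen_pair()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths (named `control`, `query`, `truth`).
#' @export
write_simulated_raw <- function(sim, dir) {
  stopifnot(all(c("control", "query", "truth") %in% names(sim)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(control = file.path(dir, "control.tsv"),
             query = file.path(dir, "query.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_timecourses(sim$control, paths["control"])
  write_timecourses(sim$query, paths["query"])
  readr::write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}
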