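# Interaction module: strain summaries, multiplicative-model slope, Welch
# tests with BH-FDR calling, and linkage-based gene stripping.

sum_tbl <- function(genes, reps) {
  summarize_screen(tibble::tibble(gene = rep(genes, lengths(reps)),
                                  fitness = unlist(reps)))
}

test_that("summarize_screen averages replicates and drops non-finite values", {
  s <- summarize_screen(data.frame(gene = c("A", "A", "A", "B"),
                                   fitness = c(1, 2, 3, 7)))
  expect_equal(s$mean_fitness[s$gene == "A"], 2)
  expect_equal(s$n[s$gene == "A"], 3)
  expect_equal(s$mean_fitness[s$gene == "B"], 7)
  expect_equal(s$n[s$gene == "B"], 1)

  expect_warning(
    s2 <- summarize_screen(data.frame(gene = c("A", "A", "B"),
                                      fitness = c(1, NaN, Inf))),
    "non-finite")
  expect_equal(s2$n[s2$gene == "A"], 1)
  expect_false("B" %in% s2$gene)
})

test_that("through-origin slope matches the closed form and a grid oracle", {
  ctl <- sum_tbl(c("a", "b", "c"), list(1, 2, 3))
  qry <- sum_tbl(c("a", "b", "c"), list(0.5, 1, 1.5))
  expect_equal(estimate_slope(ctl, qry), 0.5)
  expect_equal(estimate_slope(ctl, ctl), 1)

  ctl2 <- sum_tbl(c("a", "b"), list(1, 2))
  qry2 <- sum_tbl(c("a", "b"), list(1, 1))
  expect_equal(estimate_slope(ctl2, qry2), 0.6)  # (1*1 + 2*1) / (1 + 4)

  # the closed form minimises the through-origin RSS (dense grid oracle)
  withr::with_seed(41, {
    for (i in 1:50) {
      n <- sample(5:40, 1)
      c_mean <- runif(n, 0.1, 5)
      q_mean <- 0.7 * c_mean + rnorm(n, 0, 0.3)
      ctl <- sum_tbl(sprintf("g%02d", 1:n), as.list(c_mean))
      qry <- sum_tbl(sprintf("g%02d", 1:n), as.list(q_mean))
      m_hat <- estimate_slope(ctl, qry)
      expect_equal(m_hat, sum(c_mean * q_mean) / sum(c_mean^2),
                   tolerance = 1e-12)
      grid <- seq(m_hat - 0.5, m_hat + 0.5, length.out = 2001)
      rss <- vapply(grid, function(m) sum((q_mean - m * c_mean)^2), numeric(1))
      expect_lte(sum((q_mean - m_hat * c_mean)^2), min(rss) + 1e-9)
    }
  })

  expect_error(estimate_slope(sum_tbl(c("a", "b"), list(0, 0)),
                              sum_tbl(c("a", "b"), list(1, 1))),
               class = "qfascreen_error_params")
})

test_that("BH adjustment matches hand-applied step-up and a brute oracle", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.05), 0.05)
  expect_equal(adjust_fdr(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(adjust_fdr(c(0.5, 1.2)), class = "qfascreen_error_params")

  withr::with_seed(42, {
    for (i in 1:1000) {
      p <- runif(sample(1:50, 1))^sample(1:3, 1)
      expect_equal(adjust_fdr(p), bh_oracle(p), tolerance = 1e-12)
    }
    # permutation equivariance
    p <- runif(30)
    perm <- sample(30)
    expect_equal(adjust_fdr(p)[perm], adjust_fdr(p[perm]))
  })
})

test_that("the Welch test is the one applied per gene", {
  expect_equal(welch_p_oracle(c(1, 2, 3), c(2, 3, 4)), 0.2878641,
               tolerance = 1e-4)
  ctl <- sum_tbl(c("g1", "g2"), list(c(2, 3, 4), c(1, 2, 3)))
  qry <- sum_tbl(c("g1", "g2"), list(c(1, 2, 3), c(1, 2, 3)))
  gis <- test_interactions(ctl, qry, m = 1, q_threshold = 0.05)
  expect_equal(gis$p[gis$gene == "g1"], welch_p_oracle(c(1, 2, 3), c(2, 3, 4)),
               tolerance = 1e-12)
  # exact null: observed equals predicted replicate-for-replicate
  expect_equal(gis$p[gis$gene == "g2"], 1)
  expect_equal(gis$call[gis$gene == "g2"], "none")
})

test_that("GIS is observed minus predicted mean, with a reversible sign", {
  ctl <- sum_tbl(c("g1", "g2"), list(c(2, 3, 4), c(1, 2, 3)))
  qry <- sum_tbl(c("g1", "g2"), list(c(1, 2, 3), c(4, 5, 6)))
  gis <- test_interactions(ctl, qry, m = 1)
  expect_equal(gis$gis[gis$gene == "g1"], 2 - 3)
  expect_equal(gis$query_mean_pred[gis$gene == "g1"], 3)
  rev <- test_interactions(ctl, qry, m = 1, sign = "pred_minus_obs")
  expect_equal(rev$gis, -gis$gis)
  # calls keep their biological meaning under either convention
  expect_identical(rev$call, gis$call)
})

test_that("genes with fewer than two replicates are flagged, not tested", {
  ctl <- sum_tbl(c("g1", "g2"), list(c(2, 3, 4), 5))
  qry <- sum_tbl(c("g1", "g2"), list(c(1, 2, 3), c(4, 5)))
  gis <- test_interactions(ctl, qry, m = 1)
  expect_true(is.na(gis$p[gis$gene == "g2"]))
  expect_true(is.na(gis$q[gis$gene == "g2"]))
  expect_equal(gis$call[gis$gene == "g2"], "none")
  # the BH denominator sees only the tested gene
  expect_equal(gis$q[gis$gene == "g1"], gis$p[gis$gene == "g1"])
})

test_that("test_interactions is invariant to gene ordering", {
  withr::with_seed(43, {
    genes <- sprintf("g%02d", 1:20)
    ctl_reps <- lapply(1:20, function(i) runif(8, 1, 3))
    qry_reps <- lapply(1:20, function(i) runif(8, 0.5, 1.5))
    ctl <- sum_tbl(genes, ctl_reps)
    qry <- sum_tbl(genes, qry_reps)
    perm <- sample(20)
    g1 <- test_interactions(ctl, qry, m = 0.5)
    g2 <- test_interactions(ctl[perm, ], qry[rev(perm), ], m = 0.5)
    expect_equal(dplyr::arrange(tidy(g1), gene), dplyr::arrange(tidy(g2), gene))
  })
})

test_that("planted negative interactions dominate the calls at q < 0.05", {
  # 1000 null genes plus 50 genes with query fitness halved, 8 replicates,
  # 5% noise; repeated over 20 seeds
  fdp <- sens <- numeric(20)
  for (s in 1:20) {
    sim <- simulate_fitness_screens(n_genes = 1050, n_replicates = 8,
                                    planted_fraction = 50 / 1050,
                                    effect_range = c(0.5, 0.5),
                                    noise_sd = 0.05, seed = 100 + s)
    gis <- screen_gis(sim$control, sim$query)
    hits <- gis$gene[gis$call == "negative"]
    truth <- sim$truth$gene[sim$truth$interacting]
    fdp[s] <- if (length(hits) == 0) 0 else mean(!hits %in% truth)
    sens[s] <- mean(truth %in% hits)
  }
  expect_lte(mean(fdp), 0.1)
  expect_gte(mean(sens), 0.9)
})

loci_fix <- tibble::tibble(
  gene = c("near", "far", "othchr", "boundary", "overlap"),
  chromosome = c("chrI", "chrI", "chrII", "chrI", "chrI"),
  start = c(85000, 125000, 100000, 79000, 100500),
  end = c(85500, 125800, 101000, 80000, 100800)
)
query_fix <- tibble::tibble(gene = "qry", chromosome = "chrI",
                            start = 100000, end = 101000)

test_that("stripping removes linked and excluded genes, inclusively at 20 kb", {
  s <- tibble::tibble(gene = c(loci_fix$gene, "nolocus"), mean_fitness = 1)
  expect_message(
    out <- strip_genes(s, loci_fix, query_fix, window = 20000,
                       exclusions = "othchr"),
    "retained")
  # gap 14.5 kb -> stripped; 24 kb -> kept; other chromosome -> kept unless excluded
  expect_false("near" %in% out$gene)
  expect_true("far" %in% out$gene)
  expect_false("othchr" %in% out$gene)  # explicit exclusion
  # boundary: gap exactly 20000 -> stripped (inclusive)
  expect_false("boundary" %in% out$gene)
  expect_false("overlap" %in% out$gene)
  # gene without a locus is retained
  expect_true("nolocus" %in% out$gene)
})

test_that("stripping is idempotent and never removes distant same-chromosome genes", {
  s <- tibble::tibble(gene = loci_fix$gene, mean_fitness = 1)
  once <- suppressMessages(strip_genes(s, loci_fix, query_fix))
  twice <- suppressMessages(strip_genes(once, loci_fix, query_fix))
  expect_equal(strip_attrs(once), strip_attrs(twice))
  withr::with_seed(44, {
    for (i in 1:20) {
      pos <- sort(runif(2, 1, 5e5))
      g <- tibble::tibble(gene = "g", chromosome = "chrI",
                          start = pos[1], end = pos[2])
      gap <- max(max(g$start, query_fix$start) - min(g$end, query_fix$end), 0)
      out <- suppressMessages(
        strip_genes(tibble::tibble(gene = "g", mean_fitness = 1), g, query_fix))
      expect_equal(nrow(out) == 0, gap <= 20000)
    }
  })
})

test_that("stripping boundary arithmetic uses the gap between intervals", {
  # query at chrI:100000-101000; exactly 20 kb upstream gap
  g <- tibble::tibble(gene = "g", chromosome = "chrI",
                      start = 79000, end = 80000)
  out <- suppressMessages(
    strip_genes(tibble::tibble(gene = "g", mean_fitness = 1), g, query_fix,
                window = 20000))
  expect_equal(nrow(out), 0)
  out2 <- suppressMessages(
    strip_genes(tibble::tibble(gene = "g", mean_fitness = 1), g, query_fix,
                window = 19999))
  expect_equal(nrow(out2), 1)
})

test_that("screen_gis chains summarise, strip, slope and test", {
  sim <- simulate_fitness_screens(n_genes = 200, n_replicates = 8,
                                  planted_fraction = 0.05,
                                  effect_range = c(0.4, 0.6), seed = 7)
  loci <- tibble::tibble(gene = sim$truth$gene, chromosome = "chrI",
                         start = seq(1, by = 50000, length.out = 200),
                         end = seq(1, by = 50000, length.out = 200) + 1000)
  qloci <- tibble::tibble(chromosome = "chrI", start = 1, end = 1000)
  gis <- suppressMessages(
    screen_gis(sim$control, sim$query, loci = loci, query_loci = qloci))
  expect_false(sim$truth$gene[1] %in% gis$gene)  # linked to the query locus
  expect_equal(nrow(gis), 199)
  expect_equal(attr(gis, "m"), 0.5, tolerance = 0.05)
})
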