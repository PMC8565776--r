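toy_expression <- function() {
  tidyr::crossing(
    tibble::tibble(
      transcript_id = c("tA1", "tA2", "tB1", "tC1"),
      gene_id = c("gA", "gA", "gB", "gC"),
      biotype = c("lncRNA", "lncRNA", "protein_coding", "lncRNA")
    ),
    lineage = c("hESC", "endoderm", "mesoderm"),
    replicate = 1:2
  ) |>
    dplyr::mutate(tpm = dplyr::case_when(
      transcript_id == "tA1" & lineage == "hESC" ~ 10,
      transcript_id == "tA1" ~ 0,
      transcript_id == "tA2" ~ 0.06,
      transcript_id == "tB1" ~ 5,
      transcript_id == "tC1" & lineage == "endoderm" & replicate == 1 ~ 0.4,
      .default = 0
    ))
}

test_that("tau matches hand-computed values and its limits", {
  expect_equal(tau(c(5, 5, 5)), 0)
  expect_equal(tau(c(7, 0, 0)), 1)
  expect_equal(tau(c(10, 5, 0)), 0.75)
  expect_equal(tau(c(1, 2, 3, 4)), ((1 - 0.25) + (1 - 0.5) + (1 - 0.75)) / 3)
  expect_true(is.na(tau(c(0, 0, 0))))
  expect_error(tau(5), "at least 2")
  expect_error(tau(c(-1, 2)), "non-negative")
})

test_that("tau is scale-invariant and monotone under concentration", {
  set.seed(1)
  for (i in 1:50) {
    x <- stats::runif(3, 0, 100)
    expect_equal(tau(7.3 * x), tau(x))
  }
  # moving mass from a non-maximal lineage into the maximal one never
  # decreases tau: exhaustive small grid
  grid <- expand.grid(a = 0:5, b = 0:5, c = 0:5)
  grid <- grid[rowSums(grid) > 0 & grid$a >= grid$b, ]
  for (i in seq_len(nrow(grid))) {
    x <- as.numeric(grid[i, ])
    if (x[2] >= 1) {
      y <- x + c(1, -1, 0)
      expect_true(tau(y) >= tau(x) - 1e-12)
    }
  }
})

test_that("expression thresholding follows the lineage-mean rule", {
  expr <- toy_expression()
  tx <- expressed_set(expr, 0.1, level = "transcript")
  # tA1: hESC mean 10 -> in; tA2: 0.06 everywhere -> out;
  # tC1: endoderm mean 0.2 -> in
  expect_setequal(tx, c("tA1", "tB1", "tC1"))
  genes <- expressed_set(expr, 0.1, level = "gene")
  expect_setequal(genes, c("gA", "gB", "gC"))
  # any_sample mode rescues nothing here but demotes nothing either
  expect_setequal(expressed_set(expr, 0.1, level = "transcript", mode = "any_sample"),
    c("tA1", "tB1", "tC1"))
  # all-zero transcripts are always excluded
  zero <- dplyr::mutate(expr, tpm = 0)
  expect_length(expressed_set(zero), 0)
})

test_that("gene-level tpm is the exact sum of transcript tpm", {
  expr <- toy_expression()
  gene_tau <- calc_tau(expr, level = "gene")
  gA <- gene_tau[gene_tau$id == "gA", ]
  # gA lineage means: hESC 10.06, endo 0.06, meso 0.06
  expect_equal(gA$max_expression, 10.06)
  expect_equal(gA$tau, tau(c(10.06, 0.06, 0.06)))
})

test_that("specificity comparison recovers the generated lncRNA/mRNA contrast", {
  sim <- sim_annotation(
    n_mrna = 30,
    category_mix = c(
      intergenic = 30, promoter_overlapping = 0,
      transcript_overlapping = 0, gene_nearby = 0
    ), seed = 5
  )
  ex <- sim_expression(sim$annotation, seed = 5)
  tt <- calc_tau(ex$expression, level = "gene") |>
    dplyr::inner_join(
      dplyr::distinct(ex$expression, gene_id, biotype),
      by = c(id = "gene_id")
    ) |>
    dplyr::transmute(id, group = biotype, tau)
  res <- specificity_compare(tt)
  med <- setNames(res$summary$median_tau, res$summary$group)
  expect_gt(med[["lncRNA"]], med[["protein_coding"]])
  expect_lt(res$tests$p_value[1], 0.05)

  # identical groups: p = 1, equal medians
  same <- dplyr::bind_rows(
    tibble::tibble(id = as.character(1:10), group = "a", tau = (1:10) / 10),
    tibble::tibble(id = as.character(11:20), group = "b", tau = (1:10) / 10)
  )
  res2 <- specificity_compare(same)
  expect_equal(res2$tests$p_value, 1)
  expect_equal(res2$summary$median_tau[1], res2$summary$median_tau[2])
  expect_warning(
    specificity_compare(dplyr::bind_rows(same, tibble::tibble(id = "x", group = "tiny", tau = 0.5))),
    "skipping"
  )
})

test_that("the plumbing DE test is calibrated under the null and finds planted signal", {
  mk_expr <- function(fc, n_tx = 200, cv = 0.1, seed = 1) {
    set.seed(seed)
    base <- stats::rlnorm(n_tx, log(50), 0.5)
    tidyr::crossing(
      transcript_id = sprintf("t%03d", seq_len(n_tx)),
      lineage = c("A", "B"), replicate = 1:2
    ) |>
      dplyr::mutate(
        gene_id = transcript_id,
        mu = base[as.integer(factor(transcript_id))] * ifelse(lineage == "A", fc, 1),
        tpm = stats::rlnorm(dplyr::n(), log(mu), sqrt(log(1 + cv^2)))
      )
  }
  # null: p-values approximately uniform (KS at alpha = 0.01)
  null <- simple_de_test(mk_expr(1), "A", "B")
  expect_gt(suppressWarnings(stats::ks.test(null$p_value, "punif")$p.value), 0.01)
  expect_true(all(null$method == "welch_t_plumbing"))

  # planted 8-fold change, CV 10%: most transcripts significant
  de <- simple_de_test(mk_expr(8), "A", "B")
  expect_gte(mean(de$q_value < 0.05), 0.9)
  expect_equal(mean(de$log2fc), 3, tolerance = 0.05)

  # exact fold-change 1 with no noise: log2FC 0, zero-variance flag, p = 1
  const <- mk_expr(1, n_tx = 5, cv = 0)
  res <- simple_de_test(const, "A", "B")
  expect_equal(res$log2fc, rep(0, 5))
  expect_true(all(res$zero_variance))
  expect_equal(res$p_value, rep(1, 5))
})
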