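toy_counts <- function(tbl) {
  # tbl: tibble(guide_id, day0_1, day0_2, undiff_1, undiff_2, diff_1, diff_2)
  tbl |>
    tidyr::pivot_longer(-guide_id, names_to = "sample", values_to = "count") |>
    tidyr::separate(sample, c("population", "replicate"), sep = "_") |>
    dplyr::mutate(
      population = dplyr::recode(population,
        day0 = "day0", undiff = "undifferentiated", diff = "differentiated"
      ),
      replicate = as.integer(replicate),
      count = as.integer(count)
    )
}

test_that("cpm normalizes each sample to one million", {
  counts <- toy_counts(tibble::tibble(
    guide_id = c("g1", "g2"),
    day0_1 = c(10L, 990L), day0_2 = c(100L, 900L),
    undiff_1 = c(1L, 1L), undiff_2 = c(2L, 0L),
    diff_1 = c(5L, 5L), diff_2 = c(5L, 5L)
  ))
  cc <- add_cpm(counts)
  expect_equal(cc$cpm[cc$guide_id == "g1" & cc$population == "day0" & cc$replicate == 1], 10000)
  sums <- cc |>
    dplyr::group_by(population, replicate) |>
    dplyr::summarise(s = sum(cpm), .groups = "drop")
  expect_equal(sums$s, rep(1e6, 6))
  empty <- dplyr::mutate(counts, count = ifelse(population == "day0" & replicate == 1, 0L, count))
  expect_error(add_cpm(empty), "empty sample")
})

test_that("the filtering cascade applies the three stages with exact boundaries", {
  # library sizes of 1e6 make cpm == count
  n <- 6
  pad <- as.integer(1e6 - 0) # padding guide absorbs the remainder
  base <- tibble::tibble(
    guide_id = c("keep1", "keep2", "keep3", "edge", "lowu", "ctrl", "pad"),
    day0_1 = c(100L, 100L, 100L, 5L, 100L, 100L, 0L),
    day0_2 = c(100L, 100L, 100L, 4L, 100L, 100L, 0L), # 'edge' fails: 4.9-style cpm < 5
    undiff_1 = c(10L, 10L, 10L, 10L, 10L, 10L, 0L),
    undiff_2 = c(10L, 10L, 10L, 10L, 0L, 10L, 0L), # 'lowu' fails stage 2
    diff_1 = c(10L, 10L, 10L, 10L, 10L, 10L, 0L),
    diff_2 = c(10L, 10L, 10L, 10L, 10L, 10L, 0L)
  )
  for (col in names(base)[-1]) {
    base[[col]][base$guide_id == "pad"] <- as.integer(1e6 - sum(base[[col]]))
  }
  guides <- tibble::tibble(
    guide_id = base$guide_id,
    target_tss_id = c("tssA", "tssA", "tssA", "tssB", "tssB", NA, "tssC"),
    is_control = c(rep(FALSE, 5), TRUE, FALSE)
  )
  fc <- filter_cascade(toy_counts(base), guides)
  g <- fc$guides
  # exact boundary: cpm 5.0 in both day-0 reps is kept at stage 1
  expect_false(g$pass_stage1[g$guide_id == "edge"])
  edge5 <- base
  edge5$day0_2[edge5$guide_id == "edge"] <- 5L
  edge5$day0_2[edge5$guide_id == "pad"] <- as.integer(1e6 - sum(edge5$day0_2[-7]))
  fc5 <- filter_cascade(toy_counts(edge5), guides)
  expect_true(fc5$guides$pass_stage1[fc5$guides$guide_id == "edge"])

  # stage 2 removes guides missing from one undifferentiated replicate
  expect_true(g$pass_stage1[g$guide_id == "lowu"])
  expect_false(g$pass_stage2[g$guide_id == "lowu"])
  # stage 3: tssB has < 3 survivors -> its guides drop; scrambled exempt
  expect_false(g$filtered[g$guide_id == "edge"])
  expect_true(all(g$filtered[g$guide_id %in% c("keep1", "keep2", "keep3")]))
  expect_true(g$filtered[g$guide_id == "ctrl"])
  # monotone: survivors shrink stage by stage
  expect_true(all(diff(fc$report$n_guides) <= 0))
  expect_true(all(g$pass_stage2 <= g$pass_stage1) && all(g$pass_stage3 <= g$pass_stage2))
  expect_equal(fc$tss_guides$n_filtered_guides[fc$tss_guides$tss_id == "tssA"], 3L)
  expect_error(
    filter_cascade(dplyr::filter(toy_counts(base), population != "day0"), guides),
    "day0"
  )
})

test_that("enrichment estimation matches the paired log-ratio by hand", {
  # equal library sizes and symmetric counts: size factors 1
  base <- tibble::tibble(
    guide_id = c("up", "flat1", "flat2", "flat3"),
    day0_1 = c(100L, 100L, 100L, 100L),
    day0_2 = c(100L, 100L, 100L, 100L),
    undiff_1 = c(40L, 20L, 30L, 10L),
    undiff_2 = c(40L, 20L, 30L, 10L),
    diff_1 = c(10L, 20L, 30L, 10L),
    diff_2 = c(10L, 20L, 30L, 10L)
  )
  enr <- estimate_enrichment(toy_counts(base))
  expect_equal(
    enr$log2fc[enr$guide_id == "up"], log2(40.5 / 10.5),
    tolerance = 1e-12
  )
  expect_equal(enr$log2fc[enr$guide_id == "flat1"], 0)
  expect_equal(enr$se[enr$guide_id == "up"], 0) # replicates agree exactly
  expect_equal(enr$n_replicates, rep(2L, 4))
  expect_error(
    estimate_enrichment(dplyr::filter(toy_counts(base), population == "day0")),
    "sorted"
  )
})

test_that("enrichment estimates are unbiased against the count generator", {
  map <- toy_guide_map(n_tss = 20, guides_per_tss = 5, n_ctrl = 20)
  bias <- vapply(1:30, function(seed) {
    truth <- sim_screen_truth(map, n_functional = 2, effect_size = 1, pi_guide = 1, seed = seed)
    sc <- sim_screen_counts(map, truth, depth = 500, seed = seed)
    j <- dplyr::inner_join(estimate_enrichment(sc$counts), sc$guide_truth, by = "guide_id")
    planted <- j[j$efficiency == 1, ]
    mean(planted$log2fc - planted$true_log2fc)
  }, numeric(1))
  expect_lt(abs(mean(bias)), 0.1)
})

test_that("top-3 effect sizes follow the defining arithmetic", {
  map <- tibble::tibble(
    guide_id = sprintf("g%d", 1:8),
    target_tss_id = c(rep("tA", 4), rep("tB", 3), "tC"),
    is_control = FALSE
  )
  enr <- tibble::tibble(
    guide_id = sprintf("g%d", 1:8),
    log2fc = c(2, 1, 0.5, -1, 1, 1, 1, 3)
  )
  eff <- tss_effect_sizes(enr, map)
  expect_equal(eff$effect_size[eff$tss_id == "tA"], 3.5 / 3)
  expect_equal(eff$effect_size[eff$tss_id == "tB"], 1)
  expect_true(is.na(eff$effect_size[eff$tss_id == "tC"])) # < 3 guides
  expect_false(eff$effect_size_defined[eff$tss_id == "tC"])

  # ties at the cut rank and row order never change the mean
  enr_tie <- tibble::tibble(guide_id = sprintf("g%d", 1:4), log2fc = c(2, 1, 1, 1))
  map_tie <- tibble::tibble(guide_id = sprintf("g%d", 1:4), target_tss_id = "t", is_control = FALSE)
  expect_equal(tss_effect_sizes(enr_tie, map_tie)$effect_size, 4 / 3)
  perm <- sample(4)
  expect_equal(
    tss_effect_sizes(enr_tie[perm, ], map_tie)$effect_size, 4 / 3
  )
})

test_that("TSS classification applies hit and stringent non-hit rules exclusively", {
  calls <- tibble::tibble(
    tss_id = c("a", "b", "c", "d"),
    fdr = c(0.09, 0.95, 0.95, 0.5),
    n_guides = c(10L, 8L, 9L, 10L)
  )
  cl <- classify_tss(calls)
  expect_equal(cl$is_hit, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(cl$is_stringent_nonhit, c(FALSE, FALSE, TRUE, FALSE))
  expect_false(any(cl$is_hit & cl$is_stringent_nonhit))
  gm <- tibble::tibble(tss_id = c("a", "b", "c", "d"), gene_id = c("gA", "gB", "gC", "gC"))
  cl2 <- classify_tss(calls, gene_map = gm)
  expect_equal(attr(cl2, "nonhit_genes"), "gC")
})

test_that("validation scores match hand arithmetic and are monotone", {
  expect_equal(validation_score(50, 50, 50, 50), 0)
  expect_equal(
    validation_score(20, 80, 5, 95),
    log2((20 / 80) / (5 / 95))
  )
  s1 <- validation_score(20, 80, 5, 95)
  s2 <- validation_score(25, 80, 5, 95)
  expect_gt(s2, s1)
  expect_warning(z <- validation_score(0, 80, 5, 95), "floored")
  expect_equal(z, log2((0.1 / 80) / (5 / 95)))
})

test_that("feature comparison matches exact rank-sum enumeration", {
  feats <- tibble::tibble(
    gene_id = sprintf("g%d", 1:6),
    f1 = c(1, 2, 3, 4, 5, 6),
    f2 = c(10, 30, 20, 25, 15, 5)
  )
  res <- compare_hit_features(feats, hit_ids = sprintf("g%d", 1:3), nonhit_ids = sprintf("g%d", 4:6))
  expect_equal(res$p_value[res$feature == "f1"], 0.1) # 2/20 arrangements as extreme
  expect_equal(
    res$p_value[res$feature == "f2"],
    oracle_mann_whitney_p(feats$f2[1:3], feats$f2[4:6])
  )
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))

  # identical groups -> p = 1
  same <- tibble::tibble(gene_id = sprintf("g%d", 1:6), f = rep(c(1, 2, 3), 2))
  res_same <- suppressWarnings(compare_hit_features(same, sprintf("g%d", 1:3), sprintf("g%d", 4:6)))
  expect_equal(res_same$p_value, 1)

  # randomized instances against the enumeration oracle (no ties)
  set.seed(11)
  for (i in 1:10) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    v <- sample(100, n1 + n2)
    tb <- tibble::tibble(gene_id = sprintf("g%d", seq_len(n1 + n2)), f = v)
    got <- compare_hit_features(tb, tb$gene_id[1:n1], tb$gene_id[(n1 + 1):(n1 + n2)])
    expect_equal(got$p_value, oracle_mann_whitney_p(v[1:n1], v[(n1 + 1):(n1 + n2)]))
  }

  expect_warning(
    compare_hit_features(
      tibble::tibble(gene_id = c("a", "b"), f = c(NA_real_, 1)),
      hit_ids = "a", nonhit_ids = "b"
    ),
    "skipped"
  )
})

test_that("hit/DE association matches Fisher enumeration and the sample OR", {
  res <- de_hit_association(
    hit_de = c(rep(TRUE, 2), rep(FALSE, 3)),
    nonhit_de = c(rep(TRUE, 3), rep(FALSE, 2))
  )
  expect_equal(res$odds_ratio, 4 / 9)
  expect_equal(res$p_value, oracle_fisher_p(attr(res, "table")))

  even <- de_hit_association(
    hit_de = rep(c(TRUE, FALSE), each = 5),
    nonhit_de = rep(c(TRUE, FALSE), each = 5)
  )
  expect_equal(even$odds_ratio, 1)
  expect_equal(even$p_value, 1)

  # all small tables n <= 30 against the hypergeometric oracle
  set.seed(3)
  for (i in 1:25) {
    n_h <- sample(2:15, 1)
    n_n <- sample(2:15, 1)
    hd <- stats::runif(n_h) < 0.5
    nd <- stats::runif(n_n) < 0.5
    got <- de_hit_association(hd, nd)
    expect_equal(got$p_value, oracle_fisher_p(attr(got, "table")), tolerance = 1e-10)
  }
})
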