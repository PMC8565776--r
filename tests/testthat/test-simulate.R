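test_that("the generator's category mix is recovered exactly by the categorizer", {
  mixes <- list(
    c(intergenic = 10, promoter_overlapping = 10, transcript_overlapping = 10, gene_nearby = 10),
    c(intergenic = 3, promoter_overlapping = 0, transcript_overlapping = 7, gene_nearby = 1)
  )
  for (mix in mixes) {
    sim <- sim_annotation(category_mix = mix, seed = 2)
    got <- table(categorize_lncrna(sim$annotation)$category)
    expect_equal(as.integer(got[names(mix)]), unname(as.integer(mix)))
    # construction truth agrees gene by gene
    joined <- dplyr::inner_join(sim$truth, categorize_lncrna(sim$annotation), by = "gene_id")
    expect_equal(as.character(joined$category.x), as.character(joined$category.y))
  }
  # mRNA-only annotation is valid
  sim0 <- sim_annotation(
    n_mrna = 4,
    category_mix = c(intergenic = 0, promoter_overlapping = 0, transcript_overlapping = 0, gene_nearby = 0),
    seed = 1
  )
  expect_true(all(sim0$annotation$biotype == "protein_coding"))
  expect_equal(nrow(categorize_lncrna(sim0$annotation)), 0)
})

test_that("fixed seeds give byte-identical generated files", {
  sim1 <- sim_annotation(seed = 6)
  sim2 <- sim_annotation(seed = 6)
  f1 <- tempfile(fileext = ".gtf")
  f2 <- tempfile(fileext = ".gtf")
  write_annotation_gtf(sim1$annotation, f1)
  write_annotation_gtf(sim2$annotation, f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- tempfile(fileext = ".fa")
  write_genome_fasta(sim1$genome, g1)
  expect_identical(sim1$genome, sim2$genome)
  expect_true(startsWith(readLines(g1, n = 1), ">"))
})

test_that("generated GTF round-trips through the annotation reader", {
  skip_if_not_installed("rtracklayer")
  sim <- sim_annotation(seed = 3)
  f <- tempfile(fileext = ".gtf")
  write_annotation_gtf(sim$annotation, f)
  back <- read_annotation_gtf(f)
  orig <- dplyr::arrange(sim$annotation, transcript_id, start)
  back <- dplyr::arrange(back, transcript_id, start)
  expect_equal(back$start, orig$start)
  expect_equal(back$end, orig$end)
  expect_equal(back$strand, orig$strand)
  expect_equal(back$biotype, orig$biotype)
})

test_that("expression generator realizes lineage structure and splicing truth", {
  sim <- sim_annotation(seed = 10)
  ex <- sim_expression(sim$annotation, seed = 10)

  # zero noise makes replicates identical
  ex0 <- sim_expression(sim$annotation, noise_cv = 0, seed = 10)
  wide <- tidyr::pivot_wider(ex0$expression,
    id_cols = c("transcript_id", "lineage"),
    names_from = "replicate", values_from = "tpm"
  )
  expect_equal(wide$`1`, wide$`2`)

  # specific genes hit tau >= 0.8 in expectation (profile-level check)
  spec <- ex$truth[ex$truth$archetype == "specific", ]
  expect_true(all(spec$expected_tau >= 0.8))
  prof <- ex$profiles[ex$profiles$gene_id == spec$gene_id[1], ]
  expect_equal(tau(prof$mean_tpm), spec$expected_tau[1])

  # splicing-efficiency ground truth recovered from the emitted tables
  sp_tbl <- ex$expression |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(spliced_tpm = sum(tpm), .groups = "drop") |>
    dplyr::left_join(
      ex$unspliced |>
        dplyr::group_by(gene_id) |>
        dplyr::summarise(unspliced_tpm = sum(tpm), .groups = "drop"),
      by = "gene_id"
    )
  est <- vapply(seq_len(nrow(sp_tbl)), function(i) {
    splicing_efficiency(sp_tbl$spliced_tpm[i], sp_tbl$unspliced_tpm[i])
  }, numeric(1))
  truth <- ex$truth$splicing_efficiency[match(sp_tbl$gene_id, ex$truth$gene_id)]
  expect_true(all(abs(est - truth) <= 0.05))
})

test_that("screen count generator is deterministic and encodes the planted effects", {
  map <- toy_guide_map(n_tss = 30, guides_per_tss = 10, n_ctrl = 100)
  truth <- sim_screen_truth(map, n_functional = 3, effect_size = 2, pi_guide = 1, seed = 4)
  expect_length(truth$functional_tss, 3)
  expect_true(all(truth$tss_effects$effect[truth$tss_effects$tss_id %in% truth$functional_tss] == 2))
  expect_true(all(truth$tss_effects$effect[!truth$tss_effects$tss_id %in% truth$functional_tss] == 0))

  sc1 <- sim_screen_counts(map, truth, depth = 300, seed = 4)
  sc2 <- sim_screen_counts(map, truth, depth = 300, seed = 4)
  expect_identical(sc1$counts, sc2$counts)

  # fully effective guides of a functional TSS rank in the top decile
  enr <- estimate_enrichment(sc1$counts)
  j <- dplyr::inner_join(enr, sc1$guide_truth, by = "guide_id")
  planted <- j$log2fc[j$efficiency == 1]
  cutoff <- quantile(j$log2fc, 0.9)
  expect_true(all(planted > cutoff))
})

test_that("a null screen leaves targeting guides indistinguishable from scrambled", {
  map <- toy_guide_map(n_tss = 50, guides_per_tss = 10, n_ctrl = 200)
  rejections <- vapply(1:10, function(s) {
    truth <- sim_screen_truth(map, n_functional = 0, seed = s)
    sc <- sim_screen_counts(map, truth, depth = 300, seed = s)
    enr <- estimate_enrichment(sc$counts)
    j <- dplyr::inner_join(enr, map, by = "guide_id")
    stats::wilcox.test(j$log2fc[!j$is_control], j$log2fc[j$is_control])$p.value < 0.01
  }, logical(1))
  expect_lte(mean(rejections), 0.2)
})

test_that("guides with expected day-0 cpm below threshold are removed at stage 1", {
  map <- toy_guide_map(n_tss = 40, guides_per_tss = 10, n_ctrl = 100)
  truth <- sim_screen_truth(map, n_functional = 0, seed = 2)
  sc <- suppressWarnings(sim_screen_counts(map, truth,
    depth = 1000, dropout_frac = 0.05,
    dropout_factor = 0.001, seed = 2
  ))
  fc <- filter_cascade(sc$counts, map)
  j <- dplyr::inner_join(fc$guides, sc$guide_truth, by = "guide_id")
  exp_cpm <- j$abundance / sum(j$abundance) * 1e6
  expect_lt(mean(j$pass_stage1[exp_cpm < 2.5]), 0.2)
  expect_gt(mean(j$pass_stage1[exp_cpm > 50]), 0.99)
})
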