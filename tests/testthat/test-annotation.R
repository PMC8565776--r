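test_that("lncRNA categorization applies the 1000-bp rules with precedence", {
  mk <- function(lnc_start, lnc_end, lnc_strand = "+",
                 pc_start = 10000L, pc_end = 14000L, pc_strand = "+") {
    tibble::tibble(
      transcript_id = c("tx_pc", "tx_lnc"),
      gene_id = c("pc", "lnc"),
      chrom = "chr1",
      strand = c(pc_strand, lnc_strand),
      start = c(pc_start, lnc_start),
      end = c(pc_end, lnc_end),
      biotype = c("protein_coding", "lncRNA"),
      coding_orf_flag = FALSE
    )
  }
  cat_of <- function(ann, ...) as.character(categorize_lncrna(ann, ...)$category)

  # start 500 bp from a protein-coding start -> promoter_overlapping
  expect_equal(cat_of(mk(10500L, 11500L)), "promoter_overlapping")
  # all distances > 1000 and no overlap -> intergenic
  expect_equal(cat_of(mk(20000L, 30000L, pc_start = 5000L, pc_end = 6000L)), "intergenic")
  # overlapping transcripts with starts 3000 bp apart -> transcript_overlapping
  expect_equal(cat_of(mk(5000L, 9000L, pc_start = 8000L, pc_end = 12000L)), "transcript_overlapping")
  # downstream within 1000 bp of the gene end, no overlap -> gene_nearby
  expect_equal(cat_of(mk(14500L, 15500L)), "gene_nearby")
  # boundary: exactly 1000 bp is "within"
  expect_equal(cat_of(mk(11000L, 12000L)), "promoter_overlapping")
  # 1001 bp away but overlapping -> precedence falls through to overlap
  expect_equal(cat_of(mk(11001L, 12000L)), "transcript_overlapping")

  # strand-aware vs gene-start promoter rule: minus-strand lncRNA ending
  # (i.e. starting, 5'-wise) near the pc start
  ann <- mk(8800L, 9800L, lnc_strand = "-")
  expect_equal(cat_of(ann, promoter_rule = "tss"), "promoter_overlapping")
  # gene-start rule uses genomic min: 10000 - 8800 = 1200 > 1000
  expect_equal(cat_of(ann, promoter_rule = "gene_start"), "gene_nearby")
})

test_that("categorization is total and defaults to intergenic without protein-coding genes", {
  sim <- sim_annotation(seed = 7)
  cats <- categorize_lncrna(sim$annotation)
  expect_equal(nrow(cats), sum(grepl("^lnc", unique(sim$annotation$gene_id))))
  expect_false(any(is.na(cats$category)))
  expect_equal(sum(table(cats$category)), nrow(cats))

  lnc_only <- dplyr::filter(sim$annotation, biotype == "lncRNA")
  cats0 <- categorize_lncrna(lnc_only)
  expect_true(all(cats0$category == "intergenic"))
})

test_that("ORF-flagged lncRNAs are excluded from categorization", {
  ann <- toy_annotation()
  ann$coding_orf_flag[ann$gene_id == "lnc1"] <- TRUE
  expect_equal(nrow(categorize_lncrna(ann)), 0)
})

test_that("TSS assignment follows the explicit > CAGE-within-400bp > annotated fallback", {
  ann <- toy_annotation()
  tx_lnc <- "tx_lnc1" # plus strand, 5' end 30000

  # explicit assignment wins
  res <- assign_tss(ann, explicit_tss = tibble::tibble(transcript_id = tx_lnc, position = 1234L))
  row <- res[res$transcript_id == tx_lnc, ]
  expect_equal(row$position, 1234L)
  expect_equal(row$source, "fantom_cat_explicit")

  # same-strand CAGE at 300 bp wins over a closer opposite-strand peak
  cage <- tibble::tibble(
    chrom = "chr1", position = c(29700L, 30010L), strand = c("+", "-")
  )
  row <- assign_tss(ann, cage = cage)
  row <- row[row$transcript_id == tx_lnc, ]
  expect_equal(row$position, 29700L)
  expect_equal(row$source, "cage_proximal")

  # 450 bp away exceeds the 400-bp window -> annotated 5' end
  cage_far <- tibble::tibble(chrom = "chr1", position = 30450L, strand = "+")
  row <- assign_tss(ann, cage = cage_far)
  row <- row[row$transcript_id == tx_lnc, ]
  expect_equal(row$position, 30000L)
  expect_equal(row$source, "annotated_5prime")

  # equidistant peaks break toward the 5'-most position on the strand
  cage_tie <- tibble::tibble(chrom = "chr1", position = c(29900L, 30100L), strand = "+")
  row <- assign_tss(ann, cage = cage_tie)
  expect_equal(row$position[row$transcript_id == tx_lnc], 29900L)

  minus <- ann
  minus$strand <- "-"
  cage_tie_m <- tibble::tibble(chrom = "chr1", position = c(30899L, 31099L), strand = "-")
  row <- assign_tss(minus, cage = cage_tie_m) # 5' end of tx_lnc1 is 30999
  expect_equal(row$position[row$transcript_id == tx_lnc], 31099L)

  # without any CAGE track, every source is annotated_5prime
  expect_true(all(assign_tss(ann)$source == "annotated_5prime"))
})

test_that("TSS consolidation merges exact coordinates only", {
  tss <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    tss_id = c("chr1:5000:+", "chr1:5000:+", "chr1:5001:+"),
    chrom = "chr1", strand = "+",
    position = c(5000L, 5000L, 5001L),
    source = "annotated_5prime"
  )
  cons <- consolidate_tss(tss)
  expect_equal(nrow(cons), 2)
  expect_equal(cons$transcript_ids[cons$position == 5000], "t1,t2")
  expect_equal(cons$n_transcripts, c(2L, 1L))
  expect_equal(nrow(consolidate_tss(tss[0, ])), 0)
})

test_that("annotation validation rejects malformed transcripts", {
  ann <- toy_annotation()
  bad <- ann
  bad$strand[2] <- "-"
  expect_error(validate_annotation(bad), "mixed strand")
  bad2 <- ann
  bad2$end[1] <- 9000L
  expect_error(validate_annotation(bad2), "end < start")
  bad3 <- ann
  bad3$start[2] <- 10500L # overlaps exon 1 of the same transcript
  expect_error(validate_annotation(bad3), "overlapping")
})
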