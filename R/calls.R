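#' Top-3 effect size per TSS
#'
#' The mixture model reports an FDR but no effect size, so each TSS's effect
#' is summarised as the mean log2 fold-change of its 3 most enriched guides.
#' TSSs with fewer than `min_guides` filtered guides get `NA` (flagged). The
#' mean is invariant to guide ordering and to ties at the cut rank.
#'
#' @param enrichment Tibble (`guide_id`, `log2fc`) of filtered guides.
#' @param guide_map Tibble (`guide_id`, `target_tss_id`, `is_control`).
#' @param min_guides Minimum filtered guides for a defined effect (default 3).
#' @param top_n Number of top guides averaged (default 3).
#' @return Tibble: `tss_id`, `n_guides`, `effect_size`,
#'   `effect_size_defined`.
#' @export
tss_effect_sizes <- function(enrichment, guide_map, min_guides = 3, top_n = 3) {
  inner_join(enrichment, guide_map, by = "guide_id") |>
    filter(!.data$is_control) |>
    mutate(tss_id = strsplit(.data$target_tss_id, ",")) |>
    tidyr::unnest("tss_id") |>
    group_by(.data$tss_id) |>
    summarise(
      n_guides = n(),
      effect_size = if (n() >= min_guides) {
        mean(sort(.data$log2fc, decreasing = TRUE)[seq_len(top_n)])
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    mutate(effect_size_defined = !is.na(.data$effect_size))
}

#' Classify TSS calls into hits and stringent non-hits
#'
#' Hits are TSSs with `fdr < fdr_hit`. "Stringent non-hits" are the
#' well-powered negatives used as the comparison group in feature analyses:
#' TSSs with at least `min_guides_nonhit` filtered guides *and*
#' `fdr > fdr_nonhit`. The two labels are mutually exclusive; everything else
#' stays unlabeled.
#'
#' @param calls Per-TSS tibble with `tss_id`, `fdr`, `n_guides` (e.g.
#'   `tidy()` of a [fit_guide_mixture()] fit joined to
#'   [tss_effect_sizes()]).
#' @param fdr_hit Hit threshold (default 0.1).
#' @param fdr_nonhit Stringent non-hit threshold (default 0.9).
#' @param min_guides_nonhit Guide-count requirement for stringent non-hits
#'   (default 9).
#' @param gene_map Optional tibble (`tss_id`, `gene_id`); when given, a
#'   gene-level `nonhit_genes` attribute holds the unique stringent non-hit
#'   genes (a gene with any hit TSS is excluded).
#' @return `calls` with logical `is_hit` and `is_stringent_nonhit` columns.
#' @export
classify_tss <- function(calls, fdr_hit = 0.1, fdr_nonhit = 0.9,
                         min_guides_nonhit = 9, gene_map = NULL) {
  out <- calls |>
    mutate(
      is_hit = .data$fdr < fdr_hit,
      is_stringent_nonhit = .data$fdr > fdr_nonhit &
        .data$n_guides >= min_guides_nonhit
    )
  if (!is.null(gene_map)) {
    joined <- inner_join(out, gene_map, by = "tss_id")
    hit_genes <- unique(joined$gene_id[joined$is_hit])
    nonhit_genes <- setdiff(unique(joined$gene_id[joined$is_stringent_nonhit]), hit_genes)
    attr(out, "nonhit_genes") <- sort(nonhit_genes)
    attr(out, "hit_genes") <- sort(hit_genes)
  }
  out
}

#' Validation enrichment score for an individually tested guide
#'
#' For a guide tested outside the pooled screen, compares its ratio of
#' undifferentiated to differentiated cells with that of a scrambled control
#' measured in the same batch:
#' `log2((pct_undiff / pct_diff) / (pct_undiff_scr / pct_diff_scr))`.
#' Zero percentages are floored at `floor_pct` (default 0.1) to keep the log
#' defined, with a warning. The definition is isolated here so it can be
#' swapped by configuration.
#'
#' @param pct_undiff,pct_diff Percent undifferentiated/differentiated cells
#'   for the tested guide.
#' @param pct_undiff_scr,pct_diff_scr Same percentages for the matched
#'   scrambled control.
#' @param floor_pct Floor applied to zero percentages (default 0.1).
#' @return Numeric validation score(s); positive = more undifferentiated than
#'   the matched control.
#' @export
validation_score <- function(pct_undiff, pct_diff, pct_undiff_scr, pct_diff_scr,
                             floor_pct = 0.1) {
  vals <- list(pct_undiff, pct_diff, pct_undiff_scr, pct_diff_scr)
  if (any(unlist(vals) == 0)) {
    warn(sprintf("zero percentage floored at %.2f%%", floor_pct))
  }
  f <- function(v) pmax(v, floor_pct)
  log2((f(pct_undiff) / f(pct_diff)) / (f(pct_undiff_scr) / f(pct_diff_scr)))
}

#' Compare genomic features between hits and stringent non-hits
#'
#' Per feature, a two-sided Mann-Whitney (Wilcoxon rank-sum) test of hit vs
#' stringent non-hit values, with Benjamini-Hochberg adjustment across
#' features and a significance flag at the adjusted-FDR threshold. Features
#' with all-missing values in either group are skipped with a warning.
#'
#' @param features Tibble with `gene_id` and numeric feature columns.
#' @param hit_ids,nonhit_ids Character vectors of gene ids in each group.
#' @param feature_cols Feature columns to test (default: all numeric columns
#'   except `gene_id`).
#' @param fdr Significance threshold on the BH-adjusted p (default 0.10).
#' @return Tibble: `feature`, `statistic` (U), `p_value`, `q_value`,
#'   `median_hit`, `median_nonhit`, `significant`.
#' @export
compare_hit_features <- function(features, hit_ids, nonhit_ids,
                                 feature_cols = NULL, fdr = 0.10) {
  if (length(hit_ids) == 0 || length(nonhit_ids) == 0) {
    abort("both hit and non-hit groups must be non-empty")
  }
  if (is.null(feature_cols)) {
    feature_cols <- names(features)[vapply(features, is.numeric, logical(1))]
    feature_cols <- setdiff(feature_cols, "n_missing_features")
  }
  h <- features[features$gene_id %in% hit_ids, , drop = FALSE]
  nh <- features[features$gene_id %in% nonhit_ids, , drop = FALSE]
  rows <- map(feature_cols, function(f) {
    x <- h[[f]][!is.na(h[[f]])]
    y <- nh[[f]][!is.na(nh[[f]])]
    if (length(x) == 0 || length(y) == 0) {
      warn(sprintf("feature '%s' has no non-missing values in a group; skipped", f))
      return(NULL)
    }
    w <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    tibble(
      feature = f, statistic = unname(w$statistic), p_value = w$p.value,
      median_hit = median(x), median_nonhit = median(y)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(
      feature = character(), statistic = numeric(), p_value = numeric(),
      q_value = numeric(), median_hit = numeric(), median_nonhit = numeric(),
      significant = logical()
    ))
  }
  out |>
    mutate(
      q_value = p.adjust(.data$p_value, method = "BH"),
      significant = .data$q_value < fdr
    ) |>
    select(
      "feature", "statistic", "p_value", "q_value",
      "median_hit", "median_nonhit", "significant"
    )
}

#' Association between screen hits and differential expression
#'
#' Tests whether hit loci are enriched among differentially expressed loci
#' with a two-sided Fisher's exact test on the 2x2 table of
#' (hit vs stringent non-hit) x (DE vs not DE). Reports the sample odds ratio
#' `ad/bc` by default, or the conditional-ML estimate from the exact test.
#'
#' @param hit_de Logical vector of DE status for hit loci.
#' @param nonhit_de Logical vector of DE status for stringent non-hit loci.
#' @param or_type "sample" (`ad/bc`, default) or "cml".
#' @return Tibble with the four cell counts, `odds_ratio` (NA on a zero
#'   margin for the sample OR) and two-sided `p_value`; the 2x2 matrix rides
#'   along as attribute `"table"`.
#' @export
de_hit_association <- function(hit_de, nonhit_de, or_type = c("sample", "cml")) {
  or_type <- match.arg(or_type)
  a <- sum(hit_de)
  b <- sum(!hit_de)
  c_ <- sum(nonhit_de)
  d <- sum(!nonhit_de)
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
    dimnames = list(c("hit", "stringent_nonhit"), c("de", "not_de"))
  )
  ft <- fisher.test(tab, alternative = "two.sided")
  or <- if (or_type == "sample") {
    if (b == 0 || c_ == 0) NA_real_ else (a * d) / (b * c_)
  } else {
    unname(ft$estimate)
  }
  out <- tibble(
    n_hit_de = a, n_hit_not_de = b, n_nonhit_de = c_, n_nonhit_not_de = d,
    odds_ratio = or, p_value = ft$p.value, or_type = or_type
  )
  attr(out, "table") <- tab
  out
}
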