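#' Tau tissue-specificity statistic
#'
#' For an expression vector `x` across `n` lineages,
#' `tau = sum(1 - x / max(x)) / (n - 1)`. Ubiquitously expressed genes score
#' near 0, single-lineage genes score 1. Robust to low expression and
#' scale-invariant.
#'
#' @param x Non-negative expression vector (one value per lineage, n >= 2).
#' @return Tau in \[0, 1\]; `NA` when `max(x) == 0`.
#' @export
tau <- function(x) {
  if (length(x) < 2L) abort("tau needs expression in at least 2 lineages")
  if (any(x < 0, na.rm = TRUE)) abort("expression must be non-negative")
  m <- max(x)
  if (is.na(m) || m == 0) return(NA_real_)
  sum(1 - x / m) / (length(x) - 1)
}

# Per-lineage replicate means at transcript or gene level, from the long
# expression table (transcript_id, gene_id, biotype, lineage, replicate, tpm).
lineage_means <- function(expression, level = c("transcript", "gene")) {
  level <- match.arg(level)
  id_col <- if (level == "transcript") "transcript_id" else "gene_id"
  by_sample <- if (level == "gene") {
    # gene-level tpm is the sum of the gene's transcript tpms
    expression |>
      group_by(.data$gene_id, .data$lineage, .data$replicate) |>
      summarise(tpm = sum(.data$tpm), .groups = "drop")
  } else {
    expression
  }
  by_sample |>
    group_by(.data[[id_col]], .data$lineage) |>
    summarise(tpm = mean(.data$tpm), .groups = "drop") |>
    rename(id = all_of(id_col))
}

#' Expressed transcripts or genes above a tpm threshold
#'
#' A transcript (or gene: transcript tpms summed per sample) is called
#' expressed when its replicate-mean tpm reaches `threshold_tpm` in at least
#' one lineage (`mode = "lineage_mean"`, the default) or when any single
#' sample reaches the threshold (`mode = "any_sample"`).
#'
#' @param expression Long expression tibble (`transcript_id`, `gene_id`,
#'   `lineage`, `replicate`, `tpm`).
#' @param threshold_tpm Expression threshold (default 0.1 tpm).
#' @param level "transcript" or "gene".
#' @param mode "lineage_mean" (default) or "any_sample".
#' @return Character vector of expressed ids.
#' @export
expressed_set <- function(expression, threshold_tpm = 0.1,
                          level = c("transcript", "gene"),
                          mode = c("lineage_mean", "any_sample")) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  id_col <- if (level == "transcript") "transcript_id" else "gene_id"
  tbl <- if (mode == "lineage_mean") {
    lineage_means(expression, level)
  } else {
    base <- if (level == "gene") {
      expression |>
        group_by(.data$gene_id, .data$lineage, .data$replicate) |>
        summarise(tpm = sum(.data$tpm), .groups = "drop")
    } else {
      expression
    }
    rename(base, id = all_of(id_col))
  }
  tbl |>
    group_by(.data$id) |>
    summarise(expressed = any(.data$tpm >= threshold_tpm), .groups = "drop") |>
    filter(.data$expressed) |>
    pull(.data$id)
}

#' Tau per transcript or gene from an expression table
#'
#' Replicates are averaged within lineage before tau is computed.
#'
#' @inheritParams expressed_set
#' @return Tibble: `id`, `tau`, `n_lineages`, `max_expression`.
#' @export
calc_tau <- function(expression, level = c("gene", "transcript")) {
  level <- match.arg(level)
  lineage_means(expression, level) |>
    group_by(.data$id) |>
    summarise(
      tau = tau(.data$tpm),
      n_lineages = n(),
      max_expression = max(.data$tpm),
      .groups = "drop"
    )
}

#' Compare tau distributions between gene groups
#'
#' Summarises tissue specificity per group (e.g. lncRNA vs mRNA vs
#' transcription factors) and runs two-sided Wilcoxon rank-sum tests between
#' every pair of groups. Groups with fewer than 2 members are skipped with a
#' warning.
#'
#' @param tau_table Tibble with `id`, `group`, `tau` (NA taus are dropped).
#' @return List with `summary` (per-group n/median/mean) and `tests`
#'   (pairwise `group1`, `group2`, `statistic`, `p_value`).
#' @export
specificity_compare <- function(tau_table) {
  tt <- filter(tau_table, !is.na(.data$tau))
  sizes <- count(tt, .data$group)
  small <- sizes$group[sizes$n < 2]
  if (length(small) > 0) {
    warn(paste0("skipping groups with < 2 members: ", paste(small, collapse = ", ")))
    tt <- filter(tt, !.data$group %in% small)
  }
  summary <- tt |>
    group_by(.data$group) |>
    summarise(
      n = n(), median_tau = median(.data$tau), mean_tau = mean(.data$tau),
      .groups = "drop"
    )
  groups <- sort(unique(tt$group))
  pairs <- if (length(groups) >= 2) utils::combn(groups, 2, simplify = FALSE) else list()
  tests <- bind_rows(map(pairs, function(p) {
    x <- tt$tau[tt$group == p[1]]
    y <- tt$tau[tt$group == p[2]]
    w <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    tibble(group1 = p[1], group2 = p[2], statistic = unname(w$statistic), p_value = w$p.value)
  }))
  list(summary = summary, tests = tests)
}

#' Simple differential-expression test between two lineages
#'
#' A plumbing test for synthetic pipelines: per transcript, a Welch t-test on
#' `log2(tpm + 0.01)` between the two lineages with Benjamini-Hochberg
#' correction. This deliberately simple test exists so the end-to-end
#' synthetic pipeline runs self-contained; differential-expression calls for
#' real screens should come from a bootstrap-aware engine and be supplied as
#' input q-values. The output carries `method = "welch_t_plumbing"` to make
#' that explicit.
#'
#' @param expression Long expression tibble.
#' @param lineage_a,lineage_b Lineages to compare (log2FC is a minus b, so a
#'   positive value means higher in `lineage_a`).
#' @return Tibble: `transcript_id`, `log2fc`, `p_value`, `q_value`,
#'   `zero_variance` flag, `method`.
#' @export
simple_de_test <- function(expression, lineage_a, lineage_b) {
  wide <- expression |>
    filter(.data$lineage %in% c(lineage_a, lineage_b)) |>
    mutate(logtpm = log2(.data$tpm + 0.01))
  res <- wide |>
    group_by(.data$transcript_id) |>
    summarise(
      log2fc = mean(.data$logtpm[.data$lineage == lineage_a]) -
        mean(.data$logtpm[.data$lineage == lineage_b]),
      p_value = {
        a <- .data$logtpm[.data$lineage == lineage_a]
        b <- .data$logtpm[.data$lineage == lineage_b]
        if (length(a) < 2 || length(b) < 2) abort("need >= 2 replicates per lineage")
        if (sd(a) == 0 && sd(b) == 0) 1 else t.test(a, b)$p.value
      },
      zero_variance = sd(.data$logtpm[.data$lineage == lineage_a]) == 0 &&
        sd(.data$logtpm[.data$lineage == lineage_b]) == 0,
      .groups = "drop"
    )
  res |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH"), method = "welch_t_plumbing")
}
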