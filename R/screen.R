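#' Counts per million per sample
#'
#' @param counts Long count tibble (`guide_id`, `population`, `replicate`,
#'   `count`).
#' @return Input with a `cpm` column; within each (population, replicate)
#'   sample, `cpm = count / sum(count) * 1e6`.
#' @export
add_cpm <- function(counts) {
  counts |>
    group_by(.data$population, .data$replicate) |>
    mutate(
      cpm = {
        tot <- sum(.data$count)
        if (tot == 0) abort("empty sample column: total count is 0")
        .data$count / tot * 1e6
      }
    ) |>
    ungroup()
}

#' Three-stage guide filtering cascade
#'
#' Removes noisy guides before enrichment modelling, in three consecutive
#' steps:
#'
#' 1. keep guides with cpm >= `cpm_day0` in *every* day-0 replicate (poor
#'    initial representation);
#' 2. of those, keep guides with cpm >= `cpm_undiff` in *every*
#'    undifferentiated replicate (conservative FACS gating leaves small,
#'    noisy undifferentiated samples);
#' 3. drop targeting guides whose target TSS has fewer than `min_guides`
#'    guides surviving stages 1-2. Scrambled controls have no TSS and are
#'    exempt from stage 3.
#'
#' Thresholds are applied as `>=` with exact boundary inclusion, on cpm from
#' raw library sizes (the filter precedes size-factor normalisation). A guide
#' targeting several TSSs survives stage 3 if any of its targets keeps >= 3
#' guides.
#'
#' @param counts Long count tibble with populations `day0`, `differentiated`,
#'   `undifferentiated`.
#' @param guides Guide map tibble (`guide_id`, `target_tss_id` (NA or
#'   comma-separated), `is_control`).
#' @param cpm_day0,cpm_undiff,min_guides Filter thresholds (defaults 5, 1, 3).
#' @return List of class `filter_cascade`: `guides` (per-guide pass flags,
#'   `filtered` = survives all stages), `report` (per-stage guide/TSS/control
#'   survivor counts), `tss_guides` (filtered guide count per TSS).
#' @export
filter_cascade <- function(counts, guides, cpm_day0 = 5, cpm_undiff = 1,
                           min_guides = 3) {
  pops <- unique(counts$population)
  if (!all(c("day0", "undifferentiated") %in% pops)) {
    abort("counts must contain day0 and undifferentiated populations")
  }
  cc <- add_cpm(counts)
  pass_all <- function(pop, thr) {
    cc |>
      filter(.data$population == pop) |>
      group_by(.data$guide_id) |>
      summarise(pass = all(.data$cpm >= thr), .groups = "drop")
  }
  s1 <- pass_all("day0", cpm_day0)
  s2 <- pass_all("undifferentiated", cpm_undiff)
  g <- guides |>
    left_join(rename(s1, pass_stage1 = "pass"), by = "guide_id") |>
    left_join(rename(s2, pass_stage2 = "pass"), by = "guide_id") |>
    mutate(
      pass_stage1 = coalesce(.data$pass_stage1, FALSE),
      pass_stage2 = .data$pass_stage1 & coalesce(.data$pass_stage2, FALSE)
    )
  surv12 <- g |> filter(.data$pass_stage2, !.data$is_control)
  tss_counts <- surv12 |>
    mutate(tss = strsplit(.data$target_tss_id, ",")) |>
    tidyr::unnest(tss) |>
    count(.data$tss, name = "n_filtered_guides")
  keep_tss <- tss_counts$tss[tss_counts$n_filtered_guides >= min_guides]
  g <- g |>
    mutate(
      pass_stage3 = .data$pass_stage2 & (
        .data$is_control |
          map_lgl(strsplit(.data$target_tss_id, ","), function(t) any(t %in% keep_tss))
      ),
      filtered = .data$pass_stage3
    )
  tss_per_stage <- function(col) {
    gg <- g |> filter(.data[[col]], !.data$is_control)
    length(unique(unlist(strsplit(gg$target_tss_id, ","))))
  }
  report <- tibble(
    stage = c("input", "day0_cpm", "undiff_cpm", "min_guides_per_tss"),
    n_guides = c(
      nrow(g), sum(g$pass_stage1), sum(g$pass_stage2), sum(g$pass_stage3)
    ),
    n_tss = c(
      tss_per_stage_static(g, NULL), tss_per_stage("pass_stage1"),
      tss_per_stage("pass_stage2"), tss_per_stage("pass_stage3")
    ),
    n_scrambled = c(
      sum(g$is_control), sum(g$is_control & g$pass_stage1),
      sum(g$is_control & g$pass_stage2), sum(g$is_control & g$pass_stage3)
    )
  )
  structure(
    list(
      guides = select(
        g, "guide_id", "target_tss_id", "is_control",
        "pass_stage1", "pass_stage2", "pass_stage3", "filtered"
      ),
      report = report,
      tss_guides = g |>
        filter(.data$filtered, !.data$is_control) |>
        mutate(tss_id = strsplit(.data$target_tss_id, ",")) |>
        tidyr::unnest("tss_id") |>
        count(.data$tss_id, name = "n_filtered_guides")
    ),
    class = "filter_cascade"
  )
}

tss_per_stage_static <- function(g, ...) {
  gg <- g[!g$is_control, , drop = FALSE]
  length(unique(unlist(strsplit(gg$target_tss_id, ","))))
}

#' @export
print.filter_cascade <- function(x, ...) {
  cat("Guide filtering cascade\n")
  print(x$report, ...)
  invisible(x)
}

# Median-of-ratios size factors across the sorted samples (DESeq-style):
# reference = per-guide geometric mean over samples; factor = median ratio
# over guides positive in all samples.
size_factors <- function(mat) {
  pos <- rowSums(mat > 0) == ncol(mat)
  if (!any(pos)) abort("no guide has positive counts in all sorted samples")
  logref <- rowMeans(log(mat[pos, , drop = FALSE]))
  apply(mat[pos, , drop = FALSE], 2, function(col) exp(median(log(col) - logref)))
}

#' Batch-aware guide enrichment estimation
#'
#' Estimates, per guide, the log2 fold-change of undifferentiated over
#' differentiated counts: a positive value means the guide's cells dropped
#' out of differentiation. Counts of the sorted samples are normalised with
#' median-of-ratios size factors, then each replicate contributes a paired
#' log-ratio `log2((undiff + c) / (diff + c))` and replicates are averaged —
#' a replicate-blocked estimator whose pairing plays the role of a batch term,
#' with the standard error taken from the between-replicate spread.
#'
#' @param counts Long count tibble with `differentiated` and
#'   `undifferentiated` populations for each replicate.
#' @param filtered_guides Optional character vector restricting the output
#'   (size factors still use all guides).
#' @param pseudocount Added to normalised counts before the log ratio
#'   (default 0.5).
#' @return Tibble: `guide_id`, `log2fc`, `se` (NA with a single replicate),
#'   `n_replicates`.
#' @export
estimate_enrichment <- function(counts, filtered_guides = NULL, pseudocount = 0.5) {
  sorted <- counts |>
    filter(.data$population %in% c("differentiated", "undifferentiated")) |>
    mutate(sample = paste(.data$population, .data$replicate, sep = "_"))
  reps <- sort(unique(sorted$replicate))
  have <- sorted |> distinct(.data$population, .data$replicate)
  complete <- vapply(reps, function(r) {
    all(c("differentiated", "undifferentiated") %in% have$population[have$replicate == r])
  }, logical(1))
  if (!any(complete)) abort("need at least one replicate with both sorted populations")
  reps <- reps[complete]
  wide <- sorted |>
    filter(.data$replicate %in% reps) |>
    select("guide_id", "sample", "count") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "count", values_fill = 0L)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$guide_id
  sf <- size_factors(mat)
  norm <- sweep(mat, 2, sf, "/")
  lfc_rep <- vapply(reps, function(r) {
    u <- norm[, paste0("undifferentiated_", r)]
    d <- norm[, paste0("differentiated_", r)]
    log2((u + pseudocount) / (d + pseudocount))
  }, numeric(nrow(norm)))
  lfc_rep <- matrix(lfc_rep, nrow = nrow(norm))
  out <- tibble(
    guide_id = rownames(mat),
    log2fc = rowMeans(lfc_rep),
    se = if (length(reps) > 1) apply(lfc_rep, 1, sd) / sqrt(length(reps)) else NA_real_,
    n_replicates = length(reps)
  )
  if (!is.null(filtered_guides)) out <- filter(out, .data$guide_id %in% filtered_guides)
  out
}
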