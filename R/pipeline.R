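#' Default pipeline configuration
#'
#' All thresholds default to the screen-design values used throughout the
#' package: 0.1 tpm expression threshold; cpm filters of 5 (day 0) and 1
#' (undifferentiated); >= 3 guides per TSS; hit FDR < 0.1; stringent non-hit
#' FDR > 0.9 with >= 9 guides; feature-comparison BH FDR 0.10; k = 2
#' clusters; 400 bp CAGE reassignment window, 100 bp CAGE count window,
#' 1000 bp proximity rule, 1 Mb enhancer window; 10 guides per TSS; 500 x 10
#' scrambled controls. Every value can be overridden.
#'
#' @param ... Named overrides of any default.
#' @return Named list of class `screen_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    threshold_tpm = 0.1,
    cpm_day0 = 5,
    cpm_undiff = 1,
    min_guides = 3,
    fdr_hit = 0.1,
    fdr_nonhit = 0.9,
    min_guides_nonhit = 9,
    feature_fdr = 0.10,
    k_clusters = 2,
    cage_window = 400,
    cage_count_window = 100,
    proximity_window = 1000,
    enhancer_window = 1e6,
    guides_per_tss = 10,
    n_scrambled_seeds = 500,
    scrambles_per_seed = 10,
    pseudocount = 0.5,
    n_restarts = 5,
    seed = 1L,
    sim = list(
      n_mrna = 12,
      category_mix = c(
        intergenic = 5, promoter_overlapping = 5,
        transcript_overlapping = 5, gene_nearby = 5
      ),
      n_functional = 4,
      effect_size = 2,
      pi_guide = 0.5,
      depth = 500,
      n_reps = 2,
      undiff_frac = 0.1,
      noise_cv = 0.2
    )
  )
  overrides <- list(...)
  structure(modifyList(cfg, overrides), class = "screen_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' `write_config(read_config(p), p2)` round-trips exactly.
#'
#' @param path YAML file path.
#' @return `read_config`: a `screen_config` list. `write_config`: `path`,
#'   invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sim$category_mix)) cfg$sim$category_mix <- unlist(cfg$sim$category_mix)
  structure(modifyList(unclass(default_config()), cfg), class = "screen_config")
}

#' @rdname read_config
#' @param config A `screen_config` list.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$sim$category_mix)) cfg$sim$category_mix <- as.list(cfg$sim$category_mix)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Header comment stamped onto every output table: version, config hash, seed.
output_header <- function(config) {
  hash <- sum(utf8ToInt(paste(deparse(unclass(config)), collapse = ""))) %% 1e6
  sprintf(
    "# lncscreen %s | config_hash=%06d | seed=%s",
    as.character(packageVersion("lncscreen")), hash, config$seed
  )
}

#' Write a result table as TSV with a provenance header comment
#'
#' @param x Data frame.
#' @param path Output path.
#' @param config Pipeline configuration (stamped into the header).
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(x, path, config = default_config()) {
  writeLines(output_header(config), path)
  suppressWarnings(utils::write.table(
    x, path,
    append = TRUE, sep = "\t", quote = FALSE, row.names = FALSE
  ))
  invisible(path)
}

#' Read a tabular file written by the pipeline (TSV; CSV accepted by sniffing)
#'
#' @param path Input path; `#`-prefixed header comments are skipped.
#' @return Tibble.
#' @export
read_screen_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing input file: %s", path))
  first <- readLines(path, n = 5)
  first <- first[!startsWith(first, "#")]
  sep <- if (grepl("\t", first[1])) "\t" else ","
  as_tibble(utils::read.table(path,
    header = TRUE, sep = sep, comment.char = "#",
    stringsAsFactors = FALSE, check.names = FALSE
  ))
}

#' Write a toy annotation as GTF
#'
#' @param annotation Exon-level annotation tibble.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  attrs <- sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    annotation$gene_id, annotation$transcript_id, annotation$biotype
  )
  lines <- paste(
    annotation$chrom, "lncscreen", "exon", annotation$start, annotation$end,
    ".", annotation$strand, ".", attrs,
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write genome sequences as FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @param width Line width (default 60).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Call screen hits from counts and a guide map
#'
#' The screen-statistics core in one call: cpm filtering cascade,
#' batch-aware enrichment estimation, hierarchical mixture fit with
#' empirical-null FDR, top-3 effect sizes and hit / stringent non-hit
#' classification.
#'
#' @param counts Long count tibble.
#' @param guide_map Tibble (`guide_id`, `target_tss_id`, `is_control`).
#' @param config A [default_config()] list (thresholds and seeds).
#' @return List: `calls` (per-TSS tibble with fdr, effect size, flags),
#'   `fit` (the `guide_mixture_fit`), `cascade` (the `filter_cascade`),
#'   `enrichment` (per-guide tibble).
#' @export
call_screen_hits <- function(counts, guide_map, config = default_config()) {
  cascade <- filter_cascade(counts, guide_map,
    cpm_day0 = config$cpm_day0, cpm_undiff = config$cpm_undiff,
    min_guides = config$min_guides
  )
  kept <- cascade$guides$guide_id[cascade$guides$filtered]
  enr <- estimate_enrichment(counts, filtered_guides = kept, pseudocount = config$pseudocount)
  fit <- fit_guide_mixture(enr, guide_map,
    n_restarts = config$n_restarts, seed = config$seed
  )
  eff <- tss_effect_sizes(enr, guide_map, min_guides = config$min_guides)
  calls <- tidy(fit) |>
    left_join(select(eff, "tss_id", "effect_size", "effect_size_defined"), by = "tss_id") |>
    classify_tss(
      fdr_hit = config$fdr_hit, fdr_nonhit = config$fdr_nonhit,
      min_guides_nonhit = config$min_guides_nonhit
    )
  list(calls = calls, fit = fit, cascade = cascade, enrichment = enr)
}

#' Run the full synthetic screen pipeline
#'
#' Generates a toy dataset (annotation, expression, guide library, sorted
#' screen counts with ground truth), runs every analysis stage — TSS
#' assignment and consolidation, library design with scrambled controls,
#' the filtering cascade, enrichment estimation, mixture-model hit calling,
#' feature aggregation and k-means mechanism clustering — and writes
#' per-stage TSVs, a JSON report and the resolved configuration into
#' `out_dir`. Deterministic for a fixed `config$seed`.
#'
#' @param config A [default_config()] list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory stage results; files under
#'   `out_dir`.
#' @export
run_screen_pipeline <- function(config = default_config(), out_dir = tempfile("screen_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  sim <- config$sim

  ann <- sim_annotation(
    n_mrna = sim$n_mrna, category_mix = sim$category_mix, seed = seed
  )
  categories <- categorize_lncrna(ann$annotation)
  expr <- sim_expression(ann$annotation, noise_cv = sim$noise_cv, seed = seed + 1L)
  tau_tbl <- calc_tau(expr$expression, level = "gene")
  expressed <- expressed_set(expr$expression, threshold_tpm = config$threshold_tpm)

  tss <- assign_tss(ann$annotation, cage = ann$cage, window = config$cage_window)
  utss <- consolidate_tss(tss)
  cand <- sim_guide_candidates(utss, seed = seed + 2L)
  targeting <- select_guides(cand, tss_ids = utss$tss_id, k = config$guides_per_tss)
  n_seed <- min(config$n_scrambled_seeds, nrow(targeting))
  scrambled <- make_scrambled_controls(targeting,
    n_seed = n_seed, n_per_seed = config$scrambles_per_seed,
    genome = ann$genome, seed = seed + 3L
  )
  library_tbl <- dedup_library(bind_rows(
    select(targeting, "guide_id", "sequence", "target_tss_id", "is_control"),
    select(scrambled, "guide_id", "sequence", "target_tss_id", "is_control")
  ))
  guide_map <- select(library_tbl, "guide_id", "target_tss_id", "is_control")

  truth <- sim_screen_truth(guide_map,
    n_functional = sim$n_functional,
    effect_size = sim$effect_size, pi_guide = sim$pi_guide, seed = seed + 4L
  )
  screen <- sim_screen_counts(guide_map, truth,
    depth = sim$depth,
    n_reps = sim$n_reps, undiff_frac = sim$undiff_frac, seed = seed + 5L
  )
  res <- call_screen_hits(screen$counts, guide_map, config)

  gene_expr_panel <- expr$expression |>
    mutate(sample = paste(.data$lineage, .data$replicate, sep = "_")) |>
    group_by(.data$gene_id, .data$sample) |>
    summarise(tpm = sum(.data$tpm), .groups = "drop")
  splicing_tbl <- expr$expression |>
    group_by(.data$gene_id) |>
    summarise(spliced_tpm = sum(.data$tpm), .groups = "drop") |>
    left_join(
      expr$unspliced |>
        group_by(.data$gene_id) |>
        summarise(unspliced_tpm = sum(.data$tpm), .groups = "drop"),
      by = "gene_id"
    )
  feats <- aggregate_features(ann$annotation,
    genome = ann$genome, cage = ann$cage,
    conservation = NULL, enhancers = NULL,
    expression_panel = gene_expr_panel, splicing = splicing_tbl
  )
  std <- suppressWarnings(standardize_features(feats))
  clust <- cluster_features(std,
    biotype = feats$biotype, k = config$k_clusters,
    seed = seed
  )

  write_screen_tsv(categories, file.path(out_dir, "lncrna_categories.tsv"), config)
  write_screen_tsv(tau_tbl, file.path(out_dir, "tau.tsv"), config)
  write_screen_tsv(utss, file.path(out_dir, "tss.tsv"), config)
  write_screen_tsv(library_tbl, file.path(out_dir, "guide_library.tsv"), config)
  write_screen_tsv(res$enrichment, file.path(out_dir, "guide_enrichment.tsv"), config)
  write_screen_tsv(res$calls, file.path(out_dir, "tss_calls.tsv"), config)
  write_screen_tsv(res$cascade$report, file.path(out_dir, "filter_report.tsv"), config)
  write_screen_tsv(tidy(clust), file.path(out_dir, "cluster_assignments.tsv"), config)
  write_config(config, file.path(out_dir, "config.yaml"))
  write_sim_truth(truth, file.path(out_dir, "sim_truth.json"))
  write_annotation_gtf(ann$annotation, file.path(out_dir, "annotation.gtf"))
  write_genome_fasta(ann$genome, file.path(out_dir, "genome.fa"))

  report <- list(
    n_lncrna = nrow(categories),
    category_counts = as.list(table(categories$category)),
    n_expressed = length(expressed),
    n_tss = nrow(utss),
    n_guides = nrow(library_tbl),
    filter_report = res$cascade$report,
    n_hits = sum(res$calls$is_hit),
    n_stringent_nonhits = sum(res$calls$is_stringent_nonhit),
    n_functional_true = length(truth$functional_tss),
    n_true_hits = sum(res$calls$tss_id[res$calls$is_hit] %in% truth$functional_tss)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    annotation = ann, categories = categories, expression = expr,
    tau = tau_tbl, tss = utss, library = library_tbl, truth = truth,
    screen = screen, calls = res$calls, fit = res$fit,
    cascade = res$cascade, features = feats, clusters = clust,
    report = report, out_dir = out_dir
  ))
}
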