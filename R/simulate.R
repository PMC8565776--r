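#' Generate a toy annotation realizing a requested lncRNA category mix
#'
#' Places protein-coding genes on a toy chromosome with wide spacing, then
#' positions lncRNA genes so that the genomic-context classifier recovers the
#' requested category mix exactly:
#'
#' * `intergenic` lncRNAs sit midway between protein-coding genes, more than
#'   1000 bp from any of them;
#' * `promoter_overlapping` lncRNAs start divergently within 1000 bp of a
#'   host gene's TSS;
#' * `transcript_overlapping` lncRNAs lie inside a host transcript, with
#'   their start more than 1000 bp from the host TSS;
#' * `gene_nearby` lncRNAs start a few hundred bp downstream of a host
#'   gene's 3' end without overlapping it.
#'
#' The chromosome is automatically sized to fit the layout. A random genome
#' sequence and an optional CAGE track (summits jittered around a fraction of
#' the true TSSs) are generated alongside.
#'
#' @param n_mrna Number of protein-coding genes (grown automatically when too
#'   few to host the requested mix comfortably).
#' @param category_mix Named integer vector over the four categories.
#' @param cage_fraction Fraction of transcripts that get a CAGE summit near
#'   their TSS (default 0.5).
#' @param cage_jitter Max CAGE summit offset from the true TSS in bp
#'   (default 50).
#' @param seed RNG seed; fixed seed gives identical output.
#' @return List: `annotation` (exon tibble), `genome` (named character),
#'   `cage` (tibble `chrom`, `position`, `strand`), `truth` (tibble
#'   `gene_id`, `category`).
#' @export
sim_annotation <- function(n_mrna = 12,
                           category_mix = c(
                             intergenic = 5, promoter_overlapping = 5,
                             transcript_overlapping = 5, gene_nearby = 5
                           ),
                           cage_fraction = 0.5, cage_jitter = 50, seed = 1L) {
  stopifnot(all(category_mix >= 0), n_mrna >= 0)
  needed_hosts <- sum(category_mix[c("promoter_overlapping", "transcript_overlapping", "gene_nearby")],
    na.rm = TRUE
  )
  if (needed_hosts > 0 && n_mrna == 0) abort("hosted lncRNA categories require n_mrna > 0")
  n_lnc <- sum(category_mix)
  if (n_mrna < ceiling(needed_hosts / 3) + (sum(category_mix["intergenic"], na.rm = TRUE) > 0)) {
    n_mrna <- ceiling(needed_hosts / 3) + 2
    inform(sprintf("enlarging toy annotation to %d protein-coding genes to fit the layout", n_mrna))
  }
  set.seed(seed)
  chrom <- "chrS1"
  spacing <- 20000L
  exons <- list()
  add_tx <- function(tx_id, gene_id, strand, start, end, biotype, n_exons) {
    # split [start, end] into n_exons exons separated by fixed-size introns
    width <- end - start + 1L
    intron <- max(50L, (width %/% (n_exons * 4L)))
    exon_w <- (width - intron * (n_exons - 1L)) %/% n_exons
    starts <- start + (seq_len(n_exons) - 1L) * (exon_w + intron)
    ends <- starts + exon_w - 1L
    ends[n_exons] <- end
    tibble(
      transcript_id = tx_id, gene_id = gene_id, chrom = chrom, strand = strand,
      start = as.integer(starts), end = as.integer(ends), biotype = biotype,
      coding_orf_flag = FALSE
    )
  }
  pc_start <- 10000L + (seq_len(n_mrna) - 1L) * spacing
  pc_len <- as.integer(sample(4000:6000, n_mrna, replace = TRUE))
  for (i in seq_len(n_mrna)) {
    exons[[length(exons) + 1]] <- add_tx(
      sprintf("tx_pc_%03d", i), sprintf("pc_%03d", i), "+",
      pc_start[i], pc_start[i] + pc_len[i] - 1L, "protein_coding",
      n_exons = sample(2:4, 1)
    )
  }
  lnc_truth <- list()
  li <- 0L
  host <- 0L
  next_host <- function() {
    host <<- host %% n_mrna + 1L
    host
  }
  place <- function(category) {
    li <<- li + 1L
    gid <- sprintf("lnc_%03d", li)
    txid <- sprintf("tx_%s", gid)
    if (category == "intergenic") {
      h <- next_host()
      s <- pc_start[h] + pc_len[h] + 6000L
      len <- as.integer(sample(800:2000, 1))
      strand <- sample(c("+", "-"), 1)
      ex <- add_tx(txid, gid, strand, s, s + len - 1L, "lncRNA", 2L)
    } else if (category == "promoter_overlapping") {
      h <- next_host()
      s <- pc_start[h]
      ex <- add_tx(txid, gid, "-", s - 1500L, s - 300L, "lncRNA", 2L)
    } else if (category == "transcript_overlapping") {
      h <- next_host()
      s <- pc_start[h] + 1800L
      ex <- add_tx(txid, gid, "+", s, s + 800L, "lncRNA", 2L)
    } else { # gene_nearby
      h <- next_host()
      e <- pc_start[h] + pc_len[h] - 1L
      ex <- add_tx(txid, gid, "+", e + 400L, e + 900L, "lncRNA", 2L)
    }
    lnc_truth[[li]] <<- tibble(gene_id = gid, category = category)
    ex
  }
  for (cat_name in c("intergenic", "promoter_overlapping", "transcript_overlapping", "gene_nearby")) {
    k <- category_mix[cat_name]
    if (!is.na(k) && k > 0) {
      for (j in seq_len(k)) exons[[length(exons) + 1]] <- place(cat_name)
    }
  }
  annotation <- validate_annotation(bind_rows(exons))
  chrom_len <- max(annotation$end) + 5000L
  genome <- setNames(
    paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE), collapse = ""),
    chrom
  )
  tx <- transcript_spans(annotation)
  picked <- runif(nrow(tx)) < cage_fraction
  cage <- if (any(picked)) {
    tibble(
      chrom = tx$chrom[picked],
      position = as.integer(tx$tss[picked] +
        sample(-cage_jitter:cage_jitter, sum(picked), replace = TRUE)),
      strand = tx$strand[picked]
    )
  } else {
    tibble(chrom = character(), position = integer(), strand = character())
  }
  list(
    annotation = annotation, genome = genome, cage = cage,
    truth = bind_rows(lnc_truth)
  )
}

#' Generate a 3-lineage x 2-replicate expression table with known structure
#'
#' Each gene is assigned an archetype: "specific" genes express in one
#' lineage with residual leakage elsewhere (expected tau around 0.95),
#' "ubiquitous" genes express comparably everywhere (tau near 0). By default
#' lncRNAs are mostly lineage-specific and mRNAs mostly ubiquitous, echoing
#' the specificity contrast seen between the biotypes. Replicate noise is
#' mean-preserving log-normal at the stated coefficient of variation. A
#' per-gene splicing-efficiency ground truth is realized by emitting an
#' unspliced pre-RNA abundance alongside the spliced transcripts.
#'
#' @param annotation Exon-level annotation tibble.
#' @param lineages Lineage names (default hESC/endoderm/mesoderm).
#' @param n_reps Replicates per lineage (default 2).
#' @param noise_cv Replicate coefficient of variation (default 0.2; 0 makes
#'   replicates identical).
#' @param p_specific_lnc,p_specific_mrna Probability a lncRNA / mRNA gene is
#'   lineage-specific (defaults 0.8 / 0.2).
#' @param leak_frac Off-lineage expression fraction for specific genes
#'   (default 0.05).
#' @param seed RNG seed.
#' @return List: `expression` (long spliced tibble), `unspliced` (long
#'   gene-level pre-RNA tibble), `truth` (per gene: archetype,
#'   `specific_lineage`, `splicing_efficiency`, `expected_tau`),
#'   `profiles` (per gene x lineage mean tpm).
#' @export
sim_expression <- function(annotation, lineages = c("hESC", "endoderm", "mesoderm"),
                           n_reps = 2, noise_cv = 0.2,
                           p_specific_lnc = 0.8, p_specific_mrna = 0.2,
                           leak_frac = 0.05, seed = 1L) {
  set.seed(seed)
  tx <- transcript_spans(annotation)
  genes <- distinct(tx, .data$gene_id, .data$biotype)
  n <- nrow(genes)
  p_spec <- if_else(genes$biotype == "lncRNA", p_specific_lnc, p_specific_mrna)
  specific <- runif(n) < p_spec
  spec_lineage <- sample(lineages, n, replace = TRUE)
  base <- rlnorm(n, log(20), 0.8)
  profiles <- tidyr::crossing(gene_id = genes$gene_id, lineage = lineages) |>
    left_join(
      tibble(gene_id = genes$gene_id, specific, spec_lineage, base),
      by = "gene_id"
    ) |>
    mutate(mean_tpm = if_else(
      .data$specific,
      if_else(.data$lineage == .data$spec_lineage, .data$base, .data$base * leak_frac),
      .data$base
    )) |>
    select("gene_id", "lineage", "mean_tpm")
  se_truth <- tibble(
    gene_id = genes$gene_id, biotype = genes$biotype,
    archetype = if_else(specific, "specific", "ubiquitous"),
    specific_lineage = if_else(specific, spec_lineage, NA_character_),
    splicing_efficiency = if_else(genes$biotype == "protein_coding",
      runif(n, 0.85, 0.98), runif(n, 0.25, 0.75)
    )
  )
  expected_tau <- profiles |>
    group_by(.data$gene_id) |>
    summarise(expected_tau = tau(.data$mean_tpm), .groups = "drop")
  se_truth <- left_join(se_truth, expected_tau, by = "gene_id")

  sdlog <- sqrt(log(1 + noise_cv^2))
  noisy <- function(mu, k) {
    if (noise_cv == 0) rep(mu, k) else rlnorm(k, log(mu) - sdlog^2 / 2, sdlog)
  }
  expression <- tx |>
    select("transcript_id", "gene_id", "biotype") |>
    left_join(profiles, by = "gene_id", relationship = "many-to-many") |>
    group_by(.data$gene_id, .data$lineage) |>
    mutate(mean_tpm = .data$mean_tpm / n()) |> # split gene tpm evenly over transcripts
    ungroup() |>
    tidyr::crossing(replicate = seq_len(n_reps))
  # draw noise grouped so the draw order is deterministic
  expression <- expression |>
    arrange(.data$transcript_id, .data$lineage, .data$replicate) |>
    group_by(.data$transcript_id, .data$lineage) |>
    mutate(tpm = noisy(.data$mean_tpm[1], n())) |>
    ungroup() |>
    select("transcript_id", "gene_id", "biotype", "lineage", "replicate", "tpm")
  unspliced <- expression |>
    group_by(.data$gene_id, .data$lineage, .data$replicate) |>
    summarise(spliced = sum(.data$tpm), .groups = "drop") |>
    left_join(select(se_truth, "gene_id", "splicing_efficiency"), by = "gene_id") |>
    mutate(tpm = .data$spliced * (1 - .data$splicing_efficiency) / .data$splicing_efficiency) |>
    select("gene_id", "lineage", "replicate", "tpm")
  list(
    expression = expression, unspliced = unspliced, truth = se_truth,
    profiles = profiles
  )
}

#' Random ranked guide candidates for each TSS
#'
#' Stands in for an external guide-design tool: emits `n_candidates` random
#' 20-mers per TSS with ranks 1..n (rank 1 best).
#'
#' @param tss Consolidated TSS tibble ([consolidate_tss()]).
#' @param n_candidates Candidates per TSS (default 12).
#' @param guide_length Guide length in nt (default 20).
#' @param seed RNG seed.
#' @return Candidate tibble for [select_guides()].
#' @export
sim_guide_candidates <- function(tss, n_candidates = 12, guide_length = 20, seed = 1L) {
  set.seed(seed)
  n <- nrow(tss) * n_candidates
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), guide_length, replace = TRUE), collapse = "")
  }, character(1))
  tidyr::crossing(target_tss_id = tss$tss_id, candidate_rank = seq_len(n_candidates)) |>
    arrange(.data$target_tss_id, .data$candidate_rank) |>
    mutate(
      sequence = seqs,
      guide_id = sprintf("g_%05d", dplyr::row_number())
    ) |>
    select("guide_id", "sequence", "target_tss_id", "candidate_rank")
}

#' Ground truth for a simulated screen
#'
#' Chooses the functional TSSs, their drop-out effect sizes, and per-guide
#' efficiencies. Efficiency follows the mixture assumption of the hit-calling
#' model — only a subset of a functional TSS's guides work. The default
#' "two_point" model makes each guide of a functional TSS fully effective
#' with probability `pi_guide` and inert otherwise; a Beta option draws
#' graded efficiencies with mean `pi_guide`.
#'
#' @param guide_map Tibble (`guide_id`, `target_tss_id`, `is_control`).
#' @param n_functional Number of functional TSSs.
#' @param effect_size Log2-scale drop-out magnitude of functional TSSs
#'   (scalar or vector recycled over functional TSSs; default 2).
#' @param pi_guide Probability a guide of a functional TSS is effective
#'   (default 0.5).
#' @param efficiency_model "two_point" (default) or "beta"
#'   (Beta(2 pi, 2 (1 - pi))).
#' @param seed RNG seed.
#' @return List of class `sim_truth`: `functional_tss`, `tss_effects`
#'   (tss_id, effect), `guides` (guide_id, efficiency), `seed`.
#' @export
sim_screen_truth <- function(guide_map, n_functional, effect_size = 2,
                             pi_guide = 0.5,
                             efficiency_model = c("two_point", "beta"),
                             seed = 1L) {
  efficiency_model <- match.arg(efficiency_model)
  set.seed(seed)
  tss_ids <- sort(unique(unlist(strsplit(
    guide_map$target_tss_id[!guide_map$is_control], ","
  ))))
  if (n_functional > length(tss_ids)) abort("n_functional exceeds number of targeted TSSs")
  functional <- sort(sample(tss_ids, n_functional))
  effects <- tibble(
    tss_id = tss_ids,
    effect = if_else(tss_ids %in% functional,
      rep_len(effect_size, length(tss_ids)), 0
    )
  )
  first_tss <- vapply(strsplit(guide_map$target_tss_id, ","), function(t) t[1], character(1))
  of_functional <- !guide_map$is_control & first_tss %in% functional
  eff <- numeric(nrow(guide_map))
  k <- sum(of_functional)
  eff[of_functional] <- if (efficiency_model == "two_point") {
    rbinom(k, 1, pi_guide)
  } else {
    stats::rbeta(k, 2 * pi_guide, 2 * (1 - pi_guide))
  }
  structure(
    list(
      functional_tss = functional,
      tss_effects = effects,
      guides = tibble(
        guide_id = guide_map$guide_id, tss_id = first_tss,
        is_control = guide_map$is_control, efficiency = eff
      ),
      pi_guide = pi_guide, efficiency_model = efficiency_model, seed = seed
    ),
    class = "sim_truth"
  )
}

#' Simulate FACS-sorted screen counts with known ground truth
#'
#' Emulates the count-generating process of a sorted differentiation screen:
#'
#' * a log-normal library representation (a small `dropout_frac` of guides is
#'   crippled to exercise the representation filter);
#' * a day-0 sample per replicate, multinomial over the representation;
#' * differentiation failure: cells carrying an effective guide of a
#'   functional TSS fail differentiation at `undiff_frac * 2^effect` (capped
#'   at 0.95) instead of the baseline `undiff_frac`, so their guides enrich
#'   in the sorted undifferentiated pool;
#' * conservative gating: the undifferentiated sample is sequenced at
#'   `undiff_depth_frac` of the nominal depth, reproducing the noisier small
#'   population;
#' * a multiplicative log-normal batch offset per replicate on the sorted
#'   sample sizes.
#'
#' The per-guide expected enrichment implied by the sampled compositions,
#' `log2(phi / (1 - phi)) - log2(s0 / (1 - s0))`, is stored in the returned
#' truth so estimator bias can be measured against the generator exactly.
#'
#' @param guide_map Tibble (`guide_id`, `target_tss_id`, `is_control`).
#' @param truth A [sim_screen_truth()] object.
#' @param depth Nominal reads per guide (default 500).
#' @param n_reps Replicates (default 2).
#' @param undiff_frac Baseline probability a wild-type cell fails
#'   differentiation (sorting stringency; default 0.1).
#' @param undiff_depth_frac Undifferentiated sample depth relative to nominal
#'   (default 0.5).
#' @param batch_sd Log-sd of the per-replicate batch offset (default 0.15).
#' @param dropout_frac Fraction of guides with crippled representation
#'   (default 0.03).
#' @param dropout_factor Representation multiplier applied to crippled guides
#'   (default 0.01).
#' @param abundance_sdlog Log-sd of the library representation (default 0.3).
#' @param seed RNG seed; fixed seed gives an identical count table.
#' @return List: `counts` (long tibble `guide_id`, `population`, `replicate`,
#'   `count`), `guide_truth` (per guide: `abundance`, `phi`, `efficiency`,
#'   `true_log2fc`), `batch_offsets`.
#' @export
sim_screen_counts <- function(guide_map, truth, depth = 500, n_reps = 2,
                              undiff_frac = 0.1, undiff_depth_frac = 0.5,
                              batch_sd = 0.15, dropout_frac = 0.03,
                              dropout_factor = 0.01,
                              abundance_sdlog = 0.3, seed = 1L) {
  set.seed(seed)
  n <- nrow(guide_map)
  g <- truth$guides
  stopifnot(identical(g$guide_id, guide_map$guide_id))
  eff_tbl <- left_join(g, truth$tss_effects, by = "tss_id")
  delta <- coalesce(eff_tbl$effect, 0)
  a <- rlnorm(n, 0, abundance_sdlog)
  dropped <- runif(n) < dropout_frac
  a[dropped] <- a[dropped] * dropout_factor
  mult <- 1 + g$efficiency * (2^delta - 1)
  phi <- pmin(0.95, undiff_frac * mult)
  if (depth * min(a) / mean(a) < 1) {
    warn("sequencing depth too low to represent the rarest guides (expected count < 1)")
  }
  batch <- rlnorm(n_reps, 0, batch_sd)
  draw <- function(size, prob) as.integer(rmultinom(1, size, prob))
  counts <- bind_rows(map(seq_len(n_reps), function(r) {
    n0 <- round(depth * n)
    nu <- round(depth * n * undiff_depth_frac * batch[r])
    nd <- round(depth * n * batch[r])
    bind_rows(
      tibble(
        guide_id = guide_map$guide_id, population = "day0", replicate = r,
        count = draw(n0, a)
      ),
      tibble(
        guide_id = guide_map$guide_id, population = "undifferentiated",
        replicate = r, count = draw(nu, a * phi)
      ),
      tibble(
        guide_id = guide_map$guide_id, population = "differentiated",
        replicate = r, count = draw(nd, a * (1 - phi))
      )
    )
  }))
  guide_truth <- tibble(
    guide_id = guide_map$guide_id,
    tss_id = g$tss_id,
    is_control = g$is_control,
    efficiency = g$efficiency,
    abundance = a,
    dropped = dropped,
    phi = phi,
    true_log2fc = log2(phi / (1 - phi)) - log2(undiff_frac / (1 - undiff_frac))
  )
  list(counts = counts, guide_truth = guide_truth, batch_offsets = batch)
}

#' Serialize simulation ground truth as JSON
#'
#' @param truth A [sim_screen_truth()] object (or any list of tibbles /
#'   vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
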