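#' Splicing efficiency of a gene
#'
#' The fraction of a gene's expression attributable to its spliced
#' transcripts versus its unspliced pre-RNA, quantified by including the
#' unspliced gene sequence as an extra "transcript": a gene whose reads map
#' entirely to the unspliced form scores 0, one whose reads map only to
#' spliced transcripts scores 1.
#'
#' @param spliced Non-negative abundances (tpm) of the gene's spliced
#'   transcripts (vector, summed internally).
#' @param unspliced Non-negative abundance of the unspliced pre-RNA.
#' @return `sum(spliced) / (sum(spliced) + unspliced)`, or `NA` when both are
#'   zero.
#' @export
splicing_efficiency <- function(spliced, unspliced) {
  if (any(spliced < 0, na.rm = TRUE) || any(unspliced < 0, na.rm = TRUE)) {
    abort("abundances must be non-negative")
  }
  s <- sum(spliced, na.rm = TRUE)
  u <- sum(unspliced, na.rm = TRUE)
  if (s + u == 0) return(NA_real_)
  s / (s + u)
}

#' Distance from each query to the nearest track feature
#'
#' Minimum genomic edge-to-edge distance between each query interval (or
#' point) and a feature track, 0 when they overlap. Distances are counted
#' between closest edges, so a TSS at 10,000 and an enhancer at 7,000 are
#' 3,000 bp apart.
#'
#' @param query Tibble with `chrom`, `start`, `end` (points: start == end)
#'   and optionally `strand`.
#' @param track Tibble with `chrom`, `start`, `end` and optionally `strand`.
#' @param strand_mode "ignore" (default) or "same_strand".
#' @return Numeric vector of distances, one per query row; `NA` where the
#'   track is empty (overall or on the query's chromosome/strand).
#' @export
nearest_feature_distance <- function(query, track, strand_mode = c("ignore", "same_strand")) {
  strand_mode <- match.arg(strand_mode)
  vapply(seq_len(nrow(query)), function(i) {
    q <- query[i, ]
    keep <- track$chrom == q$chrom
    if (strand_mode == "same_strand") keep <- keep & track$strand == q$strand
    t <- track[keep, , drop = FALSE]
    if (nrow(t) == 0L) return(NA_real_)
    min(pmax(0, t$start - q$end, q$start - t$end))
  }, numeric(1))
}

#' Count track features within a window of each query point
#'
#' @param query Tibble with `chrom`, `start`, `end` and optionally `strand`.
#' @param track Feature track tibble (`chrom`, `start`, `end`, optional
#'   `strand`).
#' @param window Window half-width in bp, applied on each side (edge-to-edge
#'   distance <= `window` counts).
#' @param strand_mode "ignore" or "same_strand".
#' @return Integer vector of counts per query row (0 where the track is
#'   empty).
#' @export
count_features_within <- function(query, track, window,
                                  strand_mode = c("ignore", "same_strand")) {
  strand_mode <- match.arg(strand_mode)
  vapply(seq_len(nrow(query)), function(i) {
    q <- query[i, ]
    keep <- track$chrom == q$chrom
    if (strand_mode == "same_strand") keep <- keep & track$strand == q$strand
    t <- track[keep, , drop = FALSE]
    if (nrow(t) == 0L) return(0L)
    sum(pmax(0, t$start - q$end, q$start - t$end) <= window)
  }, integer(1))
}

# Coverage-weighted mean of a per-base summary track over [start, end];
# bases not covered by the track contribute score 0.
window_track_mean <- function(chrom, start, end, track) {
  if (is.null(track) || nrow(track) == 0L) return(NA_real_)
  t <- track[track$chrom == chrom, , drop = FALSE]
  width <- end - start + 1
  if (nrow(t) == 0L) return(0)
  ov <- pmax(0, pmin(t$end, end) - pmax(t$start, start) + 1)
  sum(ov * t$score) / width
}

# GC fraction of a transcript's spliced sequence pulled from a genome
# (named character vector or Biostrings::DNAStringSet).
transcript_gc <- function(exons, genome) {
  seqs <- vapply(seq_len(nrow(exons)), function(i) {
    chrom_seq <- as.character(genome[[exons$chrom[i]]])
    substr(chrom_seq, exons$start[i], exons$end[i])
  }, character(1))
  s <- toupper(paste(seqs, collapse = ""))
  gc_fraction(s)
}

#' GC fraction of a nucleotide sequence
#' @param seq A single character string over A/C/G/T (case-insensitive).
#' @return Fraction of G+C in \[0, 1\]; `NA` for an empty sequence.
#' @export
gc_fraction <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) == 0L) return(NA_real_)
  mean(chars %in% c("G", "C"))
}

#' Aggregate the 11 clustering features per gene
#'
#' Builds the genomic feature profile used for mechanism inference. The 11
#' features, with their per-transcript-to-gene reductions:
#'
#' * `max_transcript_length` — spliced transcript length, max over transcripts;
#' * `max_exon_count` — exon count, max;
#' * `mean_gc` — GC fraction of the spliced sequence, mean;
#' * `locus_length` — genomic TSS-to-3'-end span (introns included), max;
#' * `n_cage_tss_100bp` — same-strand CAGE TSSs within 100 bp of the
#'   transcript TSS, max;
#' * `n_enhancers_1mb` — enhancers within 1 Mb of the transcript TSS, max;
#' * `dist_closest_enhancer` — distance (bp) to the closest enhancer, min;
#' * `tss_conservation_200bp` — mean conservation over the 200 bp window
#'   centred on the TSS, max;
#' * `exon_conservation` — length-weighted mean conservation over exonic
#'   bases, max;
#' * `max_expression` — gene-level tpm (transcript sum) maximised across the
#'   expression panel's cell lines;
#' * `splicing_efficiency` — see [splicing_efficiency()].
#'
#' Missing tracks produce `NA` features (recorded per gene); downstream
#' standardization mean-imputes them.
#'
#' @param annotation Exon-level annotation tibble.
#' @param genome Optional genome sequences (named character vector or
#'   `Biostrings::DNAStringSet`) for GC content.
#' @param cage Optional CAGE TSS track (`chrom`, `position`, `strand`).
#' @param enhancers Optional enhancer track (`chrom`, `start`, `end`).
#' @param conservation Optional per-base conservation summary track
#'   (bedGraph-like: `chrom`, `start`, `end`, `score` in \[0,1\]).
#' @param expression_panel Optional long tibble (`gene_id`, `sample`, `tpm`)
#'   of gene-level expression across a cell-line panel.
#' @param splicing Optional tibble (`gene_id`, `spliced_tpm`,
#'   `unspliced_tpm`) of panel-aggregated abundances; one row per spliced
#'   transcript, with the gene's unspliced abundance repeated per row.
#' @return One row per gene: `gene_id`, `biotype`, the 11 features, and
#'   `n_missing_features`.
#' @export
aggregate_features <- function(annotation, genome = NULL, cage = NULL,
                               enhancers = NULL, conservation = NULL,
                               expression_panel = NULL, splicing = NULL) {
  annotation <- validate_annotation(annotation)
  if (nrow(annotation) == 0L) abort("annotation has no transcripts")
  tx <- transcript_spans(annotation)

  enh_track <- if (!is.null(enhancers) && nrow(enhancers) > 0) enhancers else NULL
  cage_track <- if (!is.null(cage) && nrow(cage) > 0) {
    tibble(chrom = cage$chrom, start = cage$position, end = cage$position, strand = cage$strand)
  } else {
    NULL
  }

  tx_pts <- tibble(chrom = tx$chrom, start = tx$tss, end = tx$tss, strand = tx$strand)
  tx$n_cage_tss_100bp <- if (!is.null(cage_track)) {
    count_features_within(tx_pts, cage_track, 100, "same_strand")
  } else {
    NA_integer_
  }
  tx$n_enhancers_1mb <- if (!is.null(enh_track)) {
    count_features_within(tx_pts, enh_track, 1e6, "ignore")
  } else {
    NA_integer_
  }
  tx$dist_closest_enhancer <- if (!is.null(enh_track)) {
    nearest_feature_distance(tx_pts, enh_track, "ignore")
  } else {
    NA_real_
  }
  tx$tss_conservation_200bp <- if (!is.null(conservation)) {
    vapply(seq_len(nrow(tx)), function(i) {
      window_track_mean(tx$chrom[i], tx$tss[i] - 100, tx$tss[i] + 99, conservation)
    }, numeric(1))
  } else {
    NA_real_
  }
  if (!is.null(conservation)) {
    exon_cons <- annotation |>
      mutate(cons = vapply(seq_len(n()), function(i) {
        window_track_mean(.data$chrom[i], .data$start[i], .data$end[i], conservation)
      }, numeric(1)), width = .data$end - .data$start + 1) |>
      group_by(.data$transcript_id) |>
      summarise(exon_conservation = sum(.data$cons * .data$width) / sum(.data$width), .groups = "drop")
    tx <- left_join(tx, exon_cons, by = "transcript_id")
  } else {
    tx$exon_conservation <- NA_real_
  }
  if (!is.null(genome)) {
    tx$gc <- vapply(tx$transcript_id, function(id) {
      transcript_gc(annotation[annotation$transcript_id == id, , drop = FALSE], genome)
    }, numeric(1))
  } else {
    tx$gc <- NA_real_
  }
  tx$locus_length <- tx$tx_end - tx$tx_start + 1L

  feats <- tx |>
    group_by(.data$gene_id, .data$biotype) |>
    summarise(
      max_transcript_length = max(.data$spliced_length),
      max_exon_count = max(.data$n_exons),
      mean_gc = mean(.data$gc),
      locus_length = max(.data$locus_length),
      n_cage_tss_100bp = max(.data$n_cage_tss_100bp),
      n_enhancers_1mb = max(.data$n_enhancers_1mb),
      dist_closest_enhancer = suppressWarnings(min(.data$dist_closest_enhancer)),
      tss_conservation_200bp = max(.data$tss_conservation_200bp),
      exon_conservation = max(.data$exon_conservation),
      .groups = "drop"
    ) |>
    mutate(dist_closest_enhancer = if_else(is.finite(.data$dist_closest_enhancer),
      .data$dist_closest_enhancer, NA_real_
    ))

  max_expr <- if (!is.null(expression_panel) && nrow(expression_panel) > 0) {
    expression_panel |>
      group_by(.data$gene_id, .data$sample) |>
      summarise(tpm = sum(.data$tpm), .groups = "drop") |>
      group_by(.data$gene_id) |>
      summarise(max_expression = max(.data$tpm), .groups = "drop")
  } else {
    tibble(gene_id = character(), max_expression = numeric())
  }
  se_tbl <- if (!is.null(splicing) && nrow(splicing) > 0) {
    splicing |>
      group_by(.data$gene_id) |>
      summarise(
        splicing_efficiency = splicing_efficiency(.data$spliced_tpm, .data$unspliced_tpm[1]),
        .groups = "drop"
      )
  } else {
    tibble(gene_id = character(), splicing_efficiency = numeric())
  }

  out <- feats |>
    left_join(max_expr, by = "gene_id") |>
    left_join(se_tbl, by = "gene_id")
  feature_cols <- clustering_feature_names()
  out$n_missing_features <- rowSums(is.na(out[, feature_cols]))
  out
}

#' Names of the 11 clustering features
#' @return Character vector, in canonical column order.
#' @export
clustering_feature_names <- function() {
  c(
    "max_transcript_length", "max_exon_count", "mean_gc", "locus_length",
    "n_cage_tss_100bp", "n_enhancers_1mb", "dist_closest_enhancer",
    "tss_conservation_200bp", "exon_conservation", "max_expression",
    "splicing_efficiency"
  )
}

#' Distance-to-track features kept outside the clustering matrix
#'
#' Computes, per gene, the distance from its (5'-most) TSS to the nearest
#' feature in each supplied track — e.g. endoderm-cancer GWAS SNPs, histone
#' peaks or endoderm-specific enhancers. These locus-context distances are
#' reported alongside, but never inside, the 11-feature clustering matrix.
#'
#' @param annotation Exon-level annotation tibble.
#' @param tracks Named list of tracks (`chrom`, `start`, `end`).
#' @return Tibble with `gene_id` and one `dist_<name>` column per track.
#' @export
distance_features <- function(annotation, tracks) {
  genes <- gene_spans(validate_annotation(annotation))
  pts <- tibble(
    chrom = genes$chrom, start = genes$gene_tss, end = genes$gene_tss,
    strand = genes$strand
  )
  out <- tibble(gene_id = genes$gene_id)
  for (nm in names(tracks)) {
    out[[paste0("dist_", nm)]] <- nearest_feature_distance(pts, tracks[[nm]], "ignore")
  }
  out
}
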