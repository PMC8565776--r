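#' Read a GTF annotation into the canonical exon table
#'
#' Parses a GTF file (1-based, inclusive coordinates) and returns one row per
#' exon. The `gene_biotype`/`gene_type` attribute is mapped onto the two
#' biotypes the screen design distinguishes: `protein_coding` and `lncRNA`.
#' Transcripts flagged as carrying a conserved open reading frame (an
#' externally pre-computed phyloCSF-style call, supplied via an optional
#' `coding_orf` GTF attribute) keep that flag so they can be excluded from
#' lncRNA analyses.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `biotype`, `coding_orf_flag`, one row per exon,
#'   exons sorted by start within transcript.
#' @export
read_annotation_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GTF requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (!"type" %in% names(df)) abort(sprintf("malformed GTF '%s': no feature type column", path))
  df <- df[df$type == "exon", , drop = FALSE]
  if (nrow(df) == 0L) abort(sprintf("malformed GTF '%s': no exon features", path))
  biotype_col <- intersect(c("gene_biotype", "gene_type", "biotype"), names(df))[1]
  if (is.na(biotype_col)) abort(sprintf("malformed GTF '%s': no gene biotype attribute", path))
  orf <- if ("coding_orf" %in% names(df)) {
    tolower(as.character(df$coding_orf)) %in% c("true", "1", "yes")
  } else {
    rep(FALSE, nrow(df))
  }
  out <- tibble(
    transcript_id = as.character(df$transcript_id),
    gene_id = as.character(df$gene_id),
    chrom = as.character(df$seqnames),
    strand = as.character(df$strand),
    start = as.integer(df$start),
    end = as.integer(df$end),
    biotype = as.character(df[[biotype_col]]),
    coding_orf_flag = orf
  )
  validate_annotation(arrange(out, .data$transcript_id, .data$start))
}

#' Validate the canonical exon table
#'
#' Checks the invariants every downstream operation relies on: required
#' columns, strand in {+,-}, exons sorted and non-overlapping within a
#' transcript, one strand/chromosome per transcript.
#'
#' @param annotation Exon-level annotation tibble.
#' @return The (invisibly validated) annotation, as a tibble.
#' @export
validate_annotation <- function(annotation) {
  req <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end", "biotype")
  missing_cols <- setdiff(req, names(annotation))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(annotation$strand %in% c("+", "-"))) abort("annotation strand must be '+' or '-'")
  if (any(annotation$end < annotation$start)) abort("annotation has exons with end < start")
  if (!"coding_orf_flag" %in% names(annotation)) annotation$coding_orf_flag <- FALSE
  bad <- annotation |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(
      n_strand = n_distinct(.data$strand),
      n_chrom = n_distinct(.data$chrom),
      overlapping = n() > 1 && any(.data$start[-1] <= head(.data$end, -1)),
      .groups = "drop"
    ) |>
    filter(.data$n_strand > 1 | .data$n_chrom > 1 | .data$overlapping)
  if (nrow(bad) > 0) {
    abort(paste0(
      "invalid transcripts (mixed strand/chrom or overlapping exons): ",
      paste(head(bad$transcript_id, 5), collapse = ", ")
    ))
  }
  as_tibble(annotation)
}

#' Per-transcript spans of an annotation
#'
#' @param annotation Exon-level annotation tibble.
#' @return One row per transcript with `tx_start`/`tx_end` (genomic span),
#'   `tss` (strand-aware 5' end), `spliced_length` (sum of exon lengths) and
#'   `n_exons`.
#' @export
transcript_spans <- function(annotation) {
  annotation |>
    group_by(
      .data$transcript_id, .data$gene_id, .data$chrom, .data$strand,
      .data$biotype
    ) |>
    summarise(
      tx_start = min(.data$start),
      tx_end = max(.data$end),
      spliced_length = sum(.data$end - .data$start + 1L),
      n_exons = n(),
      coding_orf_flag = any(.data$coding_orf_flag),
      .groups = "drop"
    ) |>
    mutate(tss = if_else(.data$strand == "+", .data$tx_start, .data$tx_end))
}

#' Per-gene spans of an annotation
#'
#' Gene start/end are the strand-agnostic genomic min/max over all of the
#' gene's transcripts; `gene_tss` is the strand-aware 5'-most transcription
#' start across transcripts.
#'
#' @param annotation Exon-level annotation tibble.
#' @return One row per gene.
#' @export
gene_spans <- function(annotation) {
  transcript_spans(annotation) |>
    group_by(.data$gene_id, .data$chrom, .data$strand, .data$biotype) |>
    summarise(
      gene_start = min(.data$tx_start),
      gene_end = max(.data$tx_end),
      coding_orf_flag = any(.data$coding_orf_flag),
      .groups = "drop"
    ) |>
    mutate(gene_tss = if_else(.data$strand == "+", .data$gene_start, .data$gene_end))
}

#' Classify lncRNA genes by genomic context
#'
#' Assigns each lncRNA gene exactly one of four categories relative to the
#' protein-coding annotation, applying the rules in strict precedence order:
#'
#' 1. `promoter_overlapping`: the lncRNA gene start is within 1000 bp of a
#'    protein-coding gene start;
#' 2. `transcript_overlapping`: any lncRNA transcript overlaps a
#'    protein-coding transcript;
#' 3. `gene_nearby`: no overlap with any protein-coding gene span, but a
#'    protein-coding gene start or end lies within 1000 bp of the lncRNA
#'    gene start or end;
#' 4. `intergenic` otherwise.
#'
#' A gene meeting an earlier rule is not tested against later ones. Gene
#' starts/ends for rules 3-4 are the strand-agnostic genomic min/max of the
#' gene span; the promoter rule compares transcription starts, strand-aware
#' by default (`promoter_rule = "tss"`) or the genomic gene start
#' (`promoter_rule = "gene_start"`).
#'
#' lncRNA genes flagged with a conserved ORF (`coding_orf_flag`) are removed
#' before classification, mirroring the library design's insistence on bona
#' fide non-coding loci.
#'
#' @param annotation Exon-level annotation tibble containing both lncRNA and
#'   protein_coding entries (or lncRNA only, plus `pc_annotation`).
#' @param pc_annotation Optional separate protein-coding annotation; defaults
#'   to the protein_coding rows of `annotation`.
#' @param window Distance window in bp for the promoter and nearby rules
#'   (default 1000).
#' @param promoter_rule Either "tss" (strand-aware transcription starts,
#'   default) or "gene_start" (strand-agnostic genomic gene starts).
#' @return Tibble with `gene_id` and `category` (factor with the four levels)
#'   for every non-coding-ORF lncRNA gene.
#' @export
categorize_lncrna <- function(annotation, pc_annotation = NULL, window = 1000,
                              promoter_rule = c("tss", "gene_start")) {
  promoter_rule <- match.arg(promoter_rule)
  annotation <- validate_annotation(annotation)
  if (is.null(pc_annotation)) {
    pc_annotation <- filter(annotation, .data$biotype == "protein_coding")
  }
  lnc <- filter(annotation, .data$biotype == "lncRNA", !.data$coding_orf_flag)
  levels <- c("intergenic", "promoter_overlapping", "transcript_overlapping", "gene_nearby")
  if (nrow(lnc) == 0L) {
    return(tibble(gene_id = character(), category = factor(character(), levels = levels)))
  }
  lnc_genes <- gene_spans(lnc)
  if (nrow(pc_annotation) == 0L) {
    return(tibble(
      gene_id = lnc_genes$gene_id,
      category = factor("intergenic", levels = levels)[rep(1, nrow(lnc_genes))]
    ))
  }
  pc_genes <- gene_spans(pc_annotation)
  pc_tx <- transcript_spans(pc_annotation)
  lnc_tx <- transcript_spans(lnc)
  pc_start_ref <- if (promoter_rule == "tss") pc_genes$gene_tss else pc_genes$gene_start
  categorize_one <- function(i) {
    g <- lnc_genes[i, ]
    pc_g <- pc_genes[pc_genes$chrom == g$chrom, , drop = FALSE]
    if (nrow(pc_g) == 0L) return("intergenic")
    starts <- pc_start_ref[pc_genes$chrom == g$chrom]
    lnc_start <- if (promoter_rule == "tss") g$gene_tss else g$gene_start
    if (any(abs(lnc_start - starts) <= window)) return("promoter_overlapping")
    tx_l <- lnc_tx[lnc_tx$gene_id == g$gene_id, , drop = FALSE]
    tx_p <- pc_tx[pc_tx$chrom == g$chrom, , drop = FALSE]
    if (nrow(tx_p) > 0L) {
      ov <- outer(tx_l$tx_start, tx_p$tx_end, `<=`) & outer(tx_l$tx_end, tx_p$tx_start, `>=`)
      if (any(ov)) return("transcript_overlapping")
    }
    span_overlap <- any(g$gene_start <= pc_g$gene_end & g$gene_end >= pc_g$gene_start)
    if (!span_overlap) {
      d <- pmin(
        abs(g$gene_start - pc_g$gene_start), abs(g$gene_start - pc_g$gene_end),
        abs(g$gene_end - pc_g$gene_start), abs(g$gene_end - pc_g$gene_end)
      )
      if (any(d <= window)) return("gene_nearby")
    }
    "intergenic"
  }
  tibble(
    gene_id = lnc_genes$gene_id,
    category = factor(vapply(seq_len(nrow(lnc_genes)), categorize_one, character(1)),
      levels = levels
    )
  )
}

#' Assign a screening TSS to every transcript
#'
#' CRISPRi efficacy depends on accurate TSS placement, and annotated 5' ends
#' of lowly expressed transcripts are often wrong. Each transcript is
#' assigned a TSS by a three-rule fallback: an explicitly curated TSS (CAGE
#' transcriptome catalogue) if provided; otherwise the closest same-strand
#' CAGE cluster position within `window` bp of the annotated 5' end;
#' otherwise the annotated 5' end itself.
#'
#' Ties between two equidistant CAGE positions are broken toward the 5'-most
#' position on the transcript's strand (smaller coordinate on `+`, larger on
#' `-`), keeping the assignment deterministic.
#'
#' @param annotation Exon-level annotation tibble.
#' @param explicit_tss Optional tibble (`transcript_id`, `position`) of
#'   curated TSSs.
#' @param cage Optional tibble (`chrom`, `position`, `strand`) of CAGE TSS
#'   cluster summits.
#' @param window Maximum distance (bp) from the annotated 5' end for CAGE
#'   reassignment (default 400).
#' @return Tibble with one row per transcript: `transcript_id`, `tss_id`,
#'   `chrom`, `strand`, `position`, `source` in
#'   {fantom_cat_explicit, cage_proximal, annotated_5prime}.
#' @export
assign_tss <- function(annotation, explicit_tss = NULL, cage = NULL, window = 400) {
  tx <- transcript_spans(validate_annotation(annotation))
  expl <- if (!is.null(explicit_tss) && nrow(explicit_tss) > 0) {
    setNames(as.integer(explicit_tss$position), explicit_tss$transcript_id)
  } else {
    integer(0)
  }
  pick <- function(i) {
    t <- tx[i, ]
    if (t$transcript_id %in% names(expl)) {
      return(list(position = expl[[t$transcript_id]], source = "fantom_cat_explicit"))
    }
    if (!is.null(cage) && nrow(cage) > 0) {
      cand <- cage$position[cage$chrom == t$chrom & cage$strand == t$strand]
      if (length(cand) > 0) {
        d <- abs(cand - t$tss)
        if (min(d) <= window) {
          best <- cand[d == min(d)]
          pos <- if (t$strand == "+") min(best) else max(best)
          return(list(position = as.integer(pos), source = "cage_proximal"))
        }
      }
    }
    list(position = as.integer(t$tss), source = "annotated_5prime")
  }
  res <- map(seq_len(nrow(tx)), pick)
  tx |>
    mutate(
      position = map_int(res, "position"),
      source = map_chr(res, "source"),
      tss_id = paste0(.data$chrom, ":", .data$position, ":", .data$strand)
    ) |>
    select("transcript_id", "tss_id", "chrom", "strand", "position", "source")
}

#' Consolidate per-transcript TSS assignments into unique screening TSSs
#'
#' TSSs with identical (chrom, strand, position) are merged; the transcripts
#' they represent are unioned into a comma-separated, sorted `transcript_ids`
#' field. Merging is by exact coordinate identity only: positional fuzziness
#' is the job of the CAGE reassignment upstream.
#'
#' @param tss Per-transcript TSS tibble as returned by [assign_tss()].
#' @return One row per unique TSS: `tss_id`, `chrom`, `strand`, `position`,
#'   `transcript_ids`, `n_transcripts`.
#' @export
consolidate_tss <- function(tss) {
  if (nrow(tss) == 0L) {
    return(tibble(
      tss_id = character(), chrom = character(), strand = character(),
      position = integer(), transcript_ids = character(), n_transcripts = integer()
    ))
  }
  tss |>
    group_by(.data$tss_id, .data$chrom, .data$strand, .data$position) |>
    summarise(
      transcript_ids = paste(sort(unique(.data$transcript_id)), collapse = ","),
      n_transcripts = n_distinct(.data$transcript_id),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$position)
}
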