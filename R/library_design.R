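#' Select the top-ranked guides for each TSS
#'
#' Takes externally ranked guide candidates (ranking encodes distance to the
#' TSS, off-target burden and predicted chromatin accessibility, as produced
#' by a guide-design tool) and keeps the `k` best-ranked guides per TSS, all
#' of them when fewer are available. TSSs with zero candidates are recorded
#' in a skip report attached as the `"skipped_tss"` attribute.
#'
#' @param candidates Tibble with `guide_id`, `sequence`, `target_tss_id`,
#'   `candidate_rank` (1 = best).
#' @param tss_ids Optional character vector of all TSSs that should receive
#'   guides; defaults to those present in `candidates`.
#' @param k Guides per TSS (default 10).
#' @return Tibble of selected guides (`is_control = FALSE`), ranked order
#'   preserved within TSS; attribute `skipped_tss` lists TSSs with no
#'   candidates.
#' @export
select_guides <- function(candidates, tss_ids = NULL, k = 10) {
  sel <- candidates |>
    group_by(.data$target_tss_id) |>
    arrange(.data$candidate_rank, .by_group = TRUE) |>
    slice_head(n = k) |>
    ungroup() |>
    arrange(.data$target_tss_id, .data$candidate_rank) |>
    mutate(is_control = FALSE)
  skipped <- setdiff(tss_ids %||% character(0), sel$target_tss_id)
  if (length(skipped) > 0) {
    warn(sprintf("%d TSS(s) had no guide candidates and were skipped", length(skipped)))
  }
  attr(sel, "skipped_tss") <- skipped
  sel
}

# Reverse complement of an ACGT string.
revcomp <- function(seq) {
  chartr("ACGT", "TGCA", vapply(strsplit(seq, ""), function(x) {
    paste(rev(x), collapse = "")
  }, character(1)))
}

# TRUE if `seq` occurs as an exact substring of the genome on either strand.
matches_genome <- function(seq, genome) {
  if (is.null(genome)) return(FALSE)
  chroms <- vapply(seq_along(genome), function(i) as.character(genome[[i]]), character(1))
  any(vapply(chroms, function(chr) {
    grepl(seq, chr, fixed = TRUE) || grepl(revcomp(seq), chr, fixed = TRUE)
  }, logical(1)))
}

#' Construct scrambled negative-control guides
#'
#' Samples `n_seed` targeting guides without replacement and scrambles each
#' one `n_per_seed` times by a uniform random permutation of its letters, so
#' every control preserves the length and nucleotide composition of its seed.
#' Any scramble with an exact match in the supplied genome (on either strand,
#' the deterministic stand-in for a permissive alignment screen of candidate
#' controls) is rejected and re-drawn, so the output always contains exactly
#' `n_seed * n_per_seed` controls. Seeds whose sequence has fewer than two
#' distinct letters cannot be non-identically scrambled and are replaced,
#' with a warning.
#'
#' @param library Tibble of targeting guides (`guide_id`, `sequence`).
#' @param n_seed Number of guides to sample as scramble seeds (default 500).
#' @param n_per_seed Scrambles per seed (default 10).
#' @param genome Optional genome sequences used for the exact-match rejection
#'   filter.
#' @param seed RNG seed; fixed seed gives a byte-identical control set.
#' @param max_tries Rejection-sampling guard per scramble before the seed is
#'   replaced.
#' @return Tibble of controls: `guide_id` ("scr_<i>_<j>"), `sequence`,
#'   `target_tss_id = NA`, `seed_guide_id`, `is_control = TRUE`.
#' @export
make_scrambled_controls <- function(library, n_seed = 500, n_per_seed = 10,
                                    genome = NULL, seed = 1L, max_tries = 100L) {
  if (nrow(library) == 0L) abort("library must be non-empty")
  if (n_seed > nrow(library)) {
    abort(sprintf("n_seed (%d) exceeds library size (%d)", n_seed, nrow(library)))
  }
  set.seed(seed)
  taken <- rep(FALSE, nrow(library))
  scramble_ok <- function(sq) {
    s <- paste(sample(strsplit(sq, "")[[1]]), collapse = "")
    if (identical(s, sq)) return(NULL)
    if (matches_genome(s, genome)) return(NULL)
    s
  }
  out <- vector("list", n_seed)
  i <- 1L
  while (i <= n_seed) {
    idx <- sample(which(!taken), 1L)
    taken[idx] <- TRUE
    sq <- library$sequence[idx]
    if (length(unique(strsplit(sq, "")[[1]])) < 2L) {
      warn(sprintf("seed guide '%s' has < 2 distinct letters; re-drawing", library$guide_id[idx]))
      if (!any(!taken)) abort("ran out of scrambleable seed guides")
      next
    }
    seqs <- character(n_per_seed)
    ok <- TRUE
    for (j in seq_len(n_per_seed)) {
      s <- NULL
      tries <- 0L
      while (is.null(s) && tries < max_tries) {
        s <- scramble_ok(sq)
        tries <- tries + 1L
      }
      if (is.null(s)) {
        ok <- FALSE
        break
      }
      seqs[j] <- s
    }
    if (!ok) {
      warn(sprintf("could not scramble seed guide '%s'; re-drawing", library$guide_id[idx]))
      if (!any(!taken)) abort("ran out of scrambleable seed guides")
      next
    }
    out[[i]] <- tibble(
      guide_id = sprintf("scr_%04d_%02d", i, seq_len(n_per_seed)),
      sequence = seqs,
      target_tss_id = NA_character_,
      seed_guide_id = library$guide_id[idx],
      is_control = TRUE
    )
    i <- i + 1L
  }
  bind_rows(out)
}

#' Deduplicate a guide library by sequence
#'
#' Nearby or shared TSSs can be assigned identical guide sequences; duplicate
#' sequences are consolidated into one record carrying the union of target
#' TSS ids (comma-separated, sorted). Idempotent.
#'
#' @param guides Tibble with `guide_id`, `sequence`, `target_tss_id`,
#'   `is_control`.
#' @return Tibble with one row per distinct sequence; `n_merged` counts the
#'   records collapsed into each.
#' @export
dedup_library <- function(guides) {
  guides |>
    group_by(.data$sequence) |>
    summarise(
      guide_id = .data$guide_id[1],
      target_tss_id = {
        t <- unique(unlist(strsplit(.data$target_tss_id[!is.na(.data$target_tss_id)], ",")))
        if (length(t) == 0) NA_character_ else paste(sort(t), collapse = ",")
      },
      is_control = all(.data$is_control),
      n_merged = n(),
      .groups = "drop"
    ) |>
    arrange(.data$guide_id) |>
    select("guide_id", "sequence", "target_tss_id", "is_control", "n_merged")
}

#' Write guide sequences as FASTA
#'
#' @param guides Guide tibble (`guide_id`, `sequence`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_guides_fasta <- function(guides, path) {
  writeLines(paste0(">", guides$guide_id, "\n", guides$sequence), path)
  invisible(path)
}
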