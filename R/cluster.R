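#' Standardize a feature matrix to mean 1, sd 1
#'
#' Each feature is centred and scaled to unit *population* standard
#' deviation, then shifted to mean 1 (k-means on Euclidean distance is
#' invariant to the shared translation, so this is equivalent to z-scoring).
#' Constant features are dropped with a warning; missing values are imputed
#' *after* standardization at the feature mean (i.e. 1) and flagged.
#'
#' @param features Tibble with `gene_id` and numeric feature columns (extra
#'   non-feature columns are carried through untouched if named in `keep`).
#' @param feature_cols Feature columns (default [clustering_feature_names()]
#'   intersected with what is present, else all numeric columns).
#' @return Tibble `gene_id` + standardized features; attributes
#'   `dropped_features` (constant columns) and `imputed` (gene_id x feature
#'   tibble of imputations).
#' @export
standardize_features <- function(features, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(clustering_feature_names(), names(features))
    if (length(feature_cols) == 0) {
      feature_cols <- setdiff(
        names(features)[vapply(features, is.numeric, logical(1))],
        "n_missing_features"
      )
    }
  }
  if (nrow(features) < 2) abort("standardization needs at least 2 genes")
  pop_sd <- function(v) {
    m <- mean(v, na.rm = TRUE)
    sqrt(mean((v - m)^2, na.rm = TRUE))
  }
  sds <- vapply(features[feature_cols], pop_sd, numeric(1))
  constant <- feature_cols[!is.finite(sds) | sds == 0]
  if (length(constant) == length(feature_cols)) abort("all features are constant")
  if (length(constant) > 0) {
    warn(paste0("dropping constant feature(s): ", paste(constant, collapse = ", ")))
    feature_cols <- setdiff(feature_cols, constant)
  }
  out <- tibble(gene_id = features$gene_id)
  imputed <- list()
  for (f in feature_cols) {
    v <- features[[f]]
    z <- (v - mean(v, na.rm = TRUE)) / pop_sd(v) + 1
    if (anyNA(z)) {
      imputed[[f]] <- tibble(gene_id = features$gene_id[is.na(z)], feature = f)
      z[is.na(z)] <- 1
    }
    out[[f]] <- z
  }
  attr(out, "dropped_features") <- constant
  attr(out, "imputed") <- bind_rows(imputed)
  out
}

#' k-means clustering of the standardized feature matrix
#'
#' Partitions genes into `k = 2` clusters minimising the within-cluster sum
#' of squares, with `n_restarts` random initialisations (best objective
#' kept) and a fixed seed for determinism. When biotypes are supplied the
#' cluster labels are canonicalized so that cluster 2 is the cluster with
#' the higher fraction of protein-coding genes (the "mRNA-like" cluster),
#' making labels invariant to row order and restart.
#'
#' @param standardized Output of [standardize_features()] (or any tibble with
#'   `gene_id` + numeric columns).
#' @param biotype Optional character vector (aligned with rows) of
#'   `protein_coding` / `lncRNA` labels, used for canonicalization and the
#'   `mrna_like` flag.
#' @param k Number of clusters (default 2).
#' @param seed RNG seed.
#' @param n_restarts Random restarts (default 10).
#' @return Tibble of class `lnc_cluster`: `gene_id`, `biotype`, `cluster`,
#'   `mrna_like`; attributes `tot_withinss`, `centers`.
#' @export
cluster_features <- function(standardized, biotype = NULL, k = 2, seed = 1L,
                             n_restarts = 10) {
  mat <- as.matrix(standardized[, setdiff(names(standardized), "gene_id"), drop = FALSE])
  if (nrow(mat) < k) abort(sprintf("need at least k = %d genes to cluster", k))
  set.seed(seed)
  km <- kmeans(mat, centers = k, nstart = n_restarts, iter.max = 100)
  cl <- km$cluster
  if (!is.null(biotype) && any(biotype == "protein_coding")) {
    frac_mrna <- vapply(seq_len(k), function(j) {
      mean(biotype[cl == j] == "protein_coding")
    }, numeric(1))
    relabel <- order(frac_mrna) # cluster k = highest mRNA fraction
    new <- integer(length(cl))
    for (j in seq_len(k)) new[cl == relabel[j]] <- j
    cl <- new
    centers <- km$centers[relabel, , drop = FALSE]
  } else {
    centers <- km$centers
  }
  out <- tibble(
    gene_id = standardized$gene_id,
    biotype = biotype %||% NA_character_,
    cluster = cl,
    mrna_like = if (!is.null(biotype)) cl == k else NA
  )
  attr(out, "tot_withinss") <- km$tot.withinss
  attr(out, "centers") <- centers
  class(out) <- c("lnc_cluster", class(out))
  out
}

#' Candidate RNA-mechanism lncRNA hits from cluster assignments
#'
#' CRISPRi silences both a locus's transcription and any local DNA regulatory
#' activity, so the screen alone cannot say whether a hit acts through its
#' RNA. lncRNAs whose genomic feature profile lands them in the mRNA-majority
#' cluster are predicted to act through RNA-based mechanisms; this returns
#' the screen-hit lncRNAs with `mrna_like = TRUE`. Known RNA-mechanism
#' gold standards (e.g. XIST, NEAT1, MALAT1 analogues) can be supplied as a
#' diagnostic: a warning is raised if any falls outside the mRNA-like
#' cluster.
#'
#' @param assignments A [cluster_features()] result (needs non-NA biotypes).
#' @param hit_ids Character vector of screen-hit gene ids.
#' @param gold_standards Optional character vector of gold-standard
#'   RNA-mechanism lncRNA gene ids.
#' @return Tibble of candidate genes (`gene_id`, `cluster`, `mrna_like`),
#'   i.e. hit lncRNAs in the mRNA-like cluster.
#' @export
label_mrna_like <- function(assignments, hit_ids, gold_standards = NULL) {
  if (all(is.na(assignments$biotype)) || !any(assignments$biotype == "protein_coding")) {
    abort("mRNA-like labeling requires protein-coding genes in the clustering")
  }
  if (!is.null(gold_standards)) {
    gs <- assignments |> filter(.data$gene_id %in% gold_standards)
    misplaced <- gs$gene_id[!gs$mrna_like]
    if (length(misplaced) > 0) {
      warn(paste0(
        "gold-standard RNA-mechanism lncRNA(s) outside the mRNA-like cluster: ",
        paste(misplaced, collapse = ", ")
      ))
    }
  }
  assignments |>
    filter(
      .data$gene_id %in% hit_ids, .data$biotype == "lncRNA", .data$mrna_like
    ) |>
    select("gene_id", "cluster", "mrna_like") |>
    as_tibble()
}

#' Cluster assignments as a plain tibble
#' @param x A `lnc_cluster`.
#' @param ... Unused.
#' @return Tibble of per-gene assignments.
#' @export
tidy.lnc_cluster <- function(x, ...) {
  as_tibble(unclass(x)[c("gene_id", "biotype", "cluster", "mrna_like")])
}

#' One-row summary of a clustering
#' @param x A `lnc_cluster`.
#' @param ... Unused.
#' @return One-row tibble: `k`, `n`, `tot_withinss`, `n_mrna_like`.
#' @export
glance.lnc_cluster <- function(x, ...) {
  tibble(
    k = length(unique(x$cluster)), n = nrow(x),
    tot_withinss = attr(x, "tot_withinss"),
    n_mrna_like = sum(x$mrna_like, na.rm = TRUE)
  )
}
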