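# Independent brute-force oracles used to check the package's statistics.
# These deliberately avoid the code paths they verify.

# Exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments (symmetric-tail convention, matching wilcox.test exact p).
oracle_mann_whitney_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  center <- n1 * length(y) / 2
  us <- apply(idx, 2, function(ii) sum(rank(pooled)[ii]) - n1 * (n1 + 1) / 2)
  mean(abs(us - center) >= abs(u_obs - center) - 1e-9)
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins (sum of probabilities <= observed, the
# convention fisher.test uses).
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  a_range <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(a_range, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact optimal 2-partition within-cluster sum of squares by exhaustive
# enumeration (n <= 20).
oracle_kmeans2_wss <- function(mat) {
  n <- nrow(mat)
  stopifnot(n <= 20)
  wss_of <- function(rows) {
    if (length(rows) == 0) return(0)
    m <- colMeans(mat[rows, , drop = FALSE])
    sum(sweep(mat[rows, , drop = FALSE], 2, m)^2)
  }
  best <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    best <- min(best, wss_of(which(grp)) + wss_of(which(!grp)))
  }
  best
}

# All-pairs nearest edge distance.
oracle_nearest_distance <- function(q_start, q_end, t_start, t_end) {
  min(vapply(seq_along(t_start), function(j) {
    max(0, t_start[j] - q_end, q_start - t_end[j])
  }, numeric(1)))
}

# Guide-level log2fc simulator drawn directly from the hierarchical mixture
# (null N(0,1); effective guides of functional TSSs shifted), independent of
# the count-level generator.
sim_mixture_lfc <- function(seed, n_tss = 1000, n_guides = 10, n_func = 0,
                            pi_guide = 0.5, shift = 2, n_ctrl = 1000) {
  set.seed(seed)
  tss <- rep(sprintf("t%04d", seq_len(n_tss)), each = n_guides)
  func <- if (n_func > 0) sprintf("t%04d", seq_len(n_func)) else character(0)
  eff <- (tss %in% func) & (stats::runif(n_tss * n_guides) < pi_guide)
  x <- stats::rnorm(n_tss * n_guides, ifelse(eff, shift, 0), 1)
  n_t <- n_tss * n_guides
  list(
    enrichment = tibble::tibble(
      guide_id = sprintf("g%05d", seq_len(n_t + n_ctrl)),
      log2fc = c(x, stats::rnorm(n_ctrl))
    ),
    guide_map = tibble::tibble(
      guide_id = sprintf("g%05d", seq_len(n_t + n_ctrl)),
      target_tss_id = c(tss, rep(NA_character_, n_ctrl)),
      is_control = rep(c(FALSE, TRUE), c(n_t, n_ctrl))
    ),
    functional = func
  )
}

# Small guide map shared by screen-statistics tests.
toy_guide_map <- function(n_tss = 20, guides_per_tss = 5, n_ctrl = 20) {
  tibble::tibble(
    guide_id = sprintf("g%03d", seq_len(n_tss * guides_per_tss + n_ctrl)),
    target_tss_id = c(
      rep(sprintf("t%02d", seq_len(n_tss)), each = guides_per_tss),
      rep(NA_character_, n_ctrl)
    ),
    is_control = rep(c(FALSE, TRUE), c(n_tss * guides_per_tss, n_ctrl))
  )
}

# Minimal two-gene annotation used across annotation tests.
toy_annotation <- function() {
  tibble::tibble(
    transcript_id = c("tx_pc1", "tx_pc1", "tx_lnc1", "tx_lnc1"),
    gene_id = c("pc1", "pc1", "lnc1", "lnc1"),
    chrom = "chr1",
    strand = c("+", "+", "+", "+"),
    start = c(10000L, 12000L, 30000L, 30600L),
    end = c(10999L, 13999L, 30399L, 30999L),
    biotype = c("protein_coding", "protein_coding", "lncRNA", "lncRNA"),
    coding_orf_flag = FALSE
  )
}
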