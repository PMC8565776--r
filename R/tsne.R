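#' 2-D t-SNE embedding for cluster visualization
#'
#' A compact exact (O(n^2)) t-distributed stochastic neighbour embedding used
#' only to draw the feature-space map of the clustering. The embedding is
#' strictly a visualization: no decision in the pipeline, and no numerical
#' result, depends on the coordinates, and nothing beyond "finite and
#' deterministic for a fixed seed" should be asserted about them.
#'
#' Standard t-SNE machinery: per-point Gaussian bandwidths calibrated to the
#' target perplexity by bisection, symmetrized input affinities, Student-t
#' low-dimensional kernel, gradient descent with momentum (0.5 then 0.8) and
#' early exaggeration (x12 for the first quarter of iterations).
#'
#' @param standardized Tibble with `gene_id` + numeric columns (e.g. the
#'   output of [standardize_features()]), or a numeric matrix.
#' @param seed RNG seed for the initial layout.
#' @param perplexity Target perplexity (default `min(30, (n - 1) / 3)`).
#' @param n_iter Gradient-descent iterations (default 400).
#' @param learning_rate Step size (default 100).
#' @return Tibble: `gene_id` (row index if absent), `tsne1`, `tsne2`.
#' @export
embed_tsne <- function(standardized, seed = 1L, perplexity = NULL,
                       n_iter = 400, learning_rate = 100) {
  if (is.data.frame(standardized)) {
    ids <- standardized$gene_id %||% as.character(seq_len(nrow(standardized)))
    mat <- as.matrix(standardized[, setdiff(names(standardized), "gene_id"), drop = FALSE])
  } else {
    mat <- as.matrix(standardized)
    ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  }
  n <- nrow(mat)
  if (n < 5) abort("t-SNE embedding needs at least 5 points")
  perplexity <- perplexity %||% min(30, (n - 1) / 3)
  if (3 * perplexity > n - 1) perplexity <- (n - 1) / 3

  d2 <- as.matrix(stats::dist(mat))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 0
    hi <- Inf
    beta <- 1
    for (iter in 1:50) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s == 0) {
        h <- 0
      } else {
        p <- p / s
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) {
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (beta + lo) / 2
      }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(seed)
  Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
  gains <- matrix(1, n, 2)
  inc <- matrix(0, n, 2)
  exag_until <- max(1, floor(n_iter / 4))
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= exag_until) P * 12 else P
    yd2 <- as.matrix(stats::dist(Y))^2
    num <- 1 / (1 + yd2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= exag_until) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    inc <- mom * inc - learning_rate * gains * grad
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
  }
  tibble(gene_id = ids, tsne1 = Y[, 1], tsne2 = Y[, 2])
}
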