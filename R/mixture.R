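#' Hierarchical mixture model for TSS-level hit calling
#'
#' Pooled CRISPRi screens violate the usual gene-level testing assumptions:
#' even at a genuinely functional TSS only a subset of its guides work. This
#' fit models each guide's enrichment `log2fc` hierarchically:
#'
#' * the empirical null `f0 = N(mu0, sd0)` is fit to the scrambled
#'   negative-control guides only (maximum-likelihood moments by default, or
#'   median/MAD with `null_fit = "robust"`);
#' * each TSS is functional with prior probability `p`;
#' * conditional on a functional TSS, each of its guides is independently
#'   effective with probability `pi_guide`; effective guides are drawn from a
#'   single shifted alternative `f1 = N(mu1, sd1)` (constrained to
#'   `mu1 >= mu0`, the enrichment direction), ineffective ones from `f0`.
#'
#' `p`, `pi_guide`, `mu1`, `sd1` are estimated by EM on the marginal
#' likelihood (per-TSS: `(1-p) * prod f0  +  p * prod[pi f1 + (1-pi) f0]`),
#' with multiple restarts from jittered initialisations; the best
#' log-likelihood is kept. Each TSS gets a posterior null probability, and
#' the global FDR of a TSS is the running mean of posterior null
#' probabilities over all TSSs with an equal or better (lower) posterior null
#' — the q-value convention, so the model reports one FDR per targeted TSS.
#'
#' @param enrichment Tibble (`guide_id`, `log2fc`) of filtered guides,
#'   controls included.
#' @param guide_map Tibble (`guide_id`, `target_tss_id`, `is_control`). A
#'   guide with a comma-separated multi-TSS target contributes to each of its
#'   TSSs.
#' @param null_fit "mle" (default) or "robust" (median/MAD).
#' @param max_iter,tol EM stopping rule: relative log-likelihood change below
#'   `tol` (default 1e-6) or `max_iter` (default 500) iterations.
#' @param n_restarts Number of EM restarts from jittered starts (default 5).
#' @param seed RNG seed for the restart jitter.
#' @param min_controls Below this many surviving controls the null is fit to
#'   all guides robustly instead, with a warning (degraded mode).
#' @return Object of class `guide_mixture_fit`; see [tidy.guide_mixture_fit()]
#'   and [glance.guide_mixture_fit()].
#' @export
fit_guide_mixture <- function(enrichment, guide_map,
                              null_fit = c("mle", "robust"),
                              max_iter = 500, tol = 1e-6, n_restarts = 5,
                              seed = 1L, min_controls = 100) {
  null_fit <- match.arg(null_fit)
  dat <- inner_join(enrichment, guide_map, by = "guide_id")
  ctrl <- dat$log2fc[dat$is_control]
  degraded <- length(ctrl) < min_controls
  if (degraded) {
    warn(sprintf(
      "only %d control guides available (< %d); fitting null to all guides robustly",
      length(ctrl), min_controls
    ))
    mu0 <- median(dat$log2fc)
    sd0 <- mad(dat$log2fc)
  } else if (null_fit == "robust") {
    mu0 <- median(ctrl)
    sd0 <- mad(ctrl)
  } else {
    mu0 <- mean(ctrl)
    sd0 <- sd(ctrl)
  }
  if (!is.finite(sd0) || sd0 <= 0) abort("degenerate null: zero spread among control guides")

  targ <- dat |>
    filter(!.data$is_control) |>
    mutate(tss_id = strsplit(.data$target_tss_id, ",")) |>
    tidyr::unnest("tss_id")
  if (nrow(targ) == 0L) abort("no targeting guides to model")
  x <- targ$log2fc
  tss <- factor(targ$tss_id)
  n_tss <- nlevels(tss)
  l0 <- dnorm(x, mu0, sd0, log = TRUE)
  ll_null_g <- as.numeric(rowsum(l0, tss)) # per-TSS log prod f0

  em_once <- function(mu1, sd1, pi_g, p) {
    loglik_prev <- -Inf
    iter <- 0L
    converged <- FALSE
    post_null <- NULL
    repeat {
      iter <- iter + 1L
      l1 <- dnorm(x, mu1, sd1, log = TRUE)
      # per-guide effective mixture within a functional TSS
      m <- pmax(l0, l1)
      mix <- m + log(pi_g * exp(l1 - m) + (1 - pi_g) * exp(l0 - m))
      w <- pi_g * exp(l1 - mix) # P(effective | functional, x_i)
      ll_func_g <- as.numeric(rowsum(mix, tss))
      a <- log(p) + ll_func_g
      b <- log1p(-p) + ll_null_g
      mm <- pmax(a, b)
      ll_g <- mm + log(exp(a - mm) + exp(b - mm))
      loglik <- sum(ll_g)
      r <- exp(a - ll_g) # P(functional | data)
      post_null <- 1 - r
      if (is.finite(loglik_prev) &&
        abs(loglik - loglik_prev) <= tol * (abs(loglik_prev) + 1)) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      loglik_prev <- loglik
      # M-step
      p <- min(max(mean(r), 1e-6), 1 - 1e-6)
      rg <- r[as.integer(tss)]
      u <- rg * w
      su <- sum(u)
      pi_g <- min(max(su / sum(rg), 1e-4), 1 - 1e-4)
      if (su > 1e-12) {
        mu1 <- sum(u * x) / su
        sd1 <- sqrt(sum(u * (x - mu1)^2) / su)
      }
      mu1 <- max(mu1, mu0)
      sd1 <- max(sd1, sd0 / 20)
    }
    list(
      mu1 = mu1, sd1 = sd1, pi_guide = pi_g, p_functional = p,
      loglik = loglik, n_iter = iter, converged = converged,
      post_null = post_null
    )
  }

  set.seed(seed)
  starts <- map(seq_len(n_restarts), function(i) {
    jit <- if (i == 1) c(0, 0, 0, 0) else runif(4, -0.5, 0.5)
    list(
      mu1 = mu0 + 2 * sd0 * (1 + jit[1]),
      sd1 = sd0 * exp(jit[2]),
      pi_g = min(max(0.5 + 0.4 * jit[3], 0.05), 0.95),
      p = min(max(0.1 * exp(2 * jit[4]), 0.005), 0.5)
    )
  })
  fits <- map(starts, function(s) em_once(s$mu1, s$sd1, s$pi_g, s$p))
  best <- fits[[which.max(map_dbl(fits, "loglik"))]]
  if (!best$converged) {
    warn(sprintf("EM did not converge within %d iterations (loglik %.4f)", max_iter, best$loglik))
  }

  ord <- order(best$post_null)
  fdr <- numeric(n_tss)
  fdr[ord] <- cummean(best$post_null[ord])
  # ties in the posterior share the worst (largest) running mean of the tie group
  fdr <- ave(fdr, best$post_null, FUN = max)

  calls <- tibble(
    tss_id = levels(tss),
    n_guides = as.integer(table(tss)),
    posterior_null = best$post_null,
    posterior_functional = 1 - best$post_null,
    fdr = fdr
  )
  structure(
    list(
      null = list(mu = mu0, sd = sd0, n_controls = length(ctrl), fit = null_fit, degraded = degraded),
      alt = list(mu = best$mu1, sd = best$sd1),
      pi_guide = best$pi_guide,
      p_functional = best$p_functional,
      loglik = best$loglik,
      n_iter = best$n_iter,
      converged = best$converged,
      n_restarts = n_restarts,
      restart_logliks = map_dbl(fits, "loglik"),
      calls = calls,
      guide_data = targ |> select("guide_id", "tss_id", "log2fc")
    ),
    class = "guide_mixture_fit"
  )
}

#' @export
print.guide_mixture_fit <- function(x, ...) {
  cat("Hierarchical guide mixture fit\n")
  cat(sprintf(
    "  null: N(%.3f, %.3f^2) from %d control guides (%s%s)\n",
    x$null$mu, x$null$sd, x$null$n_controls, x$null$fit,
    if (x$null$degraded) ", degraded" else ""
  ))
  cat(sprintf("  alt:  N(%.3f, %.3f^2)\n", x$alt$mu, x$alt$sd))
  cat(sprintf(
    "  pi_guide = %.3f, p_functional = %.4f, loglik = %.2f (%s, %d iters)\n",
    x$pi_guide, x$p_functional, x$loglik,
    if (x$converged) "converged" else "NOT converged", x$n_iter
  ))
  cat(sprintf("  %d TSSs scored\n", nrow(x$calls)))
  invisible(x)
}

#' Per-TSS results of a guide mixture fit
#' @param x A `guide_mixture_fit`.
#' @param ... Unused.
#' @return Tibble: `tss_id`, `n_guides`, `posterior_null`,
#'   `posterior_functional`, `fdr`.
#' @export
tidy.guide_mixture_fit <- function(x, ...) {
  x$calls
}

#' One-row model summary of a guide mixture fit
#' @param x A `guide_mixture_fit`.
#' @param ... Unused.
#' @return One-row tibble of the fitted parameters and convergence state.
#' @export
glance.guide_mixture_fit <- function(x, ...) {
  tibble(
    null_mu = x$null$mu, null_sd = x$null$sd, n_controls = x$null$n_controls,
    alt_mu = x$alt$mu, alt_sd = x$alt$sd,
    pi_guide = x$pi_guide, p_functional = x$p_functional,
    loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    degraded_null = x$null$degraded, n_tss = nrow(x$calls)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
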