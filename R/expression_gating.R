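#' Fit a two-component Gaussian mixture to log intensities
#'
#' Normalized log-intensity values pooled over control samples of one cell
#' line are bimodal: a lower mode of non-expressed genes and an upper mode
#' of expressed genes. This fits a two-component univariate Gaussian
#' mixture (unequal variances) by expectation maximization via
#' [mclust::Mclust()] (deterministic model-based initialization), and
#' orders the components so component 1 is the lower-mean, non-expressed
#' one.
#'
#' A fit is flagged degenerate when the component means are closer than
#' half the larger component S.D. or either mixing weight falls below
#' 0.05 — the unimodal-input collapse case, in which the expressed /
#' non-expressed call is refused downstream.
#'
#' @param intensities numeric vector (>= 10 finite values); typically the
#'   per-gene mean log intensities.
#' @param seed RNG seed (the fit itself is deterministic; the seed guards
#'   any future stochastic initialization and is recorded).
#' @return a `MixtureFit`: `mean`, `sd`, `weight` (each length 2, component
#'   1 = non-expressed), `loglik`, `converged`, `degenerate`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_mixture <- function(intensities, seed = 1L) {
  x <- intensities[is.finite(intensities)]
  if (length(x) < 10L) stop("need >= 10 finite intensities")
  fits <- with_seed(seed, {
    list(two = mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE),
         one = mclust::Mclust(x, G = 1, verbose = FALSE))
  })
  fit <- fits$two
  if (is.null(fit)) stop("mixture fit failed")
  mu <- as.numeric(fit$parameters$mean)
  sd_ <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sd_) == 1L) sd_ <- rep(sd_, 2L)
  w <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  mu <- mu[ord]; sd_ <- sd_[ord]; w <- w[ord]
  # collapse test: a single Gaussian explains the data at least as well
  # (BIC), or the second component is negligible or unseparated
  one_wins <- !is.null(fits$one) && is.finite(fits$one$bic) &&
    fits$one$bic >= fit$bic
  degenerate <- one_wins || (mu[2] - mu[1]) < 0.5 * max(sd_) || any(w < 0.05)
  structure(
    list(mean = mu, sd = sd_, weight = w,
         loglik = fit$loglik, converged = TRUE, degenerate = degenerate,
         n = length(x)),
    class = "MixtureFit"
  )
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat("MixtureFit: non-expressed N(", format(x$mean[1], digits = 3), ", ",
      format(x$sd[1], digits = 3), "^2) w=", format(x$weight[1], digits = 3),
      "; expressed N(", format(x$mean[2], digits = 3), ", ",
      format(x$sd[2], digits = 3), "^2) w=", format(x$weight[2], digits = 3),
      if (x$degenerate) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

#' Call expressed genes against a sampled non-expressed null
#'
#' Samples `n_null` points (default 10,000) from the fitted non-expressed
#' component and tests, gene by gene, whether the gene's expression is too
#' high to have been generated from that distribution (one-sided,
#' "greater"). P values are corrected across genes (Benjamini-Hochberg by
#' default); genes with adjusted p <= `alpha` are called expressed.
#'
#' Two test variants are available. The default, `"membership"`, tests the
#' hypothesis actually at stake — that the gene's expression level was
#' generated from the non-expressed distribution — so the null spread
#' enters as the variance of a single draw from that distribution:
#' \deqn{t = \frac{\bar x_g - \bar x_0}
#'            {\sqrt{s_0^2 (1 + 1/n_0) + s_g^2 / n_g}}}
#' with Welch-Satterthwaite degrees of freedom. The `"welch"` variant is a
#' plain Welch two-sample comparison of means; because the gene mean is
#' estimated precisely from its samples, it rejects for genes only
#' marginally above the null mean and calls a large fraction of the
#' non-expressed component expressed — it is provided for comparison only.
#'
#' @param matrix genes x samples numeric matrix (log intensity), gene ids
#'   as rownames.
#' @param fit a non-degenerate `MixtureFit`.
#' @param n_null points sampled from the non-expressed component.
#' @param alpha adjusted-p cut-off.
#' @param method p-value adjustment (see [stats::p.adjust()]).
#' @param variant `"membership"` (default) or `"welch"`.
#' @param seed RNG seed for the null sample; calls are reproducible from
#'   it.
#' @return an `ExpressionCall` data frame: `gene_id`, `mean_intensity`,
#'   `t`, `p`, `p_adj`, `expressed`.
#' @export
call_expressed <- function(matrix, fit, n_null = 10000L, alpha = 0.05,
                           method = "BH", variant = c("membership", "welch"),
                           seed = 1L) {
  stopifnot(inherits(fit, "MixtureFit"))
  variant <- match.arg(variant)
  if (fit$degenerate) {
    stop("gating refused: degenerate mixture fit (no separable components)")
  }
  X <- as.matrix(matrix)
  if (any(rowSums(is.finite(X)) < 2L)) {
    stop("every gene needs >= 2 finite sample values")
  }
  null_draws <- with_seed(seed, stats::rnorm(n_null, fit$mean[1], fit$sd[1]))
  m0 <- mean(null_draws); v0 <- stats::var(null_draws)
  n0 <- n_null
  ng <- rowSums(is.finite(X))
  mg <- rowMeans(X, na.rm = TRUE)
  vg <- apply(X, 1, stats::var, na.rm = TRUE)
  if (variant == "membership") {
    se2_g <- vg / ng
    se2_0 <- v0 * (1 + 1 / n0)
  } else {
    se2_g <- vg / ng
    se2_0 <- v0 / n0
  }
  se <- sqrt(se2_g + se2_0)
  tstat <- (mg - m0) / se
  df <- (se2_g + se2_0)^2 / (se2_g^2 / (ng - 1) + se2_0^2 / (n0 - 1))
  p <- stats::pt(tstat, df = df, lower.tail = FALSE)
  p_adj <- stats::p.adjust(p, method = method)
  data.frame(
    gene_id = rownames(X) %||% paste0("gene_", seq_len(nrow(X))),
    mean_intensity = mg, t = tstat, p = p, p_adj = p_adj,
    expressed = p_adj <= alpha,
    row.names = NULL
  )
}
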