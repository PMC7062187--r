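#' Hypergeometric over-representation of a reference gene set
#'
#' Tests whether a hit list drawn from a finite gene universe is enriched
#' for a reference set (e.g. previously reported parkin interactors).
#' With universe size N, reference size K (after intersecting the
#' reference with the universe), hit-list size n and overlap k, the
#' one-sided p value is the exact upper tail
#' \eqn{p = P(X \ge k)} for \eqn{X \sim Hypergeometric(N, K, n)},
#' computed via [stats::phyper()]. Fold enrichment is `(k/n) / (K/N)`.
#'
#' Reference genes absent from the universe are dropped (and counted);
#' hits must be a subset of the universe.
#'
#' @param hits character vector of hit gene ids.
#' @param reference character vector of reference gene ids.
#' @param universe character vector of all testable gene ids (e.g. all
#'   genes surviving screen QC).
#' @return an `EnrichmentResult`: list with `N`, `K`, `n`, `k`, `p_value`,
#'   `fold_enrichment`, `reference_dropped`.
#' @examples
#' hypergeom_enrichment(paste0("g", 1:5), paste0("g", c(1:4, 10)),
#'                      paste0("g", 1:20))
#' @export
hypergeom_enrichment <- function(hits, reference, universe) {
  universe <- unique(universe)
  hits <- unique(hits)
  reference <- unique(reference)
  if (length(universe) == 0L || length(hits) == 0L) {
    stop("input error: empty universe or hit list")
  }
  outside <- setdiff(hits, universe)
  if (length(outside) > 0L) {
    stop("input error: hit(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  dropped <- sum(!reference %in% universe)
  reference <- intersect(reference, universe)
  N <- length(universe); K <- length(reference); n <- length(hits)
  k <- length(intersect(hits, reference))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(
    list(N = N, K = K, n = n, k = k,
         p_value = p,
         fold_enrichment = if (K > 0) (k / n) / (K / N) else NA_real_,
         reference_dropped = dropped),
    class = "EnrichmentResult"
  )
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat("Hypergeometric enrichment: overlap ", x$k, " of ", x$n,
      " hits vs ", x$K, "/", x$N, " in universe; p = ",
      format(x$p_value, digits = 4), ", fold = ",
      format(x$fold_enrichment, digits = 3), "\n", sep = "")
  invisible(x)
}
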