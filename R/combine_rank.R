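#' Normalize effect measures to their absolute maximum
#'
#' Effect measures from different studies and methods (primary PCA score,
#' primary PLS SSMD, secondary per-siRNA SSMDs) are not directly
#' comparable; each vector is therefore divided by its own maximum absolute
#' value, mapping it into [-1, 1] with the sign pattern preserved.
#'
#' @param measures a named list of numeric vectors (or one vector).
#' @return the same structure, each vector scaled by `1 / max(|x|)`.
#' @export
normalize_measures <- function(measures) {
  one <- function(v) {
    m <- max(abs(v), na.rm = TRUE)
    if (!is.finite(m) || m == 0) {
      stop("normalization error: all-zero (or all-missing) measure vector")
    }
    v / m
  }
  if (is.list(measures)) lapply(measures, one) else one(measures)
}

#' Cross-screen weighted score
#'
#' The weighted score of a gene is the arithmetic mean of all its available
#' absolute-max-normalized measures. Because it is a mean of signed values
#' in [-1, 1], genes behaving oppositely across studies or methods shrink
#' toward 0 (the penalization), while consistent strong behaviour
#' approaches +/- 1. Genes absent from a study are averaged over the
#' measures they do have.
#'
#' @param measures named list of numeric vectors, each carrying gene ids as
#'   names; vectors are normalized internally via [normalize_measures()]
#'   unless `normalized = TRUE`.
#' @param normalized set TRUE if the vectors are already max-abs
#'   normalized.
#' @return a `WeightedScoreTable` data frame: `gene_id`, one column per
#'   measure, `n_measures`, `weighted_score`, `rank` (descending score).
#' @export
weighted_score <- function(measures, normalized = FALSE) {
  stopifnot(is.list(measures), length(measures) >= 1)
  if (is.null(names(measures)) || any(names(measures) == "")) {
    names(measures) <- paste0("measure_", seq_along(measures))
  }
  if (!normalized) measures <- normalize_measures(measures)
  genes <- sort(unique(unlist(lapply(measures, names))))
  if (length(genes) == 0) stop("measures must carry gene ids as names")
  M <- sapply(measures, function(v) v[match(genes, names(v))])
  M <- matrix(M, nrow = length(genes),
              dimnames = list(genes, names(measures)))
  score <- rowMeans(M, na.rm = TRUE)
  out <- data.frame(gene_id = genes, M, check.names = FALSE,
                    row.names = NULL)
  out$n_measures <- rowSums(!is.na(M))
  out$weighted_score <- score
  out$rank <- rank(-score, ties.method = "first")
  out
}

#' Select the top and bottom fraction by weighted score
#'
#' Flags the top `ceiling(fraction * n)` genes as positive regulators and
#' the bottom `ceiling(fraction * n)` as negative regulators. Ties at the
#' boundary are broken deterministically by |score| (stronger first), then
#' by gene id, so the selection does not depend on input row order.
#'
#' @param table a `WeightedScoreTable` from [weighted_score()].
#' @param fraction fraction per tail, in (0, 0.5].
#' @return `table` with added `selected` ("positive", "negative" or
#'   "none"), ordered as input.
#' @export
select_top_fraction <- function(table, fraction = 0.10) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5) {
    stop("parameter error: fraction must be in (0, 0.5]")
  }
  n <- nrow(table)
  if (n == 0) stop("parameter error: empty score table")
  k <- ceiling(fraction * n)
  s <- table$weighted_score
  ord_top <- order(-s, -abs(s), table$gene_id)
  ord_bot <- order(s, -abs(s), table$gene_id)
  top <- table$gene_id[ord_top][seq_len(k)]
  bot <- setdiff(table$gene_id[ord_bot][seq_len(k)], top)
  table$selected <- ifelse(table$gene_id %in% top, "positive",
                    ifelse(table$gene_id %in% bot, "negative", "none"))
  table
}

#' Count concordant secondary-screen siRNAs
#'
#' For each gene, counts how many of its (up to three) secondary-screen
#' siRNAs show a significantly strong effect (|SSMD| > `threshold`,
#' default 1.3) in the same direction as the gene's primary-screen call.
#' Genes without a known primary direction are reported with count 0 and
#' flagged.
#'
#' @param secondary data frame with columns `gene_id`, `sirna_id`, `ssmd`.
#' @param primary_direction named numeric vector (+1 / -1 per gene_id).
#' @param threshold strict |SSMD| threshold.
#' @return data frame: `gene_id`, `n_sirnas`, `concordant`,
#'   `direction_known`.
#' @export
concordance_count <- function(secondary, primary_direction, threshold = 1.3) {
  stopifnot(all(c("gene_id", "sirna_id", "ssmd") %in% names(secondary)))
  genes <- unique(secondary$gene_id)
  res <- lapply(genes, function(g) {
    rows <- secondary[secondary$gene_id == g, , drop = FALSE]
    if (nrow(rows) > 3L) stop("more than 3 siRNAs for gene ", g)
    dir <- primary_direction[g]
    known <- !is.na(dir) && length(dir) == 1 && dir != 0
    conc <- if (known) {
      sum(abs(rows$ssmd) > threshold & sign(rows$ssmd) == sign(dir), na.rm = TRUE)
    } else 0L
    data.frame(gene_id = g, n_sirnas = nrow(rows),
               concordant = as.integer(conc),
               direction_known = known, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
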