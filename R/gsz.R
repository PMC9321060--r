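# Gene-set Z-score (GSZ) scoring. For a sample with per-gene centered values
# x over N genes and a signature matching n of them, the GSZ is the z-score
# of the set mean under simple random sampling without replacement:
#   GSZ = (m_set - m_all) / sqrt( (sd_all^2 / n) * (N - n) / (N - 1) )
# with m_all and sd_all the mean and population sd over all N genes of that
# sample. The finite-population correction gives the statistic a calibrated
# null (mean 0, variance 1 over random sets of size n) without any tuning
# constant, and preserves the two operational uses of the score: sign
# thresholding (GSZ > 0 detection) and ROC ranking.

#' Gene-set Z-score profile of a signature
#'
#' @param E a centered `ExpressionMatrix` (see [preprocess()]).
#' @param sig a [signature()].
#' @param min_genes minimum number of matched genes.
#' @return an object of class `GSZProfile`: list with `name`, `scores`
#'   (named per-sample vector), `n_matched`, `n_universe`.
#' @export
gsz <- function(E, sig, min_genes = 2L) {
  stopifnot(inherits(E, "ExpressionMatrix"), inherits(sig, "Signature"))
  v <- E$values
  matched <- intersect(sig$genes, rownames(v))
  if (length(matched) < min_genes) {
    missing <- setdiff(sig$genes, rownames(v))
    stop(sprintf("signature '%s': only %d gene(s) matched (need >= %d); unmatched: %s",
                 sig$name, length(matched), min_genes,
                 paste(utils::head(missing, 10), collapse = ", ")))
  }
  if (length(matched) < 0.5 * length(sig$genes))
    warning(sprintf("signature '%s': only %d of %d genes found in the matrix",
                    sig$name, length(matched), length(sig$genes)))
  n <- length(matched)
  N <- nrow(v)
  m_set <- colMeans(v[matched, , drop = FALSE])
  m_all <- colMeans(v)
  sd2_all <- colMeans(v^2) - m_all^2         # population variance (N divisor)
  denom2 <- (sd2_all / n) * (N - n) / (N - 1)
  scores <- ifelse(denom2 <= 0, 0, (m_set - m_all) / sqrt(pmax(denom2, 0)))
  names(scores) <- colnames(v)
  structure(list(name = sig$name, scores = scores, n_matched = n,
                 n_universe = N), class = "GSZProfile")
}

#' GSZ profiles for a signature collection
#'
#' @param E a centered `ExpressionMatrix`.
#' @param sigs list of [signature()] objects.
#' @param min_genes minimum number of matched genes per signature.
#' @return samples x signatures matrix of GSZ values.
#' @export
gsz_matrix <- function(E, sigs, min_genes = 2L) {
  out <- vapply(sigs, function(s) gsz(E, s, min_genes = min_genes)$scores,
                numeric(ncol(E$values)))
  colnames(out) <- vapply(sigs, `[[`, "", "name")
  out
}

#' Map a signature onto the SOM grid
#'
#' Per-pixel count of the signature genes' BMUs, plus a ranking of spots by
#' the number of contained signature genes when a spot set is supplied.
#'
#' @param sig a [signature()].
#' @param model a trained `SOMModel`.
#' @param spotset optional `SpotSet` for the accumulation summary.
#' @return list with `counts` (pixel vector, sums to the number of matched
#'   genes), `n_matched`, and `spot_counts` (named vector, decreasing) when
#'   `spotset` is given.
#' @export
map_signature <- function(sig, model, spotset = NULL) {
  stopifnot(inherits(sig, "Signature"), inherits(model, "SOMModel"))
  matched <- intersect(sig$genes, names(model$bmu))
  if (!length(matched))
    stop("signature '", sig$name, "' has no gene in the mapped universe")
  counts <- tabulate(model$bmu[matched], nbins = model$rows * model$cols)
  out <- list(counts = counts, n_matched = length(matched))
  if (!is.null(spotset)) {
    sc <- vapply(spotset$spots,
                 function(s) sum(counts[s$pixels]), 0)
    out$spot_counts <- sort(sc, decreasing = TRUE)
  }
  out
}

#' Signature-to-spot enrichment by the hypergeometric (Fisher) upper tail
#'
#' One-sided overrepresentation p-value of each signature's genes among each
#' spot's genes, within the universe of genes assigned to the SOM: the upper
#' tail `P(overlap >= k)` of the hypergeometric distribution of the 2x2
#' table. No multiple-testing correction is applied by default; Bonferroni
#' values are reported alongside when requested.
#'
#' @param sigs list of [signature()] objects.
#' @param spotset a `SpotSet` with attached genes.
#' @param universe character vector of all mapped gene ids.
#' @param bonferroni also report Bonferroni-adjusted p-values.
#' @return data.frame with signature, spot, overlap, p, log10_p (and
#'   p_bonferroni if requested).
#' @export
spot_enrichment <- function(sigs, spotset, universe, bonferroni = FALSE) {
  if (!length(spotset$spots)) stop("empty spot set")
  rows <- list()
  for (sig in sigs) {
    sig_genes <- intersect(sig$genes, universe)
    for (s in spotset$spots) {
      spot_genes <- intersect(s$genes, universe)
      if (!length(spot_genes)) stop("spot ", s$letter, " has an empty gene set")
      k <- length(intersect(sig_genes, spot_genes))
      p <- stats::phyper(k - 1, length(sig_genes),
                         length(universe) - length(sig_genes),
                         length(spot_genes), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(signature = sig$name, spot = s$letter, overlap = k,
                   p = p, log10_p = log10(p))
    }
  }
  out <- do.call(rbind, rows)
  if (bonferroni) out$p_bonferroni <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}
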