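# ROC/AUC benchmarking of signature scores, joint-detection and gene-overlap
# matrices, random-subset resampling stability, GSZ-profile correlation
# clustering, and combinatorial pattern-type (PAT) assignment.

#' ROC curve and AUC of a score vector
#'
#' Threshold sweep over the unique scores; the AUC equals the Mann-Whitney
#' statistic U / (n+ * n-), computed from midranks so that ties count 1/2.
#'
#' @param scores numeric score vector.
#' @param labels vector of class labels, same length.
#' @param positive the positive-class label.
#' @return an object of class `ROCResult`: list with `thresholds`, `tpr`,
#'   `fpr` (monotone from (0,0) to (1,1)), `auc`, `n_pos`, `n_neg`.
#' @export
roc <- function(scores, labels, positive) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present (positive = ", positive, ")")
  r <- rank(scores)                       # midranks handle ties
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & pos), 0)
  fp <- vapply(thr, function(t) sum(scores >= t & !pos), 0)
  structure(list(thresholds = c(Inf, thr), tpr = c(0, tp / n1),
                 fpr = c(0, fp / n0), auc = auc, n_pos = n1, n_neg = n0,
                 positive = positive),
            class = "ROCResult")
}

#' @export
print.ROCResult <- function(x, ...) {
  cat(sprintf("ROC (positive = %s): AUC %.4f, n+ %d, n- %d\n",
              x$positive, x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' AUC table of signatures for a two-group contrast
#'
#' GSZ-scores each signature on the samples of the two contrast groups
#' (samples outside the contrast are excluded, per the two-group design of
#' the literature classifiers) and reports the ROC AUC with the first group
#' as the positive class. Signatures without matched genes are flagged, not
#' dropped.
#'
#' @param E a centered `ExpressionMatrix`.
#' @param sigs list of [signature()] objects (spot signatures included).
#' @param labels named subtype labels.
#' @param positive,negative character vectors of labels defining the groups.
#' @return data.frame with signature, n_genes, auc, n_pos, n_neg, flagged.
#' @export
evaluate_signatures <- function(E, sigs, labels, positive, negative) {
  ids <- sample_ids(E)
  lab <- labels[ids]
  keep <- lab %in% c(positive, negative)
  if (!any(lab %in% positive) || !any(lab %in% negative))
    stop("contrast group(s) absent from the labels")
  sub <- expression_matrix(E$values[, keep, drop = FALSE],
                           sample_labels = lab[keep])
  y <- ifelse(lab[keep] %in% positive, "pos", "neg")
  rows <- lapply(sigs, function(sig) {
    matched <- intersect(sig$genes, gene_ids(sub))
    if (length(matched) < 2L) {
      return(data.frame(signature = sig$name, n_genes = length(matched),
                        auc = NA_real_, n_pos = sum(y == "pos"),
                        n_neg = sum(y == "neg"), flagged = TRUE))
    }
    prof <- gsz(sub, sig)
    r <- roc(prof$scores, y, positive = "pos")
    data.frame(signature = sig$name, n_genes = prof$n_matched, auc = r$auc,
               n_pos = r$n_pos, n_neg = r$n_neg, flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Joint-detection and gene-overlap matrices
#'
#' Detection rule: a sample is detected by a signature when its GSZ is
#' strictly positive. The joint-detection entry for a signature pair is the
#' Jaccard fraction |detected by both| / |detected by either|.
#'
#' @param profiles samples x signatures GSZ matrix (see [gsz_matrix()]).
#' @return symmetric signatures x signatures matrix of joint fractions
#'   (1 on the diagonal whenever a signature detects anything).
#' @export
joint_detection <- function(profiles) {
  if (ncol(profiles) < 2L) stop("need at least two profiles")
  det <- profiles > 0
  k <- ncol(det)
  out <- matrix(0, k, k, dimnames = list(colnames(det), colnames(det)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    both <- sum(det[, i] & det[, j])
    either <- sum(det[, i] | det[, j])
    out[i, j] <- if (either == 0L) 0 else both / either
  }
  out
}

#' @rdname joint_detection
#' @param sigs list of [signature()] objects.
#' @return `gene_overlap()`: matrix of raw intersection counts.
#' @export
gene_overlap <- function(sigs) {
  k <- length(sigs)
  nms <- vapply(sigs, `[[`, "", "name")
  out <- matrix(0L, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) for (j in seq_len(k))
    out[i, j] <- length(intersect(sigs[[i]]$genes, sigs[[j]]$genes))
  out
}

#' Detection rates of a GSZ profile per label group
#'
#' @param profile a `GSZProfile` or named score vector.
#' @param labels named subtype labels.
#' @param groups named list of label vectors.
#' @return named numeric vector: fraction of each group with GSZ > 0.
#' @export
detection_rate <- function(profile, labels, groups) {
  scores <- if (inherits(profile, "GSZProfile")) profile$scores else profile
  lab <- labels[names(scores)]
  vapply(groups, function(g) mean(scores[lab %in% g] > 0), 0)
}

#' Resampling stability of a classifier gene set
#'
#' For each fraction, draws `reps` random gene subsets of the set without
#' replacement, scores each by GSZ and records the contrast AUC. Reports the
#' per-fraction AUC distribution with median and IQR; fully seeded.
#'
#' @param genes the classifier gene set (e.g. a spot's genes).
#' @param E a centered `ExpressionMatrix`.
#' @param labels named subtype labels.
#' @param positive,negative contrast label groups.
#' @param fractions subset fractions in (0, 1].
#' @param reps resamples per fraction.
#' @param seed integer seed.
#' @return list with `summary` (data.frame fraction, median, q25, q75) and
#'   `auc` (fractions x reps matrix).
#' @export
resample_stability <- function(genes, E, labels, positive, negative,
                               fractions = c(0.2, 0.4, 0.6, 0.8),
                               reps = 100L, seed = 1L) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  if (reps < 1L) stop("reps must be >= 1")
  genes <- intersect(genes, gene_ids(E))
  set.seed(seed)
  auc_mat <- matrix(NA_real_, length(fractions), reps,
                    dimnames = list(as.character(fractions), NULL))
  for (i in seq_along(fractions)) {
    size <- max(1L, round(fractions[i] * length(genes)))
    if (size < 2L) stop("subset size < 2 at fraction ", fractions[i])
    for (r in seq_len(reps)) {
      sub <- if (size == length(genes)) genes else sample(genes, size)
      sig <- signature(sprintf("resample_%g_%d", fractions[i], r), sub)
      auc_mat[i, r] <- evaluate_signatures(E, list(sig), labels,
                                           positive, negative)$auc
    }
  }
  summary <- data.frame(
    fraction = fractions,
    median = apply(auc_mat, 1L, stats::median),
    q25 = apply(auc_mat, 1L, stats::quantile, 0.25),
    q75 = apply(auc_mat, 1L, stats::quantile, 0.75))
  rownames(summary) <- NULL
  list(summary = summary, auc = auc_mat)
}

#' Correlation clustering of GSZ profiles
#'
#' Pearson correlation between signature GSZ profiles over samples, plus the
#' two-group split obtained by average-linkage hierarchical clustering of
#' `1 - r` cut at two clusters.
#'
#' @param profiles samples x signatures GSZ matrix.
#' @return list with `correlation` (signatures x signatures), `clusters`
#'   (named integer vector in {1, 2}) and the `hclust` object.
#' @export
gsz_correlation_clusters <- function(profiles) {
  if (ncol(profiles) < 2L) stop("need at least two profiles")
  sds <- apply(profiles, 2L, stats::sd)
  cm <- suppressWarnings(stats::cor(profiles))
  if (any(sds == 0)) {
    warning("constant profile(s); correlations set to 0")
    cm[sds == 0, ] <- 0; cm[, sds == 0] <- 0
  }
  diag(cm) <- 1
  hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  list(correlation = cm, clusters = stats::cutree(hc, k = 2), hclust = hc)
}

#' Pattern-type (PAT) assignment
#'
#' A spot counts as activated in a sample when its mean portrait value over
#' the spot pixels is positive and exceeds the `q` quantile of that sample's
#' portrait pixel values. The PAT label is the alphabetically sorted string
#' of activated spot letters; samples with no activated spot get
#' `"∅"`. Both rules are scale-free: portraits multiplied by a positive
#' constant yield identical labels, and raising `q` can only remove letters.
#'
#' @param P pixels x samples portrait matrix.
#' @param spotset a `SpotSet` on the same grid.
#' @param q per-sample activation quantile.
#' @return list with `labels` (named character vector of PAT strings) and
#'   `table` (PAT group counts, decreasing).
#' @export
pat_assign <- function(P, spotset, q = 0.90) {
  if (nrow(P) != spotset$rows * spotset$cols)
    stop("portraits do not match the spot grid")
  spot_means <- spot_expression(spotset, P)
  cuts <- apply(P, 2L, stats::quantile, q, names = FALSE)
  labels <- vapply(seq_len(ncol(P)), function(s) {
    act <- spot_means[, s] > 0 & spot_means[, s] > cuts[s]
    if (!any(act)) "∅" else
      paste(sort(rownames(spot_means)[act]), collapse = "")
  }, "")
  names(labels) <- colnames(P)
  list(labels = labels, table = sort(table(labels), decreasing = TRUE))
}
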