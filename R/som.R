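# Batch self-organizing map on gene expression profiles. Each grid pixel
# holds a metagene: a prototype profile across samples. Genes are assigned to
# their Euclidean best-matching unit (BMU); prototypes are updated as
# Gaussian-neighborhood-weighted means of the assigned gene profiles. The
# batch formulation plus PCA-plane initialization makes training fully
# deterministic for a given input.

#' Preprocess an expression matrix for SOM training
#'
#' Optional quantile normalization across samples (via limma), then mandatory
#' per-gene mean centering, so that portraits display differential expression
#' around each gene's cohort mean.
#'
#' @param E an [expression_matrix()].
#' @param quantile_normalize logical.
#' @return a centered `ExpressionMatrix` (every row mean 0).
#' @export
preprocess <- function(E, quantile_normalize = FALSE) {
  stopifnot(inherits(E, "ExpressionMatrix"))
  v <- E$values
  if (ncol(v) < 2L)
    stop("centering needs at least two samples")
  if (quantile_normalize) {
    qn <- limma::normalizeQuantiles(v)
    dimnames(qn) <- dimnames(v)
    v <- qn
  }
  v <- v - rowMeans(v)
  expression_matrix(v, sample_labels = E$sample_labels)
}

# squared Euclidean distances between pixel centres of a rows x cols grid
grid_dist2 <- function(rows, cols) {
  rr <- rep(seq_len(rows), each = cols)
  cc <- rep(seq_len(cols), times = rows)
  outer(rr, rr, `-`)^2 + outer(cc, cc, `-`)^2
}

#' Pixel index / coordinate conversion
#'
#' Pixels are numbered row-major: `pixel = (row - 1) * grid_cols + col`,
#' 1-based, on a planar (non-toroidal) grid.
#'
#' @param pixel integer pixel index (1-based).
#' @param rows,cols grid dimensions.
#' @return `pixel_coords()`: a matrix with columns `row`, `col`.
#' @export
pixel_coords <- function(pixel, rows, cols) {
  pixel <- as.integer(pixel)
  cols <- as.integer(cols)
  cbind(row = (pixel - 1L) %/% cols + 1L, col = (pixel - 1L) %% cols + 1L)
}

# BMU assignment: argmin over prototypes of ||x - p||^2, computed through the
# cross-product trick; ties broken toward the lowest pixel index.
assign_bmu <- function(X, P) {
  score <- X %*% t(P)
  score <- sweep(score, 2L, rowSums(P^2) / 2, `-`)
  max.col(score, ties.method = "first")
}

#' Train a batch SOM of metagenes on gene profiles
#'
#' Prototypes are initialized on the plane spanned by the first two principal
#' components of the gene profiles. Per epoch every gene is assigned to its
#' Euclidean best-matching prototype and prototypes are recomputed as
#' Gaussian-neighborhood-weighted means of the assigned profiles; the
#' neighborhood radius decays linearly from `max(rows, cols) / 2` to
#' `radius_end` over the epochs.
#'
#' @param E a centered `ExpressionMatrix` (see [preprocess()]).
#' @param rows,cols grid dimensions; `rows * cols >= 4`.
#' @param epochs number of batch epochs.
#' @param seed integer seed (kept in the model metadata; batch training with
#'   PCA initialization is itself deterministic).
#' @param radius_end final neighborhood radius.
#' @return an object of class `SOMModel` with elements `rows`, `cols`,
#'   `prototypes` (pixels x samples), `bmu` (named gene -> pixel index),
#'   `qe` (per-epoch quantization error) and `meta`.
#' @export
train_som <- function(E, rows = 50L, cols = 50L, epochs = 20L, seed = 1L,
                      radius_end = 1) {
  stopifnot(inherits(E, "ExpressionMatrix"))
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows * cols < 4L) stop("grid must have at least 4 pixels")
  X <- E$values
  if (max(abs(rowMeans(X))) > 1e-6)
    stop("input is not gene-centered; run preprocess() first")
  n_pix <- rows * cols
  if (nrow(X) < n_pix)
    warning("fewer genes than pixels; the map will be sparsely occupied")

  # PCA-plane initialization spanning the grid
  sv <- svd(X, nu = 0L, nv = min(2L, ncol(X)))
  sdev <- sv$d / sqrt(max(1L, nrow(X) - 1L))
  gx <- if (rows > 1L) seq(-1, 1, length.out = rows) else 0
  gy <- if (cols > 1L) seq(-1, 1, length.out = cols) else 0
  coords <- cbind(rep(gx, each = cols), rep(gy, times = rows))
  P <- coords[, 1L, drop = FALSE] %*% t(sv$v[, 1L]) * sdev[1L]
  if (ncol(sv$v) >= 2L)
    P <- P + coords[, 2L, drop = FALSE] %*% t(sv$v[, 2L]) * sdev[2L]
  P <- P + rep(colMeans(X), each = n_pix)

  d2g <- grid_dist2(rows, cols)
  r_start <- max(rows, cols) / 2
  radii <- if (epochs > 1L)
    seq(r_start, radius_end, length.out = epochs) else r_start
  qe <- numeric(epochs)
  sum_x2 <- rowSums(X^2)
  bmu <- NULL
  for (e in seq_len(epochs)) {
    bmu <- assign_bmu(X, P)
    # quantization error: mean distance of genes to their BMU prototype
    qe[e] <- mean(sqrt(pmax(0, sum_x2 -
      2 * rowSums(X * P[bmu, , drop = FALSE]) +
      rowSums(P^2)[bmu])))
    S <- matrix(0, n_pix, ncol(X))
    agg <- rowsum(X, group = bmu)
    S[as.integer(rownames(agg)), ] <- agg
    cnt <- tabulate(bmu, nbins = n_pix)
    H <- exp(-d2g / (2 * radii[e]^2))
    P <- (H %*% S) / as.vector(H %*% cnt)
    if (any(!is.finite(P)))
      stop("non-finite prototypes at epoch ", e)
  }
  bmu <- assign_bmu(X, P)
  names(bmu) <- rownames(X)
  dimnames(P) <- list(NULL, colnames(X))
  structure(list(rows = rows, cols = cols, prototypes = P, bmu = bmu,
                 qe = qe,
                 meta = list(epochs = epochs, radius_start = r_start,
                             radius_end = radius_end, seed = seed,
                             sample_labels = E$sample_labels)),
            class = "SOMModel")
}

#' @export
print.SOMModel <- function(x, ...) {
  cat(sprintf("SOMModel: %dx%d grid, %d genes, %d samples, %d epochs\n",
              x$rows, x$cols, length(x$bmu), ncol(x$prototypes),
              x$meta$epochs))
  invisible(x)
}

#' Per-sample metagene portraits
#'
#' A portrait is the vector of metagene (prototype) values of one sample over
#' all grid pixels -- the sample's expression image on the map.
#'
#' @param model a trained `SOMModel`.
#' @param sample_id a sample identifier present in the model.
#' @return `portrait()`: numeric pixel vector; `portraits()`: pixels x
#'   samples matrix (one column per portrait).
#' @export
portrait <- function(model, sample_id) {
  stopifnot(inherits(model, "SOMModel"))
  if (!sample_id %in% colnames(model$prototypes))
    stop("unknown sample id: ", sample_id)
  model$prototypes[, sample_id]
}

#' @rdname portrait
#' @export
portraits <- function(model) {
  stopifnot(inherits(model, "SOMModel"))
  model$prototypes
}

#' Group-mean and difference portraits
#'
#' @param P pixels x samples portrait matrix (see [portraits()]).
#' @param labels named subtype labels covering the samples of `P`.
#' @param group label of the group to average.
#' @return a pixel vector.
#' @export
group_mean_portrait <- function(P, labels, group) {
  ids <- colnames(P)[labels[colnames(P)] %in% group]
  if (!length(ids)) stop("empty group: ", paste(group, collapse = ","))
  rowMeans(P[, ids, drop = FALSE])
}

#' @rdname group_mean_portrait
#' @param pA,pB pixel vectors of equal length.
#' @export
difference_portrait <- function(pA, pB) {
  if (length(pA) != length(pB)) stop("portraits differ in grid size")
  pA - pB
}

#' Pairwise portrait correlation map
#'
#' Pearson correlation between the portrait pixel vectors of all sample
#' pairs; symmetric with unit diagonal. Zero-variance portraits get
#' correlation 0 with a warning.
#'
#' @param P pixels x samples portrait matrix.
#' @return samples x samples correlation matrix.
#' @export
correlation_map <- function(P) {
  if (ncol(P) < 2L) stop("need at least two portraits")
  sds <- apply(P, 2L, stats::sd)
  cm <- suppressWarnings(stats::cor(P))
  if (any(sds == 0)) {
    warning("zero-variance portrait(s); correlations set to 0")
    cm[sds == 0, ] <- 0
    cm[, sds == 0] <- 0
  }
  diag(cm) <- 1
  cm
}

#' Grid distance between the BMUs of two genes
#'
#' @param model a `SOMModel`.
#' @param g1,g2 gene ids.
#' @param metric `"euclidean"` or `"chebyshev"`.
#' @return numeric distance in grid units.
#' @export
bmu_distance <- function(model, g1, g2, metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  a <- pixel_coords(model$bmu[[g1]], model$rows, model$cols)
  b <- pixel_coords(model$bmu[[g2]], model$rows, model$cols)
  d <- abs(a - b)
  if (metric == "euclidean") sqrt(sum(d^2)) else max(d)
}

#' Permutation test for co-localization of a gene set on the map
#'
#' Tests whether the genes of a set map closer together on the grid than
#' equally sized random gene sets, using the mean pairwise Euclidean BMU
#' distance as statistic (estimated from at most `max_pairs` sampled pairs
#' for large sets).
#'
#' @param model a `SOMModel`.
#' @param genes gene ids of the set.
#' @param n_perm number of random sets.
#' @param max_pairs pair subsample cap per set.
#' @param seed integer seed.
#' @return list with `statistic`, `null` (permutation statistics) and the
#'   permutation `p.value` `(1 + #{null <= obs}) / (n_perm + 1)`.
#' @export
colocalization_test <- function(model, genes, n_perm = 199L,
                                max_pairs = 2000L, seed = 1L) {
  stopifnot(inherits(model, "SOMModel"))
  genes <- intersect(genes, names(model$bmu))
  if (length(genes) < 2L) stop("need at least two mapped genes")
  coords <- pixel_coords(model$bmu, model$rows, model$cols)
  set.seed(seed)
  mean_pair_dist <- function(idx) {
    n <- length(idx)
    pairs <- if (n * (n - 1) / 2 <= max_pairs) {
      utils::combn(idx, 2L)
    } else {
      rbind(sample(idx, max_pairs, replace = TRUE),
            sample(idx, max_pairs, replace = TRUE))
    }
    keep <- pairs[1L, ] != pairs[2L, ]
    pairs <- pairs[, keep, drop = FALSE]
    mean(sqrt((coords[pairs[1L, ], 1L] - coords[pairs[2L, ], 1L])^2 +
              (coords[pairs[1L, ], 2L] - coords[pairs[2L, ], 2L])^2))
  }
  obs <- mean_pair_dist(match(genes, names(model$bmu)))
  null <- replicate(n_perm, mean_pair_dist(
    sample.int(length(model$bmu), length(genes))))
  p <- (1 + sum(null <= obs)) / (n_perm + 1)
  list(statistic = obs, null = null, p.value = p)
}
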