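# Over-expression spot segmentation on the metagene landscape. Spots are
# 8-connected components of pixels whose summary-map value strictly exceeds a
# quantile threshold; each spot carries the genes whose BMU lies inside it
# and serves as a candidate classifier gene set.

#' Spot summary map
#'
#' Pixel-wise maximum over group-mean portraits: the landscape on which
#' over-expression spots are segmented.
#'
#' @param group_portraits pixels x groups matrix (or a single pixel vector).
#' @return numeric pixel vector.
#' @export
summary_map <- function(group_portraits) {
  gp <- as.matrix(group_portraits)
  if (!ncol(gp)) stop("need at least one group portrait")
  apply(gp, 1L, max)
}

# 8-connected components of a logical pixel mask on a rows x cols grid;
# returns an integer label vector (0 = background), deterministic.
connected_components <- function(mask, rows, cols) {
  labels <- integer(length(mask))
  current <- 0L
  for (start in which(mask)) {
    if (labels[start]) next
    current <- current + 1L
    queue <- start
    labels[start] <- current
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      r <- (p - 1L) %/% cols + 1L
      cc <- (p - 1L) %% cols + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        nr <- r + dr; nc <- cc + dc
        if (nr < 1L || nr > rows || nc < 1L || nc > cols) next
        q <- (nr - 1L) * cols + nc
        if (mask[q] && !labels[q]) {
          labels[q] <- current
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Segment over-expression spots from a map
#'
#' Pixels whose map value strictly exceeds the `q` quantile of the map form
#' the foreground; 8-connected components of at least `min_size` pixels
#' become spots, lettered `A`, `B`, ... in decreasing order of their peak
#' value. A constant map yields an empty spot set (no pixel strictly exceeds
#' the quantile). When a model is supplied, each spot collects the genes
#' whose BMU falls inside it.
#'
#' @param map numeric pixel vector (e.g. from [summary_map()]).
#' @param rows,cols grid dimensions; defaults taken from `model`.
#' @param q threshold quantile in (0, 1).
#' @param min_size minimum spot size in pixels.
#' @param model optional `SOMModel` used to attach genes.
#' @return an object of class `SpotSet`: list with `spots` (each with
#'   `letter`, `pixels`, `genes`, `seed_pixel`, `peak`), `threshold`, `q`,
#'   `rows`, `cols`.
#' @export
detect_spots <- function(map, rows = model$rows, cols = model$cols,
                         q = 0.85, min_size = 3L, model = NULL) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  if (min_size < 1L) stop("min_size must be >= 1")
  if (length(map) != rows * cols) stop("map length does not match grid")
  thr <- stats::quantile(map, q, names = FALSE)
  mask <- map > thr
  comp <- connected_components(mask, rows, cols)
  spots <- list()
  if (max(comp) > 0L) {
    for (k in seq_len(max(comp))) {
      pix <- which(comp == k)
      if (length(pix) < min_size) next
      peak_pix <- pix[which.max(map[pix])]
      genes <- if (!is.null(model))
        names(model$bmu)[model$bmu %in% pix] else character()
      spots[[length(spots) + 1L]] <-
        list(pixels = pix, genes = genes, seed_pixel = peak_pix,
             peak = map[peak_pix])
    }
    if (length(spots)) {
      ord <- order(vapply(spots, `[[`, 0, "peak"), decreasing = TRUE)
      spots <- spots[ord]
      letters_pool <- c(LETTERS, paste0("Z", seq_len(max(0, length(spots) - 26L))))
      for (i in seq_along(spots)) spots[[i]]$letter <- letters_pool[[i]]
      names(spots) <- vapply(spots, `[[`, "", "letter")
    }
  }
  structure(list(spots = spots, threshold = thr, q = q,
                 min_size = as.integer(min_size),
                 rows = rows, cols = cols),
            class = "SpotSet")
}

#' @export
print.SpotSet <- function(x, ...) {
  cat(sprintf("SpotSet: %d spot(s) above quantile %.3g (threshold %.3g)\n",
              length(x$spots), x$q, x$threshold))
  for (s in x$spots)
    cat(sprintf("  %s: %d pixels, %d genes, peak %.3f\n", s$letter,
                length(s$pixels), length(s$genes), s$peak))
  invisible(x)
}

#' Spot summary table
#'
#' @param spotset a `SpotSet`.
#' @return data.frame with letter, pixel count, gene count and peak height.
#' @export
spot_table <- function(spotset) {
  data.frame(
    letter = vapply(spotset$spots, `[[`, "", "letter"),
    n_pixels = vapply(spotset$spots, function(s) length(s$pixels), 0L),
    n_genes = vapply(spotset$spots, function(s) length(s$genes), 0L),
    peak = vapply(spotset$spots, `[[`, 0, "peak"),
    row.names = NULL)
}

#' Spot gene sets as signatures
#'
#' @param spotset a `SpotSet` with attached genes.
#' @param prefix name prefix for the emitted signatures.
#' @return named list of [signature()] objects, one per spot.
#' @export
spot_signatures <- function(spotset, prefix = "spot") {
  sigs <- lapply(spotset$spots, function(s) {
    if (!length(s$genes)) stop("spot ", s$letter, " has no genes attached")
    signature(paste0(prefix, "_", s$letter, "_up"), s$genes,
              direction = "up", provenance = "spot module")
  })
  stats::setNames(sigs, vapply(spotset$spots, `[[`, "", "letter"))
}

#' Mean spot expression per sample
#'
#' @param spotset a `SpotSet`.
#' @param P pixels x samples portrait matrix.
#' @return spots x samples matrix of mean portrait values over spot pixels.
#' @export
spot_expression <- function(spotset, P) {
  if (nrow(P) != spotset$rows * spotset$cols)
    stop("portraits do not match the spot grid")
  if (!length(spotset$spots)) stop("empty spot set")
  out <- matrix(NA_real_, length(spotset$spots), ncol(P),
                dimnames = list(names(spotset$spots), colnames(P)))
  for (i in seq_along(spotset$spots))
    out[i, ] <- colMeans(P[spotset$spots[[i]]$pixels, , drop = FALSE])
  out
}

#' Match detected spots to planted truth modules
#'
#' For each planted module, the spot with maximal Jaccard index between its
#' gene set and the module's genes.
#'
#' @param spotset a `SpotSet` with attached genes.
#' @param truth a `CohortTruth`.
#' @return data.frame with module, matched spot letter, Jaccard index and
#'   overlap count (NA letter when the spot set is empty).
#' @export
match_spots_to_modules <- function(spotset, truth) {
  mod_genes <- truth_module_genes(truth)
  if (!length(spotset$spots)) {
    return(data.frame(module = names(mod_genes), spot = NA_character_,
                      jaccard = 0, overlap = 0L, row.names = NULL))
  }
  rows <- lapply(names(mod_genes), function(m) {
    jac <- vapply(spotset$spots, function(s) {
      length(intersect(s$genes, mod_genes[[m]])) /
        length(union(s$genes, mod_genes[[m]]))
    }, 0)
    best <- which.max(jac)
    data.frame(module = m, spot = names(spotset$spots)[best],
               jaccard = jac[[best]],
               overlap = length(intersect(spotset$spots[[best]]$genes,
                                          mod_genes[[m]])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
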