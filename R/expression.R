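#' Construct an expression matrix container
#'
#' The central data container of the pipeline: a genes-by-samples matrix of
#' log2-scale expression values with unique gene and sample identifiers and an
#' optional map from sample to subtype label. Gene identifiers are treated as
#' opaque strings; no symbol/probe mapping is attempted.
#'
#' @param values numeric matrix, genes in rows and samples in columns, with
#'   row and column names set.
#' @param sample_labels optional named character vector mapping sample ids to
#'   subtype labels; names must be a subset of `colnames(values)`.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values` and `sample_labels`.
#' @export
expression_matrix <- function(values, sample_labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene row names and sample column names")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  dup <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup))
    stop("duplicate sample id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  if (any(!is.finite(values)))
    stop("`values` contains non-finite entries (NA/NaN/Inf)")
  if (!is.null(sample_labels)) {
    if (is.null(names(sample_labels)))
      stop("`sample_labels` must be named by sample id")
    unknown <- setdiff(names(sample_labels), colnames(values))
    if (length(unknown))
      stop("labels for unknown sample(s): ", paste(unknown, collapse = ", "))
    sample_labels <- as.character(sample_labels)[
      match(colnames(values), names(sample_labels))]
    names(sample_labels) <- colnames(values)
  }
  structure(list(values = values, sample_labels = sample_labels),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$sample_labels)) {
    tab <- table(x$sample_labels)
    cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

impute_gene_means <- function(values) {
  na <- is.na(values)
  if (any(na)) {
    means <- rowMeans(values, na.rm = TRUE)
    values[na] <- means[row(values)[na]]
  }
  values
}

#' Read an expression matrix from TSV or GCT
#'
#' TSV layout: header row of sample ids, first column gene ids. GCT is the
#' 1.2 dialect: a `#1.2` version line, a `<genes> <samples>` dimension line,
#' then a table with `Name` and `Description` columns. Row and column order
#' is preserved from the file.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @param sample_labels optional named character vector of subtype labels.
#' @param impute_missing if `TRUE`, missing cells are imputed by the gene
#'   mean; by default any missing cell is a hard error.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "gct"),
                            sample_labels = NULL, impute_missing = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
    ids <- df[[1L]]
    body <- df[, -1L, drop = FALSE]
  } else {
    lines <- readLines(path)
    if (length(lines) < 3L || !startsWith(lines[[1L]], "#1.2"))
      stop("not a GCT 1.2 file (missing '#1.2' header): ", path)
    dims <- as.integer(strsplit(trimws(lines[[2L]]), "[ \t]+")[[1L]])
    df <- utils::read.delim(text = lines[-(1:2)], header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
    if (!identical(toupper(names(df)[1:2]), c("NAME", "DESCRIPTION")))
      stop("GCT table must start with Name and Description columns")
    if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L])
      stop(sprintf(
        "GCT dimension line declares %d x %d but table has %d x %d",
        dims[1L], dims[2L], nrow(df), ncol(df) - 2L))
    ids <- df[[1L]]
    body <- df[, -(1:2), drop = FALSE]
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicate gene id(s) in ", path, ": ",
                        paste(utils::head(dup, 5), collapse = ", "))
  dup <- unique(names(body)[duplicated(names(body))])
  if (length(dup)) stop("duplicate sample id(s) in ", path, ": ",
                        paste(utils::head(dup, 5), collapse = ", "))
  values <- matrix(NA_real_, nrow(body), ncol(body),
                   dimnames = list(ids, names(body)))
  for (j in seq_len(ncol(body))) {
    cell <- body[[j]]
    missing <- is.na(cell) | cell == "" | cell == "NA"
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!missing & is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at row %d (gene %s), column %s",
                   cell[bad[1L]], bad[1L], ids[bad[1L]], names(body)[j]))
    values[, j] <- num
  }
  if (any(is.na(values))) {
    if (!impute_missing)
      stop("missing values present; rerun with impute_missing = TRUE to ",
           "impute by gene means")
    values <- impute_gene_means(values)
  }
  expression_matrix(values, sample_labels = sample_labels)
}

#' Write an expression matrix to TSV or GCT
#'
#' Values are serialized with 17 significant digits so that a
#' write-then-read cycle reproduces them bit-exactly.
#'
#' @param E an [expression_matrix()].
#' @param path output file path.
#' @param format `"tsv"` or `"gct"`.
#' @export
write_expression <- function(E, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  v <- E$values
  chr <- matrix(format_full(v), nrow(v), ncol(v))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(paste(c("gene_id", colnames(v)), collapse = "\t"), con)
    writeLines(paste(rownames(v), apply(chr, 1, paste, collapse = "\t"),
                     sep = "\t"), con)
  } else {
    writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), con)
    writeLines(paste(c("Name", "Description", colnames(v)), collapse = "\t"), con)
    writeLines(paste(rownames(v), "na",
                     apply(chr, 1, paste, collapse = "\t"), sep = "\t"), con)
  }
  invisible(path)
}

#' Read / write a sample annotation table
#'
#' Two-column tab-separated table `sample_id<TAB>label` with a header line.
#'
#' @param path file path.
#' @return named character vector of labels.
#' @export
read_sample_labels <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("label table needs two columns: sample_id, label")
  stats::setNames(df[[2L]], df[[1L]])
}

#' @rdname read_sample_labels
#' @param labels named character vector of subtype labels.
#' @export
write_sample_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
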