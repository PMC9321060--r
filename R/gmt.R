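#' Gene signature
#'
#' A directional gene set. The direction convention of this package encodes
#' direction in the signature name: a `_up` or `_down` suffix (or an `up` /
#' `down` token in the GMT description field) marks the set as up- or
#' down-regulated in its target group; unmarked sets default to `up`, which
#' matches the convention of treating all classifier sets as unidirectionally
#' upregulated between the contrasted groups.
#'
#' @param name signature name, unique within a collection.
#' @param genes character vector of gene ids; duplicates are removed.
#' @param direction `"up"` or `"down"`.
#' @param provenance free-text provenance note.
#' @return an object of class `Signature`.
#' @export
signature <- function(name, genes, direction = c("up", "down"),
                      provenance = "") {
  direction <- match.arg(direction)
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("signature '", name, "' has no genes")
  structure(list(name = name, genes = genes, direction = direction,
                 provenance = provenance), class = "Signature")
}

#' @export
print.Signature <- function(x, ...) {
  cat(sprintf("Signature %s (%s): %d genes\n", x$name, x$direction,
              length(x$genes)))
  invisible(x)
}

direction_from <- function(name, description) {
  if (grepl("_down$", name) || grepl("\\bdown\\b", tolower(description)))
    "down" else "up"
}

#' Read gene signatures from a GMT file
#'
#' Standard tab-separated GMT: one signature per line, fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are dropped with a warning.
#'
#' @param path file path.
#' @return a named list of [signature()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description and at least one gene",
                   i, length(fields)))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): %d duplicate gene id(s) removed",
                      i, fields[[1L]], sum(duplicated(genes))))
      genes <- unique(genes)
    }
    if (!length(genes))
      stop(sprintf("GMT line %d ('%s') has an empty gene list", i, fields[[1L]]))
    sigs[[i]] <- signature(fields[[1L]], genes,
                           direction = direction_from(fields[[1L]], fields[[2L]]),
                           provenance = fields[[2L]])
  }
  names(sigs) <- vapply(sigs, `[[`, "", "name")
  dup <- unique(names(sigs)[duplicated(names(sigs))])
  if (length(dup)) stop("duplicate signature name(s): ",
                        paste(dup, collapse = ", "))
  sigs
}

#' Write signatures to a GMT file
#'
#' @param sigs a list of [signature()] objects.
#' @param path output file path.
#' @export
write_gmt <- function(sigs, path) {
  lines <- vapply(sigs, function(s) {
    desc <- if (nzchar(s$provenance)) s$provenance else s$direction
    paste(c(s$name, desc, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
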