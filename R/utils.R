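# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apportion a total into integer counts proportional to weights
#'
#' Largest-remainder (Hamilton) apportionment. Every stratum with positive
#' weight receives at least one sample so that rare strata survive
#' down-scaling.
#'
#' @param weights named non-negative numeric vector.
#' @param total positive integer to distribute.
#' @return named integer vector summing to `total`.
#' @keywords internal
apportion_counts <- function(weights, total) {
  stopifnot(is.numeric(weights), all(weights >= 0), sum(weights) > 0,
            total >= sum(weights > 0))
  quota <- weights / sum(weights) * total
  counts <- floor(quota)
  rem <- total - sum(counts)
  if (rem > 0) {
    take <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[take] <- counts[take] + 1L
  }
  # guarantee positivity by moving singles from the largest strata
  while (any(zero <- (counts == 0 & weights > 0))) {
    i <- which(zero)[1L]
    j <- which.max(counts)
    counts[i] <- 1L
    counts[j] <- counts[j] - 1L
  }
  stats::setNames(as.integer(counts), names(weights))
}

# Derive a stage seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% (.Machine$integer.max - 1))
}

# format doubles so that read.delim round-trips them bit-exactly
format_full <- function(x) sprintf("%.17g", x)

log_msg <- function(..., logfile = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  paste0(...))
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE, sep = "")
  invisible(line)
}
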