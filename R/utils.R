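# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open (BED convention); conversions happen only at
# file-format boundaries.

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic chromosome ordering: byte-wise (C locale), independent of the
# session locale, so sorted outputs are reproducible across platforms.
chrom_rank <- function(chrom) {
  lv <- sort(unique(as.character(chrom)), method = "radix")
  match(as.character(chrom), lv)
}

# Order rows of an interval data frame by (chrom, start, end).
interval_order <- function(df) {
  order(chrom_rank(df$chrom), df$start, df$end)
}

#' Construct a validated interval table
#'
#' The atomic region container used throughout the package: a data frame with
#' columns `chrom`, `start`, `end` (0-based half-open) and optional `name`,
#' `score`, `strand`.
#'
#' @param chrom Chromosome names (non-empty strings).
#' @param start 0-based inclusive start positions (`>= 0`).
#' @param end 0-based exclusive end positions (`> start`).
#' @param name Optional feature names.
#' @param score Optional numeric scores.
#' @param strand Strand, one of `"+"`, `"-"`, `"*"` (unstranded).
#' @return A `data.frame` with one row per interval.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              score = NA_real_, strand = "*") {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(chrom)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  if (any(!nzchar(df$chrom)) || anyNA(df$chrom))
    stopf("%s: empty chromosome name", what)
  if (anyNA(df$start) || anyNA(df$end))
    stopf("%s: missing coordinate", what)
  if (any(df$start < 0)) stopf("%s: negative start coordinate", what)
  if (any(df$end <= df$start)) stopf("%s: end <= start", what)
  if (!all(df$strand %in% c("+", "-", "*")))
    stopf("%s: strand must be one of '+', '-', '*'", what)
  invisible(df)
}

#' Merge overlapping or near-adjacent intervals
#'
#' Union-merges intervals per chromosome. Two intervals are merged when the
#' gap between them is at most `max_gap` bp (`max_gap = 0` merges touching or
#' overlapping intervals only).
#'
#' @param df Interval data frame (`chrom`, `start`, `end`).
#' @param max_gap Maximum gap in bp bridged by a merge.
#' @return Merged interval data frame sorted by (chrom, start).
#' @export
merge_intervals <- function(df, max_gap = 0) {
  if (nrow(df) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  df <- df[interval_order(df), , drop = FALSE]
  out <- lapply(split(df, factor(df$chrom, levels = unique(df$chrom))),
                function(d) {
    hi <- cummax(d$end)
    new_block <- c(TRUE, d$start[-1] > hi[-nrow(d)] + max_gap)
    grp <- cumsum(new_block)
    data.frame(chrom = d$chrom[1],
               start = tapply(d$start, grp, min),
               end = tapply(d$end, grp, max),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[interval_order(out), , drop = FALSE]
}

# TRUE for each query interval that overlaps (>= 1 bp) any subject interval.
# Subjects are union-merged first, so binary search is valid.
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  m <- merge_intervals(subject)
  res <- rep(FALSE, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    s <- m[m$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0) next
    # last merged interval starting at or before the query end - 1
    idx <- findInterval(query$end[qi] - 1, s$start)
    hit <- idx >= 1 & s$end[pmax(idx, 1)] > query$start[qi]
    res[qi] <- hit
  }
  res
}
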