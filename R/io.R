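# Readers and writers for the plain-text interchange formats consumed by the
# pipeline: BED3/BED6, BEDPE (7-8 columns), gene models (BED6 or GTF gene
# lines), tab-separated count matrices, GMT gene sets, JASPAR-style PFM text
# and FASTA. Parsing is strict: malformed coordinates fail with the offending
# line number rather than being silently dropped. All output files are sorted
# by (chrom, start) in byte order for bit-stable results.

data_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", x) & !grepl("^(#|track\\b|browser\\b)", x)
  list(lines = x[keep], lineno = which(keep))
}

parse_coord <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v != floor(v)
  if (any(bad))
    stopf("%s: non-integer %s at line %d", path, what, lineno[which(bad)[1]])
  v
}

#' Read a BED file
#'
#' @param path Path to a BED file; comment, `track` and `browser` lines are
#'   skipped.
#' @param min_columns Minimum number of tab-separated fields required on every
#'   data line (at least 3).
#' @return Interval data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`; 0-based half-open coordinates preserved verbatim, rows
#'   in file order.
#' @export
read_bed <- function(path, min_columns = 3) {
  min_columns <- max(3, min_columns)
  dl <- data_lines(path)
  if (length(dl$lines) == 0)
    return(genomic_intervals(character(), numeric(), numeric()))
  f <- strsplit(dl$lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < min_columns))
    stopf("%s: expected >= %d fields at line %d", path, min_columns,
          dl$lineno[which(nf < min_columns)[1]])
  g <- function(i) vapply(f, function(z) if (length(z) >= i) z[i] else NA_character_, "")
  chrom <- g(1)
  start <- parse_coord(g(2), path, dl$lineno, "start")
  end <- parse_coord(g(3), path, dl$lineno, "end")
  bad <- end <= start
  if (any(bad)) stopf("%s: end <= start at line %d", path, dl$lineno[which(bad)[1]])
  name <- g(4)
  score <- suppressWarnings(as.numeric(g(5)))
  strand <- g(6)
  strand[is.na(strand) | strand == "."] <- "*"
  ok <- strand %in% c("+", "-", "*")
  if (!all(ok)) stopf("%s: unknown strand symbol at line %d", path, dl$lineno[which(!ok)[1]])
  genomic_intervals(chrom, start, end, name, score, strand)
}

#' Write intervals as BED
#'
#' Rows are sorted by (chrom, start, end) in byte order. Name, score and
#' strand columns are emitted only when any value is non-missing.
#'
#' @param df Interval data frame.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  df <- df[interval_order(df), , drop = FALSE]
  cols <- list(df$chrom, format_coord(df$start), format_coord(df$end))
  has_name <- !is.null(df$name) && any(!is.na(df$name))
  has_score <- !is.null(df$score) && any(!is.na(df$score))
  has_strand <- !is.null(df$strand) && any(df$strand != "*")
  if (has_name || has_score || has_strand)
    cols <- c(cols, list(ifelse(is.na(df$name), ".", df$name)))
  if (has_score || has_strand)
    cols <- c(cols, list(ifelse(is.na(df$score), "0", format_num(df$score))))
  if (has_strand)
    cols <- c(cols, list(ifelse(df$strand == "*", ".", df$strand)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)
format_num <- function(x) {
  ifelse(x == floor(x), format(x, scientific = FALSE, trim = TRUE),
         vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                                      digits = 15), ""))
}

#' Read loop calls from a BEDPE file
#'
#' Expects at least 7 tab-separated columns (chrom1, start1, end1, chrom2,
#' start2, end2, count) with an optional 8th FDR column. Anchors are
#' canonically ordered so that anchor A precedes anchor B by (chrom, start).
#' Only intra-chromosomal loops are supported.
#'
#' @param path Path to a BEDPE file.
#' @param sample_id Sample label attached to every loop; defaults to the file
#'   name without extension.
#' @param on_interchrom `"error"` (default) rejects inter-chromosomal lines;
#'   `"drop"` removes them with a warning.
#' @return Data frame with columns `sample_id`, `chrom`, `start1`, `end1`,
#'   `start2`, `end2`, `count`, `fdr`.
#' @export
read_bedpe <- function(path, sample_id = NULL,
                       on_interchrom = c("error", "drop")) {
  on_interchrom <- match.arg(on_interchrom)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  dl <- data_lines(path)
  empty <- data.frame(sample_id = character(), chrom = character(),
                      start1 = numeric(), end1 = numeric(),
                      start2 = numeric(), end2 = numeric(),
                      count = numeric(), fdr = numeric(),
                      stringsAsFactors = FALSE)
  if (length(dl$lines) == 0) return(empty)
  f <- strsplit(dl$lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 7))
    stopf("%s: expected >= 7 fields at line %d", path, dl$lineno[which(nf < 7)[1]])
  g <- function(i) vapply(f, function(z) if (length(z) >= i) z[i] else NA_character_, "")
  chrom1 <- g(1); chrom2 <- g(4)
  inter <- chrom1 != chrom2
  if (any(inter)) {
    if (on_interchrom == "error")
      stopf("%s: inter-chromosomal loop at line %d (only intra-chromosomal loops are supported)",
            path, dl$lineno[which(inter)[1]])
    warnf("%s: dropped %d inter-chromosomal loop(s)", path, sum(inter))
  }
  start1 <- parse_coord(g(2), path, dl$lineno, "start1")
  end1 <- parse_coord(g(3), path, dl$lineno, "end1")
  start2 <- parse_coord(g(5), path, dl$lineno, "start2")
  end2 <- parse_coord(g(6), path, dl$lineno, "end2")
  count <- parse_coord(g(7), path, dl$lineno, "count")
  if (any(count < 0, na.rm = TRUE)) stopf("%s: negative loop count", path)
  fdr <- suppressWarnings(as.numeric(g(8)))
  if (any(!is.na(fdr) & (fdr < 0 | fdr > 1)))
    stopf("%s: FDR outside [0, 1]", path)
  loops <- data.frame(sample_id = sample_id, chrom = chrom1,
                      start1 = start1, end1 = end1,
                      start2 = start2, end2 = end2,
                      count = count, fdr = fdr, stringsAsFactors = FALSE)
  loops <- loops[!inter, , drop = FALSE]
  bad <- loops$end1 <= loops$start1 | loops$end2 <= loops$start2
  if (any(bad)) stopf("%s: anchor with end <= start", path)
  canonical_loops(loops)
}

# Order each loop's anchors so (start1, end1) <= (start2, end2).
canonical_loops <- function(loops) {
  swap <- loops$start2 < loops$start1 |
    (loops$start2 == loops$start1 & loops$end2 < loops$end1)
  if (any(swap)) {
    s1 <- loops$start1[swap]; e1 <- loops$end1[swap]
    loops$start1[swap] <- loops$start2[swap]
    loops$end1[swap] <- loops$end2[swap]
    loops$start2[swap] <- s1
    loops$end2[swap] <- e1
  }
  rownames(loops) <- NULL
  loops
}

#' Write loop calls as BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, count and, when any
#' FDR is present, an 8th FDR column. Rows sorted by (chrom, start1, start2).
#'
#' @param loops Loop data frame as returned by [read_bedpe()].
#' @param path Output path.
#' @export
write_bedpe <- function(loops, path) {
  o <- order(chrom_rank(loops$chrom), loops$start1, loops$start2, loops$end1,
             loops$end2)
  loops <- loops[o, , drop = FALSE]
  cols <- list(loops$chrom, format_coord(loops$start1), format_coord(loops$end1),
               loops$chrom, format_coord(loops$start2), format_coord(loops$end2),
               format_coord(loops$count))
  if (!is.null(loops$fdr) && any(!is.na(loops$fdr)))
    cols <- c(cols, list(ifelse(is.na(loops$fdr), ".",
                                format(loops$fdr, scientific = FALSE,
                                       trim = TRUE, digits = 10))))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read gene models with strand-aware TSS
#'
#' The transcription start site (TSS) is the 5' end of the locus:
#' `start` on the plus strand, `end - 1` on the minus strand (0-based).
#'
#' @param path Path to a BED6 file or a GTF whose `gene` feature lines carry a
#'   `gene_id` attribute. GTF 1-based closed coordinates are converted to the
#'   0-based half-open convention at this boundary.
#' @param format `"bed6"` or `"gtf"`.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`.
#' @export
read_gene_models <- function(path, format = c("bed6", "gtf")) {
  format <- match.arg(format)
  if (format == "bed6") {
    bed <- read_bed(path, min_columns = 6)
    if (any(bed$strand == "*"))
      stopf("%s: gene without strand (TSS undefined)", path)
    genes <- data.frame(gene_id = bed$name, chrom = bed$chrom,
                        start = bed$start, end = bed$end,
                        strand = bed$strand, stringsAsFactors = FALSE)
  } else {
    dl <- data_lines(path)
    f <- strsplit(dl$lines, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf < 9)) stopf("%s: expected 9 GTF fields at line %d", path,
                           dl$lineno[which(nf < 9)[1]])
    feat <- vapply(f, `[`, "", 3)
    f <- f[feat == "gene"]
    if (length(f) == 0) stopf("%s: no gene feature lines", path)
    ids <- vapply(f, function(z) {
      m <- regmatches(z[9], regexec('gene_id "([^"]+)"', z[9]))[[1]]
      if (length(m) < 2) NA_character_ else m[2]
    }, "")
    if (anyNA(ids)) stopf("%s: gene line without gene_id attribute", path)
    strand <- vapply(f, `[`, "", 7)
    if (!all(strand %in% c("+", "-")))
      stopf("%s: gene without strand (TSS undefined)", path)
    genes <- data.frame(gene_id = ids,
                        chrom = vapply(f, `[`, "", 1),
                        start = as.numeric(vapply(f, `[`, "", 4)) - 1,
                        end = as.numeric(vapply(f, `[`, "", 5)),
                        strand = strand, stringsAsFactors = FALSE)
  }
  dup <- duplicated(genes$gene_id)
  if (any(dup)) stopf("%s: duplicate gene_id '%s'", path, genes$gene_id[dup][1])
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes
}

#' Read a tab-separated count matrix
#'
#' First column holds gene identifiers, remaining columns one sample each,
#' with a header row of sample names.
#'
#' @param path Path to the counts file.
#' @return Integer matrix (genes x samples) with dimnames.
#' @export
read_counts <- function(path) {
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2) stopf("%s: counts file needs gene column plus samples", path)
  genes <- as.character(d[[1]])
  if (anyDuplicated(genes)) stopf("%s: duplicate gene ids", path)
  if (anyDuplicated(colnames(d)[-1])) stopf("%s: duplicate sample ids", path)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (anyNA(m) || any(m < 0) || any(m != floor(m)))
    stopf("%s: counts must be non-negative integers", path)
  rownames(m) <- genes
  m
}

#' Write a count matrix
#' @param counts Matrix genes x samples with dimnames.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path Path to a GMT file (set name, description, then member genes,
#'   tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  dl <- data_lines(path)
  f <- strsplit(dl$lines, "\t", fixed = TRUE)
  bad <- lengths(f) < 3
  if (any(bad)) stopf("%s: GMT line %d has fewer than 3 fields", path,
                      dl$lineno[which(bad)[1]])
  sets <- lapply(f, function(z) unique(z[-(1:2)]))
  names(sets) <- vapply(f, `[`, "", 1)
  if (anyDuplicated(names(sets))) stopf("%s: duplicate gene-set name", path)
  sets
}

#' Read JASPAR-style position frequency matrices
#'
#' Each motif is a `>id` header followed by four rows of equal-length,
#' non-negative counts in A, C, G, T order; rows may be bare numbers or the
#' JASPAR `A [ 1 2 3 ]` style. Counts are converted column-wise to
#' probabilities as `(c + pseudocount) / (colsum + 4 * pseudocount)`.
#'
#' @param path Path to the PFM file.
#' @param pseudocount Pseudocount added to every cell before normalization.
#' @param background Background base frequencies (A, C, G, T); must sum to 1.
#' @return List of `pwm` objects (see [make_pwm()]).
#' @export
read_pfm <- function(path, pseudocount = 0, background = rep(0.25, 4)) {
  dl <- data_lines(path)
  x <- dl$lines
  hdr <- grep("^>", x)
  if (length(hdr) == 0) stopf("%s: no '>' motif headers", path)
  ends <- c(hdr[-1] - 1, length(x))
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    id <- sub("^>\\s*", "", x[hdr[i]])
    id <- strsplit(id, "[ \t]+")[[1]][1]
    body <- x[(hdr[i] + 1):ends[i]]
    if (length(body) != 4)
      stopf("%s: motif '%s' needs exactly 4 count rows", path, id)
    rows <- lapply(body, function(line) {
      line <- gsub("^[ \t]*[ACGTacgt][ \t]*\\[?", "", line)
      line <- gsub("\\]", "", line)
      v <- suppressWarnings(as.numeric(strsplit(trimws(line), "[ \t]+")[[1]]))
      if (anyNA(v)) stopf("%s: non-numeric count in motif '%s'", path, id)
      v
    })
    if (length(unique(lengths(rows))) != 1)
      stopf("%s: ragged count rows in motif '%s'", path, id)
    cnt <- do.call(rbind, rows)
    if (any(cnt < 0)) stopf("%s: negative count in motif '%s'", path, id)
    out[[i]] <- make_pwm(id, counts = cnt, pseudocount = pseudocount,
                         background = background)
  }
  names(out) <- vapply(out, function(p) p$motif_id, "")
  out
}

#' Write position frequency matrices
#' @param pwms List of `pwm` objects carrying a `counts` matrix, or count
#'   matrices will be reconstructed from probabilities (x 100, rounded).
#' @param path Output path.
#' @export
write_pfm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    cnt <- p$counts %||% round(p$probs * 100)
    writeLines(paste0(">", p$motif_id), con)
    for (i in 1:4)
      writeLines(paste(format_coord(cnt[i, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Construct a position weight matrix object
#'
#' @param motif_id Motif identifier.
#' @param counts Optional 4 x width matrix of base counts (A, C, G, T rows).
#' @param probs Optional 4 x width matrix of base probabilities (columns sum
#'   to 1); exactly one of `counts`/`probs` is required.
#' @param pseudocount Pseudocount applied when converting counts.
#' @param background Background base frequencies; must sum to 1.
#' @return Object of class `pwm` with elements `motif_id`, `probs`,
#'   `background`, `pseudocount` and (when given) `counts`.
#' @export
make_pwm <- function(motif_id, counts = NULL, probs = NULL, pseudocount = 0,
                     background = rep(0.25, 4)) {
  if (abs(sum(background) - 1) > 1e-9) stopf("background must sum to 1")
  if (is.null(probs)) {
    if (is.null(counts)) stopf("make_pwm: need counts or probs")
    cs <- colSums(counts) + 4 * pseudocount
    if (any(cs == 0)) stopf("motif '%s': zero-count column without pseudocount",
                            motif_id)
    probs <- sweep(counts + pseudocount, 2, cs, "/")
  }
  if (any(abs(colSums(probs) - 1) > 1e-9))
    stopf("motif '%s': probability columns must sum to 1", motif_id)
  rownames(probs) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, probs = probs, background = background,
                 pseudocount = pseudocount, counts = counts), class = "pwm")
}

#' Read sequences from a FASTA file
#' @param path Path to an (uncompressed) FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  x <- toupper(as.character(ss))
  names(x) <- sub("\\s.*$", "", names(ss))
  x
}

#' Write sequences to a FASTA file
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 80)
  invisible(path)
}
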