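# Multi-sample consensus segmentation and presence/absence differential
# region calling. A boundary sweep partitions the union of all per-sample
# peaks into maximal segments of constant per-sample presence; quantifier
# rules over the presence vectors (control present/absent, >= k of n cases)
# then label each segment lost, gained, shared or other, mirroring
# multi-intersection ("multiinter") semantics.

#' Atomic consensus segments across samples
#'
#' Partitions the covered genome into maximal segments on which the set of
#' samples overlapping the segment is constant. Presence means >= 1 bp
#' overlap. Adjacent segments with identical presence vectors are merged; the
#' union of the returned segments equals the union of all input peaks.
#'
#' @param interval_sets Named list, one interval data frame per sample
#'   (control sample(s) included); overlapping intervals within a sample are
#'   union-merged first.
#' @return Object of class `consensus_segments`: list with `segments`
#'   (data frame `chrom`, `start`, `end`), `presence` (logical matrix,
#'   segments x samples) and `samples`.
#' @export
atomic_segments <- function(interval_sets) {
  if (is.null(names(interval_sets)) || any(!nzchar(names(interval_sets))))
    stopf("atomic_segments: interval_sets must be a named list (sample ids)")
  samples <- names(interval_sets)
  merged <- lapply(interval_sets, function(df) {
    validate_intervals(df)
    merge_intervals(df)
  })
  chroms <- sort(unique(unlist(lapply(merged, function(d) d$chrom))),
                 method = "radix")
  seg_list <- list()
  pres_list <- list()
  for (ch in chroms) {
    per <- lapply(merged, function(d) d[d$chrom == ch, , drop = FALSE])
    bounds <- sort(unique(unlist(lapply(per, function(d) c(d$start, d$end)))))
    if (length(bounds) < 2) next
    s <- bounds[-length(bounds)]
    e <- bounds[-1]
    pres <- vapply(per, function(d) {
      if (nrow(d) == 0) return(rep(FALSE, length(s)))
      idx <- findInterval(s, d$start)
      idx >= 1 & d$end[pmax(idx, 1)] > s
    }, logical(length(s)))
    pres <- matrix(pres, nrow = length(s), dimnames = list(NULL, samples))
    covered <- rowSums(pres) > 0
    s <- s[covered]; e <- e[covered]; pres <- pres[covered, , drop = FALSE]
    if (length(s) == 0) next
    # merge adjacent segments with identical presence vectors
    key <- apply(pres, 1, paste0, collapse = "")
    new_block <- c(TRUE, s[-1] != e[-length(e)] | key[-1] != key[-length(key)])
    grp <- cumsum(new_block)
    first <- !duplicated(grp)
    seg_list[[ch]] <- data.frame(chrom = ch,
                                 start = tapply(s, grp, min),
                                 end = tapply(e, grp, max),
                                 stringsAsFactors = FALSE)
    pres_list[[ch]] <- pres[first, , drop = FALSE]
  }
  if (length(seg_list) == 0) {
    segs <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                       stringsAsFactors = FALSE)
    pres <- matrix(logical(0), nrow = 0, ncol = length(samples),
                   dimnames = list(NULL, samples))
  } else {
    segs <- do.call(rbind, seg_list)
    rownames(segs) <- NULL
    pres <- do.call(rbind, pres_list)
  }
  structure(list(segments = segs, presence = pres, samples = samples),
            class = "consensus_segments")
}

#' @export
print.consensus_segments <- function(x, ...) {
  cat("consensus_segments:", nrow(x$segments), "segments across",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Presence/absence quantifier rule
#'
#' Describes one side of a differential-region definition: what the control
#' sample(s) must show and what fraction of the case samples must agree.
#' The canonical lost rule is control `"present"` with cases
#' `"absent_in_all"`; the canonical gained rule is control `"absent"` with
#' cases `"present_in_at_least_k"` (k = 10 of 15 for histone/ATAC panels,
#' 6 of 13 with two control slots for TF binding panels).
#'
#' @param control `"present"` or `"absent"` — required state of every control
#'   sample.
#' @param case_mode `"absent_in_all"` or `"present_in_at_least_k"`.
#' @param k Minimum number of case samples for `"present_in_at_least_k"`.
#' @return Object of class `presence_rule`.
#' @export
presence_rule <- function(control = c("present", "absent"),
                          case_mode = c("absent_in_all", "present_in_at_least_k"),
                          k = NULL) {
  control <- match.arg(control)
  case_mode <- match.arg(case_mode)
  if (case_mode == "present_in_at_least_k") {
    if (is.null(k) || k < 0) stopf("presence_rule: need k >= 0")
  } else {
    k <- 0
  }
  structure(list(control = control, case_mode = case_mode, k = k),
            class = "presence_rule")
}

rule_matches <- function(rule, ctl_pres, case_pres) {
  ctl_ok <- if (rule$control == "present") all(ctl_pres) else all(!ctl_pres)
  case_ok <- switch(rule$case_mode,
    absent_in_all = !any(case_pres),
    present_in_at_least_k = sum(case_pres) >= rule$k)
  ctl_ok && case_ok
}

#' Label consensus segments as lost/gained/shared/other
#'
#' Applies the lost and gained presence rules to every segment's presence
#' vector. `shared` marks segments present in every sample; everything else
#' is `other`. After labelling, adjacent same-label segments are merged and
#' segments narrower than `min_width` are dropped.
#'
#' @param cs A `consensus_segments` object from [atomic_segments()].
#' @param control_samples Character vector naming the control sample(s);
#'   all remaining samples are cases.
#' @param lost_rule,gained_rule [presence_rule()] objects; defaults encode
#'   control-specific loss and >= 10-of-n recurrent gain.
#' @param min_width Minimum segment width in bp retained after merging
#'   (default 1: no filtering).
#' @return Data frame `chrom`, `start`, `end`, `label`, `width`.
#' @export
classify_segments <- function(cs, control_samples,
                              lost_rule = presence_rule("present", "absent_in_all"),
                              gained_rule = presence_rule("absent",
                                                          "present_in_at_least_k",
                                                          k = 10),
                              min_width = 1) {
  if (!inherits(cs, "consensus_segments"))
    stopf("classify_segments: expected a consensus_segments object")
  if (!all(control_samples %in% cs$samples))
    stopf("classify_segments: unknown control sample")
  ctl_idx <- match(control_samples, cs$samples)
  case_idx <- setdiff(seq_along(cs$samples), ctl_idx)
  n_cases <- length(case_idx)
  for (r in list(lost_rule, gained_rule))
    if (r$case_mode == "present_in_at_least_k" && r$k > n_cases)
      stopf("classify_segments: rule requires %d cases but only %d present",
            r$k, n_cases)
  segs <- cs$segments
  if (nrow(segs) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      label = character(), width = numeric(),
                      stringsAsFactors = FALSE))
  lab <- vapply(seq_len(nrow(segs)), function(i) {
    ctl <- cs$presence[i, ctl_idx]
    cas <- cs$presence[i, case_idx]
    if (rule_matches(lost_rule, ctl, cas)) return("lost")
    if (rule_matches(gained_rule, ctl, cas)) return("gained")
    if (all(cs$presence[i, ])) return("shared")
    "other"
  }, "")
  segs$label <- lab
  # merge contiguous same-label segments, then width-filter
  o <- interval_order(segs)
  segs <- segs[o, , drop = FALSE]
  new_block <- c(TRUE, !(segs$chrom[-1] == segs$chrom[-nrow(segs)] &
                         segs$start[-1] == segs$end[-nrow(segs)] &
                         segs$label[-1] == segs$label[-nrow(segs)]))
  grp <- cumsum(new_block)
  out <- data.frame(chrom = tapply(segs$chrom, grp, `[`, 1),
                    start = as.numeric(tapply(segs$start, grp, min)),
                    end = as.numeric(tapply(segs$end, grp, max)),
                    label = tapply(segs$label, grp, `[`, 1),
                    stringsAsFactors = FALSE)
  out$width <- out$end - out$start
  out <- out[out$width >= min_width, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate intervals relative to the nearest TSS
#'
#' Distance is 0 when the interval contains the TSS, otherwise the signed bp
#' gap from the nearest interval edge to the TSS (positive when the TSS lies
#' beyond the interval end, negative when before the start). The nearest gene
#' minimizes `|distance|`; ties break to the lexicographically smallest
#' `gene_id`. Zone is `"proximal"` when `|distance| < window`, else
#' `"distal"`.
#'
#' @param intervals Interval data frame.
#' @param genes Gene models from [read_gene_models()] (strand-aware `tss`).
#' @param window Promoter window in bp (default 2000).
#' @return Data frame `chrom`, `start`, `end`, `nearest_gene_id`,
#'   `distance_to_tss`, `zone`.
#' @export
annotate_to_tss <- function(intervals, genes, window = 2000) {
  if (nrow(genes) == 0) stopf("annotate_to_tss: empty gene list")
  validate_intervals(intervals)
  n <- nrow(intervals)
  gene_id <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  g <- genes[order(genes$gene_id), , drop = FALSE]  # lexicographic tie-break
  for (ch in unique(intervals$chrom)) {
    qi <- which(intervals$chrom == ch)
    gc <- g[g$chrom == ch, , drop = FALSE]
    if (nrow(gc) == 0) next
    for (i in qi) {
      s <- intervals$start[i]; e <- intervals$end[i]
      d <- ifelse(gc$tss >= s & gc$tss < e, 0,
                  ifelse(gc$tss < s, gc$tss - s, gc$tss - e))
      j <- which.min(abs(d))  # first minimum = smallest gene_id on ties
      gene_id[i] <- gc$gene_id[j]
      dist[i] <- d[j]
    }
  }
  data.frame(chrom = intervals$chrom, start = intervals$start,
             end = intervals$end, nearest_gene_id = gene_id,
             distance_to_tss = dist,
             zone = ifelse(is.na(dist), NA_character_,
                           ifelse(abs(dist) < window, "proximal", "distal")),
             stringsAsFactors = FALSE)
}

#' Promoter windows around strand-aware TSSs
#'
#' One symmetric window `[tss - window, tss + window)` per gene, clipped at
#' zero; overlapping windows of nearby genes are retained unmerged
#' (per-gene semantics).
#'
#' @param genes Gene models with a `tss` column.
#' @param window Half-width in bp (default 2000).
#' @return Interval data frame with `name` = gene_id.
#' @export
promoter_windows <- function(genes, window = 2000) {
  if (window <= 0) stopf("promoter_windows: window must be positive")
  genomic_intervals(genes$chrom, pmax(0, genes$tss - window),
                    genes$tss + window, name = genes$gene_id,
                    strand = genes$strand)
}
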