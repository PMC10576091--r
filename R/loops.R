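# HiChIP loop post-processing: significance filtering, cross-sample anchor
# unification, presence/absence differential calling, promoter/enhancer
# classification, multi-anchor hub detection, and loop-length statistics.
# Loop span is the distance between anchor midpoints (floor division); this
# convention is stable under anchor widening and is recorded in all outputs.

#' Loop span in bp
#'
#' Distance between the midpoints of the two anchors, with midpoints taken
#' as `floor((start + end) / 2)`.
#'
#' @param loops Loop data frame (`start1`, `end1`, `start2`, `end2`).
#' @return Numeric vector of spans (>= 0).
#' @export
loop_span <- function(loops) {
  abs(floor((loops$start2 + loops$end2) / 2) -
      floor((loops$start1 + loops$end1) / 2))
}

#' Filter loop calls on support, FDR and length
#'
#' A call is kept when `count >= min_count`, `span >= min_length` and, where
#' an FDR is recorded, `fdr < max_fdr`. When the FDR column is entirely
#' missing the FDR filter is skipped with a warning.
#'
#' @param loops Loop data frame from [read_bedpe()].
#' @param min_count Minimum read-pair support (default 2).
#' @param max_fdr FDR cutoff (default 0.01).
#' @param min_length Minimum span in bp (default 5000).
#' @return Filtered loop data frame.
#' @export
filter_loops <- function(loops, min_count = 2, max_fdr = 0.01,
                         min_length = 5000) {
  if (nrow(loops) == 0) return(loops)
  span <- loop_span(loops)
  keep <- loops$count >= min_count & span >= min_length
  if (all(is.na(loops$fdr))) {
    warnf("filter_loops: no FDR column; FDR filter skipped")
  } else {
    keep <- keep & (is.na(loops$fdr) | loops$fdr < max_fdr)
  }
  out <- loops[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Unify loop anchors across samples
#'
#' Single-linkage merge of all anchor intervals per chromosome: anchors whose
#' gap is at most `max_gap` bp end up in the same unified anchor (transitive
#' chaining). Every original call maps to a pair of unified anchors; calls
#' from different samples mapping to the same unified pair become one
#' unified loop with a per-sample count vector (a loop absent from a
#' sample's file has implicit count 0; within-sample duplicates are summed).
#'
#' @param loops Filtered loop data frame covering all samples (column
#'   `sample_id`).
#' @param max_gap Maximum merge gap in bp (default 500).
#' @param samples Optional full sample vector (to retain zero-loop samples
#'   as all-zero count columns).
#' @return Object of class `unified_loops`: list with `anchors` (data frame
#'   `anchor_id`, `chrom`, `start`, `end`), `loops` (data frame `loop_id`,
#'   `anchor_a`, `anchor_b`, `chrom`, coordinates, `span_bp`), `counts`
#'   (matrix loops x samples) and `samples`.
#' @export
unify_anchors <- function(loops, max_gap = 500, samples = NULL) {
  samples <- samples %||% sort(unique(loops$sample_id), method = "radix")
  if (nrow(loops) == 0) stopf("unify_anchors: no loops")
  raw <- unique(rbind(
    data.frame(chrom = loops$chrom, start = loops$start1, end = loops$end1,
               stringsAsFactors = FALSE),
    data.frame(chrom = loops$chrom, start = loops$start2, end = loops$end2,
               stringsAsFactors = FALSE)))
  raw <- raw[interval_order(raw), , drop = FALSE]
  anchors <- merge_intervals(raw, max_gap = max_gap)
  anchors$anchor_id <- sprintf("A%06d", seq_len(nrow(anchors)))
  # map an original anchor to its unified anchor via binary search
  lookup <- function(chrom, start) {
    id <- character(length(chrom))
    for (ch in unique(chrom)) {
      qi <- which(chrom == ch)
      a <- anchors[anchors$chrom == ch, , drop = FALSE]
      idx <- findInterval(start[qi], a$start)
      if (any(idx < 1)) stopf("unify_anchors: anchor outside unified set")
      id[qi] <- a$anchor_id[idx]
    }
    id
  }
  id_a <- lookup(loops$chrom, loops$start1)
  id_b <- lookup(loops$chrom, loops$start2)
  # canonical pair order by anchor genomic position
  pos <- match(c(id_a, id_b), anchors$anchor_id)
  pa <- pos[seq_len(nrow(loops))]
  pb <- pos[-seq_len(nrow(loops))]
  swap <- pb < pa
  tmp <- id_a[swap]; id_a[swap] <- id_b[swap]; id_b[swap] <- tmp
  key <- paste(id_a, id_b, sep = "|")
  ukey <- sort(unique(key), method = "radix")
  counts <- matrix(0, nrow = length(ukey), ncol = length(samples),
                   dimnames = list(ukey, samples))
  agg <- tapply(loops$count, list(key, loops$sample_id), sum)
  counts[rownames(agg), colnames(agg)] <-
    ifelse(is.na(agg), 0, agg)
  ai <- match(sub("\\|.*$", "", ukey), anchors$anchor_id)
  bi <- match(sub("^.*\\|", "", ukey), anchors$anchor_id)
  ldf <- data.frame(loop_id = sprintf("L%06d", seq_along(ukey)),
                    anchor_a = anchors$anchor_id[ai],
                    anchor_b = anchors$anchor_id[bi],
                    chrom = anchors$chrom[ai],
                    start1 = anchors$start[ai], end1 = anchors$end[ai],
                    start2 = anchors$start[bi], end2 = anchors$end[bi],
                    stringsAsFactors = FALSE)
  ldf$span_bp <- loop_span(ldf)
  # stable genomic ordering of loops
  o <- order(chrom_rank(ldf$chrom), ldf$start1, ldf$start2)
  ldf <- ldf[o, , drop = FALSE]
  counts <- counts[o, , drop = FALSE]
  ldf$loop_id <- sprintf("L%06d", seq_len(nrow(ldf)))
  rownames(ldf) <- NULL
  rownames(counts) <- ldf$loop_id
  anchors <- anchors[, c("anchor_id", "chrom", "start", "end")]
  rownames(anchors) <- NULL
  structure(list(anchors = anchors, loops = ldf, counts = counts,
                 samples = samples), class = "unified_loops")
}

#' @export
print.unified_loops <- function(x, ...) {
  cat("unified_loops:", nrow(x$loops), "loops over", nrow(x$anchors),
      "anchors,", length(x$samples), "samples\n")
  if (!is.null(x$loops$diff_label))
    print(table(x$loops$diff_label))
  invisible(x)
}

#' Differential-loop rule
#'
#' Lost: present in the control (count >= `min_count`) and absent (count 0)
#' in every case. Gained: absent in the control and present (count >=
#' `min_count`) in at least `gained_min_cases` cases.
#'
#' @param min_count Count threshold defining "present" (default 2).
#' @param gained_min_cases Minimum number of supporting cases for a gained
#'   loop (default 8, of a 14-line panel).
#' @return Object of class `loop_diff_rule`.
#' @export
loop_diff_rule <- function(min_count = 2, gained_min_cases = 8) {
  if (min_count < 0 || gained_min_cases < 0)
    stopf("loop_diff_rule: thresholds must be non-negative")
  structure(list(min_count = min_count, gained_min_cases = gained_min_cases),
            class = "loop_diff_rule")
}

#' Call lost/gained/shared loops by presence rules
#'
#' Labels every unified loop: `lost` when the control count passes
#' `min_count` and all case counts are zero; `gained` when the control count
#' is zero and at least `gained_min_cases` cases pass `min_count`; `shared`
#' when control and at least `gained_min_cases` cases all pass `min_count`;
#' `other` otherwise.
#'
#' @param ul A `unified_loops` object.
#' @param control_sample Name of the control sample column.
#' @param rule A [loop_diff_rule()].
#' @return The `unified_loops` object with `loops$diff_label` added.
#' @export
call_differential_loops <- function(ul, control_sample,
                                    rule = loop_diff_rule()) {
  if (!control_sample %in% ul$samples)
    stopf("call_differential_loops: control sample '%s' not in counts",
          control_sample)
  cases <- setdiff(ul$samples, control_sample)
  if (rule$gained_min_cases > length(cases))
    stopf("call_differential_loops: rule requires %d cases but only %d present",
          rule$gained_min_cases, length(cases))
  cc <- ul$counts[, control_sample]
  cm <- ul$counts[, cases, drop = FALSE]
  n_present <- rowSums(cm >= rule$min_count)
  lost <- cc >= rule$min_count & rowSums(cm > 0) == 0
  gained <- cc == 0 & n_present >= rule$gained_min_cases
  shared <- cc >= rule$min_count & n_present >= rule$gained_min_cases & !lost
  label <- rep("other", nrow(ul$loops))
  label[shared] <- "shared"
  label[gained] <- "gained"
  label[lost] <- "lost"
  ul$loops$diff_label <- label
  ul
}

#' Classify loops as P-P, P-E or E-E
#'
#' An anchor is a promoter anchor when it overlaps (>= 1 bp) any promoter
#' window; loops are `P-P` (both anchors), `P-E` (exactly one) or `E-E`
#' (none, i.e. distal-distal).
#'
#' @param ul A `unified_loops` object.
#' @param promoters Promoter windows from [promoter_windows()].
#' @return The `unified_loops` object with `anchors$is_promoter` and
#'   `loops$class` added.
#' @export
classify_loops <- function(ul, promoters) {
  ul$anchors$is_promoter <- overlaps_any(ul$anchors, promoters)
  pa <- ul$anchors$is_promoter[match(ul$loops$anchor_a, ul$anchors$anchor_id)]
  pb <- ul$anchors$is_promoter[match(ul$loops$anchor_b, ul$anchors$anchor_id)]
  ul$loops$class <- ifelse(pa & pb, "P-P", ifelse(pa | pb, "P-E", "E-E"))
  ul
}

#' Differential-label by class contingency table
#'
#' Counts and within-label fractions of P-P / P-E / E-E among lost and
#' gained loops.
#'
#' @param ul A classified and differential-called `unified_loops` object.
#' @return List with `counts` (matrix label x class) and `fractions`
#'   (row-normalized).
#' @export
loop_class_table <- function(ul) {
  if (is.null(ul$loops$class) || is.null(ul$loops$diff_label))
    stopf("loop_class_table: run classify_loops and call_differential_loops first")
  keep <- ul$loops$diff_label %in% c("lost", "gained")
  tb <- table(factor(ul$loops$diff_label[keep], levels = c("lost", "gained")),
              factor(ul$loops$class[keep], levels = c("P-P", "P-E", "E-E")))
  counts <- matrix(as.integer(tb), nrow = 2,
                   dimnames = list(c("lost", "gained"), c("P-P", "P-E", "E-E")))
  fr <- counts / pmax(rowSums(counts), 1)
  list(counts = counts, fractions = fr)
}

#' Flag multi-anchor loops and hub components
#'
#' Anchors are graph nodes and loops edges; a loop is multi-anchor when
#' either endpoint has degree >= 2 (the anchor is used by two or more
#' loops). Hubs are connected components containing at least two loops.
#'
#' @param ul A `unified_loops` object.
#' @param subset Optional logical/loop_id subset of loops to analyse (e.g.
#'   only differential loops); defaults to all loops.
#' @return List with `multi_anchor` (named logical per loop), `hub_id`
#'   (named; NA for loops outside hubs), `n_hubs`, `fraction_multi_anchor`
#'   and, when labels and classes are available,
#'   `gained_multi_anchor_pp_fraction`.
#' @export
multi_anchor_flags <- function(ul, subset = NULL) {
  l <- ul$loops
  if (!is.null(subset)) {
    l <- if (is.logical(subset)) l[subset, , drop = FALSE]
         else l[l$loop_id %in% subset, , drop = FALSE]
  }
  if (nrow(l) == 0) stopf("multi_anchor_flags: no loops")
  deg <- table(c(l$anchor_a, l$anchor_b))
  multi <- as.vector(deg[l$anchor_a] >= 2 | deg[l$anchor_b] >= 2)
  g <- igraph::graph_from_data_frame(l[, c("anchor_a", "anchor_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)$membership
  edge_comp <- unname(comp[l$anchor_a])
  comp_sizes <- table(edge_comp)
  hub_comps <- as.integer(names(comp_sizes)[comp_sizes >= 2])
  hub_id <- ifelse(edge_comp %in% hub_comps,
                   paste0("hub", match(edge_comp, hub_comps)), NA_character_)
  names(multi) <- names(hub_id) <- l$loop_id
  out <- list(multi_anchor = multi, hub_id = hub_id,
              n_hubs = length(hub_comps),
              fraction_multi_anchor = mean(multi))
  if (!is.null(l$diff_label) && !is.null(l$class)) {
    gm <- l$diff_label == "gained" & multi
    out$gained_multi_anchor_pp_fraction <-
      if (any(gm)) mean(l$class[gm] == "P-P") else NA_real_
  }
  out
}

#' Compare lost vs gained loop lengths
#'
#' Medians and interquartile ranges of the span distributions plus a
#' two-sided Welch t-test. When several marks or conditions are tested,
#' adjust the returned p-values across the family with [bh_adjust()].
#'
#' @param lost_spans,gained_spans Numeric span vectors (bp), both non-empty.
#' @return List with `median_lost`, `median_gained`, `iqr_lost`,
#'   `iqr_gained`, `n_lost`, `n_gained` and `test` (a [test_result()]).
#' @export
compare_loop_lengths <- function(lost_spans, gained_spans) {
  if (length(lost_spans) == 0 || length(gained_spans) == 0)
    stopf("compare_loop_lengths: both span sets must be non-empty")
  list(median_lost = stats::median(lost_spans),
       median_gained = stats::median(gained_spans),
       iqr_lost = unname(diff(stats::quantile(lost_spans, c(0.25, 0.75)))),
       iqr_gained = unname(diff(stats::quantile(gained_spans, c(0.25, 0.75)))),
       n_lost = length(lost_spans), n_gained = length(gained_spans),
       test = welch_t(lost_spans, gained_spans))
}

#' Genes at the anchors of differential loops
#'
#' Genes whose promoter window (TSS +/- `window`) overlaps any anchor of a
#' lost or gained loop, and their overlap with a core DEG set.
#'
#' @param ul A differential-called `unified_loops` object.
#' @param genes Gene models.
#' @param core_degs Optional character vector of core DEG ids.
#' @param window Promoter half-width in bp (default 2000).
#' @return List with `genes`, `n_genes`, and (when `core_degs` given)
#'   `deg_overlap`, `n_deg_overlap`.
#' @export
genes_at_differential_anchors <- function(ul, genes, core_degs = NULL,
                                          window = 2000) {
  if (is.null(ul$loops$diff_label))
    stopf("genes_at_differential_anchors: run call_differential_loops first")
  diff <- ul$loops[ul$loops$diff_label %in% c("lost", "gained"), , drop = FALSE]
  aid <- unique(c(diff$anchor_a, diff$anchor_b))
  an <- ul$anchors[ul$anchors$anchor_id %in% aid, , drop = FALSE]
  pw <- promoter_windows(genes, window)
  hit <- overlaps_any(pw, an)
  out <- list(genes = sort(pw$name[hit], method = "radix"),
              n_genes = sum(hit))
  if (!is.null(core_degs)) {
    out$deg_overlap <- intersect(out$genes, core_degs)
    out$n_deg_overlap <- length(out$deg_overlap)
  }
  out
}
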