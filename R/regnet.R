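# Regulatory-network stage: PWM scanning with log-odds scores, motif
# enrichment in differential regions against a background set, key-TF
# selection by DEG intersection, target-gene assignment within gained
# regions, common-target analysis, and the motif-pair distance statistic.

#' Maximum attainable log-odds score of a PWM
#' @param pwm A `pwm` object.
#' @return Maximum score in bits.
#' @export
pwm_max_score <- function(pwm) {
  sum(apply(log2(pwm$probs / pwm$background), 2, max))
}

revcomp_pwm <- function(pwm) {
  p <- pwm$probs[4:1, ncol(pwm$probs):1, drop = FALSE]
  rownames(p) <- c("A", "C", "G", "T")
  p
}

scan_one_strand <- function(code, lut, width) {
  L <- length(code)
  n <- L - width + 1
  if (n < 1) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(width)) {
    v <- lut[, j][code[j:(n + j - 1)]]
    s <- s + v
  }
  s  # windows containing N carry NA
}

#' Scan sequences with a PWM
#'
#' Scores every window on both strands with the log-odds score
#' `sum(log2(p_base / bg_base))` in bits; windows containing `N` are
#' skipped. The minus strand is scanned by scoring the reverse-complemented
#' matrix on the plus strand, so hit coordinates always refer to the plus
#' strand.
#'
#' @param sequences Named character vector of sequences (names become
#'   chromosome names of the hits).
#' @param pwm A `pwm` object.
#' @param threshold Absolute score threshold in bits; when `NULL`,
#'   `min_score_frac * pwm_max_score(pwm)` is used.
#' @param min_score_frac Fraction of the maximum attainable score used as the
#'   default threshold (default 0.8).
#' @return Hit data frame: `motif_id`, `chrom`, `start`, `end` (0-based
#'   half-open, width = motif width), `strand`, `score`.
#' @export
scan_pwm <- function(sequences, pwm, threshold = NULL, min_score_frac = 0.8) {
  if (!inherits(pwm, "pwm")) stopf("scan_pwm: expected a pwm object")
  threshold <- threshold %||% (min_score_frac * pwm_max_score(pwm))
  if (!is.finite(threshold)) stopf("scan_pwm: non-finite threshold")
  width <- ncol(pwm$probs)
  lut_fwd <- log2(pwm$probs / pwm$background)
  lut_rev <- log2(revcomp_pwm(pwm) / pwm$background)
  res <- list()
  for (ch in names(sequences)) {
    code <- match(strsplit(toupper(sequences[[ch]]), "", fixed = TRUE)[[1]],
                  c("A", "C", "G", "T"))
    for (strand in c("+", "-")) {
      s <- scan_one_strand(code, if (strand == "+") lut_fwd else lut_rev, width)
      hit <- which(!is.na(s) & s >= threshold)
      if (length(hit) == 0) next
      res[[length(res) + 1]] <- data.frame(
        motif_id = pwm$motif_id, chrom = ch, start = hit - 1,
        end = hit - 1 + width, strand = strand, score = s[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0)
    return(data.frame(motif_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out <- out[order(chrom_rank(out$chrom), out$start,
                   match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Count, for each region, the hits fully contained in it. Hits of one motif
# have constant width, so containment reduces to start ranges and binary
# search on sorted hit starts. Returns an integer vector per region.
hits_per_region <- function(regions, hits) {
  n <- nrow(regions)
  res <- integer(n)
  if (n == 0 || nrow(hits) == 0) return(res)
  w <- hits$end[1] - hits$start[1]
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    hs <- sort(hits$start[hits$chrom == ch])
    if (length(hs) == 0) next
    lo <- findInterval(regions$start[ri] - 1, hs)       # hits before region
    hi <- findInterval(regions$end[ri] - w, hs)          # hits fitting inside
    res[ri] <- pmax(hi - lo, 0)
  }
  res
}

#' Motif enrichment in target vs background regions
#'
#' A region carries a motif when at least one hit of that motif lies fully
#' inside it. For every motif, enrichment of carrier targets over carrier
#' backgrounds is tested with the exact upper-tail hypergeometric
#' probability (population = targets + backgrounds, successes = all carrier
#' regions, draws = targets, observed = carrier targets), with
#' Benjamini-Hochberg adjustment across motifs. Background regions
#' overlapping a target region are removed first.
#'
#' @param target_regions,background_regions Interval data frames; the
#'   background must be non-empty after exclusion of target overlaps.
#' @param hits Hit data frame from [scan_pwm()] (may cover several motifs).
#' @return Data frame: `motif_id`, `targets_with_hit`, `targets_total`,
#'   `background_with_hit`, `background_total`, `p_value`, `q_value`.
#' @export
motif_enrichment <- function(target_regions, background_regions, hits) {
  if (nrow(background_regions) == 0) stopf("motif_enrichment: empty background")
  drop <- overlaps_any(background_regions, target_regions)
  if (any(drop)) {
    message(sprintf("motif_enrichment: excluded %d background region(s) overlapping targets",
                    sum(drop)))
    background_regions <- background_regions[!drop, , drop = FALSE]
  }
  if (nrow(background_regions) == 0)
    stopf("motif_enrichment: empty background after target exclusion")
  motifs <- sort(unique(hits$motif_id), method = "radix")
  nt <- nrow(target_regions); nb <- nrow(background_regions)
  if (length(motifs) == 0)
    return(data.frame(motif_id = character(), targets_with_hit = integer(),
                      targets_total = integer(), background_with_hit = integer(),
                      background_total = integer(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(motifs, function(m) {
    h <- hits[hits$motif_id == m, , drop = FALSE]
    kt <- sum(hits_per_region(target_regions, h) > 0)
    kb <- sum(hits_per_region(background_regions, h) > 0)
    data.frame(motif_id = m, targets_with_hit = kt, targets_total = nt,
               background_with_hit = kb, background_total = nb,
               p_value = hypergeom_upper_tail(nt + nb, kt + kb, nt, kt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Select key TFs: enriched motif and differentially expressed gene
#'
#' A transcription factor is selected when its motif is significantly
#' enriched (`p < alpha`) and its own gene belongs to the core DEG set.
#' Motifs without a gene mapping are excluded with a warning.
#'
#' @param enrichment Data frame from [motif_enrichment()].
#' @param core_degs Character vector of core DEG ids.
#' @param motif_gene_map Data frame with columns `motif_id`, `gene_id`.
#' @param alpha Enrichment p-value cutoff (default 0.01).
#' @return Data frame of selected TFs: `motif_id`, `gene_id`, `p_value`,
#'   `q_value`.
#' @export
select_key_tfs <- function(enrichment, core_degs, motif_gene_map,
                           alpha = 0.01) {
  gid <- motif_gene_map$gene_id[match(enrichment$motif_id,
                                      motif_gene_map$motif_id)]
  unmapped <- is.na(gid)
  if (any(unmapped))
    warnf("select_key_tfs: no gene mapping for motif(s): %s",
          paste(enrichment$motif_id[unmapped], collapse = ", "))
  keep <- !unmapped & enrichment$p_value < alpha & gid %in% core_degs
  out <- data.frame(motif_id = enrichment$motif_id[keep],
                    gene_id = gid[keep],
                    p_value = enrichment$p_value[keep],
                    q_value = enrichment$q_value[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assign TF target genes from motif hits in gained regions
#'
#' An edge TF -> gene is created for every motif hit fully contained in a
#' gained region: the gene is the one whose TSS is nearest to the hit
#' midpoint (ties to the lexicographically smallest `gene_id`; genes whose
#' TSS distance is within 1 bp of the minimum each receive an edge). Zone is
#' `"proximal"` when the TSS distance is below `window`, else `"distal"`.
#'
#' @param hits Hit data frame from [scan_pwm()].
#' @param gained_regions Interval data frame of gained regions.
#' @param genes Gene models.
#' @param window Promoter cutoff in bp (default 2000).
#' @return Edge data frame: `tf_id`, `gene_id`, `chrom`, `region_start`,
#'   `region_end`, `hit_start`, `hit_end`, `strand`, `tss_distance`
#'   (absolute bp), `zone`.
#' @export
assign_targets <- function(hits, gained_regions, genes, window = 2000) {
  empty <- data.frame(tf_id = character(), gene_id = character(),
                      chrom = character(), region_start = numeric(),
                      region_end = numeric(), hit_start = numeric(),
                      hit_end = numeric(), strand = character(),
                      tss_distance = numeric(), zone = character(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0 || nrow(gained_regions) == 0) return(empty)
  if (nrow(genes) == 0) stopf("assign_targets: empty gene list")
  g <- genes[order(genes$gene_id), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    reg <- gained_regions[gained_regions$chrom == hits$chrom[i] &
                          gained_regions$start <= hits$start[i] &
                          gained_regions$end >= hits$end[i], , drop = FALSE]
    if (nrow(reg) == 0) next
    reg <- reg[1, ]
    gc <- g[g$chrom == hits$chrom[i], , drop = FALSE]
    if (nrow(gc) == 0) next
    mid <- floor((hits$start[i] + hits$end[i]) / 2)
    d <- abs(gc$tss - mid)
    near <- which(d <= min(d) + 1)
    for (j in near) {
      rows[[length(rows) + 1]] <- data.frame(
        tf_id = hits$motif_id[i], gene_id = gc$gene_id[j],
        chrom = hits$chrom[i], region_start = reg$start,
        region_end = reg$end, hit_start = hits$start[i],
        hit_end = hits$end[i], strand = hits$strand[i],
        tss_distance = d[j],
        zone = if (d[j] < window) "proximal" else "distal",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  # containment audit: every edge's hit must lie inside its evidence region
  stopifnot(all(out$hit_start >= out$region_start),
            all(out$hit_end <= out$region_end))
  rownames(out) <- NULL
  out
}

#' Common targets of two TFs
#'
#' Intersects the target gene sets of two TFs (set semantics: duplicate
#' edges are collapsed), optionally restricted to a gene set such as the
#' core DEGs, and reports the fraction of the first TF's targets shared.
#'
#' @param edges_tf_a,edges_tf_b Edge data frames from [assign_targets()].
#' @param restrict_to Optional character vector restricting both target
#'   sets.
#' @return List with `targets_a`, `targets_b`, `common`, `n_a`, `n_b`,
#'   `n_common`, `fraction_of_a` (NA with a message when `n_a` is 0).
#' @export
common_targets <- function(edges_tf_a, edges_tf_b, restrict_to = NULL) {
  a <- unique(edges_tf_a$gene_id)
  b <- unique(edges_tf_b$gene_id)
  if (!is.null(restrict_to)) {
    a <- intersect(a, restrict_to)
    b <- intersect(b, restrict_to)
  }
  common <- sort(intersect(a, b), method = "radix")
  fraction <- if (length(a) == 0) {
    message("common_targets: first TF has no targets; fraction undefined")
    NA_real_
  } else length(common) / length(a)
  list(targets_a = sort(a, method = "radix"),
       targets_b = sort(b, method = "radix"), common = common,
       n_a = length(a), n_b = length(b), n_common = length(common),
       fraction_of_a = fraction)
}

min_pair_distance <- function(regions, hits_a, hits_b) {
  d <- rep(NA_real_, nrow(regions))
  if (nrow(regions) == 0) return(d)
  mid <- function(h) floor((h$start + h$end) / 2)
  for (i in seq_len(nrow(regions))) {
    ina <- hits_a$chrom == regions$chrom[i] &
      hits_a$start >= regions$start[i] & hits_a$end <= regions$end[i]
    inb <- hits_b$chrom == regions$chrom[i] &
      hits_b$start >= regions$start[i] & hits_b$end <= regions$end[i]
    if (!any(ina) || !any(inb)) next
    ma <- mid(hits_a[ina, , drop = FALSE])
    mb <- mid(hits_b[inb, , drop = FALSE])
    d[i] <- min(abs(outer(ma, mb, "-")))
  }
  d
}

#' Motif-pair distance statistic
#'
#' For every region containing at least one hit of each motif, the distance
#' is the minimum over hit pairs of the absolute midpoint distance. The
#' target distance distribution (e.g. promoters of common target genes) is
#' compared to the background distribution (e.g. common peaks at promoters
#' genome-wide) with a two-sided Wilcoxon rank-sum test; regions lacking
#' either motif are skipped and counted.
#'
#' @param hits_a,hits_b Hit data frames for the two motifs.
#' @param target_regions,background_regions Interval data frames.
#' @return List with `target_distances`, `background_distances`, medians and
#'   IQRs per side, skipped-region counts and `test` (a [test_result()]).
#' @export
motif_pair_distance <- function(hits_a, hits_b, target_regions,
                                background_regions) {
  dt <- min_pair_distance(target_regions, hits_a, hits_b)
  db <- min_pair_distance(background_regions, hits_a, hits_b)
  td <- dt[!is.na(dt)]; bd <- db[!is.na(db)]
  if (length(td) == 0 || length(bd) == 0)
    stopf("motif_pair_distance: no contributing region on one side")
  list(target_distances = td, background_distances = bd,
       median_target = stats::median(td), median_background = stats::median(bd),
       iqr_target = unname(diff(stats::quantile(td, c(0.25, 0.75)))),
       iqr_background = unname(diff(stats::quantile(bd, c(0.25, 0.75)))),
       n_skipped_target = sum(is.na(dt)),
       n_skipped_background = sum(is.na(db)),
       test = wilcoxon_rank_sum(td, bd, mode = "auto"))
}
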