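# Deterministic synthetic-data generator with planted ground truth. It
# emulates the statistical structure of a one-control / N-case epigenome
# panel: recurrent case-specific peak gains and control-specific losses,
# long-range lost loops versus short-range gained promoter-hub loops,
# negative-binomial counts with a planted core DEG set, and promoter
# sequences carrying planted TF motif pairs at fixed spacing. Every
# generator seeds its own RNG substream from `config$seed`, so outputs are
# byte-identical for a given (config, seed) whether stages run standalone or
# composed.

#' Synthetic study configuration
#'
#' Returns the full parameter set of the synthetic generator. Defaults
#' encode the emulated study design: 1 control vs 15 case lines for region
#' calling (gains recurrent in >= 10), 1 control vs 14 case lines for loops
#' (gains recurrent in >= 8), lost/gained loop span medians 254 kb / 114 kb,
#' 85% of gained loops promoter-promoter, core DEGs at |log2FC| = 2 with NB
#' dispersion 0.05 and 3 replicates per line, motif pairs spaced 56 bp in
#' target promoters vs median 124 bp in background promoters, and a
#' 47-target TF sharing 33 targets with its partner TF (70.2%).
#'
#' @param seed Integer seed (< 2^30); all randomness derives from it.
#' @param preset `"default"` (2 x 5 Mb desk scale), `"tiny"` (2 x 2 Mb) or
#'   `"stress"` (larger counts).
#' @param ... Named overrides of any config field.
#' @return Object of class `synth_config` (a named list).
#' @export
synth_config <- function(seed = 1, preset = c("default", "tiny", "stress"),
                         ...) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = as.integer(seed),
    preset = preset,
    chrom_sizes = c(chr1 = 5e6, chr2 = 5e6),
    gc_content = 0.41,
    n_genes = 400,
    # regions
    n_cases_regions = 15,
    n_shared_peaks = 400,
    n_lost_regions = 40,
    n_gained_regions = 60,
    gained_region_min_cases = 10,
    peak_width = c(600, 1500),
    peak_jitter_bp = 0,
    dropout_prob = 0,
    # loops
    n_cases_loops = 14,
    n_shared_loops = 300,
    n_lost_loops = 50,
    n_gained_loops = 80,
    gained_loop_min_cases = 8,
    lost_span_median = 254000,
    gained_span_median = 114000,
    shared_span_median = 150000,
    span_sdlog = 0.35,
    gained_pp_fraction = 0.85,
    lost_pp_fraction = 0.134,
    shared_pp_fraction = 0.2,
    anchor_width = 1000,
    n_junk_loops = 25,
    # expression
    n_genes_counts = 2000,
    n_core_degs = 100,
    n_sporadic_degs = 30,
    deg_log2fc = 2,
    nb_dispersion = 0.05,
    n_replicates = 3,
    base_mean_log_mean = log(200),
    base_mean_log_sd = 1,
    # motifs
    motif_a_consensus = "GGCGCTAGACGT",
    motif_b_consensus = "TTCAGCAACTGA",
    motif_consensus_prob = 0.91,
    n_targets_tf_a = 47,
    n_common_targets = 33,
    n_targets_tf_b_only = 15,
    n_background_motif_regions = 100,
    target_spacing = 56,
    background_spacing_median = 124,
    background_spacing_spread = 60
  )
  if (preset == "tiny") {
    cfg[c("chrom_sizes", "n_genes", "n_shared_peaks", "n_lost_regions",
          "n_gained_regions", "n_shared_loops", "n_lost_loops",
          "n_gained_loops", "n_genes_counts", "n_core_degs",
          "n_sporadic_degs", "n_targets_tf_a", "n_common_targets",
          "n_targets_tf_b_only", "n_background_motif_regions",
          "n_junk_loops")] <-
      list(c(chr1 = 2e6, chr2 = 2e6), 160, 120, 12, 18, 60, 15, 24,
           600, 40, 10, 12, 8, 4, 40, 10)
  } else if (preset == "stress") {
    cfg[c("n_shared_peaks", "n_shared_loops")] <- list(1000, 600)
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stopf("synth_config: unknown field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$seed < 0 || cfg$seed >= 2^30) stopf("synth_config: seed must be in [0, 2^30)")
  if (cfg$gained_region_min_cases > cfg$n_cases_regions ||
      cfg$gained_loop_min_cases > cfg$n_cases_loops)
    stopf("synth_config: k exceeds the number of case samples")
  if (cfg$n_common_targets > cfg$n_targets_tf_a)
    stopf("synth_config: common targets exceed TF-A targets")
  if (cfg$gained_pp_fraction < 0 || cfg$gained_pp_fraction > 1 ||
      cfg$dropout_prob < 0 || cfg$dropout_prob > 1)
    stopf("synth_config: fractions must lie in [0, 1]")
  structure(cfg, class = c("synth_config", "list"))
}

# span sample whose sample median equals `med` exactly: symmetric
# multiplicative pairs around med plus one or two exact-median entries.
spans_exact_median <- function(n, med, sdlog) {
  if (n == 0) return(numeric(0))
  n_exact <- if (n %% 2 == 1) 1 else 2
  n_pairs <- (n - n_exact) / 2
  f <- exp(abs(stats::rnorm(n_pairs, 0, sdlog))) + 1e-6
  spans <- c(rep(med, n_exact), round(med * f), round(med / f))
  sample(spans)
}

#' Generate a toy genome: gene models plus random sequence
#'
#' Genes are placed on a jittered grid (no TSS collisions), on both strands,
#' with lengths 2-20 kb. Deterministic for a given config. Gene models are
#' drawn before the sequence, so `include_sequence = FALSE` (for stages that
#' only need coordinates) yields exactly the same gene models.
#'
#' @param config A [synth_config()].
#' @param include_sequence Generate the random chromosome sequences
#'   (default `TRUE`).
#' @return List with `sequences` (named character vector; empty strings when
#'   not generated) and `genes` (gene model data frame with `tss`).
#' @export
generate_genome <- function(config, include_sequence = TRUE) {
  set.seed(config$seed)
  n_genes <- config$n_genes
  genes <- NULL
  if (n_genes > 0) {
    alloc <- round(n_genes * config$chrom_sizes / sum(config$chrom_sizes))
    alloc[1] <- n_genes - sum(alloc[-1])
    rows <- list()
    for (ci in seq_along(config$chrom_sizes)) {
      n <- alloc[ci]
      if (n == 0) next
      L <- config$chrom_sizes[ci]
      margin <- 50000
      spacing <- floor((L - 2 * margin) / n)
      if (spacing < 5000)
        stopf("generate_genome: genes do not fit chromosome %s",
              names(config$chrom_sizes)[ci])
      tss <- margin + spacing * (seq_len(n) - 1) +
        sample.int(max(1, floor(spacing / 4)), n, replace = TRUE)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      len <- sample(2000:20000, n, replace = TRUE)
      start <- ifelse(strand == "+", tss, pmax(0, tss + 1 - len))
      end <- ifelse(strand == "+", pmin(L, tss + len), tss + 1)
      rows[[ci]] <- data.frame(chrom = names(config$chrom_sizes)[ci],
                               start = start, end = end, strand = strand,
                               tss = tss, stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, rows)
    genes <- genes[order(chrom_rank(genes$chrom), genes$tss), , drop = FALSE]
    genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
    genes <- genes[, c("gene_id", "chrom", "start", "end", "strand", "tss")]
    rownames(genes) <- NULL
  } else {
    genes <- data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        strand = character(), tss = numeric(),
                        stringsAsFactors = FALSE)
  }
  gc <- config$gc_content
  base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sequences <- if (include_sequence) {
    vapply(config$chrom_sizes, function(L) {
      paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                    prob = base_prob), collapse = "")
    }, "")
  } else {
    stats::setNames(rep("", length(config$chrom_sizes)),
                    names(config$chrom_sizes))
  }
  names(sequences) <- names(config$chrom_sizes)
  list(sequences = sequences, genes = genes)
}

# Distal slot grid: candidate centers >= 4 kb from every TSS, spaced 6 kb.
distal_slots <- function(config, genes) {
  out <- list()
  for (ch in names(config$chrom_sizes)) {
    L <- config$chrom_sizes[[ch]]
    pos <- seq(20000, L - 20000, by = 6000)
    tss <- genes$tss[genes$chrom == ch]
    if (length(tss) > 0) {
      near <- vapply(pos, function(p) min(abs(tss - p)) < 4000, TRUE)
      pos <- pos[!near]
    }
    out[[ch]] <- pos
  }
  out
}

take_slots <- function(slots, chrom, n) {
  if (length(slots[[chrom]]) < n)
    stopf("synthetic generator: planted regions exceed genome space on %s", chrom)
  idx <- sample(seq_along(slots[[chrom]]), n)
  taken <- slots[[chrom]][idx]
  slots[[chrom]] <- slots[[chrom]][-idx]
  list(slots = slots, centers = taken)
}

#' Generate per-sample peak sets with planted differential regions
#'
#' Shared peaks appear in every sample; planted lost peaks only in the
#' control; planted gained peaks in `k` randomly chosen cases (k drawn
#' uniformly between `gained_region_min_cases` and the panel size per
#' region) and never in the control. When `target_genes` /
#' `background_genes` are supplied, additional gained (resp. shared) peaks
#' of width 1000 are planted centred on those genes' TSSs, for downstream
#' motif analyses. Optional per-occurrence jitter and case dropout emulate
#' noise (defaults off).
#'
#' @param config A [synth_config()].
#' @param genome Output of [generate_genome()].
#' @param target_genes Optional data frame `gene_id`, `role` (one of
#'   `"common"`, `"a_only"`, `"b_only"`) for promoter gained peaks.
#' @param background_genes Optional character vector of gene ids receiving
#'   promoter shared peaks (motif background).
#' @return List with `peak_sets` (named list of interval data frames),
#'   `truth` (region table), `samples`, `control_sample`.
#' @export
generate_peak_sets <- function(config, genome, target_genes = NULL,
                               background_genes = NULL) {
  set.seed(config$seed + 101L)
  n_cases <- config$n_cases_regions
  samples <- c("control", sprintf("case%02d", seq_len(n_cases)))
  chroms <- names(config$chrom_sizes)
  slots <- distal_slots(config, genome$genes)

  rand_regions <- function(n, label) {
    if (n == 0) return(NULL)
    alloc <- round(n * config$chrom_sizes / sum(config$chrom_sizes))
    alloc[1] <- n - sum(alloc[-1])
    rows <- list()
    for (ci in seq_along(chroms)) {
      if (alloc[ci] == 0) next
      tk <- take_slots(slots, chroms[ci], alloc[ci])
      slots <<- tk$slots
      w <- sample(config$peak_width[1]:config$peak_width[2], alloc[ci],
                  replace = TRUE)
      rows[[ci]] <- data.frame(chrom = chroms[ci],
                               start = tk$centers - floor(w / 2),
                               end = tk$centers - floor(w / 2) + w,
                               label = label, target_gene = NA_character_,
                               role = NA_character_, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  promoter_regions <- function(gene_ids, label, roles) {
    if (length(gene_ids) == 0) return(NULL)
    g <- genome$genes[match(gene_ids, genome$genes$gene_id), , drop = FALSE]
    if (anyNA(g$gene_id)) stopf("generate_peak_sets: unknown target gene id")
    data.frame(chrom = g$chrom, start = g$tss - 500, end = g$tss + 500,
               label = label, target_gene = g$gene_id, role = roles,
               stringsAsFactors = FALSE)
  }

  regions <- rbind(
    rand_regions(config$n_shared_peaks, "shared"),
    rand_regions(config$n_lost_regions, "lost"),
    rand_regions(config$n_gained_regions, "gained"),
    if (!is.null(target_genes))
      promoter_regions(target_genes$gene_id, "gained", target_genes$role),
    if (!is.null(background_genes))
      promoter_regions(background_genes, "shared", "background"))
  regions$region_id <- sprintf("R%05d", seq_len(nrow(regions)))
  regions$n_case_samples <- NA_integer_

  occupancy <- matrix(FALSE, nrow(regions), length(samples),
                      dimnames = list(regions$region_id, samples))
  for (i in seq_len(nrow(regions))) {
    lab <- regions$label[i]
    if (lab == "shared") {
      occupancy[i, ] <- TRUE
      regions$n_case_samples[i] <- n_cases
    } else if (lab == "lost") {
      occupancy[i, "control"] <- TRUE
      regions$n_case_samples[i] <- 0L
    } else {
      k <- sample(config$gained_region_min_cases:n_cases, 1)
      occupancy[i, 1 + sample.int(n_cases, k)] <- TRUE
      regions$n_case_samples[i] <- k
    }
  }
  # noise: dropout of case occurrences, then jitter per occurrence
  if (config$dropout_prob > 0) {
    case_cols <- samples != "control"
    occ <- occupancy[, case_cols]
    drop <- stats::runif(length(occ)) < config$dropout_prob
    occupancy[, case_cols] <- occ & !drop
  }
  peak_sets <- lapply(samples, function(s) {
    idx <- which(occupancy[, s])
    d <- regions[idx, c("chrom", "start", "end"), drop = FALSE]
    if (config$peak_jitter_bp > 0 && nrow(d) > 0) {
      j <- config$peak_jitter_bp
      d$start <- pmax(0, d$start + sample(-j:j, nrow(d), replace = TRUE))
      d$end <- pmax(d$start + 50, d$end + sample(-j:j, nrow(d), replace = TRUE))
    }
    gi <- genomic_intervals(d$chrom, d$start, d$end,
                            name = regions$region_id[idx])
    gi[interval_order(gi), , drop = FALSE]
  })
  names(peak_sets) <- samples
  truth <- regions[, c("region_id", "chrom", "start", "end", "label",
                       "n_case_samples", "target_gene", "role")]
  rownames(truth) <- NULL
  list(peak_sets = peak_sets, truth = truth, samples = samples,
       control_sample = "control")
}

# pick an unused gene whose TSS is nearest `pos` on `chrom`; returns index
nearest_free_gene <- function(genes, used, chrom, pos) {
  cand <- which(genes$chrom == chrom & !used)
  if (length(cand) == 0) stopf("synthetic generator: ran out of genes for loop anchors")
  cand[which.min(abs(genes$tss[cand] - pos))]
}

# reserve a distal anchor centre near `pos`, >= 4 kb from TSSs and >= 2 kb
# from existing anchor centres; nudges in 2 kb steps, errors when the
# collision budget is exhausted.
place_enhancer_anchor <- function(pos, chrom, chrom_size, tss, centers) {
  for (off in c(0, 2000 * rep(1:10, each = 2) * c(1, -1))) {
    p <- pos + off
    if (p < 10000 || p > chrom_size - 10000) next
    if (length(tss) > 0 && min(abs(tss - p)) < 4000) next
    if (length(centers) > 0 && min(abs(centers - p)) < 2000) next
    return(p)
  }
  stopf("synthetic generator: anchor placement collision budget exhausted")
}

#' Generate per-sample loop sets with planted differential loops
#'
#' Plants lost loops (control count >= 2, absent in every case) with
#' long-range spans, gained loops (absent in control, count >= 2 in >= k of
#' n cases) with short-range spans, the configured fraction of gained loops
#' promoter-promoter and organized into multi-anchor hubs (2-4 loops
#' sharing a promoter anchor), shared loops present everywhere, and
#' per-sample junk calls that fail the significance filters (count 1, span
#' < 5 kb, or high FDR). Promoter anchors are 1 kb intervals overlapping a
#' gene's promoter window; enhancer anchors lie >= 4 kb from every TSS.
#'
#' @param config A [synth_config()].
#' @param genome Output of [generate_genome()].
#' @return List with `loop_sets` (named list of loop data frames in
#'   [read_bedpe()] layout), `truth` (loop table with label, class, span,
#'   hub id), `samples`, `control_sample`.
#' @export
generate_loop_sets <- function(config, genome) {
  set.seed(config$seed + 202L)
  n_cases <- config$n_cases_loops
  samples <- c("control", sprintf("case%02d", seq_len(n_cases)))
  genes <- genome$genes
  used_gene <- rep(FALSE, nrow(genes))
  anchor_centers <- lapply(names(config$chrom_sizes), function(ch) numeric(0))
  names(anchor_centers) <- names(config$chrom_sizes)
  hw <- floor(config$anchor_width / 2)
  loops <- list()

  add_loop <- function(chrom, c1, c2, label, class, hub) {
    loops[[length(loops) + 1]] <<- data.frame(
      chrom = chrom, c1 = min(c1, c2), c2 = max(c1, c2), label = label,
      class = class, hub = hub, stringsAsFactors = FALSE)
  }
  pick_center_gene <- function(chrom, span) {
    L <- config$chrom_sizes[[chrom]]
    cand <- which(genes$chrom == chrom & !used_gene &
                  genes$tss > span / 2 & genes$tss < L - span / 2)
    if (length(cand) == 0)
      cand <- which(genes$chrom == chrom & !used_gene)
    if (length(cand) == 0) stopf("synthetic generator: ran out of genes for loop anchors")
    sample(cand, 1)
  }
  # promoter partner: nearest free gene to pos, anchor centre corrected
  # toward the exact target within the promoter-overlap slack (+/- 2 kb)
  partner_center <- function(chrom, pos) {
    gi <- nearest_free_gene(genes, used_gene, chrom, pos)
    used_gene[gi] <<- TRUE
    tss <- genes$tss[gi]
    tss + max(-2000, min(2000, pos - tss))
  }

  plant_family <- function(n, label, pp_fraction, span_median, hubbed) {
    if (n == 0) return(invisible())
    n_pp <- round(pp_fraction * n)
    spans <- spans_exact_median(n, span_median, config$span_sdlog)
    # exact placements (non-PP) get the spans closest to the median last;
    # assignment order: PP first
    li <- 0
    while (li < n_pp) {
      h <- if (hubbed) min(n_pp - li, sample(2:4, 1)) else 1
      chrom <- sample(names(config$chrom_sizes), 1)
      ci <- pick_center_gene(chrom, max(spans[li + seq_len(h)]))
      used_gene[ci] <<- TRUE
      t0 <- genes$tss[ci]
      hub_id <- if (hubbed && h >= 2) sprintf("%s_hub%03d", label, li + 1)
                else NA_character_
      for (m in seq_len(h)) {
        li <- li + 1
        s <- spans[li]
        dir <- sample(c(-1, 1), 1)
        target <- t0 + dir * s
        if (target < 20000 || target > config$chrom_sizes[[chrom]] - 20000)
          target <- t0 - dir * s
        pc <- partner_center(chrom, target)
        add_loop(chrom, t0, pc, label, "P-P", hub_id)
      }
    }
    n_rest <- n - n_pp
    if (n_rest == 0) return(invisible())
    rest_class <- if (label == "lost") {
      c(rep("P-E", ceiling(n_rest / 2)), rep("E-E", floor(n_rest / 2)))
    } else if (label == "gained") rep("P-E", n_rest) else rep("E-E", n_rest)
    for (m in seq_len(n_rest)) {
      li <- li + 1
      s <- spans[li]
      chrom <- sample(names(config$chrom_sizes), 1)
      L <- config$chrom_sizes[[chrom]]
      tssv <- genes$tss[genes$chrom == chrom]
      if (rest_class[m] == "P-E") {
        ci <- pick_center_gene(chrom, s)
        used_gene[ci] <<- TRUE
        a <- genes$tss[ci]
      } else {
        a0 <- round(stats::runif(1, 20000 + s / 2, L - 20000 - s / 2))
        a <- place_enhancer_anchor(a0, chrom, L, tssv, anchor_centers[[chrom]])
        anchor_centers[[chrom]] <<- c(anchor_centers[[chrom]], a)
      }
      dir <- sample(c(-1, 1), 1)
      target <- a + dir * s
      if (target < 20000 || target > L - 20000) target <- a - dir * s
      b <- place_enhancer_anchor(target, chrom, L, tssv,
                                 anchor_centers[[chrom]])
      anchor_centers[[chrom]] <<- c(anchor_centers[[chrom]], b)
      add_loop(chrom, a, b, label, rest_class[m], NA_character_)
    }
    invisible()
  }

  plant_family(config$n_gained_loops, "gained", config$gained_pp_fraction,
               config$gained_span_median, hubbed = TRUE)
  plant_family(config$n_lost_loops, "lost", config$lost_pp_fraction,
               config$lost_span_median, hubbed = FALSE)
  plant_family(config$n_shared_loops, "shared", config$shared_pp_fraction,
               config$shared_span_median, hubbed = FALSE)

  ldf <- do.call(rbind, loops)
  ldf$start1 <- ldf$c1 - hw; ldf$end1 <- ldf$c1 - hw + config$anchor_width
  ldf$start2 <- ldf$c2 - hw; ldf$end2 <- ldf$c2 - hw + config$anchor_width
  ldf$span <- loop_span(ldf)
  ldf$loop_id <- sprintf("T%05d", seq_len(nrow(ldf)))

  counts <- matrix(0, nrow(ldf), length(samples),
                   dimnames = list(ldf$loop_id, samples))
  ldf$n_case_samples <- NA_integer_
  for (i in seq_len(nrow(ldf))) {
    if (ldf$label[i] == "lost") {
      counts[i, "control"] <- sample(2:6, 1)
      ldf$n_case_samples[i] <- 0L
    } else if (ldf$label[i] == "gained") {
      k <- sample(config$gained_loop_min_cases:n_cases, 1)
      counts[i, 1 + sample.int(n_cases, k)] <- sample(2:6, k, replace = TRUE)
      ldf$n_case_samples[i] <- k
    } else {
      counts[i, ] <- sample(2:6, length(samples), replace = TRUE)
      ldf$n_case_samples[i] <- n_cases
    }
  }

  junk_slots <- distal_slots(config, genes)
  loop_sets <- lapply(samples, function(s) {
    idx <- which(counts[, s] > 0)
    good <- data.frame(sample_id = s, chrom = ldf$chrom[idx],
                       start1 = ldf$start1[idx], end1 = ldf$end1[idx],
                       start2 = ldf$start2[idx], end2 = ldf$end2[idx],
                       count = counts[idx, s], fdr = 0.001,
                       stringsAsFactors = FALSE)
    nj <- config$n_junk_loops
    if (nj > 0) {
      ch <- sample(names(config$chrom_sizes), 1)
      tk <- take_slots(junk_slots, ch, 2 * nj)
      junk_slots <<- tk$slots
      a <- tk$centers[seq_len(nj)]
      fail_mode <- sample(c("count", "span", "fdr"), nj, replace = TRUE)
      b <- ifelse(fail_mode == "span", a + 3000,
                  tk$centers[nj + seq_len(nj)])
      junk <- data.frame(sample_id = s, chrom = ch,
                         start1 = pmin(a, b) - hw,
                         end1 = pmin(a, b) - hw + config$anchor_width,
                         start2 = pmax(a, b) - hw,
                         end2 = pmax(a, b) - hw + config$anchor_width,
                         count = ifelse(fail_mode == "count", 1, 3),
                         fdr = ifelse(fail_mode == "fdr", 0.5, 0.001),
                         stringsAsFactors = FALSE)
      good <- rbind(good, junk)
    }
    canonical_loops(good)
  })
  names(loop_sets) <- samples

  truth <- canonical_loops(
    ldf[, c("loop_id", "chrom", "start1", "end1", "start2", "end2", "label",
            "class", "span", "hub", "n_case_samples")])
  list(loop_sets = loop_sets, truth = truth, samples = samples,
       control_sample = "control")
}

#' Generate negative-binomial counts with a planted core DEG set
#'
#' Counts follow NB(mu, dispersion) per gene and sample. Core DEGs are
#' shifted by `+/- deg_log2fc` in every case line; sporadic DEGs are shifted
#' in only a few lines and must not enter the core intersection.
#'
#' @param config A [synth_config()].
#' @param gene_ids Optional gene id vector (default `n_genes_counts`
#'   synthetic ids).
#' @param forced_core Optional gene ids guaranteed to be core DEGs (must fit
#'   within `n_core_degs`).
#' @return List with `counts` (matrix genes x samples), `sample_groups`
#'   (data frame `sample_id`, `group`), `truth` (core/sporadic ids with
#'   directions), `control_group`, `case_groups`.
#' @export
generate_counts <- function(config, gene_ids = NULL, forced_core = NULL) {
  set.seed(config$seed + 303L)
  gene_ids <- gene_ids %||% sprintf("gene%05d", seq_len(config$n_genes_counts))
  n <- length(gene_ids)
  if (config$n_core_degs > n)
    stopf("generate_counts: more core DEGs than genes")
  forced_core <- unique(forced_core)
  if (length(forced_core) > config$n_core_degs)
    stopf("generate_counts: forced core DEGs exceed n_core_degs")
  pool <- setdiff(gene_ids, forced_core)
  core <- c(forced_core,
            sample(pool, config$n_core_degs - length(forced_core)))
  pool <- setdiff(pool, core)
  n_sporadic <- min(config$n_sporadic_degs, length(pool))
  sporadic <- if (n_sporadic > 0) sample(pool, n_sporadic) else character(0)
  n_lines <- config$n_cases_regions
  reps <- config$n_replicates
  groups <- c("control", sprintf("case%02d", seq_len(n_lines)))
  sample_ids <- unlist(lapply(groups, function(g) paste0(g, "_r", seq_len(reps))))
  sample_groups <- data.frame(sample_id = sample_ids,
                              group = rep(groups, each = reps),
                              stringsAsFactors = FALSE)
  mu <- stats::rlnorm(n, config$base_mean_log_mean, config$base_mean_log_sd)
  direction <- stats::setNames(rep(0, n), gene_ids)
  direction[core] <- sample(c(-1, 1), length(core), replace = TRUE)
  direction[sporadic] <- sample(c(-1, 1), length(sporadic), replace = TRUE)
  sporadic_lines <- lapply(sporadic, function(g)
    sort(sample.int(n_lines, sample(2:5, 1))))
  names(sporadic_lines) <- sporadic
  spor_by_line <- lapply(seq_len(n_lines), function(l)
    sporadic[vapply(sporadic, function(g) l %in% sporadic_lines[[g]], TRUE)])
  counts <- matrix(0, n, length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    grp <- sample_groups$group[j]
    lfc <- rep(0, n)
    if (grp != "control") {
      line <- as.integer(sub("case", "", grp))
      active <- gene_ids %in% core | gene_ids %in% spor_by_line[[line]]
      lfc <- config$deg_log2fc * unname(direction) * active
    }
    counts[, j] <- stats::rnbinom(n, mu = mu * 2^lfc,
                                  size = 1 / config$nb_dispersion)
  }
  list(counts = counts, sample_groups = sample_groups,
       truth = list(core_degs = sort(core, method = "radix"),
                    sporadic_degs = sort(sporadic, method = "radix"),
                    direction = direction[direction != 0]),
       control_group = "control", case_groups = groups[-1])
}

# remove every occurrence of a set of words (and their reverse complements)
# from the sequences by flipping one base per occurrence; iterates until no
# occurrence remains so planted instances are provably exclusive.
revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x)
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""), ""))
}

scrub_words <- function(sequences, words) {
  words <- unique(c(words, unname(revcomp(words))))
  for (iter in 1:20) {
    dirty <- FALSE
    for (ch in names(sequences)) {
      for (w in words) {
        repeat {
          p <- regexpr(w, sequences[[ch]], fixed = TRUE)
          if (p < 0) break
          dirty <- TRUE
          mid <- p + floor(nchar(w) / 2)
          cur <- substr(sequences[[ch]], mid, mid)
          substr(sequences[[ch]], mid, mid) <-
            chartr("ACGT", "CGTA", cur)
        }
      }
    }
    if (!dirty) return(sequences)
  }
  stopf("scrub_words: could not clear motif occurrences")
}

#' Plant motif pairs into promoter peak sequences
#'
#' Writes exact consensus instances of two motifs (TF-A, TF-B) into the
#' genome: both motifs spaced exactly `target_spacing` bp (midpoint to
#' midpoint) in the promoter gained peaks of common target genes, single
#' motifs in A-only / B-only target peaks, and both motifs at spacings with
#' exact sample median `background_spacing_median` in the background shared
#' promoter peaks. All chance occurrences of either consensus (both
#' strands) are first scrubbed from the genome, so planted hits are the
#' only max-score matches. PFMs matching the planted consensi are returned
#' (consensus base probability `motif_consensus_prob`).
#'
#' @param config A [synth_config()].
#' @param sequences Named character vector of chromosome sequences.
#' @param peak_truth Region truth from [generate_peak_sets()] (roles
#'   `common`, `a_only`, `b_only`, `background`).
#' @return List with `sequences` (edited), `pwms` (list of 2), `hits`
#'   (planted hit table), `spacings` (per-region planted pair spacing).
#' @export
plant_motifs <- function(config, sequences, peak_truth) {
  set.seed(config$seed + 404L)
  ca <- config$motif_a_consensus
  cb <- config$motif_b_consensus
  w <- nchar(ca)
  if (nchar(cb) != w) stopf("plant_motifs: consensi must have equal width")
  sequences <- scrub_words(sequences, c(ca, cb))

  mk_pfm <- function(id, consensus) {
    bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
    p <- config$motif_consensus_prob
    cnt <- matrix(round(100 * (1 - p) / 3), 4, nchar(consensus))
    rownames(cnt) <- c("A", "C", "G", "T")
    for (j in seq_along(bases)) cnt[bases[j], j] <- round(100 * p)
    make_pwm(id, counts = cnt)
  }
  pwms <- list(mk_pfm("motif_a", ca), mk_pfm("motif_b", cb))
  names(pwms) <- c("motif_a", "motif_b")

  regs <- peak_truth[!is.na(peak_truth$role) &
                     peak_truth$role %in% c("common", "a_only", "b_only",
                                            "background"), , drop = FALSE]
  if (nrow(regs) == 0) stopf("plant_motifs: no motif regions in peak truth")
  n_bg <- sum(regs$role == "background")
  bg_spacings <- numeric(0)
  # symmetric integer spacings with exact sample median
  if (n_bg > 0) {
    n_exact <- if (n_bg %% 2 == 1) 1 else 2
    n_pairs <- (n_bg - n_exact) / 2
    d <- sample(seq(4, config$background_spacing_spread, by = 2), n_pairs,
                replace = TRUE)
    bg_spacings <- sample(c(rep(config$background_spacing_median, n_exact),
                            config$background_spacing_median + d,
                            config$background_spacing_median - d))
  }
  plant_at <- function(chrom, start0, word) {
    # start0 is 0-based; substr is 1-based
    substr(sequences[[chrom]], start0 + 1, start0 + nchar(word)) <<- word
  }
  hits <- list()
  spacings <- list()
  bg_i <- 0
  for (i in seq_len(nrow(regs))) {
    role <- regs$role[i]
    chrom <- regs$chrom[i]
    rs <- regs$start[i]; re <- regs$end[i]
    if (role %in% c("common", "background")) {
      sp <- if (role == "common") config$target_spacing else {
        bg_i <- bg_i + 1
        bg_spacings[bg_i]
      }
      max_off <- (re - rs) - (sp + w) - 40
      a0 <- rs + 20 + sample.int(max(1, max_off), 1)
      b0 <- a0 + sp
      plant_at(chrom, a0, ca)
      plant_at(chrom, b0, cb)
      hits[[length(hits) + 1]] <- data.frame(
        motif_id = c("motif_a", "motif_b"), chrom = chrom,
        start = c(a0, b0), end = c(a0, b0) + w, strand = "+",
        region_id = regs$region_id[i], role = role,
        stringsAsFactors = FALSE)
      spacings[[length(spacings) + 1]] <- data.frame(
        region_id = regs$region_id[i], role = role, spacing = sp,
        stringsAsFactors = FALSE)
    } else {
      word <- if (role == "a_only") ca else cb
      a0 <- rs + 20 + sample.int((re - rs) - w - 40, 1)
      plant_at(chrom, a0, word)
      hits[[length(hits) + 1]] <- data.frame(
        motif_id = if (role == "a_only") "motif_a" else "motif_b",
        chrom = chrom, start = a0, end = a0 + w, strand = "+",
        region_id = regs$region_id[i], role = role, stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hits)
  hits <- hits[order(chrom_rank(hits$chrom), hits$start, hits$motif_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  # planting audit: exact plus-strand occurrences must equal the planted
  # set, and no reverse-complement occurrence may exist, so planted hits
  # are provably the only max-score matches on either strand.
  occurrences <- function(word) {
    unlist(lapply(names(sequences), function(ch) {
      g <- gregexpr(word, sequences[[ch]], fixed = TRUE)[[1]]
      if (g[1] < 0) numeric(0) else as.numeric(g) - 1
    }))
  }
  for (m in c("motif_a", "motif_b")) {
    word <- if (m == "motif_a") ca else cb
    planted <- sort(hits$start[hits$motif_id == m])
    if (!identical(sort(occurrences(word)), as.numeric(planted)) ||
        length(occurrences(unname(revcomp(word)))) > 0)
      stopf("plant_motifs: planting audit failed for %s", m)
  }
  list(sequences = sequences, pwms = pwms, hits = hits,
       spacings = do.call(rbind, spacings))
}

#' Write / read / validate the ground-truth file
#'
#' The truth is stored as a single JSON document with top-level sections
#' `config`, `regions`, `loops`, `degs` and `motifs`.
#'
#' @param truth Truth list assembled by [generate_synthetic_study()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  validate_truth(truth)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_truth(truth)
  truth
}

#' @rdname write_truth
#' @export
validate_truth <- function(truth) {
  need <- c("config", "regions", "loops", "degs", "motifs")
  missing <- setdiff(need, names(truth))
  if (length(missing) > 0)
    stopf("truth file missing section(s): %s", paste(missing, collapse = ", "))
  if (!all(c("region_id", "chrom", "start", "end", "label") %in%
           names(truth$regions)))
    stopf("truth file: malformed regions table")
  if (!all(c("loop_id", "chrom", "start1", "end1", "start2", "end2", "label",
             "class", "span") %in% names(truth$loops)))
    stopf("truth file: malformed loops table")
  invisible(truth)
}

#' Generate the complete synthetic study
#'
#' Runs every generator in a fixed order: genome, gene-role assignment
#' (TF genes, common/A-only/B-only target genes, background genes), peak
#' sets (with promoter gained/background peaks), loop sets, counts (target
#' and TF genes forced into the core DEG set), and motif planting. With
#' `outdir` set, writes all pipeline input files (per-sample BED/BEDPE,
#' genes BED6, counts TSV, genome FASTA, PFMs, motif-gene map, sample
#' manifest) plus `truth.json`.
#'
#' @param config A [synth_config()].
#' @param outdir Optional output directory (created if needed).
#' @return List with `genome`, `peaks`, `loops`, `expression`, `motifs`,
#'   `roles`, `truth` and (when written) `paths`.
#' @export
generate_synthetic_study <- function(config = synth_config(), outdir = NULL) {
  genome <- generate_genome(config)
  set.seed(config$seed + 50L)
  need <- 2 + config$n_targets_tf_a + config$n_targets_tf_b_only +
    config$n_background_motif_regions
  if (need > nrow(genome$genes))
    stopf("generate_synthetic_study: not enough genes for roles (need %d)", need)
  perm <- sample(genome$genes$gene_id)
  i <- 0
  tk <- function(n) { out <- perm[i + seq_len(n)]; i <<- i + n; out }
  tf_genes <- tk(2)
  common <- tk(config$n_common_targets)
  a_only <- tk(config$n_targets_tf_a - config$n_common_targets)
  b_only <- tk(config$n_targets_tf_b_only)
  background <- tk(config$n_background_motif_regions)
  target_genes <- data.frame(
    gene_id = c(common, a_only, b_only),
    role = c(rep("common", length(common)), rep("a_only", length(a_only)),
             rep("b_only", length(b_only))), stringsAsFactors = FALSE)
  motif_gene_map <- data.frame(motif_id = c("motif_a", "motif_b"),
                               gene_id = tf_genes, stringsAsFactors = FALSE)

  peaks <- generate_peak_sets(config, genome, target_genes = target_genes,
                              background_genes = background)
  loops <- generate_loop_sets(config, genome)
  expression <- generate_counts(config, gene_ids = genome$genes$gene_id,
                                forced_core = c(target_genes$gene_id, tf_genes))
  motifs <- plant_motifs(config, genome$sequences, peaks$truth)
  genome$sequences <- motifs$sequences

  truth <- list(
    config = unclass(config)[c("seed", "preset", "n_cases_regions",
                               "n_cases_loops", "n_lost_regions",
                               "n_gained_regions", "n_lost_loops",
                               "n_gained_loops", "n_core_degs",
                               "gained_pp_fraction", "target_spacing",
                               "background_spacing_median")],
    regions = peaks$truth, loops = loops$truth,
    degs = expression$truth,
    motifs = list(hits = motifs$hits, spacings = motifs$spacings,
                  motif_gene_map = motif_gene_map),
    roles = list(tf_genes = tf_genes, common_targets = sort(common),
                 a_only_targets = sort(a_only), b_only_targets = sort(b_only),
                 background_genes = sort(background)))

  out <- list(genome = genome, peaks = peaks, loops = loops,
              expression = expression, motifs = motifs,
              roles = truth$roles, truth = truth,
              motif_gene_map = motif_gene_map)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(outdir = outdir)
    paths$peaks <- vapply(names(peaks$peak_sets), function(s) {
      p <- file.path(outdir, paste0("peaks_", s, ".bed"))
      write_bed(peaks$peak_sets[[s]], p)
      p
    }, "")
    paths$loops <- vapply(names(loops$loop_sets), function(s) {
      p <- file.path(outdir, paste0("loops_", s, ".bedpe"))
      write_bedpe(loops$loop_sets[[s]], p)
      p
    }, "")
    g <- genome$genes
    paths$genes <- file.path(outdir, "genes.bed")
    write_bed(genomic_intervals(g$chrom, g$start, g$end, name = g$gene_id,
                                score = 0, strand = g$strand), paths$genes)
    paths$counts <- file.path(outdir, "counts.tsv")
    write_counts(expression$counts, paths$counts)
    paths$fasta <- file.path(outdir, "genome.fa")
    write_fasta(genome$sequences, paths$fasta)
    paths$pfm <- file.path(outdir, "motifs.pfm")
    write_pfm(motifs$pwms, paths$pfm)
    paths$motif_gene_map <- file.path(outdir, "motif_gene_map.tsv")
    utils::write.table(motif_gene_map, paths$motif_gene_map, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths$truth <- file.path(outdir, "truth.json")
    write_truth(truth, paths$truth)
    out$paths <- paths
  }
  out
}
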