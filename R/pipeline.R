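# End-to-end orchestration: a single validated configuration drives the
# region, expression, loop and regulatory-network stages over files on disk
# (or over a freshly generated synthetic study), emits all stage outputs as
# plain-text files, and writes a machine-readable JSON report whose bytes
# are reproducible for a given (inputs, seed).

#' Pipeline configuration
#'
#' All thresholds of the analysis in one place. Input files may be given
#' explicitly (manifests) or generated by attaching a [synth_config()] as
#' `synth`.
#'
#' @param outdir Output directory.
#' @param synth Optional [synth_config()]; when set, inputs are generated
#'   under `outdir/inputs`.
#' @param peak_files,loop_files Named character vectors (sample id -> path).
#' @param genes_file,counts_file,fasta_file,pfm_file,motif_gene_map_file,gmt_file
#'   Paths to the remaining inputs (BED6 gene models, counts TSV, FASTA,
#'   PFM, motif-gene map TSV, optional GMT).
#' @param control_sample Control sample id in the manifests (default
#'   `"control"`).
#' @param seed Integer seed.
#' @param alpha_p,alpha_q DE dual thresholds (default 0.01 / 0.01).
#' @param region_gained_min_cases Recurrence threshold k for gained regions
#'   (default 10).
#' @param loop_min_count,loop_max_fdr,loop_min_length Loop significance
#'   filters (defaults 2, 0.01, 5000).
#' @param loop_gained_min_cases Recurrence threshold k for gained loops
#'   (default 8).
#' @param promoter_window Promoter half-width in bp (default 2000).
#' @param anchor_max_gap Anchor unification gap in bp (default 500).
#' @param scan_min_score_frac PWM scan threshold as a fraction of the
#'   maximum score (default 0.8).
#' @param de_engine `"moderated"` or `"welch"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, synth = NULL, peak_files = NULL,
                            loop_files = NULL, genes_file = NULL,
                            counts_file = NULL, fasta_file = NULL,
                            pfm_file = NULL, motif_gene_map_file = NULL,
                            gmt_file = NULL, control_sample = "control",
                            seed = 1, alpha_p = 0.01, alpha_q = 0.01,
                            region_gained_min_cases = 10,
                            loop_min_count = 2, loop_max_fdr = 0.01,
                            loop_min_length = 5000,
                            loop_gained_min_cases = 8,
                            promoter_window = 2000, anchor_max_gap = 500,
                            scan_min_score_frac = 0.8,
                            de_engine = c("moderated", "welch")) {
  cfg <- list(outdir = outdir, synth = synth, peak_files = peak_files,
              loop_files = loop_files, genes_file = genes_file,
              counts_file = counts_file, fasta_file = fasta_file,
              pfm_file = pfm_file, motif_gene_map_file = motif_gene_map_file,
              gmt_file = gmt_file, control_sample = control_sample,
              seed = as.integer(seed), alpha_p = alpha_p, alpha_q = alpha_q,
              region_gained_min_cases = region_gained_min_cases,
              loop_min_count = loop_min_count, loop_max_fdr = loop_max_fdr,
              loop_min_length = loop_min_length,
              loop_gained_min_cases = loop_gained_min_cases,
              promoter_window = promoter_window,
              anchor_max_gap = anchor_max_gap,
              scan_min_score_frac = scan_min_score_frac,
              de_engine = match.arg(de_engine))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, rejects inconsistent thresholds with actionable messages
#' and attaches a content hash that is stable under key reordering.
#'
#' @param config A [pipeline_config()] or plain named list.
#' @return Normalized `pipeline_config` with attribute `hash`.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    known <- names(formals(pipeline_config))
    unknown <- setdiff(names(config), known)
    if (length(unknown) > 0)
      stopf("validate_config: unknown field(s): %s",
            paste(unknown, collapse = ", "))
    config <- do.call(pipeline_config, config)
  }
  with(config, {
    if (alpha_p <= 0 || alpha_p > 1 || alpha_q <= 0 || alpha_q > 1)
      stopf("validate_config: alpha thresholds must lie in (0, 1]")
    if (promoter_window <= 0)
      stopf("validate_config: promoter window must be positive")
    if (anchor_max_gap < 0 || loop_min_count < 0 || loop_min_length < 0)
      stopf("validate_config: negative threshold")
    if (region_gained_min_cases < 1 || loop_gained_min_cases < 1)
      stopf("validate_config: k must be at least 1")
  })
  if (!is.null(config$synth)) {
    if (config$region_gained_min_cases > config$synth$n_cases_regions)
      stopf("validate_config: region rule k=%d exceeds n=%d case samples",
            config$region_gained_min_cases, config$synth$n_cases_regions)
    if (config$loop_gained_min_cases > config$synth$n_cases_loops)
      stopf("validate_config: loop rule k=%d exceeds n=%d case samples",
            config$loop_gained_min_cases, config$synth$n_cases_loops)
  }
  for (f in c("peak_files", "loop_files", "genes_file", "counts_file",
              "fasta_file", "pfm_file", "motif_gene_map_file", "gmt_file")) {
    paths <- config[[f]]
    if (!is.null(paths) && !all(file.exists(paths)))
      stopf("validate_config: missing %s: %s", f,
            paths[!file.exists(paths)][1])
  }
  attr(config, "hash") <- config_hash(config)
  config
}

# hash over the analysis-relevant configuration: thresholds, seed, synth
# parameters and input file basenames — not output locations, so reruns of
# the same analysis in different directories compare equal.
config_hash <- function(config) {
  x <- unclass(config)
  x$outdir <- NULL
  for (f in c("peak_files", "loop_files", "genes_file", "counts_file",
              "fasta_file", "pfm_file", "motif_gene_map_file", "gmt_file"))
    if (!is.null(x[[f]])) x[[f]] <- basename(x[[f]])
  x$synth <- if (!is.null(x$synth)) unclass(x$synth)[order(names(x$synth))]
  x <- x[order(names(x))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(x, digits.d = 15)), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# scan only within regions of interest, mapping hits back to genome
# coordinates; hits cannot span region boundaries by construction.
scan_regions <- function(sequences, regions, pwm, min_score_frac = 0.8,
                         threshold = NULL) {
  if (nrow(regions) == 0)
    return(scan_pwm(character(0), pwm))
  regions <- merge_intervals(regions)
  sub <- vapply(seq_len(nrow(regions)), function(i)
    substr(sequences[[regions$chrom[i]]], regions$start[i] + 1,
           regions$end[i]), "")
  names(sub) <- sprintf("reg%06d", seq_len(nrow(regions)))
  h <- scan_pwm(sub, pwm, threshold = threshold,
                min_score_frac = min_score_frac)
  if (nrow(h) == 0) return(h)
  ri <- match(h$chrom, names(sub))
  h$start <- h$start + regions$start[ri]
  h$end <- h$end + regions$start[ri]
  h$chrom <- regions$chrom[ri]
  h <- h[order(chrom_rank(h$chrom), h$start, match(h$strand, c("+", "-"))), ,
         drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Over-representation analysis against GMT gene sets
#'
#' Per set: exact upper-tail hypergeometric test of the gene list against
#' the universe, Benjamini-Hochberg adjusted across sets, sorted by
#' q-value.
#'
#' @param gene_list Character vector of genes of interest (intersected with
#'   the universe).
#' @param universe Character vector of all assayed genes (non-empty).
#' @param gmt_sets Named list of gene sets (see [read_gmt()]).
#' @param alpha Significance threshold recorded in the `significant` column
#'   (default 0.01).
#' @return Data frame: `set`, `set_size`, `overlap`, `list_size`,
#'   `universe_size`, `p_value`, `q_value`, `significant`.
#' @export
ora_gene_sets <- function(gene_list, universe, gmt_sets, alpha = 0.01) {
  universe <- unique(universe)
  if (length(universe) == 0) stopf("ora_gene_sets: empty universe")
  gene_list <- intersect(unique(gene_list), universe)
  sets <- lapply(gmt_sets, intersect, universe)
  keep <- lengths(sets) > 0
  if (!any(keep)) stopf("ora_gene_sets: no gene set overlaps the universe")
  sets <- sets[keep]
  N <- length(universe); n <- length(gene_list)
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    k <- length(intersect(gene_list, sets[[nm]]))
    data.frame(set = nm, set_size = K, overlap = k, list_size = n,
               universe_size = N,
               p_value = hypergeom_upper_tail(N, K, n, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$significant <- out$p_value < alpha & out$q_value < alpha
  out <- out[order(out$q_value, out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order — regions, expression and loops
#' independently, then the regulatory network, then the report — writing
#' every output as a plain-text file under `config$outdir` plus a
#' `report.json` whose bytes are identical across reruns with the same
#' inputs and seed. A self-audit recounts the rows of every emitted file
#' against the report before returning.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `report`, `report_path`, `report_hash`
#'   and the main in-memory stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  study <- NULL
  if (!is.null(cfg$synth)) {
    study <- generate_synthetic_study(cfg$synth,
                                      outdir = file.path(cfg$outdir, "inputs"))
    cfg$peak_files <- study$paths$peaks
    cfg$loop_files <- study$paths$loops
    cfg$genes_file <- study$paths$genes
    cfg$counts_file <- study$paths$counts
    cfg$fasta_file <- study$paths$fasta
    cfg$pfm_file <- study$paths$pfm
    cfg$motif_gene_map_file <- study$paths$motif_gene_map
  }
  for (f in c("peak_files", "loop_files", "genes_file", "counts_file"))
    if (is.null(cfg[[f]])) stopf("run_pipeline: missing input '%s'", f)
  message("thresholds: alpha_p=", cfg$alpha_p, " alpha_q=", cfg$alpha_q,
          " region_k=", cfg$region_gained_min_cases,
          " loop_count>=", cfg$loop_min_count,
          " loop_fdr<", cfg$loop_max_fdr,
          " loop_len>=", cfg$loop_min_length,
          " loop_k=", cfg$loop_gained_min_cases,
          " promoter_window=", cfg$promoter_window,
          " anchor_gap=", cfg$anchor_max_gap)
  genes <- read_gene_models(cfg$genes_file, "bed6")
  promoters <- promoter_windows(genes, cfg$promoter_window)
  files <- list()
  emit <- function(obj, name, writer, rows) {
    p <- file.path(cfg$outdir, name)
    writer(obj, p)
    files[[length(files) + 1]] <<- list(file = name, rows = rows)
    p
  }

  ## ---- regions ----
  message("stage regions: consensus segmentation and lost/gained calling")
  peak_sets <- lapply(cfg$peak_files, read_bed)
  names(peak_sets) <- names(cfg$peak_files)
  cs <- atomic_segments(peak_sets)
  segs <- classify_segments(
    cs, control_samples = cfg$control_sample,
    gained_rule = presence_rule("absent", "present_in_at_least_k",
                                k = cfg$region_gained_min_cases))
  seg_bed <- genomic_intervals(segs$chrom, segs$start, segs$end,
                               name = segs$label)
  emit(seg_bed, "segments.bed", write_bed, nrow(segs))
  presence_tab <- data.frame(cs$segments,
                             ifelse(cs$presence, 1L, 0L),
                             check.names = FALSE, stringsAsFactors = FALSE)
  emit(presence_tab, "segment_presence.tsv", write_tsv, nrow(presence_tab))
  region_ann <- annotate_to_tss(segs[segs$label %in% c("lost", "gained"), ],
                                genes, cfg$promoter_window)
  region_ann$label <- segs$label[segs$label %in% c("lost", "gained")]
  emit(region_ann, "differential_regions_tss.tsv", write_tsv, nrow(region_ann))

  ## ---- expression ----
  message("stage expression: pairwise DE and core intersection")
  counts <- read_counts(cfg$counts_file)
  counts <- filter_low_count_genes(counts)
  grp <- sub("_r?[0-9]+$", "", colnames(counts))
  ctl_cols <- colnames(counts)[grp == cfg$control_sample]
  case_groups <- sort(unique(grp[grp != cfg$control_sample]), method = "radix")
  if (length(ctl_cols) < 2) stopf("run_pipeline: control group needs >= 2 replicates")
  de <- lapply(case_groups, function(g)
    pairwise_de(counts, colnames(counts)[grp == g], ctl_cols,
                alpha_p = cfg$alpha_p, alpha_q = cfg$alpha_q,
                engine = cfg$de_engine, comparison_id = paste0(g, "_vs_control")))
  names(de) <- case_groups
  de_table <- do.call(rbind, lapply(de, as.data.frame))
  emit(de_table, "de_results.tsv", write_tsv, nrow(de_table))
  core <- intersect_de_sets(de, rule = "all")
  emit(data.frame(gene_id = core$core), "core_degs.txt",
       function(d, p) writeLines(d$gene_id, p), length(core$core))
  emit(core$pattern_table, "de_intersection_patterns.tsv", write_tsv,
       nrow(core$pattern_table))

  ## ---- loops ----
  message("stage loops: filtering, unification, differential calling")
  loop_sets <- lapply(names(cfg$loop_files), function(s)
    read_bedpe(cfg$loop_files[[s]], sample_id = s))
  all_loops <- do.call(rbind, lapply(loop_sets, filter_loops,
                                     min_count = cfg$loop_min_count,
                                     max_fdr = cfg$loop_max_fdr,
                                     min_length = cfg$loop_min_length))
  ul <- unify_anchors(all_loops, max_gap = cfg$anchor_max_gap,
                      samples = names(cfg$loop_files))
  ul <- call_differential_loops(
    ul, cfg$control_sample,
    loop_diff_rule(cfg$loop_min_count, cfg$loop_gained_min_cases))
  ul <- classify_loops(ul, promoters)
  ctab <- loop_class_table(ul)
  diff_idx <- ul$loops$diff_label %in% c("lost", "gained")
  maf <- multi_anchor_flags(ul, subset = diff_idx)
  len <- compare_loop_lengths(
    ul$loops$span_bp[ul$loops$diff_label == "lost"],
    ul$loops$span_bp[ul$loops$diff_label == "gained"])
  anchor_genes <- genes_at_differential_anchors(ul, genes, core$core,
                                                cfg$promoter_window)
  loop_table <- data.frame(ul$loops,
                           multi_anchor = NA, hub_id = NA_character_,
                           stringsAsFactors = FALSE)
  loop_table$multi_anchor[diff_idx] <- unname(maf$multi_anchor)
  loop_table$hub_id[diff_idx] <- unname(maf$hub_id)
  loop_table <- cbind(loop_table, ul$counts)
  emit(loop_table, "unified_loops.tsv", write_tsv, nrow(loop_table))
  bedpe_out <- data.frame(sample_id = "unified", chrom = ul$loops$chrom,
                          start1 = ul$loops$start1, end1 = ul$loops$end1,
                          start2 = ul$loops$start2, end2 = ul$loops$end2,
                          count = rowSums(ul$counts), fdr = NA_real_,
                          stringsAsFactors = FALSE)
  emit(bedpe_out, "unified_loops.bedpe", write_bedpe, nrow(bedpe_out))

  ## ---- regulatory network ----
  regnet <- NULL
  if (!is.null(cfg$fasta_file) && !is.null(cfg$pfm_file)) {
    message("stage regnet: motif scanning, enrichment, target assignment")
    sequences <- read_fasta(cfg$fasta_file)
    pwms <- read_pfm(cfg$pfm_file)
    gained_regions <- segs[segs$label == "gained", c("chrom", "start", "end")]
    shared_regions <- segs[segs$label == "shared", c("chrom", "start", "end")]
    scan_space <- rbind(gained_regions, shared_regions)
    hits <- do.call(rbind, lapply(pwms, function(p)
      scan_regions(sequences, scan_space, p,
                   min_score_frac = cfg$scan_min_score_frac)))
    rownames(hits) <- NULL
    emit(genomic_intervals(hits$chrom, hits$start, hits$end,
                           name = hits$motif_id,
                           score = round(hits$score * 100),
                           strand = hits$strand),
         "motif_hits.bed", write_bed, nrow(hits))
    gained_ann <- annotate_to_tss(gained_regions, genes, cfg$promoter_window)
    gained_prox <- gained_regions[gained_ann$zone == "proximal" &
                                  !is.na(gained_ann$zone), , drop = FALSE]
    enr <- motif_enrichment(gained_prox, shared_regions, hits)
    emit(enr, "motif_enrichment.tsv", write_tsv, nrow(enr))
    key_tfs <- NULL
    edges <- assign_targets(hits, gained_regions, genes, cfg$promoter_window)
    emit(edges, "tf_target_edges.tsv", write_tsv, nrow(edges))
    if (!is.null(cfg$motif_gene_map_file)) {
      map <- utils::read.delim(cfg$motif_gene_map_file,
                               stringsAsFactors = FALSE)
      key_tfs <- select_key_tfs(enr, core$core, map, alpha = cfg$alpha_p)
      emit(key_tfs, "key_tfs.tsv", write_tsv, nrow(key_tfs))
    }
    # motif-pair statistic for the first two motifs: target regions are
    # gained promoter-proximal regions of the TFs' common proximal targets,
    # background the shared promoter-proximal regions genome-wide
    pair <- NULL
    if (length(pwms) >= 2) {
      ids <- vapply(pwms[1:2], function(p) p$motif_id, "")
      ha <- hits[hits$motif_id == ids[1], , drop = FALSE]
      hb <- hits[hits$motif_id == ids[2], , drop = FALSE]
      ea <- edges[edges$tf_id == ids[1] & edges$zone == "proximal", , drop = FALSE]
      eb <- edges[edges$tf_id == ids[2] & edges$zone == "proximal", , drop = FALSE]
      ct <- common_targets(ea, eb, restrict_to = core$core)
      prox_common <- gained_prox[
        gained_ann$nearest_gene_id[gained_ann$zone == "proximal" &
                                   !is.na(gained_ann$zone)] %in% ct$common, ,
        drop = FALSE]
      shared_ann <- annotate_to_tss(shared_regions, genes, cfg$promoter_window)
      shared_prox <- shared_regions[shared_ann$zone == "proximal" &
                                    !is.na(shared_ann$zone), , drop = FALSE]
      pair <- tryCatch(
        motif_pair_distance(ha, hb, prox_common, shared_prox),
        error = function(e) NULL)
      regnet <- list(hits = hits, enrichment = enr, key_tfs = key_tfs,
                     edges = edges, common = ct, pair = pair)
    } else {
      regnet <- list(hits = hits, enrichment = enr, key_tfs = key_tfs,
                     edges = edges)
    }
  }

  ## ---- optional ORA ----
  ora <- NULL
  if (!is.null(cfg$gmt_file)) {
    ora <- ora_gene_sets(core$core, rownames(counts),
                         read_gmt(cfg$gmt_file), alpha = cfg$alpha_p)
    emit(ora, "ora.tsv", write_tsv, nrow(ora))
  }

  ## ---- report ----
  report <- list(
    tool = "loopregnet",
    version = as.character(utils::packageVersion("loopregnet")),
    config_hash = attr(cfg, "hash"),
    seed = cfg$seed,
    thresholds = cfg[c("alpha_p", "alpha_q", "region_gained_min_cases",
                       "loop_min_count", "loop_max_fdr", "loop_min_length",
                       "loop_gained_min_cases", "promoter_window",
                       "anchor_max_gap", "scan_min_score_frac", "de_engine")],
    regions = as.list(table(segs$label)),
    core_degs = length(core$core),
    n_comparisons = core$n_comparisons,
    loops = as.list(table(ul$loops$diff_label)),
    loop_class_fractions = list(
      lost = as.list(ctab$fractions["lost", ]),
      gained = as.list(ctab$fractions["gained", ])),
    loop_length = list(median_lost = len$median_lost,
                       median_gained = len$median_gained,
                       p_value = len$test$p_value),
    multi_anchor = list(fraction = maf$fraction_multi_anchor,
                        n_hubs = maf$n_hubs),
    genes_at_differential_anchors = anchor_genes$n_genes,
    degs_at_differential_anchors = anchor_genes$n_deg_overlap,
    regnet = if (!is.null(regnet)) list(
      n_hits = nrow(regnet$hits),
      n_enriched = sum(regnet$enrichment$p_value < cfg$alpha_p),
      key_tfs = if (!is.null(regnet$key_tfs)) regnet$key_tfs$gene_id,
      n_edges = nrow(regnet$edges),
      common_target_fraction = regnet$common$fraction_of_a,
      pair_median_target = if (!is.null(regnet$pair)) regnet$pair$median_target,
      pair_median_background = if (!is.null(regnet$pair)) regnet$pair$median_background,
      pair_p_value = if (!is.null(regnet$pair)) regnet$pair$test$p_value),
    files = files)
  report_path <- file.path(cfg$outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  # self-audit: every emitted table's row count must match the report
  for (f in files) {
    p <- file.path(cfg$outdir, f$file)
    n <- length(readLines(p, warn = FALSE))
    has_header <- grepl("\\.tsv$", f$file)
    if (n - as.integer(has_header) != f$rows)
      stopf("run_pipeline: self-audit failed for %s (%d rows vs %d reported)",
            f$file, n - as.integer(has_header), f$rows)
  }
  invisible(list(report = report, report_path = report_path,
                 report_hash = unname(tools::md5sum(report_path)),
                 segments = segs, consensus = cs, de = de, core = core,
                 loops = ul, loop_class = ctab, multi_anchor = maf,
                 loop_length = len, anchor_genes = anchor_genes,
                 regnet = regnet, ora = ora, study = study))
}
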