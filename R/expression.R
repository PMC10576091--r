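# Expression stage: count filtering, median-of-ratios normalization, a
# documented stand-in pairwise differential-expression test, N-way core DEG
# intersection, and expression-signature distances. The DE engine is a
# stand-in for a negative-binomial Wald test and is pluggable: externally
# computed tables in the same schema can be fed to intersect_de_sets().

#' Drop genes below a total-count threshold
#'
#' @param counts Count matrix (genes x samples).
#' @param min_row_sum Minimum total count across samples for a gene to be
#'   kept (default 10).
#' @return Filtered count matrix, gene order preserved.
#' @export
filter_low_count_genes <- function(counts, min_row_sum = 10) {
  if (nrow(counts) == 0) stopf("filter_low_count_genes: empty count matrix")
  keep <- rowSums(counts) >= min_row_sum
  if (!any(keep)) stopf("filter_low_count_genes: all genes removed")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the reference is the per-gene geometric
#' mean over samples, computed over genes with all counts positive; each
#' sample's factor is the median ratio of its counts to the reference.
#'
#' @param counts Count matrix (genes x samples).
#' @return Named numeric vector of size factors.
#' @export
size_factors_median_ratios <- function(counts) {
  ref_rows <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref_rows))
    stopf("size_factors: no gene with positive counts in every sample")
  lgm <- rowMeans(log(counts[ref_rows, , drop = FALSE]))
  sf <- apply(counts[ref_rows, , drop = FALSE], 2,
              function(cc) stats::median(cc / exp(lgm)))
  sf
}

#' Pairwise differential expression (stand-in engine)
#'
#' One case line versus the control line. Counts of the involved samples are
#' normalized by median-of-ratios size factors; the log2 fold change is
#' computed from mean normalized counts with a 0.5 pseudo-count; p-values
#' come from the selected engine on `log2(normalized + 1)` and are adjusted
#' by Benjamini-Hochberg within the comparison. A gene is significant when
#' `p < alpha_p` AND `q < alpha_q`.
#'
#' The default engine is a variance-moderated t-test (empirical-Bayes
#' pooling of per-gene variances across the transcriptome), which restores
#' the information sharing that a negative-binomial Wald test obtains from
#' shared dispersion estimation; `engine = "welch"` uses a plain per-gene
#' Welch t-test. Neither engine is a negative-binomial Wald test; the engine
#' used is recorded in the result metadata.
#'
#' @param counts Count matrix (genes x samples), already depth-filtered.
#' @param case_samples,control_samples Column names; >= 2 replicates each.
#' @param alpha_p,alpha_q Dual significance thresholds (defaults 0.01).
#' @param engine `"moderated"` (default) or `"welch"`.
#' @param comparison_id Label for the comparison; default
#'   `"<case1..>_vs_<control1..>"` built from sample prefixes.
#' @return Object of class `pairwise_de`: data frame with columns
#'   `comparison_id`, `gene_id`, `log2_fold_change`, `p_value`, `q_value`,
#'   `significant`; attributes `engine` and `significant_genes`.
#' @export
pairwise_de <- function(counts, case_samples, control_samples,
                        alpha_p = 0.01, alpha_q = 0.01,
                        engine = c("moderated", "welch"),
                        comparison_id = NULL) {
  engine <- match.arg(engine)
  if (length(case_samples) < 2 || length(control_samples) < 2)
    stopf("pairwise_de: need >= 2 replicates per side")
  if (!all(c(case_samples, control_samples) %in% colnames(counts)))
    stopf("pairwise_de: unknown sample id")
  comparison_id <- comparison_id %||%
    paste0(sub("_r?[0-9]+$", "", case_samples[1]), "_vs_",
           sub("_r?[0-9]+$", "", control_samples[1]))
  m <- counts[, c(control_samples, case_samples), drop = FALSE]
  sf <- size_factors_median_ratios(m)
  norm <- sweep(m, 2, sf, "/")
  is_case <- colnames(m) %in% case_samples
  mean_case <- rowMeans(norm[, is_case, drop = FALSE])
  mean_ctl <- rowMeans(norm[, !is_case, drop = FALSE])
  lfc <- log2((mean_case + 0.5) / (mean_ctl + 0.5))
  y <- log2(norm + 1)
  if (engine == "moderated") {
    design <- cbind(intercept = 1, case = as.numeric(is_case))
    fit <- limma::eBayes(limma::lmFit(y, design))
    p <- fit$p.value[, "case"]
    engine_label <- "moderated t on log2 normalized counts (limma eBayes); DE stand-in, not NB Wald"
  } else {
    p <- apply(y, 1, function(row)
      welch_t(row[is_case], row[!is_case])$p_value)
    engine_label <- "Welch t on log2 normalized counts; DE stand-in, not NB Wald"
  }
  q <- bh_adjust(p)
  res <- data.frame(comparison_id = comparison_id, gene_id = rownames(counts),
                    log2_fold_change = unname(lfc), p_value = unname(p),
                    q_value = unname(q),
                    significant = unname(p < alpha_p & q < alpha_q),
                    stringsAsFactors = FALSE)
  structure(res, class = c("pairwise_de", "data.frame"),
            engine = engine_label,
            significant_genes = res$gene_id[res$significant])
}

#' Intersect per-comparison significant gene sets into a core set
#'
#' `rule = "all"` returns the intersection over every comparison (the core
#' DEG set); `rule = "at_least_k"` keeps genes significant in at least `k`
#' comparisons. Also reports, UpSet-style, the sizes of all observed
#' exclusive membership patterns over the union of the sets.
#'
#' @param sets Named list of character vectors (significant genes per
#'   comparison), or a list of `pairwise_de` objects.
#' @param rule `"all"` or `"at_least_k"`.
#' @param k Minimum number of comparisons for `"at_least_k"`.
#' @return List with `core` (character vector), `n_comparisons`, `rule`, and
#'   `pattern_table` (data frame `pattern`, `count`; pattern digits follow
#'   the order of `sets`).
#' @export
intersect_de_sets <- function(sets, rule = c("all", "at_least_k"), k = NULL) {
  rule <- match.arg(rule)
  if (length(sets) == 0) stopf("intersect_de_sets: need >= 1 set")
  sets <- lapply(sets, function(s) {
    if (inherits(s, "pairwise_de")) attr(s, "significant_genes") else unique(s)
  })
  universe <- sort(unique(unlist(sets)), method = "radix")
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  hits <- rowSums(member)
  core <- switch(rule,
    all = universe[hits == length(sets)],
    at_least_k = {
      if (is.null(k)) stopf("intersect_de_sets: need k for rule 'at_least_k'")
      universe[hits >= k]
    })
  if (length(universe) > 0) {
    pat <- apply(member, 1, function(r) paste0(as.integer(r), collapse = ""))
    tb <- table(pat)
    pattern_table <- data.frame(pattern = names(tb), count = as.integer(tb),
                                stringsAsFactors = FALSE)
    pattern_table <- pattern_table[order(-pattern_table$count,
                                         pattern_table$pattern), , drop = FALSE]
    rownames(pattern_table) <- NULL
  } else {
    pattern_table <- data.frame(pattern = character(), count = integer(),
                                stringsAsFactors = FALSE)
  }
  list(core = core, n_comparisons = length(sets), rule = rule,
       pattern_table = pattern_table)
}

#' Sample distances over an expression signature
#'
#' Euclidean distances between samples restricted to a gene subset (an
#' expression signature), with an average-linkage dendrogram for a
#' deterministic leaf order. Samples are ordered by id before clustering so
#' ties resolve reproducibly.
#'
#' @param expr Log-scale normalized expression matrix (genes x samples).
#' @param gene_subset Character vector of signature genes (subset of
#'   rownames).
#' @return List with `dist` (symmetric matrix), `hclust` and `leaf_order`
#'   (sample ids in dendrogram order).
#' @export
signature_distance <- function(expr, gene_subset) {
  if (length(gene_subset) == 0) stopf("signature_distance: empty gene subset")
  missing <- setdiff(gene_subset, rownames(expr))
  if (length(missing) > 0)
    stopf("signature_distance: genes absent from matrix: %s",
          paste(utils::head(missing, 3), collapse = ", "))
  expr <- expr[, order(colnames(expr)), drop = FALSE]
  sub <- t(expr[gene_subset, , drop = FALSE])
  d <- euclidean_distance_matrix(sub)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(dist = d, hclust = hc, leaf_order = rownames(sub)[hc$order])
}

#' Co-expression of two genes across samples
#'
#' Pearson correlation with a two-sided test; thin wrapper over
#' [pearson_corr()] for paired per-sample expression of a gene pair.
#'
#' @param expr_gene_a,expr_gene_b Paired expression vectors (same samples).
#' @return A [test_result()] with `estimate` = r.
#' @export
coexpression <- function(expr_gene_a, expr_gene_b) {
  pearson_corr(expr_gene_a, expr_gene_b)
}
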