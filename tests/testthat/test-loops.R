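mk_loops <- function(a, b, sample_id = "s", count = 3, fdr = 0.001,
                     chrom = "chr1", width = 1000) {
  data.frame(sample_id = sample_id, chrom = chrom,
             start1 = a, end1 = a + width, start2 = b, end2 = b + width,
             count = count, fdr = fdr, stringsAsFactors = FALSE)
}

test_that("loop span is the anchor midpoint distance", {
  expect_equal(loop_span(mk_loops(0, 100000)), 100000)
  expect_equal(loop_span(mk_loops(5000, 5000)), 0)
  # invariant under anchor swap
  l <- mk_loops(2000, 90000)
  swapped <- l
  swapped[, c("start1", "end1", "start2", "end2")] <-
    l[, c("start2", "end2", "start1", "end1")]
  expect_equal(loop_span(l), loop_span(swapped))
})

test_that("loop filters drop low-count, short and high-FDR calls", {
  l <- rbind(mk_loops(0, 100000, count = 1),          # count fails
             mk_loops(0, 4000, width = 500),          # span 4000 fails
             mk_loops(0, 50000, count = 3, fdr = 0.005),
             mk_loops(0, 60000, fdr = 0.5))           # fdr fails
  out <- filter_loops(l)
  expect_equal(out$start2, 50000)
  # missing FDR column: filter skipped with warning
  l2 <- mk_loops(0, 50000); l2$fdr <- NA_real_
  expect_warning(kept <- filter_loops(l2), "FDR filter skipped")
  expect_equal(nrow(kept), 1)
})

test_that("anchor unification merges by gap with single linkage", {
  l <- rbind(mk_loops(0, 100000, "s1", width = 100),
             mk_loops(50, 100050, "s2", width = 100))
  ul <- unify_anchors(l, max_gap = 500)
  expect_equal(nrow(ul$anchors), 2)
  expect_equal(ul$anchors$start, c(0, 100000))
  expect_equal(ul$anchors$end, c(150, 100150))
  expect_equal(nrow(ul$loops), 1)
  expect_equal(unname(ul$counts[1, ]), c(3, 3))

  # gap 600 with max_gap 500 stays separate
  l2 <- rbind(mk_loops(0, 100000, "s1", width = 100),
              mk_loops(700, 100700, "s2", width = 100))
  expect_equal(nrow(unify_anchors(l2, max_gap = 500)$anchors), 4)

  # chain a-b-c with pairwise gaps 400 collapses transitively
  l3 <- rbind(mk_loops(0, 100000, "s1", width = 100),
              mk_loops(500, 100000, "s2", width = 100),
              mk_loops(1000, 100000, "s3", width = 100))
  ul3 <- unify_anchors(l3, max_gap = 500)
  expect_equal(sum(ul3$anchors$start == 0), 1)
  expect_equal(ul3$anchors$end[1], 1100)

  # within-sample duplicates summed
  l4 <- rbind(mk_loops(0, 100000, "s1", count = 2),
              mk_loops(0, 100000, "s1", count = 5))
  expect_equal(unname(unify_anchors(l4)$counts[1, "s1"]), 7)
})

test_that("anchor unification is invariant to sample input order", {
  set.seed(53)
  a <- sample.int(5e5, 30) * 2
  l <- do.call(rbind, lapply(1:3, function(s)
    mk_loops(a[1:10 + (s - 1) * 10], a[1:10 + (s - 1) * 10] + 150000,
             paste0("s", s))))
  ul1 <- unify_anchors(l)
  ul2 <- unify_anchors(l[rev(seq_len(nrow(l))), ])
  expect_equal(ul1$anchors, ul2$anchors)
  expect_equal(ul1$counts, ul2$counts)
})

test_that("differential loop rules follow the presence quantifiers", {
  counts <- function(ctl, cases) {
    l <- do.call(rbind, lapply(which(c(ctl, cases) > 0), function(i)
      mk_loops(0, 100000, c("control", paste0("case", 1:14))[i],
               count = c(ctl, cases)[i])))
    unify_anchors(l, samples = c("control", paste0("case", 1:14)))
  }
  lab <- function(ul) call_differential_loops(ul, "control")$loops$diff_label
  expect_equal(lab(counts(3, rep(0, 14))), "lost")
  expect_equal(lab(counts(0, rep(c(2, 0), c(9, 5)))), "gained")
  expect_equal(lab(counts(2, rep(c(2, 0), c(5, 9)))), "other")
  expect_equal(lab(counts(2, rep(2, 14))), "shared")
  # a single case read defeats the lost rule (counts must be 0 in all cases)
  expect_equal(lab(counts(3, rep(c(1, 0), c(1, 13)))), "other")
  expect_error(call_differential_loops(counts(3, rep(0, 14)), "nope"),
               "control sample")
})

test_that("loop classes follow promoter-window overlap of both anchors", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(10000, 200000), end = c(15000, 205000),
                      strand = "+", tss = c(10000, 200000),
                      stringsAsFactors = FALSE)
  pw <- promoter_windows(genes)
  l <- rbind(mk_loops(9500, 199500),    # both promoter -> P-P
             mk_loops(9500, 100000),    # one -> P-E
             mk_loops(50000, 150000))   # none -> E-E
  ul <- classify_loops(unify_anchors(l), pw)
  # unified loops are genomically sorted: (9500,100000) P-E precedes
  # (9500,199500) P-P, then (50000,150000) E-E
  expect_equal(ul$loops$class, c("P-E", "P-P", "E-E"))
  # adding non-overlapping windows never changes a class
  more <- rbind(genes, data.frame(gene_id = "g3", chrom = "chr2",
                                  start = 1e6, end = 1.1e6, strand = "+",
                                  tss = 1e6))
  ul2 <- classify_loops(ul, promoter_windows(more))
  expect_equal(ul2$loops$class, ul$loops$class)
})

test_that("multi-anchor flags match a brute-force degree count", {
  l <- rbind(mk_loops(0, 100000, "s1"),        # shares anchor at 100000
             mk_loops(100000, 200000, "s1"),
             mk_loops(400000, 480000, "s1"))   # isolated
  ul <- unify_anchors(l)
  maf <- multi_anchor_flags(ul)
  expect_equal(unname(maf$multi_anchor), c(TRUE, TRUE, FALSE))
  expect_equal(maf$n_hubs, 1)
  set.seed(59)
  for (i in 1:20) {
    n <- sample(3:20, 1)
    pos <- sample.int(200, n * 2, replace = TRUE) * 5000
    keep <- pos[seq_len(n)] != pos[n + seq_len(n)]
    lr <- mk_loops(pmin(pos[seq_len(n)], pos[n + seq_len(n)])[keep],
                   pmax(pos[seq_len(n)], pos[n + seq_len(n)])[keep],
                   width = 1000)
    if (nrow(lr) == 0) next
    ulr <- unify_anchors(lr, max_gap = 0)
    m <- multi_anchor_flags(ulr)
    deg <- table(c(ulr$loops$anchor_a, ulr$loops$anchor_b))
    brute <- as.vector(deg[ulr$loops$anchor_a] >= 2 |
                       deg[ulr$loops$anchor_b] >= 2)
    expect_equal(unname(m$multi_anchor), brute)
  }
})

test_that("loop length comparison reports medians, IQR and Welch test", {
  set.seed(61)
  lost <- round(rlnorm(500, log(254000), 0.35))
  gained <- round(rlnorm(500, log(114000), 0.35))
  r <- compare_loop_lengths(lost, gained)
  expect_equal(r$median_lost, median(lost))
  expect_lt(r$test$p_value, 1e-10)
  same <- compare_loop_lengths(c(1000, 2000, 3000), c(1000, 2000, 3000))
  expect_equal(same$test$p_value, 1)
  expect_error(compare_loop_lengths(numeric(0), gained), "non-empty")
})

test_that("genes at differential anchors intersect the core DEG set", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      start = c(10000, 200000, 900000),
                      end = c(15000, 205000, 905000), strand = "+",
                      tss = c(10000, 200000, 900000), stringsAsFactors = FALSE)
  l <- rbind(mk_loops(9500, 100000, "control", count = 3),
             mk_loops(500000, 600000, "control", count = 3))  # gene desert
  ul <- unify_anchors(l, samples = c("control", paste0("case", 1:14)))
  ul <- call_differential_loops(ul, "control")
  expect_equal(ul$loops$diff_label, c("lost", "lost"))
  r <- genes_at_differential_anchors(ul, genes, core_degs = c("g1", "g9"))
  expect_equal(r$genes, "g1")
  expect_equal(r$deg_overlap, "g1")
})
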