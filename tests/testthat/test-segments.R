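test_that("atomic segments partition overlapping peaks by presence", {
  cs <- atomic_segments(list(
    S1 = genomic_intervals("chr1", 0, 100),
    S2 = genomic_intervals("chr1", 50, 150)))
  expect_equal(cs$segments$start, c(0, 50, 100))
  expect_equal(cs$segments$end, c(50, 100, 150))
  expect_equal(unname(cs$presence),
               matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE), 3, 2))
  empty <- atomic_segments(list(
    A = genomic_intervals(character(), numeric(), numeric())))
  expect_equal(nrow(empty$segments), 0)
})

test_that("atomic segments agree with the per-base presence oracle", {
  set.seed(19)
  L <- 100000
  for (i in 1:40) {
    ns <- sample(1:8, 1)
    sets <- lapply(seq_len(ns), function(s)
      random_interval_set(sample(0:15, 1), max_pos = L))
    names(sets) <- paste0("s", seq_len(ns))
    cs <- atomic_segments(sets)
    expect_identical(segments_to_base_matrix(cs, L),
                     presence_by_base(sets, L))
    # adjacent segments differ in presence or are non-contiguous
    segs <- cs$segments
    if (nrow(segs) > 1) {
      same_chrom <- segs$chrom[-1] == segs$chrom[-nrow(segs)]
      contiguous <- segs$start[-1] == segs$end[-nrow(segs)]
      key <- apply(cs$presence, 1, paste, collapse = "")
      expect_false(any(same_chrom & contiguous & key[-1] == key[-nrow(segs)]))
    }
  }
})

test_that("presence rules label lost, gained and shared segments", {
  mk <- function(pres) {
    structure(list(
      segments = data.frame(chrom = "chr1",
                            start = 1000 * (seq_len(nrow(pres)) - 1) + 1,
                            end = 1000 * seq_len(nrow(pres)),
                            stringsAsFactors = FALSE),
      presence = pres, samples = colnames(pres)),
      class = "consensus_segments")
  }
  pres <- rbind(c(TRUE, rep(FALSE, 15)),     # control only -> lost
                c(FALSE, rep(c(TRUE, FALSE), c(12, 3))),  # 12/15 -> gained
                c(TRUE, rep(TRUE, 15)),      # everywhere -> shared
                c(FALSE, rep(c(TRUE, FALSE), c(5, 10))))  # 5/15 -> other
  colnames(pres) <- c("control", paste0("case", 1:15))
  out <- classify_segments(mk(pres), "control")
  expect_equal(out$label, c("lost", "gained", "shared", "other"))
  # rule referencing more cases than present is rejected
  expect_error(classify_segments(
    mk(pres), "control",
    gained_rule = presence_rule("absent", "present_in_at_least_k", k = 16)),
    "requires 16 cases")
})

test_that("two-control quantifier rules support control-absent gains", {
  cs <- atomic_segments(list(
    ctrlA = genomic_intervals("chr1", 0, 100),
    ctrlB = genomic_intervals("chr1", 0, 100),
    c1 = genomic_intervals("chr1", 500, 600),
    c2 = genomic_intervals("chr1", 500, 600),
    c3 = genomic_intervals("chr1", 2000, 2100)))
  out <- classify_segments(
    cs, control_samples = c("ctrlA", "ctrlB"),
    lost_rule = presence_rule("present", "absent_in_all"),
    gained_rule = presence_rule("absent", "present_in_at_least_k", k = 2))
  expect_equal(out$label[out$start == 0], "lost")
  expect_equal(out$label[out$start == 500], "gained")
  expect_equal(out$label[out$start == 2000], "other")
})

test_that("swapping rules and roles maps lost to gained (symmetry)", {
  set.seed(23)
  sets <- lapply(1:4, function(i) random_interval_set(12, max_pos = 50000))
  names(sets) <- c("ctl", "a", "b", "c")
  cs <- atomic_segments(sets)
  fwd <- classify_segments(
    cs, "ctl",
    lost_rule = presence_rule("present", "absent_in_all"),
    gained_rule = presence_rule("absent", "present_in_at_least_k", k = 3))
  # reversed roles: the three cases become controls, the control the case
  rev <- classify_segments(
    cs, c("a", "b", "c"),
    lost_rule = presence_rule("present", "absent_in_all"),
    gained_rule = presence_rule("absent", "present_in_at_least_k", k = 1))
  key <- function(d, lab) paste(d$chrom[d$label == lab], d$start[d$label == lab])
  expect_setequal(key(fwd, "lost"), key(rev, "gained"))
  expect_setequal(key(fwd, "gained"), key(rev, "lost"))
})

test_that("labelled segment coverage conserves the input union", {
  set.seed(29)
  sets <- lapply(1:5, function(i) random_interval_set(15, max_pos = 80000))
  names(sets) <- c("ctl", paste0("case", 1:4))
  cs <- atomic_segments(sets)
  out <- classify_segments(cs, "ctl",
    gained_rule = presence_rule("absent", "present_in_at_least_k", k = 3))
  union_bp <- sum({
    m <- merge_intervals(do.call(rbind, lapply(sets, function(d)
      d[, c("chrom", "start", "end")])))
    m$end - m$start
  })
  expect_equal(sum(out$width), union_bp)
})

test_that("min_width drops narrow segments after merging", {
  cs <- atomic_segments(list(ctl = genomic_intervals("chr1", c(0, 200), c(10, 300)),
                             c1 = genomic_intervals("chr1", 205, 300)))
  out <- classify_segments(
    cs, "ctl", min_width = 20,
    gained_rule = presence_rule("absent", "present_in_at_least_k", k = 1))
  expect_false(any(out$width < 20))
  expect_false(any(out$start == 0))  # the 10 bp lost fragment is gone
})

test_that("TSS annotation distances, zones and strand rule are exact", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(10000, 5000), end = c(12000, 9000),
                      strand = c("+", "-"), tss = c(10000, 8999),
                      stringsAsFactors = FALSE)
  ann <- annotate_to_tss(genomic_intervals("chr1", 9500, 9600), genes)
  expect_equal(ann$nearest_gene_id, "g1")
  expect_equal(ann$distance_to_tss, 400)
  expect_equal(ann$zone, "proximal")

  # peak far downstream: nearest TSS (g1 at 10000) lies 50 kb before the start
  far <- annotate_to_tss(genomic_intervals("chr1", 60000, 60100), genes)
  expect_equal(far$distance_to_tss, -50000)
  expect_equal(far$zone, "distal")

  # minus-strand gene: TSS at end - 1; containing peak has distance 0
  minus <- annotate_to_tss(genomic_intervals("chr1", 8990, 9010), genes)
  expect_equal(minus$nearest_gene_id, "g2")
  expect_equal(minus$distance_to_tss, 0)
  expect_equal(minus$zone, "proximal")

  expect_error(annotate_to_tss(genomic_intervals("chr1", 0, 10), genes[0, ]),
               "empty gene list")
})

test_that("promoter windows are symmetric, clipped and per-gene", {
  genes <- data.frame(gene_id = c("ga", "gb", "gc"), chrom = "chr1",
                      start = c(10000, 500, 11000), end = c(20000, 4000, 21000),
                      strand = "+", tss = c(10000, 500, 11000),
                      stringsAsFactors = FALSE)
  pw <- promoter_windows(genes, 2000)
  expect_equal(pw$start, c(8000, 0, 9000))
  expect_equal(pw$end, c(12000, 2500, 13000))
  expect_equal(nrow(pw), 3)  # overlapping windows retained unmerged
})
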