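simple_pwm <- function(consensus, p = 0.9, id = "m") {
  bases <- strsplit(consensus, "")[[1]]
  probs <- matrix((1 - p) / 3, 4, length(bases),
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) probs[bases[j], j] <- p
  make_pwm(id, probs = probs)
}

# exhaustive per-window scorer, independent of the vectorized scan
brute_scan <- function(seq, pwm, threshold) {
  chars <- strsplit(seq, "")[[1]]
  w <- ncol(pwm$probs)
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  out <- NULL
  score_window <- function(win) {
    sum(vapply(seq_len(w), function(j)
      log2(pwm$probs[win[j], j] /
           pwm$background[match(win[j], rownames(pwm$probs))]), 0))
  }
  for (i in seq_len(nchar(seq) - w + 1)) {
    win <- chars[i:(i + w - 1)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    fs <- score_window(win)
    rs <- score_window(rev(unname(rc[win])))
    if (fs >= threshold) out <- rbind(out, c(i - 1, 1, fs))
    if (rs >= threshold) out <- rbind(out, c(i - 1, -1, rs))
  }
  out
}

test_that("PWM scanning scores log-odds on both strands and skips N", {
  pw <- simple_pwm("AC")
  h <- scan_pwm(c(s = "ACGT"), pw, threshold = 3)
  plus <- h[h$strand == "+", ]
  expect_equal(plus$start, 0)
  expect_equal(plus$score, 2 * log2(0.9 / 0.25), tolerance = 1e-12)
  # reverse complement of AC (GT) sits at offset 2 on the minus strand
  expect_equal(h$start[h$strand == "-"], 2)

  # palindromic consensus hits both strands symmetrically
  hp <- scan_pwm(c(s = "ACGT"), simple_pwm("ACGT"), threshold = 4)
  expect_setequal(hp$strand, c("+", "-"))
  expect_equal(hp$score[1], hp$score[2])

  # threshold above the maximum score yields nothing
  expect_equal(nrow(scan_pwm(c(s = "ACGTACGT"), pw,
                             threshold = pwm_max_score(pw) + 1)), 0)
  # N voids overlapping windows only
  hn <- scan_pwm(c(s = "ACNAC"), pw, threshold = 3)
  expect_equal(hn$start[hn$strand == "+"], c(0, 3))
  # motif wider than the sequence: no hits, no error
  expect_equal(nrow(scan_pwm(c(s = "AC"), simple_pwm("ACGTA"), threshold = 0)), 0)
})

test_that("PWM scanning equals the exhaustive per-window scorer", {
  set.seed(67)
  for (i in 1:8) {
    seq <- paste0(sample(c("A", "C", "G", "T", "N"), 400,
                         replace = TRUE, prob = c(rep(0.245, 4), 0.02)),
                  collapse = "")
    pw <- simple_pwm(paste0(sample(c("A", "C", "G", "T"), 6, TRUE),
                            collapse = ""), p = 0.7)
    thr <- 0.5 * pwm_max_score(pw)
    got <- scan_pwm(c(chr = seq), pw, threshold = thr)
    ref <- brute_scan(seq, pw, thr)
    expect_equal(nrow(got), if (is.null(ref)) 0 else nrow(ref))
    if (!is.null(ref)) {
      o <- order(ref[, 1], -ref[, 2])
      expect_equal(got$start, ref[o, 1])
      expect_equal(got$score, ref[o, 3], tolerance = 1e-9)
    }
  }
})

test_that("motif enrichment uses the exact hypergeometric tail", {
  regions <- function(n, offset = 0)
    genomic_intervals("chr1", offset + 10000 * seq_len(n),
                      offset + 10000 * seq_len(n) + 1000)
  tg <- regions(5); bg <- regions(15, offset = 1e6)
  hit_in <- function(r, idx, id = "m1")
    data.frame(motif_id = rep(id, length(idx)),
               chrom = rep("chr1", length(idx)),
               start = r$start[idx] + 100, end = r$start[idx] + 110,
               strand = rep("+", length(idx)),
               score = rep(10, length(idx)), stringsAsFactors = FALSE)
  # all 5 targets and no background carry the motif: p = 1 / C(20,5)
  enr <- motif_enrichment(tg, bg, hit_in(tg, 1:5))
  expect_equal(enr$p_value, 1 / choose(20, 5))
  expect_equal(enr$targets_with_hit, 5)
  # equal carrier frequency is not enriched
  enr2 <- motif_enrichment(tg, bg, rbind(hit_in(tg, 1), hit_in(bg, 1:3)))
  expect_gte(enr2$p_value, 0.5)
  # a motif with no hits anywhere has p = 1
  enr3 <- motif_enrichment(tg, bg,
                           hit_in(tg, integer(0)))
  expect_equal(nrow(enr3), 0)
  expect_error(motif_enrichment(tg, tg[0, ], hit_in(tg, 1)), "empty background")
})

test_that("enrichment p-values are uniform under random target labels", {
  set.seed(71)
  all_regions <- genomic_intervals("chr1", 5000 * (1:60), 5000 * (1:60) + 800)
  carriers <- sample(60, 20)
  hits <- data.frame(motif_id = "m", chrom = "chr1",
                     start = all_regions$start[carriers] + 10,
                     end = all_regions$start[carriers] + 18, strand = "+",
                     score = 5, stringsAsFactors = FALSE)
  ps <- replicate(300, {
    t_idx <- sample(60, 12)
    motif_enrichment(all_regions[t_idx, ], all_regions[-t_idx, ], hits)$p_value
  })
  # discrete conservative p-values: P(p <= a) <= a at several thresholds
  for (a in c(0.05, 0.2, 0.5))
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / 300))
})

test_that("key TFs require both motif enrichment and a DEG gene", {
  enr <- data.frame(motif_id = c("m1", "m2", "m3", "m4"),
                    p_value = c(0.005, 0.005, 0.02, 0.001),
                    q_value = c(0.01, 0.01, 0.03, 0.004),
                    stringsAsFactors = FALSE)
  map <- data.frame(motif_id = c("m1", "m2", "m3"),
                    gene_id = c("tf1", "tf2", "tf3"), stringsAsFactors = FALSE)
  expect_warning(sel <- select_key_tfs(enr, core_degs = c("tf1", "tf3"), map),
                 "m4")
  expect_equal(sel$gene_id, "tf1")  # m2 not a DEG, m3 above alpha
})

test_that("target assignment respects gained regions, distance and zone", {
  genes <- data.frame(gene_id = c("g7", "g8"), chrom = "chr1",
                      start = c(50000, 90000), end = c(55000, 95000),
                      strand = "+", tss = c(50000, 90000),
                      stringsAsFactors = FALSE)
  gained <- genomic_intervals("chr1", c(48000, 60000), c(49000, 61000))
  hits <- data.frame(motif_id = "m", chrom = "chr1",
                     start = c(48490, 60490, 70000),
                     end = c(48510, 60510, 70020), strand = "+", score = 9,
                     stringsAsFactors = FALSE)
  e <- assign_targets(hits, gained, genes)
  expect_equal(nrow(e), 2)             # third hit outside any gained region
  expect_equal(e$gene_id, c("g7", "g7"))
  expect_equal(e$zone, c("proximal", "distal"))
  expect_equal(e$tss_distance, c(1500, 10500))
  expect_true(all(e$hit_start >= e$region_start & e$hit_end <= e$region_end))
})

test_that("common-target fractions use set semantics", {
  mk_edges <- function(genes) data.frame(tf_id = rep("t", length(genes)),
                                         gene_id = genes,
                                         stringsAsFactors = FALSE)
  a <- mk_edges(c(paste0("g", 1:47), paste0("g", 1:5)))  # duplicates collapse
  b <- mk_edges(c(paste0("g", 1:33), paste0("x", 1:15)))
  ct <- common_targets(a, b)
  expect_equal(ct$n_a, 47)
  expect_equal(ct$n_common, 33)
  expect_equal(round(100 * ct$fraction_of_a, 1), 70.2)
  expect_equal(common_targets(a, a)$fraction_of_a, 1)
  expect_equal(common_targets(a, mk_edges("zz"))$fraction_of_a, 0)
  expect_message(und <- common_targets(mk_edges(character(0)), b), "undefined")
  expect_true(is.na(und$fraction_of_a))
})

test_that("motif-pair distances take per-region minima and skip one-sided regions", {
  regions <- genomic_intervals("chr1", c(0, 1000, 2000), c(500, 1500, 2500))
  ha <- data.frame(motif_id = "a", chrom = "chr1", start = c(95, 1095),
                   end = c(105, 1105), strand = "+", score = 1,
                   stringsAsFactors = FALSE)
  hb <- data.frame(motif_id = "b", chrom = "chr1", start = c(151, 2100),
                   end = c(161, 2110), strand = "+", score = 1,
                   stringsAsFactors = FALSE)
  # region 1: |100 - 156| = 56; region 2: only motif a; region 3: only b
  bg <- genomic_intervals("chr1", 5000, 6000)
  hab <- rbind(ha, data.frame(motif_id = "a", chrom = "chr1", start = 5095,
                              end = 5105, strand = "+", score = 1))
  hbb <- rbind(hb, data.frame(motif_id = "b", chrom = "chr1", start = 5219,
                              end = 5229, strand = "+", score = 1))
  r <- motif_pair_distance(hab, hbb, regions, bg)
  expect_equal(r$target_distances, 56)
  expect_equal(r$n_skipped_target, 2)
  expect_equal(r$background_distances, 124)
  expect_error(motif_pair_distance(ha, hb, regions[2, ], bg[0, ]),
               "no contributing region")
})
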