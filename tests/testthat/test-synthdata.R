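tiny <- function(seed = 5, ...) synth_config(seed = seed, preset = "tiny", ...)

test_that("generators are byte-deterministic for a given seed", {
  g1 <- generate_genome(tiny())
  g2 <- generate_genome(tiny())
  expect_identical(g1, g2)
  expect_false(identical(generate_genome(tiny(seed = 6))$sequences,
                         g1$sequences))
  # gene models do not depend on whether the sequence is generated
  expect_identical(generate_genome(tiny(), include_sequence = FALSE)$genes,
                   g1$genes)
  p1 <- generate_peak_sets(tiny(), g1)
  p2 <- generate_peak_sets(tiny(), g1)
  expect_identical(p1, p2)
  l1 <- generate_loop_sets(tiny(), g1)
  expect_identical(l1, generate_loop_sets(tiny(), g1))
})

test_that("genome composition and gene placement follow the config", {
  cfg <- tiny()
  g <- generate_genome(cfg)
  expect_equal(nchar(g$sequences[["chr1"]]), 2e6)
  one_mb <- substr(g$sequences[["chr1"]], 1, 1e6)
  gc <- sum(strsplit(one_mb, "")[[1]] %in% c("G", "C")) / 1e6
  expect_lt(abs(gc - cfg$gc_content), 0.02)
  expect_equal(nrow(g$genes), cfg$n_genes)
  expect_false(any(duplicated(paste(g$genes$chrom, g$genes$tss))))
  expect_true(all(g$genes$tss == ifelse(g$genes$strand == "+",
                                        g$genes$start, g$genes$end - 1)))
  g0 <- generate_genome(tiny(n_genes = 0))
  expect_equal(nrow(g0$genes), 0)
})

test_that("planted peak truth matches the configured design", {
  cfg <- tiny()
  g <- generate_genome(cfg, include_sequence = FALSE)
  p <- generate_peak_sets(cfg, g)
  tr <- p$truth
  expect_equal(sum(tr$label == "lost"), cfg$n_lost_regions)
  expect_equal(sum(tr$label == "gained"), cfg$n_gained_regions)
  expect_equal(sum(tr$label == "shared"), cfg$n_shared_peaks)
  expect_true(all(tr$n_case_samples[tr$label == "gained"] >=
                  cfg$gained_region_min_cases))
  expect_equal(length(p$peak_sets), cfg$n_cases_regions + 1)
  # zero planted losses produce zero lost labels end to end
  p0 <- generate_peak_sets(tiny(n_lost_regions = 0), g)
  segs0 <- classify_segments(atomic_segments(p0$peak_sets), "control")
  expect_equal(sum(segs0$label == "lost"), 0)
})

test_that("noise-free peak sets are recovered exactly by classification", {
  cfg <- tiny()
  g <- generate_genome(cfg, include_sequence = FALSE)
  p <- generate_peak_sets(cfg, g)
  segs <- classify_segments(atomic_segments(p$peak_sets), p$control_sample)
  key <- function(d) paste(d$chrom, d$start, d$end)
  for (lab in c("lost", "gained"))
    expect_setequal(key(segs[segs$label == lab, ]),
                    key(p$truth[p$truth$label == lab, ]))
})

test_that("increasing dropout degrades gained-region recall", {
  g <- generate_genome(tiny(), include_sequence = FALSE)
  recall_at <- function(drop, seed) {
    cfg <- tiny(seed = seed, dropout_prob = drop)
    p <- generate_peak_sets(cfg, g)
    segs <- classify_segments(atomic_segments(p$peak_sets), "control")
    key <- function(d) paste(d$chrom, d$start, d$end)
    mean(key(p$truth[p$truth$label == "gained", ]) %in%
         key(segs[segs$label == "gained", ]))
  }
  rec <- vapply(c(0, 0.25, 0.5), function(d)
    mean(vapply(1:3, function(s) recall_at(d, s), 0)), 0)
  expect_equal(rec[1], 1)
  expect_true(all(diff(rec) < 0))
})

test_that("planted loops carry consistent spans, classes and hubs", {
  cfg <- tiny()
  g <- generate_genome(cfg, include_sequence = FALSE)
  l <- generate_loop_sets(cfg, g)
  tr <- l$truth
  expect_equal(sum(tr$label == "lost"), cfg$n_lost_loops)
  expect_equal(sum(tr$label == "gained"), cfg$n_gained_loops)
  expect_equal(tr$span, loop_span(tr))
  # configured gained P-P share, exactly as planted
  expect_equal(mean(tr$class[tr$label == "gained"] == "P-P"),
               round(cfg$gained_pp_fraction * cfg$n_gained_loops) /
                 cfg$n_gained_loops)
  # hubs exist and group >= 2 gained loops each
  hubs <- table(tr$hub[tr$label == "gained"])
  expect_true(length(hubs) > 0 && all(hubs >= 2))
  # classes verified against promoter windows
  pw <- promoter_windows(g$genes)
  a_is_p <- overlaps_any(data.frame(chrom = tr$chrom, start = tr$start1,
                                    end = tr$end1), pw)
  b_is_p <- overlaps_any(data.frame(chrom = tr$chrom, start = tr$start2,
                                    end = tr$end2), pw)
  expect_equal(ifelse(a_is_p & b_is_p, "P-P",
                      ifelse(a_is_p | b_is_p, "P-E", "E-E")), tr$class)
})

test_that("negative-binomial counts match their target moments", {
  cfg <- synth_config(seed = 8, n_genes_counts = 1, n_core_degs = 0,
                      n_sporadic_degs = 0, n_replicates = 3)
  set.seed(8)
  mu <- 300; disp <- cfg$nb_dispersion
  draws <- rnbinom(10000, mu = mu, size = 1 / disp)
  expect_lt(abs(mean(draws) - mu) / mu, 0.05)
  expect_lt(abs(var(draws) - (mu + disp * mu^2)) / (mu + disp * mu^2), 0.05)
  ex <- generate_counts(tiny())
  expect_equal(dim(ex$counts),
               c(600, (tiny()$n_cases_regions + 1) * 3))
  expect_equal(length(ex$truth$core_degs), tiny()$n_core_degs)
  # forced genes always land in the core truth
  forced <- c("gx1", "gx2")
  exf <- generate_counts(tiny(), gene_ids = c(paste0("g", 1:100), forced),
                         forced_core = forced)
  expect_true(all(forced %in% exf$truth$core_degs))
})

test_that("planted motifs are exclusive and spacings have exact medians", {
  cfg <- tiny()
  study <- generate_synthetic_study(cfg)
  sp <- study$motifs$spacings
  expect_equal(unique(sp$spacing[sp$role == "common"]), cfg$target_spacing)
  expect_equal(median(sp$spacing[sp$role == "background"]),
               cfg$background_spacing_median)
  # scrubbing + planting: consensus occurs exactly at planted positions
  for (m in c("motif_a", "motif_b")) {
    word <- if (m == "motif_a") cfg$motif_a_consensus else cfg$motif_b_consensus
    found <- unlist(lapply(names(study$genome$sequences), function(ch) {
      hit <- gregexpr(word, study$genome$sequences[[ch]], fixed = TRUE)[[1]]
      if (hit[1] < 0) numeric(0) else as.numeric(hit) - 1
    }))
    expect_setequal(found, study$truth$motifs$hits$start[
      study$truth$motifs$hits$motif_id == m])
  }
})

test_that("truth files round-trip and reject corrupted schemas", {
  study <- generate_synthetic_study(tiny())
  p <- tempfile(fileext = ".json")
  write_truth(study$truth, p)
  back <- read_truth(p)
  expect_equal(back$regions$region_id, study$truth$regions$region_id)
  expect_equal(back$loops$span, study$truth$loops$span)
  expect_equal(sort(back$degs$core_degs), sort(study$truth$degs$core_degs))
  bad <- jsonlite::fromJSON(p, simplifyVector = TRUE)
  bad$loops <- NULL
  p2 <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, p2, auto_unbox = TRUE)
  expect_error(read_truth(p2), "missing section")
})
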