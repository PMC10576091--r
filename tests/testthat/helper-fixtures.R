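# Shared fixtures for the test suite: small random generators and an
# independent per-base presence oracle for the segmentation code.

random_interval_set <- function(n, chrom = "chrT", max_pos = 100000,
                                max_width = 5000) {
  if (n == 0)
    return(genomic_intervals(character(), numeric(), numeric()))
  start <- sample.int(max_pos - max_width, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  genomic_intervals(chrom, start, start + width)
}

# per-base presence matrix oracle (single chromosome, positions 1..L are
# bases 0..L-1)
presence_by_base <- function(interval_sets, L) {
  ns <- length(interval_sets)
  m <- matrix(FALSE, L, ns, dimnames = list(NULL, names(interval_sets)))
  for (s in seq_len(ns)) {
    d <- interval_sets[[s]]
    for (i in seq_len(nrow(d)))
      m[(d$start[i] + 1):min(d$end[i], L), s] <- TRUE
  }
  m
}

segments_to_base_matrix <- function(cs, L) {
  m <- matrix(FALSE, L, length(cs$samples),
              dimnames = list(NULL, cs$samples))
  segs <- cs$segments
  for (i in seq_len(nrow(segs)))
    for (s in which(cs$presence[i, ]))
      m[(segs$start[i] + 1):min(segs$end[i], L), s] <- TRUE
  m
}

write_temp_lines <- function(lines) {
  p <- tempfile()
  writeLines(lines, p)
  p
}
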