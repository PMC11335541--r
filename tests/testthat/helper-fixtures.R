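# Shared fixtures: small simulated datasets and truth-table accounting.

small_scfg <- function(...) {
  sim_config(
    n_animals = 3L, molecules_per_animal = 40L,
    error_rate = 0, nonfunctional_fraction = 0, shared_fraction = 0,
    library_sizes = c(SP = 1L, "LRR-NT" = 8L, LRR1 = 6L, LRRv = 30L,
                      CP = 5L, "LRR-CT" = 9L, stalk = 1L),
    ...
  )
}

small_sim <- function(seed = 7, scfg = small_scfg()) {
  lib <- build_cassette_library(scfg, seed = seed)
  tx <- simulate_repertoire(lib, scfg, seed = seed + 1L)
  rd <- simulate_reads(tx, scfg, seed = seed + 2L)
  list(lib = lib, tx = tx, reads = rd$reads, truth = rd$truth,
       umi = rd$molecule_umi, scfg = scfg)
}

# Expected subunit spans (0-based half-open) of an error-free simulated
# transcript, from its cassette composition.
truth_spans <- function(lrrv_count, ct_core_length) {
  k <- lrrv_count
  core <- ct_core_length
  ct_start <- 81L + 24L * k
  ct_len <- core + 22L
  list(
    sp = c(0L, 21L), lrr_nt = c(21L, 52L), lrr1 = c(52L, 70L),
    lrrv = lapply(seq_len(k), function(j) c(70L + 24L * (j - 1L), 70L + 24L * j)),
    cp = c(70L + 24L * k, 81L + 24L * k),
    lrr_ct = c(ct_start, ct_start + ct_len),
    core_loop = c(ct_start + 14L, ct_start + 14L + core),
    extended_loop = c(ct_start + 10L, ct_start + 17L + core),
    stalk = c(ct_start + ct_len, ct_start + ct_len + 87L)
  )
}

span_vec <- function(s) c(s$start, s$end)

# TRUE iff every span of an annotation equals the truth layout.
spans_match_truth <- function(ann, lrrv_count, ct_core_length) {
  ts <- truth_spans(lrrv_count, ct_core_length)
  if (!identical(ann$lrrv_count, as.integer(lrrv_count))) return(FALSE)
  for (nm in c("sp", "lrr_nt", "lrr1", "cp", "lrr_ct",
               "core_loop", "extended_loop", "stalk")) {
    if (!identical(span_vec(ann$spans[[nm]]), ts[[nm]])) return(FALSE)
  }
  identical(lapply(ann$spans$lrrv, span_vec), ts$lrrv)
}

# Expectation wrapper with per-span diagnostics for single records.
expect_spans_match_truth <- function(ann, lrrv_count, ct_core_length) {
  ts <- truth_spans(lrrv_count, ct_core_length)
  expect_identical(ann$lrrv_count, as.integer(lrrv_count))
  for (nm in c("sp", "lrr_nt", "lrr1", "cp", "lrr_ct",
               "core_loop", "extended_loop", "stalk")) {
    expect_identical(span_vec(ann$spans[[nm]]), ts[[nm]],
                     label = paste("span", nm))
  }
  expect_identical(lapply(ann$spans$lrrv, span_vec), ts$lrrv)
}

# Truth-table accounting of UMI collisions: molecules whose (sample, UMI)
# bin contains more than one distinct insert are discarded whole by the
# collapse step.
flag_conflicted_bins <- function(tx, umi) {
  key <- paste(tx$sample_id, umi)
  n_distinct <- tapply(tx$nt, key, function(x) length(unique(x)))
  tx$conflicted <- key %in% names(n_distinct)[n_distinct > 1]
  tx
}

random_peptides <- function(n, lengths = 5:40) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  vapply(seq_len(n), function(i) {
    L <- lengths[sample.int(length(lengths), 1L)]
    paste(sample(aa, L, replace = TRUE), collapse = "")
  }, character(1))
}

# Substitute k distinct positions of a string with a different letter.
mutate_positions <- function(x, positions, to = "G", alt = "H") {
  for (p in positions) {
    cur <- substr(x, p, p)
    substr(x, p, p) <- if (cur == to) alt else to
  }
  x
}
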