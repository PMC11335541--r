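test_that("gravy and polarity match direct table lookups", {
  expect_equal(gravy("LLLL"), 3.8)
  for (r in names(aa_hydropathy)) {
    expect_identical(gravy(r), unname(aa_hydropathy[r]))
    expect_identical(polarity(r), unname(aa_polarity[r]))
  }
  expect_identical(polarity("GG"), unname(aa_polarity["G"]))

  # 1000 random peptides against an independent lookup-and-average
  set.seed(410)
  peps <- random_peptides(1000)
  oracle <- function(x, scale) vapply(strsplit(x, "", fixed = TRUE),
                                      function(ch) sum(scale[ch]) / length(ch),
                                      numeric(1))
  expect_equal(gravy(peps), oracle(peps, aa_hydropathy), tolerance = 1e-12)
  expect_equal(polarity(peps), oracle(peps, aa_polarity), tolerance = 1e-12)

  # concatenation: gravy(AB) is the length-weighted mean
  a <- "LLLL"
  b <- "RRRRRR"
  expect_equal(gravy(paste0(a, b)),
               (4 * gravy(a) + 6 * gravy(b)) / 10)

  expect_error(gravy("LLXZ"), "unknown residue")
  expect_error(gravy(""), "empty")
})

test_that("frequency matrix is column-stochastic with majority consensus", {
  M <- frequency_matrix(rep("ACDE", 7))
  expect_true(all(abs(colSums(M) - 1) < 1e-12))
  expect_identical(attr(M, "consensus"), c("A", "C", "D", "E"))
  expect_identical(sum(M == 1), 4L)

  # one differing position splits 0.5/0.5
  M2 <- frequency_matrix(c("AAAA", "AACA"))
  expect_equal(M2["A", 3], 0.5)
  expect_equal(M2["C", 3], 0.5)

  # simulated LRRv units: conserved leucine positions have frequency 1
  s <- small_sim()
  units <- s$lib$LRRv
  M3 <- frequency_matrix(units)
  off <- vlrbkit:::LRRV_MOTIF_OFFSET
  cons <- vlrb_config()$lrrv_conserved
  for (ix in cons$index) expect_equal(M3["L", off + ix + 1], 1.0)
  expect_true(all(abs(colSums(M3) - 1) < 1e-12))

  expect_error(frequency_matrix(c("AA", "AAA")), "equal length")
})

test_that("loop hydropathy split partitions at the threshold", {
  high <- strrep("L", 12)          # gravy 3.8
  low <- strrep("R", 12)           # gravy -4.5
  res <- split_loops_by_hydropathy(c(high, low), threshold = 0.35)
  expect_identical(res$high$loop, high)
  expect_identical(res$low$loop, low)

  set.seed(411)
  loops <- random_peptides(200, lengths = 8:25)
  res <- split_loops_by_hydropathy(loops)
  expect_identical(nrow(res$high) + nrow(res$low), 200L)
  expect_true(all(res$high$score >= 0.35))
  expect_true(all(res$low$score < 0.35))

  empty <- split_loops_by_hydropathy(character(0))
  expect_identical(nrow(empty$high), 0L)
  expect_identical(nrow(empty$low), 0L)
})

test_that("positional LRRv statistics match a brute-force recount", {
  s <- small_sim()
  anns <- lapply(which(s$tx$functional), function(i) {
    annotate_protein(s$tx$protein[i])
  })
  stats_tab <- positional_subunit_stats(anns)
  expect_true("LRRve" %in% stats_tab$group)

  # brute-force group-by from the truth table
  units <- do.call(rbind, lapply(seq_along(anns), function(j) {
    a <- anns[[j]]
    k <- a$lrrv_count
    data.frame(seq = vapply(a$spans$lrrv, function(sp) span_seq(a$protein, sp),
                            character(1)),
               grp = ifelse(seq_len(k) == k, "LRRve", paste0("LRRv", seq_len(k))),
               stringsAsFactors = FALSE)
  }))
  for (g in unique(units$grp)) {
    scores <- gravy(units$seq[units$grp == g])
    row <- stats_tab[stats_tab$group == g, ]
    expect_equal(row$hydropathy_mean, mean(scores), label = g)
    expect_equal(row$n, sum(units$grp == g), label = g)
  }

  # molecules with a single unit contribute only to the LRRve group
  k1 <- sum(s$tx$lrrv_count[s$tx$functional] == 1)
  n_lrrve <- stats_tab$n[stats_tab$group == "LRRve"]
  expect_identical(n_lrrve, length(anns))
  expect_identical(sum(stats_tab$n) - n_lrrve,
                   sum(s$tx$lrrv_count[s$tx$functional]) - length(anns))
  expect_gt(k1, 0L)

  # identical units give zero SD
  same <- list(synthetic_annotation(), synthetic_annotation())
  st <- positional_subunit_stats(same)
  expect_true(all(st$hydropathy_sd == 0))
})

test_that("length distributions concentrate on the 24-aa lattice", {
  s <- small_sim()
  anns <- lapply(which(s$tx$functional), function(i) {
    annotate_protein(s$tx$protein[i])
  })
  ld <- length_distributions(anns)

  # LRRv-count histogram equals the simulator's drawn distribution
  expect_identical(as.vector(ld$lrrv_count),
                   as.vector(table(s$tx$lrrv_count[s$tx$functional])))

  # core-loop histogram equals the truth
  expect_identical(as.vector(ld$core_loop_length),
                   as.vector(table(s$tx$ct_core_length[s$tx$functional])))

  # length lattice: without length noise the core-loop spread is the only
  # off-lattice term, so the modal residue class carries the modal core length
  expect_equal(ld$lattice_fraction,
               max(table(nchar(s$tx$protein[s$tx$functional]) %% 24)) /
                 sum(s$tx$functional))

  # single record: SD reported as 0
  one <- length_distributions(list(synthetic_annotation()))
  expect_identical(one$summary$sd, c(0, 0, 0))
})
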