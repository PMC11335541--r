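cfg <- vlrb_config()

test_that("consensus filter charges the first failing step in order", {
  ok <- synthetic_annotation()
  res <- apply_consensus_filter(list(ok), cfg)
  expect_identical(length(res$retained), 1L)
  expect_identical(sum(res$report$removed), 0L)

  # a 23-aa LRRv is charged to step 12a
  bad_lrrv <- synthetic_annotation(lrrv = c(24L, 23L))
  res <- apply_consensus_filter(list(bad_lrrv), cfg)
  expect_identical(res$report$removed[res$report$step == "12a"], 1L)
  expect_identical(length(res$retained), 0L)

  # combined violations are charged to the first failing step only
  double_bad <- synthetic_annotation(lrr_nt = 30L, lrrv = c(23L))
  res <- apply_consensus_filter(list(double_bad), cfg)
  expect_identical(res$report$removed[res$report$step == "12a"], 1L)
  expect_identical(res$report$removed[res$report$step == "12c"], 0L)

  # each step fires for its own length violation
  per_step <- list(
    "12b" = synthetic_annotation(lrr1 = 17L),
    "12c" = synthetic_annotation(lrr_nt = 32L),
    "12d" = synthetic_annotation(stalk = 86L),
    "12e" = synthetic_annotation(sp = 20L),
    "12f" = synthetic_annotation(cp = 12L)
  )
  for (step in names(per_step)) {
    r <- apply_consensus_filter(per_step[step], cfg)$report
    expect_identical(r$removed[r$step == step], 1L, label = step)
  }

  # conservation: input = retained + sum of rejections
  mixed <- c(list(ok, ok), per_step, list(bad_lrrv))
  res <- apply_consensus_filter(mixed, cfg)
  expect_identical(length(mixed),
                   length(res$retained) + sum(res$report$removed))

  expect_error(apply_consensus_filter(list(structure(list(status = "no_lrr1"),
                                                     class = "vlrb_annotation"))),
               "annotated")
})

test_that("length screens retain exactly the canonical subunit lengths", {
  # CP lengths 9..13: only 11 survives
  res <- apply_consensus_filter(lapply(9:13, function(L) synthetic_annotation(cp = L)), cfg)
  expect_identical(length(res$retained), 1L)
  expect_identical(span_length(res$retained[[1]]$spans$cp), 11L)

  # LRR-NT lengths 28..34: only 31 survives
  res <- apply_consensus_filter(lapply(28:34, function(L) synthetic_annotation(lrr_nt = L)), cfg)
  expect_identical(length(res$retained), 1L)
  expect_identical(span_length(res$retained[[1]]$spans$lrr_nt), 31L)

  # stalk lengths 84..90: only 87 survives
  res <- apply_consensus_filter(lapply(84:90, function(L) synthetic_annotation(stalk = L)), cfg)
  expect_identical(length(res$retained), 1L)
  expect_identical(span_length(res$retained[[1]]$spans$stalk), 87L)
})

test_that("greedy clustering follows the CD-HIT conventions", {
  # n identical sequences: one cluster of size n
  cs <- greedy_cluster(rep("PEPTIDEPEPTIDE", 5), 0.8)
  expect_identical(length(cs$clusters), 1L)
  expect_identical(length(cs$clusters[[1]]$members), 5L)

  # two 20-aa sequences differing at one position at threshold 0.95
  a <- strrep("AC", 10)
  b <- mutate_positions(a, 7)
  cs <- greedy_cluster(c(a, b), 0.95)
  expect_identical(length(cs$clusters), 1L)

  # at threshold 1.0 the cluster count equals the number of distinct strings
  set.seed(406)
  seqs <- sample(random_peptides(20, lengths = 10:20), 60, replace = TRUE)
  cs <- greedy_cluster(seqs, 1.0)
  expect_identical(length(cs$clusters), length(unique(seqs)))

  # every member reaches the threshold identity to its representative
  cs <- greedy_cluster(random_sequence_family(40), 0.75)
  for (cl in cs$clusters) {
    mem_seqs <- cs$assignment$sequence[cs$assignment$id %in% cl$members]
    for (m in mem_seqs) {
      expect_gte(seq_identity(m, cl$representative, denom = "shorter"), 0.75)
    }
  }

  expect_identical(length(greedy_cluster(character(0), 0.9)$clusters), 0L)
  expect_error(greedy_cluster("A", 0), "threshold")
})

test_that("cluster-size CDF matches an independent recount", {
  cs <- greedy_cluster(c(rep("AAAA", 3), "TTTT"), 1.0)
  cdf <- cluster_size_cdf(cs)
  expect_identical(cdf$rank, 1:2)
  expect_identical(cdf$size, c(3L, 1L))
  expect_equal(cdf$cum_fraction, c(0.75, 1.0))

  # all singletons: the diagonal k/n
  singles <- random_peptides(8, lengths = 25:30)
  cdf <- cluster_size_cdf(greedy_cluster(singles, 1.0))
  expect_equal(cdf$cum_fraction, (1:8) / 8)

  # skewed set: recount by brute force
  set.seed(407)
  fam <- random_sequence_family(60)
  cs <- greedy_cluster(fam, 0.85)
  cdf <- cluster_size_cdf(cs)
  sizes <- sort(table(cs$assignment$cluster), decreasing = TRUE)
  expect_equal(cdf$cum_fraction, unname(cumsum(sizes) / 60))
  expect_equal(cdf$cum_fraction[nrow(cdf)], 1.0)
})

test_that("a stalk-like set at 95 percent lands in a single cluster", {
  # invariant subunit with up to ~2 % substitution noise
  set.seed(408)
  stalk <- build_cassette_library(small_scfg(), seed = 77)$stalk[1]
  noisy <- vapply(1:50, function(i) {
    k <- sample(0:2, 1)
    if (k == 0) stalk else mutate_positions(stalk, sample(87, k))
  }, character(1))
  sweep <- threshold_sweep(noisy, c(0.95, 1.0), loci_n = 1L)
  expect_identical(sweep$n_clusters[sweep$threshold == 0.95], 1L)
  expect_equal(sweep$pct_in_top_n[sweep$threshold == 0.95], 100)
  expect_gt(sweep$n_clusters[sweep$threshold == 1.0], 1L)

  # single unique sequence: one cluster, 100 % in top-1 at any threshold
  one <- threshold_sweep(rep("STALKSTALK", 4), c(0.65, 1.0), loci_n = 1L)
  expect_identical(one$n_clusters, c(1L, 1L))
  expect_equal(one$pct_in_top_n, c(100, 100))
})

test_that("sharing counts identical proteins across animals", {
  everywhere <- "SHAREDPROTEIN"
  per_animal <- lapply(1:6, function(i) c(everywhere, sprintf("PRIVATE%d", i)))
  names(per_animal) <- paste0("larva", 1:6)
  sh <- shared_sequences(per_animal)
  expect_identical(sh$k, 2:6)
  expect_identical(sh$count, rep(1L, 5))
  expect_equal(sh$fraction, rep(1 / 12, 5))

  # disjoint repertoires share nothing
  disjoint <- lapply(1:3, function(i) sprintf("P%d_%d", i, 1:4))
  expect_identical(shared_sequences(disjoint)$count, c(0L, 0L))

  # monotone in k
  set.seed(409)
  pool <- random_peptides(30, lengths = 8:12)
  rand <- lapply(1:5, function(i) sample(pool, 12))
  sh <- shared_sequences(rand)
  expect_true(all(diff(sh$count) <= 0))

  expect_error(shared_sequences(list(c("A"))), "at least 2")
})

test_that("sharing injected by the simulator is recovered from the truth table", {
  scfg <- small_scfg(shared_fraction = 0.1)
  lib <- build_cassette_library(scfg, seed = 41)
  tx <- simulate_repertoire(lib, scfg, seed = 42)
  per_animal <- lapply(split(tx$protein, tx$sample_id), unique)
  sh <- shared_sequences(per_animal)
  truth_tab <- table(unlist(lapply(split(tx$protein, tx$sample_id), unique)))
  expect_identical(sh$count,
                   vapply(2:3, function(k) sum(truth_tab >= k), integer(1)))
  expect_gt(sh$count[1], 0L)
})
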