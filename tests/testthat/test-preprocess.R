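cfg <- vlrb_config()

# A hand-built, error-free amplicon read for one transcript.
build_read <- function(nt, sample_id = "larva1", umi = strrep("A", 12),
                       conf = cfg) {
  bc <- conf$barcode_table[[sample_id]]
  paste0("TAT", bc, nt,
         revcomp(paste0("TAT", bc, conf$rev_const, umi, conf$stalk_anneal)))
}

test_that("error-free simulated reads demultiplex to the truth table", {
  s <- small_sim()
  dem <- demultiplex(s$reads, cfg)
  expect_identical(nrow(dem$rejected), 0L)
  m <- match(dem$records$read_id, s$truth$read_id)
  expect_false(anyNA(m))
  expect_identical(dem$records$sample_id, s$truth$sample_id[m])
  expect_identical(dem$records$umi, s$truth$umi[m])
  tx_nt <- s$tx$nt[match(s$truth$transcript_id[m], s$tx$transcript_id)]
  expect_identical(dem$records$insert, tx_nt)
})

test_that("orientation symmetry and exact-primer rejection rules hold", {
  s <- small_sim()
  nt <- s$tx$nt[1]
  read <- build_read(nt, umi = "ACGTACGTACGT")
  rec <- orient_and_trim(read, cfg)
  expect_identical(rec$sample_id, "larva1")
  expect_identical(rec$umi, "ACGTACGTACGT")
  expect_identical(rec$insert, nt)

  # reverse-complemented copy gives the identical record
  rec_rc <- orient_and_trim(revcomp(read), cfg)
  rec_rc$read_id <- rec$read_id
  expect_identical(rec_rc, rec)

  reason_of <- function(r) {
    rej <- orient_and_trim(r, cfg)
    expect_s3_class(rej, "vlrb_rejection")
    rej$reason
  }

  # one substitution inside the forward-primer constant segment: rejected
  bad_fwd <- mutate_positions(read, 15)  # within positions 10..27
  expect_identical(reason_of(bad_fwd), "no_fwd_primer")

  # one substitution inside the reverse-primer constant segment: rejected
  L <- nchar(read)
  bad_rev <- mutate_positions(read, L - 12)  # within rc(rev_const)
  expect_identical(reason_of(bad_rev), "no_rev_primer")

  # barcode disagreement between the two ends
  bad_bc <- read
  substr(bad_bc, 4, 9) <- cfg$barcode_table[["larva2"]]
  expect_identical(reason_of(bad_bc), "barcode_mismatch")

  # barcode absent from the table (changed coherently at both ends)
  alien <- "TTTTTT"
  bad_tab <- read
  substr(bad_tab, 4, 9) <- alien
  substr(bad_tab, L - 8, L - 3) <- revcomp(alien)
  expect_identical(reason_of(bad_tab), "barcode_mismatch")

  expect_identical(reason_of(""), "no_fwd_primer")
})

test_that("UMI bins collapse by the 99 percent identity rule", {
  set.seed(405)
  nt <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  recs <- function(inserts, umi = strrep("T", 12)) {
    data.frame(read_id = sprintf("r%d", seq_along(inserts)),
               sample_id = "larva1", umi = umi, insert = inserts,
               stringsAsFactors = FALSE)
  }

  # three identical reads, one UMI -> one molecule with read_count 3
  res <- collapse_umi_bins(recs(rep(nt, 3)), cfg)
  expect_identical(nrow(res$molecules), 1L)
  expect_identical(res$molecules$read_count, 3L)
  expect_identical(res$molecules$consensus_nt, nt)

  # one substitution in 300 nt (99.7 % identity): collapsed into one molecule
  nt_mut <- mutate_positions(nt, 57)
  res <- collapse_umi_bins(recs(c(nt, nt_mut)), cfg)
  expect_identical(nrow(res$molecules), 1L)
  expect_identical(res$molecules$read_count, 2L)
  # column tie resolves to the lexicographically smaller member's residue
  expect_identical(res$molecules$consensus_nt, min(nt, nt_mut))

  # 3 % divergence: the whole bin is discarded
  nt_far <- mutate_positions(nt, seq(5, 300, length.out = 9))
  res <- collapse_umi_bins(recs(c(nt, nt_far)), cfg)
  expect_identical(nrow(res$molecules), 0L)
  expect_identical(res$discarded_bins, 1L)
  expect_identical(res$discarded_reads, 2L)

  # majority vote: 2 vs 1 at the mutated column
  res <- collapse_umi_bins(recs(c(nt, nt, nt_mut)), cfg)
  expect_identical(res$molecules$consensus_nt, nt)

  # idempotence: collapsing the collapsed output changes nothing
  s <- small_sim()
  dem <- demultiplex(s$reads, cfg)
  once <- collapse_umi_bins(dem$records, cfg)
  again <- collapse_umi_bins(
    data.frame(read_id = once$molecules$umi, sample_id = once$molecules$sample_id,
               umi = once$molecules$umi, insert = once$molecules$consensus_nt,
               stringsAsFactors = FALSE), cfg)
  expect_identical(again$molecules[, c("sample_id", "umi", "consensus_nt")],
                   once$molecules[, c("sample_id", "umi", "consensus_nt")])
})

test_that("1-nt UMI neighbors resolve to the best-supported molecule", {
  mol <- function(umi, count, nt = strrep("ACGT", 30), sample = "larva1") {
    data.frame(sample_id = sample, umi = umi, consensus_nt = nt,
               read_count = count, stringsAsFactors = FALSE)
  }

  # identical inserts, UMIs 1 apart, counts 5 vs 1 -> keep the count-5 one
  m <- rbind(mol("AAAAAAAAAAAA", 5L), mol("AAAAAAAAAAAC", 1L))
  res <- remove_umi_neighbors(m, cfg)
  expect_identical(res$molecules$umi, "AAAAAAAAAAAA")
  expect_identical(res$removed$umi, "AAAAAAAAAAAC")

  # UMIs 2 apart: both kept
  m <- rbind(mol("AAAAAAAAAAAA", 5L), mol("AAAAAAAAAACC", 1L))
  expect_identical(nrow(remove_umi_neighbors(m, cfg)$molecules), 2L)

  # different inserts: both kept even at distance 1
  m <- rbind(mol("AAAAAAAAAAAA", 5L),
             mol("AAAAAAAAAAAC", 1L, nt = strrep("TGCA", 30)))
  expect_identical(nrow(remove_umi_neighbors(m, cfg)$molecules), 2L)

  # a chain A-B-C collapses to the single best-supported member
  m <- rbind(mol("AAAAAAAAAAAA", 3L), mol("AAAAAAAAAAAC", 2L),
             mol("AAAAAAAAAACC", 1L))
  res <- remove_umi_neighbors(m, cfg)
  expect_identical(res$molecules$umi, "AAAAAAAAAAAA")
  expect_identical(sort(res$removed$umi), c("AAAAAAAAAAAC", "AAAAAAAAAACC"))

  # read-count tie keeps the lexicographically smaller UMI
  m <- rbind(mol("AAAAAAAAAAAC", 2L), mol("AAAAAAAAAAAA", 2L))
  expect_identical(remove_umi_neighbors(m, cfg)$molecules$umi, "AAAAAAAAAAAA")
})
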