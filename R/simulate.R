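# Synthetic-data generator: cassette libraries, cassette-assembled VLRB
# transcripts, and barcoded/UMI-tagged amplicon reads with configurable
# errors, so every downstream stage is testable without deposited data.
#
# A mature VLRB is assembled SP -> LRR-NT -> LRR1 -> LRRv x (k-1) -> LRRve ->
# CP -> LRR-CT -> stalk, with 1..9 variable units (the last one being the
# LRRve).  Cassette counts default to the published genomic locus counts.

# One fixed codon per amino acid (no codon-usage model).  The first six SP
# residues VDQVDR reverse-translate to the forward-primer annealing segment
# GTGGATCAAGTGGATCGC, anchoring the reading frame of the trimmed insert.
CODON_TABLE <- c(
  A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGT",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAT",
  P = "CCT", Q = "CAA", R = "CGC", S = "TCT", T = "ACT", V = "GTG",
  W = "TGG", Y = "TAT"
)
STOP_CODON <- "TAA"

# Filler alphabet for non-conserved cassette positions: the 15 residues that
# are neither motif-conserved letters (L, N, F) nor loop anchors (W, C), so
# motif hits and anchor pairs occur exactly where the architecture puts them.
FILLER_AA <- c("A", "D", "E", "G", "H", "I", "K", "M", "P", "Q",
               "R", "S", "T", "V", "Y")

# Offset of the LRRv motif within a 24-aa variable cassette.
LRRV_MOTIF_OFFSET <- 4L
# LRR-CT cassette geometry: residues before the anchor W and after the anchor C.
CT_PRE <- 10L
CT_POST <- 5L

#' Reverse-translate a protein with the fixed codon table
#' @param protein Amino-acid string (canonical residues).
#' @return Nucleotide string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein) {
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), names(CODON_TABLE))
  if (length(bad)) stop("cannot reverse-translate residue(s): ", paste(bad, collapse = ""))
  paste(CODON_TABLE[ch], collapse = "")
}

# Probability vector over 1..kmax for a truncated geometric with given mean.
lrrv_count_probs <- function(mean, kmax = 9L) {
  k <- seq_len(kmax)
  if (mean <= 1 || mean >= (1 + kmax) / 2 + kmax / 2) stop("unattainable lrrv mean")
  f <- function(q) sum(k * q^(k - 1)) / sum(q^(k - 1)) - mean
  q <- stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
  p <- q^(k - 1)
  p / sum(p)
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 6 animals, a truncated-geometric
#' LRRv-count distribution on 1..9 with mean 2.2, HiFi-scale substitution
#' errors (0.1 %), sparse PCR duplication (1 + Poisson(0.4) reads per
#' molecule), 1.7 % of transcripts shared verbatim between animals, and a 5 %
#' nonfunctional fraction (in-frame stop or 1-nt deletion).
#'
#' @param ... Named overrides (`n_animals`, `molecules_per_animal`,
#'   `lrrv_mean`, `lrrv_max`, `pcr_dup_lambda`, `error_rate`,
#'   `nonfunctional_fraction`, `shared_fraction`, `library_sizes`,
#'   `core_loop_range`).
#' @return A list of class `vlrb_sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_animals = 6L,
    molecules_per_animal = 1000L,
    lrrv_mean = 2.2,
    lrrv_max = 9L,
    pcr_dup_lambda = 0.4,
    error_rate = 0.001,
    nonfunctional_fraction = 0.05,
    shared_fraction = 0.017,
    library_sizes = c(SP = 1L, "LRR-NT" = 79L, LRR1 = 66L, LRRv = 601L,
                      CP = 29L, "LRR-CT" = 91L, stalk = 1L),
    core_loop_range = c(10L, 25L)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown sim config field: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  frs <- c(cfg$error_rate, cfg$nonfunctional_fraction, cfg$shared_fraction)
  if (any(frs < 0 | frs > 1)) stop("fractions must lie in [0, 1]")
  structure(cfg, class = "vlrb_sim_config")
}

random_filler <- function(n) {
  paste(sample(FILLER_AA, n, replace = TRUE), collapse = "")
}

# n distinct random cassettes produced by `make` (a function of no arguments).
distinct_cassettes <- function(n, make) {
  out <- character(0)
  while (length(out) < n) {
    out <- unique(c(out, vapply(seq_len(n - length(out)), function(i) make(), character(1))))
  }
  out
}

#' Build a synthetic cassette library
#'
#' Generates amino-acid cassettes for every structural subunit.  Default
#' library sizes follow the published genomic locus counts (SP 1, LRR-NT 79,
#' LRR1 66, LRRv 601, CP 29, LRR-CT 91, stalk 1).  Every LRR1 cassette is
#' 18 aa and carries the 5 conserved LRR1-motif residues; every LRRv cassette
#' is 24 aa with the 4 conserved motif leucines; every LRR-CT cassette
#' contains exactly one W...C anchor pair bracketing a core loop whose length
#' is drawn uniformly from `core_loop_range`; the stalk cassette is 87 aa
#' ending in the diagnostic 30-aa motif.
#'
#' @param scfg A [sim_config()].
#' @param seed Integer seed (mandatory for reproducibility).
#' @param pcfg A [vlrb_config()] supplying motifs and subunit lengths.
#' @return A list of class `vlrb_cassette_library` with one character vector
#'   per subunit, the per-cassette core-loop lengths for LRR-CT, and
#'   `library_sizes`.
#' @export
build_cassette_library <- function(scfg = sim_config(), seed, pcfg = vlrb_config()) {
  sizes <- scfg$library_sizes
  len <- pcfg$subunit_length_spec
  l1c <- pcfg$lrr1_conserved
  lvc <- pcfg$lrrv_conserved
  with_seed(seed, {
    sp <- distinct_cassettes(sizes[["SP"]], function() {
      paste0("VDQVDR", random_filler(len[["SP"]] - 6L))
    })
    lrrnt <- distinct_cassettes(sizes[["LRR-NT"]], function() random_filler(len[["LRR-NT"]]))
    lrr1 <- distinct_cassettes(sizes[["LRR1"]], function() {
      ch <- sample(FILLER_AA, len[["LRR1"]], replace = TRUE)
      ch[l1c$index + 1L] <- l1c$residue
      paste(ch, collapse = "")
    })
    lrrv <- distinct_cassettes(sizes[["LRRv"]], function() {
      ch <- sample(FILLER_AA, len[["LRRv"]], replace = TRUE)
      ch[LRRV_MOTIF_OFFSET + lvc$index + 1L] <- lvc$residue
      paste(ch, collapse = "")
    })
    cp <- distinct_cassettes(sizes[["CP"]], function() random_filler(len[["CP"]]))
    lrrct <- distinct_cassettes(sizes[["LRR-CT"]], function() {
      core <- sample(scfg$core_loop_range[1]:scfg$core_loop_range[2], 1L)
      paste0(random_filler(CT_PRE), "W", random_filler(3L),
             random_filler(core), random_filler(2L), "C",
             random_filler(CT_POST))
    })
    # core-loop length read back from the W...C anchor pair of each cassette
    core_lens <- vapply(lrrct, function(ct) {
      w <- regexpr("W", ct, fixed = TRUE)[1]
      cpos <- w + 6L + regexpr("C", substr(ct, w + 7L, nchar(ct)), fixed = TRUE)[1]
      as.integer(cpos - w - 6L)
    }, integer(1), USE.NAMES = FALSE)
    stalk <- distinct_cassettes(sizes[["stalk"]], function() {
      paste0(random_filler(len[["stalk"]] - nchar(pcfg$stalk_motif)), pcfg$stalk_motif)
    })
    structure(list(
      SP = sp, `LRR-NT` = lrrnt, LRR1 = lrr1, LRRv = lrrv, CP = cp,
      `LRR-CT` = lrrct, ct_core_length = core_lens, stalk = stalk,
      library_sizes = sizes
    ), class = "vlrb_cassette_library")
  })
}

#' Assemble one VLRB protein from cassette indices
#'
#' @param lib A [build_cassette_library()] result.
#' @param sp,lrrnt,lrr1,cp,lrrct,stalk Cassette indices (1-based).
#' @param lrrv Integer vector of LRRv cassette indices, N-terminal first; the
#'   last one is the LRRve.
#' @return Amino-acid string of the mature protein.
#' @export
assemble_protein <- function(lib, sp = 1L, lrrnt = 1L, lrr1 = 1L, lrrv = 1L,
                             cp = 1L, lrrct = 1L, stalk = 1L) {
  if (length(lrrv) < 1L) stop("at least one LRRv cassette is required")
  paste0(lib$SP[sp], lib$`LRR-NT`[lrrnt], lib$LRR1[lrr1],
         paste(lib$LRRv[lrrv], collapse = ""), lib$CP[cp],
         lib$`LRR-CT`[lrrct], lib$stalk[stalk])
}

#' Simulate a ground-truth repertoire
#'
#' Assembles per-animal transcripts by drawing cassettes uniformly and the
#' LRRv count from the configured truncated-geometric distribution; injects
#' `shared_fraction` of transcripts verbatim into a second randomly chosen
#' animal (replacing one of its transcripts, so per-animal totals are
#' unchanged) and makes `nonfunctional_fraction` of molecules nonfunctional
#' by a random in-frame stop codon or a 1-nt deletion placed in the variable
#' body (downstream of the primer-annealing segment, upstream of the stalk
#' coding region).
#'
#' @param lib A cassette library.
#' @param scfg A [sim_config()].
#' @param seed Integer seed.
#' @return A data.frame (one row per molecule) with `transcript_id`,
#'   `sample_id`, `lrrv_count`, `protein` (the intended translation), `nt`
#'   (coding sequence + stop, with any lesion applied), `functional`,
#'   `ct_core_length`, and the cassette indices.
#' @export
simulate_repertoire <- function(lib, scfg = sim_config(), seed) {
  for (su in c("SP", "LRR-NT", "LRR1", "LRRv", "CP", "LRR-CT", "stalk")) {
    if (length(lib[[su]]) == 0L) stop("empty cassette library for subunit ", su)
  }
  probs <- lrrv_count_probs(scfg$lrrv_mean, scfg$lrrv_max)
  n_an <- scfg$n_animals
  n_mol <- scfg$molecules_per_animal
  with_seed(seed, {
    total <- n_an * n_mol
    sample_id <- rep(paste0("larva", seq_len(n_an)), each = n_mol)
    k <- sample(seq_len(scfg$lrrv_max), total, replace = TRUE, prob = probs)
    i_sp <- sample(length(lib$SP), total, replace = TRUE)
    i_nt <- sample(length(lib$`LRR-NT`), total, replace = TRUE)
    i_l1 <- sample(length(lib$LRR1), total, replace = TRUE)
    i_cp <- sample(length(lib$CP), total, replace = TRUE)
    i_ct <- sample(length(lib$`LRR-CT`), total, replace = TRUE)
    i_lv <- lapply(k, function(kk) sample(length(lib$LRRv), kk, replace = TRUE))
    df <- data.frame(
      transcript_id = sprintf("tx%06d", seq_len(total)),
      sample_id = sample_id,
      lrrv_count = k,
      sp = i_sp, lrrnt = i_nt, lrr1 = i_l1, cp = i_cp, lrrct = i_ct,
      stringsAsFactors = FALSE
    )
    df$lrrv_idx <- vapply(i_lv, paste, character(1), collapse = ",")
    df$ct_core_length <- lib$ct_core_length[i_ct]
    df$protein <- vapply(seq_len(total), function(i) {
      assemble_protein(lib, i_sp[i], i_nt[i], i_l1[i], i_lv[[i]], i_cp[i], i_ct[i])
    }, character(1))

    # verbatim sharing between animals
    n_sh <- round(scfg$shared_fraction * total)
    if (n_sh > 0L && n_an >= 2L) {
      src <- sample(total, n_sh)
      for (i in src) {
        target <- sample(setdiff(seq_len(n_an), match(df$sample_id[i], paste0("larva", seq_len(n_an)))), 1L)
        slot <- sample(which(df$sample_id == paste0("larva", target)), 1L)
        copy_cols <- c("lrrv_count", "sp", "lrrnt", "lrr1", "cp", "lrrct",
                       "lrrv_idx", "ct_core_length", "protein")
        df[slot, copy_cols] <- df[i, copy_cols]
      }
    }

    df$nt <- paste0(vapply(df$protein, reverse_translate, character(1), USE.NAMES = FALSE),
                    STOP_CODON)
    df$functional <- TRUE

    # nonfunctional lesions
    n_nf <- round(scfg$nonfunctional_fraction * total)
    if (n_nf > 0L) {
      nf <- sample(total, n_nf)
      kind <- sample(c("stop", "del"), n_nf, replace = TRUE)
      for (j in seq_len(n_nf)) {
        i <- nf[j]
        L <- nchar(df$protein[i])
        if (kind[j] == "stop") {
          # replace a codon in the variable body with an in-frame stop
          codon <- sample(8:(L - 2L), 1L)
          substr(df$nt[i], 3L * codon - 2L, 3L * codon) <- STOP_CODON
        } else {
          # delete one nucleotide upstream of the stalk coding region
          pos <- sample(22:(3L * (L - 87L)), 1L)
          df$nt[i] <- paste0(substr(df$nt[i], 1L, pos - 1L),
                             substr(df$nt[i], pos + 1L, nchar(df$nt[i])))
        }
        df$functional[i] <- FALSE
      }
    }
    rownames(df) <- NULL
    df
  })
}

random_umis <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

apply_substitutions <- function(reads, rate) {
  if (rate <= 0) return(reads)
  bases <- c("A", "C", "G", "T")
  n_err <- stats::rbinom(length(reads), nchar(reads), rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    pos <- sample(length(ch), n_err[i])
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1L), character(1))
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate amplicon reads from a repertoire
#'
#' Each molecule receives a random 12-nt UMI; each read is
#' `TAT + barcode + insert + revcomp(stalk-anneal + UMI + rev-primer-with-
#' barcode)` where the insert is the coding sequence (beginning with the
#' forward-primer annealing segment, which encodes SP residues) plus the stop
#' codon, and the stalk-annealing site lies immediately downstream of the
#' stop.  PCR duplicates share the molecule's UMI and carry independent
#' substitution errors at `error_rate`; about half of the reads are emitted
#' reverse-complemented.
#'
#' @param transcripts Output of [simulate_repertoire()].
#' @param scfg A [sim_config()].
#' @param seed Integer seed.
#' @param pcfg A [vlrb_config()] supplying primers and barcodes.
#' @return A list with `reads` (named character vector, names are read ids)
#'   and `truth` (data.frame `read_id`, `sample_id`, `umi`, `transcript_id`,
#'   `lrrv_count`, `functional`).
#' @export
simulate_reads <- function(transcripts, scfg = sim_config(), seed, pcfg = vlrb_config()) {
  bc <- pcfg$barcode_table
  if (!all(unique(transcripts$sample_id) %in% names(bc))) {
    stop("sample ids without a barcode in the config")
  }
  with_seed(seed, {
    n_mol <- nrow(transcripts)
    umi <- random_umis(n_mol, pcfg$umi_length)
    dups <- 1L + stats::rpois(n_mol, scfg$pcr_dup_lambda)
    mol_of_read <- rep(seq_len(n_mol), dups)
    tail_rc <- revcomp(paste0("TAT", bc[transcripts$sample_id], pcfg$rev_const,
                              umi, pcfg$stalk_anneal))
    template <- paste0("TAT", bc[transcripts$sample_id], transcripts$nt, tail_rc)
    reads <- template[mol_of_read]
    reads <- apply_substitutions(reads, scfg$error_rate)
    flip <- stats::runif(length(reads)) < 0.5
    if (any(flip)) reads[flip] <- revcomp(reads[flip])
    ids <- sprintf("read%07d", seq_along(reads))
    names(reads) <- ids
    truth <- data.frame(
      read_id = ids,
      sample_id = transcripts$sample_id[mol_of_read],
      umi = umi[mol_of_read],
      transcript_id = transcripts$transcript_id[mol_of_read],
      lrrv_count = transcripts$lrrv_count[mol_of_read],
      functional = transcripts$functional[mol_of_read],
      stringsAsFactors = FALSE
    )
    list(reads = reads, truth = truth, molecule_umi = umi)
  })
}

#' Write reads as FASTQ
#'
#' Uniform quality (`I`, Q40) — HiFi reads are modeled as high-accuracy
#' strings.
#'
#' @param reads Named character vector of reads.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::PhredQuality(vapply(nchar(reads), function(n) strrep("I", n), character(1)))
  xq <- Biostrings::QualityScaledDNAStringSet(x, q)
  Biostrings::writeQualityScaledXStringSet(xq, path)
  invisible(path)
}

#' Read sequences from FASTQ or FASTA
#'
#' @param path Input path; format is taken from the extension
#'   (`.fastq`/`.fq` vs anything else), `.gz` accepted.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Construct a synthetic annotation with prescribed subunit lengths
#'
#' Builds a `vlrb_annotation` whose spans are laid out contiguously with the
#' requested subunit lengths, backed by a structurally consistent placeholder
#' protein (motif residues and loop anchors are placed wherever the lengths
#' allow).  Useful for exercising the consensus length filter on controlled
#' off-consensus records that the annotator itself would not produce.
#'
#' @param sp,lrr_nt,lrr1,cp,stalk Subunit lengths in residues.
#' @param lrrv Integer vector of LRRv unit lengths (last unit is the LRRve).
#' @param core_loop Core-loop length; the LRR-CT length follows from it.
#' @param sample_id Sample label attached to the record.
#' @return A `vlrb_annotation` with status `annotated`.
#' @export
synthetic_annotation <- function(sp = 21L, lrr_nt = 31L, lrr1 = 18L,
                                 lrrv = c(24L, 24L), cp = 11L,
                                 core_loop = 15L, stalk = 87L,
                                 sample_id = "synthetic") {
  if (length(lrrv) < 1L) stop("at least one LRRv unit is required")
  base <- function(n) strrep("A", n)
  sp_seq <- if (sp >= 6L) paste0("VDQVDR", base(sp - 6L)) else base(sp)
  l1_seq <- base(lrr1)
  if (lrr1 >= 18L) {
    for (r in seq_len(nrow(conserved_positions("xLxLxxNxxxxLxxxxFx")))) {
      cp_ <- conserved_positions("xLxLxxNxxxxLxxxxFx")
      substr(l1_seq, cp_$index[r] + 1L, cp_$index[r] + 1L) <- cp_$residue[r]
    }
  }
  lv_cons <- conserved_positions("xLxxLxxLxLx")
  lv_seq <- vapply(lrrv, function(L) {
    s <- base(L)
    off <- if (L >= 11L + LRRV_MOTIF_OFFSET) LRRV_MOTIF_OFFSET else if (L >= 11L) 0L else NA_integer_
    if (!is.na(off)) {
      for (r in seq_len(nrow(lv_cons))) {
        substr(s, off + lv_cons$index[r] + 1L, off + lv_cons$index[r] + 1L) <- lv_cons$residue[r]
      }
    }
    s
  }, character(1))
  ct_seq <- paste0(base(CT_PRE), "W", base(3L), base(core_loop), base(2L), "C", base(CT_POST))
  lrr_ct <- nchar(ct_seq)
  stalk_motif <- "DCGKPACTTLLNCANFLSCLCSTCALCRKR"
  stalk_seq <- if (stalk >= nchar(stalk_motif)) {
    paste0(base(stalk - nchar(stalk_motif)), stalk_motif)
  } else base(stalk)
  protein <- paste0(sp_seq, base(lrr_nt), l1_seq, paste(lv_seq, collapse = ""),
                    base(cp), ct_seq, stalk_seq)
  o <- 0L
  nxt <- function(n) { s <- span(o, o + n); o <<- o + n; s }
  sp_s <- nxt(sp); nt_s <- nxt(lrr_nt); l1_s <- nxt(lrr1)
  lv_s <- lapply(lrrv, nxt)
  cp_s <- nxt(cp); ct_s <- nxt(lrr_ct); stalk_s <- nxt(stalk)
  w0 <- ct_s$start + CT_PRE
  c0 <- w0 + 6L + core_loop
  structure(list(
    protein = protein, status = "annotated", lrrv_count = length(lrrv),
    sample_id = sample_id, abundance = 1L,
    spans = list(sp = sp_s, lrr_nt = nt_s, lrr1 = l1_s, lrrv = lv_s,
                 cp = cp_s, lrr_ct = ct_s,
                 core_loop = span(w0 + 4L, c0 - 2L),
                 extended_loop = span(w0, c0 + 1L),
                 stalk = stalk_s)
  ), class = "vlrb_annotation")
}
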