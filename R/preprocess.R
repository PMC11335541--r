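# Read orientation, primer/barcode trimming, demultiplexing, UMI extraction,
# within-UMI collapse and 1-nt UMI-neighbor removal.
#
# Amplicon layout (sense strand, 1-based):
#   TAT(3) | barcode(6) | insert (starts with the 18-nt forward-primer
#   annealing segment, ends with the stop codon) | rc(stalk anneal)(22) |
#   rc(UMI)(12) | rc(rev const)(17) | rc(barcode)(6) | ATA(3)
# Primer and barcode matching is exact (0 mismatches); reads failing it are
# rejected with a reason, mirroring the discard-on-imperfect-primer rule.

demux_offsets <- function(cfg) {
  list(
    fwd_start = 10L,
    fwd_len = nchar(cfg$fwd_const),
    tail_len = nchar(cfg$stalk_anneal) + cfg$umi_length + nchar(cfg$rev_const) + 6L + 3L,
    sa_len = nchar(cfg$stalk_anneal),
    rev_len = nchar(cfg$rev_const)
  )
}

# Structural field extraction for reads assumed to be in sense orientation.
# Returns a data.frame of logical checks plus barcode/umi/insert columns.
demux_fields <- function(reads, cfg) {
  off <- demux_offsets(cfg)
  L <- nchar(reads)
  u <- toupper(reads)
  min_len <- 9L + off$fwd_len + off$tail_len
  long_enough <- L >= min_len
  fwd_ok <- long_enough &
    substr(u, 1L, 3L) == "TAT" &
    substr(u, off$fwd_start, off$fwd_start + off$fwd_len - 1L) == cfg$fwd_const
  rev_ok <- long_enough &
    substr(u, L - 2L, L) == "ATA" &
    substr(u, L - 8L - off$rev_len, L - 9L) == revcomp(cfg$rev_const) &
    substr(u, L - 8L - off$rev_len - cfg$umi_length - off$sa_len,
           L - 9L - off$rev_len - cfg$umi_length) == revcomp(cfg$stalk_anneal)
  bc_f <- substr(u, 4L, 9L)
  bc_r <- ifelse(long_enough, revcomp(substr(u, L - 8L, L - 3L)), "")
  umi <- ifelse(long_enough,
                revcomp(substr(u, L - 8L - off$rev_len - cfg$umi_length, L - 9L - off$rev_len)),
                "")
  insert <- ifelse(long_enough, substr(u, off$fwd_start, L - off$tail_len), "")
  data.frame(fwd_ok = fwd_ok, rev_ok = rev_ok, bc_f = bc_f, bc_r = bc_r,
             umi = umi, insert = insert, stringsAsFactors = FALSE)
}

#' Orient, trim and demultiplex reads
#'
#' Searches both strands for the exact forward-primer constant segment at its
#' fixed 5' offset and the reverse-primer/UMI tail at its fixed 3' offsets;
#' reverse-strand reads are reverse-complemented first.  The two 6-nt
#' barcodes must agree and be present in the barcode table.  The trimmed
#' insert retains the SP-annealing segment (it encodes SP residues).
#' Rejection reasons are `no_fwd_primer`, `no_rev_primer` and
#' `barcode_mismatch`.
#'
#' @param reads Named character vector of reads (or a FASTQ/FASTA path).
#' @param cfg A [vlrb_config()].
#' @return A list with `records` (data.frame `read_id`, `sample_id`, `umi`,
#'   `insert`) and `rejected` (data.frame `read_id`, `reason`).
#' @export
demultiplex <- function(reads, cfg = vlrb_config()) {
  if (is.character(reads) && length(reads) == 1L &&
      !grepl("^[ACGTNacgtn]*$", reads) && file.exists(reads)) {
    reads <- read_sequences(reads)
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read%07d", seq_along(reads))
  n <- length(reads)
  if (n == 0L) {
    return(list(
      records = data.frame(read_id = character(0), sample_id = character(0),
                           umi = character(0), insert = character(0),
                           stringsAsFactors = FALSE),
      rejected = data.frame(read_id = character(0), reason = character(0),
                            stringsAsFactors = FALSE)
    ))
  }
  fw <- demux_fields(reads, cfg)
  need_rc <- which(!fw$fwd_ok)
  if (length(need_rc)) {
    rc <- demux_fields(revcomp(toupper(reads[need_rc])), cfg)
    use <- which(rc$fwd_ok)
    if (length(use)) fw[need_rc[use], ] <- rc[use, ]
  }
  reason <- rep(NA_character_, n)
  reason[!fw$fwd_ok] <- "no_fwd_primer"
  sel <- is.na(reason) & !fw$rev_ok
  reason[sel] <- "no_rev_primer"
  sel <- is.na(reason) &
    (fw$bc_f != fw$bc_r | !(fw$bc_f %in% cfg$barcode_table))
  reason[sel] <- "barcode_mismatch"
  ok <- is.na(reason)
  sample_id <- names(cfg$barcode_table)[match(fw$bc_f, cfg$barcode_table)]
  list(
    records = data.frame(read_id = names(reads)[ok], sample_id = sample_id[ok],
                         umi = fw$umi[ok], insert = fw$insert[ok],
                         stringsAsFactors = FALSE),
    rejected = data.frame(read_id = names(reads)[!ok], reason = reason[!ok],
                          stringsAsFactors = FALSE)
  )
}

#' Orient and trim a single read
#'
#' Single-read wrapper around [demultiplex()].
#'
#' @param read One nucleotide string.
#' @param cfg A [vlrb_config()].
#' @return A one-row record data.frame, or an object of class
#'   `vlrb_rejection` (a list with `reason`) for a rejected read.
#' @export
orient_and_trim <- function(read, cfg = vlrb_config()) {
  if (length(read) != 1L) stop("orient_and_trim takes a single read")
  if (!nzchar(read)) {
    return(structure(list(reason = "no_fwd_primer"), class = "vlrb_rejection"))
  }
  res <- demultiplex(stats::setNames(read, "read"), cfg)
  if (nrow(res$records) == 1L) return(res$records)
  structure(list(reason = res$rejected$reason[1]), class = "vlrb_rejection")
}

# Connected components of an undirected graph given as an edge-list matrix
# (rows are index pairs over 1..n); returns integer component labels.
connected_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  if (length(edges) && nrow(edges) > 0L) {
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) parent[b] <- a
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Majority consensus of a bin of sequences.  Columns are taken over members
# of the modal length; ties go to the residue of the most frequent
# full-length member, then lexicographic.
consensus_of <- function(seqs) {
  tab <- table(nchar(seqs))
  modal_len <- as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1])
  mem <- seqs[nchar(seqs) == modal_len]
  full_tab <- table(mem)
  full_rank <- names(full_tab)[order(-full_tab, names(full_tab))]
  top_full <- strsplit(full_rank[1], "", fixed = TRUE)[[1]]
  chars <- matrix(unlist(strsplit(mem, "", fixed = TRUE)), nrow = modal_len)
  cons <- vapply(seq_len(modal_len), function(p) {
    t <- table(chars[p, ])
    best <- names(t)[t == max(t)]
    if (length(best) == 1L) return(best)
    if (top_full[p] %in% best) return(top_full[p])
    sort(best)[1]
  }, character(1))
  paste(cons, collapse = "")
}

#' Collapse reads within UMI bins into molecules
#'
#' Groups records by sample and exact UMI.  Within a bin, reads are clustered
#' at `umi_collapse_identity` (single linkage on pairwise identity; identical
#' columns over max sequence length, with the Hamming shortcut for
#' equal-length pairs).  A bin yielding exactly one cluster collapses to one
#' molecule whose consensus is the position-wise majority; a bin with more
#' than one cluster — i.e. with more than 1 % internal divergence — is
#' discarded entirely.
#'
#' @param records Demultiplexed records (`sample_id`, `umi`, `insert`).
#' @param cfg A [vlrb_config()].
#' @return A list with `molecules` (data.frame `sample_id`, `umi`,
#'   `consensus_nt`, `read_count`), `discarded_bins` and `discarded_reads`.
#' @export
collapse_umi_bins <- function(records, cfg = vlrb_config()) {
  empty <- data.frame(sample_id = character(0), umi = character(0),
                      consensus_nt = character(0), read_count = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(records) == 0L) {
    return(list(molecules = empty, discarded_bins = 0L, discarded_reads = 0L))
  }
  key <- paste(records$sample_id, records$umi, sep = "\r")
  idx <- split(seq_len(nrow(records)), key)
  n_bins <- length(idx)
  sample_id <- character(n_bins); umi <- character(n_bins)
  consensus <- character(n_bins); count <- integer(n_bins)
  keep <- logical(n_bins)
  disc_bins <- 0L; disc_reads <- 0L
  b <- 0L
  for (ii in idx) {
    b <- b + 1L
    seqs <- records$insert[ii]
    sample_id[b] <- records$sample_id[ii[1]]
    umi[b] <- records$umi[ii[1]]
    uq <- unique(seqs)
    if (length(uq) == 1L) {
      consensus[b] <- uq
      count[b] <- length(seqs)
      keep[b] <- TRUE
      next
    }
    pairs <- utils::combn(length(uq), 2)
    edge_ok <- apply(pairs, 2, function(p) {
      seq_identity(uq[p[1]], uq[p[2]], denom = "longer") >= cfg$umi_collapse_identity
    })
    comp <- connected_components(length(uq), t(pairs[, edge_ok, drop = FALSE]))
    if (length(unique(comp)) == 1L) {
      consensus[b] <- consensus_of(seqs)
      count[b] <- length(seqs)
      keep[b] <- TRUE
    } else {
      disc_bins <- disc_bins + 1L
      disc_reads <- disc_reads + length(seqs)
    }
  }
  mol <- data.frame(sample_id = sample_id[keep], umi = umi[keep],
                    consensus_nt = consensus[keep], read_count = count[keep],
                    stringsAsFactors = FALSE)
  mol <- mol[order(mol$sample_id, mol$umi), , drop = FALSE]
  rownames(mol) <- NULL
  list(molecules = mol, discarded_bins = disc_bins, discarded_reads = disc_reads)
}

#' Remove 1-nt UMI neighbors
#'
#' Molecules of one sample with identical consensus sequences whose UMIs
#' differ by at most `umi_neighbor_distance` (default 1 nt of 12) are
#' resolved as PCR-mutated UMIs: connected components of the neighbor graph
#' keep only their highest-read-support member (ties keep the
#' lexicographically smallest UMI).
#'
#' @param molecules Molecule data.frame from [collapse_umi_bins()].
#' @param cfg A [vlrb_config()].
#' @return A list with `molecules` (filtered) and `removed` (data.frame of
#'   removed molecules).
#' @export
remove_umi_neighbors <- function(molecules, cfg = vlrb_config()) {
  if (nrow(molecules) == 0L) {
    return(list(molecules = molecules, removed = molecules[0, ]))
  }
  drop <- logical(nrow(molecules))
  key <- paste(molecules$sample_id, molecules$consensus_nt, sep = "\r")
  for (ii in split(seq_len(nrow(molecules)), key)) {
    if (length(ii) < 2L) next
    umis <- molecules$umi[ii]
    pairs <- utils::combn(length(ii), 2)
    near <- apply(pairs, 2, function(p) {
      hamming(umis[p[1]], umis[p[2]]) <= cfg$umi_neighbor_distance
    })
    comp <- connected_components(length(ii), t(pairs[, near, drop = FALSE]))
    for (cc in unique(comp)) {
      mem <- which(comp == cc)
      if (length(mem) < 2L) next
      counts <- molecules$read_count[ii[mem]]
      ord <- order(-counts, umis[mem])
      drop[ii[mem[ord[-1]]]] <- TRUE
    }
  }
  out <- molecules[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(molecules = out, removed = molecules[drop, , drop = FALSE])
}
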