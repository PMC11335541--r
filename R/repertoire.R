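# Consensus length filtering with per-step accounting, CD-HIT-style greedy
# identity clustering, cluster-size CDFs, threshold sweeps and cross-animal
# sharing analysis.

ann_len <- function(ann, what) {
  s <- ann$spans[[what]]
  if (is.null(s)) return(NA_integer_)
  span_length(s)
}

#' Apply the consensus length filter
#'
#' Applies the six canonical-length checks sequentially — LRRv 24 aa (and at
#' least one unit), LRR1 18 aa, LRR-NT 31 aa, stalk 87 aa, SP 21 aa,
#' CP 11 aa — charging each rejected record to the first failing step, so
#' the per-step counts depend on this order.
#'
#' @param annotations List of `vlrb_annotation` with status `annotated`.
#' @param cfg A [vlrb_config()].
#' @return A list with `retained` (annotations) and `report` (a data.frame
#'   with `step`, `check`, `removed`, plus attribute `retained` count).
#' @export
apply_consensus_filter <- function(annotations, cfg = vlrb_config()) {
  status <- vapply(annotations, `[[`, character(1), "status")
  if (any(status != "annotated")) stop("consensus filter expects annotated records")
  len <- cfg$subunit_length_spec
  steps <- c(lrrv_length = "12a", lrr1_length = "12b", lrrnt_length = "12c",
             stalk_length = "12d", sp_length = "12e", cp_length = "12f")
  removed <- stats::setNames(integer(length(steps)), names(steps))
  keep <- logical(length(annotations))
  for (i in seq_along(annotations)) {
    a <- annotations[[i]]
    lrrv_ok <- a$lrrv_count >= 1L &&
      all(vapply(a$spans$lrrv, span_length, integer(1)) == len[["LRRv"]])
    fail <- if (!lrrv_ok) "lrrv_length"
      else if (ann_len(a, "lrr1") != len[["LRR1"]]) "lrr1_length"
      else if (ann_len(a, "lrr_nt") != len[["LRR-NT"]]) "lrrnt_length"
      else if (ann_len(a, "stalk") != len[["stalk"]]) "stalk_length"
      else if (ann_len(a, "sp") != len[["SP"]]) "sp_length"
      else if (ann_len(a, "cp") != len[["CP"]]) "cp_length"
      else NA_character_
    if (is.na(fail)) keep[i] <- TRUE else removed[fail] <- removed[fail] + 1L
  }
  report <- data.frame(step = unname(steps), check = names(steps),
                       removed = unname(removed), stringsAsFactors = FALSE)
  attr(report, "input") <- length(annotations)
  attr(report, "retained") <- sum(keep)
  list(retained = annotations[keep], report = report)
}

#' Greedy incremental identity clustering
#'
#' CD-HIT-style clustering: sequences are sorted by decreasing length (ties
#' lexicographic) and each sequence joins the first existing cluster whose
#' representative has identity at least `threshold`, else founds a new
#' cluster.  Identity is identical residues in a unit-score global alignment
#' divided by the length of the shorter sequence (CD-HIT's denominator);
#' equal-length pairs use the ungapped shortcut.  No k-mer prefilter is used
#' — clustering is exact at desk scale.
#'
#' @param sequences Character vector of amino-acid sequences.
#' @param threshold Identity threshold in (0, 1].
#' @param ids Optional sequence ids (default `seq_along(sequences)`).
#' @return A list of class `vlrb_cluster_set`: `threshold`, `clusters` (list
#'   of lists with `representative`, `members` ids) and `assignment`
#'   (data.frame `id`, `sequence`, `cluster`, `is_representative`).
#' @export
greedy_cluster <- function(sequences, threshold, ids = NULL) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  n <- length(sequences)
  if (n == 0L) {
    return(structure(list(threshold = threshold, clusters = list(),
                          assignment = data.frame(id = character(0),
                                                  sequence = character(0),
                                                  cluster = integer(0),
                                                  is_representative = logical(0),
                                                  stringsAsFactors = FALSE)),
                     class = "vlrb_cluster_set"))
  }
  uq <- unique(sequences)
  uq <- uq[order(-nchar(uq), uq)]
  reps <- character(0)
  cluster_of_uq <- integer(length(uq))
  for (i in seq_along(uq)) {
    s <- uq[i]
    assigned <- 0L
    for (k in seq_along(reps)) {
      if (seq_identity(s, reps[k], denom = "shorter") >= threshold) {
        assigned <- k
        break
      }
    }
    if (assigned == 0L) {
      reps <- c(reps, s)
      assigned <- length(reps)
    }
    cluster_of_uq[i] <- assigned
  }
  cl <- cluster_of_uq[match(sequences, uq)]
  assignment <- data.frame(id = ids, sequence = sequences, cluster = cl,
                           is_representative = sequences == reps[cl],
                           stringsAsFactors = FALSE)
  clusters <- lapply(seq_along(reps), function(k) {
    list(representative = reps[k], members = ids[cl == k])
  })
  structure(list(threshold = threshold, clusters = clusters,
                 assignment = assignment),
            class = "vlrb_cluster_set")
}

#' @export
print.vlrb_cluster_set <- function(x, ...) {
  cat(sprintf("%d clusters of %d sequences at threshold %.2f\n",
              length(x$clusters), nrow(x$assignment), x$threshold))
  invisible(x)
}

#' Cumulative distribution of cluster sizes
#'
#' Used as a surrogate diversity measure: clusters are ranked from largest
#' to smallest and the cumulative fraction of sequences is reported per
#' rank (the final value is 1).
#'
#' @param cs A `vlrb_cluster_set`.
#' @return Data.frame `rank`, `size`, `cum_fraction`.
#' @export
cluster_size_cdf <- function(cs) {
  sizes <- sort(vapply(cs$clusters, function(cl) length(cl$members), integer(1)),
                decreasing = TRUE)
  if (!length(sizes)) stop("empty cluster set")
  data.frame(rank = seq_along(sizes), size = sizes,
             cum_fraction = cumsum(sizes) / sum(sizes))
}

#' Cluster-threshold sweep
#'
#' Clusters a sequence set at each threshold and reports the total cluster
#' count and the percentage of sequences contained in the `loci_n` largest
#' clusters (the published genomic-locus count for the subunit).
#'
#' @param sequences Character vector.
#' @param thresholds Numeric vector of identity thresholds.
#' @param loci_n Number of genomic loci for the subunit.
#' @return Data.frame `threshold`, `n_clusters`, `pct_in_top_n`.
#' @export
threshold_sweep <- function(sequences, thresholds, loci_n) {
  res <- lapply(thresholds, function(t) {
    cs <- greedy_cluster(sequences, t)
    sizes <- sort(vapply(cs$clusters, function(cl) length(cl$members), integer(1)),
                  decreasing = TRUE)
    data.frame(threshold = t, n_clusters = length(sizes),
               pct_in_top_n = 100 * sum(sizes[seq_len(min(loci_n, length(sizes)))]) /
                 sum(sizes))
  })
  do.call(rbind, res)
}

#' Cross-animal sharing of identical proteins
#'
#' Counts, for k = 2..n_animals, the distinct protein sequences present with
#' 100 % identity in at least k animals; fractions are relative to the
#' combined number of per-animal unique proteins.
#'
#' @param per_animal Named list of character vectors (each the unique
#'   proteins of one animal).
#' @return Data.frame `k`, `count`, `fraction`.
#' @export
shared_sequences <- function(per_animal) {
  n <- length(per_animal)
  if (n < 2L) stop("sharing analysis needs at least 2 animals")
  per_animal <- lapply(per_animal, unique)
  total <- sum(lengths(per_animal))
  tab <- table(unlist(per_animal, use.names = FALSE))
  ks <- 2:n
  count <- vapply(ks, function(k) sum(tab >= k), integer(1))
  data.frame(k = ks, count = count, fraction = count / total)
}
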