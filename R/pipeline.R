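# End-to-end orchestration with Fig-2-style stepwise accounting.

#' Run the full VLRB analysis pipeline
#'
#' Executes demultiplexing, UMI collapse, UMI-neighbor removal, translation
#' and stalk filtering, per-sample protein deduplication, structural
#' annotation, the consensus length filter, cross-animal sharing and the
#' property analytics, and assembles a stepwise run report whose counts
#' telescope (each stage's output is the next stage's input).  The run is
#' deterministic: no randomness downstream of simulation.
#'
#' @param reads Named character vector of reads, or a FASTQ/FASTA path.
#' @param cfg A [vlrb_config()].
#' @param cluster_thresholds Optional numeric vector; when given, retained
#'   full-length proteins are greedily clustered at each threshold and the
#'   cluster-size CDFs are attached.
#' @param out_dir Optional directory; when given, stage outputs (TSV/FASTA)
#'   and the JSON run report are written there.
#' @return A list with stage outputs (`molecules`, `proteins`,
#'   `unique_proteins`, `annotations`, `retained`, `filter_report`,
#'   `sharing`, `properties`, `clustering`) and `report` (class
#'   `vlrb_run_report`).
#' @export
run_pipeline <- function(reads, cfg = vlrb_config(), cluster_thresholds = NULL,
                         out_dir = NULL) {
  t0 <- Sys.time()
  dem <- demultiplex(reads, cfg)
  n_reads <- nrow(dem$records) + nrow(dem$rejected)

  col <- collapse_umi_bins(dem$records, cfg)
  nb <- remove_umi_neighbors(col$molecules, cfg)
  molecules <- nb$molecules

  prot <- orf_filter(molecules, cfg)
  uniq <- dedup_proteins(prot)

  ann <- annotate_set(uniq, cfg)
  annotated <- Filter(function(a) a$status == "annotated", ann$annotations)
  flt <- apply_consensus_filter(annotated, cfg)

  samples <- sort(unique(vapply(flt$retained, `[[`, character(1), "sample_id")))
  per_animal <- lapply(samples, function(s) {
    vapply(Filter(function(a) a$sample_id == s, flt$retained),
           `[[`, character(1), "protein")
  })
  names(per_animal) <- samples
  sharing <- if (length(per_animal) >= 2L) shared_sequences(per_animal) else NULL

  properties <- if (length(flt$retained)) {
    loops <- vapply(flt$retained, function(a) span_seq(a$protein, a$spans$extended_loop),
                    character(1))
    list(lengths = length_distributions(flt$retained),
         positional = positional_subunit_stats(flt$retained),
         loop_split = split_loops_by_hydropathy(loops, cfg$hydropathy_split))
  } else NULL

  clustering <- if (!is.null(cluster_thresholds) && length(flt$retained)) {
    seqs <- vapply(flt$retained, `[[`, character(1), "protein")
    lapply(stats::setNames(cluster_thresholds, cluster_thresholds), function(t) {
      cs <- greedy_cluster(seqs, t)
      list(cluster_set = cs, cdf = cluster_size_cdf(cs))
    })
  } else NULL

  rejected_demux <- nrow(dem$rejected)
  report <- structure(list(
    n_reads = n_reads,
    rejected_primer_barcode = rejected_demux,
    n_demultiplexed = nrow(dem$records),
    discarded_umi_bin_reads = col$discarded_reads,
    n_molecules = nrow(col$molecules),
    umi_neighbors_removed = nrow(nb$removed),
    n_after_neighbor_removal = nrow(molecules),
    premature_stop = sum(prot$status == "premature_stop"),
    no_stalk = sum(prot$status == "no_stalk"),
    n_ok_proteins = sum(prot$status == "ok"),
    dedup_collapsed = sum(prot$status == "ok") - nrow(uniq),
    n_unique_proteins = nrow(uniq),
    no_lrr1 = unname(ann$status_counts["no_lrr1"]),
    no_lrrv = unname(ann$status_counts["no_lrrv"]),
    no_loop = unname(ann$status_counts["no_loop"]),
    n_annotated = unname(ann$status_counts["annotated"]),
    filter_removed = stats::setNames(flt$report$removed, flt$report$check),
    n_retained = attr(flt$report, "retained"),
    wall_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "vlrb_run_report")
  validate_report(report)

  result <- list(demux_rejected = dem$rejected, molecules = molecules,
                 proteins = prot, unique_proteins = uniq,
                 annotations = ann$annotations, retained = flt$retained,
                 filter_report = flt$report, sharing = sharing,
                 properties = properties, clustering = clustering,
                 report = report)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Check that a run report telescopes
#'
#' Each stage's output count must equal the next stage's input count minus
#' its rejections.
#'
#' @param report A `vlrb_run_report`.
#' @return `TRUE` invisibly; errors on the first broken identity.
#' @export
validate_report <- function(report) {
  with(report, {
    stopifnot(
      n_demultiplexed == n_reads - rejected_primer_barcode,
      n_after_neighbor_removal == n_molecules - umi_neighbors_removed,
      n_ok_proteins == n_after_neighbor_removal - premature_stop - no_stalk,
      n_unique_proteins == n_ok_proteins - dedup_collapsed,
      n_annotated == n_unique_proteins - no_lrr1 - no_lrrv - no_loop,
      n_retained == n_annotated - sum(filter_removed)
    )
  })
  invisible(TRUE)
}

#' @export
print.vlrb_run_report <- function(x, ...) {
  cat("VLRB pipeline run report\n")
  cat(sprintf("  reads                      %8d\n", x$n_reads))
  cat(sprintf("  rejected (primer/barcode)  %8d\n", x$rejected_primer_barcode))
  cat(sprintf("  demultiplexed              %8d\n", x$n_demultiplexed))
  cat(sprintf("  UMI molecules              %8d\n", x$n_molecules))
  cat(sprintf("  UMI neighbors removed      %8d\n", x$umi_neighbors_removed))
  cat(sprintf("  premature stop (8a)        %8d\n", x$premature_stop))
  cat(sprintf("  no stalk (8b)              %8d\n", x$no_stalk))
  cat(sprintf("  unique proteins            %8d\n", x$n_unique_proteins))
  cat(sprintf("  no LRR1 (10a)              %8d\n", x$no_lrr1))
  cat(sprintf("  no LRRv (10b)              %8d\n", x$no_lrrv))
  cat(sprintf("  no loop (11)               %8d\n", x$no_loop))
  cat(sprintf("  annotated                  %8d\n", x$n_annotated))
  for (i in seq_along(x$filter_removed)) {
    cat(sprintf("  filter %-18s  %8d\n", names(x$filter_removed)[i],
                x$filter_removed[i]))
  }
  cat(sprintf("  retained                   %8d\n", x$n_retained))
  invisible(x)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$molecules, file.path(out_dir, "molecules.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$unique_proteins, file.path(out_dir, "unique_proteins.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  ann_df <- do.call(rbind, lapply(result$annotations, function(a) {
    spans <- if (a$status == "annotated") {
      vapply(a$spans[c("sp", "lrr_nt", "lrr1", "cp", "lrr_ct",
                       "core_loop", "extended_loop", "stalk")],
             function(s) sprintf("%d-%d", s$start, s$end), character(1))
    } else rep(NA_character_, 8L)
    lv <- if (a$status == "annotated") {
      paste(vapply(a$spans$lrrv, function(s) sprintf("%d-%d", s$start, s$end),
                   character(1)), collapse = ";")
    } else NA_character_
    data.frame(sample_id = a$sample_id, status = a$status,
               lrrv_count = a$lrrv_count, sp = spans[1], lrr_nt = spans[2],
               lrr1 = spans[3], lrrv = lv, cp = spans[4], lrr_ct = spans[5],
               core_loop = spans[6], extended_loop = spans[7],
               stalk = spans[8], protein = a$protein,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(ann_df, file.path(out_dir, "annotations.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(result$sharing)) {
    utils::write.table(result$sharing, file.path(out_dir, "sharing.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  rep_json <- result$report
  class(rep_json) <- NULL
  rep_json$filter_removed <- as.list(rep_json$filter_removed)
  jsonlite::write_json(rep_json, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
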