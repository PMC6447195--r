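#' End-to-end signal-aware deduplication
#'
#' Chains the full workflow on one library: read and filter alignments,
#' mark duplicates, filter peaks against a blacklist, compute the library
#' QC summary, partition in-peak duplicates into signal and noise, and
#' write the properly deduplicated BAM together with the per-peak
#' accounting table.
#'
#' @param file BAM/SAM of coordinate-sorted unique alignments.
#' @param peaks GRanges of peaks (or a path read with [read_peaks()]).
#' @param out_dir Output directory (created if needed).
#' @param blacklist Optional GRanges (or BED path) of excluded regions.
#' @param mode `"single"` or `"paired"`.
#' @param min_mapq,check_first Alignment filters, see [passes_filters()].
#' @param cap,span,iterations Partition controls, see
#'   [partition_duplicates()].
#' @param seed Seed for the random extraction of noise duplicates.
#' @param chrom_sizes Optional named lengths; defaults to the BAM header.
#' @return List: `qc` (one-row library summary), `partition`, `plan`,
#'   `dedup_bam`, `peak_table`; TSVs and the deduplicated BAM are written
#'   under `out_dir`.
#' @export
run_peakdedup <- function(file, peaks, out_dir, blacklist = NULL,
                          mode = c("single", "paired"), min_mapq = 20L,
                          check_first = 5L, cap = 5L, span = 2/3,
                          iterations = 3L, seed = 1L, chrom_sizes = NULL) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.character(peaks)) peaks <- read_peaks(peaks)
  if (is.character(blacklist)) blacklist <- rtracklayer::import(blacklist)
  aln <- read_alignments(file)
  if (is.null(chrom_sizes)) chrom_sizes <- attr(aln, "chrom_sizes")
  aln <- aln[passes_filters(aln, min_mapq, check_first, on_missing = "nm0"), ]
  marking <- mark_duplicates(aln, mode)
  if (!is.null(blacklist)) peaks <- filter_blacklist(peaks, blacklist)
  qc <- library_metrics(marking, peaks, chrom_sizes)
  part <- partition_duplicates(peaks, marking, cap = cap, span = span,
                               iterations = iterations)
  plan <- build_rewrite_plan(marking, peaks, part, cap = cap, seed = seed)
  dedup <- write_deduplicated(file, marking, peaks, plan,
                              out = file.path(out_dir, "dedup"))
  utils::write.table(qc, file.path(out_dir, "library_qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(part),
                     file.path(out_dir, "partition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dedup$peak_table,
                     file.path(out_dir, "peak_dups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_plan(plan, file.path(out_dir, "plan.tsv"))
  list(qc = qc, partition = part, plan = plan, dedup_bam = dedup$bam,
       peak_table = dedup$peak_table)
}
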