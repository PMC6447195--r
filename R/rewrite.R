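#' Randomly select noise duplicates for removal
#'
#' Uniform sample without replacement of `n_noise` read ids from a peak's
#' duplicate pool; the remaining ids are kept as signal. Reproducible when a
#' seed is given.
#'
#' @param dup_ids Character vector of duplicate read ids in the pool.
#' @param n_noise Number of ids to drop (0 <= n_noise <= length(dup_ids)).
#' @param seed Optional integer seed for reproducibility.
#' @return Character vector of dropped ids.
#' @export
select_noise_reads <- function(dup_ids, n_noise, seed = NULL) {
  if (n_noise > length(dup_ids)) {
    stop("n_noise (", n_noise, ") exceeds pool size (", length(dup_ids),
         "); partition inconsistent with the duplicate pool")
  }
  if (n_noise == 0L) return(character(0))
  pick <- function() dup_ids[sample.int(length(dup_ids), n_noise)]
  if (is.null(seed)) pick() else withr::with_seed(seed, pick())
}

#' Build the peak-wise keep/drop plan for proper deduplication
#'
#' For every peak, collects the duplicate read ids mapped to it (by
#' duplicate-key coordinate), removes those beyond the per-position cap
#' (treated as noise outright; within a key, duplicates are ordered by read
#' id and the first `cap` stay in the pool), and randomly extracts `N` noise
#' ids from the remaining `S + N` pool; the `S` ids left over are kept as
#' signal. All duplicates outside peaks are dropped.
#'
#' @param marking `"dup_marking"` for the library.
#' @param peaks GRanges of the peaks used for the partition.
#' @param partition `"dup_partition"` rows aligned with `peaks`.
#' @param cap Per-position duplicate cap used in the partition (default 5).
#' @param seed Integer seed driving the random extraction.
#' @return List of class `"rewrite_plan"`: `keep_ids` (signal duplicates to
#'   retain), `drop_ids` (noise + over-cap + non-peak duplicates),
#'   `per_peak` (data.frame peak_id, S, N, n_overcap), `seed`, `cap`.
#' @export
build_rewrite_plan <- function(marking, peaks, partition, cap = 5L,
                               seed = 1L) {
  stopifnot(nrow(partition) == length(peaks))
  flags <- marking$flags
  tallies <- marking$tallies
  key_peak <- GenomicRanges::findOverlaps(tally_positions(tallies), peaks,
                                          ignore.strand = TRUE,
                                          select = "first")
  names(key_peak) <- tallies$key
  dup_flags <- flags[flags$is_duplicate, , drop = FALSE]
  dup_flags <- dup_flags[order(dup_flags$key, dup_flags$read_id), ,
                         drop = FALSE]
  within_key_rank <- stats::ave(seq_len(nrow(dup_flags)), dup_flags$key,
                                FUN = seq_along)
  in_pool <- within_key_rank <= cap
  dup_flags$peak <- key_peak[dup_flags$key]
  pool <- dup_flags[in_pool & !is.na(dup_flags$peak), , drop = FALSE]
  keep_ids <- character(0)
  drop_noise <- character(0)
  per_peak <- data.frame(peak_id = partition$peak_id,
                         S = NA_integer_, N = NA_integer_,
                         n_overcap = 0L, stringsAsFactors = FALSE)
  overcap <- dup_flags[!in_pool & !is.na(dup_flags$peak), , drop = FALSE]
  oc <- table(overcap$peak)
  per_peak$n_overcap[as.integer(names(oc))] <- as.integer(oc)
  withr::with_seed(seed, {
    for (p in seq_along(peaks)) {
      ids <- pool$read_id[pool$peak == p]
      n_noise <- partition$N[p]
      if (length(ids) != partition$S[p] + partition$N[p]) {
        stop("peak ", partition$peak_id[p], ": duplicate pool size ",
             length(ids), " != S + N = ",
             partition$S[p] + partition$N[p],
             "; partition and marking are inconsistent")
      }
      drop_p <- if (n_noise > 0L) ids[sample.int(length(ids), n_noise)]
        else character(0)
      keep_p <- setdiff(ids, drop_p)
      keep_ids <- c(keep_ids, keep_p)
      drop_noise <- c(drop_noise, drop_p)
      per_peak$S[p] <- length(keep_p)
      per_peak$N[p] <- length(drop_p)
    }
  })
  structure(list(
    keep_ids = keep_ids,
    drop_ids = c(drop_noise, overcap$read_id,
                 dup_flags$read_id[is.na(dup_flags$peak)]),
    per_peak = per_peak, seed = seed, cap = cap),
    class = "rewrite_plan")
}

#' @export
print.rewrite_plan <- function(x, ...) {
  cat("Rewrite plan (seed ", x$seed, ", cap ", x$cap, ")\n", sep = "")
  cat("  signal duplicates kept:", length(x$keep_ids),
      "  duplicates dropped:", length(x$drop_ids), "\n")
  invisible(x)
}

#' Write the plan's retained read ids as TSV
#'
#' Emits one row per duplicate covered by the plan (`read_id`, `fate`) in a
#' deterministic order, so identical seeds yield byte-identical files.
#'
#' @param plan `"rewrite_plan"`.
#' @param file Output TSV path.
#' @return `file`, invisibly.
#' @export
write_plan <- function(plan, file) {
  df <- rbind(
    data.frame(read_id = sort(plan$keep_ids), fate = "keep_signal",
               stringsAsFactors = FALSE),
    data.frame(read_id = sort(plan$drop_ids), fate = "drop_noise",
               stringsAsFactors = FALSE))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Write the properly deduplicated alignment file
#'
#' Produces the signal-aware deduplicated BAM: all nonredundant reads, plus
#' the in-peak duplicates the plan keeps as signal; every other duplicate
#' (non-peak, over-cap, sampled noise) is removed. Records are filtered from
#' the input BAM in place, so the output stays coordinate-sorted and
#' byte-faithful per record. Also returns the per-peak accounting table
#' (nonredundant reads, signal duplicates S, noise duplicates N).
#'
#' @param file Input BAM/SAM of filtered unique alignments.
#' @param marking `"dup_marking"` for `file`.
#' @param peaks GRanges used in the partition.
#' @param plan `"rewrite_plan"` from [build_rewrite_plan()].
#' @param out Output BAM path (".bam" appended if absent).
#' @return List: `bam` (output path), `peak_table` (data.frame peak_id,
#'   n_nondup, S, N).
#' @export
write_deduplicated <- function(file, marking, peaks, plan, out) {
  bam <- as_bam_path(file)
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    Rsamtools::indexBam(bam)
  }
  all_ids <- unique(marking$flags$read_id)
  missing_ids <- setdiff(c(plan$keep_ids, plan$drop_ids), all_ids)
  if (length(missing_ids)) {
    stop("plan references read id(s) absent from the marking/BAM, e.g. ",
         missing_ids[1])
  }
  keep <- c(marking$flags$read_id[!marking$flags$is_duplicate],
            plan$keep_ids)
  keep_env <- new.env(parent = emptyenv())
  for (id in keep) assign(id, TRUE, envir = keep_env)
  rule <- S4Vectors::FilterRules(list(keep_read = function(df) {
    vapply(as.character(df$qname), exists, logical(1), envir = keep_env,
           inherits = FALSE)
  }))
  out <- sub("\\.bam$", "", out)
  dest <- Rsamtools::filterBam(
    bam, destination = paste0(out, ".bam"),
    filter = rule,
    param = Rsamtools::ScanBamParam(what = "qname"))
  counts <- count_regions(peaks, marking)
  peak_table <- data.frame(peak_id = plan$per_peak$peak_id,
                           n_nondup = counts$n_nondup,
                           S = plan$per_peak$S, N = plan$per_peak$N,
                           stringsAsFactors = FALSE)
  list(bam = dest, peak_table = peak_table)
}
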