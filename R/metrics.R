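#' GRanges of duplicate-key coordinates
#'
#' One-base ranges at each tally's 5' key coordinate (the first/leftmost end
#' in paired mode), used to assign keys — and with them all their reads — to
#' regions by point membership, which keeps region partitions exact.
#'
#' @param tallies Tally data.frame from [mark_duplicates()].
#' @return GRanges, one range per tally row, strand kept.
#' @export
tally_positions <- function(tallies) {
  GenomicRanges::GRanges(
    seqnames = tallies$chrom,
    ranges = IRanges::IRanges(start = tallies$fpos, width = 1L),
    strand = tallies$strand)
}

#' Per-region read and duplicate counts
#'
#' Counts reads and duplicates assigned to each region. A read belongs to a
#' region iff its duplicate-key 5' coordinate lies within the region (point
#' assignment; set `rule = "any"` to assign keys by any overlap of the
#' one-base key position — identical here, kept for interface symmetry with
#' interval-overlap counting).
#'
#' @param regions GRanges of regions (counted independently; may overlap).
#' @param marking `"dup_marking"` from [mark_duplicates()], or its tally
#'   data.frame.
#' @param rule Assignment rule, `"point"` (default) or `"any"`.
#' @return data.frame with one row per region: `region_id`, `n_total`,
#'   `n_nondup`, `n_dup`, `n_positions`, `n_positions_with_dup`.
#' @export
count_regions <- function(regions, marking, rule = c("point", "any")) {
  rule <- match.arg(rule)
  tallies <- if (inherits(marking, "dup_marking")) marking$tallies else marking
  pos <- tally_positions(tallies)
  ov <- GenomicRanges::findOverlaps(pos, regions, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  region_id <- if (!is.null(regions$name)) as.character(regions$name)
    else as.character(seq_along(regions))
  agg <- function(v, f) {
    out <- rep(0L, length(regions))
    if (length(qh)) {
      x <- tapply(v[qh], sh, f)
      out[as.integer(names(x))] <- as.integer(x)
    }
    out
  }
  data.frame(
    region_id = region_id,
    n_total = agg(tallies$n_reads, sum),
    n_nondup = agg(rep(1L, nrow(tallies)), sum),
    n_dup = agg(tallies$duplicates, sum),
    n_positions = agg(rep(1L, nrow(tallies)), sum),
    n_positions_with_dup = agg(as.integer(tallies$duplicates > 0L), sum),
    stringsAsFactors = FALSE)
}

#' Library-level duplicate QC summary
#'
#' The one-row quality summary of a filtered library: total reads, duplicate
#' rate (duplicates / uniquely mapped reads), NRF (distinct positions /
#' uniquely mapped reads), FRiP (nonredundant reads in peaks / total
#' nonredundant reads), the peak fraction of the mappable genome, and the
#' share of duplicates falling in peaks.
#'
#' @param marking `"dup_marking"` for the library.
#' @param peaks GRanges of (blacklist-filtered) peaks.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param mappable_frac Mappable fraction of the genome used for the
#'   peak-size denominator (default 0.75).
#' @return One-row data.frame: `n_uniq`, `n_positions`, `dup_rate`, `nrf`,
#'   `frip`, `peak_size_frac`, `pct_dups_in_peaks`.
#' @export
library_metrics <- function(marking, peaks, chrom_sizes,
                            mappable_frac = 0.75) {
  tallies <- marking$tallies
  n_uniq <- sum(tallies$n_reads)
  if (n_uniq == 0L) stop("zero-read library")
  n_dup <- sum(tallies$duplicates)
  pk <- count_regions(GenomicRanges::reduce(GenomicRanges::granges(peaks),
                                            ignore.strand = TRUE), marking)
  data.frame(
    n_uniq = n_uniq,
    n_positions = nrow(tallies),
    dup_rate = n_dup / n_uniq,
    nrf = nrow(tallies) / n_uniq,
    frip = sum(pk$n_nondup) / nrow(tallies),
    peak_size_frac = sum(GenomicRanges::width(GenomicRanges::reduce(
      GenomicRanges::granges(peaks), ignore.strand = TRUE))) /
      (mappable_frac * sum(chrom_sizes)),
    pct_dups_in_peaks = if (n_dup > 0L) sum(pk$n_dup) / n_dup else NA_real_)
}

#' Reads per kilobase per 10 million
#'
#' Length- and depth-normalized count: `count / (length_bp/1e3) /
#' (library_size/1e7)`.
#'
#' @param count Read counts.
#' @param length_bp Region lengths in bp (> 0).
#' @param library_size Total uniquely mapped reads in the library (> 0).
#' @return Numeric vector of RPK10M values.
#' @export
rpk10m <- function(count, length_bp, library_size) {
  stopifnot(all(length_bp > 0), all(library_size > 0))
  count / (length_bp / 1e3) / (library_size / 1e7)
}

#' Target enrichment level of an IP over its input
#'
#' `(IP reads in peaks / IP total) / (input reads in peak-corresponding
#' regions / input total)`, conventionally computed on nonredundant reads.
#' When the input has zero reads in the peak regions the ratio is reported
#' as `Inf`.
#'
#' @param ip_in_peaks,ip_total IP counts (nonredundant), in peaks and total.
#' @param input_in_peaks,input_total Input counts over the same regions.
#' @return Single numeric enrichment ratio.
#' @export
enrichment_level <- function(ip_in_peaks, ip_total, input_in_peaks,
                             input_total) {
  if (ip_total <= 0 || input_total <= 0) stop("zero-total library")
  num <- ip_in_peaks / ip_total
  den <- input_in_peaks / input_total
  if (den == 0) return(Inf)
  num / den
}

#' Confidence-group duplicate profiles
#'
#' Sorts peaks by confidence score ascending (smallest p first; ties broken
#' by coordinate) and splits them into `k` equal-sized groups, the remainder
#' going to the earliest groups. Per group, the duplicate rate (group
#' duplicates / group reads) and the percentage of all library duplicates in
#' the group are reported for the IP, and for the same coordinates in a
#' matched input library when given.
#'
#' @param peaks GRanges with a `p_value` (or `fdr`, see `score`) column.
#' @param marking IP `"dup_marking"`.
#' @param k Number of groups (default 10).
#' @param input_marking Optional input-library `"dup_marking"`.
#' @param score Metadata column holding the confidence score (default
#'   `"p_value"`).
#' @return data.frame, one row per group: `group_index`, `n_peaks`,
#'   `n_reads`, `n_dup`, `dup_rate_in_group`, `pct_library_dups_in_group`,
#'   and `matched_input_dup_rate` / `matched_input_pct` when an input is
#'   supplied.
#' @export
confidence_groups <- function(peaks, marking, k = 10L,
                              input_marking = NULL, score = "p_value") {
  p <- S4Vectors::mcols(peaks)[[score]]
  if (is.null(p) || anyNA(p)) {
    bad <- if (is.null(p)) seq_along(peaks) else which(is.na(p))
    stop("missing ", score, " for peak(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ord <- order(p, as.character(GenomicRanges::seqnames(peaks)),
               GenomicRanges::start(peaks))
  n <- length(peaks)
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  grp <- rep(seq_len(k), sizes)
  peaks_sorted <- peaks[ord]
  counts <- count_regions(peaks_sorted, marking)
  lib_dups <- sum(marking$tallies$duplicates)
  out <- data.frame(
    group_index = seq_len(k),
    n_peaks = sizes,
    n_reads = as.integer(tapply(counts$n_total, grp, sum)),
    n_dup = as.integer(tapply(counts$n_dup, grp, sum)))
  out$dup_rate_in_group <- ifelse(out$n_reads > 0,
                                  out$n_dup / out$n_reads, NA_real_)
  out$pct_library_dups_in_group <-
    if (lib_dups > 0) 100 * out$n_dup / lib_dups else NA_real_
  if (!is.null(input_marking)) {
    ic <- count_regions(peaks_sorted, input_marking)
    in_dups <- sum(input_marking$tallies$duplicates)
    in_reads <- as.integer(tapply(ic$n_total, grp, sum))
    in_dup <- as.integer(tapply(ic$n_dup, grp, sum))
    out$matched_input_dup_rate <- ifelse(in_reads > 0, in_dup / in_reads,
                                         NA_real_)
    out$matched_input_pct <-
      if (in_dups > 0) 100 * in_dup / in_dups else NA_real_
  }
  attr(out, "group_of_peak") <- grp[order(ord)]  # group per input peak
  out
}

#' Most-duplicated positions
#'
#' Ranks occupied positions by duplicate count (descending; ties broken by
#' chromosome, coordinate, strand) and labels each with peak membership.
#'
#' @param marking `"dup_marking"` (or tally data.frame).
#' @param n Number of top positions to return (all, with a message, if fewer
#'   exist).
#' @param peaks GRanges of peaks for the in-peak label.
#' @return data.frame of the top `n` tallies with an `in_peak` logical and a
#'   `peak_idx` column (NA outside peaks); summary attributes
#'   `frac_in_peak` and `n_peaks_hit`.
#' @export
top_positions <- function(marking, n, peaks) {
  tallies <- if (inherits(marking, "dup_marking")) marking$tallies else marking
  if (n > nrow(tallies)) {
    message("requested ", n, " positions, only ", nrow(tallies),
            " available; returning all")
    n <- nrow(tallies)
  }
  ord <- order(-tallies$duplicates, tallies$chrom, tallies$fpos,
               tallies$strand)
  top <- tallies[ord[seq_len(n)], , drop = FALSE]
  pos <- tally_positions(top)
  ov <- GenomicRanges::findOverlaps(pos, peaks, ignore.strand = TRUE,
                                    select = "first")
  top$in_peak <- !is.na(ov)
  top$peak_idx <- ov
  rownames(top) <- NULL
  attr(top, "frac_in_peak") <- mean(top$in_peak)
  attr(top, "n_peaks_hit") <- length(unique(stats::na.omit(ov)))
  top
}

#' Replicate correlation of in-peak duplicate levels
#'
#' Pearson correlation between replicates of the per-merged-peak duplicate
#' RPK10M on the log2 scale (with an offset added before the log so peaks
#' with zero duplicates are retained), with the Fisher-z 95% confidence
#' interval.
#'
#' @param merged_peaks GRanges of merged replicate peaks (>= 3).
#' @param counts1,counts2 Per-merged-peak duplicate counts in replicate 1
#'   and 2 (same order as `merged_peaks`).
#' @param lib_size1,lib_size2 Uniquely mapped read totals of the replicates.
#' @param log2_offset Offset added before the log2 transform (default 1).
#' @return data.frame with `pearson_r`, `ci_low`, `ci_high`, `n`.
#' @export
replicate_correlation <- function(merged_peaks, counts1, counts2,
                                  lib_size1, lib_size2, log2_offset = 1) {
  stopifnot(length(counts1) == length(merged_peaks),
            length(counts2) == length(merged_peaks))
  if (length(merged_peaks) < 3L) stop("need at least 3 merged peaks")
  w <- GenomicRanges::width(merged_peaks)
  x <- log2(rpk10m(counts1, w, lib_size1) + log2_offset)
  y <- log2(rpk10m(counts2, w, lib_size2) + log2_offset)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in log2 RPK10M values")
  }
  r <- stats::cor(x, y)
  # Fisher z-transform confidence interval
  n <- length(x)
  z <- atanh(r)
  half <- stats::qnorm(0.975) / sqrt(max(n - 3, 1))
  data.frame(pearson_r = r,
             ci_low = tanh(z - half), ci_high = tanh(z + half),
             n = n)
}

#' Spearman correlation of peak duplicate level with six features
#'
#' Rank correlation of the per-peak duplicate level (duplicates per kb,
#' without library-size normalization) against the six candidate
#' determinants: nonduplicate level, input duplicate and nonduplicate level
#' over the same coordinates, GC fraction, and the segmental-duplication and
#' low-complexity overlap fractions. A constant column yields `NA` with a
#' warning.
#'
#' @param peak_table data.frame with columns `dup_level`, `nondup_level`,
#'   `input_dup_level`, `input_nondup_level`, `gc_fraction`, `pct_segdup`,
#'   `pct_lowcomplex`.
#' @return Named numeric vector of six Spearman rho values.
#' @export
feature_correlations <- function(peak_table) {
  feats <- c("nondup_level", "input_dup_level", "input_nondup_level",
             "gc_fraction", "pct_segdup", "pct_lowcomplex")
  missing_cols <- setdiff(c("dup_level", feats), names(peak_table))
  if (length(missing_cols)) {
    stop("peak_table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  vapply(feats, function(f) {
    x <- peak_table$dup_level
    y <- peak_table[[f]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("constant column in Spearman correlation: ", f)
      return(NA_real_)
    }
    stats::cor(x, y, method = "spearman")
  }, numeric(1))
}

#' Mean duplicates per occupied position
#'
#' Total duplicates divided by the number of positions holding at least one
#' read, after excluding positions whose key coordinate overlaps the
#' blacklist.
#'
#' @param marking `"dup_marking"` (or tally data.frame).
#' @param blacklist Optional GRanges of excluded regions.
#' @return Single numeric mean.
#' @export
mean_dups_per_position <- function(marking, blacklist = NULL) {
  tallies <- if (inherits(marking, "dup_marking")) marking$tallies else marking
  if (!is.null(blacklist) && nrow(tallies)) {
    hit <- IRanges::overlapsAny(tally_positions(tallies), blacklist,
                                ignore.strand = TRUE)
    tallies <- tallies[!hit, , drop = FALSE]
  }
  if (nrow(tallies) == 0L) stop("no positions left after blacklist exclusion")
  sum(tallies$duplicates) / nrow(tallies)
}
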