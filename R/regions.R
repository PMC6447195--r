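#' Read peak calls from BED or narrowPeak files
#'
#' Imports a peak list into a GRanges. ENCODE narrowPeak columns
#' (signalValue, pValue, qValue, peak) are recognized; for plain BED6 the
#' score column is kept. `pValue`/`qValue` are stored on the natural scale in
#' metadata columns `p_value` / `fdr` (narrowPeak encodes them as -log10,
#' which is undone here).
#'
#' @param file Path to a BED3/BED6 or narrowPeak file.
#' @param format `"auto"` (default; by extension), `"narrowPeak"` or `"bed"`.
#' @return GRanges with optional metadata columns `name`, `score`,
#'   `p_value`, `fdr`.
#' @export
read_peaks <- function(file, format = c("auto", "narrowPeak", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("narrowPeak$", file, ignore.case = TRUE))
      "narrowPeak" else "bed"
  }
  if (format == "narrowPeak") {
    gr <- rtracklayer::import(file, format = "BED",
      extraCols = c(signalValue = "numeric", pValue = "numeric",
                    qValue = "numeric", peak = "integer"))
    gr$p_value <- ifelse(gr$pValue < 0, NA_real_, 10^(-gr$pValue))
    gr$fdr <- ifelse(gr$qValue < 0, NA_real_, 10^(-gr$qValue))
  } else {
    first <- readLines(file, n = 1L)
    n_fields <- length(strsplit(first, "\t")[[1]])
    if (n_fields == 7L) {
      # BED6 + natural-scale p-value column (the simulator's peak format)
      gr <- rtracklayer::import(file, format = "BED",
                                extraCols = c(p_value = "numeric"))
    } else {
      gr <- rtracklayer::import(file, format = "BED")
    }
  }
  gr
}

#' Read a two-column chromosome sizes file
#'
#' @param file Tab-separated text: chromosome name, length.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"),
                           colClasses = c("character", "integer"))
  stats::setNames(tab$size, tab$chrom)
}

# GRanges spanning each whole chromosome.
genome_ranges <- function(chrom_sizes) {
  GenomicRanges::GRanges(
    seqnames = names(chrom_sizes),
    ranges = IRanges::IRanges(start = 1L, end = unname(chrom_sizes)),
    seqlengths = chrom_sizes)
}

#' Remove peaks overlapping a blacklist
#'
#' A peak is dropped when it overlaps any blacklist interval by at least one
#' base. Counts of kept/removed peaks are attached as attributes; a warning
#' with a per-chromosome summary is raised when the two sets share no
#' chromosome names (a likely assembly mismatch).
#'
#' @param peaks GRanges of peaks.
#' @param blacklist GRanges of excluded regions.
#' @return The kept peaks, with `attr(, "n_removed")` / `attr(, "n_kept")`.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  pc <- unique(as.character(GenomicRanges::seqnames(peaks)))
  bc <- unique(as.character(GenomicRanges::seqnames(blacklist)))
  if (length(pc) && length(bc) && !length(intersect(pc, bc))) {
    warning("no shared chromosome names between peaks (",
            paste(utils::head(pc, 3), collapse = ","), ") and blacklist (",
            paste(utils::head(bc, 3), collapse = ","), ")")
  }
  hit <- IRanges::overlapsAny(peaks, blacklist, minoverlap = 1L,
                              ignore.strand = TRUE)
  kept <- peaks[!hit]
  attr(kept, "n_removed") <- sum(hit)
  attr(kept, "n_kept") <- sum(!hit)
  kept
}

#' Non-peak complement of the genome
#'
#' The non-peak region set: every base not covered by a peak nor by the
#' `buffer_bp` exclusion strip on either side of a peak. Padded peaks are
#' clipped at chromosome ends before complementing, so the complement plus
#' the padded peaks tile each chromosome exactly once.
#'
#' @param peaks Blacklist-filtered peaks (GRanges).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param buffer_bp Exclusion buffer around each peak (default 100).
#' @return GRanges of non-peak intervals (sorted, disjoint).
#' @export
nonpeak_complement <- function(peaks, chrom_sizes, buffer_bp = 100L) {
  gen <- genome_ranges(chrom_sizes)
  if (length(peaks) == 0L) return(gen)
  padded <- pad_peaks(peaks, chrom_sizes, buffer_bp)
  GenomicRanges::setdiff(gen, padded, ignore.strand = TRUE)
}

# Peaks extended by buffer_bp on both sides, clipped, merged.
pad_peaks <- function(peaks, chrom_sizes, buffer_bp) {
  p <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(peaks),
    ranges = IRanges::IRanges(
      start = pmax(1L, GenomicRanges::start(peaks) - buffer_bp),
      end = pmin(chrom_sizes[as.character(GenomicRanges::seqnames(peaks))],
                 GenomicRanges::end(peaks) + buffer_bp)),
    seqlengths = chrom_sizes)
  GenomicRanges::reduce(p, ignore.strand = TRUE)
}

#' Peak-flanking regions
#'
#' For each peak, the 5' and 3' flanking windows: peak-sized intervals
#' `gap_bp` away from the peak on either side (the gap approximates the
#' fragment size, keeping the flank clear of peak influence). Flanks are
#' truncated at chromosome ends; fully out-of-bounds flanks are dropped with
#' a message.
#'
#' @param peaks GRanges of peaks.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param gap_bp Distance between peak edge and flank (default 300).
#' @return A list with GRanges elements `flank5` and `flank3`, each carrying
#'   a `peak_idx` metadata column linking back to its peak.
#' @export
flanking_regions <- function(peaks, chrom_sizes, gap_bp = 300L) {
  L <- GenomicRanges::width(peaks)
  s <- GenomicRanges::start(peaks)
  e <- GenomicRanges::end(peaks)
  chr <- as.character(GenomicRanges::seqnames(peaks))
  len <- unname(chrom_sizes[chr])
  mk <- function(start, end) {
    idx <- seq_along(peaks)
    ok <- end >= 1L & start <= len
    n_drop <- sum(!ok)
    if (n_drop) message(n_drop, " flank(s) fully outside chromosome bounds, dropped")
    start <- pmax(1L, start[ok]); end <- pmin(len[ok], end[ok])
    gr <- GenomicRanges::GRanges(chr[ok], IRanges::IRanges(start, end),
                                 seqlengths = chrom_sizes)
    gr$peak_idx <- idx[ok]
    gr
  }
  list(flank5 = mk(s - gap_bp - L, s - gap_bp - 1L),
       flank3 = mk(e + gap_bp + 1L, e + gap_bp + L))
}

#' Merge replicate peak lists
#'
#' Single-linkage merge of peaks from two or more replicates: intervals
#' overlapping by at least one base (transitively) become one merged
#' interval. Each merged interval records the replicate membership of its
#' source peaks.
#'
#' @param peak_lists List of two or more GRanges.
#' @return GRanges of merged intervals with metadata columns `n_sources`
#'   (number of source peaks) and `replicates` (comma-separated replicate
#'   indices contributing).
#' @export
merge_replicate_peaks <- function(peak_lists) {
  stopifnot(is.list(peak_lists), length(peak_lists) >= 2L)
  rep_idx <- rep(seq_along(peak_lists),
                 vapply(peak_lists, length, integer(1)))
  all_peaks <- suppressWarnings(do.call(c, lapply(peak_lists, function(g) {
    GenomicRanges::granges(g)
  })))
  # min.gapwidth = 0: touching intervals share no base and stay separate
  merged <- GenomicRanges::reduce(all_peaks, ignore.strand = TRUE,
                                  with.revmap = TRUE, min.gapwidth = 0L)
  merged$n_sources <- lengths(merged$revmap)
  merged$replicates <- vapply(merged$revmap, function(i) {
    paste(sort(unique(rep_idx[i])), collapse = ",")
  }, character(1))
  merged$revmap <- NULL
  merged
}

#' Sequence-composition features of peaks
#'
#' Per-peak GC fraction and overlap fractions with segmental-duplication and
#' low-complexity annotation sets. GC counts G/C case-insensitively; `N`
#' bases enter the denominator but never the numerator. Overlap fractions
#' are overlapping bases divided by peak length.
#'
#' @param peaks GRanges of peaks.
#' @param genome_fasta Path to an indexed FASTA (the index is created when
#'   missing).
#' @param segdup,lowcomplex GRanges annotation sets (either may be NULL, in
#'   which case the corresponding column is NA).
#' @return data.frame with columns `gc_fraction`, `pct_segdup`,
#'   `pct_lowcomplex`, one row per peak.
#' @export
annotate_composition <- function(peaks, genome_fasta, segdup = NULL,
                                 lowcomplex = NULL) {
  if (!file.exists(paste0(genome_fasta, ".fai"))) {
    Rsamtools::indexFa(genome_fasta)
  }
  fa <- Rsamtools::FaFile(genome_fasta)
  contig_len <- Rsamtools::scanFaIndex(fa)
  bad <- !IRanges::overlapsAny(peaks, contig_len, type = "within",
                               ignore.strand = TRUE)
  if (any(bad)) {
    stop("peak(s) beyond FASTA contig bounds, e.g. index ", which(bad)[1])
  }
  seqs <- Rsamtools::getSeq(fa, GenomicRanges::granges(peaks))
  gc <- as.numeric(Biostrings::letterFrequency(seqs, letters = "GC")) /
    GenomicRanges::width(peaks)
  data.frame(
    gc_fraction = gc,
    pct_segdup = overlap_fraction(peaks, segdup),
    pct_lowcomplex = overlap_fraction(peaks, lowcomplex))
}

# Fraction of each query interval covered by the (merged) subject set.
overlap_fraction <- function(query, subject) {
  if (is.null(subject)) return(rep(NA_real_, length(query)))
  subject <- GenomicRanges::reduce(GenomicRanges::granges(subject),
                                   ignore.strand = TRUE)
  out <- numeric(length(query))
  ov <- GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE)
  if (length(ov)) {
    q <- query[S4Vectors::queryHits(ov)]
    s <- subject[S4Vectors::subjectHits(ov)]
    w <- pmin(GenomicRanges::end(q), GenomicRanges::end(s)) -
      pmax(GenomicRanges::start(q), GenomicRanges::start(s)) + 1L
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out / GenomicRanges::width(query)
}
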