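#' Read uniquely mapped primary alignments from a BAM or SAM file
#'
#' Loads primary alignment records (secondary, supplementary and unmapped
#' records are skipped) into a plain data frame, one row per aligned read
#' (per end, for paired data). Positions are 1-based leftmost mapped
#' coordinates, as in SAM. The `MD` and `NM` auxiliary tags are carried along
#' when present; `MD` is the per-base match/mismatch evidence used by
#' [passes_filters()].
#'
#' @param file Path to a coordinate-sorted BAM file, or a SAM text file
#'   (converted on the fly).
#' @return A data.frame with columns `read_id`, `flag`, `chrom`, `pos`
#'   (1-based leftmost), `cigar`, `strand`, `mapq`, `nm`, `md`, `mate_chrom`,
#'   `mate_pos`, `is_first` (logical; `NA` for unpaired reads). The
#'   chromosome order of the file header is kept in
#'   `attr(, "chrom_order")` and sequence lengths in `attr(, "chrom_sizes")`.
#' @export
read_alignments <- function(file) {
  bam <- as_bam_path(file)
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
             "mrnm", "mpos"),
    tag = c("MD", "NM"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(res$qname)
  aln <- data.frame(
    read_id = res$qname,
    flag = res$flag,
    chrom = as.character(res$rname),
    pos = res$pos,
    cigar = res$cigar,
    strand = as.character(res$strand),
    mapq = res$mapq,
    nm = if (is.null(res$tag$NM)) rep(NA_integer_, n) else res$tag$NM,
    md = if (is.null(res$tag$MD)) rep(NA_character_, n) else res$tag$MD,
    mate_chrom = as.character(res$mrnm),
    mate_pos = res$mpos,
    is_first = ifelse(bitwAnd(res$flag, 0x1L) > 0L,
                      bitwAnd(res$flag, 0x40L) > 0L, NA),
    stringsAsFactors = FALSE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  attr(aln, "chrom_order") <- names(hdr)
  attr(aln, "chrom_sizes") <- hdr
  aln
}

# Convert a SAM text file to an indexed BAM in tempdir(); pass BAM through.
as_bam_path <- function(file) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(file, destination = dest, overwrite = TRUE,
                     indexDestination = TRUE)
  } else {
    file
  }
}

#' Alignment filters: mapping quality and leading-base mismatches
#'
#' Tests whether reads satisfy the uniqueness filters applied before any
#' duplicate accounting: a minimum mapping quality and no mismatch within the
#' first `check_first` sequenced bases. "First" is in sequencing order, i.e.
#' the read's 5' end: for reverse-strand alignments these are the
#' reference-rightmost aligned bases. Mismatch evidence comes from the `MD`
#' tag combined with the CIGAR (insertions count as mismatches; clipped bases
#' are not evaluable and are treated as non-mismatches).
#'
#' @param aln Alignment data.frame from [read_alignments()] (or any data
#'   frame with `cigar`, `strand`, `mapq`, `md`, `nm` columns).
#' @param min_mapq Minimum mapping quality (default 20).
#' @param check_first Number of leading sequenced bases that must be
#'   mismatch-free (default 5; 0 disables the check).
#' @param on_missing What to do when `check_first > 0` but a record has no
#'   `MD` tag: `"error"` (default) or `"nm0"`, which falls back to requiring
#'   a zero edit distance (`NM == 0`) for that record.
#' @return Logical vector, one element per row of `aln`.
#' @export
passes_filters <- function(aln, min_mapq = 20L, check_first = 5L,
                           on_missing = c("error", "nm0")) {
  on_missing <- match.arg(on_missing)
  ok <- !is.na(aln$mapq) & aln$mapq >= min_mapq
  if (check_first > 0L) {
    has_md <- !is.na(aln$md)
    if (any(!has_md)) {
      if (on_missing == "error") {
        stop("missing MD mismatch evidence for ",
             sum(!has_md), " record(s) with check_first > 0; ",
             "use on_missing = \"nm0\" to fall back to NM == 0")
      }
      ok[!has_md] <- ok[!has_md] & !is.na(aln$nm[!has_md]) &
        aln$nm[!has_md] == 0L
    }
    idx <- which(ok & has_md)
    if (length(idx)) {
      # evaluate once per distinct (cigar, md, strand) combination
      combo <- paste(aln$cigar[idx], aln$md[idx], aln$strand[idx],
                     sep = "\r")
      u <- !duplicated(combo)
      clean_u <- vapply(idx[u], function(i) {
        first_n_clean(aln$cigar[i], aln$md[i], aln$strand[i], check_first)
      }, logical(1))
      names(clean_u) <- combo[u]
      ok[idx] <- unname(clean_u[combo])
    }
  }
  ok
}

# TRUE iff none of the first n sequenced bases (read 5' end) mismatches the
# reference. Builds a per-query-base mismatch vector in reference order from
# CIGAR + MD, then reads it from the sequencing 5' end.
first_n_clean <- function(cigar, md, strand, n) {
  mm <- query_mismatch_vector(cigar, md)
  if (length(mm) == 0L) return(TRUE)
  if (strand == "-") mm <- rev(mm)
  !any(mm[seq_len(min(n, length(mm)))])
}

# Per-query-base status in reference order: TRUE = mismatch (substitution or
# inserted base), FALSE = match or clipped (unevaluable).
query_mismatch_vector <- function(cigar, md) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  # mismatch calls along aligned (M/=/X) bases, from MD
  md_mm <- md_mismatch_vector(md)
  out <- logical(0)
  mdi <- 0L
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      out <- c(out, md_mm[mdi + seq_len(len)])
      mdi <- mdi + len
    } else if (op == "I") {
      out <- c(out, rep(TRUE, len))
    } else if (op == "S") {
      out <- c(out, rep(FALSE, len))
    } # D/N/H/P consume no query bases (MD deletions handled in md_mm parse)
  }
  out
}

# Parse an MD tag into a logical vector over aligned reference bases
# (deletions excluded): TRUE = substitution.
md_mismatch_vector <- function(md) {
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1]]
  out <- logical(0)
  for (t in toks) {
    if (grepl("^\\d+$", t)) {
      out <- c(out, rep(FALSE, as.integer(t)))
    } else if (startsWith(t, "^")) {
      # deleted reference bases: no query base consumed
    } else {
      out <- c(out, TRUE)
    }
  }
  out
}

#' Strand-aware unclipped 5' coordinates
#'
#' Computes the duplicate-key coordinate of each alignment: the 5' position
#' of the read with soft/hard-clipped bases restored (the "unclipped"
#' position, as used by standard duplicate markers), so identical fragments
#' that differ only in clipping collide. For forward-strand reads this is the
#' unclipped leftmost base; for reverse-strand reads the unclipped rightmost
#' aligned base.
#'
#' @param pos 1-based leftmost mapped positions.
#' @param cigar CIGAR strings.
#' @param strand `"+"` or `"-"` per record.
#' @return Integer vector of 1-based 5' coordinates.
#' @export
five_prime_pos <- function(pos, cigar, strand) {
  # per distinct CIGAR: leading/trailing clip lengths and reference width
  uc <- unique(cigar)
  ops <- GenomicAlignments::explodeCigarOps(uc)
  lens <- GenomicAlignments::explodeCigarOpLengths(uc)
  lead_u <- mapply(function(o, l) {
    i <- which(!o %in% c("S", "H"))
    if (length(i) == 0L) 0L else sum(l[seq_len(min(i) - 1L)])
  }, ops, lens)
  trail_u <- mapply(function(o, l) {
    i <- which(!o %in% c("S", "H"))
    if (length(i) == 0L) 0L else {
      j <- max(i)
      if (j == length(o)) 0L else sum(l[(j + 1L):length(l)])
    }
  }, ops, lens)
  refw_u <- GenomicAlignments::cigarWidthAlongReferenceSpace(uc)
  m <- match(cigar, uc)
  ifelse(strand == "-",
         as.integer(pos + refw_u[m] - 1L + trail_u[m]),
         as.integer(pos - lead_u[m]))
}

#' Duplicate grouping keys
#'
#' Builds the duplicate key of each read (single-end mode) or each read pair
#' (paired mode). Two single-end reads are duplicates when they share
#' chromosome, unclipped 5' coordinate and strand; two pairs are duplicates
#' only when both ends match, with the two ends of a key ordered canonically
#' (smaller coordinate first) so the key does not depend on which end is
#' read first.
#'
#' @param aln Alignment data.frame (see [read_alignments()]).
#' @param mode `"single"` or `"paired"`.
#' @return In single mode, a data.frame with one row per read: `read_id`,
#'   `chrom`, `fpos`, `strand`, `key`. In paired mode, one row per complete
#'   pair: `read_id`, `chrom`, `fpos1`, `strand1`, `fpos2`, `strand2`, `key`,
#'   plus `row1`/`row2` giving the member rows of `aln`.
#' @export
dup_key <- function(aln, mode = c("single", "paired")) {
  mode <- match.arg(mode)
  fpos <- five_prime_pos(aln$pos, aln$cigar, aln$strand)
  if (mode == "single") {
    return(data.frame(
      read_id = aln$read_id, chrom = aln$chrom, fpos = fpos,
      strand = aln$strand,
      key = paste(aln$chrom, fpos, aln$strand, sep = ":"),
      stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(aln)), aln$read_id)
  complete <- vapply(sp, length, integer(1)) == 2L
  if (any(!complete)) {
    stop("paired mode: ", sum(!complete),
         " read id(s) without exactly two primary ends, e.g. ",
         names(sp)[which(!complete)[1]])
  }
  rows1 <- vapply(sp, `[`, integer(1), 1L)
  rows2 <- vapply(sp, `[`, integer(1), 2L)
  if (any(aln$chrom[rows1] != aln$chrom[rows2])) {
    bad <- names(sp)[aln$chrom[rows1] != aln$chrom[rows2]][1]
    stop("paired mode: mates on different chromosomes (e.g. ", bad, ")")
  }
  f1 <- fpos[rows1]; f2 <- fpos[rows2]
  s1 <- aln$strand[rows1]; s2 <- aln$strand[rows2]
  swap <- f2 < f1 | (f2 == f1 & s2 < s1)
  a_pos <- ifelse(swap, f2, f1); b_pos <- ifelse(swap, f1, f2)
  a_str <- ifelse(swap, s2, s1); b_str <- ifelse(swap, s1, s2)
  data.frame(
    read_id = names(sp), chrom = aln$chrom[rows1],
    fpos1 = as.integer(a_pos), strand1 = a_str,
    fpos2 = as.integer(b_pos), strand2 = b_str,
    key = paste(aln$chrom[rows1], a_pos, a_str, b_pos, b_str, sep = ":"),
    row1 = rows1, row2 = rows2,
    stringsAsFactors = FALSE)
}

#' Mark duplicate reads
#'
#' Groups filtered, coordinate-sorted alignments by duplicate key and flags,
#' within each key, one representative as nonredundant and the remaining
#' `n - 1` reads (or pairs) as duplicates. Reads at the same position on
#' opposite strands occupy distinct keys and are counted separately. The
#' representative is the first record in (coordinate, read id) order, which
#' makes the marking deterministic and order-invariant.
#'
#' @param aln Alignment data.frame, coordinate-sorted (an error names the
#'   first out-of-order record otherwise). Apply [passes_filters()] first;
#'   dropped reads must not be present.
#' @param mode `"single"` or `"paired"`.
#' @return A list of class `"dup_marking"`:
#'   \describe{
#'     \item{tallies}{data.frame, one row per occupied key: `chrom`, `fpos`,
#'       `strand` (plus `fpos2`, `strand2` in paired mode), `key`, `n_reads`,
#'       `duplicates` (`= n_reads - 1`), `representative_read_id`.}
#'     \item{flags}{data.frame, one row per read (per pair in paired mode):
#'       `read_id`, `key`, `is_duplicate`.}
#'     \item{mode}{the mode used.}
#'   }
#' @export
mark_duplicates <- function(aln, mode = c("single", "paired")) {
  mode <- match.arg(mode)
  check_sorted(aln)
  keys <- dup_key(aln, mode)
  # deterministic representative: first by (coordinate, read_id) within key
  anchor <- if (mode == "single") aln$pos else pmin(keys$fpos1, keys$fpos2)
  ord <- order(keys$chrom, anchor, keys$read_id)
  keys_o <- keys[ord, , drop = FALSE]
  first <- !duplicated(keys_o$key)
  is_dup <- logical(nrow(keys_o))
  is_dup[!first] <- TRUE
  flags <- data.frame(read_id = keys_o$read_id, key = keys_o$key,
                      is_duplicate = is_dup, stringsAsFactors = FALSE)
  n_reads <- table(keys$key)
  rep_ids <- keys_o$read_id[first]
  names(rep_ids) <- keys_o$key[first]
  uk <- keys_o[first, , drop = FALSE]
  tallies <- data.frame(
    chrom = uk$chrom,
    fpos = if (mode == "single") uk$fpos else uk$fpos1,
    strand = if (mode == "single") uk$strand else uk$strand1,
    key = uk$key,
    n_reads = as.integer(n_reads[uk$key]),
    representative_read_id = rep_ids[uk$key],
    stringsAsFactors = FALSE)
  if (mode == "paired") {
    tallies$fpos2 <- uk$fpos2
    tallies$strand2 <- uk$strand2
  }
  tallies$duplicates <- tallies$n_reads - 1L
  rownames(tallies) <- rownames(flags) <- NULL
  structure(list(tallies = tallies, flags = flags, mode = mode),
            class = "dup_marking")
}

#' @export
print.dup_marking <- function(x, ...) {
  cat("Duplicate marking (", x$mode, "-end)\n", sep = "")
  cat("  reads/pairs: ", nrow(x$flags),
      "  positions: ", nrow(x$tallies),
      "  duplicates: ", sum(x$tallies$duplicates), "\n", sep = "")
  invisible(x)
}

check_sorted <- function(aln) {
  if (nrow(aln) < 2L) return(invisible(TRUE))
  chrom <- aln$chrom
  new_block <- c(TRUE, chrom[-1] != chrom[-length(chrom)])
  blocks <- chrom[new_block]
  if (anyDuplicated(blocks)) {
    bad <- blocks[duplicated(blocks)][1]
    i <- which(new_block & chrom == bad)[2]
    stop("alignments not coordinate-sorted: chromosome ", bad,
         " re-appears at record ", i, " (", aln$read_id[i], ")")
  }
  run <- cumsum(new_block)
  off <- which(diff(aln$pos) < 0 & run[-1] == run[-length(run)])
  if (length(off)) {
    i <- off[1] + 1L
    stop("alignments not coordinate-sorted: record ", i, " (",
         aln$read_id[i], ", ", chrom[i], ":", aln$pos[i],
         ") precedes its predecessor")
  }
  invisible(TRUE)
}

#' Write a duplicate-flagged BAM
#'
#' Re-emits the records of `file` with the SAM duplicate flag bit (0x400) set
#' on every read marked duplicate, producing a sorted, indexed BAM. Records
#' are rebuilt from parsed fields; of the auxiliary tags only `MD` and `NM`
#' are carried over.
#'
#' @param file Input BAM/SAM with primary unique alignments.
#' @param marking A `"dup_marking"` from [mark_duplicates()] for this file.
#' @param out Output BAM path (".bam" appended if absent).
#' @return The output BAM path, invisibly.
#' @export
write_marked_bam <- function(file, marking, out) {
  bam <- as_bam_path(file)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
             "mrnm", "mpos", "isize", "seq", "qual"),
    tag = c("MD", "NM"))
  r <- Rsamtools::scanBam(bam, param = param)[[1]]
  dup_ids <- marking$flags$read_id[marking$flags$is_duplicate]
  flag <- r$flag
  hit <- r$qname %in% dup_ids
  flag[hit] <- bitwOr(flag[hit], 0x400L)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  seqs <- as.character(r$seq)
  quals <- as.character(r$qual)
  seqs[seqs == ""] <- "*"; quals[quals == ""] <- "*"
  fields <- cbind(
    r$qname, flag, as.character(r$rname), r$pos, r$mapq, r$cigar,
    ifelse(is.na(as.character(r$mrnm)), "*",
           ifelse(as.character(r$mrnm) == as.character(r$rname), "=",
                  as.character(r$mrnm))),
    ifelse(is.na(r$mpos), 0L, r$mpos),
    ifelse(is.na(r$isize), 0L, r$isize), seqs, quals)
  lines <- apply(fields, 1L, paste, collapse = "\t")
  if (!is.null(r$tag$NM)) {
    has <- !is.na(r$tag$NM)
    lines[has] <- paste0(lines[has], "\tNM:i:", r$tag$NM[has])
  }
  if (!is.null(r$tag$MD)) {
    has <- !is.na(r$tag$MD)
    lines[has] <- paste0(lines[has], "\tMD:Z:", r$tag$MD[has])
  }
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", names(hdr), "\tLN:", hdr),
              paste("@PG\tID:peakdedup", "PN:peakdedup",
                    paste0("VN:", as.character(utils::packageVersion("peakdedup"))),
                    sep = "\t"))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, lines), sam)
  out <- sub("\\.bam$", "", out)
  Rsamtools::asBam(sam, destination = out, overwrite = TRUE,
                   indexDestination = TRUE)
  unlink(sam)
  invisible(paste0(out, ".bam"))
}
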