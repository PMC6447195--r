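#' Synthetic ChIP-seq library configuration
#'
#' Assembles the parameters of the synthetic library generator. The
#' generator emulates a small genome in which peaks cover a small fraction
#' of the sequence but receive most fragments, background fragments fall
#' uniformly elsewhere, natural duplicates arise purely from coordinate
#' collisions of independent templates, and PCR duplicates arise from
#' amplified extra copies of templates. Amplification propensity is
#' locus-structured: only templates from amplification-prone ("hotspot")
#' loci, drawn with probability `hotspot_frac`, receive geometric extra-copy
#' counts, with the per-template mean scaled so the library-wide mean number
#' of extra copies stays `pcr_rho / (1 - pcr_rho)` regardless of
#' `hotspot_frac`.
#'
#' @param chrom_sizes Named vector of toy-genome chromosome lengths
#'   (default one 1 Mb chromosome).
#' @param n_peaks Number of non-overlapping peaks (default 50).
#' @param n_fragments Number of independent DNA templates (default 50000;
#'   sequenced reads exceed this by the amplified copies).
#' @param frip Fraction of templates originating in peaks (default 0.8).
#' @param peak_len_range Min/max peak length in bp (default 800-1600).
#' @param intensity_sdlog Log-normal sd of relative peak intensities
#'   (default 0.5), giving the spread of enrichment levels.
#' @param center_spread_frac Standard deviation of fragment centers around
#'   the peak center, as a fraction of peak length (default 0.25).
#' @param frag_len_mean,frag_len_sd Fragment length distribution
#'   (default 200 +/- 20).
#' @param read_len Read length (default 50).
#' @param pcr_rho Geometric amplification rate in `[0, 1)`; mean extra
#'   copies per template is `pcr_rho / (1 - pcr_rho)`; 0 = PCR-free.
#' @param hotspot_frac Fraction of loci that are amplification-prone
#'   (default 0.2).
#' @param paired Emit read pairs instead of single-end reads.
#' @param frac_low_mapq,frac_early_mismatch Fractions of reads emitted with
#'   sub-threshold mapping quality / with a mismatch within the first five
#'   sequenced bases, to exercise the alignment filters (defaults 0).
#' @param p_scale Scale of the pseudo p-values, `p = exp(-templates /
#'   p_scale)` (default 50).
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(chrom_sizes = c(chrS = 1e6L),
                       n_peaks = 50L,
                       n_fragments = 50000L,
                       frip = 0.8,
                       peak_len_range = c(800L, 1600L),
                       intensity_sdlog = 0.5,
                       center_spread_frac = 0.25,
                       frag_len_mean = 200,
                       frag_len_sd = 20,
                       read_len = 50L,
                       pcr_rho = 0,
                       hotspot_frac = 0.2,
                       paired = FALSE,
                       frac_low_mapq = 0,
                       frac_early_mismatch = 0,
                       p_scale = 50) {
  stopifnot(all(chrom_sizes > 0), n_peaks >= 1, n_fragments >= 1,
            frip >= 0, frip <= 1, pcr_rho >= 0, pcr_rho < 1,
            hotspot_frac > 0, hotspot_frac <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a ChIP-seq alignment library with duplicate ground truth
#'
#' Draws non-overlapping peaks, template 5' positions concentrated around
#' peak centers (background templates uniform elsewhere), and emits each
#' template `1 + copies` times, `copies` following the locus-structured
#' geometric amplification model of [sim_config()]. Every read is uniquely
#' mapped with high mapping quality and clean leading bases unless the
#' filter-exercise fractions are set. Pseudo p-values per peak decrease
#' monotonically in template count.
#'
#' @param config `"sim_config"`.
#' @param seed Integer seed (mandatory; every random draw depends on it).
#' @param dir Optional directory; when given, a sorted indexed BAM
#'   (`sim.bam`), a peaks BED6+ file (`peaks.bed`: name, score,
#'   strand, p-value) and a truth TSV (`truth.tsv`) are written there.
#' @return List: `alignments` (data.frame in [read_alignments()] layout,
#'   coordinate-sorted), `peaks` (GRanges with `name`, `score`, `p_value`),
#'   `truth` (data.frame `read_id`, `template_id`, `is_pcr_copy`, `origin`,
#'   `pass_filters`), `config`, `seed`, and the file paths when `dir` is
#'   given.
#' @export
simulate_library <- function(config, seed, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  res <- withr::with_seed(seed, simulate_library_impl(config))
  res$seed <- seed
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    res$bam <- write_alignment_bam(res$alignments, config$chrom_sizes,
                                   file.path(dir, "sim"),
                                   paired = config$paired)
    peak_df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(res$peaks)),
      start = GenomicRanges::start(res$peaks) - 1L,
      end = GenomicRanges::end(res$peaks),
      name = res$peaks$name,
      score = res$peaks$score,
      strand = ".",
      p_value = res$peaks$p_value)
    res$peaks_file <- file.path(dir, "peaks.bed")
    utils::write.table(peak_df, res$peaks_file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    res$truth_file <- file.path(dir, "truth.tsv")
    utils::write.table(res$truth, res$truth_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res
}

# Draw the binding landscape shared by replicate libraries: peak placement,
# relative intensities and amplification-prone (hotspot) status.
draw_landscape <- function(cf) {
  sizes <- cf$chrom_sizes
  # peaks: allocate across chromosomes by length, place one per slot so the
  # set is non-overlapping by construction
  n_per_chrom <- round(cf$n_peaks * sizes / sum(sizes))
  n_per_chrom[1] <- cf$n_peaks - sum(n_per_chrom[-1])
  peak_chrom <- rep(names(sizes), n_per_chrom)
  peak_len <- sample(cf$peak_len_range[1]:cf$peak_len_range[2], cf$n_peaks,
                     replace = TRUE)
  peak_start <- integer(cf$n_peaks)
  margin <- 2000L
  for (ch in names(sizes)) {
    idx <- which(peak_chrom == ch)
    if (!length(idx)) next
    slot <- sizes[[ch]] %/% length(idx)
    if (slot < max(peak_len[idx]) + 2L * margin) {
      stop("genome too small for ", length(idx), " peaks on ", ch)
    }
    off <- vapply(idx, function(i) {
      sample.int(slot - peak_len[i] - 2L * margin, 1L) + margin
    }, integer(1))
    peak_start[idx] <- (seq_along(idx) - 1L) * slot + off
  }
  peaks <- GenomicRanges::GRanges(
    peak_chrom,
    IRanges::IRanges(start = peak_start, width = peak_len),
    seqlengths = sizes)
  stopifnot(!any(GenomicRanges::countOverlaps(peaks, peaks) > 1L))

  # relative intensities: log-normal
  w <- stats::rlnorm(cf$n_peaks, meanlog = 0, sdlog = cf$intensity_sdlog)

  # amplification-prone peaks: hotspot status is independent of binding
  # intensity, enforced in realization by stratified assignment (one random
  # hotspot per intensity stratum), as in stratified randomization
  n_hot <- max(1L, round(cf$hotspot_frac * cf$n_peaks))
  hot_peak <- rep(FALSE, cf$n_peaks)
  by_intensity <- order(w)
  strata <- split(by_intensity,
                  cut(seq_len(cf$n_peaks), breaks = n_hot, labels = FALSE))
  hot_peak[vapply(strata, function(s) s[sample.int(length(s), 1L)],
                  integer(1))] <- TRUE
  list(peaks = peaks, peak_chrom = peak_chrom, peak_len = peak_len,
       w = w, hot_peak = hot_peak)
}

simulate_library_impl <- function(cf, landscape = NULL) {
  sizes <- cf$chrom_sizes
  if (is.null(landscape)) landscape <- draw_landscape(cf)
  peaks <- landscape$peaks
  peak_chrom <- landscape$peak_chrom
  peak_len <- landscape$peak_len
  w <- landscape$w
  hot_peak <- landscape$hot_peak

  # templates per peak: Poisson around the landscape intensities
  t_peak <- stats::rpois(cf$n_peaks, cf$frip * cf$n_fragments * w / sum(w))
  t_bg <- stats::rpois(1, (1 - cf$frip) * cf$n_fragments)

  # in-peak templates: fragment centers normal around the peak center
  origin <- rep(seq_len(cf$n_peaks), t_peak)
  centers <- GenomicRanges::start(peaks)[origin] +
    peak_len[origin] / 2 +
    stats::rnorm(length(origin), 0, peak_len[origin] * cf$center_spread_frac)
  frag_len <- pmax(cf$read_len * 2L,
                   round(stats::rnorm(length(origin) + t_bg,
                                      cf$frag_len_mean, cf$frag_len_sd)))
  chrom <- c(peak_chrom[origin], character(t_bg))
  # background templates: uniform over the genome
  if (t_bg > 0L) {
    bg_chrom <- sample(names(sizes), t_bg, replace = TRUE,
                       prob = sizes / sum(sizes))
    chrom[length(origin) + seq_len(t_bg)] <- bg_chrom
    bg_centers <- stats::runif(t_bg, 1, unname(sizes[bg_chrom]))
    centers <- c(centers, bg_centers)
  }
  n_tpl <- length(centers)
  tpl_origin <- c(paste0("peak_", origin), rep("background", t_bg))
  left <- round(centers - frag_len / 2)
  right <- left + frag_len - 1L
  # clamp fragments inside chromosomes
  len_of <- unname(sizes[chrom])
  shift <- pmax(0L, 1L - left) - pmax(0L, right - len_of)
  left <- as.integer(left + shift); right <- as.integer(right + shift)

  # locus-structured amplification
  mu <- cf$pcr_rho / (1 - cf$pcr_rho)
  hot <- c(hot_peak[origin],
           if (t_bg > 0L) stats::runif(t_bg) < cf$hotspot_frac else logical(0))
  copies <- integer(n_tpl)
  if (mu > 0 && any(hot)) {
    mu_hot <- mu / cf$hotspot_frac
    copies[hot] <- stats::rgeom(sum(hot), prob = 1 / (1 + mu_hot))
  }

  # one sequenced unit (read or pair) per template copy
  rep_idx <- rep(seq_len(n_tpl), copies + 1L)
  is_pcr <- unlist(lapply(copies + 1L, function(k) {
    c(FALSE, rep(TRUE, k - 1L))
  }), use.names = FALSE)
  n_read <- length(rep_idx)
  read_id <- sprintf("r%08d", seq_len(n_read))
  tpl_strand <- sample(c("+", "-"), n_tpl, replace = TRUE)

  truth <- data.frame(
    read_id = read_id,
    template_id = sprintf("t%08d", rep_idx),
    is_pcr_copy = is_pcr,
    origin = tpl_origin[rep_idx],
    pass_filters = TRUE,
    stringsAsFactors = FALSE)

  mapq <- sample(30:60, n_read, replace = TRUE)
  md <- rep(as.character(cf$read_len), n_read)
  nm <- rep(0L, n_read)
  if (cf$frac_low_mapq > 0) {
    k <- stats::runif(n_read) < cf$frac_low_mapq
    mapq[k] <- sample(0:19, sum(k), replace = TRUE)
    truth$pass_filters[k] <- FALSE
  }
  cigar <- paste0(cf$read_len, "M")

  if (!cf$paired) {
    str <- tpl_strand[rep_idx]
    fpos <- ifelse(str == "+", left[rep_idx], right[rep_idx])
    pos <- ifelse(str == "+", fpos, fpos - cf$read_len + 1L)
    if (cf$frac_early_mismatch > 0) {
      k <- stats::runif(n_read) < cf$frac_early_mismatch
      # mismatch at sequenced base 3: reference-order position depends on
      # strand (reverse reads are sequenced from the reference-right end)
      md[k & str == "+"] <- paste0("2A", cf$read_len - 3L)
      md[k & str == "-"] <- paste0(cf$read_len - 3L, "A2")
      nm[k] <- 1L
      truth$pass_filters[k] <- FALSE
    }
    aln <- data.frame(
      read_id = read_id, flag = ifelse(str == "-", 16L, 0L),
      chrom = chrom[rep_idx], pos = as.integer(pos), cigar = cigar,
      strand = str, mapq = mapq, nm = nm, md = md,
      mate_chrom = NA_character_, mate_pos = NA_integer_, is_first = NA,
      stringsAsFactors = FALSE)
  } else {
    # two records per pair: forward read at the fragment left end, reverse
    # read at the right end; which one is "first" follows the template strand
    l <- left[rep_idx]; r <- right[rep_idx]
    first_fwd <- tpl_strand[rep_idx] == "+"
    mk_end <- function(p, strand_chr, first) data.frame(
      read_id = read_id,
      flag = 1L + (if (strand_chr == "-") 16L else 32L) +
        ifelse(first, 64L, 128L),
      chrom = chrom[rep_idx],
      pos = as.integer(if (strand_chr == "-") p - cf$read_len + 1L else p),
      cigar = cigar, strand = strand_chr, mapq = mapq, nm = nm, md = md,
      mate_chrom = chrom[rep_idx], mate_pos = NA_integer_,
      is_first = first, stringsAsFactors = FALSE)
    fwd <- mk_end(l, "+", first_fwd)
    rev <- mk_end(r, "-", !first_fwd)
    fwd$mate_pos <- rev$pos; rev$mate_pos <- fwd$pos
    aln <- rbind(fwd, rev)
  }
  aln <- aln[order(match(aln$chrom, names(sizes)), aln$pos, aln$read_id), ]
  rownames(aln) <- NULL
  attr(aln, "chrom_order") <- names(sizes)
  attr(aln, "chrom_sizes") <- sizes

  t_per_peak <- t_peak
  peaks$name <- paste0("peak_", seq_len(cf$n_peaks))
  peaks$score <- t_per_peak
  peaks$p_value <- exp(-t_per_peak / cf$p_scale)
  list(alignments = aln, peaks = peaks, truth = truth, config = cf)
}

#' Simulate replicate libraries over a shared binding landscape
#'
#' Draws the peak landscape (placement, relative intensities, hotspot
#' status) once and then samples `n` independent libraries from it, so the
#' replicates agree on where signal lives while fragment sampling, natural
#' collisions and amplification are independent — the situation replicate
#' correlation analyses assume.
#'
#' @param config `"sim_config"`.
#' @param seed Integer seed.
#' @param n Number of replicates (default 2).
#' @return List of `n` library lists as returned by [simulate_library()].
#' @export
simulate_replicates <- function(config, seed, n = 2L) {
  stopifnot(inherits(config, "sim_config"), n >= 1L)
  withr::with_seed(seed, {
    landscape <- draw_landscape(config)
    lapply(seq_len(n), function(i) {
      res <- simulate_library_impl(config, landscape)
      res$seed <- seed
      res$replicate <- i
      res
    })
  })
}

#' Write an alignment data frame as a sorted, indexed BAM
#'
#' Serializes simulator-style alignment records (sequence bases are emitted
#' as placeholder `A`s with uniform qualities; MD/NM tags carry the mismatch
#' evidence) into SAM text and converts to a coordinate-sorted indexed BAM.
#'
#' @param aln Alignment data.frame ([read_alignments()] layout).
#' @param chrom_sizes Named chromosome lengths for the header.
#' @param destination Output path without the ".bam" extension.
#' @param paired Whether records are paired ends.
#' @return Path to the BAM file, invisibly.
#' @export
write_alignment_bam <- function(aln, chrom_sizes, destination,
                                paired = FALSE) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", names(chrom_sizes), "\tLN:",
                     as.integer(chrom_sizes)))
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(
    aln$cigar, after.soft.clipping = FALSE)
  seq <- strrep("A", qlen)
  qual <- strrep("I", qlen)
  mate_ref <- if (paired) "=" else "*"
  mate_pos <- if (paired) aln$mate_pos else 0L
  # the strand column is authoritative for unpaired records
  if (!paired) aln$flag <- ifelse(aln$strand == "-", 16L, 0L)
  lines <- paste(aln$read_id, aln$flag, aln$chrom, aln$pos, aln$mapq,
                 aln$cigar, mate_ref, mate_pos, 0L, seq, qual,
                 paste0("NM:i:", aln$nm), paste0("MD:Z:", aln$md),
                 sep = "\t")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(header, lines), sam)
  out <- Rsamtools::asBam(sam, destination = destination, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  invisible(out)
}

#' Ground-truth duplicate composition
#'
#' Labels the duplicates of a simulated library from the truth table:
#' within each occupied duplicate key, one read per distinct template is an
#' independent observation, so a key with `n` reads from `t` templates holds
#' `t - 1` natural duplicates and `n - t` PCR duplicates. Reported overall
#' and split by peak membership of the key coordinate, for both the raw
#' duplicate pool and the pool capped at `cap` duplicates per key (PCR
#' copies beyond the cap are trimmed first, since amplified copies pile up
#' on a single key).
#'
#' @param truth Truth data.frame from [simulate_library()].
#' @param aln The (filtered) alignment data.frame of the same library.
#' @param peaks GRanges of the simulated peaks.
#' @param mode `"single"` or `"paired"`.
#' @param cap Per-position duplicate cap used for the capped pool
#'   (default 5).
#' @return List: `n_dup_in_peak`, `n_natural_in_peak`, `n_pcr_in_peak`,
#'   `natural_fraction_in_peak`, capped counterparts (`*_capped`),
#'   genome-wide totals (`n_dup`, `n_natural`, `n_pcr`), and `per_peak`
#'   (data.frame peak_idx, natural, pcr).
#' @export
truth_summary <- function(truth, aln, peaks, mode = c("single", "paired"),
                          cap = 5L) {
  mode <- match.arg(mode)
  keys <- dup_key(aln, mode)
  tpl <- truth$template_id[match(keys$read_id, truth$read_id)]
  if (anyNA(tpl)) stop("truth table lacks read id(s) present in alignments")
  kf <- factor(keys$key)
  ki <- as.integer(kf)
  n <- tabulate(ki, nbins = nlevels(kf))
  pair_first <- !duplicated(paste(ki, tpl, sep = "\r"))
  t_distinct <- as.integer(rowsum(as.integer(pair_first), ki,
                                  reorder = TRUE))
  natural <- t_distinct - 1L
  pcr <- n - t_distinct
  # capped pool: min(n - 1, cap) duplicates per key; natural duplicates are
  # retained first up to the cap, the remainder of the cap holds PCR copies
  capped_dup <- pmin(n - 1L, cap)
  natural_capped <- pmin(natural, capped_dup)
  pcr_capped <- capped_dup - natural_capped
  first_of_key <- match(levels(kf), keys$key)
  key_pos <- GenomicRanges::GRanges(
    seqnames = keys$chrom[first_of_key],
    ranges = IRanges::IRanges(
      start = if ("fpos" %in% names(keys)) keys$fpos[first_of_key]
        else keys$fpos1[first_of_key],
      width = 1L))
  pk <- GenomicRanges::findOverlaps(key_pos, peaks, ignore.strand = TRUE,
                                    select = "first")
  in_peak <- !is.na(pk)
  per_peak <- data.frame(
    peak_idx = sort(unique(pk[in_peak])),
    natural = as.integer(tapply(natural[in_peak], pk[in_peak], sum)),
    pcr = as.integer(tapply(pcr[in_peak], pk[in_peak], sum)))
  frac <- function(a, b) if (a + b > 0) a / (a + b) else NA_real_
  list(
    n_dup = sum(n - 1L), n_natural = sum(natural), n_pcr = sum(pcr),
    n_dup_in_peak = sum(n[in_peak] - 1L),
    n_natural_in_peak = sum(natural[in_peak]),
    n_pcr_in_peak = sum(pcr[in_peak]),
    natural_fraction_in_peak = frac(sum(natural[in_peak]),
                                    sum(pcr[in_peak])),
    n_dup_in_peak_capped = sum(capped_dup[in_peak]),
    n_natural_in_peak_capped = sum(natural_capped[in_peak]),
    n_pcr_in_peak_capped = sum(pcr_capped[in_peak]),
    natural_fraction_in_peak_capped = frac(sum(natural_capped[in_peak]),
                                           sum(pcr_capped[in_peak])),
    per_peak = per_peak)
}

#' Calibrate the amplification rate for a target natural fraction
#'
#' Finds the geometric amplification rate `pcr_rho` under which the true
#' natural-duplicate fraction among in-peak duplicates of libraries drawn
#' from `config` equals a target `f`. Starts from the closed-form rate
#' implied by the PCR-free collision count and refines it with a short
#' fixed-point iteration on simulated libraries (deterministic for fixed
#' `seeds`).
#'
#' @param config `"sim_config"` (its `pcr_rho` is ignored).
#' @param target_f Target natural fraction in (0, 1].
#' @param seeds Integer seeds for the calibration simulations.
#' @param capped Calibrate the fraction of the capped duplicate pool (the
#'   partition's substrate; default TRUE) rather than of all in-peak
#'   duplicates.
#' @param iterations Bisection steps on log mean-copy-number (default 10).
#' @param cap Per-position cap for the capped pool (default 5).
#' @return The calibrated `pcr_rho` value.
#' @export
calibrate_pcr_rho <- function(config, target_f, seeds = 101:102,
                              capped = TRUE, iterations = 10L, cap = 5L) {
  stopifnot(target_f > 0, target_f <= 1)
  if (target_f == 1) return(0)
  measure <- function(rho) {
    cf <- config; cf$pcr_rho <- rho
    mean(vapply(seeds, function(s) {
      sim <- simulate_library(cf, seed = s)
      ts <- truth_summary(sim$truth, sim$alignments, sim$peaks,
                          mode = if (cf$paired) "paired" else "single",
                          cap = cap)
      if (capped) ts$natural_fraction_in_peak_capped
      else ts$natural_fraction_in_peak
    }, numeric(1)))
  }
  # natural fraction decreases monotonically in the mean copy number mu;
  # bisect on log(mu)
  lo <- log(1e-3); hi <- log(8)
  f_hi <- measure(exp(hi) / (1 + exp(hi)))
  if (f_hi > target_f) {
    warning("target natural fraction ", target_f,
            " unreachable within the amplification range; returning the ",
            "maximum rate")
    return(exp(hi) / (1 + exp(hi)))
  }
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    f_mid <- measure(exp(mid) / (1 + exp(mid)))
    if (f_mid > target_f) lo <- mid else hi <- mid
  }
  mu <- exp((lo + hi) / 2)
  mu / (1 + mu)
}
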