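# Independent brute-force oracles and fixture builders used across the
# suite. These deliberately re-derive everything from first principles
# (regex CIGAR parsing, hash grouping, per-point weighted least squares)
# so they share no code with the package internals they check.

# --- 5' coordinate / duplicate-key oracle --------------------------------

oracle_cigar_parts <- function(cigar) {
  m <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", m))
  op <- sub("^\\d+", "", m)
  list(op = op, len = len)
}

oracle_fpos <- function(pos, cigar, strand) {
  mapply(function(p, cg, st) {
    cp <- oracle_cigar_parts(cg)
    aligned <- !(cp$op %in% c("S", "H"))
    lead <- if (any(aligned)) sum(cp$len[seq_len(which(aligned)[1] - 1)]) else 0L
    j <- max(which(aligned))
    trail <- if (j < length(cp$op)) sum(cp$len[(j + 1):length(cp$op)]) else 0L
    refw <- sum(cp$len[cp$op %in% c("M", "D", "N", "=", "X")])
    if (st == "-") p + refw - 1L + trail else p - lead
  }, pos, cigar, strand)
}

# hash-grouping duplicate oracle; representative = first by (pos, read_id)
oracle_mark_single <- function(aln) {
  fp <- oracle_fpos(aln$pos, aln$cigar, aln$strand)
  key <- paste(aln$chrom, fp, aln$strand)
  groups <- split(seq_len(nrow(aln)), key)
  is_dup <- logical(nrow(aln))
  for (g in groups) {
    g <- g[order(aln$pos[g], aln$read_id[g])]
    is_dup[g[-1]] <- TRUE
  }
  data.frame(read_id = aln$read_id, is_duplicate = is_dup,
             key = key, stringsAsFactors = FALSE)
}

oracle_mark_paired <- function(aln) {
  fp <- oracle_fpos(aln$pos, aln$cigar, aln$strand)
  ends <- split(seq_len(nrow(aln)), aln$read_id)
  ids <- names(ends)
  key <- vapply(ends, function(e) {
    a <- list(p = fp[e[1]], s = aln$strand[e[1]])
    b <- list(p = fp[e[2]], s = aln$strand[e[2]])
    if (b$p < a$p || (b$p == a$p && b$s < a$s)) { tmp <- a; a <- b; b <- tmp }
    paste(aln$chrom[e[1]], a$p, a$s, b$p, b$s)
  }, character(1))
  anchor <- vapply(ends, function(e) min(fp[e]), numeric(1))
  is_dup <- logical(length(ids))
  for (g in split(seq_along(ids), key)) {
    g <- g[order(anchor[g], ids[g])]
    is_dup[g[-1]] <- TRUE
  }
  data.frame(read_id = ids, is_duplicate = is_dup, key = key,
             stringsAsFactors = FALSE)
}

# --- random alignment fixtures -------------------------------------------

random_single_fixture <- function(n, chroms = c("chr1", "chr2"),
                                  max_pos = 400L,
                                  cigars = c("50M", "2S48M", "48M2S",
                                             "10H40M", "20M2D30M")) {
  aln <- data.frame(
    read_id = sprintf("r%04d", seq_len(n)),
    flag = 0L,
    chrom = sample(chroms, n, replace = TRUE),
    pos = sample.int(max_pos, n, replace = TRUE) + 50L,
    cigar = sample(cigars, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    mapq = 30L, nm = 0L, md = "50",
    mate_chrom = NA_character_, mate_pos = NA_integer_, is_first = NA,
    stringsAsFactors = FALSE)
  aln <- aln[order(aln$chrom, aln$pos, aln$read_id), ]
  rownames(aln) <- NULL
  aln
}

random_paired_fixture <- function(n_pairs, chroms = c("chr1", "chr2"),
                                  max_pos = 300L) {
  id <- sprintf("p%04d", seq_len(n_pairs))
  chrom <- sample(chroms, n_pairs, replace = TRUE)
  p1 <- sample.int(max_pos, n_pairs, replace = TRUE) + 50L
  frag <- sample(120:240, n_pairs, replace = TRUE)
  p2 <- p1 + frag - 50L
  mk <- function(id, chrom, pos, strand, first, mpos) data.frame(
    read_id = id, flag = 1L, chrom = chrom, pos = pos, cigar = "50M",
    strand = strand, mapq = 30L, nm = 0L, md = "50",
    mate_chrom = chrom, mate_pos = mpos, is_first = first,
    stringsAsFactors = FALSE)
  aln <- rbind(mk(id, chrom, p1, "+", TRUE, p2),
               mk(id, chrom, p2, "-", FALSE, p1))
  aln <- aln[order(aln$chrom, aln$pos, aln$read_id), ]
  rownames(aln) <- NULL
  aln
}

# --- per-point robust local regression oracle ----------------------------
# Cleveland's algorithm written out directly: tricube neighborhood weights,
# local linear weighted least squares at every x, bisquare robustness
# weights from six times the median absolute residual, `iter` robustifying
# passes, no interpolation shortcut.

oracle_lowess <- function(x, y, f = 2/3, iter = 3L) {
  o <- order(x)
  xs <- x[o]; ys_in <- y[o]
  n <- length(xs)
  ns <- max(2L, min(n, floor(f * n + 1e-7)))
  rw <- rep(1, n)
  fit <- numeric(n)
  rng <- xs[n] - xs[1]
  for (it in seq_len(iter + 1L)) {
    nleft <- 1L; nright <- ns
    for (i in seq_len(n)) {
      while (nright < n) {
        d1 <- xs[i] - xs[nleft]
        d2 <- xs[nright + 1L] - xs[i]
        if (d1 > d2) { nleft <- nleft + 1L; nright <- nright + 1L }
        else break
      }
      h <- max(xs[i] - xs[nleft], xs[nright] - xs[i])
      h9 <- 0.999 * h; h1 <- 0.001 * h
      j <- nleft:n
      r <- abs(xs[j] - xs[i])
      w <- numeric(length(j))
      inside <- r <= h9
      w[inside & r <= h1] <- 1
      tri <- inside & r > h1
      w[tri] <- (1 - (r[tri] / h)^3)^3
      past <- which(!inside & xs[j] > xs[i])
      jmax <- if (length(past)) past[1] - 1L else length(j)
      j <- j[seq_len(jmax)]; w <- w[seq_len(jmax)]
      if (it > 1L) w <- w * rw[j]
      a <- sum(w)
      if (a <= 0) { fit[i] <- fit[max(1L, i - 1L)]; next }
      w <- w / a
      if (h > 0) {
        xm <- sum(w * xs[j])
        b <- xs[i] - xm
        cc <- sum(w * (xs[j] - xm)^2)
        if (sqrt(cc) > 0.001 * rng) {
          b <- b / cc
          w <- w * (b * (xs[j] - xm) + 1)
        }
      }
      fit[i] <- sum(w * ys_in[j])
    }
    res <- ys_in - fit
    if (it > iter) break
    ar <- abs(res)
    m1 <- floor(n / 2) + 1L
    m2 <- n - m1 + 1L
    sa <- sort(ar, partial = c(m1, m2))
    cmad <- 3 * (sa[m1] + sa[m2])
    if (cmad < 1e-7 * sum(ar) / n) break
    c9 <- 0.999 * cmad; c1 <- 0.001 * cmad
    rw <- ifelse(ar <= c1, 1, ifelse(ar <= c9, (1 - (ar / cmad)^2)^2, 0))
  }
  out <- numeric(n)
  out[o] <- fit
  out
}

# --- misc ----------------------------------------------------------------

# Spearman via explicit average ranks then Pearson
oracle_spearman <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

# O(tallies x regions) membership scan
oracle_count_region <- function(tallies, chrom, start, end) {
  inside <- tallies$chrom == chrom & tallies$fpos >= start &
    tallies$fpos <= end
  list(n_total = sum(tallies$n_reads[inside]),
       n_nondup = sum(inside),
       n_dup = sum(tallies$duplicates[inside]))
}

# default small simulated library shared by several tests
sim_small <- function(seed = 7L, rho = 0.15, dir = NULL, ...) {
  cf <- sim_config(chrom_sizes = c(chrS = 400000L), n_peaks = 12L,
                   n_fragments = 8000L, pcr_rho = rho, ...)
  simulate_library(cf, seed = seed, dir = dir)
}

# independent peak padding (clip at chromosome bounds), for partition tests
pad_peaks_for_test <- function(peaks, sizes, buffer) {
  GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(
      pmax(1L, GenomicRanges::start(peaks) - buffer),
      pmin(unname(sizes[as.character(GenomicRanges::seqnames(peaks))]),
           GenomicRanges::end(peaks) + buffer)))
}
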