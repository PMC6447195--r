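gr <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), ...)
}

test_that("region counting matches a per-read membership oracle", {
  withr::with_seed(31, {
    aln <- random_single_fixture(500, max_pos = 450L)
    m <- mark_duplicates(aln, "single")
    s <- sample.int(450, 20)
    regions <- gr(sample(c("chr1", "chr2"), 20, TRUE), s, s + 40L)
  })
  counts <- count_regions(regions, m)
  for (i in seq_along(regions)) {
    o <- oracle_count_region(m$tallies,
                             as.character(GenomicRanges::seqnames(regions))[i],
                             GenomicRanges::start(regions)[i],
                             GenomicRanges::end(regions)[i])
    expect_identical(counts$n_total[i], o$n_total, info = i)
    expect_identical(counts$n_nondup[i], o$n_nondup, info = i)
    expect_identical(counts$n_dup[i], o$n_dup, info = i)
  }
  # an empty region yields all-zero counts
  empty <- suppressWarnings(count_regions(gr("chr9", 1, 10), m))
  expect_true(all(empty[, -1] == 0L))
  # invariants
  expect_true(all(counts$n_dup == counts$n_total - counts$n_nondup))
  expect_true(all(counts$n_positions_with_dup <= counts$n_positions))
})

test_that("library QC arithmetic: dup rate, NRF, FRiP, peak size fraction", {
  # 1000 reads over 800 keys -> dup rate 0.20, NRF 0.80
  withr::with_seed(32, {
    pos <- c(seq_len(800), sample.int(800, 200, replace = TRUE))
    aln <- data.frame(read_id = sprintf("r%04d", 1:1000), flag = 0L,
                      chrom = "chr1", pos = sort(pos), cigar = "50M",
                      strand = "+", mapq = 30L, nm = 0L, md = "50",
                      mate_chrom = NA, mate_pos = NA, is_first = NA)
  })
  m <- mark_duplicates(aln, "single")
  sizes <- c(chr1 = 100000L)
  peaks <- gr("chr1", 1, 900)
  qc <- library_metrics(m, peaks, sizes)
  expect_equal(qc$dup_rate, 0.20)
  expect_equal(qc$nrf, 0.80)
  expect_equal(qc$frip, 1.0)  # every key inside the peak
  expect_equal(qc$peak_size_frac, 900 / (0.75 * 100000))
  expect_equal(qc$pct_dups_in_peaks, 1.0)
  expect_error(library_metrics(list(tallies = m$tallies[0, ]), peaks, sizes),
               "zero-read")
})

test_that("RPK10M is the documented formula and is (inversely) linear", {
  expect_equal(rpk10m(10, 500, 2e7), 10)
  expect_equal(rpk10m(0, 500, 2e7), 0)
  withr::with_seed(33, {
    cnt <- runif(50, 0, 1000); len <- runif(50, 100, 5000)
    lib <- runif(50, 1e6, 1e8)
  })
  expect_equal(rpk10m(cnt, len, lib), cnt / (len / 1e3) / (lib / 1e7))
  expect_equal(rpk10m(2 * cnt, len, lib), 2 * rpk10m(cnt, len, lib))
  expect_equal(rpk10m(cnt, 2 * len, lib), rpk10m(cnt, len, lib) / 2)
  expect_equal(rpk10m(cnt, len, 2 * lib), rpk10m(cnt, len, lib) / 2)
})

test_that("enrichment level is the IP/input in-peak ratio", {
  expect_equal(enrichment_level(10, 100, 1, 100), 10)
  expect_equal(enrichment_level(37, 500, 37, 500), 1)
  expect_identical(enrichment_level(10, 100, 0, 100), Inf)
  expect_error(enrichment_level(1, 0, 1, 10), "zero-total")
  # enrichment grows with simulated peak intensity
  ratios <- vapply(c(0.3, 0.6, 0.9), function(frip) {
    cf <- sim_config(chrom_sizes = c(chrS = 400000L), n_peaks = 12L,
                     n_fragments = 6000L, frip = frip)
    sim <- simulate_library(cf, seed = 34)
    cfi <- sim_config(chrom_sizes = c(chrS = 400000L), n_peaks = 12L,
                      n_fragments = 6000L, frip = 0)
    inp <- simulate_library(cfi, seed = 35)
    mi <- mark_duplicates(sim$alignments, "single")
    mo <- mark_duplicates(inp$alignments, "single")
    ci <- count_regions(GenomicRanges::reduce(sim$peaks), mi)
    co <- count_regions(GenomicRanges::reduce(sim$peaks), mo)
    enrichment_level(sum(ci$n_nondup), nrow(mi$tallies),
                     sum(co$n_nondup), nrow(mo$tallies))
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("confidence grouping sorts by p and spreads the remainder early", {
  withr::with_seed(36, {
    pv <- runif(23)
    peaks <- gr("chr1", seq(1, by = 500, length.out = 23),
                seq(1, by = 500, length.out = 23) + 100L)
    peaks$p_value <- pv
    aln <- random_single_fixture(300, chroms = "chr1", max_pos = 11000L)
  })
  m <- mark_duplicates(aln, "single")
  g <- confidence_groups(peaks, m, k = 10L)
  expect_identical(g$n_peaks, c(3L, 3L, 3L, rep(2L, 7)))
  # group assignment follows ascending p
  grp <- attr(g, "group_of_peak")
  expect_identical(grp[order(pv)], rep(1:10, c(3, 3, 3, rep(2, 7))))
  # missing scores are reported
  peaks2 <- peaks
  peaks2$p_value[c(2, 5)] <- NA
  expect_error(confidence_groups(peaks2, m), "2")
})

test_that("group duplicate rates reconstitute the peak-wide rate", {
  # equal-length PCR-free peaks: duplicate rate is collision-driven, so the
  # most intense (most confident) group must rank first
  sim <- sim_small(seed = 37, rho = 0, peak_len_range = c(1000L, 1000L))
  m <- mark_duplicates(sim$alignments, "single")
  g <- confidence_groups(sim$peaks, m, k = 5L)
  all_counts <- count_regions(sim$peaks, m)
  expect_identical(sum(g$n_dup), sum(all_counts$n_dup))
  expect_equal(sum(g$dup_rate_in_group * g$n_reads) / sum(g$n_reads),
               sum(all_counts$n_dup) / sum(all_counts$n_total))
  # with intensity-proportional confidence, group 1 has the top dup rate
  expect_identical(which.max(g$dup_rate_in_group), 1L)
})

test_that("top positions follow the count-then-coordinate tie rule", {
  tallies <- data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr1"),
    fpos = c(500L, 100L, 50L, 200L),
    strand = "+",
    key = letters[1:4],
    n_reads = c(6L, 4L, 4L, 2L),
    duplicates = c(5L, 3L, 3L, 1L),
    representative_read_id = "r")
  peaks <- gr("chr1", 90, 110)
  top <- top_positions(tallies, 2L, peaks)
  expect_identical(top$duplicates, c(5L, 3L))
  expect_identical(top$fpos, c(500L, 100L))  # chr1:100 beats chr2:50
  expect_identical(top$in_peak, c(FALSE, TRUE))
  # all-equal counts: pure coordinate order
  tallies$duplicates <- 2L
  top2 <- top_positions(tallies, 4L, peaks)
  expect_identical(top2$fpos, c(100L, 200L, 500L, 50L))
  # n beyond the table returns everything with a message
  expect_message(top3 <- top_positions(tallies, 10L, peaks), "available")
  expect_identical(nrow(top3), 4L)
  # random tallies equal a full-sort oracle
  withr::with_seed(38, {
    rt <- data.frame(chrom = sample(c("c1", "c2"), 200, TRUE),
                     fpos = sample.int(1000, 200), strand = "+",
                     key = sprintf("k%03d", 1:200),
                     n_reads = rpois(200, 3) + 1L)
    rt$duplicates <- rt$n_reads - 1L
  })
  topr <- top_positions(rt, 50L, gr("c1", 90, 110))
  o <- rt[order(-rt$duplicates, rt$chrom, rt$fpos, rt$strand), ][1:50, ]
  expect_identical(topr$key, o$key)
})

test_that("replicate correlation is Pearson on log2 RPK10M with Fisher CI", {
  mp <- gr("chr1", seq(1, by = 1000, length.out = 50),
           seq(1, by = 1000, length.out = 50) + 499L)
  withr::with_seed(39, c1 <- rpois(50, 40))
  r1 <- replicate_correlation(mp, c1, c1, 1e6, 1e6)
  expect_equal(r1$pearson_r, 1.0)
  # anti-ordered counts on 3 peaks give negative r
  mp3 <- mp[1:3]
  GenomicRanges::width(mp3)
  r2 <- replicate_correlation(mp3, c(1, 10, 100), c(100, 10, 1), 1e6, 1e6)
  expect_true(r2$pearson_r < 0)
  expect_error(replicate_correlation(mp[1:2], 1:2, 1:2, 1e6, 1e6),
               "at least 3")
  expect_error(replicate_correlation(mp, rep(5, 50), rep(5, 50), 1e6, 1e6),
               "zero variance")
  # known-correlation bivariate log-normal recovers rho within its CI
  withr::with_seed(40, {
    n <- 1000
    z1 <- rnorm(n); z2 <- 0.8 * z1 + sqrt(1 - 0.64) * rnorm(n)
    mpn <- gr("chr1", seq(1, by = 600, length.out = n),
              seq(1, by = 600, length.out = n) + 499L)
    cc1 <- round(exp(3 + z1)); cc2 <- round(exp(3 + z2))
  })
  rr <- replicate_correlation(mpn, cc1, cc2, 1e6, 1e6)
  expect_true(rr$ci_low < 0.84 && rr$ci_high > 0.74)
  expect_true(rr$ci_low < rr$pearson_r && rr$pearson_r < rr$ci_high)
})

test_that("feature correlations are Spearman with average-rank ties", {
  withr::with_seed(41, {
    n <- 300
    tab <- data.frame(
      dup_level = round(runif(n, 0, 50), 1),
      nondup_level = round(runif(n, 0, 200), 1),
      input_dup_level = round(runif(n, 0, 5), 1),
      input_nondup_level = round(runif(n, 0, 20), 1),
      gc_fraction = runif(n),
      pct_segdup = sample(c(0, 0, runif(10)), n, TRUE),
      pct_lowcomplex = sample(c(0, runif(5)), n, TRUE))
  })
  rho <- feature_correlations(tab)
  for (f in names(rho)) {
    expect_equal(unname(rho[f]), oracle_spearman(tab$dup_level, tab[[f]]),
                 tolerance = 1e-12, info = f)
  }
  # self-correlation = 1, rank reversal = -1
  tab2 <- tab
  tab2$nondup_level <- tab2$dup_level
  tab2$input_dup_level <- -tab2$dup_level
  rho2 <- feature_correlations(tab2)
  expect_equal(unname(rho2["nondup_level"]), 1.0)
  expect_equal(unname(rho2["input_dup_level"]), -1.0)
  # constant column -> NA sentinel with warning
  tab2$gc_fraction <- 0.5
  expect_warning(rho3 <- feature_correlations(tab2), "constant")
  expect_true(is.na(rho3["gc_fraction"]))
})

test_that("mean duplicates per position excludes blacklisted keys", {
  tallies <- data.frame(chrom = "chr1", fpos = c(10L, 20L, 30L),
                        strand = "+", key = c("a", "b", "c"),
                        n_reads = c(3L, 1L, 2L),
                        duplicates = c(2L, 0L, 1L),
                        representative_read_id = "r")
  expect_equal(mean_dups_per_position(tallies), 1.0)
  expect_equal(mean_dups_per_position(tallies[2, ]), 0.0)
  bl <- gr("chr1", 5, 15)
  expect_equal(mean_dups_per_position(tallies, bl), 0.5)
  expect_error(mean_dups_per_position(tallies, gr("chr1", 1, 100)),
               "no positions")
  withr::with_seed(42, {
    rt <- data.frame(chrom = "c1", fpos = sample.int(5000, 400),
                     strand = "+", key = sprintf("k%03d", 1:400),
                     n_reads = rpois(400, 2) + 1L)
    rt$duplicates <- rt$n_reads - 1L
    s <- sample.int(5000, 30)
    rbl <- gr("c1", s, s + 60L)
  })
  keep <- !vapply(seq_len(nrow(rt)), function(i) {
    any(rt$fpos[i] >= GenomicRanges::start(rbl) &
          rt$fpos[i] <= GenomicRanges::end(rbl))
  }, logical(1))
  expect_equal(mean_dups_per_position(rt, rbl),
               sum(rt$duplicates[keep]) / sum(keep))
})
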