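make_read <- function(pos = 100L, cigar = "50M", strand = "+", mapq = 30L,
                      md = "50", nm = 0L, id = "r1", chrom = "chr1") {
  data.frame(read_id = id, flag = 0L, chrom = chrom, pos = pos,
             cigar = cigar, strand = strand, mapq = mapq, nm = nm, md = md,
             mate_chrom = NA_character_, mate_pos = NA_integer_,
             is_first = NA, stringsAsFactors = FALSE)
}

test_that("mapping-quality threshold is applied at 20", {
  expect_false(passes_filters(make_read(mapq = 19L)))
  expect_true(passes_filters(make_read(mapq = 20L)))
})

test_that("leading-base mismatch filter follows sequencing orientation", {
  # mismatch at sequenced base k of a 50M forward read: MD "(k-1)A(50-k)"
  for (k in 1:10) {
    md <- paste0(k - 1L, "A", 50L - k)
    fwd <- passes_filters(make_read(md = md, nm = 1L))
    expect_identical(fwd, k > 5, info = paste("forward, base", k))
    # same sequenced base on a reverse read sits at the reference-right end
    md_rev <- paste0(50L - k, "A", k - 1L)
    rev <- passes_filters(make_read(md = md_rev, nm = 1L, strand = "-"))
    expect_identical(rev, k > 5, info = paste("reverse, base", k))
  }
  # mismatch positions against a hand-parsed match/mismatch expectation:
  # "2A47" = 2 matches, mismatch, 47 matches
  expect_false(passes_filters(make_read(md = "2A47", nm = 1L)))
  expect_true(passes_filters(make_read(md = "5A44", nm = 1L)))
})

test_that("insertions count as mismatches, clips and deletions do not", {
  # 3M1I46M: inserted base is sequenced base 4 -> fails
  expect_false(passes_filters(make_read(cigar = "3M1I46M", md = "49",
                                        nm = 1L)))
  # 6M1I43M: insertion at base 7 -> passes
  expect_true(passes_filters(make_read(cigar = "6M1I43M", md = "49",
                                       nm = 1L)))
  # deletion consumes no query base: clean
  expect_true(passes_filters(make_read(cigar = "20M2D30M", md = "20^AC30",
                                       nm = 2L)))
  # leading soft clip is unevaluable, not a mismatch
  expect_true(passes_filters(make_read(cigar = "3S47M", md = "47")))
})

test_that("missing mismatch evidence errors in strict mode, NM fallback works", {
  r <- make_read(md = NA_character_, nm = 0L)
  expect_error(passes_filters(r), "MD")
  expect_true(passes_filters(r, on_missing = "nm0"))
  r$nm <- 1L
  expect_false(passes_filters(r, on_missing = "nm0"))
  expect_true(passes_filters(r, check_first = 0L))
})

test_that("duplicate keys use unclipped strand-aware 5' coordinates", {
  expect_identical(five_prime_pos(100L, "50M", "+"), 100L)
  expect_identical(five_prime_pos(100L, "50M", "-"), 149L)
  expect_identical(five_prime_pos(100L, "2S48M", "+"), 98L)
  expect_identical(five_prime_pos(100L, "48M2S", "-"), 149L)
  expect_identical(five_prime_pos(100L, "2S48M", "-"), 147L)
  expect_identical(five_prime_pos(100L, "10H40M", "+"), 90L)
  # deletions extend the reference footprint of reverse reads
  expect_identical(five_prime_pos(100L, "20M2D30M", "-"), 151L)
  # clipped and unclipped versions of the same fragment collide
  a <- rbind(make_read(pos = 100L, cigar = "50M", id = "a"),
             make_read(pos = 102L, cigar = "2S48M", id = "b"))
  k <- dup_key(a, "single")
  expect_identical(k$key[1], k$key[2])
})

test_that("marking applies the n-1 rule and conserves read counts", {
  one <- make_read(id = "only")
  m1 <- mark_duplicates(one, "single")
  expect_identical(sum(m1$tallies$duplicates), 0L)

  three <- do.call(rbind, lapply(1:3, function(i) make_read(id = paste0("r", i))))
  m3 <- mark_duplicates(three, "single")
  expect_identical(nrow(m3$tallies), 1L)
  expect_identical(m3$tallies$n_reads, 3L)
  expect_identical(sum(m3$flags$is_duplicate), 2L)
  expect_identical(m3$tallies$representative_read_id, "r1")

  withr::with_seed(11, {
    aln <- random_single_fixture(200, max_pos = 25L)
    m <- mark_duplicates(aln, "single")
    expect_identical(sum(!m$flags$is_duplicate) + sum(m$flags$is_duplicate),
                     nrow(aln))
    expect_identical(sum(m$tallies$n_reads), nrow(aln))
    expect_identical(sum(m$tallies$duplicates),
                     nrow(aln) - nrow(m$tallies))
  })
})

test_that("opposite strands at one position occupy distinct keys", {
  a <- rbind(make_read(id = "f", strand = "+"),
             make_read(id = "r", strand = "-", pos = 51L))
  # reverse read at pos 51 has 5' 100 also? no: 51+49=100 -> same coordinate
  k <- dup_key(a, "single")
  expect_identical(k$fpos[1], 100L)
  expect_identical(k$fpos[2], 100L)
  m <- mark_duplicates(a[order(a$pos), ], "single")
  expect_identical(sum(m$flags$is_duplicate), 0L)
})

test_that("re-marking the nonredundant subset is duplicate-free", {
  withr::with_seed(12, aln <- random_single_fixture(300, max_pos = 40L))
  m <- mark_duplicates(aln, "single")
  keep <- aln[aln$read_id %in% m$flags$read_id[!m$flags$is_duplicate], ]
  m2 <- mark_duplicates(keep, "single")
  expect_identical(sum(m2$flags$is_duplicate), 0L)
  expect_identical(nrow(m2$tallies), nrow(m$tallies))
})

test_that("shuffling equally-positioned records never changes counts", {
  withr::with_seed(13, aln <- random_single_fixture(150, max_pos = 10L))
  m <- mark_duplicates(aln, "single")
  for (i in 1:3) {
    shuf <- do.call(rbind, lapply(split(aln, list(aln$chrom, aln$pos),
                                        drop = TRUE),
                                  function(b) b[sample(nrow(b)), ]))
    shuf <- shuf[order(shuf$chrom, shuf$pos), ]
    m2 <- mark_duplicates(shuf, "single")
    t1 <- m$tallies[order(m$tallies$key), c("key", "n_reads")]
    t2 <- m2$tallies[order(m2$tallies$key), c("key", "n_reads")]
    rownames(t1) <- rownames(t2) <- NULL
    expect_identical(t1, t2)
    # representative rule is (coordinate, read_id), so even ids agree
    expect_setequal(m2$flags$read_id[!m2$flags$is_duplicate],
                    m$flags$read_id[!m$flags$is_duplicate])
  }
})

test_that("unsorted input is rejected with the first offender named", {
  a <- rbind(make_read(pos = 500L, id = "x"), make_read(pos = 100L, id = "y"))
  expect_error(mark_duplicates(a, "single"), "y")
  b <- rbind(make_read(chrom = "chr2", id = "a"),
             make_read(chrom = "chr1", id = "b"),
             make_read(chrom = "chr2", id = "c"))
  expect_error(mark_duplicates(b, "single"), "not coordinate-sorted")
})

test_that("pairs with different mate coordinates are not duplicates", {
  # two pairs share the forward end but fragment sizes differ
  mk_pair <- function(id, p1, p2) rbind(
    data.frame(read_id = id, flag = 1L, chrom = "chr1", pos = p1,
               cigar = "50M", strand = "+", mapq = 30L, nm = 0L, md = "50",
               mate_chrom = "chr1", mate_pos = p2, is_first = TRUE,
               stringsAsFactors = FALSE),
    data.frame(read_id = id, flag = 1L, chrom = "chr1", pos = p2,
               cigar = "50M", strand = "-", mapq = 30L, nm = 0L, md = "50",
               mate_chrom = "chr1", mate_pos = p1, is_first = FALSE,
               stringsAsFactors = FALSE))
  aln <- rbind(mk_pair("p1", 100L, 260L), mk_pair("p2", 100L, 300L),
               mk_pair("p3", 100L, 260L))
  aln <- aln[order(aln$pos, aln$read_id), ]
  m <- mark_duplicates(aln, "paired")
  expect_identical(nrow(m$flags), 3L)  # one row per pair
  expect_identical(sum(m$flags$is_duplicate), 1L)
  expect_true(m$flags$is_duplicate[m$flags$read_id == "p3"])
})

test_that("alignments round-trip through BAM", {
  withr::with_seed(14, aln <- random_single_fixture(50))
  sizes <- c(chr1 = 1000L, chr2 = 1000L)
  bam <- write_alignment_bam(aln, sizes, tempfile())
  back <- read_alignments(bam)
  expect_identical(nrow(back), nrow(aln))
  expect_identical(attr(back, "chrom_sizes"), sizes)
  ord <- order(back$read_id)
  ord0 <- order(aln$read_id)
  for (col in c("read_id", "chrom", "pos", "cigar", "strand", "mapq",
                "nm", "md")) {
    expect_identical(back[[col]][ord], aln[[col]][ord0], info = col)
  }
})

test_that("the duplicate flag bit is set on re-written marked BAMs", {
  withr::with_seed(15, aln <- random_single_fixture(120, max_pos = 15L))
  sizes <- c(chr1 = 1000L, chr2 = 1000L)
  bam <- write_alignment_bam(aln, sizes, tempfile())
  m <- mark_duplicates(aln, "single")
  out <- write_marked_bam(bam, m, tempfile())
  back <- read_alignments(out)
  flagged <- back$read_id[bitwAnd(back$flag, 0x400L) > 0L]
  expect_setequal(flagged, m$flags$read_id[m$flags$is_duplicate])
})
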