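# peakdedup — signal-aware duplicate handling for ChIP-seq peaks

ChIP-seq libraries contain *duplicates*: reads mapping to the same genomic
position and strand (for read pairs, the same position and strand of both
ends). They come from two very different sources. **PCR duplicates** are
sequenced copies of the same amplified template — artifacts that inflate
apparent signal. **Natural duplicates** are independent DNA fragments that
happen to share a 5′ coordinate — genuine signal, and inevitable inside
narrow peaks where read density is high. The standard practice of removing
*all* duplicates therefore systematically underestimates the signal in
exactly the peaks with the strongest enrichment.

`peakdedup` implements a signal-aware alternative for users analysing
transcription-factor or histone-mark ChIP-seq:

1. **Duplicate accounting.** Mark duplicates on filtered unique alignments
   (MAPQ ≥ 20, no mismatch in the first five sequenced bases) and compute
   the QC suite: duplicate rate, NRF (nonredundant fraction = distinct
   positions / uniquely mapped reads), FRiP (fraction of nonredundant reads
   in peaks), RPK10M (reads per kb per 10 M reads), duplicate rates in
   peaks vs peak flanks vs the non-peak genome (with a 100 bp exclusion
   buffer), confidence-decile profiles, top-duplicated positions, replicate
   correlation and six-feature Spearman correlations (GC, segmental
   duplication, low complexity, input levels).
2. **Signal/noise partition.** Within blacklist-filtered peaks, cap each
   position at 5 duplicates, then model the capped duplicate level
   *y* (duplicates/kb) as a function of the target enrichment level
   *x* (nonredundant reads/kb) with robust locally weighted regression
   (`lowess`, span 2/3, 3 bisquare iterations). The natural-duplicate level
   of each peak is `min(observed, fitted)`, giving integer counts *S*
   (signal, kept) and *N* (noise, removed) with `S + N = capped`
   duplicates.
3. **Proper deduplication.** Rewrite the alignment file keeping all
   nonredundant reads plus the *S* signal duplicates per peak; *N* read ids
   are drawn uniformly at random (seeded) from each peak's duplicate pool
   and removed, along with all non-peak and over-cap duplicates. The output
   BAM stays coordinate-sorted, with a per-peak table of nonredundant
   reads, *S* and *N*.
4. **Synthetic libraries with ground truth.** A generator emulating peaks
   on a toy genome, collision-driven natural duplicates, and
   locus-structured PCR amplification, with per-read truth labels
   (template id, PCR-copy flag) — the substrate for validating every step
   above.

## Worked example

Simulate a small amplified library, mark duplicates, and partition the
in-peak duplicates:

```r
library(peakdedup)

cf  <- sim_config(chrom_sizes = c(chrS = 500000L), n_peaks = 20L,
                  n_fragments = 20000L, pcr_rho = 0.2)
sim <- simulate_library(cf, seed = 7)

aln     <- sim$alignments[passes_filters(sim$alignments), ]
marking <- mark_duplicates(aln, mode = "single")
marking
#> Duplicate marking (single-end)
#>   reads/pairs: 25949  positions: 16989  duplicates: 8960

round(library_metrics(marking, sim$peaks, cf$chrom_sizes), 3)
#>   n_uniq n_positions dup_rate   nrf  frip peak_size_frac pct_dups_in_peaks
#> 1  25949       16989    0.345 0.655 0.725          0.063             0.853

part <- partition_duplicates(sim$peaks, marking, cap = 5)
part
#> Signal/noise duplicate partition over 20 peaks
#>   capped duplicates: 6949  signal (S): 3032  noise (N): 3917
#>   library signal fraction: 0.436
```

Reading the output: the library has 25,949 filtered unique reads of which
34.5% are duplicates (NRF 0.655); peaks cover 6.3% of the mappable genome
yet hold 85% of all duplicates — the signature of natural duplication. The
partition predicts that 43.6% of the capped in-peak duplicates are natural;
the simulator's ground truth for this library is 45.5%
(`truth_summary(sim$truth, aln, sim$peaks)$natural_fraction_in_peak_capped`).

Writing the properly deduplicated BAM and the per-peak table:

```r
plan <- build_rewrite_plan(marking, sim$peaks, part, cap = 5, seed = 17)
out  <- write_deduplicated("sim.bam", marking, sim$peaks, plan, "clean.bam")
head(out$peak_table)   # peak_id, n_nondup, S, N
```

A shell front end covers the same workflow
(`exec/peakdedup simulate|mark|regions|metrics|partition|run`), e.g.

```sh
peakdedup run --bam aln.bam --peaks peaks.narrowPeak \
              --blacklist blacklist.bed --seed 17 --out-dir results/
```

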