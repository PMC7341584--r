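# scpolya

Splice-aware polyA-site peak calling and differential transcript usage
(DTU) analysis for 3′-biased single-cell RNA-seq (10x-style) data.

Droplet scRNA-seq protocols capture the 3′ ends of transcripts, so read
pileups mark polyadenylation sites rather than whole gene bodies. Genes
with alternative polyA sites produce several distinct pileups, and shifts
in their relative use between cell populations — alternative
polyadenylation, 3′UTR shortening, alternative terminal exons — are
invisible to gene-level counting. `scpolya` recovers this signal in five
stages, each usable on its own:

1. **Peak calling** — per gene, read coverage is split into
   *across-junction* and *within-junction* tracks using splice junctions
   taken from the alignments (CIGAR `N` operations) or a junction BED.
   On each track the coverage maximum is found and a Gaussian
   `y = k · exp(−½ (x − μ)² / σ²)` is fitted by bounded non-linear least
   squares over a 600-bp window (initial values μ = 300, σ = 100,
   k = max coverage). The called peak spans `centre ± 3σ` with
   `centre = s − 300 + μ` (s = coverage apex); its coverage is zeroed and
   the procedure repeats until the residual-coverage or peak-height
   stopping rules fire.
2. **Peak merging** — peak sets from several datasets are unified with a
   coordinate similarity score
   `max(0, 1 − (|Δstart| + |Δend|) / width)`; pairs are matched at a 0.75
   threshold (one direction may relax to 0.5625) and matched peaks are
   collapsed to their coordinate union.
3. **UMI counting** — a sparse peaks × cells matrix of distinct UMIs per
   whitelisted barcode, written/read as MatrixMarket triplets.
4. **Annotation** — each peak gets the features it overlaps
   (hierarchy 3′UTR > 5′UTR > exon > intron) plus sequence flags near its
   boundaries: the canonical polyA motif (AATAAA), an A-rich stretch
   downstream (13-mer with ≤ 1 mismatch; the internal-priming signature),
   and a T-rich stretch upstream.
5. **Differential usage** — cells of two populations are dealt into
   pseudo-bulk replicates (default 6 per population), size factors are
   estimated by median-of-ratios with the *shorth* location estimator,
   and each peak is tested with a two-bin negative-binomial GLM
   (`column + bin + population:bin`, log link, size-factor offsets,
   per-peak Cox–Reid dispersion) via a 1-df likelihood-ratio test of the
   interaction — the peak's share of its gene, independent of gene-level
   expression. A gene with ≥ 1 differentially used peak is a DTU gene.

Downstream, `utr_location_scores()` + `test_utr_shortening()` score DU
3′UTR peaks by proximity to the terminating exon (0 = proximal,
1 = distal) and compare up- vs down-regulated peaks with a Wilcoxon
rank-sum test to detect 3′UTR shortening, and
`relative_peak_expression()` computes `R = log2(x / (G + v) · P + 1)` for
within-gene usage visualisation.

A fully synthetic fixture generator (`generate_scenario()`,
`write_fixture_files()`) emits BAM/GTF/FASTA/whitelist fixtures with
machine-readable truth tables, so the whole pipeline is testable without
any external data.

## Worked example

The synthetic default scenario has six genes; gene `G1` switches the
usage of its two 3′UTR peaks between populations A and B
(0.8/0.2 → 0.2/0.8), and gene `G6` carries an intronic internal-priming
decoy peak.

```r
library(scpolya)

scn   <- generate_scenario(scenario_config(umis_per_cell = 60, seed = 1))
paths <- write_fixture_files(scn, "fixture")

wl     <- read_whitelist(paths$whitelist)
reads  <- read_alignments(paths$bam, whitelist = wl)
models <- read_gene_models(paths$gtf)

peaks <- find_peaks(reads, models, junctions = paths$junctions)
head(peaks[, c("peak_id", "centre", "k", "sigma", "junction_class")], 4)
#> 1 G1:chrS:6876-7434:+     7155 1156.  92.9 across_junction
#> 2 G1:chrS:4658-5259:+     4958 1099. 100.0 across_junction
#> 3 G2:chrS:18205-18706:+  18455 1316.  83.4 across_junction
#> 4 G2:chrS:15571-16332:+  15951  858. 127.  across_junction

ann    <- annotate_peaks(peaks, models, paths$fasta)
#> peak features: exon 6.2%, intron 12.5%, UTR3 81.2%; A-rich downstream: 6.2%
counts <- count_umis(reads, peaks, wl)
#> <peak_count_matrix> 16 peaks x 600 cells; 8731 non-zero entries

pops <- readr::read_tsv(paths$populations)
pb   <- make_pseudobulk(counts, pops, n = 6, seed = 1)
du   <- du_test(pb, annotations = ann, sc_counts = counts,
                populations = pops)
du
#> <du_result> B vs A: 14 peaks tested, 2 differentially used
dplyr::filter(tidy(du), du)[, c("peak_id", "p_adj", "usage_lfc")]
#> 1 G1:chrS:6876-7434:+     0      3.99
#> 2 G1:chrS:4658-5259:+     0     -3.99
glance(du)
#>   n_peaks n_tested n_du_peaks n_genes_tested n_dtu_genes
#> 1      16       14          2              6           1
```

The two called `G1` peaks sit within a few bases of the planted truth
(sites 5000 and 7200 minus the 45-bp read-geometry offset), the intronic
decoy is flagged `a_rich_downstream` and excluded from testing by
feature filtering, and the usage log2 fold-changes of ±3.99 recover the
simulated switch (`log2((0.8/0.2)/(0.2/0.8)) = 4`) with the expected
signs. `autoplot(du)` draws the volcano plot;
`run_pipeline()` chains all stages and writes TSV/MTX outputs with a
JSON metadata sidecar.

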