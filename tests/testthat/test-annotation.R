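hier_models <- function() {
  gene_model_table(tibble::tribble(
    ~chrom, ~start, ~end, ~strand, ~type, ~gene_id, ~transcript_id,
    # transcript T1: exon 1000-1999 (CDS), intron, exon 3000-5000 with
    # CDS to 3600 and 3'UTR 3601-5000
    "chr1", 1000L, 1999L, "+", "exon", "G1", "T1",
    "chr1", 3000L, 5000L, "+", "exon", "G1", "T1",
    "chr1", 1200L, 1999L, "+", "CDS", "G1", "T1",
    "chr1", 3000L, 3600L, "+", "CDS", "G1", "T1",
    # transcript T2: single long exon, fully coding across 3500-4200
    "chr1", 1000L, 4500L, "+", "exon", "G1", "T2",
    "chr1", 1000L, 4500L, "+", "CDS", "G1", "T2"))
}

test_that("feature hierarchy resolves multi-transcript overlap", {
  models <- hier_models()
  # inside T1's 3'UTR and T2's CDS -> UTR3 wins the hierarchy
  p1 <- tibble::tibble(peak_id = "p1", gene_id = "G1", chrom = "chr1",
                       start = 4000L, end = 4100L, strand = "+")
  a1 <- annotate_feature_type(p1, models)
  expect_equal(a1$primary_feature, "UTR3")
  expect_true(grepl("UTR3", a1$feature_types))
  expect_true(grepl("exon", a1$feature_types))

  # spanning T1's exon/intron boundary (and T2 CDS): all features returned
  p2 <- tibble::tibble(peak_id = "p2", gene_id = "G1", chrom = "chr1",
                       start = 1950L, end = 2100L, strand = "+")
  a2 <- annotate_feature_type(p2, models)
  expect_setequal(strsplit(a2$feature_types, ";")[[1]],
                  c("exon", "intron"))
  expect_equal(a2$primary_feature, "exon")

  # intron of both transcripts? T2 covers 2000-2999 as CDS; restrict to T1
  p3 <- tibble::tibble(peak_id = "p3", gene_id = "G1", chrom = "chr1",
                       start = 2200L, end = 2300L, strand = "+")
  a3 <- annotate_feature_type(p3, models)
  expect_equal(a3$primary_feature, "exon")  # T2's CDS outranks T1's intron

  # outside every transcript of the gene
  p4 <- tibble::tibble(peak_id = "p4", gene_id = "G1", chrom = "chr1",
                       start = 8000L, end = 8100L, strand = "+")
  a4 <- annotate_feature_type(p4, models)
  expect_equal(a4$primary_feature, "intergenic")
  expect_equal(a4$feature_types, "")
})

test_that("5'UTR overlap ranks above exon but below 3'UTR", {
  models <- gene_model_table(tibble::tribble(
    ~chrom, ~start, ~end, ~strand, ~type, ~gene_id, ~transcript_id,
    "chr1", 1000L, 3000L, "+", "exon", "G1", "T1",
    "chr1", 1500L, 2500L, "+", "CDS", "G1", "T1"))
  p <- tibble::tibble(peak_id = c("a", "b"), gene_id = "G1",
                      chrom = "chr1", start = c(1100L, 2600L),
                      end = c(1200L, 2700L), strand = "+")
  a <- annotate_feature_type(p, models)
  expect_equal(a$primary_feature, c("UTR5", "UTR3"))
})

seq_with <- function(len, inserts, fill = "C") {
  bases <- rep(fill, len)
  for (ins in inserts) {
    motif <- strsplit(ins$motif, "")[[1]]
    bases[ins$at + seq_along(motif) - 1] <- motif
  }
  Biostrings::DNAStringSet(setNames(paste(bases, collapse = ""), "chr1"))
}

test_that("polyA motif and A/T-rich stretches are detected with one-mismatch tolerance", {
  peak <- tibble::tibble(peak_id = "p", gene_id = "G1", chrom = "chr1",
                         start = 1000L, end = 1500L, strand = "+")
  # AATAAA 40 nt downstream of the peak end
  g1 <- seq_with(3000, list(list(at = 1540, motif = "AATAAA")))
  r1 <- scan_sequence_motifs(peak, g1, window = 200)
  expect_true(r1$polyA_motif)
  expect_false(r1$a_rich_downstream)
  expect_false(r1$t_rich_upstream)

  # 13-mer with one mismatch downstream -> A-rich
  g2 <- seq_with(3000, list(list(at = 1600, motif = "AAAAAACAAAAAA")))
  r2 <- scan_sequence_motifs(peak, g2, window = 200)
  expect_true(r2$a_rich_downstream)
  expect_false(r2$polyA_motif)

  # two mismatches in every 13-frame -> not A-rich
  g3 <- seq_with(3000, list(list(at = 1600, motif = "AAAAACAAACAAA")))
  expect_false(scan_sequence_motifs(peak, g3,
                                    window = 200)$a_rich_downstream)

  # T-rich upstream
  g4 <- seq_with(3000, list(list(at = 900, motif = "TTTTTTGTTTTTT")))
  r4 <- scan_sequence_motifs(peak, g4, window = 200)
  expect_true(r4$t_rich_upstream)
  expect_false(r4$a_rich_downstream)

  # GC background with no signals -> all flags false
  g5 <- seq_with(3000, list())
  r5 <- scan_sequence_motifs(peak, g5, window = 200)
  expect_false(any(r5$polyA_motif, r5$a_rich_downstream,
                   r5$t_rich_upstream))
})

test_that("minus-strand scanning mirrors the plus strand", {
  n <- 3000L
  plus_peak <- tibble::tibble(peak_id = "p", gene_id = "G1",
                              chrom = "chr1", start = 1000L, end = 1500L,
                              strand = "+")
  g <- seq_with(n, list(list(at = 1540, motif = "AATAAA"),
                        list(at = 900, motif = "TTTTTTTTTTTTT")))
  fwd <- scan_sequence_motifs(plus_peak, g, window = 200)
  # mirror the genome and the peak
  rc <- Biostrings::reverseComplement(g[[1]])
  g_rc <- Biostrings::DNAStringSet(setNames(as.character(rc), "chr1"))
  minus_peak <- tibble::tibble(peak_id = "p", gene_id = "G1",
                               chrom = "chr1",
                               start = n - 1500L + 1L, end = n - 1000L + 1L,
                               strand = "-")
  rev <- scan_sequence_motifs(minus_peak, g_rc, window = 200)
  expect_equal(unlist(rev[, c("polyA_motif", "a_rich_downstream",
                              "t_rich_upstream")]),
               unlist(fwd[, c("polyA_motif", "a_rich_downstream",
                              "t_rich_upstream")]))
})

test_that("windows truncate at contig ends without error", {
  peak <- tibble::tibble(peak_id = "p", gene_id = "G1", chrom = "chr1",
                         start = 10L, end = 2990L, strand = "+")
  g <- seq_with(3000, list())
  expect_no_error(scan_sequence_motifs(peak, g, window = 200))
})

test_that("annotate_peaks is total, order-independent, and validates chromosomes", {
  models <- hier_models()
  g <- seq_with(9000, list(list(at = 4150, motif = "AATAAA")))
  peaks <- tibble::tibble(
    peak_id = c("p1", "p2", "p3"), gene_id = "G1", chrom = "chr1",
    start = c(4000L, 2200L, 1100L), end = c(4100L, 2300L, 1200L),
    strand = "+")
  ann <- suppressMessages(annotate_peaks(peaks, models, g))
  expect_equal(nrow(ann), nrow(peaks))
  expect_true(ann$polyA_motif[ann$peak_id == "p1"])

  shuffled <- suppressMessages(
    annotate_peaks(peaks[c(3, 1, 2), ], models, g))
  expect_equal(dplyr::arrange(ann, peak_id),
               dplyr::arrange(shuffled, peak_id))

  bad <- peaks
  bad$chrom <- "chrZ"
  expect_error(suppressWarnings(suppressMessages(
    annotate_peaks(bad, models, g))), "chrZ")

  empty <- suppressMessages(annotate_peaks(peaks[0, ], models, g))
  expect_equal(nrow(empty), 0L)
})
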