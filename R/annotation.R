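#' Annotate peaks with genomic feature types
#'
#' For each peak, all features it overlaps across the transcripts of its
#' gene are collected (3'UTR, 5'UTR, exon, intron); the `primary_feature`
#' is chosen by the hierarchy UTR3 > UTR5 > exon > intron, reflecting the
#' 3'-biased chemistry.  `exon` means overlap with coding sequence for
#' transcripts whose CDS is annotated; for transcripts without CDS/UTR
#' information the whole exon counts.  Peaks outside every transcript of
#' their gene are labelled `intergenic`.
#'
#' @param peaks peak table with `peak_id`, `gene_id`, `chrom`, `start`,
#'   `end`.
#' @param gene_models gene-model table ([read_gene_models()]).
#' @return `peaks` with `feature_types` (`;`-separated) and
#'   `primary_feature` columns appended.
#' @export
annotate_feature_type <- function(peaks, gene_models) {
  hierarchy <- c("UTR3", "UTR5", "exon", "intron")
  # exon evidence: CDS where a transcript has one, whole exon otherwise
  has_cds <- gene_models |>
    filter(.data$type == "CDS") |>
    pull(.data$transcript_id) |>
    unique()
  feats <- gene_models |>
    filter(.data$type %in% c("UTR3", "UTR5", "CDS", "exon", "intron")) |>
    mutate(feature = dplyr::case_when(
      .data$type == "CDS" ~ "exon",
      .data$type == "exon" & .data$transcript_id %in% has_cds ~ NA_character_,
      .data$type == "exon" ~ "exon",
      TRUE ~ .data$type)) |>
    filter(!is.na(.data$feature))
  if (nrow(peaks) == 0L) {
    return(peaks |> mutate(feature_types = character(),
                           primary_feature = character()))
  }
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start, peaks$end))
  feat_gr <- GenomicRanges::GRanges(
    feats$chrom, IRanges::IRanges(feats$start, feats$end))
  hits <- GenomicRanges::findOverlaps(peak_gr, feat_gr)
  ov <- tibble(peak = S4Vectors::queryHits(hits),
               feat = S4Vectors::subjectHits(hits)) |>
    filter(peaks$gene_id[.data$peak] == feats$gene_id[.data$feat]) |>
    mutate(feature = feats$feature[.data$feat]) |>
    distinct(.data$peak, .data$feature)
  summarise_feats <- function(fs) {
    fs <- hierarchy[hierarchy %in% fs]
    if (length(fs) == 0L) return(c("", "intergenic"))
    c(paste(fs, collapse = ";"), fs[1])
  }
  per_peak <- map(seq_len(nrow(peaks)), function(i) {
    summarise_feats(ov$feature[ov$peak == i])
  })
  peaks |>
    mutate(feature_types = map_chr(per_peak, 1),
           primary_feature = map_chr(per_peak, 2))
}

# load a genome as DNAStringSet from a FASTA path / FaFile / DNAStringSet
load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (methods::is(genome, "FaFile")) {
    return(Biostrings::readDNAStringSet(Rsamtools::path(genome)))
  }
  seqs <- Biostrings::readDNAStringSet(genome)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

# does a sequence contain a w-mer with at least w - max_mismatch copies
# of `base`?
has_base_run <- function(seq, base, w = 13L, max_mismatch = 1L) {
  if (length(seq) < w) return(FALSE)
  counts <- Biostrings::letterFrequencyInSlidingView(seq, w, base)
  any(counts >= w - max_mismatch)
}

#' Scan peak-proximal sequence for polyA / internal-priming signals
#'
#' On each peak's sense strand, the `window` nucleotides downstream of the
#' peak's 3' end are scanned for the canonical polyA motif (AATAAA in DNA
#' sense) and for an A-rich stretch (a 13-mer with at most one non-A);
#' the `window` nucleotides upstream of the 5' end are scanned for a T-rich
#' stretch (13-mer with at most one non-T).  Minus-strand peaks use the
#' reverse complement with mirrored windows.  Windows running past a
#' contig end are truncated.  A-rich downstream flags likely internal
#' (oligo-dT mis-)priming sites rather than true cleavage sites.
#'
#' @param peaks peak table with `peak_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param genome FASTA path, `FaFile`, or `DNAStringSet`.
#' @param window scan window length in nt.
#' @return `peaks` with logical columns `polyA_motif`,
#'   `a_rich_downstream`, `t_rich_upstream` appended.
#' @export
scan_sequence_motifs <- function(peaks, genome, window = 200L) {
  seqs <- load_genome(genome)
  missing <- setdiff(unique(peaks$chrom), names(seqs))
  if (length(missing) > 0L) {
    abort(paste0("chromosome(s) absent from the genome FASTA: ",
                 paste(missing, collapse = ", ")))
  }
  fetch <- function(chrom, start, end, revcomp) {
    len <- length(seqs[[chrom]])
    start <- max(1L, start); end <- min(len, end)
    if (start > end) return(Biostrings::DNAString(""))
    s <- Biostrings::subseq(seqs[[chrom]], start, end)
    if (revcomp) Biostrings::reverseComplement(s) else s
  }
  res <- map(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    minus <- identical(p$strand, "-")
    down <- if (minus) {
      fetch(p$chrom, p$start - window, p$start - 1L, TRUE)
    } else {
      fetch(p$chrom, p$end + 1L, p$end + window, FALSE)
    }
    up <- if (minus) {
      fetch(p$chrom, p$end + 1L, p$end + window, TRUE)
    } else {
      fetch(p$chrom, p$start - window, p$start - 1L, FALSE)
    }
    tibble(
      polyA_motif = Biostrings::countPattern("AATAAA", down) > 0,
      a_rich_downstream = has_base_run(down, "A"),
      t_rich_upstream = has_base_run(up, "T"))
  }) |> list_rbind()
  bind_cols(peaks, res)
}

#' Annotate peaks with features and sequence signals
#'
#' Convenience wrapper combining [annotate_feature_type()] and
#' [scan_sequence_motifs()]; logs summary fractions per primary feature
#' and the A-rich fraction.
#'
#' @inheritParams annotate_feature_type
#' @inheritParams scan_sequence_motifs
#' @param out_path optional TSV path for the annotated table.
#' @return annotated peak tibble (one row per input peak).
#' @export
annotate_peaks <- function(peaks, gene_models, genome, window = 200L,
                           out_path = NULL) {
  ann <- peaks |>
    annotate_feature_type(gene_models) |>
    scan_sequence_motifs(genome, window = window)
  if (nrow(ann) > 0L) {
    tab <- table(ann$primary_feature)
    inform(paste0(
      "peak features: ",
      paste(names(tab), sprintf("%.1f%%", 100 * tab / nrow(ann)),
            collapse = ", "),
      "; A-rich downstream: ",
      sprintf("%.1f%%", 100 * mean(ann$a_rich_downstream))))
  }
  if (!is.null(out_path)) write_peaks(ann, out_path)
  ann
}
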