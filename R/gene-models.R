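#' Read gene models from a GTF file
#'
#' Imports gene/transcript/exon/CDS/UTR features from a GTF annotation and
#' returns a normalised feature table.  Missing structural rows are derived:
#' transcript and gene spans from exon extents, introns as the gaps between a
#' transcript's exons, and 5'/3' UTRs from the CDS extent when the GTF does
#' not carry explicit UTR features.  Generic `UTR` rows are classified into
#' `UTR5`/`UTR3` using the CDS position and strand.
#'
#' @param gtf_path path to a GTF file.
#' @return a tibble with columns `chrom`, `start`, `end`, `strand`, `type`
#'   (one of `gene`, `transcript`, `exon`, `CDS`, `UTR5`, `UTR3`, `intron`),
#'   `gene_id` and `transcript_id` (`NA` for gene rows). Coordinates are
#'   1-based inclusive.
#' @export
read_gene_models <- function(gtf_path) {
  if (!file.exists(gtf_path)) abort(paste0("GTF file not found: ", gtf_path))
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  feats <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    transcript_id = if ("transcript_id" %in% names(md)) {
      as.character(md$transcript_id)
    } else NA_character_
  )
  gene_model_table(feats)
}

#' Build a normalised gene-model table from raw features
#'
#' Used by [read_gene_models()] and directly by tests that construct gene
#' structures in code.  Accepts GTF-style type names
#' (`three_prime_utr`, `five_prime_utr`, `UTR`, ...) and fills in derived
#' rows (transcript/gene spans, introns, UTRs from CDS).
#'
#' @param feats tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `type`, `gene_id`, and optionally `transcript_id`.
#' @return tibble in the format documented in [read_gene_models()].
#' @export
gene_model_table <- function(feats) {
  stopifnot(all(c("chrom", "start", "end", "strand", "type", "gene_id") %in%
                  names(feats)))
  if (!"transcript_id" %in% names(feats)) feats$transcript_id <- NA_character_
  feats <- feats |>
    mutate(
      start = as.integer(.data$start), end = as.integer(.data$end),
      type = dplyr::case_match(
        .data$type,
        "three_prime_utr" ~ "UTR3", "three_prime_UTR" ~ "UTR3",
        "five_prime_utr" ~ "UTR5", "five_prime_UTR" ~ "UTR5",
        .default = .data$type
      )
    ) |>
    filter(.data$type %in% c("gene", "transcript", "exon", "CDS",
                             "UTR", "UTR3", "UTR5", "intron"))
  per_tx <- feats |>
    filter(!is.na(.data$transcript_id),
           .data$type %in% c("exon", "CDS", "UTR", "UTR3", "UTR5", "intron")) |>
    group_by(.data$gene_id, .data$transcript_id) |>
    dplyr::group_split()
  derived <- map(per_tx, derive_transcript_features) |> list_rbind()
  genes <- derived |>
    group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), strand = first(.data$strand),
              .groups = "drop") |>
    mutate(type = "gene", transcript_id = NA_character_)
  explicit_genes <- feats |> filter(.data$type == "gene")
  if (nrow(explicit_genes) > 0L) {
    genes <- explicit_genes |>
      select(all_of(c("chrom", "start", "end", "strand", "gene_id"))) |>
      mutate(type = "gene", transcript_id = NA_character_) |>
      bind_rows(genes |> anti_join(explicit_genes, by = "gene_id"))
  }
  bind_rows(derived, genes) |>
    select(all_of(c("chrom", "start", "end", "strand", "type",
                    "gene_id", "transcript_id"))) |>
    arrange(.data$chrom, .data$gene_id, .data$transcript_id, .data$start)
}

# complete one transcript: classify UTRs, derive missing UTRs from CDS,
# add intron rows and the transcript span
derive_transcript_features <- function(tx) {
  chrom <- tx$chrom[1]; strand <- tx$strand[1]
  gid <- tx$gene_id[1]; tid <- tx$transcript_id[1]
  exons <- tx |> filter(.data$type == "exon")
  if (nrow(exons) == 0L) {
    # fall back to treating any feature extent as exonic
    exons <- tx |> mutate(type = "exon")
  }
  exon_ir <- IRanges::reduce(IRanges::IRanges(exons$start, exons$end))
  cds <- tx |> filter(.data$type == "CDS")
  utr <- tx |> filter(.data$type %in% c("UTR", "UTR3", "UTR5"))

  row_tbl <- function(ir, type) {
    if (length(ir) == 0L) return(NULL)
    tibble(chrom = chrom, start = IRanges::start(ir), end = IRanges::end(ir),
           strand = strand, type = type, gene_id = gid, transcript_id = tid)
  }
  classify_utr <- function(u) {
    if (nrow(u) == 0L || nrow(cds) == 0L) return(u)
    cmid <- (min(cds$start) + max(cds$end)) / 2
    u |> mutate(type = if_else(
      .data$type %in% c("UTR3", "UTR5"), .data$type,
      if_else(xor(.data$start + .data$end < 2 * cmid, strand == "+"),
              "UTR3", "UTR5")))
  }
  utr <- classify_utr(utr)
  if (!any(utr$type %in% c("UTR3", "UTR5")) && nrow(cds) > 0L) {
    cds_span <- IRanges::IRanges(min(cds$start), max(cds$end))
    utr_ir <- IRanges::setdiff(exon_ir, cds_span)
    if (length(utr_ir) > 0L) {
      left <- IRanges::end(utr_ir) < IRanges::start(cds_span)
      type <- if_else(xor(left, strand == "+"), "UTR3", "UTR5")
      utr <- tibble(chrom = chrom, start = IRanges::start(utr_ir),
                    end = IRanges::end(utr_ir), strand = strand,
                    type = type, gene_id = gid, transcript_id = tid)
    }
  }
  intron_ir <- IRanges::gaps(exon_ir)
  span <- tibble(chrom = chrom, start = min(IRanges::start(exon_ir)),
                 end = max(IRanges::end(exon_ir)), strand = strand,
                 type = "transcript", gene_id = gid, transcript_id = tid)
  bind_rows(
    row_tbl(exon_ir, "exon"),
    if (nrow(cds) > 0L) cds |> select(all_of(names(span))),
    utr |> filter(.data$type %in% c("UTR3", "UTR5")),
    row_tbl(intron_ir, "intron"),
    span
  )
}

#' Per-gene spans from a gene-model table
#'
#' @param models table from [read_gene_models()] / [gene_model_table()].
#' @return one row per gene: `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
gene_spans <- function(models) {
  models |>
    filter(.data$type == "gene") |>
    select(all_of(c("gene_id", "chrom", "start", "end", "strand")))
}

#' @importFrom rlang .data
NULL
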