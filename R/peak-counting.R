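#' Count UMIs per peak per cell
#'
#' Builds the sparse peaks-by-cells UMI count matrix.  An entry (p, c) is
#' the number of distinct UMIs among whitelisted-barcode alignments of cell
#' c with at least one aligned block overlapping peak p (spliced N gaps do
#' not count as overlap).  A (cell, UMI) molecule overlapping several peaks
#' of a gene increments each overlapped peak.  Reads without a barcode or
#' UMI, or with a barcode outside the whitelist, are ignored.
#'
#' @param x a BAM path or an alignment table from [read_alignments()].
#' @param peaks peak table (`peak_id`, `chrom`, `strand`, `start`, `end`).
#' @param whitelist character vector of cell barcodes; defines the matrix
#'   columns (in the given order).
#' @param stranded if `TRUE`, only alignments on the peak's strand count.
#' @return a `peak_count_matrix`: list with `counts` (dgCMatrix, peaks x
#'   cells), `peak_ids`, `barcodes`.
#' @export
count_umis <- function(x, peaks, whitelist, stranded = FALSE) {
  if (nrow(peaks) == 0L) abort("no peaks supplied to count_umis()")
  if (length(whitelist) == 0L) abort("empty whitelist in count_umis()")
  reads <- if (is.character(x)) read_alignments(x) else x
  reads <- reads |>
    filter(!is.na(.data$barcode), .data$barcode %in% whitelist,
           !is.na(.data$umi))
  counts <- Matrix::sparseMatrix(
    i = integer(), j = integer(), x = integer(),
    dims = c(nrow(peaks), length(whitelist)))
  if (nrow(reads) > 0L) {
    blocks <- aln_block_ranges(reads)
    nb <- S4Vectors::elementNROWS(blocks)
    block_gr <- GenomicRanges::GRanges(
      rep(reads$chrom, nb), unlist(blocks, use.names = FALSE),
      strand = rep(reads$strand, nb))
    peak_gr <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(peaks$start, peaks$end),
      strand = peaks$strand)
    hits <- GenomicRanges::findOverlaps(
      block_gr, peak_gr,
      ignore.strand = !stranded)
    if (length(hits) > 0L) {
      read_of <- rep.int(seq_len(nrow(reads)), nb)
      trips <- tibble(
        peak = S4Vectors::subjectHits(hits),
        barcode = reads$barcode[read_of[S4Vectors::queryHits(hits)]],
        umi = reads$umi[read_of[S4Vectors::queryHits(hits)]]) |>
        distinct() |>
        count(.data$peak, .data$barcode, name = "n")
      counts <- Matrix::sparseMatrix(
        i = trips$peak, j = match(trips$barcode, whitelist), x = trips$n,
        dims = c(nrow(peaks), length(whitelist)))
    }
  }
  counts <- methods::as(methods::as(counts, "CsparseMatrix"),
                        "generalMatrix")
  dimnames(counts) <- list(peaks$peak_id, whitelist)
  structure(list(counts = counts, peak_ids = peaks$peak_id,
                 barcodes = whitelist),
            class = "peak_count_matrix")
}

#' @export
print.peak_count_matrix <- function(x, ...) {
  cat("<peak_count_matrix> ", length(x$peak_ids), " peaks x ",
      length(x$barcodes), " cells; ", Matrix::nnzero(x$counts),
      " non-zero entries\n", sep = "")
  invisible(x)
}

#' Write / read a peak count matrix (MatrixMarket triplet layout)
#'
#' Writes `matrix.mtx` (coordinate MatrixMarket), `peaks.tsv` and
#' `barcodes.tsv` (one id per line) into `out_dir`; `read_count_matrix()`
#' is the exact inverse.
#'
#' @param m a `peak_count_matrix`.
#' @param out_dir output directory (created if needed).
#' @return `write_count_matrix()` returns `out_dir` invisibly.
#' @export
write_count_matrix <- function(m, out_dir) {
  stopifnot(inherits(m, "peak_count_matrix"))
  if (nrow(m$counts) != length(m$peak_ids) ||
      ncol(m$counts) != length(m$barcodes)) {
    abort("count matrix dimensions do not match the id lists")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(out_dir, "matrix.mtx"))
  writeLines(m$peak_ids, file.path(out_dir, "peaks.tsv"))
  writeLines(m$barcodes, file.path(out_dir, "barcodes.tsv"))
  invisible(out_dir)
}

#' @rdname write_count_matrix
#' @param dir directory written by [write_count_matrix()].
#' @export
read_count_matrix <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  counts <- methods::as(methods::as(counts, "CsparseMatrix"),
                        "generalMatrix")
  peak_ids <- readLines(file.path(dir, "peaks.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(counts) != length(peak_ids) || ncol(counts) != length(barcodes)) {
    abort("matrix dimensions do not match the id files")
  }
  dimnames(counts) <- list(peak_ids, barcodes)
  structure(list(counts = counts, peak_ids = peak_ids,
                 barcodes = barcodes),
            class = "peak_count_matrix")
}
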