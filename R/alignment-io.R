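#' Read tagged alignments from a BAM file
#'
#' Reads alignments into a tidy one-row-per-read table carrying the fields
#' the peak caller and UMI counter need: position, CIGAR, strand, and the
#' cell-barcode / UMI tags.  Secondary, supplementary and duplicate-flagged
#' records are excluded by default.  When a barcode whitelist is supplied,
#' reads with a missing or non-whitelisted barcode are dropped (the number
#' dropped is reported via a message).
#'
#' @param bam_path path to a coordinate-sorted BAM file.
#' @param region optional `"chrom:start-end"` string (or list with `chrom`,
#'   `start`, `end`); requires a BAM index.
#' @param whitelist optional character vector of allowed cell barcodes.
#' @param barcode_tag,umi_tag primary BAM tags for cell barcode and UMI
#'   (CellRanger's corrected tags by default).
#' @param barcode_fallback,umi_fallback raw-tag fallbacks used when the
#'   primary tag is absent on a record.
#' @param drop_flagged exclude secondary/supplementary/duplicate records.
#' @return tibble with columns `chrom`, `pos` (1-based leftmost aligned
#'   base), `cigar`, `strand`, `barcode`, `umi`.
#' @export
read_alignments <- function(bam_path, region = NULL, whitelist = NULL,
                            barcode_tag = "CB", umi_tag = "UB",
                            barcode_fallback = "CR", umi_fallback = "UR",
                            drop_flagged = TRUE) {
  if (!file.exists(bam_path)) abort(paste0("BAM file not found: ", bam_path))
  region <- parse_region(region)
  which <- NULL
  if (!is.null(region)) {
    idx <- paste0(bam_path, ".bai")
    if (!file.exists(idx) && !file.exists(paste0(bam_path, ".csi")) &&
        !file.exists(sub("\\.bam$", ".bai", bam_path))) {
      abort(paste0("region queries need a BAM index; none found for ",
                   bam_path))
    }
    which <- GenomicRanges::GRanges(region$chrom,
                                    IRanges::IRanges(region$start, region$end))
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = if (drop_flagged) FALSE else NA,
    isSupplementaryAlignment = if (drop_flagged) FALSE else NA,
    isDuplicate = if (drop_flagged) FALSE else NA
  )
  tags <- unique(c(barcode_tag, umi_tag, barcode_fallback, umi_fallback))
  param <- if (is.null(which)) {
    Rsamtools::ScanBamParam(flag = flag, tag = tags,
                            what = c("rname", "pos", "cigar", "strand"))
  } else {
    Rsamtools::ScanBamParam(flag = flag, tag = tags, which = which,
                            what = c("rname", "pos", "cigar", "strand"))
  }
  res <- Rsamtools::scanBam(bam_path, param = param)
  coalesce_tag <- function(chunk, primary, fallback, n) {
    x <- chunk$tag[[primary]] %||% rep(NA_character_, n)
    y <- chunk$tag[[fallback]] %||% rep(NA_character_, n)
    dplyr::coalesce(as.character(x), as.character(y))
  }
  reads <- map(res, function(chunk) {
    n <- length(chunk$pos)
    tibble(
      chrom = as.character(chunk$rname),
      pos = chunk$pos,
      cigar = chunk$cigar,
      strand = as.character(chunk$strand),
      barcode = coalesce_tag(chunk, barcode_tag, barcode_fallback, n),
      umi = coalesce_tag(chunk, umi_tag, umi_fallback, n)
    )
  }) |> list_rbind()
  bad <- is.na(reads$cigar) | !grepl("^([0-9]+[MIDNSHP=X])+$", reads$cigar)
  if (any(bad)) {
    warn(paste0(sum(bad), " record(s) with missing/malformed CIGAR skipped"))
    reads <- reads[!bad, ]
  }
  if (!is.null(whitelist)) {
    keep <- !is.na(reads$barcode) & reads$barcode %in% whitelist
    if (any(!keep)) {
      inform(paste0(sum(!keep),
                    " record(s) dropped by the barcode whitelist"))
    }
    reads <- reads[keep, ]
  }
  reads
}

#' Read a barcode whitelist (one barcode per line)
#'
#' @param path text file with one cell barcode per line.
#' @return character vector of unique barcodes.
#' @export
read_whitelist <- function(path) {
  bc <- readLines(path)
  bc <- bc[nzchar(bc)]
  if (length(bc) == 0L) abort("whitelist is empty")
  unique(bc)
}

# reference-space aligned blocks per read (M/D merged, split at N ops);
# returns a CompressedIRangesList parallel to the rows of `reads`
aln_block_ranges <- function(reads) {
  GenomicAlignments::extractAlignmentRangesOnReference(
    reads$cigar, pos = reads$pos, drop.D.ranges = FALSE)
}

# N-op (intron skip) reference spans per read
aln_skip_ranges <- function(reads) {
  GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar, pos = reads$pos, ops = "N")
}

#' Extract splice junctions from alignments
#'
#' Junctions are taken from CIGAR N operations.  A read supports a junction
#' only when its aligned blocks flanking the skip both span at least
#' `min_overhang` reference bases; support is the number of such reads.
#'
#' @param reads alignment table from [read_alignments()] (one chromosome).
#' @param min_overhang minimum flanking aligned bases on each side.
#' @return tibble with columns `chrom`, `intron_start`, `intron_end`
#'   (1-based inclusive intronic span), `strand`, `support`, sorted by
#'   coordinate.
#' @export
extract_junctions <- function(reads, min_overhang = 5L) {
  empty <- tibble(chrom = character(), intron_start = integer(),
                  intron_end = integer(), strand = character(),
                  support = integer())
  if (nrow(reads) == 0L) return(empty)
  skips <- aln_skip_ranges(reads)
  nskip <- S4Vectors::elementNROWS(skips)
  if (sum(nskip) == 0L) return(empty)
  blocks <- aln_block_ranges(reads)
  read_of <- rep.int(seq_len(nrow(reads)), nskip)
  skip_index <- sequence(nskip)  # i-th skip lies between blocks i and i+1
  sk <- unlist(skips, use.names = FALSE)
  bw <- IRanges::width(blocks)
  left_w <- as.integer(unlist(bw, use.names = FALSE)[
    cumsum(c(0L, head(S4Vectors::elementNROWS(blocks), -1L)))[read_of] +
      skip_index])
  right_w <- as.integer(unlist(bw, use.names = FALSE)[
    cumsum(c(0L, head(S4Vectors::elementNROWS(blocks), -1L)))[read_of] +
      skip_index + 1L])
  ok <- left_w >= min_overhang & right_w >= min_overhang
  if (!any(ok)) return(empty)
  tibble(
    chrom = reads$chrom[read_of][ok],
    intron_start = IRanges::start(sk)[ok],
    intron_end = IRanges::end(sk)[ok],
    strand = reads$strand[read_of][ok]
  ) |>
    count(.data$chrom, .data$intron_start, .data$intron_end, .data$strand,
          name = "support") |>
    arrange(.data$intron_start, .data$intron_end)
}

#' Per-base read coverage over a gene span
#'
#' @param reads alignment table (already restricted to the gene's
#'   chromosome or fetched by region).
#' @param gene_span list/tibble row with `chrom`, `start`, `end`, and
#'   optionally `strand`.
#' @return a `coverage_track`: list with `chrom`, `origin` (genomic
#'   position of `values[1]`), `strand`, and integer `values` over the span.
#'   Intronic N skips contribute no coverage.
#' @export
build_gene_coverage <- function(reads, gene_span) {
  span <- parse_region(gene_span)
  strand <- if (is.list(gene_span) && !is.null(gene_span$strand)) {
    as.character(gene_span$strand[1])
  } else "*"
  len <- span$end - span$start + 1L
  reads <- reads[reads$chrom == span$chrom, , drop = FALSE]
  vals <- integer(len)
  if (nrow(reads) > 0L) {
    ir <- unlist(aln_block_ranges(reads), use.names = FALSE)
    ir <- IRanges::restrict(ir, start = span$start, end = span$end)
    ir <- ir[IRanges::width(ir) > 0L]
    if (length(ir) > 0L) {
      vals <- as.integer(IRanges::coverage(
        IRanges::shift(ir, 1L - span$start), width = len))
    }
  }
  structure(list(chrom = span$chrom, origin = span$start, strand = strand,
                 values = vals),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", x$chrom, ":", x$origin, "-",
      x$origin + length(x$values) - 1L, " (", x$strand, "), max depth ",
      max(x$values), "\n", sep = "")
  invisible(x)
}

#' @method as_tibble coverage_track
#' @export
as_tibble.coverage_track <- function(x, ...) {
  tibble(chrom = x$chrom, pos = x$origin + seq_along(x$values) - 1L,
         depth = x$values)
}

#' Split a BAM file by cell population
#'
#' Writes one indexed BAM per population label containing exactly the input
#' records whose cell barcode maps to that label (header preserved).
#'
#' @param bam_path input BAM.
#' @param populations tibble with columns `barcode` and `population`.
#' @param out_dir output directory (created if needed).
#' @param barcode_tag BAM tag holding the cell barcode.
#' @param labels population labels to emit (defaults to the labels present
#'   in `populations`); a label with no assigned barcodes produces an
#'   empty BAM with a warning.
#' @return tibble with `population`, `path`, `n_records`.
#' @export
split_bam_by_population <- function(bam_path, populations, out_dir,
                                    barcode_tag = "CB",
                                    labels = unique(populations$population)) {
  stopifnot(all(c("barcode", "population") %in% names(populations)))
  if (anyDuplicated(populations$barcode)) {
    abort("each barcode may be assigned to one population only")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- map(labels, function(lab) {
    bcs <- populations$barcode[populations$population == lab]
    if (length(bcs) == 0L) warn(paste0("population '", lab,
                                       "' has no barcodes; output is empty"))
    dest <- file.path(out_dir, paste0(lab, ".bam"))
    rules <- S4Vectors::FilterRules(list(pop = function(df) {
      bc <- df[[barcode_tag]]
      !is.na(bc) & bc %in% bcs
    }))
    Rsamtools::filterBam(
      bam_path, dest, filter = rules,
      param = Rsamtools::ScanBamParam(tag = barcode_tag, what = "qname"),
      indexDestination = TRUE)
    n <- Rsamtools::countBam(dest)$records
    tibble(population = lab, path = dest, n_records = n)
  }) |> list_rbind()
  out
}

#' Export binned coverage as bedGraph
#'
#' Computes per-bin mean coverage over a region and writes/returns it in
#' bedGraph convention (0-based half-open intervals).  Zero-valued bins are
#' omitted by default (sparse bedGraph dialect).
#'
#' @param bam_path indexed BAM.
#' @param region `"chrom:start-end"` region string.
#' @param binsize bin width in bases (`1` reproduces raw per-base coverage).
#' @param out_path optional path; when given, records are written as
#'   4-column TSV.
#' @param densify keep zero-valued bins.
#' @return tibble with `chrom`, `start` (0-based), `end`, `value`.
#' @export
export_coverage <- function(bam_path, region, binsize = 1L, out_path = NULL,
                            densify = FALSE) {
  if (binsize < 1L) abort("binsize must be >= 1")
  span <- parse_region(region)
  reads <- read_alignments(bam_path, region = span)
  track <- build_gene_coverage(reads, span)
  bins <- bin_track(track, binsize)
  if (!densify) bins <- bins[bins$value > 0, , drop = FALSE]
  if (!is.null(out_path)) {
    readr::write_tsv(bins, out_path, col_names = FALSE)
  }
  bins
}

# mean coverage per bin, bedGraph coordinates
bin_track <- function(track, binsize) {
  len <- length(track$values)
  bin <- (seq_len(len) - 1L) %/% binsize
  means <- as.numeric(tapply(track$values, bin, mean))
  nb <- length(means)
  start0 <- (track$origin - 1L) + (seq_len(nb) - 1L) * binsize
  end0 <- pmin(start0 + binsize, track$origin - 1L + len)
  tibble(chrom = track$chrom, start = start0, end = end0, value = means)
}
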