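# in-code fixture builders shared across the suite

sim_reads <- function(pos, cigar = "91M", chrom = "chr1", strand = "+",
                      barcode = NA_character_, umi = NA_character_) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), cigar = cigar,
                 strand = strand, barcode = barcode, umi = umi)
}

# stack of 1-bp reads reproducing an arbitrary integer coverage profile
coverage_reads <- function(values, origin = 1L, chrom = "chr1",
                           strand = "+") {
  values <- as.integer(round(values))
  pos <- rep(origin + seq_along(values) - 1L, values)
  sim_reads(pos, cigar = "1M", chrom = chrom, strand = strand)
}

gaussian_values <- function(k, mu, sigma, len) {
  x <- seq_len(len) - 1
  k * exp(-0.5 * (x - mu)^2 / sigma^2)
}

# write an alignment table to a sorted + indexed BAM under a temp dir
write_test_bam <- function(reads, chrom_lens,
                           dir = withr::local_tempdir(
                             .local_envir = parent.frame())) {
  sam <- file.path(dir, "t.sam")
  header <- c("@HD\tVN:1.6",
              paste0("@SQ\tSN:", names(chrom_lens), "\tLN:", chrom_lens))
  opt <- function(tag, v) ifelse(is.na(v), "", paste0("\t", tag, v))
  body <- if (nrow(reads) == 0L) character() else {
    paste0("r", seq_len(nrow(reads)), "\t",
           ifelse(reads$strand == "-", 16L, 0L), "\t", reads$chrom, "\t",
           reads$pos, "\t255\t", reads$cigar, "\t*\t0\t0\t*\t*",
           opt("CB:Z:", reads$barcode), opt("UB:Z:", reads$umi))
  }
  writeLines(c(header, body), sam)
  bam0 <- Rsamtools::asBam(sam, file.path(dir, "unsorted"),
                           overwrite = TRUE, indexDestination = FALSE)
  bam <- Rsamtools::sortBam(bam0, file.path(dir, "sorted"))
  Rsamtools::indexBam(bam)
  unlink(c(sam, bam0))
  bam
}

# one-gene span row in the gene_spans() shape
gene_row <- function(gene_id = "G", chrom = "chr1", start = 1L,
                     end = 10000L, strand = "+") {
  tibble::tibble(gene_id = gene_id, chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand)
}

# brute-force UMI counting oracle: enumerate (read, peak, cell, UMI)
brute_force_counts <- function(reads, peaks, whitelist) {
  m <- matrix(0L, nrow(peaks), length(whitelist),
              dimnames = list(peaks$peak_id, whitelist))
  for (p in seq_len(nrow(peaks))) {
    for (cc in seq_along(whitelist)) {
      umis <- character()
      for (r in seq_len(nrow(reads))) {
        if (is.na(reads$barcode[r]) || reads$barcode[r] != whitelist[cc] ||
            is.na(reads$umi[r])) next
        if (reads$chrom[r] != peaks$chrom[p]) next
        blocks <- scpolya:::aln_block_ranges(reads[r, ])[[1]]
        hit <- any(IRanges::start(blocks) <= peaks$end[p] &
                     IRanges::end(blocks) >= peaks$start[p])
        if (hit) umis <- union(umis, reads$umi[r])
      }
      m[p, cc] <- length(umis)
    }
  }
  m
}

# minimal hand-built du_result for downstream-analysis tests
fake_du_result <- function(results, populations = c("A", "B")) {
  structure(list(results = results, populations = populations,
                 size_factors = NULL, params = list()),
            class = "du_result")
}
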