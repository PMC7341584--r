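test_that("read_alignments parses tags, applies the whitelist, and keeps optional fields optional", {
  reads <- dplyr::bind_rows(
    sim_reads(c(100, 200, 300), barcode = c("BC1", "BC2", "BC3"),
              umi = c("U1", "U2", "U3")),
    sim_reads(c(400, 500), barcode = c("XX1", NA), umi = c("U4", NA)))
  bam <- write_test_bam(reads, c(chr1 = 5000))

  all_reads <- read_alignments(bam)
  expect_equal(nrow(all_reads), 5L)
  expect_true(is.na(all_reads$umi[all_reads$pos == 500]))
  expect_true(is.na(all_reads$barcode[all_reads$pos == 500]))

  kept <- suppressMessages(
    read_alignments(bam, whitelist = c("BC1", "BC2", "BC3")))
  expect_equal(nrow(kept), 3L)
  expect_setequal(kept$barcode, c("BC1", "BC2", "BC3"))
  expect_message(read_alignments(bam, whitelist = "BC1"), "dropped")
})

test_that("empty BAM yields zero records and missing files error", {
  bam <- write_test_bam(sim_reads(integer()), c(chr1 = 1000))
  expect_equal(nrow(read_alignments(bam)), 0L)
  expect_error(read_alignments(file.path(tempdir(), "nope.bam")),
               "not found")
})

test_that("region queries demand an index that names the file", {
  reads <- sim_reads(c(100, 2000))
  bam <- write_test_bam(reads, c(chr1 = 5000))
  got <- read_alignments(bam, region = "chr1:1-1000")
  expect_equal(got$pos, 100L)
  file.remove(paste0(bam, ".bai"))
  expect_error(read_alignments(bam, region = "chr1:1-1000"), basename(bam))
})

test_that("junction extraction reproduces CIGAR block arithmetic", {
  expect_equal(nrow(extract_junctions(sim_reads(1001, "100M"))), 0L)

  one <- extract_junctions(sim_reads(1001, "50M100N50M"))
  expect_equal(one$intron_start, 1051L)
  expect_equal(one$intron_end, 1150L)
  expect_equal(one$support, 1L)

  many <- extract_junctions(sim_reads(rep(1001L, 60), "50M100N50M"))
  expect_equal(many$support, 60L)

  # flanks below the overhang are not counted as support
  short <- extract_junctions(
    dplyr::bind_rows(sim_reads(1001, "3M100N97M"),
                     sim_reads(1001, "50M100N50M")),
    min_overhang = 5)
  expect_equal(short$support, 1L)

  # deletions merge into blocks and do not break junctions
  del <- extract_junctions(sim_reads(1001, "20M5D25M100N50M"))
  expect_equal(del$intron_start, 1051L)
})

test_that("junction support is invariant under read order permutation", {
  reads <- dplyr::bind_rows(
    sim_reads(rep(1001L, 10), "50M100N50M"),
    sim_reads(rep(2001L, 5), "40M200N60M"),
    sim_reads(rep(1501L, 7), "91M"))
  shuffled <- reads[withr::with_seed(42, sample(nrow(reads))), ]
  expect_equal(extract_junctions(reads), extract_junctions(shuffled))
})

test_that("gene coverage counts aligned blocks only and is additive", {
  span <- gene_row(start = 1000, end = 2000)
  expect_true(all(build_gene_coverage(sim_reads(integer()),
                                      span)$values == 0))

  one <- build_gene_coverage(sim_reads(1101, "100M"), span)
  expect_equal(sum(one$values), 100L)
  expect_equal(one$values[102:201], rep(1L, 100))
  expect_equal(one$values[1:101], rep(0L, 101))

  spliced <- build_gene_coverage(sim_reads(1101, "50M100N50M"), span)
  expect_equal(spliced$values[102:151], rep(1L, 50))
  expect_equal(spliced$values[152:251], rep(0L, 100))  # N span uncovered
  expect_equal(spliced$values[252:301], rep(1L, 50))

  both <- build_gene_coverage(
    dplyr::bind_rows(sim_reads(1101, "100M"), sim_reads(1101, "50M100N50M")),
    span)
  expect_equal(both$values, one$values + spliced$values)
})

test_that("BAM splitting partitions reads by population without loss", {
  reads <- sim_reads(seq(100, 1000, by = 100),
                     barcode = c(rep("BC1", 2), rep("BC2", 2), rep("BC3", 3),
                                 rep("BC4", 3)),
                     umi = sprintf("U%02d", 1:10))
  bam <- write_test_bam(reads, c(chr1 = 5000))
  dir <- withr::local_tempdir()
  pops <- tibble::tibble(barcode = c("BC1", "BC2", "BC3", "BC4"),
                         population = c("A", "A", "B", "B"))
  out <- split_bam_by_population(bam, pops, dir)
  expect_equal(out$n_records[out$population == "A"], 4)
  expect_equal(out$n_records[out$population == "B"], 6)
  expect_equal(sum(out$n_records), nrow(reads))
  a <- read_alignments(out$path[out$population == "A"])
  expect_setequal(unique(a$barcode), c("BC1", "BC2"))
  expect_true(file.exists(paste0(out$path[1], ".bai")))
})

test_that("splitting with an unpopulated label warns and writes an empty indexed BAM", {
  reads <- sim_reads(c(100, 200), barcode = "BC1", umi = c("U1", "U2"))
  bam <- write_test_bam(reads, c(chr1 = 5000))
  dir <- withr::local_tempdir()
  pops <- tibble::tibble(barcode = "BC1", population = "A")
  expect_warning(
    out <- split_bam_by_population(bam, pops, dir,
                                   labels = c("A", "B")),
    "no barcodes")
  expect_equal(out$n_records[out$population == "B"], 0)
  expect_true(file.exists(paste0(out$path[out$population == "B"], ".bai")))
})

test_that("coverage export bins means in bedGraph convention", {
  reads <- sim_reads(rep(1L, 3), "100M")
  bam <- write_test_bam(reads, c(chr1 = 100))
  bins <- export_coverage(bam, "chr1:1-100", binsize = 10)
  expect_equal(nrow(bins), 10L)
  expect_true(all(bins$value == 3))
  expect_equal(bins$start[1], 0)
  expect_equal(bins$end[1], 10)

  raw <- export_coverage(bam, "chr1:1-100", binsize = 1)
  track <- build_gene_coverage(read_alignments(bam),
                               gene_row(start = 1, end = 100))
  expect_equal(raw$value, as.numeric(track$values))

  empty <- export_coverage(bam, "chr1:1-100", binsize = 10,
                           densify = FALSE)
  expect_true(all(empty$value > 0))
  zeros <- sim_reads(integer())
  bam0 <- write_test_bam(zeros, c(chr1 = 100))
  dense <- export_coverage(bam0, "chr1:1-100", binsize = 10,
                           densify = TRUE)
  expect_equal(nrow(dense), 10L)
  expect_true(all(dense$value == 0))
  expect_equal(nrow(export_coverage(bam0, "chr1:1-100", binsize = 10)), 0L)
  expect_error(export_coverage(bam, "chr1:1-100", binsize = 0), "binsize")

  out <- file.path(withr::local_tempdir(), "cov.bedgraph")
  export_coverage(bam, "chr1:1-100", binsize = 10, out_path = out)
  expect_equal(nrow(readr::read_tsv(out, col_names = FALSE,
                                    show_col_types = FALSE)), 10L)
})
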