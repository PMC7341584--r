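test_that("junction filtering applies the dual support threshold", {
  jx <- tibble::tibble(chrom = "chr1",
                       intron_start = c(1000L, 2000L, 3000L),
                       intron_end = c(1500L, 2500L, 3500L),
                       strand = "+", support = c(49L, 60L, 120L))
  # max coverage 900: threshold max(50, 45) = 50
  expect_equal(nrow(filter_junctions(jx[1, ], 900)), 0L)
  # max coverage 2000: threshold max(50, 100) = 100
  kept <- filter_junctions(jx[2:3, ], 2000)
  expect_equal(kept$support, 120L)
})

test_that("coverage splits into across/within tracks that partition the gene", {
  gene <- gene_row(start = 1, end = 3000)
  reads <- dplyr::bind_rows(
    sim_reads(500, "91M"),                    # plain exonic
    sim_reads(951, "50M1000N41M"),            # spliced across the intron
    sim_reads(1300, "91M"))                   # wholly intronic
  jx <- extract_junctions(reads)
  expect_equal(jx$intron_start, 1001L)
  expect_equal(jx$intron_end, 2000L)

  tracks <- split_coverage_by_junctions(reads, jx, gene)
  expect_length(tracks$within, 1L)
  within <- tracks$within[[1]]
  expect_equal(sum(within$values), 91L)        # only the intronic read
  expect_true(all(within$positions >= 1001 & within$positions <= 2000))
  # across track has no positions inside the retained intron
  expect_false(any(tracks$across$positions >= 1001 &
                     tracks$across$positions <= 2000))
  # reads partition: total coverage mass is conserved across the tracks
  total <- build_gene_coverage(reads, gene)
  expect_equal(sum(tracks$across$values) + sum(within$values),
               sum(total$values))
  # and per-position: across values re-mapped match total outside the intron
  pos_map <- tracks$across$positions
  expect_equal(tracks$across$values, total$values[pos_map])

  # no junctions: across equals the full coverage
  none <- split_coverage_by_junctions(reads, jx[0, ], gene)
  expect_length(none$within, 0L)
  expect_equal(none$across$values, as.numeric(total$values))
})

test_that("gaussian fitting recovers noiseless model parameters", {
  vals <- gaussian_values(k = 500, mu = 300, sigma = 100, len = 600)
  fit <- fit_gaussian_peak(vals, which.max(vals))
  expect_true(fit$converged)
  expect_lt(abs(fit$k - 500) / 500, 1e-3)
  expect_lt(abs(fit$mu - 300) / 300, 1e-3)
  expect_lt(abs(fit$sigma - 100) / 100, 1e-3)
})

test_that("degenerate windows do not produce converged fits", {
  expect_false(fit_gaussian_peak(rep(0, 600), 1)$converged)
  flat <- rep(100, 600)
  expect_false(fit_gaussian_peak(flat, 1)$converged)
})

test_that("truncated windows at track edges remain fittable", {
  # peak apex 80 bp from the track start
  vals <- gaussian_values(k = 400, mu = 80, sigma = 60, len = 900)
  fit <- fit_gaussian_peak(vals, which.max(vals))
  expect_true(fit$converged)
  centre <- fit$window_start + fit$mu
  expect_lt(abs(centre - 81), 2)  # track index of the true apex
})

test_that("iterative calling finds both well-separated peaks, tallest first", {
  vals <- round(gaussian_values(1000, 1500, 100, 6000) +
                  gaussian_values(800, 4000, 120, 6000))
  reads <- coverage_reads(vals, origin = 1L)
  peaks <- call_peaks_for_gene(reads, gene_row(start = 1, end = 6000))
  expect_equal(nrow(peaks), 2L)
  expect_equal(peaks$rank, 1:2)
  expect_lt(abs(peaks$centre[1] - 1501), 5)   # height-1000 apex first
  expect_lt(abs(peaks$centre[2] - 4001), 5)
  expect_lt(abs(peaks$sigma[1] - 100), 3)
  # interval approximates centre +/- 3 sigma
  expect_lt(abs((peaks$end[1] - peaks$start[1]) - 6 * peaks$sigma[1]), 3)

  # determinism
  again <- call_peaks_for_gene(reads, gene_row(start = 1, end = 6000))
  expect_identical(peaks, again)
})

test_that("sub-threshold bumps stop the iteration (height rule)", {
  vals <- round(gaussian_values(3000, 2000, 100, 6000) +
                  gaussian_values(150, 4500, 80, 6000))
  reads <- coverage_reads(vals, origin = 1L)
  peaks <- call_peaks_for_gene(reads, gene_row(start = 1, end = 6000))
  # bump: height 150 < 200 and 150 <= 5% of 3000 -> never called
  expect_equal(nrow(peaks), 1L)
  expect_lt(abs(peaks$centre[1] - 2001), 5)
})

test_that("zero-coverage genes yield no peaks", {
  expect_equal(nrow(call_peaks_for_gene(sim_reads(integer()),
                                        gene_row(start = 1, end = 5000))),
               0L)
})

test_that("across-junction peaks never overlap a retained intron interior", {
  # gene with a 5-kb intron; exonic reads only; junction supplied externally
  gene <- gene_row(start = 1, end = 12000)
  jx <- tibble::tibble(chrom = "chr1", intron_start = 1001L,
                       intron_end = 6000L, strand = "+",
                       support = 10000L)
  ends <- withr::with_seed(7, as.integer(round(rnorm(20000, 8000, 90))))
  far <- sim_reads(ends - 90L, "91M")
  peaks <- call_peaks_for_gene(far, gene, junctions = jx)
  expect_gt(nrow(peaks), 0L)
  across <- peaks[peaks$junction_class == "across_junction", ]
  expect_false(any(across$start <= 5999 & across$end >= 1002))

  # apex close to the excision seam: the reported interval is clipped to
  # the contiguous segment containing the centre
  seam_ends <- withr::with_seed(8, as.integer(round(rnorm(20000, 6150, 80))))
  seam_ends <- seam_ends[seam_ends - 90L > 6000L]
  near <- sim_reads(seam_ends - 90L, "91M")
  peaks2 <- call_peaks_for_gene(near, gene, junctions = jx)
  across2 <- peaks2[peaks2$junction_class == "across_junction", ]
  expect_gt(nrow(across2), 0L)
  expect_false(any(across2$start <= 5999 & across2$end >= 1002))
  expect_lt(abs(across2$centre[1] - 6150), 25)
})

test_that("BED12 junction files parse to intronic spans", {
  path <- file.path(withr::local_tempdir(), "jx.bed")
  jx <- tibble::tibble(chrom = "chr1", intron_start = 1001L,
                       intron_end = 2000L, strand = "+", support = 77L)
  write_junction_bed(jx, path)
  back <- read_junction_bed(path)
  expect_equal(back$intron_start, 1001L)
  expect_equal(back$intron_end, 2000L)
  expect_equal(back$support, 77L)
})
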