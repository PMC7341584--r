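toy_matrix <- function(n_peaks = 4, cells = 12, seed = 5) {
  counts <- withr::with_seed(seed, {
    matrix(rpois(n_peaks * cells, 5), n_peaks, cells)
  })
  rownames(counts) <- paste0("g", rep(1:(n_peaks / 2), each = 2),
                             ":pk", rep(1:2, n_peaks / 2))
  colnames(counts) <- paste0("C", seq_len(cells))
  counts
}

test_that("pseudo-bulk profiles conserve population counts exactly", {
  counts <- toy_matrix()
  pops <- tibble::tibble(barcode = colnames(counts),
                         population = rep(c("A", "B"), each = 6))
  pb <- make_pseudobulk(counts, pops, n = 3, seed = 1)
  expect_equal(ncol(pb$counts), 6L)
  for (pop in c("A", "B")) {
    cells <- pops$barcode[pops$population == pop]
    expect_equal(
      unname(rowSums(pb$counts[, pb$population_labels == pop])),
      unname(rowSums(counts[, cells])))
  }
  # every cell assigned exactly once
  expect_setequal(pb$cell_assignment$barcode, colnames(counts))
  expect_equal(anyDuplicated(pb$cell_assignment$barcode), 0L)

  # n = 1 reduces to population column sums
  pb1 <- make_pseudobulk(counts, pops, n = 1, seed = 1)
  expect_equal(unname(pb1$counts[, 1]),
               unname(rowSums(counts[, pops$population == "A"])))
})

test_that("pseudo-bulk assignment is seed-reproducible and n is capped by cells", {
  counts <- toy_matrix()
  pops <- tibble::tibble(barcode = colnames(counts),
                         population = rep(c("A", "B"), each = 6))
  pb1 <- make_pseudobulk(counts, pops, n = 6, seed = 42)
  pb2 <- make_pseudobulk(counts, pops, n = 6, seed = 42)
  expect_identical(pb1$counts, pb2$counts)
  expect_identical(pb1$cell_assignment, pb2$cell_assignment)
  pb3 <- make_pseudobulk(counts, pops, n = 6, seed = 43)
  expect_false(identical(pb1$cell_assignment, pb3$cell_assignment))

  small <- pops[c(1:4, 7:12), ]
  expect_warning(pbs <- make_pseudobulk(counts[, small$barcode], small,
                                        n = 6, seed = 1),
                 "reducing n to 4")
  expect_equal(sum(pbs$population_labels == "A"), 4L)

  none <- tibble::tibble(barcode = "ZZZ", population = "A") |>
    dplyr::bind_rows(pops[7:12, ])
  expect_error(make_pseudobulk(counts, none, n = 2), "no cells")
})

test_that("shorth is the mean of the shortest half", {
  expect_equal(shorth(rep(3.5, 10)), 3.5)
  expect_equal(shorth(c(1, 1.1, 1.2, 5, 9)), 1.1)
  expect_error(shorth(numeric()), "finite")
  # symmetric unimodal: close to the median
  x <- withr::with_seed(1, rnorm(2000))
  expect_lt(abs(shorth(x) - median(x)), 0.12)
})

test_that("size factors recover depth ratios and are permutation invariant", {
  counts <- withr::with_seed(2, matrix(rpois(200 * 6, 100), 200, 6))
  rownames(counts) <- paste0("g", 1:200, ":pk1")
  expect_equal(unname(estimate_size_factors(cbind(counts[, 1], counts[, 1],
                                                  counts[, 1]))),
               rep(1, 3))
  deep <- withr::with_seed(4, matrix(rpois(500 * 6, 10000), 500, 6))
  rownames(deep) <- paste0("g", 1:500, ":pk1")
  doubled <- deep
  doubled[, 3] <- 2L * deep[, 3]
  sf <- estimate_size_factors(doubled)
  expect_lt(abs(sf[3] / mean(sf[-3]) - 2), 0.02)
  expect_lt(abs(exp(mean(log(sf))) - 1), 1e-10)  # geometric mean 1
  perm <- withr::with_seed(3, sample(nrow(doubled)))
  expect_equal(unname(estimate_size_factors(doubled[perm, ])),
               unname(estimate_size_factors(doubled)))
  zero <- counts
  zero[, 1] <- 0L
  expect_error(estimate_size_factors(zero), "positive")
})

test_that("null genes with matched usage are not flagged", {
  pb <- simulate_du_counts(20, prop_1 = c(0.5, 0.5), prop_2 = c(0.5, 0.5),
                           n_rep = 6, mean_count = 2000, seed = 4)
  du <- du_test(pb, feature_types = NULL)
  r <- tidy(du)
  expect_true(all(r$status == "tested"))
  expect_lt(max(abs(r$usage_lfc)), 0.5)
  expect_equal(sum(r$du), 0L)
})

test_that("a usage switch is detected with the right sign and magnitude", {
  pb <- simulate_du_counts(10, prop_1 = c(0.8, 0.2), prop_2 = c(0.2, 0.8),
                           n_rep = 6, mean_count = 1000, seed = 9)
  du <- du_test(pb, feature_types = NULL)
  r <- tidy(du)
  pk1 <- r[grepl(":pk1$", r$peak_id), ]
  expect_true(all(pk1$du))
  # truth: log2((0.2/0.8) / (0.8/0.2)) = -4
  expect_true(all(abs(pk1$usage_lfc + 4) < 1))
  expect_true(all(pk1$usage_lfc < 0))
  pk2 <- r[grepl(":pk2$", r$peak_id), ]
  expect_true(all(pk2$usage_lfc > 0))
  g <- dtu_genes(du)
  expect_true(all(g$dtu))
  expect_equal(glance(du)$n_dtu_genes, 10L)
})

test_that("swapping population labels flips the usage LFC and keeps p-values", {
  pb <- simulate_du_counts(8, prop_1 = c(0.7, 0.3), prop_2 = c(0.5, 0.5),
                           n_rep = 6, mean_count = 800, seed = 10)
  swapped <- as_pseudobulk(pb$counts,
                           ifelse(pb$population_labels == "A", "B", "A"))
  du_ab <- du_test(pb, feature_types = NULL, comparison = c("A", "B"))
  du_ba <- du_test(swapped, feature_types = NULL,
                   comparison = c("A", "B"))
  a <- tidy(du_ab); b <- tidy(du_ba)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-8)
  expect_equal(a$usage_lfc, -b$usage_lfc, tolerance = 1e-8)
})

test_that("filters route peaks away from testing with recorded statuses", {
  pb <- simulate_du_counts(3, prop_1 = c(0.5, 0.5), prop_2 = c(0.5, 0.5),
                           n_rep = 6, mean_count = 500, seed = 12)
  ann <- tibble::tibble(
    peak_id = rownames(pb$counts),
    gene_id = sub(":.*$", "", rownames(pb$counts)),
    primary_feature = c("UTR3", "UTR3", "intron", "UTR3", "UTR3", "UTR3"),
    a_rich_downstream = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  du <- du_test(pb, annotations = ann, feature_types = c("UTR3", "exon"),
                exclude_a_rich = TRUE)
  r <- tidy(du)
  expect_equal(r$status[r$peak_id == "g2:pk1"], "filtered_feature")
  expect_equal(r$status[r$peak_id == "g3:pk1"], "filtered_A_rich")
  # their partners now sit in single-peak genes
  expect_equal(r$status[r$peak_id == "g2:pk2"], "filtered_single_peak")
  expect_equal(r$status[r$peak_id == "g3:pk2"], "filtered_single_peak")
  expect_equal(sum(r$status == "tested"), 2L)
})

test_that("the single-cell detection-rate filter applies per population", {
  counts <- matrix(0L, 2, 40,
                   dimnames = list(c("g1:pk1", "g1:pk2"),
                                   paste0("C", 1:40)))
  counts[1, ] <- 1L                       # pk1 detected everywhere
  counts[2, 1:2] <- 1L                    # pk2 in 2/20 cells of pop A only
  pops <- tibble::tibble(barcode = colnames(counts),
                         population = rep(c("A", "B"), each = 20))
  pb <- make_pseudobulk(counts, pops, n = 2, seed = 1)
  m <- structure(list(counts = methods::as(Matrix::Matrix(counts,
                                                          sparse = TRUE),
                                           "generalMatrix"),
                      peak_ids = rownames(counts),
                      barcodes = colnames(counts)),
                 class = "peak_count_matrix")
  du <- du_test(pb, sc_counts = m, populations = pops,
                feature_types = NULL, detection_rate = 0.2)
  r <- tidy(du)
  expect_equal(r$status[r$peak_id == "g1:pk2"],
               "filtered_low_expression")
})
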