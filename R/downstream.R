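#' Rank 3'UTR peaks by proximity to the terminating exon
#'
#' For each differentially used 3'UTR peak, the peaks expressed on the
#' same transcript-level 3'UTR are ordered by strand-aware distance from
#' the start of the UTR (the end of the last coding exon) and assigned a
#' location score: 0 for the most proximal peak, 1 for the most distal,
#' evenly spaced in between (a UTR with a single peak scores 0).  When a
#' peak lies on several overlapping annotated 3'UTRs, the longest one is
#' used so that compared peaks share a UTR.
#'
#' @param du a `du_result` computed on 3'UTR peaks (run [du_test()] with
#'   `feature_types = "UTR3"` and `exclude_a_rich = TRUE`).
#' @param gene_models gene-model table with UTR3 rows
#'   ([read_gene_models()]).
#' @param annotations annotated peak table giving peak coordinates
#'   (`peak_id`, `chrom`, `start`, `end`, `strand`).
#' @return tibble with `peak_id`, `gene_id`, `utr_id`, `location_score`,
#'   `du_direction` (`up` / `down` / `untested`; up means higher usage in
#'   the second population of the comparison).
#' @export
utr_location_scores <- function(du, gene_models, annotations) {
  stopifnot(inherits(du, "du_result"))
  res <- du$results
  peaks <- annotations |>
    inner_join(res |> select(all_of(c("peak_id", "status", "du",
                                      "usage_lfc"))),
               by = "peak_id")
  utr3 <- gene_models |>
    filter(.data$type == "UTR3", !is.na(.data$transcript_id)) |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), strand = first(.data$strand),
              width = sum(.data$end - .data$start + 1),
              .groups = "drop")
  if (nrow(utr3) == 0L || nrow(peaks) == 0L) {
    return(tibble(peak_id = character(), gene_id = character(),
                  utr_id = character(), location_score = numeric(),
                  du_direction = character()))
  }
  peak_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start, peaks$end))
  utr_gr <- GenomicRanges::GRanges(
    utr3$chrom, IRanges::IRanges(utr3$start, utr3$end))
  hits <- GenomicRanges::findOverlaps(peak_gr, utr_gr)
  ov <- tibble(peak = S4Vectors::queryHits(hits),
               utr = S4Vectors::subjectHits(hits)) |>
    filter(peaks$gene_id[.data$peak] == utr3$gene_id[.data$utr])
  du_idx <- which(peaks$du)
  dropped <- setdiff(du_idx, unique(ov$peak))
  if (length(dropped) > 0L) {
    inform(paste0(length(dropped), " DU peak(s) not assignable to an ",
                  "annotated 3'UTR were excluded"))
  }
  # pick, per DU peak, the longest containing UTR; rank its peaks
  chosen_utrs <- ov |>
    filter(.data$peak %in% du_idx) |>
    mutate(w = utr3$width[.data$utr]) |>
    group_by(.data$peak) |>
    slice_max(.data$w, n = 1, with_ties = FALSE) |>
    ungroup() |>
    pull(.data$utr) |>
    unique()
  out <- map(chosen_utrs, function(u) {
    members <- ov$peak[ov$utr == u]
    p <- peaks[members, , drop = FALSE]
    centre <- (p$start + p$end) / 2
    dist <- if (utr3$strand[u] == "-") {
      utr3$end[u] - centre  # 5' end of a minus-strand UTR is its max coord
    } else {
      centre - utr3$start[u]
    }
    o <- order(dist)
    k <- length(o)
    score <- if (k == 1L) 0 else (seq_len(k) - 1) / (k - 1)
    tibble(
      peak_id = p$peak_id[o],
      gene_id = p$gene_id[o],
      utr_id = utr3$transcript_id[u],
      location_score = score,
      du_direction = dplyr::case_when(
        !p$du[o] ~ "untested",
        p$usage_lfc[o] > 0 ~ "up",
        TRUE ~ "down"))
  }) |> list_rbind()
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble(peak_id = character(), gene_id = character(),
                  utr_id = character(), location_score = numeric(),
                  du_direction = character()))
  }
  out
}

#' Test for 3'UTR shortening
#'
#' Compares the UTR location scores of upregulated versus downregulated
#' peaks with a two-sided Wilcoxon rank-sum test (normal approximation
#' with tie correction).  An excess of upregulated peaks proximal to the
#' terminating exon (low scores) indicates a shift toward shortened
#' 3'UTRs in the upregulated population.
#'
#' @param ranks tibble from [utr_location_scores()].
#' @param p_threshold reporting threshold for calling a direction.
#' @param comparison optional label carried into the result.
#' @return one-row tibble: `comparison`, `W`, `p_value`, `direction`
#'   (`shortening` / `lengthening` / `none`), `n_up`, `n_down`.
#' @export
test_utr_shortening <- function(ranks, p_threshold = 0.05,
                                comparison = NA_character_) {
  up <- ranks$location_score[ranks$du_direction == "up"]
  down <- ranks$location_score[ranks$du_direction == "down"]
  if (length(up) == 0L || length(down) == 0L) {
    return(tibble(comparison = comparison, W = NA_real_,
                  p_value = NA_real_, direction = "none",
                  n_up = length(up), n_down = length(down)))
  }
  wt <- suppressWarnings(
    wilcox.test(up, down, exact = FALSE, correct = FALSE))
  direction <- if (wt$p.value >= p_threshold) {
    "none"
  } else if (median(up) < median(down)) {
    "shortening"
  } else if (median(up) > median(down)) {
    "lengthening"
  } else "none"
  tibble(comparison = comparison, W = unname(wt$statistic),
         p_value = wt$p.value, direction = direction,
         n_up = length(up), n_down = length(down))
}

#' Per-cell library-size normalisation (counts-per-ten-thousand, log1p)
#'
#' @param counts peaks x cells matrix (sparse or dense).
#' @return matrix of `log1p(count / cell_total * 1e4)` values.
#' @export
normalize_cp10k <- function(counts) {
  totals <- Matrix::colSums(counts)
  totals[totals == 0] <- 1
  log1p(Matrix::t(Matrix::t(counts) / totals) * 1e4)
}

#' Relative peak expression within a gene
#'
#' Rescales per-cell peak expression by the peak's relative usage within
#' its gene and cluster, so usage differences remain visible when overall
#' gene expression varies: for a gene with n >= 2 peaks, within cluster c
#' of m cells, `G` is the mean expression over all n peaks and m cells,
#' `P_i = mean_j(x_ij) / G` is peak i's relative usage, and every value is
#' transformed as `R = log2(x / (G + v) * P + 1)`.  A cluster with `G = 0`
#' returns 0 for all its cells, and `x = 0` always maps to `R = 0`.
#'
#' @param m a `peak_count_matrix` (normalised internally with
#'   [normalize_cp10k()]) or an already-normalised peaks x cells matrix.
#' @param gene_id gene whose peaks are transformed (matched against the
#'   leading `gene:` component of the peak ids); `NULL` uses all rows.
#' @param clusters tibble with `barcode` and `cluster`.
#' @param v pseudo-count added to `G`.
#' @return a `relative_expression` tibble: `barcode`, `cluster`,
#'   `peak_id`, `x` (input expression), `relative_expression`.
#' @export
relative_peak_expression <- function(m, gene_id = NULL, clusters, v = 1) {
  x <- if (inherits(m, "peak_count_matrix")) {
    as.matrix(normalize_cp10k(m$counts))
  } else {
    as.matrix(m)
  }
  if (!is.null(gene_id)) {
    keep <- sub(":.*$", "", rownames(x)) == gene_id
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) < 2L) {
    abort("relative expression needs a gene with at least two peaks")
  }
  stopifnot(all(c("barcode", "cluster") %in% names(clusters)))
  out <- map(unique(clusters$cluster), function(cl) {
    cells <- intersect(clusters$barcode[clusters$cluster == cl],
                       colnames(x))
    if (length(cells) == 0L) return(NULL)
    xc <- x[, cells, drop = FALSE]
    G <- mean(xc)
    if (G == 0) {
      R <- xc * 0
    } else {
      P <- rowMeans(xc) / G
      R <- log2(xc / (G + v) * P + 1)
    }
    tibble(barcode = rep(cells, each = nrow(xc)),
           cluster = cl,
           peak_id = rep(rownames(xc), length(cells)),
           x = as.vector(xc),
           relative_expression = as.vector(R))
  }) |> list_rbind()
  class(out) <- c("relative_expression", class(out))
  out
}

#' Box plot of relative peak expression by cluster
#' @param object a `relative_expression` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot relative_expression
#' @export
autoplot.relative_expression <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$cluster),
                               y = .data$relative_expression,
                               fill = .data$peak_id)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = "cluster", y = "relative peak expression",
                  fill = "peak") +
    ggplot2::theme_minimal()
}
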