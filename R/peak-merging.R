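#' Coordinate similarity between two peaks
#'
#' The distance between two peaks of the same gene is the sum of the
#' absolute start and end differences divided by the width of the scoring
#' peak; the similarity is one minus that distance, clipped at zero.  A
#' score of 1 means identical coordinates; 0 means the coordinate
#' differences exceed the peak width.  The score is asymmetric when the two
#' widths differ (each peak scores the other against its own width).
#'
#' @param a_start,a_end coordinates of the scoring peak.
#' @param b_start,b_end coordinates of the other peak.
#' @return numeric similarity in `[0, 1]` (vectorised).
#' @export
peak_similarity <- function(a_start, a_end, b_start, b_end) {
  width <- a_end - a_start
  if (any(width <= 0)) abort("zero-width peak in similarity computation")
  pmax(0, 1 - (abs(b_start - a_start) + abs(b_end - a_end)) / width)
}

#' Match peaks between two datasets
#'
#' Within each gene, peaks are compared in both directions; a pair is
#' matched when one direction's similarity reaches `threshold` and the
#' other reaches the relaxed threshold `threshold * (1 - relax)`.  Each
#' peak is matched at most once, assigning best-scoring pairs first
#' (greedy).
#'
#' @param set_a,set_b peak tables (need `peak_id`, `gene_id`, `strand`,
#'   `start`, `end`).
#' @param threshold similarity threshold for the better direction.
#' @param relax allowed fractional deviation for the second direction.
#' @return tibble with `peak_a`, `peak_b`, `score_ab`, `score_ba`.
#' @export
match_peaks_pairwise <- function(set_a, set_b, threshold = 0.75,
                                 relax = 0.25) {
  empty <- tibble(peak_a = character(), peak_b = character(),
                  score_ab = numeric(), score_ba = numeric())
  genes <- intersect(unique(set_a$gene_id), unique(set_b$gene_id))
  if (length(genes) == 0L) return(empty)
  relaxed <- threshold * (1 - relax)
  pairs <- map(genes, function(g) {
    a <- set_a |> filter(.data$gene_id == g)
    b <- set_b |> filter(.data$gene_id == g)
    grid <- tidyr::expand_grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    grid <- grid |> filter(a$strand[.data$i] == b$strand[.data$j])
    if (nrow(grid) == 0L) return(NULL)
    grid |>
      mutate(
        peak_a = a$peak_id[.data$i], peak_b = b$peak_id[.data$j],
        score_ab = peak_similarity(a$start[.data$i], a$end[.data$i],
                                   b$start[.data$j], b$end[.data$j]),
        score_ba = peak_similarity(b$start[.data$j], b$end[.data$j],
                                   a$start[.data$i], a$end[.data$i])) |>
      filter((.data$score_ab >= threshold & .data$score_ba >= relaxed) |
               (.data$score_ba >= threshold & .data$score_ab >= relaxed))
  }) |> list_rbind()
  if (nrow(pairs) == 0L) return(empty)
  pairs <- pairs |>
    mutate(best = pmax(.data$score_ab, .data$score_ba)) |>
    arrange(desc(.data$best), .data$peak_a, .data$peak_b)
  used_a <- character(); used_b <- character(); keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (pairs$peak_a[i] %in% used_a || pairs$peak_b[i] %in% used_b) next
    keep[i] <- TRUE
    used_a <- c(used_a, pairs$peak_a[i])
    used_b <- c(used_b, pairs$peak_b[i])
  }
  pairs[keep, c("peak_a", "peak_b", "score_ab", "score_ba")]
}

#' Merge peak sets from multiple datasets
#'
#' Iterative pairwise merging in input order: matched peaks are collapsed
#' to the union of their start/end coordinates (so every source peak is
#' contained in its merged peak); unmatched peaks are carried through
#' unchanged.  A final pass sorts by coordinate and re-derives `peak_id`
#' from the merged coordinates.
#'
#' @param peak_sets a list of peak tables, or a single peak table (returned
#'   normalised but otherwise unchanged).
#' @param threshold,relax matching thresholds (see
#'   [match_peaks_pairwise()]).
#' @return merged peak tibble with `peak_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `n_datasets` and a `source_peak_ids` list-column of
#'   the contributing original peak ids.
#' @export
merge_peak_sets <- function(peak_sets, threshold = 0.75, relax = 0.25) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  stopifnot(length(peak_sets) >= 1L)
  norm <- function(p) {
    p |>
      select(all_of(c("peak_id", "gene_id", "chrom", "strand",
                      "start", "end"))) |>
      mutate(source_peak_ids = as.list(.data$peak_id))
  }
  merged <- norm(peak_sets[[1]])
  for (s in seq_along(peak_sets)[-1]) {
    nxt <- norm(peak_sets[[s]])
    m <- match_peaks_pairwise(merged, nxt, threshold, relax)
    mi <- match(m$peak_a, merged$peak_id)
    ni <- match(m$peak_b, nxt$peak_id)
    if (length(mi) > 0L) {
      merged$start[mi] <- pmin(merged$start[mi], nxt$start[ni])
      merged$end[mi] <- pmax(merged$end[mi], nxt$end[ni])
      merged$source_peak_ids[mi] <- map2(
        merged$source_peak_ids[mi], nxt$source_peak_ids[ni],
        ~ c(.x, .y))
    }
    unmatched <- if (length(ni) > 0L) nxt[-ni, , drop = FALSE] else nxt
    merged <- bind_rows(merged, unmatched)
  }
  merged |>
    arrange(.data$chrom, .data$gene_id, .data$start, .data$end) |>
    mutate(
      peak_id = peak_id_string(.data$gene_id, .data$chrom, .data$start,
                               .data$end, .data$strand),
      n_datasets = map_int(.data$source_peak_ids, length)) |>
    select(all_of(c("peak_id", "gene_id", "chrom", "strand", "start",
                    "end", "n_datasets", "source_peak_ids")))
}

#' Write / read a peak table as TSV
#'
#' The `source_peak_ids` list-column (merged peaks) is serialised as a
#' comma-separated string.
#'
#' @param peaks peak tibble.
#' @param path TSV path.
#' @return `write_peaks()` returns `path` invisibly; `read_peaks()` returns
#'   the peak tibble.
#' @export
write_peaks <- function(peaks, path) {
  if ("source_peak_ids" %in% names(peaks)) {
    peaks$source_peak_ids <- map_chr(peaks$source_peak_ids, paste,
                                     collapse = ",")
  }
  readr::write_tsv(peaks, path)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  peaks <- readr::read_tsv(path, show_col_types = FALSE)
  if ("source_peak_ids" %in% names(peaks)) {
    peaks$source_peak_ids <- strsplit(peaks$source_peak_ids, ",",
                                      fixed = TRUE)
  }
  peaks
}
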