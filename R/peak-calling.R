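#' Peak-calling configuration
#'
#' Thresholds and fitting constants for splice-aware peak discovery.
#' Junctions are retained when their read support reaches
#' `max(min_jcutoff, min_jcutoff_prop * max_coverage)`.  Iterative
#' fit-and-subtract stops when either (1) the unassigned gene coverage is at
#' or below both `min_cov_cutoff` and `min_cov_prop` of the gene total, or
#' (2) the current apex height is below `min_peak_cutoff` and at or below
#' `min_peak_prop` of the gene's maximum coverage.
#'
#' @param min_jcutoff absolute junction-support floor (reads).
#' @param min_jcutoff_prop junction-support floor as a fraction of the
#'   gene's maximum coverage.
#' @param min_cov_prop,min_cov_cutoff residual-coverage stopping thresholds
#'   (fraction of gene total; absolute coverage).
#' @param min_peak_cutoff,min_peak_prop apex-height stopping thresholds
#'   (absolute reads/bp; fraction of gene maximum).
#' @param fit_window width in bp of the window fitted at each iteration.
#' @param mu_init,sigma_init Gaussian initial values (bp).
#' @param sigma_bounds allowed sigma range during optimisation; converged
#'   fits pinned at a bound are rejected as degenerate.
#' @param max_iterations per-track safety valve.
#' @return a `fit_config` list.
#' @export
fit_config <- function(min_jcutoff = 50L, min_jcutoff_prop = 0.05,
                       min_cov_prop = 0.05, min_cov_cutoff = 500L,
                       min_peak_cutoff = 200L, min_peak_prop = 0.05,
                       fit_window = 600L, mu_init = 300, sigma_init = 100,
                       sigma_bounds = c(5, 350), max_iterations = 200L) {
  stopifnot(min_jcutoff >= 0, min_cov_cutoff >= 0, min_peak_cutoff >= 0,
            min_jcutoff_prop >= 0, min_jcutoff_prop <= 1,
            min_cov_prop >= 0, min_cov_prop <= 1,
            min_peak_prop >= 0, min_peak_prop <= 1,
            fit_window > 0, fit_window %% 2 == 0,
            length(sigma_bounds) == 2, sigma_bounds[1] > 0,
            sigma_bounds[2] > sigma_bounds[1], max_iterations >= 1)
  structure(list(
    min_jcutoff = min_jcutoff, min_jcutoff_prop = min_jcutoff_prop,
    min_cov_prop = min_cov_prop, min_cov_cutoff = min_cov_cutoff,
    min_peak_cutoff = min_peak_cutoff, min_peak_prop = min_peak_prop,
    fit_window = as.integer(fit_window), mu_init = mu_init,
    sigma_init = sigma_init, sigma_bounds = sigma_bounds,
    max_iterations = as.integer(max_iterations)
  ), class = "fit_config")
}

#' Filter junctions by read support
#'
#' Removes junctions supported by fewer reads than
#' `max(min_jcutoff, min_jcutoff_prop * max_coverage)`; the double criterion
#' keeps junction filtering stringent across genes with very different
#' depths.
#'
#' @param junctions junction table from [extract_junctions()].
#' @param max_coverage maximum per-base coverage of the gene.
#' @param config [fit_config()].
#' @return the retained junctions.
#' @export
filter_junctions <- function(junctions, max_coverage,
                             config = fit_config()) {
  thr <- max(config$min_jcutoff, config$min_jcutoff_prop * max_coverage)
  junctions |> filter(.data$support >= thr)
}

# a working track: integer values plus the genomic position of every index
new_peak_track <- function(values, positions, chrom, strand) {
  stopifnot(length(values) == length(positions))
  list(values = as.numeric(values), positions = as.integer(positions),
       chrom = chrom, strand = strand)
}

#' Split gene coverage into across- and within-junction tracks
#'
#' Reads aligning wholly inside a retained intronic span form that
#' junction's "within" track; all remaining reads form the "across" track,
#' from which the retained intronic spans are excised and the flanks
#' concatenated.  Each track keeps a map from track index back to genomic
#' position, so peak intervals can be re-projected after fitting.
#'
#' @param reads alignment table restricted to the gene.
#' @param junctions retained junction table (possibly empty).
#' @param gene_span list/row with `chrom`, `start`, `end`, `strand`.
#' @return list with elements `across` (one track) and `within` (list of
#'   tracks, one per retained junction, genomic order).
#' @export
split_coverage_by_junctions <- function(reads, junctions, gene_span) {
  span <- parse_region(gene_span)
  strand <- if (!is.null(gene_span$strand)) as.character(gene_span$strand[1]) else "*"
  if (is.null(junctions) || nrow(junctions) == 0L) {
    cov <- build_gene_coverage(reads, gene_span)
    return(list(
      across = new_peak_track(cov$values, span$start:span$end, span$chrom,
                              strand),
      within = list()))
  }
  jx <- junctions |>
    filter(.data$chrom == span$chrom,
           .data$intron_start <= span$end, .data$intron_end >= span$start) |>
    mutate(intron_start = pmax(.data$intron_start, span$start),
           intron_end = pmin(.data$intron_end, span$end)) |>
    arrange(.data$intron_start, .data$intron_end)
  if (nrow(jx) == 0L) {
    return(split_coverage_by_junctions(reads, NULL, gene_span))
  }
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  read_end <- reads$pos + ref_w - 1L
  # assign each fully-intronic read to the shortest containing junction
  within_of <- rep(NA_integer_, nrow(reads))
  jx_order <- order(jx$intron_end - jx$intron_start)
  for (j in jx_order) {
    inside <- is.na(within_of) & reads$pos >= jx$intron_start[j] &
      read_end <= jx$intron_end[j]
    within_of[inside] <- j
  }
  across_reads <- reads[is.na(within_of), , drop = FALSE]
  cov <- build_gene_coverage(across_reads, gene_span)
  positions <- span$start:span$end
  intronic <- rep(FALSE, length(positions))
  for (j in seq_len(nrow(jx))) {
    intronic[(jx$intron_start[j] - span$start + 1L):
               (jx$intron_end[j] - span$start + 1L)] <- TRUE
  }
  across <- new_peak_track(cov$values[!intronic], positions[!intronic],
                           span$chrom, strand)
  within <- map(seq_len(nrow(jx)), function(j) {
    jr <- reads[!is.na(within_of) & within_of == j, , drop = FALSE]
    jspan <- list(chrom = span$chrom, start = jx$intron_start[j],
                  end = jx$intron_end[j])
    jcov <- build_gene_coverage(jr, jspan)
    new_peak_track(jcov$values, jx$intron_start[j]:jx$intron_end[j],
                   span$chrom, strand)
  })
  list(across = across, within = within)
}

#' Fit a Gaussian to the coverage around an apex
#'
#' Extracts a `fit_window`-wide region centred on the apex (clipped at the
#' track bounds) and fits `y = k * exp(-0.5 * (x - mu)^2 / sigma^2)` by
#' non-linear least squares (bounded port algorithm).  `mu` is expressed in
#' window coordinates (0 at the window's first base), so the peak centre in
#' track coordinates is `window_start + mu`.
#'
#' @param values numeric coverage vector (track values).
#' @param apex index of the current coverage maximum in `values`.
#' @param config [fit_config()].
#' @return list with `k`, `mu`, `sigma`, `converged`, `window_start`,
#'   `window_end`.
#' @export
fit_gaussian_peak <- function(values, apex, config = fit_config()) {
  len <- length(values)
  half <- config$fit_window %/% 2L
  w_lo <- max(1L, apex - half)
  w_hi <- min(len, apex + half - 1L)
  y <- values[w_lo:w_hi]
  out <- list(k = NA_real_, mu = NA_real_, sigma = NA_real_,
              converged = FALSE, window_start = w_lo, window_end = w_hi)
  if (all(y == 0)) return(out)
  x <- seq_along(y) - 1
  mu0 <- if (w_lo == apex - half && w_hi == apex + half - 1L) {
    config$mu_init
  } else {
    apex - w_lo  # truncated window: start from the observed apex
  }
  fit <- tryCatch(
    nls(y ~ k * exp(-0.5 * (x - mu)^2 / sigma^2),
        start = list(k = max(y), mu = mu0, sigma = config$sigma_init),
        algorithm = "port",
        lower = c(k = 0, mu = -Inf, sigma = config$sigma_bounds[1]),
        upper = c(k = Inf, mu = Inf, sigma = config$sigma_bounds[2]),
        control = list(warnOnly = FALSE)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(out)
  p <- coef(fit)
  eps <- 1e-6
  if (p[["sigma"]] <= config$sigma_bounds[1] + eps ||
      p[["sigma"]] >= config$sigma_bounds[2] - eps || p[["k"]] <= 0) {
    return(out)
  }
  out$k <- unname(p[["k"]]); out$mu <- unname(p[["mu"]])
  out$sigma <- unname(p[["sigma"]]); out$converged <- TRUE
  out
}

# iterative fit-and-subtract over one track; `state` carries gene-level
# assigned coverage and the discovery rank
iterate_peaks_track <- function(track, junction_class, gene_id, gene_total,
                                gene_max, config, state) {
  vals <- track$values
  len <- length(vals)
  peaks <- list()
  if (len == 0L) return(peaks)
  for (it in seq_len(config$max_iterations)) {
    unassigned <- gene_total - state$assigned
    if (unassigned <= config$min_cov_cutoff &&
        unassigned <= config$min_cov_prop * gene_total) {
      state$stop_gene <- TRUE
      break
    }
    apex <- which.max(vals)
    h <- vals[apex]
    if (h <= 0) break
    if (h < config$min_peak_cutoff && h <= config$min_peak_prop * gene_max) {
      break
    }
    fit <- fit_gaussian_peak(vals, apex, config)
    if (!fit$converged) {
      # degenerate window: discard its signal and move on
      state$assigned <- state$assigned +
        sum(vals[fit$window_start:fit$window_end])
      vals[fit$window_start:fit$window_end] <- 0
      next
    }
    centre <- fit$window_start + fit$mu
    lo <- max(1L, as.integer(floor(centre - 3 * fit$sigma)))
    hi <- min(len, as.integer(ceiling(centre + 3 * fit$sigma)))
    if (hi < lo) {
      state$assigned <- state$assigned +
        sum(vals[fit$window_start:fit$window_end])
      vals[fit$window_start:fit$window_end] <- 0
      next
    }
    state$assigned <- state$assigned + sum(vals[lo:hi])
    vals[lo:hi] <- 0
    state$rank <- state$rank + 1L
    c0 <- pmin(pmax(as.integer(round(centre)), lo), hi)
    # clip the reported interval to the contiguous genomic segment that
    # contains the centre, so peaks never span an excised intron
    seg <- track$positions[lo:hi] - track$positions[c0]
    contiguous <- seg == (lo:hi) - c0
    seg_lo <- lo; seg_hi <- hi
    below <- which(!contiguous[seq_len(c0 - lo + 1L)])
    if (length(below) > 0L) seg_lo <- lo + max(below)
    above <- which(!contiguous[(c0 - lo + 1L):(hi - lo + 1L)])
    if (length(above) > 0L) seg_hi <- c0 + min(above) - 2L
    peaks[[length(peaks) + 1L]] <- tibble(
      gene_id = gene_id, chrom = track$chrom, strand = track$strand,
      start = track$positions[seg_lo], end = track$positions[seg_hi],
      centre = track$positions[c0],
      k = fit$k, mu = fit$mu, sigma = fit$sigma,
      junction_class = junction_class, rank = state$rank)
  }
  peaks
}

#' Call peaks for a single gene
#'
#' Splice-aware iterative Gaussian peak discovery: the gene's coverage is
#' split into an across-junction track (retained introns excised) and one
#' within-junction track per retained intron; each track is scanned by
#' repeated fit-and-subtract at the current coverage maximum until the
#' stopping rules fire.  Peak intervals span three fitted standard
#' deviations either side of the fitted centre, re-projected to genomic
#' coordinates and clipped to the gene span.
#'
#' @param reads alignment table covering the gene.
#' @param gene one row of [gene_spans()] (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param junctions optional pre-extracted junction table; extracted from
#'   `reads` when `NULL`.
#' @param config [fit_config()].
#' @return peak tibble (possibly empty) with columns `peak_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `centre`, `k`, `mu`, `sigma`,
#'   `junction_class`, `rank`, in discovery order.
#' @export
call_peaks_for_gene <- function(reads, gene, junctions = NULL,
                                config = fit_config()) {
  empty <- tibble(peak_id = character(), gene_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), centre = integer(), k = numeric(),
                  mu = numeric(), sigma = numeric(),
                  junction_class = character(), rank = integer())
  reads <- reads[reads$chrom == gene$chrom, , drop = FALSE]
  cov <- build_gene_coverage(reads, gene)
  gene_total <- sum(cov$values)
  if (gene_total == 0) return(empty)
  gene_max <- max(cov$values)
  if (is.null(junctions)) junctions <- extract_junctions(reads)
  junctions <- filter_junctions(junctions, gene_max, config)
  tracks <- split_coverage_by_junctions(reads, junctions, gene)
  state <- new.env(parent = emptyenv())
  state$assigned <- 0
  state$rank <- 0L
  state$stop_gene <- FALSE
  peaks <- iterate_peaks_track(tracks$across, "across_junction",
                               gene$gene_id, gene_total, gene_max, config,
                               state)
  for (tr in tracks$within) {
    if (state$stop_gene) break
    peaks <- c(peaks, iterate_peaks_track(tr, "within_junction",
                                          gene$gene_id, gene_total,
                                          gene_max, config, state))
  }
  if (length(peaks) == 0L) return(empty)
  list_rbind(peaks) |>
    mutate(peak_id = peak_id_string(.data$gene_id, .data$chrom,
                                    .data$start, .data$end, .data$strand)) |>
    select(all_of(names(empty)))
}

peak_id_string <- function(gene_id, chrom, start, end, strand) {
  paste0(gene_id, ":", chrom, ":", start, "-", end, ":", strand)
}

#' Call peaks across all genes of an annotation
#'
#' @param x a BAM path or an alignment table from [read_alignments()].
#' @param gene_models gene-model table ([read_gene_models()]).
#' @param junctions optional junction source: a junction table, or a path
#'   to a BED12 junction file ([read_junction_bed()]); when `NULL`,
#'   junctions are extracted from the alignments per gene.
#' @param config [fit_config()].
#' @param whitelist optional barcode whitelist applied while reading a BAM.
#' @param dataset_id optional label recorded in the `dataset_id` column.
#' @return peak tibble over all genes (columns as in
#'   [call_peaks_for_gene()] plus `dataset_id`).
#' @export
find_peaks <- function(x, gene_models, junctions = NULL,
                       config = fit_config(), whitelist = NULL,
                       dataset_id = NA_character_) {
  reads <- if (is.character(x)) {
    read_alignments(x, whitelist = whitelist)
  } else x
  if (is.character(junctions)) junctions <- read_junction_bed(junctions)
  spans <- gene_spans(gene_models)
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  read_gr <- GenomicRanges::GRanges(
    reads$chrom, IRanges::IRanges(reads$pos, reads$pos + ref_w - 1L))
  gene_gr <- GenomicRanges::GRanges(
    spans$chrom, IRanges::IRanges(spans$start, spans$end))
  hits <- GenomicRanges::findOverlaps(read_gr, gene_gr)
  by_gene <- split(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  peaks <- map(seq_len(nrow(spans)), function(g) {
    idx <- by_gene[[as.character(g)]]
    if (is.null(idx)) return(NULL)
    call_peaks_for_gene(reads[idx, , drop = FALSE], spans[g, ],
                        junctions = junctions, config = config)
  }) |> list_rbind()
  if (nrow(peaks) == 0L) {
    peaks <- call_peaks_for_gene(reads[0, ], spans[1, ])  # empty template
  }
  peaks |> mutate(dataset_id = dataset_id)
}

#' Read a BED12 junction file (regtools-style)
#'
#' Each record's two blocks flank one intron; the junction is the gap
#' between them and `score` is taken as the supporting read count.
#'
#' @param path BED12 file.
#' @return junction tibble as from [extract_junctions()].
#' @export
read_junction_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = "c"),
                         show_col_types = FALSE)
  if (ncol(bed) < 12L) abort("expected a 12-column BED junction file")
  sizes <- strsplit(as.character(bed[[11]]), ",")
  starts <- strsplit(as.character(bed[[12]]), ",")
  map(seq_len(nrow(bed)), function(i) {
    sz <- as.integer(sizes[[i]]); st <- as.integer(starts[[i]])
    k <- min(length(sz), length(st))
    if (k < 2L) return(NULL)
    tibble(
      chrom = as.character(bed[[1]][i]),
      intron_start = as.integer(bed[[2]][i]) + st[1:(k - 1)] +
        sz[1:(k - 1)] + 1L,
      intron_end = as.integer(bed[[2]][i]) + st[2:k],
      strand = as.character(bed[[6]][i]),
      support = as.integer(bed[[5]][i]))
  }) |> list_rbind()
}
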