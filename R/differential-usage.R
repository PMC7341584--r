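#' Build pseudo-bulk replicate profiles from single cells
#'
#' Cells of each population are shuffled (seeded) and dealt round-robin
#' into `n` groups; each group's peak counts are summed into one
#' pseudo-bulk column.  Pseudo-bulk replicates make the peak counts
#' amenable to count-model testing with a handful of columns instead of
#' thousands of sparse cells.  If a population has fewer than `n` cells,
#' `n` is reduced to the cell count with a warning.
#'
#' @param m a `peak_count_matrix` (from [count_umis()]) or a sparse/dense
#'   counts matrix with barcode column names.
#' @param populations tibble with columns `barcode`, `population`
#'   (exactly two population labels, disjoint barcodes).
#' @param n pseudo-bulk replicates per population.
#' @param seed integer seed for the random cell assignment.
#' @return a `pseudobulk` object: `counts` (peaks x columns), per-column
#'   `population_labels` / `replicate_labels`, the `cell_assignment`
#'   tibble, and the `seed`.
#' @export
make_pseudobulk <- function(m, populations, n = 6L, seed = 1L) {
  counts <- if (inherits(m, "peak_count_matrix")) m$counts else m
  stopifnot(all(c("barcode", "population") %in% names(populations)))
  if (anyDuplicated(populations$barcode)) {
    abort("barcodes assigned to more than one population")
  }
  pops <- unique(populations$population)
  if (length(pops) != 2L) abort("exactly two populations are required")
  cols <- list(); assignment <- list()
  for (pi in seq_along(pops)) {
    pop <- pops[pi]
    cells <- intersect(populations$barcode[populations$population == pop],
                       colnames(counts))
    if (length(cells) == 0L) {
      abort(paste0("population '", pop, "' has no cells in the matrix"))
    }
    n_pop <- n
    if (length(cells) < n) {
      n_pop <- length(cells)
      warn(paste0("population '", pop, "' has ", length(cells),
                  " cells; reducing n to ", n_pop))
    }
    cells <- withr::with_seed(derive_seed(seed, pi), sample(cells))
    grp <- rep_len(seq_len(n_pop), length(cells))
    for (g in seq_len(n_pop)) {
      sub <- counts[, cells[grp == g], drop = FALSE]
      cols[[length(cols) + 1L]] <- list(
        pop = pop, rep = g, counts = Matrix::rowSums(sub))
    }
    assignment[[pi]] <- tibble(barcode = cells, population = pop,
                               replicate = grp)
  }
  mat <- do.call(cbind, map(cols, "counts"))
  colnames(mat) <- map_chr(cols, ~ paste0(.x$pop, "_rep", .x$rep))
  structure(list(
    counts = mat,
    population_labels = map_chr(cols, "pop"),
    replicate_labels = map_int(cols, "rep"),
    cell_assignment = list_rbind(assignment),
    seed = seed
  ), class = "pseudobulk")
}

#' Wrap an existing counts matrix as pseudo-bulk profiles
#'
#' Constructor used when replicate-level counts are produced directly
#' (e.g. by a simulation) rather than by aggregating single cells.
#'
#' @param counts peaks x columns matrix.
#' @param population_labels population label per column.
#' @param seed seed recorded in the object metadata.
#' @return a `pseudobulk` object.
#' @export
as_pseudobulk <- function(counts, population_labels, seed = NA_integer_) {
  stopifnot(ncol(counts) == length(population_labels))
  reps <- stats::ave(seq_along(population_labels), population_labels,
                     FUN = seq_along)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0(population_labels, "_rep", reps)
  }
  structure(list(counts = as.matrix(counts),
                 population_labels = population_labels,
                 replicate_labels = as.integer(reps),
                 cell_assignment = NULL, seed = seed),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat("<pseudobulk> ", nrow(x$counts), " peaks x ", ncol(x$counts),
      " profiles (", paste(unique(x$population_labels), collapse = " vs "),
      ")\n", sep = "")
  invisible(x)
}

#' Median-of-ratios size factors with the shorth estimator
#'
#' For each column, the per-peak ratios of count to the peak's geometric
#' mean across columns are summarised with [shorth()] (better behaved than
#' the median for low, discrete counts); only peaks with all-positive
#' counts enter.  Factors are rescaled to geometric mean 1.
#'
#' @param pb a `pseudobulk` object or a counts matrix.
#' @return positive numeric vector, one factor per column.
#' @export
estimate_size_factors <- function(pb) {
  counts <- if (inherits(pb, "pseudobulk")) pb$counts else as.matrix(pb)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    abort("no peak has positive counts in every column; filter peaks first")
  }
  mat <- counts[pos, , drop = FALSE]
  log_geo <- rowMeans(log(mat))
  sf <- apply(mat, 2, function(col) shorth(exp(log(col) - log_geo)))
  sf <- sf / geometric_mean(sf)
  setNames(sf, colnames(counts))
}

# --- negative-binomial GLM machinery (log link, fixed dispersion) -------

nb_loglik <- function(y, mu, alpha) {
  if (alpha < 1e-8) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

fit_nb_glm <- function(y, X, offset, alpha) {
  fam <- if (alpha < 1e-8) {
    stats::poisson(link = "log")
  } else {
    MASS::negative.binomial(theta = 1 / alpha, link = "log")
  }
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = fam, offset = offset,
                                    control = list(maxit = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  fit
}

# Cox-Reid adjusted profile log-likelihood of the dispersion alpha
cr_profile_loglik <- function(alpha, y, X, offset) {
  fit <- fit_nb_glm(y, X, offset, alpha)
  if (is.null(fit)) return(-Inf)
  mu <- fit$fitted.values
  w <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X * sqrt(pmax(w, 1e-12)))
  ld <- determinant(xtwx, logarithm = TRUE)$modulus
  nb_loglik(y, mu, alpha) - 0.5 * as.numeric(ld)
}

# per-peak Cox-Reid dispersion on the full model, floored at `floor`
estimate_dispersion_cr <- function(y, X, offset, floor = 1e-6) {
  opt <- tryCatch(
    optimize(function(la) cr_profile_loglik(exp(la), y, X, offset),
             interval = c(log(floor), log(10)), maximum = TRUE),
    error = function(e) NULL)
  if (is.null(opt)) return(floor)
  max(floor, exp(opt$maximum))
}

# simple gene-wise moment dispersion (fallback for very few replicates)
moment_dispersion <- function(counts, sf, floor = 1e-6) {
  norm <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  a <- (v - mu) / mu^2
  max(floor, median(a[is.finite(a)], na.rm = TRUE), na.rm = TRUE)
}

#' Differential peak-usage test between two cell populations
#'
#' For every peak of every multi-peak gene, counts are collapsed to two
#' bins per pseudo-bulk column — the peak itself and the sum of the gene's
#' other peaks — and a negative-binomial GLM with log link is fitted with
#' terms `column + bin + population:bin` and `log(size factor)` offsets.
#' A 1-df likelihood-ratio test of the interaction asks whether the peak's
#' share of its gene differs between the populations, independent of
#' overall gene expression.  Dispersion is estimated per peak by Cox-Reid
#' adjusted profile likelihood on the full model (floored at 1e-6; a
#' gene-wise moment fallback is used with fewer than 4 columns).
#'
#' Prior to testing, peaks can be filtered by annotated feature type
#' (default: 3'UTR and exon peaks), by the A-rich internal-priming flag,
#' and by single-cell detection rate (fraction of cells with a nonzero
#' count must reach `detection_rate` in at least one population).
#'
#' @param pb a `pseudobulk` object ([make_pseudobulk()] /
#'   [as_pseudobulk()]).
#' @param annotations optional annotated peak table ([annotate_peaks()]);
#'   enables the feature and A-rich filters and supplies `gene_id`.
#' @param size_factors optional; computed with [estimate_size_factors()]
#'   when `NULL`.
#' @param sc_counts,populations optional single-cell `peak_count_matrix`
#'   and barcode-to-population tibble used for the detection-rate filter.
#' @param feature_types primary features retained (`NULL` disables).
#' @param exclude_a_rich drop peaks flagged `a_rich_downstream`.
#' @param detection_rate minimum single-cell detection fraction.
#' @param padj_cutoff,lfc_cutoff thresholds flagging a peak as
#'   differentially used.
#' @param comparison optional character vector `c(reference, target)`
#'   fixing the direction of `usage_lfc`; defaults to the order the
#'   population labels appear in the pseudo-bulk columns.
#' @return a `du_result` object; `tidy()` gives the per-peak table
#'   (`p_value`, `p_adj`, `usage_lfc` in log2, per-population mean
#'   normalised counts, `status`, `du` flag), `glance()` the run summary,
#'   and [dtu_genes()] the gene-level roll-up.
#' @export
du_test <- function(pb, annotations = NULL, size_factors = NULL,
                    sc_counts = NULL, populations = NULL,
                    feature_types = c("UTR3", "exon"),
                    exclude_a_rich = FALSE, detection_rate = 0.10,
                    padj_cutoff = 0.01, lfc_cutoff = 0.5,
                    comparison = NULL) {
  stopifnot(inherits(pb, "pseudobulk"))
  counts <- pb$counts
  pops <- comparison %||% unique(pb$population_labels)
  if (length(pops) != 2L ||
      !setequal(pops, unique(pb$population_labels))) {
    abort("du_test() needs exactly two populations")
  }
  if (min(table(pb$population_labels)) < 2L) {
    abort("at least two pseudo-bulk replicates per population are required")
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(pb)
  peak_ids <- rownames(counts)
  if (is.null(peak_ids)) abort("pseudo-bulk counts need peak_id rownames")
  gene_of <- if (!is.null(annotations)) {
    annotations$gene_id[match(peak_ids, annotations$peak_id)]
  } else {
    sub(":.*$", "", peak_ids)
  }
  status <- rep("tested", length(peak_ids))

  if (!is.null(annotations) && !is.null(feature_types)) {
    feat <- annotations$primary_feature[match(peak_ids,
                                              annotations$peak_id)]
    status[!(feat %in% feature_types)] <- "filtered_feature"
  }
  if (!is.null(annotations) && exclude_a_rich &&
      "a_rich_downstream" %in% names(annotations)) {
    ar <- annotations$a_rich_downstream[match(peak_ids,
                                              annotations$peak_id)]
    status[status == "tested" & !is.na(ar) & ar] <- "filtered_A_rich"
  }
  if (!is.null(sc_counts) && !is.null(populations)) {
    det <- detection_fraction(sc_counts, populations)
    det <- det[match(peak_ids, rownames(det)), , drop = FALSE]
    low <- apply(det, 1, max) < detection_rate
    status[status == "tested" & low] <- "filtered_low_expression"
  }
  testable <- status == "tested"
  multi <- table(gene_of[testable])
  single <- names(multi[multi < 2])
  status[testable & gene_of %in% single] <- "filtered_single_peak"

  df <- tibble(
    sample = factor(colnames(counts), levels = colnames(counts)),
    pop = factor(pb$population_labels, levels = pops))
  # symmetric +/- 0.5 population coding keeps the test exactly label-
  # symmetric; usage_lfc is reported for pops[2] relative to pops[1]
  pop_code <- if_else(df$pop == pops[2], 0.5, -0.5)
  offset_col <- log(size_factors)
  is_a <- pb$population_labels == pops[1]

  results <- map(which(status == "tested"), function(i) {
    this <- counts[i, ]
    others <- colSums(counts[gene_of == gene_of[i] &
                               rownames(counts) != peak_ids[i], ,
                             drop = FALSE])
    y <- c(others, this)
    bin_this <- rep(c(0, 1), each = ncol(counts))
    sample_f <- factor(rep(colnames(counts), 2),
                       levels = colnames(counts))
    X_null <- cbind(model.matrix(~ sample_f), bin = bin_this)
    X_full <- cbind(X_null, itx = bin_this * rep(pop_code, 2))
    offs <- rep(offset_col, 2)
    alpha <- if (ncol(counts) < 4L) {
      moment_dispersion(counts[gene_of == gene_of[i], , drop = FALSE],
                        size_factors)
    } else {
      estimate_dispersion_cr(y, X_full, offs)
    }
    full <- fit_nb_glm(y, X_full, offs, alpha)
    null <- fit_nb_glm(y, X_null, offs, alpha)
    if (is.null(full) || is.null(null) || !full$converged ||
        !null$converged) {
      return(tibble(peak_id = peak_ids[i], gene_id = gene_of[i],
                    p_value = NA_real_, usage_lfc = NA_real_,
                    usage_lfc_simple = NA_real_,
                    mean_norm_1 = NA_real_, mean_norm_2 = NA_real_,
                    dispersion = alpha, status = "not_converged"))
    }
    lr <- 2 * (nb_loglik(y, full$fitted.values, alpha) -
                 nb_loglik(y, null$fitted.values, alpha))
    p <- pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    norm_this <- this / size_factors
    lfc_simple <- log2(((sum(this[!is_a]) + 1) / (sum(others[!is_a]) + 1)) /
                         ((sum(this[is_a]) + 1) / (sum(others[is_a]) + 1)))
    tibble(peak_id = peak_ids[i], gene_id = gene_of[i],
           p_value = p,
           usage_lfc = unname(coef(full)["itx"]) / log(2),
           usage_lfc_simple = lfc_simple,
           mean_norm_1 = mean(norm_this[is_a]),
           mean_norm_2 = mean(norm_this[!is_a]),
           dispersion = alpha, status = "tested")
  }) |> list_rbind()

  skipped <- tibble(peak_id = peak_ids[status != "tested"],
                    gene_id = gene_of[status != "tested"],
                    p_value = NA_real_, usage_lfc = NA_real_,
                    usage_lfc_simple = NA_real_,
                    mean_norm_1 = NA_real_, mean_norm_2 = NA_real_,
                    dispersion = NA_real_,
                    status = status[status != "tested"])
  results <- bind_rows(results, skipped)
  tested <- results$status == "tested"
  results$p_adj <- NA_real_
  results$p_adj[tested] <- p.adjust(results$p_value[tested], method = "BH")
  results$du <- tested & !is.na(results$p_adj) &
    results$p_adj < padj_cutoff & abs(results$usage_lfc) > lfc_cutoff
  results <- results[match(peak_ids, results$peak_id), ] |>
    select(all_of(c("peak_id", "gene_id", "p_value", "p_adj", "usage_lfc",
                    "usage_lfc_simple", "mean_norm_1", "mean_norm_2",
                    "dispersion", "status", "du")))
  structure(list(
    results = results,
    populations = pops,
    size_factors = size_factors,
    params = list(feature_types = feature_types,
                  exclude_a_rich = exclude_a_rich,
                  detection_rate = detection_rate,
                  padj_cutoff = padj_cutoff, lfc_cutoff = lfc_cutoff,
                  seed = pb$seed)
  ), class = "du_result")
}

# fraction of cells with a nonzero count, per peak per population
detection_fraction <- function(sc_counts, populations) {
  counts <- if (inherits(sc_counts, "peak_count_matrix")) {
    sc_counts$counts
  } else sc_counts
  pops <- unique(populations$population)
  out <- sapply(pops, function(pop) {
    cells <- intersect(populations$barcode[populations$population == pop],
                       colnames(counts))
    if (length(cells) == 0L) return(rep(0, nrow(counts)))
    Matrix::rowSums(counts[, cells, drop = FALSE] > 0) / length(cells)
  })
  rownames(out) <- rownames(counts)
  out
}

#' Gene-level differential-transcript-usage roll-up
#'
#' A gene is called DTU when it carries at least one differentially used
#' peak.
#'
#' @param du a `du_result` from [du_test()].
#' @return tibble per tested gene: `gene_id`, `n_peaks_tested`,
#'   `n_du_peaks`, `min_p_adj`, `dtu`.
#' @export
dtu_genes <- function(du) {
  stopifnot(inherits(du, "du_result"))
  du$results |>
    filter(.data$status == "tested") |>
    group_by(.data$gene_id) |>
    summarise(n_peaks_tested = n(),
              n_du_peaks = sum(.data$du),
              min_p_adj = suppressWarnings(min(.data$p_adj, na.rm = TRUE)),
              .groups = "drop") |>
    mutate(dtu = .data$n_du_peaks > 0)
}

#' @export
print.du_result <- function(x, ...) {
  r <- x$results
  cat("<du_result> ", x$populations[2], " vs ", x$populations[1], ": ",
      sum(r$status == "tested"), " peaks tested, ", sum(r$du),
      " differentially used\n", sep = "")
  invisible(x)
}

#' Tidy a differential-usage result
#' @param x a `du_result`.
#' @param ... unused.
#' @return the per-peak results tibble.
#' @method tidy du_result
#' @export
tidy.du_result <- function(x, ...) x$results

#' One-row summary of a differential-usage run
#' @param x a `du_result`.
#' @param ... unused.
#' @method glance du_result
#' @export
glance.du_result <- function(x, ...) {
  r <- x$results
  g <- dtu_genes(x)
  tibble(n_peaks = nrow(r),
         n_tested = sum(r$status == "tested"),
         n_du_peaks = sum(r$du),
         n_genes_tested = nrow(g),
         n_dtu_genes = sum(g$dtu))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano-style plot of a differential-usage result
#' @param object a `du_result`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot du_result
#' @export
autoplot.du_result <- function(object, ...) {
  d <- object$results |> filter(.data$status == "tested")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$usage_lfc,
                                  y = -log10(.data$p_adj),
                                  colour = .data$du)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "usage log2 fold-change",
                  y = "-log10 adjusted p",
                  colour = "differentially used") +
    ggplot2::theme_minimal()
}
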