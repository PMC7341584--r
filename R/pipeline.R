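#' Run the full peak-to-DTU pipeline on one dataset
#'
#' Convenience chain over the package's stages: peak calling
#' ([find_peaks()]), annotation ([annotate_peaks()]), UMI counting
#' ([count_umis()]), pseudo-bulk construction ([make_pseudobulk()]) and
#' differential-usage testing ([du_test()]).  Stage outputs are written to
#' `out_dir` together with a JSON metadata sidecar (package version,
#' parameters, seed, input checksums) so a run can be reproduced from its
#' sidecar alone.
#'
#' @param bam path to the tagged, indexed BAM.
#' @param gtf path to the annotation GTF.
#' @param fasta path to the genome FASTA.
#' @param whitelist path to the barcode whitelist (one barcode per line).
#' @param populations path to a barcode/population TSV, or a tibble.
#' @param out_dir output directory.
#' @param junctions optional junction BED path or junction table.
#' @param config [fit_config()].
#' @param n_pseudobulk pseudo-bulk replicates per population.
#' @param seed seed for the pseudo-bulk assignment.
#' @param ... further options passed to [du_test()].
#' @return list with `peaks`, `annotations`, `counts`, `pseudobulk`,
#'   `du` and the sidecar path.
#' @export
run_pipeline <- function(bam, gtf, fasta, whitelist, populations, out_dir,
                         junctions = NULL, config = fit_config(),
                         n_pseudobulk = 6L, seed = 1L, ...) {
  for (f in c(bam, gtf, fasta)) {
    if (!file.exists(f)) abort(paste0("input file not found: ", f))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wl <- read_whitelist(whitelist)
  pops <- if (is.character(populations)) {
    readr::read_tsv(populations, show_col_types = FALSE)
  } else populations
  models <- read_gene_models(gtf)
  reads <- read_alignments(bam, whitelist = wl)
  peaks <- find_peaks(reads, models, junctions = junctions,
                      config = config)
  write_peaks(peaks, file.path(out_dir, "peaks.tsv"))
  ann <- annotate_peaks(peaks, models, fasta,
                        out_path = file.path(out_dir,
                                             "peaks_annotated.tsv"))
  counts <- count_umis(reads, peaks, wl)
  write_count_matrix(counts, file.path(out_dir, "counts"))
  pb <- make_pseudobulk(counts, pops, n = n_pseudobulk, seed = seed)
  du <- du_test(pb, annotations = ann, sc_counts = counts,
                populations = pops, ...)
  readr::write_tsv(tidy(du), file.path(out_dir, "du_results.tsv"))
  readr::write_tsv(dtu_genes(du), file.path(out_dir, "dtu_genes.tsv"))
  sidecar <- file.path(out_dir, "run_metadata.json")
  meta <- list(
    package = "scpolya",
    version = as.character(utils::packageVersion("scpolya")),
    seed = seed, n_pseudobulk = n_pseudobulk,
    fit_config = unclass(config),
    du_params = du$params,
    inputs = list(bam = unname(tools::md5sum(bam)),
                  gtf = unname(tools::md5sum(gtf)),
                  fasta = unname(tools::md5sum(fasta))))
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE)
  list(peaks = peaks, annotations = ann, counts = counts, pseudobulk = pb,
       du = du, metadata = sidecar)
}

#' Coverage-with-fit plot for one gene
#'
#' Plots the gene's read coverage with the called peak intervals shaded,
#' a quick visual check of the iterative Gaussian fits.
#'
#' @param reads alignment table.
#' @param gene one row of [gene_spans()].
#' @param peaks peak table for the gene.
#' @return a ggplot.
#' @export
plot_gene_coverage <- function(reads, gene, peaks) {
  cov <- as_tibble(build_gene_coverage(reads, gene))
  pk <- peaks |> filter(.data$gene_id == gene$gene_id)
  ggplot2::ggplot(cov, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::geom_rect(
      data = pk, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = 0, ymax = Inf, fill = .data$junction_class),
      alpha = 0.25) +
    ggplot2::labs(title = gene$gene_id, x = "genomic position",
                  y = "coverage", fill = "peak class") +
    ggplot2::theme_minimal()
}
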