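#' Synthetic scenario configuration
#'
#' Describes a fully synthetic 3'-biased scRNA-seq experiment: gene
#' structures with true polyA-site peaks (and optional intronic
#' internal-priming decoys), two cell populations with per-population peak
#' usage, and fixed per-cell molecule counts.  Every random draw is
#' governed by `seed`, so the same configuration always produces
#' byte-identical truth tables.
#'
#' @param genes gene tibble: `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `intron_start`, `intron_end` (`NA` for unspliced genes),
#'   `utr3_boundary` (genomic 5' edge of the 3'UTR in transcription
#'   direction), and a `peaks` list-column of tibbles with `site`,
#'   `sigma`, `decoy`, and one `usage_<label>` column per population.
#' @param populations tibble with `label`, `n_cells`.
#' @param umis_per_cell exact number of molecules drawn per cell.
#' @param read_length read length in nt (10x v3-like default).
#' @param gene_allocation `"balanced"` deals molecules across genes in
#'   exactly equal numbers (shuffled); `"random"` samples genes uniformly.
#' @param seed integer master seed.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(genes = default_scenario_genes(),
                            populations = tibble(label = c("A", "B"),
                                                 n_cells = c(300L, 300L)),
                            umis_per_cell = 60L, read_length = 91L,
                            gene_allocation = c("balanced", "random"),
                            seed = 1L) {
  gene_allocation <- match.arg(gene_allocation)
  stopifnot(all(populations$n_cells >= 1L), umis_per_cell >= 1L,
            read_length >= 20L)
  for (i in seq_len(nrow(genes))) {
    pk <- genes$peaks[[i]]
    for (lab in populations$label) {
      u <- pk[[paste0("usage_", lab)]]
      if (is.null(u) || any(u < 0) ||
          abs(sum(u) - 1) > 1e-8) {
        abort(paste0("usage proportions for gene ", genes$gene_id[i],
                     ", population ", lab,
                     " must be non-negative and sum to 1"))
      }
    }
  }
  structure(list(genes = genes, populations = populations,
                 umis_per_cell = as.integer(umis_per_cell),
                 read_length = as.integer(read_length),
                 gene_allocation = gene_allocation,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Default synthetic gene set
#'
#' Six genes on one synthetic chromosome: a usage-switching two-peak gene,
#' stable multi-peak genes on both strands, and one intron-containing gene
#' with an intronic A-rich decoy peak.  Peak centres are spaced widely
#' enough (>= 1200 bp) that their 3-sigma intervals do not collide.
#'
#' @return gene tibble accepted by [scenario_config()].
#' @export
default_scenario_genes <- function() {
  pk <- function(site, sigma, decoy, uA, uB) {
    tibble(site = site, sigma = sigma, decoy = decoy,
           usage_A = uA, usage_B = uB)
  }
  tibble(
    gene_id = paste0("G", 1:6),
    chrom = "chrS",
    strand = c("+", "+", "-", "+", "-", "+"),
    start = c(1000L, 12000L, 23000L, 34000L, 45000L, 56000L),
    end = c(9000L, 20000L, 31000L, 42000L, 53000L, 70000L),
    intron_start = c(NA, NA, NA, NA, NA, 56301L),
    intron_end = c(NA, NA, NA, NA, NA, 61300L),
    utr3_boundary = c(4000L, 15000L, 28000L, 37000L, 50000L, 64000L),
    peaks = list(
      pk(c(5000L, 7200L), c(100, 90), c(FALSE, FALSE),
         c(0.8, 0.2), c(0.2, 0.8)),
      pk(c(16000L, 18500L), c(120, 80), c(FALSE, FALSE),
         c(0.5, 0.5), c(0.5, 0.5)),
      pk(c(25000L, 26600L), c(90, 110), c(FALSE, FALSE),
         c(0.6, 0.4), c(0.6, 0.4)),
      pk(c(38000L, 39500L, 41000L), c(80, 100, 70),
         c(FALSE, FALSE, FALSE),
         c(0.4, 0.3, 0.3), c(0.4, 0.3, 0.3)),
      pk(c(46500L, 48200L), c(100, 100), c(FALSE, FALSE),
         c(0.5, 0.5), c(0.5, 0.5)),
      pk(c(58800L, 61370L, 65500L, 67500L), c(80, 70, 90, 100),
         c(TRUE, FALSE, FALSE, FALSE),
         c(0.1, 0.3, 0.3, 0.3), c(0.1, 0.3, 0.3, 0.3))
    )
  )
}

# expected coverage mode of a peak: reads end at the sampled site and
# extend (read_length - 1) bases against transcription
truth_centre <- function(site, strand, read_length) {
  shift <- (read_length - 1) / 2
  site + ifelse(rep_len(strand, length(site)) == "-", shift, -shift)
}

#' Generate a synthetic scenario
#'
#' Draws every molecule (cell, UMI, gene, peak, genomic position) for the
#' configured experiment and returns the read table plus machine-readable
#' truth tables.  Reads end at the sampled polyA position and extend
#' `read_length` bases against the direction of transcription; reads
#' crossing an annotated intron are spliced (N CIGAR), while decoy
#' (internal-priming) molecules stay unspliced since they arise from
#' pre-mRNA.
#'
#' @param config a [scenario_config()].
#' @return an `apa_scenario`: list with `reads` (alignment-table columns
#'   plus `gene_id`, `peak_index` attribution), `barcodes`
#'   (barcode/population), `truth_peaks`, `truth_junctions`, and the
#'   `config`.
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  genes <- config$genes
  pops <- config$populations
  L <- config$read_length
  withr::with_seed(config$seed, {
    barcodes <- map(seq_len(nrow(pops)), function(p) {
      tibble(barcode = sprintf("BC%s%05d", pops$label[p],
                               seq_len(pops$n_cells[p])),
             population = pops$label[p])
    }) |> list_rbind()
    n_cells <- nrow(barcodes)
    n_mol <- n_cells * config$umis_per_cell
    cell_of <- rep(seq_len(n_cells), each = config$umis_per_cell)
    umi <- sprintf("U%05d", rep(seq_len(config$umis_per_cell), n_cells))
    gene_of <- if (config$gene_allocation == "balanced") {
      sample(rep_len(seq_len(nrow(genes)), n_mol))
    } else {
      sample.int(nrow(genes), n_mol, replace = TRUE)
    }
    pop_of <- barcodes$population[cell_of]
    peak_of <- integer(n_mol)
    for (g in seq_len(nrow(genes))) {
      pkt <- genes$peaks[[g]]
      for (lab in pops$label) {
        idx <- which(gene_of == g & pop_of == lab)
        if (length(idx) == 0L) next
        peak_of[idx] <- sample.int(nrow(pkt), length(idx), replace = TRUE,
                                   prob = pkt[[paste0("usage_", lab)]])
      }
    }
    site <- numeric(n_mol); sigma <- numeric(n_mol)
    decoy <- logical(n_mol)
    for (g in seq_len(nrow(genes))) {
      pkt <- genes$peaks[[g]]
      idx <- which(gene_of == g)
      site[idx] <- pkt$site[peak_of[idx]]
      sigma[idx] <- pkt$sigma[peak_of[idx]]
      decoy[idx] <- pkt$decoy[peak_of[idx]]
    }
    e <- as.integer(round(rnorm(n_mol, site, sigma)))
    strand <- genes$strand[gene_of]
    is_v <- genes$intron_start[gene_of]
    ie_v <- genes$intron_end[gene_of]
    has_intron <- !is.na(is_v)
    plus <- strand == "+"
    # default unspliced read
    pos <- ifelse(plus, e - L + 1L, e)
    cigar <- rep(paste0(L, "M"), n_mol)
    # splice plus-strand mRNA reads whose span crosses the intron
    spl_p <- which(plus & has_intron & !decoy & e > ie_v &
                     (e - L + 1L) <= ie_v & (e - ie_v) < L)
    if (length(spl_p) > 0L) {
      c1 <- e[spl_p] - ie_v[spl_p]
      pos[spl_p] <- is_v[spl_p] - (L - c1)
      cigar[spl_p] <- paste0(L - c1, "M",
                             ie_v[spl_p] - is_v[spl_p] + 1L, "N", c1, "M")
    }
    spl_m <- which(!plus & has_intron & !decoy & e < is_v &
                     (e + L - 1L) >= is_v & (is_v - e) < L)
    if (length(spl_m) > 0L) {
      c1 <- is_v[spl_m] - e[spl_m]
      cigar[spl_m] <- paste0(c1, "M",
                             ie_v[spl_m] - is_v[spl_m] + 1L, "N",
                             L - c1, "M")
    }
    pos <- pmax(pos, 1L)
    reads <- tibble(
      chrom = genes$chrom[gene_of], pos = as.integer(pos), cigar = cigar,
      strand = strand, barcode = barcodes$barcode[cell_of], umi = umi,
      gene_id = genes$gene_id[gene_of], peak_index = peak_of)
    truth_peaks <- map(seq_len(nrow(genes)), function(g) {
      pkt <- genes$peaks[[g]]
      tibble(
        gene_id = genes$gene_id[g], peak_index = seq_len(nrow(pkt)),
        chrom = genes$chrom[g], strand = genes$strand[g],
        site = pkt$site, sigma = pkt$sigma, decoy = pkt$decoy,
        centre = truth_centre(pkt$site, genes$strand[g], L)) |>
        bind_cols(pkt |> select(dplyr::starts_with("usage_")))
    }) |> list_rbind()
    attribution <- reads |> count(.data$gene_id, .data$peak_index,
                                  name = "n_reads")
    truth_peaks <- truth_peaks |>
      left_join(attribution, by = c("gene_id", "peak_index")) |>
      mutate(n_reads = dplyr::coalesce(.data$n_reads, 0L))
    truth_junctions <- genes |>
      filter(!is.na(.data$intron_start)) |>
      mutate(support = map_int(.data$gene_id, function(gid) {
        sum(grepl("N", reads$cigar[reads$gene_id == gid], fixed = TRUE))
      })) |>
      select(all_of(c("chrom", "intron_start", "intron_end", "strand",
                      "support")))
    structure(list(reads = reads, barcodes = barcodes,
                   truth_peaks = truth_peaks,
                   truth_junctions = truth_junctions, config = config),
              class = "apa_scenario")
  })
}

#' @export
print.apa_scenario <- function(x, ...) {
  cat("<apa_scenario> ", nrow(x$reads), " reads, ", nrow(x$barcodes),
      " cells, ", nrow(x$truth_peaks), " true peaks\n", sep = "")
  invisible(x)
}

# plant a motif into a character vector of single bases (in place)
plant_seq <- function(bases, at, motif) {
  motif <- strsplit(motif, "")[[1]]
  idx <- at + seq_along(motif) - 1L
  ok <- idx >= 1L & idx <= length(bases)
  bases[idx[ok]] <- motif[ok]
  bases
}

#' Write a scenario to standard fixture files
#'
#' Emits a sorted, indexed BAM (reads tagged CB/UB), a GTF with
#' gene/transcript/exon/CDS rows (3'UTRs derivable from the CDS extent),
#' a genome FASTA (+ .fai) with the canonical polyA motif planted
#' downstream of every true peak's expected interval end and an A-run at
#' every decoy, a barcode whitelist, a population table, a BED12 junction
#' file, and the truth tables.
#'
#' @param scenario an `apa_scenario` from [generate_scenario()].
#' @param out_dir output directory.
#' @return named list of the written file paths.
#' @export
write_fixture_files <- function(scenario, out_dir) {
  stopifnot(inherits(scenario, "apa_scenario"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- scenario$config
  genes <- config$genes
  L <- config$read_length

  # --- genome FASTA with planted sequence signals ---
  fa_path <- file.path(out_dir, "genome.fa")
  chroms <- unique(genes$chrom)
  glen <- setNames(integer(length(chroms)), chroms)
  for (ch in chroms) {
    glen[ch] <- max(genes$end[genes$chrom == ch]) + 500L
  }
  seqs <- withr::with_seed(derive_seed(config$seed, 11L), {
    lapply(chroms, function(ch) {
      sample(c("A", "C", "G", "T"), glen[ch], replace = TRUE)
    })
  })
  names(seqs) <- chroms
  for (i in seq_len(nrow(scenario$truth_peaks))) {
    p <- scenario$truth_peaks[i, ]
    sig_eff <- sqrt(p$sigma^2 + (L^2 - 1) / 12)
    if (p$strand == "+") {
      peak_end <- round(p$centre + 3 * sig_eff)
      if (p$decoy) {
        # long A stretch, as at genuine internal-priming loci; stays inside
        # the 200-nt scan window even when the fitted boundary shifts
        seqs[[p$chrom]] <- plant_seq(seqs[[p$chrom]], peak_end + 30L,
                                     strrep("A", 80))
      } else {
        for (off in c(25L, 75L, 125L)) {
          seqs[[p$chrom]] <- plant_seq(seqs[[p$chrom]], peak_end + off,
                                       "AATAAA")
        }
      }
    } else {
      peak_start <- round(p$centre - 3 * sig_eff)
      if (p$decoy) {
        seqs[[p$chrom]] <- plant_seq(seqs[[p$chrom]], peak_start - 109L,
                                     strrep("T", 80))
      } else {
        for (off in c(25L, 75L, 125L)) {
          seqs[[p$chrom]] <- plant_seq(seqs[[p$chrom]],
                                       peak_start - off - 5L, "TTTATT")
        }
      }
    }
  }
  dna <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(dna) <- chroms
  Biostrings::writeXStringSet(dna, fa_path)
  Rsamtools::indexFa(fa_path)

  # --- GTF ---
  gtf_path <- file.path(out_dir, "annotation.gtf")
  gtf_lines <- character()
  gtf_row <- function(chrom, feat, start, end, strand, gid, tid = NULL) {
    attr <- paste0("gene_id \"", gid, "\";",
                   if (!is.null(tid)) paste0(" transcript_id \"", tid,
                                             "\";") else "")
    paste(chrom, "synthetic", feat, start, end, ".", strand, ".", attr,
          sep = "\t")
  }
  for (g in seq_len(nrow(genes))) {
    gn <- genes[g, ]
    tid <- paste0(gn$gene_id, ".t1")
    exons <- if (is.na(gn$intron_start)) {
      tibble(start = gn$start, end = gn$end)
    } else {
      tibble(start = c(gn$start, gn$intron_end + 1L),
             end = c(gn$intron_start - 1L, gn$end))
    }
    cds_span <- if (gn$strand == "+") {
      c(gn$start + 50L, gn$utr3_boundary - 1L)
    } else {
      c(gn$utr3_boundary + 1L, gn$end - 50L)
    }
    cds <- exons |>
      mutate(start = pmax(.data$start, cds_span[1]),
             end = pmin(.data$end, cds_span[2])) |>
      filter(.data$start <= .data$end)
    gtf_lines <- c(
      gtf_lines,
      gtf_row(gn$chrom, "gene", gn$start, gn$end, gn$strand, gn$gene_id),
      gtf_row(gn$chrom, "transcript", gn$start, gn$end, gn$strand,
              gn$gene_id, tid),
      vapply(seq_len(nrow(exons)), function(i) {
        gtf_row(gn$chrom, "exon", exons$start[i], exons$end[i],
                gn$strand, gn$gene_id, tid)
      }, ""),
      vapply(seq_len(nrow(cds)), function(i) {
        gtf_row(gn$chrom, "CDS", cds$start[i], cds$end[i], gn$strand,
                gn$gene_id, tid)
      }, ""))
  }
  writeLines(gtf_lines, gtf_path)

  # --- BAM (via SAM text) ---
  sam_path <- file.path(out_dir, "reads.sam")
  reads <- scenario$reads
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", chroms, "\tLN:", glen[chroms]))
  body <- paste(
    paste0("r", seq_len(nrow(reads))),
    ifelse(reads$strand == "-", 16L, 0L),
    reads$chrom, reads$pos, 255L, reads$cigar, "*", 0L, 0L, "*", "*",
    paste0("CB:Z:", reads$barcode), paste0("UB:Z:", reads$umi),
    sep = "\t")
  writeLines(c(header, body), sam_path)
  bam_tmp <- Rsamtools::asBam(sam_path,
                              file.path(out_dir, "reads_unsorted"),
                              overwrite = TRUE, indexDestination = FALSE)
  bam_path <- Rsamtools::sortBam(bam_tmp, file.path(out_dir, "reads"))
  Rsamtools::indexBam(bam_path)
  unlink(c(sam_path, bam_tmp))

  # --- whitelist, populations, junctions, truth tables ---
  wl_path <- file.path(out_dir, "whitelist.tsv")
  writeLines(scenario$barcodes$barcode, wl_path)
  pop_path <- file.path(out_dir, "populations.tsv")
  readr::write_tsv(scenario$barcodes, pop_path)
  jx_path <- file.path(out_dir, "junctions.bed")
  write_junction_bed(scenario$truth_junctions, jx_path)
  truth_path <- file.path(out_dir, "truth_peaks.tsv")
  readr::write_tsv(scenario$truth_peaks, truth_path)
  list(bam = bam_path, gtf = gtf_path, fasta = fa_path,
       whitelist = wl_path, populations = pop_path, junctions = jx_path,
       truth_peaks = truth_path)
}

#' Write a junction table as BED12
#'
#' @param junctions junction tibble (`chrom`, `intron_start`,
#'   `intron_end`, `strand`, `support`).
#' @param path output path.
#' @param flank anchor block size either side of the intron.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(junctions, path, flank = 20L) {
  if (nrow(junctions) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  chrom_start <- junctions$intron_start - flank - 1L  # 0-based
  chrom_end <- junctions$intron_end + flank
  lines <- paste(
    junctions$chrom, chrom_start, chrom_end,
    paste0("JUNC", seq_len(nrow(junctions))),
    junctions$support, junctions$strand, chrom_start, chrom_end,
    "255,0,0", 2L,
    paste0(flank, ",", flank),
    paste0(0L, ",", junctions$intron_end - chrom_start),
    sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Twenty-gene benchmark scenario for peak recovery
#'
#' A fixed-layout truth set for measuring peak-calling precision and
#' recall: 20 genes with 2-4 true peaks each, sigma drawn from
#' [60, 150] bp, peak centres spaced >= 1300 bp; six genes carry a 5-kb
#' intron with an intronic internal-priming decoy peak whose junction is
#' supplied externally (as from a junction file), and strands alternate.
#' Reads are dealt so every gene receives exactly `reads_per_gene`
#' molecules.
#'
#' @param seed master seed.
#' @param n_genes number of genes.
#' @param reads_per_gene molecules per gene.
#' @return list with `scenario` (an `apa_scenario`), `junctions` (the
#'   external junction table) and `truth_peaks`.
#' @export
peak_benchmark_scenario <- function(seed = 1L, n_genes = 20L,
                                    reads_per_gene = 50000L) {
  spacing <- 16000L
  genes <- withr::with_seed(derive_seed(seed, 23L), {
    map(seq_len(n_genes), function(g) {
      s <- 1000L + (g - 1L) * spacing
      with_intron <- g > 14  # six intron genes
      strand <- if (with_intron) "+" else if (g %% 2 == 0) "-" else "+"
      k <- sample(2:4, 1)
      sig <- runif(k, 60, 150)
      if (!with_intron) {
        sites <- s + 2000L + (seq_len(k) - 1L) * 1300L +
          as.integer(round(runif(k, -80, 80)))
        tibble(
          gene_id = sprintf("BG%02d", g), chrom = "chrB",
          strand = strand, start = s, end = s + 8000L,
          intron_start = NA_integer_, intron_end = NA_integer_,
          utr3_boundary = if (strand == "+") s + 1500L else s + 6500L,
          peaks = list(tibble(
            site = sites, sigma = sig, decoy = FALSE,
            usage_A = rep(1 / k, k), usage_B = rep(1 / k, k))))
      } else {
        k <- min(k, 3L)
        sig <- sig[seq_len(k)]
        is_ <- s + 801L; ie_ <- s + 5800L
        # terminal-exon peaks, all clear of the junction (>= 1500 bp)
        exonic <- ie_ + 1500L + (seq_len(k) - 1L) * 1300L +
          as.integer(round(runif(k, -80, 80)))
        decoy_site <- as.integer((is_ + ie_) / 2)
        usage <- rep(0.9 / k, k)
        tibble(
          gene_id = sprintf("BG%02d", g), chrom = "chrB",
          strand = strand, start = s, end = s + 13000L,
          intron_start = is_, intron_end = ie_,
          utr3_boundary = if (strand == "+") ie_ + 700L else s + 13000L - 700L,
          peaks = list(tibble(
            site = c(exonic, decoy_site),
            sigma = c(sig, 80), decoy = c(rep(FALSE, k), TRUE),
            usage_A = c(usage, 0.1), usage_B = c(usage, 0.1))))
      }
    }) |> list_rbind()
  })
  n_cells <- 200L
  total <- n_genes * reads_per_gene
  upc <- as.integer(ceiling(total / n_cells))
  config <- scenario_config(
    genes = genes,
    populations = tibble(label = c("A", "B"),
                         n_cells = c(n_cells %/% 2L, n_cells %/% 2L)),
    umis_per_cell = upc, gene_allocation = "balanced", seed = seed)
  scenario <- generate_scenario(config)
  junctions <- genes |>
    filter(!is.na(.data$intron_start)) |>
    mutate(support = 1000000L) |>
    select(all_of(c("chrom", "intron_start", "intron_end", "strand",
                    "support")))
  list(scenario = scenario, junctions = junctions,
       truth_peaks = scenario$truth_peaks)
}

#' Simulate pseudo-bulk peak counts for differential-usage checks
#'
#' Generates replicate-level counts directly: per gene and pseudo-bulk
#' column, a negative-binomial gene total is split between the gene's
#' peaks according to the population's usage proportions.
#'
#' @param n_genes number of simulated genes.
#' @param prop_1,prop_2 peak usage proportions (one entry per peak) in
#'   populations 1 and 2; must each sum to 1.
#' @param n_rep pseudo-bulk replicates per population.
#' @param mean_count mean gene total per replicate (UMIs).
#' @param size negative-binomial size of the gene totals.
#' @param seed integer seed.
#' @return a `pseudobulk` object with peak ids `g<i>:pk<j>`.
#' @export
simulate_du_counts <- function(n_genes, prop_1 = c(0.5, 0.5),
                               prop_2 = prop_1, n_rep = 6L,
                               mean_count = 1000, size = 10, seed = 1L) {
  stopifnot(length(prop_1) == length(prop_2),
            abs(sum(prop_1) - 1) < 1e-8, abs(sum(prop_2) - 1) < 1e-8)
  k <- length(prop_1)
  n_col <- 2L * n_rep
  pop <- rep(c("A", "B"), each = n_rep)
  counts <- withr::with_seed(seed, {
    m <- matrix(0L, nrow = n_genes * k, ncol = n_col)
    for (g in seq_len(n_genes)) {
      for (j in seq_len(n_col)) {
        total <- rnbinom(1, mu = mean_count, size = size)
        pr <- if (pop[j] == "A") prop_1 else prop_2
        m[(g - 1L) * k + seq_len(k), j] <-
          as.integer(rmultinom(1, total, pr))
      }
    }
    m
  })
  rownames(counts) <- paste0("g", rep(seq_len(n_genes), each = k),
                             ":pk", rep(seq_len(k), n_genes))
  as_pseudobulk(counts, pop, seed = seed)
}

#' Match called peaks to a truth table and score recovery
#'
#' Greedy one-to-one matching of called peak centres to truth centres
#' within the same gene, closest pairs first, accepting matches within
#' `tolerance` bp.
#'
#' @param peaks called peak table (needs `gene_id`, `centre`).
#' @param truth truth table from a scenario (needs `gene_id`, `centre`).
#' @param tolerance maximum centre distance in bp.
#' @return list with `precision`, `recall`, `n_called`, `n_truth`, and
#'   the logical match vectors `called_matched`, `truth_matched`.
#' @export
peak_recovery_stats <- function(peaks, truth, tolerance = 50) {
  d <- abs(outer(peaks$centre, truth$centre, "-"))
  d[!outer(peaks$gene_id, truth$gene_id, "==")] <- Inf
  called_matched <- rep(FALSE, nrow(peaks))
  truth_matched <- rep(FALSE, nrow(truth))
  while (any(is.finite(d)) && min(d) <= tolerance) {
    i <- which(d == min(d), arr.ind = TRUE)[1, ]
    called_matched[i[1]] <- TRUE
    truth_matched[i[2]] <- TRUE
    d[i[1], ] <- Inf
    d[, i[2]] <- Inf
  }
  list(precision = mean(called_matched), recall = mean(truth_matched),
       n_called = nrow(peaks), n_truth = nrow(truth),
       called_matched = called_matched, truth_matched = truth_matched)
}
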