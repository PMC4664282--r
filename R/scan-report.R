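#' Founder haplotype means at a position
#'
#' Summarizes line-mean phenotypes by the founder haplotype confidently
#' assigned to each line at a position (see [hard_call()]). Founders with
#' fewer than `min_n` assigned lines are retained in the output but flagged
#' `reported = FALSE`, the conventional suppression rule for displaying
#' founder means.
#'
#' @param line_means Tibble with `line` and `mean` columns.
#' @param hard_calls Tibble `line`, `founder` (NA for unassigned lines), or
#'   a named character vector.
#' @param min_n Minimum assigned lines for a founder mean to be reported.
#' @return Tibble `founder`, `mean`, `sd`, `n`, `reported`.
#' @export
founder_effects <- function(line_means, hard_calls, min_n = 5) {
  if (!is.data.frame(hard_calls)) {
    hard_calls <- tibble(line = names(hard_calls), founder = unname(hard_calls))
  }
  dat <- dplyr::inner_join(line_means, hard_calls, by = "line") |>
    dplyr::filter(!is.na(.data$founder))
  if (nrow(dat) == 0) {
    warn("No line has a confident founder call at this position.")
    return(tibble(founder = character(), mean = numeric(), sd = numeric(),
      n = integer(), reported = logical()))
  }
  dat |>
    dplyr::group_by(.data$founder) |>
    dplyr::summarise(sd = sd(.data$mean), mean = mean(.data$mean),
      n = dplyr::n(), .groups = "drop") |>
    dplyr::select("founder", "mean", "sd", "n") |>
    dplyr::mutate(reported = .data$n >= min_n)
}

#' Intersection of two panels' QTL support intervals
#'
#' A QTL detected in two mapping panels localizes the shared causative
#' locus to the intersection of the two support intervals.
#'
#' @param peak_a,peak_b One-row tibbles (or lists) with `chrom`, `ci_lo_bp`,
#'   `ci_hi_bp` (as returned by [peaks_and_intervals()]).
#' @return One-row tibble `chrom`, `lo_bp`, `hi_bp`, `width_kb`, or `NULL`
#'   when the intervals are disjoint or on different chromosomes.
#' @export
cross_panel_overlap <- function(peak_a, peak_b) {
  if (!identical(as.character(peak_a$chrom), as.character(peak_b$chrom))) {
    return(NULL)
  }
  lo <- max(peak_a$ci_lo_bp, peak_b$ci_lo_bp)
  hi <- min(peak_a$ci_hi_bp, peak_b$ci_hi_bp)
  if (lo > hi) return(NULL)
  tibble(chrom = as.character(peak_a$chrom), lo_bp = lo, hi_bp = hi,
    width_kb = (hi - lo) / 1000)
}

#' Read a gene annotation into the tabular form used for gene counting
#'
#' Imports BED (0-based half-open, converted to 1-based inclusive) or GFF
#' (already 1-based inclusive) via \pkg{rtracklayer}. GFF inputs are
#' filtered to `type == "gene"`; a `gene_biotype`/`biotype` attribute, when
#' present, sets the `protein_coding` flag (otherwise all genes are assumed
#' protein-coding).
#'
#' @param path Annotation file (.bed, .gff/.gff3/.gtf).
#' @return Tibble `chrom`, `start`, `end`, `gene`, `protein_coding` with
#'   1-based inclusive coordinates.
#' @export
read_gene_annotation <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("Package 'rtracklayer' is required to read BED/GFF annotations.")
  }
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if ("type" %in% names(df) && any(df$type == "gene")) {
    df <- df[df$type == "gene", ]
  }
  bt <- df[["gene_biotype"]] %||% df[["biotype"]]
  tibble(
    chrom = as.character(df$seqnames),
    start = as.integer(df$start), end = as.integer(df$end),
    gene = df[["Name"]] %||% df[["name"]] %||% df[["gene_id"]] %||%
      df[["ID"]] %||% sprintf("gene_%05d", seq_len(nrow(df))),
    protein_coding = if (is.null(bt)) TRUE else bt == "protein_coding"
  )
}

#' Count protein-coding genes in an interval
#'
#' Genes overlapping the interval by at least 1 bp are counted, with
#' 1-based inclusive bounds on both sides (a gene starting exactly at the
#' interval end is counted).
#'
#' @param annotation Tibble `chrom`, `start`, `end`, `gene`,
#'   `protein_coding` (see [read_gene_annotation()]).
#' @param chrom Chromosome of the query interval.
#' @param lo_bp,hi_bp Closed interval bounds (bp).
#' @return List with `n` (count) and `genes` (the overlapping rows).
#' @export
count_genes <- function(annotation, chrom, lo_bp, hi_bp) {
  req <- c("chrom", "start", "end", "protein_coding")
  if (!all(req %in% names(annotation))) {
    abort("`annotation` needs columns chrom, start, end, protein_coding.")
  }
  bad <- which(annotation$end < annotation$start)
  if (length(bad)) abort(sprintf("Malformed annotation row %d: end < start.", bad[1]))
  hits <- annotation |>
    dplyr::filter(.data$protein_coding, .data$chrom == !!chrom,
      .data$start <= hi_bp, .data$end >= lo_bp)
  list(n = nrow(hits), genes = hits)
}

#' Summary table of mapped QTL
#'
#' Produces the conventional per-QTL accounting: LOD, support-interval
#' bounds on both scales, interval width, protein-coding gene count
#' (when an annotation is supplied or a `n_genes` column is present), the
#' fraction of line-mean variance explained, and that fraction as a percent
#' of the broad-sense heritability of line means. Under the assumption that
#' QTL are independent and additive, the summed percents estimate the total
#' share of heritability the mapped loci account for.
#'
#' @param peaks Peak tibble from [peaks_and_intervals()] (optionally with a
#'   pre-tabulated `n_genes` column).
#' @param h2_mean Broad-sense heritability of line means, in (0, 1].
#' @param n Number of lines used in the scan.
#' @param annotation Optional annotation tibble for gene counting.
#' @return A tibble of class `qtl_report`, one row per QTL, with attribute
#'   `"total_pct_h2"`; see also [glance.qtl_report()].
#' @export
qtl_report <- function(peaks, h2_mean, n, annotation = NULL) {
  if (nrow(peaks) == 0) {
    out <- tibble(chrom = character(), peak_cm = numeric(),
      peak_bp = numeric(), lod = numeric(), ci_lo_bp = numeric(),
      ci_hi_bp = numeric(), width_kb = numeric(), n_genes = integer(),
      varexp = numeric(), pct_h2 = numeric())
    return(structure(out, class = c("qtl_report", class(tibble())),
      total_pct_h2 = 0, h2_mean = h2_mean, n = n))
  }
  ve <- variance_explained_pct(peaks$lod, n, h2_mean)
  out <- peaks |>
    dplyr::mutate(
      width_kb = (.data$ci_hi_bp - .data$ci_lo_bp) / 1000,
      varexp = ve$varexp, pct_h2 = ve$pct_h2
    )
  if (!is.null(annotation)) {
    out$n_genes <- vapply(seq_len(nrow(out)), function(i) {
      count_genes(annotation, out$chrom[i], out$ci_lo_bp[i], out$ci_hi_bp[i])$n
    }, integer(1))
  }
  structure(out, class = c("qtl_report", class(tibble())),
    total_pct_h2 = sum(out$pct_h2), h2_mean = h2_mean, n = n)
}

#' One-row summary of a QTL report
#'
#' @param x A `qtl_report`.
#' @param ... Unused.
#' @return Tibble: number of QTL, summed percent of heritability, and the
#'   mean/range of interval widths and gene counts.
#' @export
#' @method glance qtl_report
glance.qtl_report <- function(x, ...) {
  tibble(
    n_qtl = nrow(x),
    total_pct_h2 = attr(x, "total_pct_h2"),
    mean_width_kb = if (nrow(x)) mean(x$width_kb) else NA_real_,
    min_width_kb = if (nrow(x)) min(x$width_kb) else NA_real_,
    mean_n_genes = if (nrow(x) && "n_genes" %in% names(x)) mean(x$n_genes) else NA_real_,
    min_n_genes = if (nrow(x) && "n_genes" %in% names(x)) min(x$n_genes) else NA_real_,
    max_n_genes = if (nrow(x) && "n_genes" %in% names(x)) max(x$n_genes) else NA_real_
  )
}

#' Write a genome scan in the standard per-position TSV layout
#'
#' Columns: `Chromosome`, `PhysicalPosition`, `GeneticPosition`,
#' `LODscore`, `VarianceExplained`.
#'
#' @param scan A `qtl_scan` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  readr::write_tsv(
    tibble(
      Chromosome = scan$chrom,
      PhysicalPosition = round(scan$bp),
      GeneticPosition = scan$cm,
      LODscore = scan$lod,
      VarianceExplained = scan$varexp
    ),
    path
  )
  invisible(path)
}
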