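# Strand-aware promoter windows and promoter/genic/intergenic peak
# classification. The promoter is anchored at the TSS: tx_start for + strand
# genes, tx_end for - strand genes.

#' Strand-aware promoter windows around transcription start sites
#'
#' For a `+` strand gene the window is `[tx_start - upstream,
#' tx_start + downstream)`; for a `-` strand gene it is the mirror
#' `[tx_end - downstream, tx_end + upstream)`. Windows are clipped to
#' chromosome bounds; windows clipped to zero width are dropped and counted
#' in the `n_dropped` attribute.
#'
#' @param genes Gene-model tibble (see [read_gene_models()]).
#' @param upstream,downstream Window extent in bp on either side of the TSS,
#'   in the gene's own orientation. Both >= 0, not both 0. Default
#'   -1000/+500, a common promoter convention.
#' @param chrom_sizes chrom.sizes tibble; genes on chromosomes absent from it
#'   are an error.
#' @return Tibble with `chrom`, `start`, `end`, `gene_id`, `strand`.
#' @examples
#' genes <- tibble::tibble(chrom = "chrA", start = 10000, end = 20000,
#'                         gene_id = "g1", score = 0, strand = "+")
#' sizes <- tibble::tibble(chrom = "chrA", size = 1e6)
#' promoter_regions(genes, 1000, 500, sizes)  # [9000, 10500)
#' @export
promoter_regions <- function(genes, upstream = 1000, downstream = 500,
                             chrom_sizes) {
  genes <- validate_genes(genes)
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  upstream <- pc_stopifnot_scalar_count(upstream, "upstream")
  downstream <- pc_stopifnot_scalar_count(downstream, "downstream")
  if (upstream == 0L && downstream == 0L) {
    pc_abort("`upstream` and `downstream` must not both be 0.",
             class = "peakcoloc_usage_error")
  }
  unknown <- setdiff(unique(genes$chrom), chrom_sizes$chrom)
  if (length(unknown)) {
    pc_abort(sprintf("genes on chromosome(s) absent from chrom_sizes: %s",
                     paste(unknown, collapse = ", ")),
             class = "peakcoloc_data_error")
  }
  sz <- setNames(chrom_sizes$size, chrom_sizes$chrom)
  plus <- genes$strand == "+"
  tss <- ifelse(plus, genes$start, genes$end)
  win_start <- ifelse(plus, tss - upstream, tss - downstream)
  win_end <- ifelse(plus, tss + downstream, tss + upstream)
  win_start <- pmax(win_start, 0)
  win_end <- pmin(win_end, sz[genes$chrom])
  keep <- win_start < win_end
  out <- tibble(
    chrom = genes$chrom[keep],
    start = as.integer(win_start[keep]),
    end = as.integer(win_end[keep]),
    gene_id = genes$gene_id[keep],
    strand = genes$strand[keep]
  )
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Classify peaks as promoter, genic or intergenic
#'
#' Precedence is promoter > genic > intergenic: a peak overlapping any
#' promoter window is `promoter` regardless of gene-body overlap; otherwise
#' a peak overlapping any transcript span is `genic`; the rest are
#' `intergenic`. Every peak receives exactly one label.
#'
#' @param peaks Peak tibble.
#' @param promoters Promoter windows from [promoter_regions()].
#' @param genes Gene-model tibble (transcript spans).
#' @param by_summit If `TRUE`, membership is decided by the 1-bp summit
#'   position ([peak_center()]) instead of the full peak interval.
#' @return `peaks` with added columns `class` (factor promoter/genic/
#'   intergenic) and `gene_id` (first overlapping promoter's gene, else ".").
#' @export
classify_peaks <- function(peaks, promoters, genes, by_summit = FALSE) {
  peaks <- validate_peaks(peaks)
  genes <- validate_genes(genes)
  query <- if (by_summit) {
    ctr <- peak_center(peaks)
    tibble(chrom = peaks$chrom, start = ctr, end = ctr + 1L)
  } else {
    peaks
  }
  in_prom <- overlap_membership(query, promoters)
  in_gene <- overlap_membership(query, genes)
  cls <- ifelse(in_prom, "promoter", ifelse(in_gene, "genic", "intergenic"))
  gene_id <- rep(".", nrow(peaks))
  if (nrow(promoters) && any(in_prom)) {
    hits <- find_hits(query, promoters)
    first_hit <- rep(NA_integer_, nrow(query))
    keep <- !duplicated(S4Vectors::queryHits(hits))
    first_hit[S4Vectors::queryHits(hits)[keep]] <- S4Vectors::subjectHits(hits)[keep]
    gene_id[in_prom] <- promoters$gene_id[first_hit[in_prom]]
  }
  peaks$class <- factor(cls, levels = c("promoter", "genic", "intergenic"))
  peaks$gene_id <- gene_id
  peaks
}

#' Fraction of peaks located in promoter windows
#'
#' The promoter-localization percentage: 100 x (number of peaks overlapping
#' at least one promoter window) / (total number of peaks).
#'
#' @param peaks Non-empty peak tibble.
#' @param promoters Promoter windows from [promoter_regions()].
#' @param by_summit Use the summit point rather than the full interval.
#' @return A percentage in \[0, 100\].
#' @export
promoter_fraction <- function(peaks, promoters, by_summit = FALSE) {
  peaks <- validate_peaks(peaks)
  if (!nrow(peaks)) {
    pc_abort("promoter fraction is undefined for an empty peak set.",
             class = "peakcoloc_usage_error")
  }
  query <- if (by_summit) {
    ctr <- peak_center(peaks)
    tibble(chrom = peaks$chrom, start = ctr, end = ctr + 1L)
  } else {
    peaks
  }
  100 * sum(overlap_membership(query, promoters)) / nrow(peaks)
}

#' Write peak classifications to TSV
#' @param classified Output of [classify_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_classes <- function(classified, path) {
  if (!all(c("name", "class", "gene_id") %in% names(classified))) {
    pc_abort("`classified` must come from classify_peaks().",
             class = "peakcoloc_usage_error")
  }
  lines <- c(
    paste("peak", "class", "gene_id", sep = "\t"),
    paste(classified$name, as.character(classified$class), classified$gene_id,
          sep = "\t")
  )
  readr::write_lines(lines, path)
  invisible(path)
}
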