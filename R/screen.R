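# The co-localization screen: per-protein overlap percentages of ChIP-seq
# peak sets against R-loop and G4 structure loci, and the cross-protein
# correlation of the two percentage vectors.

#' Overlap percentage of one peak set against another
#'
#' The screen's core statistic: the percentage of `a`'s peaks that overlap
#' at least one peak of `b` — (number of overlapped peaks) / (total number of
#' peaks) x 100, with record-level `-wa -u` overlap semantics.
#'
#' @param a Query peak tibble; must be non-empty (the statistic is undefined
#'   on an empty set).
#' @param b Reference peak tibble (may be empty, giving 0).
#' @return A single percentage in \[0, 100\].
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = c(0, 100, 200, 300) * 10,
#'                     end = c(0, 100, 200, 300) * 10 + 50)
#' b <- a[1:2, ]
#' overlap_percentage(a, b)  # 50
#' @export
overlap_percentage <- function(a, b) {
  a <- validate_peaks(a, "a")
  if (!nrow(a)) {
    pc_abort("overlap percentage is undefined for an empty query set.",
             class = "peakcoloc_usage_error")
  }
  100 * sum(overlap_membership(a, b)) / nrow(a)
}

#' Pearson product-moment correlation with explicit guards
#'
#' Thin wrapper around [stats::cor()] that enforces the screen's contract:
#' at least 3 paired observations and nonzero variance in both vectors.
#' A degenerate input yields `NA` with a classed warning rather than silent
#' NaN propagation.
#'
#' @param xs,ys Numeric vectors of equal length >= 3.
#' @return The correlation coefficient in \[-1, 1\], or `NA_real_` when
#'   either vector has zero variance.
#' @export
pearson_r <- function(xs, ys) {
  if (length(xs) != length(ys)) {
    pc_abort("`xs` and `ys` must have equal length.", class = "peakcoloc_usage_error")
  }
  if (length(xs) < 3L) {
    pc_abort("correlation requires at least 3 paired observations.",
             class = "peakcoloc_usage_error")
  }
  if (anyNA(xs) || anyNA(ys)) {
    pc_abort("`xs` and `ys` must not contain NA.", class = "peakcoloc_usage_error")
  }
  if (sd(xs) == 0 || sd(ys) == 0) {
    warn("correlation undefined: zero variance in at least one vector.",
         class = "peakcoloc_degenerate_warning")
    return(NA_real_)
  }
  cor(xs, ys, method = "pearson")
}

#' Run the co-localization screen
#'
#' For every protein, computes how many of its peaks overlap the R-loop set,
#' the G4 set, and both, plus the two overlap percentages; then the Pearson
#' correlation between the G4 and R-loop percentage vectors across proteins.
#'
#' @param tf_sets Named list of peak tibbles, one per protein. Proteins with
#'   zero peaks are skipped with a warning (their statistic is undefined) and
#'   recorded in the `skipped` attribute.
#' @param rloop,g4 Structure peak tibbles; either may be empty, giving
#'   all-zero percentages for that column.
#' @return A `screen_table`: a tibble with one row per retained protein in
#'   name-sorted order (`protein`, `n_peaks`, `n_rloop`, `pct_rloop`, `n_g4`,
#'   `pct_g4`, `n_both`) and attributes `pearson_r` (NA when undefined) and
#'   `skipped`.
#' @seealso [rank_candidates()], [tidy.screen_table()], [glance.screen_table()]
#' @export
run_screen <- function(tf_sets, rloop, g4) {
  if (!is.list(tf_sets) || !length(tf_sets)) {
    pc_abort("`tf_sets` must be a non-empty named list of peak tibbles.",
             class = "peakcoloc_usage_error")
  }
  if (is.null(names(tf_sets)) || any(names(tf_sets) == "")) {
    pc_abort("every element of `tf_sets` must be named by its protein.",
             class = "peakcoloc_usage_error")
  }
  rloop <- validate_peaks(rloop, "rloop")
  g4 <- validate_peaks(g4, "g4")
  empty <- vapply(tf_sets, function(p) nrow(as_tibble(p)) == 0L, logical(1))
  if (any(empty)) {
    warn(sprintf("skipping %d protein(s) with zero peaks: %s",
                 sum(empty), paste(names(tf_sets)[empty], collapse = ", ")),
         class = "peakcoloc_skip_warning")
  }
  kept <- tf_sets[!empty]
  if (!length(kept)) {
    pc_abort("no protein has any peaks; nothing to screen.",
             class = "peakcoloc_usage_error")
  }
  kept <- kept[order(names(kept))]
  records <- map_dfr(names(kept), function(protein) {
    counts <- three_way_cooccupancy(kept[[protein]], rloop, g4)
    tibble(
      protein = protein,
      n_peaks = counts$n_peaks,
      n_rloop = counts$n_rloop,
      pct_rloop = 100 * counts$n_rloop / counts$n_peaks,
      n_g4 = counts$n_g4,
      pct_g4 = 100 * counts$n_g4 / counts$n_peaks,
      n_both = counts$n_both
    )
  })
  r <- NA_real_
  if (nrow(records) >= 3L && sd(records$pct_g4) > 0 && sd(records$pct_rloop) > 0) {
    r <- pearson_r(records$pct_g4, records$pct_rloop)
  }
  new_screen_table(records, pearson_r = r, skipped = names(tf_sets)[empty])
}

new_screen_table <- function(records, pearson_r, skipped = character()) {
  structure(records,
            pearson_r = pearson_r,
            skipped = skipped,
            class = c("screen_table", class(tibble())))
}

#' Rank candidate structure-binding proteins
#'
#' Retains proteins whose overlap percentages with both structure sets reach
#' `min_pct`, ranked by the smaller of the two percentages (descending), ties
#' broken alphabetically. The ranking statistic min(pct_rloop, pct_g4)
#' rewards proteins high on *both* axes rather than on either alone.
#'
#' @param table A `screen_table` from [run_screen()].
#' @param min_pct Threshold percentage applied to both columns.
#' @return A tibble (`protein`, `pct_rloop`, `pct_g4`, `pct_min`) in rank
#'   order; `$protein` is the ranked candidate list.
#' @export
rank_candidates <- function(table, min_pct = 25) {
  if (!inherits(table, "screen_table") || !nrow(table)) {
    pc_abort("`table` must be a non-empty screen_table.",
             class = "peakcoloc_usage_error")
  }
  table |>
    as_tibble() |>
    mutate(pct_min = pmin(.data$pct_rloop, .data$pct_g4)) |>
    filter(.data$pct_rloop >= min_pct, .data$pct_g4 >= min_pct) |>
    arrange(desc(.data$pct_min), .data$protein) |>
    select("protein", "pct_rloop", "pct_g4", "pct_min")
}

#' @export
print.screen_table <- function(x, ...) {
  r <- attr(x, "pearson_r")
  cat(sprintf("# Co-localization screen: %d protein(s); Pearson r = %s\n",
              nrow(x), if (is.na(r)) "undefined" else sprintf("%.4f", r)))
  NextMethod()
}

#' Tidy a screen table
#' @param x A `screen_table`.
#' @param ... Unused.
#' @return A plain tibble of per-protein records.
#' @export
tidy.screen_table <- function(x, ...) {
  as_tibble(unclass_screen(x))
}

#' One-row summary of a screen
#' @param x A `screen_table`.
#' @param ... Unused.
#' @return Tibble with `n_proteins`, `pearson_r`, `n_skipped`.
#' @export
glance.screen_table <- function(x, ...) {
  tibble(
    n_proteins = nrow(x),
    pearson_r = attr(x, "pearson_r"),
    n_skipped = length(attr(x, "skipped"))
  )
}

unclass_screen <- function(x) {
  attr(x, "pearson_r") <- NULL
  attr(x, "skipped") <- NULL
  class(x) <- class(tibble())
  x
}

#' Scatter plot of a co-localization screen
#'
#' One point per protein: overlap percentage with G4 loci against overlap
#' percentage with R-loop loci, annotated with the cross-protein Pearson r.
#'
#' @param object A `screen_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_table <- function(object, ...) {
  r <- attr(object, "pearson_r")
  ggplot2::ggplot(as_tibble(unclass_screen(object)),
                  ggplot2::aes(x = .data$pct_g4, y = .data$pct_rloop)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "peaks overlapping G4 loci (%)",
      y = "peaks overlapping R-loop loci (%)",
      title = "Co-localization of binding sites with R-loop and G4 loci",
      subtitle = if (is.na(r)) NULL else sprintf("Pearson r = %.4f", r)
    ) +
    ggplot2::theme_minimal()
}

#' Write a screen table to TSV
#'
#' Percentages are written to 4 decimal places; `#`-prefixed metadata lines
#' carry the Pearson r (full precision) and the record count.
#'
#' @param table A `screen_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(table, path) {
  if (!inherits(table, "screen_table")) {
    pc_abort("`table` must be a screen_table.", class = "peakcoloc_usage_error")
  }
  r <- attr(table, "pearson_r")
  hdr <- c(
    sprintf("# peakcoloc screen: %d proteins", nrow(table)),
    sprintf("# pearson_r\t%s", if (is.na(r)) "NA" else as.character(r)),
    paste("protein", "n_peaks", "n_rloop", "pct_rloop", "n_g4", "pct_g4",
          "n_both", sep = "\t")
  )
  body <- sprintf("%s\t%d\t%d\t%.4f\t%d\t%.4f\t%d",
                  table$protein, table$n_peaks, table$n_rloop, table$pct_rloop,
                  table$n_g4, table$pct_g4, table$n_both)
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}
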