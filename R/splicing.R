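# Exon exclusion-ratio summaries for alternative-splicing quantification.
# Exclusion ratio = exclusion / (inclusion + exclusion), computed per
# replicate and then summarized as mean +/- SEM per event and condition,
# matching per-lane gel quantification.

#' Exon exclusion ratio
#'
#' `exclusion / (inclusion + exclusion)`, in \[0, 1\]. The operands may be
#' band intensities or junction counts — the ratio is scale-invariant.
#' When both operands are zero the ratio is undefined and returned as `NA`
#' (never 0).
#'
#' @param inclusion,exclusion Non-negative numeric vectors (recycled).
#' @return Numeric vector of ratios.
#' @examples
#' exclusion_ratio(50, 50)   # 0.5
#' exclusion_ratio(10, 0)    # 0
#' @export
exclusion_ratio <- function(inclusion, exclusion) {
  if (any(inclusion < 0, na.rm = TRUE) || any(exclusion < 0, na.rm = TRUE)) {
    pc_abort("inclusion and exclusion must be non-negative.",
             class = "peakcoloc_usage_error")
  }
  tot <- inclusion + exclusion
  out <- exclusion / tot
  out[tot == 0] <- NA_real_
  out
}

#' Per-event, per-condition exclusion-ratio summary
#'
#' Computes the exclusion ratio per replicate, then the mean and standard
#' error of the mean (sd / sqrt(n)) over replicates within each event and
#' condition. Ratios are averaged per replicate rather than pooled across
#' replicates, so each lane/replicate contributes equally. With a single
#' replicate the SEM is `NA`; replicates with an undefined ratio (both
#' operands 0) are excluded from the summary and counted.
#'
#' @param counts Tibble with columns `event_id`, `condition`, `replicate`,
#'   `inclusion`, `exclusion` (see [read_splice_counts()]).
#' @return Tibble with `event_id`, `condition`, `mean_ratio`, `sem`, `n`,
#'   one row per event x condition present in the input.
#' @export
ratio_table <- function(counts) {
  need <- c("event_id", "condition", "replicate", "inclusion", "exclusion")
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    pc_abort("`counts` must have event_id/condition/replicate/inclusion/exclusion.",
             class = "peakcoloc_usage_error")
  }
  counts |>
    as_tibble() |>
    mutate(ratio = exclusion_ratio(.data$inclusion, .data$exclusion)) |>
    group_by(.data$event_id, .data$condition) |>
    summarise(
      n_ok = sum(!is.na(.data$ratio)),
      n_undefined = sum(is.na(.data$ratio)),
      mean_ratio = if (n_ok > 0) mean(.data$ratio, na.rm = TRUE) else NA_real_,
      sem = if (n_ok > 1) sd(.data$ratio, na.rm = TRUE) / sqrt(n_ok) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::rename(n = "n_ok") |>
    select("event_id", "condition", "mean_ratio", "sem", "n", "n_undefined")
}

#' Read a splice-counts TSV
#'
#' Expected columns: `event_id`, `condition`, `replicate`, `inclusion`,
#' `exclusion` (tab-separated with a header; `#` comment lines skipped).
#'
#' @param path Path to the TSV.
#' @return A tibble of splice counts.
#' @export
read_splice_counts <- function(path) {
  counts <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("event_id", "condition", "replicate", "inclusion", "exclusion")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols)) {
    pc_abort(sprintf("splice-counts file lacks column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             class = "peakcoloc_parse_error")
  }
  if (any(counts$inclusion < 0 | counts$exclusion < 0)) {
    pc_abort("inclusion/exclusion quantities must be non-negative.",
             class = "peakcoloc_data_error")
  }
  counts[need]
}

#' Write a ratio table to TSV
#' @param table Output of [ratio_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratio_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}
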