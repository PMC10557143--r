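# End-to-end driver: simulate -> screen -> annotate -> profile -> metagene
# -> density, with a report comparing every pipeline result against the
# generator's ground-truth ledger. All outputs are deterministic functions
# of (config, seed): plain TSV with "#" metadata headers, no timestamps.

#' Run the whole pipeline on a simulated scenario
#'
#' Simulates a scenario, then runs every analysis stage on the *written
#' files* (never on in-memory shortcuts) and checks the results against the
#' ledger: planted overlap counts must match exactly, the screen correlation
#' must equal the correlation of realized planted fractions to 1e-12, the
#' planted promoter fraction must be recovered exactly, the aggregation
#' curve must peak at the anchor, and the planted promoter/body signal ratio
#' must be recovered within tolerance.
#'
#' @param out_dir Output directory; inputs land in `out_dir/inputs`, stage
#'   outputs and `report.tsv` in `out_dir`.
#' @param seed Integer seed passed to the simulator.
#' @param config Named list of overrides forwarded to [simulate_scenario()]
#'   (e.g. `n_proteins`, `n_peaks`, `relation`).
#' @param ratio_tol Relative tolerance for the promoter/body ratio check.
#' @return List with `screen`, `classes`, `profile`, `metagene`, `density`,
#'   `checks` (the report tibble), `passed` (logical) and `paths`.
#' @export
run_end_to_end <- function(out_dir, seed = 7, config = list(),
                           ratio_tol = 0.1) {
  seed <- pc_stopifnot_scalar_count(seed, "seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scen_args <- c(list(out_dir = file.path(out_dir, "inputs"), seed = seed),
                 config)
  scenario <- do.call(simulate_scenario, scen_args)
  p <- scenario$paths
  led <- scenario$ledger

  # stage 1: screen, from the written files
  chrom_sizes <- read_chrom_sizes(p$chrom_sizes)
  genes <- read_gene_models(p$genes)
  rloop <- read_peaks(p$rloop, dialect = "narrowPeak")
  g4 <- read_peaks(p$g4, dialect = "narrowPeak")
  tf_files <- list.files(p$tf_dir, pattern = "\\.narrowPeak$", full.names = TRUE)
  tf_sets <- setNames(lapply(tf_files, read_peaks, dialect = "narrowPeak"),
                      sub("\\.narrowPeak$", "", basename(tf_files)))
  screen <- run_screen(tf_sets, rloop, g4)
  write_screen_table(screen, file.path(out_dir, "screen.tsv"))

  # stage 2: promoter annotation of the structure sets
  promoters <- promoter_regions(genes, led$params$upstream,
                                led$params$downstream, chrom_sizes)
  classes <- classify_peaks(rloop, promoters, genes)
  write_peak_classes(classes, file.path(out_dir, "classes.tsv"))
  pf_rloop <- promoter_fraction(rloop, promoters)
  pf_g4 <- promoter_fraction(g4, promoters)

  # stage 3: aggregation profile of coverage at R-loop peak centers
  coverage <- read_bedgraph(p$coverage, chrom_sizes)
  prof <- aggregate_profile(coverage, rloop, chrom_sizes)
  write_profile_tsv(tidy(prof), file.path(out_dir, "profile.tsv"),
                    sprintf("# aggregation profile: %d anchors", prof$n_anchors))

  # stage 4: metagene of the polymerase-style track
  rnapii <- read_bedgraph(p$rnapii, chrom_sizes)
  meta <- metagene_profile(rnapii, genes, chrom_sizes)
  write_profile_tsv(tidy(meta), file.path(out_dir, "metagene.tsv"),
                    sprintf("# metagene profile: %d genes", meta$n_genes))

  # stage 5: promoter vs body densities of the same track
  prom_merged <- regions_reduce(promoters)
  body_minus_prom <- regions_setdiff(genes, prom_merged)
  regions <- bind_rows(
    mutate(prom_merged, class = "promoter"),
    mutate(body_minus_prom, class = "body")
  )
  regions$region_id <- sprintf("%s_%05d", regions$class,
                               seq_len(nrow(regions)))
  dens <- region_density(rnapii, regions)
  readr::write_tsv(dens, file.path(out_dir, "density.tsv"))

  # ledger checks
  ledp <- led$proteins[order(led$proteins$protein), ]
  count_mismatch <- sum(screen$n_rloop != ledp$n_rloop) +
    sum(screen$n_g4 != ledp$n_g4) + sum(screen$n_both != ledp$n_both)
  r_realized <- pearson_r(100 * ledp$n_g4 / ledp$n_peaks,
                          100 * ledp$n_rloop / ledp$n_peaks)
  planted_pf <- 100 * round(led$params$n_structure * led$params$promoter_frac) /
    led$params$n_structure
  n_flank <- sum(meta$segment == "upstream")
  prom_bins <- (n_flank - led$params$upstream %/% 50 + 1):n_flank
  body_mid <- n_flank + seq(0.4 * meta$body_bins, 0.6 * meta$body_bins)
  ratio <- mean(meta$mean_curve[prom_bins]) / mean(meta$mean_curve[body_mid])
  planted_ratio <- led$params$rnapii$promoter_level / led$params$rnapii$body_level
  center_bin <- which.max(prof$mean_curve)
  n_bins <- length(prof$mean_curve)

  checks <- tibble(
    check = c("screen_counts_match_ledger",
              "screen_r_equals_realized_fraction_r",
              "promoter_fraction_exact",
              "aggregation_peak_at_center",
              "metagene_promoter_body_ratio"),
    expected = c(0, r_realized, planted_pf, (n_bins + 1) / 2, planted_ratio),
    observed = c(count_mismatch, attr(screen, "pearson_r"), pf_rloop,
                 center_bin, ratio),
    pass = c(
      count_mismatch == 0,
      abs(attr(screen, "pearson_r") - r_realized) <= 1e-12,
      identical(pf_rloop, planted_pf) || abs(pf_rloop - planted_pf) < 1e-9,
      center_bin %in% c(n_bins %/% 2, n_bins %/% 2 + 1L),
      abs(ratio - planted_ratio) <= ratio_tol * planted_ratio
    )
  )
  report_lines <- c(
    "# peakcoloc end-to-end report",
    sprintf("# seed\t%d", seed),
    paste0("# config\t", jsonlite::toJSON(led$params, auto_unbox = TRUE,
                                          digits = NA)),
    paste("check", "expected", "observed", "pass", sep = "\t"),
    sprintf("%s\t%s\t%s\t%s", checks$check, as.character(checks$expected),
            as.character(checks$observed), checks$pass)
  )
  readr::write_lines(report_lines, file.path(out_dir, "report.tsv"))

  list(scenario = scenario, screen = screen, classes = classes,
       promoter_fraction = c(rloop = pf_rloop, g4 = pf_g4),
       profile = prof, metagene = meta, density = dens,
       checks = checks, passed = all(checks$pass),
       paths = c(p, list(report = file.path(out_dir, "report.tsv"))))
}

write_profile_tsv <- function(tidy_tbl, path, header) {
  lines <- c(header,
             paste(names(tidy_tbl), collapse = "\t"),
             do.call(sprintf, c(
               list(paste(rep("%s", ncol(tidy_tbl)), collapse = "\t")),
               lapply(tidy_tbl, as.character))))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Validate a set of pipeline input files
#'
#' Report-only sanity checks: per-file format detection and record counts,
#' and a comparison of chromosome-name sets across files that flags disjoint
#' sets — the classic silent failure when one file says `chr1` and another
#' says `1`.
#'
#' @param paths Named character vector/list of file paths. Names are labels;
#'   format is guessed from the extension (`.narrowPeak`, `.bed`,
#'   `.bedgraph`, `.sizes`).
#' @return A tibble (`file`, `label`, `format`, `n_records`, `chroms`) with
#'   a `warnings` attribute listing any cross-file chromosome mismatches.
#' @export
validate_inputs <- function(paths) {
  paths <- unlist(paths)
  if (is.null(names(paths)) || any(names(paths) == "")) {
    names(paths) <- basename(unlist(paths))
  }
  rows <- map_dfr(names(paths), function(label) {
    path <- paths[[label]]
    if (!file.exists(path)) {
      return(tibble(file = path, label = label, format = "missing",
                    n_records = NA_integer_, chroms = list(character())))
    }
    fmt <- guess_format(path)
    rec <- tryCatch(switch(fmt,
      narrowPeak = read_peaks(path, "narrowPeak"),
      bed6 = read_peaks(path, "bed6"),
      bed3 = read_peaks(path, "bed3"),
      bedgraph = read_bedgraph(path),
      chrom_sizes = read_chrom_sizes(path),
      NULL
    ), error = function(e) NULL)
    if (is.null(rec)) {
      return(tibble(file = path, label = label, format = paste0(fmt, " (unreadable)"),
                    n_records = 0L, chroms = list(character())))
    }
    tibble(file = path, label = label, format = fmt, n_records = nrow(rec),
           chroms = list(sort(unique(rec$chrom))))
  })
  warnings <- character()
  sets <- rows$chroms[lengths(rows$chroms) > 0]
  labs <- rows$label[lengths(rows$chroms) > 0]
  if (length(sets) > 1) {
    for (i in seq_along(sets)[-1]) {
      if (!length(intersect(sets[[1]], sets[[i]]))) {
        hint <- if (any(startsWith(sets[[1]], "chr")) !=
                      any(startsWith(sets[[i]], "chr"))) {
          " (likely 'chr' prefix mismatch; see normalize_chrom_names())"
        } else ""
        warnings <- c(warnings, sprintf(
          "chromosome names of '%s' and '%s' are disjoint%s",
          labs[1], labs[i], hint))
      }
    }
  }
  zero <- rows$label[!is.na(rows$n_records) & rows$n_records == 0L]
  if (length(zero)) {
    warnings <- c(warnings,
                  sprintf("file with zero records: %s",
                          paste(zero, collapse = ", ")))
  }
  if (length(warnings)) {
    warn(paste(warnings, collapse = "\n"), class = "peakcoloc_validate_warning")
  }
  attr(rows, "warnings") <- warnings
  rows
}

guess_format <- function(path) {
  low <- tolower(path)
  if (endsWith(low, ".narrowpeak")) return("narrowPeak")
  if (endsWith(low, ".bedgraph") || endsWith(low, ".bdg")) return("bedgraph")
  if (endsWith(low, ".sizes")) return("chrom_sizes")
  if (endsWith(low, ".bed")) return("bed6")
  "bed3"
}
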