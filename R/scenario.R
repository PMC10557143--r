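# One-call scenario builder: toy genome, genes, promoter windows, two
# structure peak sets (promoter-enriched, mutually co-occurring), TF peak
# sets with planted overlap fractions, and two coverage tracks (bumps at
# structure peak centers; promoter/body plateaus for the polymerase-style
# track). Everything is written as plain text plus a JSON ground-truth
# ledger, and the written files are re-read and re-screened before returning
# so the ledger is guaranteed consistent with the emitted bytes.

#' Simulate a complete co-localization scenario
#'
#' Generates and writes every input the pipeline consumes, with exact
#' planted ground truth. The same seed produces byte-identical output files.
#'
#' Files written under `out_dir`: `chrom.sizes`, `genes.bed`,
#' `rloop.narrowPeak`, `g4.narrowPeak`, `tf/TFnnn.narrowPeak`,
#' `coverage.bedgraph` (Gaussian bumps at R-loop peak centers),
#' `rnapii.bedgraph` (promoter/body plateau track) and `ledger.json`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed fixing every random draw.
#' @param n_proteins,n_peaks TF screen size: number of peak sets and peaks
#'   per set.
#' @param n_genes Number of genes on the toy genome.
#' @param n_structure Peaks per structure set.
#' @param promoter_frac Fraction of structure peaks planted in promoters.
#' @param cooccur_frac Fraction of G4 peaks planted inside R-loop peaks.
#' @param relation Planted linear relation between per-protein G4 and R-loop
#'   overlap fractions: list with `slope`, `intercept`, `noise_sd`.
#' @param upstream,downstream Promoter window extent in bp around the TSS.
#' @param n_chroms,chrom_length Toy genome shape.
#' @param coverage Bump-track parameters: list with `amplitude`, `sigma`,
#'   `background`, `noise_sd`, `bin`.
#' @param rnapii Plateau-track parameters: list with `promoter_level`,
#'   `body_level`, `noise_sd`.
#' @return A `coloc_scenario` list: paths to every written file, the in-memory
#'   tables, and `ledger` (also serialized as `ledger.json`).
#' @export
simulate_scenario <- function(out_dir, seed = 7,
                              n_proteins = 50, n_peaks = 500,
                              n_genes = 500, n_structure = 1000,
                              promoter_frac = 0.7, cooccur_frac = 0.5,
                              relation = list(slope = 0.8, intercept = 0.05,
                                              noise_sd = 0.05),
                              upstream = 1000, downstream = 500,
                              n_chroms = 2, chrom_length = 1e7,
                              coverage = list(amplitude = 10, sigma = 150,
                                              background = 5, noise_sd = 1,
                                              bin = 50),
                              rnapii = list(promoter_level = 3,
                                            body_level = 1,
                                            noise_sd = 0.1)) {
  seed <- pc_stopifnot_scalar_count(seed, "seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "tf"), recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)

  chrom_sizes <- make_genome(n_chroms, chrom_length)
  genes <- make_genes(chrom_sizes, n = n_genes)
  promoters <- promoter_regions(genes, upstream, downstream, chrom_sizes)
  rloop <- make_structure_peaks(promoters, chrom_sizes, n = n_structure,
                                promoter_frac = promoter_frac,
                                name_prefix = "rloop")
  g4 <- make_structure_peaks(promoters, chrom_sizes, n = n_structure,
                             promoter_frac = promoter_frac,
                             cooccur_with = rloop,
                             cooccur_frac = cooccur_frac,
                             name_prefix = "g4")
  tf <- make_tf_sets(rloop, g4, chrom_sizes, n_proteins = n_proteins,
                     n_peaks = n_peaks, relation = relation)

  anchors <- tibble(chrom = rloop$chrom, pos = peak_center(rloop))
  cov <- make_coverage(anchors, chrom_sizes,
                       amplitude = coverage$amplitude, sigma = coverage$sigma,
                       background = coverage$background,
                       noise_sd = coverage$noise_sd, bin = coverage$bin)
  # disjoint plateau pieces: promoter windows at promoter_level, gene bodies
  # minus any promoter overlap at body_level, so each bin sees exactly one
  # planted level
  prom_merged <- regions_reduce(promoters)
  body_minus_prom <- regions_setdiff(genes, prom_merged)
  region_levels <- bind_rows(
    mutate(prom_merged, level = rnapii$promoter_level),
    mutate(body_minus_prom, level = rnapii$body_level)
  )
  pol <- make_coverage(anchors = NULL, chrom_sizes,
                       amplitude = 0, sigma = 1,
                       background = 0, noise_sd = rnapii$noise_sd,
                       bin = coverage$bin,
                       region_levels = region_levels)

  paths <- list(
    dir = out_dir,
    chrom_sizes = file.path(out_dir, "chrom.sizes"),
    genes = file.path(out_dir, "genes.bed"),
    rloop = file.path(out_dir, "rloop.narrowPeak"),
    g4 = file.path(out_dir, "g4.narrowPeak"),
    tf_dir = file.path(out_dir, "tf"),
    coverage = file.path(out_dir, "coverage.bedgraph"),
    rnapii = file.path(out_dir, "rnapii.bedgraph"),
    ledger = file.path(out_dir, "ledger.json")
  )
  write_chrom_sizes(chrom_sizes, paths$chrom_sizes)
  write_gene_models(genes, paths$genes)
  write_peaks(rloop, paths$rloop, dialect = "narrowPeak")
  write_peaks(g4, paths$g4, dialect = "narrowPeak")
  tf_paths <- file.path(paths$tf_dir, paste0(names(tf$tf_sets), ".narrowPeak"))
  walk(seq_along(tf$tf_sets), function(i) {
    write_peaks(tf$tf_sets[[i]], tf_paths[i], dialect = "narrowPeak")
  })
  write_bedgraph(cov$track, paths$coverage)
  write_bedgraph(pol$track, paths$rnapii)

  ledger <- list(
    seed = seed,
    params = list(
      n_proteins = n_proteins, n_peaks = n_peaks, n_genes = n_genes,
      n_structure = n_structure, promoter_frac = promoter_frac,
      cooccur_frac = cooccur_frac, relation = relation,
      upstream = upstream, downstream = downstream,
      n_chroms = n_chroms, chrom_length = chrom_length,
      coverage = coverage, rnapii = rnapii
    ),
    structure = list(
      rloop_n_promoter = attr(rloop, "n_promoter"),
      g4_n_promoter = attr(g4, "n_promoter"),
      g4_n_cooccur = attr(g4, "n_cooccur")
    ),
    proteins = tf$ledger
  )
  jsonlite::write_json(
    c(ledger[c("seed", "params", "structure")],
      list(proteins = tf$ledger)),
    paths$ledger, auto_unbox = TRUE, digits = NA)

  # ledger consistency: re-read the emitted files and re-derive every planted
  # count with the pipeline's own operations
  verify_scenario_ledger(paths, ledger)

  structure(
    list(paths = paths, chrom_sizes = chrom_sizes, genes = genes,
         promoters = promoters, rloop = rloop, g4 = g4,
         tf_sets = tf$tf_sets, coverage = cov, rnapii = pol,
         ledger = ledger),
    class = "coloc_scenario"
  )
}

verify_scenario_ledger <- function(paths, ledger) {
  rloop <- read_peaks(paths$rloop, dialect = "narrowPeak")
  g4 <- read_peaks(paths$g4, dialect = "narrowPeak")
  tf_files <- list.files(paths$tf_dir, pattern = "\\.narrowPeak$",
                         full.names = TRUE)
  tf_sets <- setNames(
    lapply(tf_files, read_peaks, dialect = "narrowPeak"),
    sub("\\.narrowPeak$", "", basename(tf_files))
  )
  tab <- suppressWarnings(run_screen(tf_sets, rloop, g4))
  led <- ledger$proteins[order(ledger$proteins$protein), ]
  ok <- identical(tab$protein, led$protein) &&
    identical(tab$n_rloop, led$n_rloop) &&
    identical(tab$n_g4, led$n_g4) &&
    identical(tab$n_both, as.integer(led$n_both))
  if (!isTRUE(ok)) {
    pc_abort("scenario self-check failed: screen of emitted files != ledger.",
             class = "peakcoloc_internal_error")
  }
  invisible(TRUE)
}

#' @export
print.coloc_scenario <- function(x, ...) {
  cat(sprintf(
    "# Synthetic co-localization scenario (seed %d)\n# %d proteins x %d peaks; %d genes; %d structure peaks/set\n# written to %s\n",
    x$ledger$seed, x$ledger$params$n_proteins, x$ledger$params$n_peaks,
    x$ledger$params$n_genes, x$ledger$params$n_structure, x$paths$dir))
  invisible(x)
}
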