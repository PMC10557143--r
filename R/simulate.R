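# Seeded synthetic-data generator. It emulates the structure of the real
# screen inputs — many TF peak sets with heterogeneous, mutually correlated
# overlap fractions against two structure peak sets, structure peaks enriched
# in strand-aware promoter windows, and coverage tracks with localized
# enrichment at peak centers and at promoters versus gene bodies — while
# planting every overlap EXACTLY, so the pipeline's outputs can be checked
# against a ground-truth ledger with no sampling error on counts.
#
# Planting strategy: a peak that must overlap set X and not set Y is placed
# wholly inside a piece of reduce(X) \ reduce(Y); a background peak is placed
# wholly inside the complement of all structure/promoter regions. Placement
# inside a region piece guarantees >= 1 bp overlap with some member of X and
# zero overlap with Y, so planted counts are exact by construction (and are
# re-verified with the package's own overlap engine before returning).

#' Deterministic toy genome
#'
#' @param n_chroms Number of chromosomes (>= 1).
#' @param chrom_length Length of each chromosome in bp (>= 1e5).
#' @return chrom.sizes tibble with chromosomes `chrS1..chrSn`.
#' @export
make_genome <- function(n_chroms = 2, chrom_length = 1e7) {
  n_chroms <- pc_stopifnot_scalar_count(n_chroms, "n_chroms", min = 1L)
  if (!is.numeric(chrom_length) || chrom_length < 1e5) {
    pc_abort("`chrom_length` must be >= 1e5 bp.", class = "peakcoloc_usage_error")
  }
  tibble(chrom = paste0("chrS", seq_len(n_chroms)),
         size = rep(as.numeric(chrom_length), n_chroms))
}

#' Random non-overlapping gene models
#'
#' Genes are placed by batched rejection sampling: lengths uniform in
#' `len_range`, chromosome chosen proportional to its size, strand a fair
#' coin. Placement must be feasible (total expected gene length at most half
#' the genome); infeasible requests error after a bounded number of rounds.
#'
#' @param chrom_sizes chrom.sizes tibble.
#' @param n Number of genes.
#' @param len_range Length-2 vector of min/max gene length in bp.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Gene-model tibble sorted by chromosome and start, ids `g0001...`.
#' @export
make_genes <- function(chrom_sizes, n = 500, len_range = c(5000, 15000),
                       seed = NULL) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  n <- pc_stopifnot_scalar_count(n, "n")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) {
    return(validate_genes(tibble(chrom = character(), start = integer(),
                                 end = integer(), gene_id = character(),
                                 score = numeric(), strand = character())))
  }
  genome_bp <- sum(chrom_sizes$size)
  if (n * max(len_range) > 0.5 * genome_bp) {
    pc_abort("gene placement infeasible: requested genes exceed half the genome.",
             class = "peakcoloc_usage_error")
  }
  accepted <- tibble(chrom = character(), start = integer(), end = integer())
  lens <- integer(0)
  rounds <- 0L
  while (nrow(accepted) < n && rounds < 1000L) {
    rounds <- rounds + 1L
    need <- n - nrow(accepted)
    len <- as.integer(round(runif(need, len_range[1], len_range[2])))
    ci <- sample.int(nrow(chrom_sizes), need, replace = TRUE,
                     prob = chrom_sizes$size)
    start <- as.integer(floor(runif(need) * (chrom_sizes$size[ci] - len)))
    prop <- tibble(chrom = chrom_sizes$chrom[ci], start = start,
                   end = start + len)
    # reject proposals clashing with accepted genes or with each other
    ok <- !overlap_membership(prop, accepted)
    prop <- prop[ok, , drop = FALSE]
    len <- len[ok]
    if (nrow(prop) > 1L) {
      gr <- regions_to_gr(prop)
      keep <- GenomicRanges::countOverlaps(gr, gr) == 1L  # only self-hit
      prop <- prop[keep, , drop = FALSE]
    }
    accepted <- bind_rows(accepted, prop)
  }
  if (nrow(accepted) < n) {
    pc_abort("gene placement failed: density too high after bounded attempts.",
             class = "peakcoloc_data_error")
  }
  accepted <- accepted[seq_len(n), ]
  strand <- sample(c("+", "-"), n, replace = TRUE)
  out <- tibble(chrom = accepted$chrom, start = accepted$start,
                end = accepted$end,
                gene_id = sprintf("g%04d", seq_len(n)),
                score = 0, strand = strand) |>
    arrange(.data$chrom, .data$start)
  out$gene_id <- sprintf("g%04d", seq_len(n))
  validate_genes(out)
}

# Lognormal peak widths, discretized; median/spread on the bp scale.
sample_peak_widths <- function(n, width_median = 300, width_sdlog = 0.35,
                               min_width = 50, max_width = 2000) {
  w <- round(stats::rlnorm(n, meanlog = log(width_median), sdlog = width_sdlog))
  as.integer(pmin(pmax(w, min_width), max_width))
}

# Place n peaks wholly inside pieces of a merged region set. Piece chosen
# with probability proportional to its length; widths are clipped to the
# piece. Guarantees overlap with the set the pieces derive from and zero
# overlap with anything disjoint from the pieces.
place_in_regions <- function(regions, n, widths, what = "peaks") {
  if (n == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  if (!nrow(regions)) {
    pc_abort(sprintf("no space available to place %s.", what),
             class = "peakcoloc_data_error")
  }
  piece_len <- regions$end - regions$start
  idx <- sample.int(nrow(regions), n, replace = TRUE, prob = piece_len)
  w <- pmin(widths, piece_len[idx])
  offset_max <- piece_len[idx] - w
  start <- regions$start[idx] + as.integer(floor(runif(n) * (offset_max + 1)))
  tibble(chrom = regions$chrom[idx], start = start, end = start + w)
}

#' Structure peak set with planted promoter enrichment and co-occurrence
#'
#' Plants `round(n * promoter_frac)` peaks inside promoter windows and the
#' rest in structure-free background space, so the promoter-localization
#' fraction is exact by construction. When `cooccur_with` is given,
#' `round(n * cooccur_frac)` peaks are placed inside the target peaks
#' (guaranteed overlap) and all remaining peaks avoid the target set
#' entirely, so the co-occurrence count is exact too. Realized counts are
#' re-checked with the overlap engine and attached as attributes
#' (`n_promoter`, `n_cooccur`).
#'
#' @param promoters Promoter windows from [promoter_regions()].
#' @param chrom_sizes chrom.sizes tibble.
#' @param n Number of peaks.
#' @param promoter_frac Fraction of peaks planted in promoter windows.
#' @param cooccur_with Optional target peak tibble.
#' @param cooccur_frac Fraction of peaks planted inside `cooccur_with`.
#' @param width_median,width_sdlog Discretized-lognormal width parameters.
#' @param name_prefix Prefix for peak names.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A peak tibble of `n` rows (summits at peak midpoints).
#' @export
make_structure_peaks <- function(promoters, chrom_sizes, n = 1000,
                                 promoter_frac = 0.7, cooccur_with = NULL,
                                 cooccur_frac = 0, width_median = 300,
                                 width_sdlog = 0.35, name_prefix = "peak",
                                 seed = NULL) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  n <- pc_stopifnot_scalar_count(n, "n", min = 1L)
  if (promoter_frac < 0 || promoter_frac > 1 || cooccur_frac < 0 || cooccur_frac > 1) {
    pc_abort("`promoter_frac` and `cooccur_frac` must be in [0, 1].",
             class = "peakcoloc_usage_error")
  }
  if (!is.null(seed)) set.seed(seed)
  prom_regions <- regions_reduce(promoters)
  genome <- genome_regions(chrom_sizes)
  target_regions <- if (is.null(cooccur_with)) {
    tibble(chrom = character(), start = integer(), end = integer())
  } else {
    regions_reduce(validate_peaks(cooccur_with, "cooccur_with"))
  }

  k_co <- if (is.null(cooccur_with)) 0L else as.integer(round(n * cooccur_frac))
  co <- place_in_regions(target_regions, k_co,
                         sample_peak_widths(k_co, width_median, width_sdlog),
                         what = "co-occurring structure peaks")
  # promoter quota net of co-occurring peaks that already landed in promoters
  m_prom_in_co <- if (k_co) sum(overlap_membership(co, prom_regions)) else 0L
  k_prom <- max(0L, as.integer(round(n * promoter_frac)) - m_prom_in_co)
  k_prom <- min(k_prom, n - k_co)
  prom_free <- regions_setdiff(prom_regions, target_regions)
  prom <- place_in_regions(prom_free, k_prom,
                           sample_peak_widths(k_prom, width_median, width_sdlog),
                           what = "promoter structure peaks")
  k_bg <- n - k_co - k_prom
  bg_space <- regions_setdiff(genome, bind_rows(prom_regions, target_regions))
  bg <- place_in_regions(bg_space, k_bg,
                         sample_peak_widths(k_bg, width_median, width_sdlog),
                         what = "background structure peaks")

  peaks <- bind_rows(co, prom, bg)
  peaks <- new_peaks(peaks$chrom, peaks$start, peaks$end,
                     name = sprintf("%s_%05d", name_prefix, seq_len(n)),
                     score = rep(0, n),
                     summit = (peaks$end - peaks$start) %/% 2L)
  # verify the planting with the pipeline's own engine
  n_promoter <- sum(overlap_membership(peaks, prom_regions))
  n_cooccur <- if (is.null(cooccur_with)) 0L else
    sum(overlap_membership(peaks, target_regions))
  if (!is.null(cooccur_with) && n_cooccur != k_co) {
    pc_abort("internal planting error: realized co-occurrence != planted.",
             class = "peakcoloc_internal_error")
  }
  if (is.null(cooccur_with) && n_promoter != as.integer(round(n * promoter_frac))) {
    pc_abort("internal planting error: realized promoter count != planted.",
             class = "peakcoloc_internal_error")
  }
  attr(peaks, "n_promoter") <- n_promoter
  attr(peaks, "n_cooccur") <- n_cooccur
  peaks
}

#' TF peak sets with exactly planted overlap fractions
#'
#' Per protein, a target R-loop overlap fraction is drawn uniform on
#' `f_range` and the G4 fraction follows the planted linear relation
#' `f_g4 = clamp(slope * f_rloop + intercept + Normal(0, noise_sd), 0, 1)`.
#' Exact counts `round(n_peaks * f)` of peaks are then placed inside the
#' structure sets — jointly sampled memberships decide which peaks overlap
#' R-loops only, G4 only, both, or neither — and every placement is wholly
#' inside the corresponding region class, so the realized counts equal the
#' planted counts exactly. The ledger records targets, realized counts and
#' the exact membership index lists.
#'
#' @param rloop,g4 Structure peak tibbles.
#' @param chrom_sizes chrom.sizes tibble.
#' @param n_proteins Number of TF peak sets.
#' @param n_peaks Peaks per protein (>= 20).
#' @param relation List with `slope`, `intercept`, `noise_sd`.
#' @param f_range Range for the uniform R-loop fraction draw.
#' @param width_median,width_sdlog Peak-width parameters.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return List with `tf_sets` (named list of peak tibbles, `TF001...`) and
#'   `ledger` (per-protein tibble incl. membership list-columns).
#' @export
make_tf_sets <- function(rloop, g4, chrom_sizes, n_proteins = 50,
                         n_peaks = 500,
                         relation = list(slope = 0.8, intercept = 0.05,
                                         noise_sd = 0.05),
                         f_range = c(0.05, 0.9), width_median = 300,
                         width_sdlog = 0.35, seed = NULL) {
  rloop <- validate_peaks(rloop, "rloop")
  g4 <- validate_peaks(g4, "g4")
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  n_proteins <- pc_stopifnot_scalar_count(n_proteins, "n_proteins", min = 1L)
  n_peaks <- pc_stopifnot_scalar_count(n_peaks, "n_peaks", min = 20L)
  if (!is.null(seed)) set.seed(seed)

  r_regions <- regions_reduce(rloop)
  g_regions <- regions_reduce(g4)
  both_regions <- regions_intersect(r_regions, g_regions)
  r_only_regions <- regions_setdiff(r_regions, g_regions)
  g_only_regions <- regions_setdiff(g_regions, r_regions)
  free_regions <- regions_setdiff(genome_regions(chrom_sizes),
                                  bind_rows(r_regions, g_regions))

  proteins <- sprintf("TF%03d", seq_len(n_proteins))
  f_r <- runif(n_proteins, f_range[1], f_range[2])
  f_g_noiseless <- pmin(pmax(relation$slope * f_r + relation$intercept, 0), 1)
  f_g <- pmin(pmax(f_g_noiseless + rnorm(n_proteins, 0, relation$noise_sd), 0), 1)

  tf_sets <- vector("list", n_proteins)
  names(tf_sets) <- proteins
  ledger_rows <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    k_r <- as.integer(round(n_peaks * f_r[i]))
    k_g <- as.integer(round(n_peaks * f_g[i]))
    members_r <- sort(sample.int(n_peaks, k_r))
    members_g <- sort(sample.int(n_peaks, k_g))
    in_r <- seq_len(n_peaks) %in% members_r
    in_g <- seq_len(n_peaks) %in% members_g
    cls <- ifelse(in_r & in_g, "both",
                  ifelse(in_r, "r_only", ifelse(in_g, "g_only", "none")))
    need <- table(factor(cls, levels = c("both", "r_only", "g_only", "none")))
    feasible <- c(both = nrow(both_regions) > 0 || need[["both"]] == 0,
                  r_only = nrow(r_only_regions) > 0 || need[["r_only"]] == 0,
                  g_only = nrow(g_only_regions) > 0 || need[["g_only"]] == 0,
                  none = nrow(free_regions) > 0 || need[["none"]] == 0)
    if (!all(feasible)) {
      pc_abort(sprintf("protein %s: planted overlap targets infeasible (no %s space).",
                       proteins[i], names(feasible)[!feasible][1]),
               class = "peakcoloc_data_error")
    }
    placed <- tibble(chrom = character(n_peaks), start = integer(n_peaks),
                     end = integer(n_peaks))
    for (class_name in names(need)) {
      ix <- which(cls == class_name)
      if (!length(ix)) next
      reg <- switch(class_name, both = both_regions, r_only = r_only_regions,
                    g_only = g_only_regions, none = free_regions)
      p <- place_in_regions(reg, length(ix),
                            sample_peak_widths(length(ix), width_median,
                                               width_sdlog),
                            what = sprintf("%s peaks for %s", class_name,
                                           proteins[i]))
      placed[ix, ] <- p
    }
    pk <- new_peaks(placed$chrom, placed$start, placed$end,
                    name = sprintf("%s_%04d", proteins[i], seq_len(n_peaks)),
                    score = rep(0, n_peaks),
                    summit = (placed$end - placed$start) %/% 2L)
    # engine-backed verification of the planting
    got_r <- overlap_membership(pk, rloop)
    got_g <- overlap_membership(pk, g4)
    if (sum(got_r) != k_r || sum(got_g) != k_g ||
          !identical(which(got_r), members_r) ||
          !identical(which(got_g), members_g)) {
      pc_abort(sprintf("internal planting error for %s.", proteins[i]),
               class = "peakcoloc_internal_error")
    }
    tf_sets[[i]] <- pk
    ledger_rows[[i]] <- tibble(
      protein = proteins[i], n_peaks = n_peaks,
      f_rloop = f_r[i], f_g4 = f_g[i], f_g4_noiseless = f_g_noiseless[i],
      n_rloop = k_r, n_g4 = k_g, n_both = sum(in_r & in_g),
      members_rloop = list(members_r), members_g4 = list(members_g)
    )
  }
  list(tf_sets = tf_sets, ledger = bind_rows(ledger_rows))
}

#' Coverage track with planted Gaussian bumps and region plateaus
#'
#' Builds a binned track: `background` everywhere, plus a Gaussian bump of
#' the given amplitude and width at every anchor position, plus optional
#' per-region plateau levels, plus Gaussian noise truncated at zero (the
#' default background keeps truncation negligible). The bump is evaluated at
#' each bin midpoint. The exact noiseless track is returned alongside as the
#' ground truth.
#'
#' @param anchors Tibble with `chrom` and `pos` (e.g. peak centers).
#' @param chrom_sizes chrom.sizes tibble.
#' @param amplitude,sigma Bump height and standard deviation (bp).
#' @param background Constant baseline level.
#' @param noise_sd Standard deviation of additive noise (0 for none).
#' @param bin Track step size in bp.
#' @param region_levels Optional tibble `chrom`,`start`,`end`,`level` of
#'   plateaus added where the bin midpoint falls inside the region.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return List with `track` (noisy) and `truth` (noiseless) track tibbles.
#' @export
make_coverage <- function(anchors, chrom_sizes, amplitude = 10, sigma = 150,
                          background = 5, noise_sd = 1, bin = 50,
                          region_levels = NULL, seed = NULL) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  bin <- pc_stopifnot_scalar_count(bin, "bin", min = 1L)
  if (amplitude < 0 || background < 0 || noise_sd < 0 || sigma <= 0) {
    pc_abort("amplitude/background/noise_sd must be >= 0 and sigma > 0.",
             class = "peakcoloc_usage_error")
  }
  if (!is.null(seed)) set.seed(seed)
  bins <- map_dfr(seq_len(nrow(chrom_sizes)), function(i) {
    size <- chrom_sizes$size[i]
    starts <- seq(0L, size - 1L, by = bin)
    tibble(chrom = chrom_sizes$chrom[i], start = as.integer(starts),
           end = as.integer(pmin(starts + bin, size)))
  })
  mid <- (bins$start + bins$end) / 2
  signal <- rep(background, nrow(bins))
  if (!is.null(anchors) && nrow(anchors)) {
    by_chrom <- split(seq_len(nrow(bins)), bins$chrom)
    # beyond 8 sigma the bump is < 1.5e-13 of the amplitude: negligible
    # against any stated agreement tolerance
    reach <- 8 * sigma
    for (j in seq_len(nrow(anchors))) {
      ix <- by_chrom[[anchors$chrom[j]]]
      if (is.null(ix)) next
      pos <- anchors$pos[j]
      lo <- findInterval(pos - reach, bins$start[ix])
      hi <- findInterval(pos + reach, bins$start[ix])
      sel <- ix[max(lo, 1L):max(hi, 1L)]
      signal[sel] <- signal[sel] +
        amplitude * exp(-((mid[sel] - pos)^2) / (2 * sigma^2))
    }
  }
  if (!is.null(region_levels) && nrow(region_levels)) {
    pts <- tibble(chrom = bins$chrom, start = as.integer(floor(mid)),
                  end = as.integer(floor(mid)) + 1L)
    hits <- find_hits(pts, region_levels)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    add <- rowsum(region_levels$level[s], group = q, reorder = TRUE)
    signal[as.integer(rownames(add))] <- signal[as.integer(rownames(add))] +
      add[, 1]
  }
  truth <- bins
  truth$value <- signal
  noisy <- bins
  noisy$value <- if (noise_sd > 0) {
    pmax(signal + rnorm(length(signal), 0, noise_sd), 0)
  } else {
    signal
  }
  list(track = validate_track(noisy, chrom_sizes),
       truth = validate_track(truth, chrom_sizes))
}
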