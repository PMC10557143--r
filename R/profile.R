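# Signal profiles over a step-function coverage track: peak-center
# aggregation curves, scaled-gene metagene curves, per-region densities and
# RPKM-style normalization. Bin values are length-weighted means of the step
# function over the bin (gaps count as 0), which makes a constant track give
# a constant curve for any bin size.

#' Anchor position of a peak
#'
#' The called summit (`start + summit`) when a summit offset is defined,
#' otherwise the midpoint `floor((start + end) / 2)`.
#'
#' @param peaks Peak tibble.
#' @return Integer vector of positions, one per peak.
#' @export
peak_center <- function(peaks) {
  peaks <- validate_peaks(peaks)
  as.integer(ifelse(peaks$summit >= 0L,
                    peaks$start + peaks$summit,
                    (peaks$start + peaks$end) %/% 2L))
}

#' Total signal carried by a coverage track
#'
#' The integral of the step function: sum of value x step width.
#'
#' @param track A track tibble.
#' @return A single number.
#' @export
track_total_signal <- function(track) {
  track <- validate_track(track)
  sum(track$value * (track$end - track$start))
}

# Length-weighted mean of the track over each bin (chrom/start/end rows).
# Gaps in the track count as value 0; denominator is the full bin width.
track_bin_means <- function(track, bins) {
  vals <- numeric(nrow(bins))
  if (!nrow(track) || !nrow(bins)) return(vals)
  hits <- find_hits(bins, track)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    w <- pmin(bins$end[q], track$end[s]) - pmax(bins$start[q], track$start[s])
    contrib <- rowsum(track$value[s] * w, group = q, reorder = TRUE)
    vals[as.integer(rownames(contrib))] <- contrib[, 1]
  }
  vals / (bins$end - bins$start)
}

# Sum (not mean) of signal over each bin.
track_bin_sums <- function(track, bins) {
  track_bin_means(track, bins) * (bins$end - bins$start)
}

#' Aggregation profile around anchor positions
#'
#' Tiles `[center - window, center + window)` around each anchor into
#' fixed-size bins and records the length-weighted mean track signal per
#' bin; the aggregation curve is the per-bin mean over anchors. Anchors
#' whose window extends past a chromosome end are dropped entirely (and
#' counted) rather than zero-padded, to avoid edge bias in the mean.
#'
#' @param track A coverage track tibble.
#' @param anchors Either a peak tibble (anchored at [peak_center()]) or a
#'   tibble with `chrom` and `pos` columns.
#' @param chrom_sizes chrom.sizes tibble; anchors on unknown chromosomes are
#'   an error.
#' @param window Half-window in bp on either side of the anchor.
#' @param bin_size Bin width in bp; must divide `window`.
#' @return A `profile_matrix`: the anchors x bins value matrix, the mean
#'   curve, bin offsets relative to the anchor, and the dropped-anchor count.
#' @export
aggregate_profile <- function(track, anchors, chrom_sizes,
                              window = 2000, bin_size = 50) {
  track <- validate_track(track)
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  window <- pc_stopifnot_scalar_count(window, "window", min = 1L)
  bin_size <- pc_stopifnot_scalar_count(bin_size, "bin_size", min = 1L)
  if (window %% bin_size != 0L) {
    pc_abort("`window` must be divisible by `bin_size`.",
             class = "peakcoloc_usage_error")
  }
  if (all(c("chrom", "pos") %in% names(anchors))) {
    pos <- as.integer(anchors$pos)
    chrom <- as.character(anchors$chrom)
  } else {
    anchors <- validate_peaks(anchors, "anchors")
    pos <- peak_center(anchors)
    chrom <- anchors$chrom
  }
  unknown <- setdiff(unique(chrom), chrom_sizes$chrom)
  if (length(unknown)) {
    pc_abort(sprintf("anchors on unknown chromosome(s): %s",
                     paste(unknown, collapse = ", ")),
             class = "peakcoloc_data_error")
  }
  sz <- setNames(chrom_sizes$size, chrom_sizes$chrom)
  usable <- pos - window >= 0L & pos + window <= sz[chrom]
  n_dropped <- sum(!usable)
  if (!any(usable)) {
    pc_abort("no anchor window fits inside its chromosome.",
             class = "peakcoloc_data_error")
  }
  pos <- pos[usable]
  chrom <- chrom[usable]
  n_anchors <- length(pos)
  n_bins <- 2L * window %/% bin_size
  offs <- seq(-window, window - bin_size, by = bin_size)
  bins <- tibble(
    chrom = rep(chrom, each = n_bins),
    start = rep(pos, each = n_bins) + rep(offs, times = n_anchors),
    end = rep(pos, each = n_bins) + rep(offs + bin_size, times = n_anchors)
  )
  values <- matrix(track_bin_means(track, bins), nrow = n_anchors,
                   ncol = n_bins, byrow = TRUE)
  structure(
    list(
      values = values,
      mean_curve = colMeans(values),
      bin_offset = offs + bin_size / 2,
      window = window,
      bin_size = bin_size,
      n_anchors = n_anchors,
      n_dropped = n_dropped
    ),
    class = "profile_matrix"
  )
}

#' Scaled-gene metagene profile
#'
#' Computes the mean signal curve over genes after dividing each gene body
#' into `body_bins` equal-length coordinate slices, flanked by fixed-size
#' bins of `flank_bin` bp covering `flank` bp upstream of the TSS and
#' downstream of the TES. Minus-strand genes are reversed before averaging
#' so the position axis runs TSS to TES for every gene. Genes shorter than
#' `body_bins` bp, or whose flanks leave the chromosome, are dropped and
#' counted.
#'
#' @param track A coverage track tibble.
#' @param genes Gene-model tibble.
#' @param chrom_sizes chrom.sizes tibble.
#' @param flank Flank extent in bp; must be divisible by `flank_bin`.
#' @param body_bins Number of body slices.
#' @param flank_bin Flank bin width in bp.
#' @return A `metagene_profile`: genes x bins matrix, mean curve, the bin
#'   axis (upstream / body / downstream), and the dropped-gene count.
#' @export
metagene_profile <- function(track, genes, chrom_sizes,
                             flank = 2000, body_bins = 100, flank_bin = 50) {
  track <- validate_track(track)
  genes <- validate_genes(genes)
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  flank <- pc_stopifnot_scalar_count(flank, "flank", min = 1L)
  body_bins <- pc_stopifnot_scalar_count(body_bins, "body_bins", min = 1L)
  flank_bin <- pc_stopifnot_scalar_count(flank_bin, "flank_bin", min = 1L)
  if (flank %% flank_bin != 0L) {
    pc_abort("`flank` must be divisible by `flank_bin`.",
             class = "peakcoloc_usage_error")
  }
  sz <- setNames(chrom_sizes$size, chrom_sizes$chrom)
  unknown <- setdiff(unique(genes$chrom), names(sz))
  if (length(unknown)) {
    pc_abort(sprintf("genes on unknown chromosome(s): %s",
                     paste(unknown, collapse = ", ")),
             class = "peakcoloc_data_error")
  }
  len <- genes$end - genes$start
  usable <- len >= body_bins & genes$start - flank >= 0L &
    genes$end + flank <= sz[genes$chrom]
  n_dropped <- sum(!usable)
  genes <- genes[usable, , drop = FALSE]
  if (!nrow(genes)) {
    pc_abort("no usable genes for the metagene profile.",
             class = "peakcoloc_data_error")
  }
  n_flank <- flank %/% flank_bin
  n_bins <- 2L * n_flank + body_bins
  # breakpoints per gene, genomic left-to-right
  breaks <- lapply(seq_len(nrow(genes)), function(i) {
    s <- genes$start[i]; e <- genes$end[i]; L <- e - s
    c(seq(s - flank, s, by = flank_bin),
      s + floor(seq_len(body_bins - 1L) * (L / body_bins)),
      seq(e, e + flank, by = flank_bin))
  })
  bins <- tibble(
    chrom = rep(genes$chrom, each = n_bins),
    start = unlist(lapply(breaks, function(b) b[-length(b)])),
    end = unlist(lapply(breaks, function(b) b[-1]))
  )
  values <- matrix(track_bin_means(track, bins), nrow = nrow(genes),
                   ncol = n_bins, byrow = TRUE)
  minus <- genes$strand == "-"
  if (any(minus)) {
    values[minus, ] <- values[minus, rev(seq_len(n_bins)), drop = FALSE]
  }
  structure(
    list(
      values = values,
      mean_curve = colMeans(values),
      segment = rep(c("upstream", "body", "downstream"),
                    times = c(n_flank, body_bins, n_flank)),
      flank = flank,
      body_bins = body_bins,
      flank_bin = flank_bin,
      n_genes = nrow(genes),
      n_dropped = n_dropped,
      gene_id = genes$gene_id
    ),
    class = "metagene_profile"
  )
}

#' Signal density of genomic regions
#'
#' Depth- and length-normalized density per region:
#' (signal in region) / (region length in kb) / (total signal / 1e6).
#'
#' @param track A coverage track tibble.
#' @param regions Tibble with `region_id`, `class`, `chrom`, `start`, `end`.
#' @param total_signal Positive library-size denominator; defaults to
#'   [track_total_signal()] of `track`.
#' @return Tibble with `region_id`, `class`, `length_bp`, `signal`,
#'   `density`.
#' @export
region_density <- function(track, regions, total_signal = NULL) {
  track <- validate_track(track)
  need <- c("region_id", "class", "chrom", "start", "end")
  if (!is.data.frame(regions) || !all(need %in% names(regions))) {
    pc_abort("`regions` must have region_id/class/chrom/start/end columns.",
             class = "peakcoloc_usage_error")
  }
  regions <- as_tibble(regions)
  if (any(regions$start >= regions$end)) {
    pc_abort("`regions` must have start < end.", class = "peakcoloc_data_error")
  }
  total_signal <- total_signal %||% track_total_signal(track)
  if (!is.numeric(total_signal) || length(total_signal) != 1L ||
        !is.finite(total_signal) || total_signal <= 0) {
    pc_abort("`total_signal` must be a single positive number.",
             class = "peakcoloc_usage_error")
  }
  sig <- track_bin_sums(track, regions)
  len <- regions$end - regions$start
  tibble(
    region_id = regions$region_id,
    class = regions$class,
    length_bp = as.integer(len),
    signal = sig,
    density = sig / (len / 1000) / (total_signal / 1e6)
  )
}

#' RPKM-normalized coverage from read intervals
#'
#' Tiles every chromosome into fixed-size bins and assigns each bin
#' (reads overlapping the bin) / (bin width in kb) / (total reads / 1e6) —
#' reads-per-kilobase-per-million coverage normalization. The last bin of a
#' chromosome may be shorter; its own width is used.
#'
#' @param reads Tibble of read intervals (`chrom`, `start`, `end`);
#'   must be non-empty.
#' @param bin_size Bin width in bp.
#' @param chrom_sizes chrom.sizes tibble.
#' @return A coverage track tibble covering the whole genome (zero bins
#'   included).
#' @export
rpkm_normalize <- function(reads, bin_size, chrom_sizes) {
  reads <- validate_peaks(reads, "reads")
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  bin_size <- pc_stopifnot_scalar_count(bin_size, "bin_size", min = 1L)
  if (!nrow(reads)) {
    pc_abort("RPKM normalization needs at least one read.",
             class = "peakcoloc_usage_error")
  }
  n_total <- nrow(reads)
  bins <- map_dfr(seq_len(nrow(chrom_sizes)), function(i) {
    size <- chrom_sizes$size[i]
    starts <- seq(0L, size - 1L, by = bin_size)
    tibble(chrom = chrom_sizes$chrom[i], start = as.integer(starts),
           end = as.integer(pmin(starts + bin_size, size)))
  })
  hits <- find_hits(bins, reads)
  counts <- tabulate(S4Vectors::queryHits(hits), nbins = nrow(bins))
  bins$value <- counts / ((bins$end - bins$start) / 1000) / (n_total / 1e6)
  bins
}

# --- result-object methods --------------------------------------------------

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf(
    "# Aggregation profile: %d anchors (%d dropped), %d bins of %d bp over +/- %d bp\n",
    x$n_anchors, x$n_dropped, length(x$mean_curve), x$bin_size, x$window))
  cat(sprintf("# peak mean signal %.4g at offset %+d bp\n",
              max(x$mean_curve), as.integer(x$bin_offset[which.max(x$mean_curve)])))
  invisible(x)
}

#' Tidy an aggregation profile
#' @param x A `profile_matrix`.
#' @param ... Unused.
#' @return Tibble with `bin`, `offset` (bp from anchor, bin midpoint) and
#'   `mean_signal`.
#' @export
tidy.profile_matrix <- function(x, ...) {
  tibble(bin = seq_along(x$mean_curve), offset = x$bin_offset,
         mean_signal = x$mean_curve)
}

#' One-row summary of an aggregation profile
#' @param x A `profile_matrix`.
#' @param ... Unused.
#' @return Tibble with anchor counts, the curve maximum and its offset.
#' @export
glance.profile_matrix <- function(x, ...) {
  tibble(
    n_anchors = x$n_anchors,
    n_dropped = x$n_dropped,
    max_signal = max(x$mean_curve),
    max_offset = x$bin_offset[which.max(x$mean_curve)]
  )
}

#' Plot an aggregation profile
#' @param object A `profile_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.profile_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$offset, y = .data$mean_signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "distance from anchor (bp)", y = "mean signal",
                  title = sprintf("Aggregation profile (%d anchors)", object$n_anchors)) +
    ggplot2::theme_minimal()
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf(
    "# Metagene profile: %d genes (%d dropped); %d flank bins x2 + %d body bins\n",
    x$n_genes, x$n_dropped, sum(x$segment == "upstream"), x$body_bins))
  invisible(x)
}

#' Tidy a metagene profile
#' @param x A `metagene_profile`.
#' @param ... Unused.
#' @return Tibble with `bin`, `segment` (upstream/body/downstream) and
#'   `mean_signal`.
#' @export
tidy.metagene_profile <- function(x, ...) {
  tibble(bin = seq_along(x$mean_curve), segment = x$segment,
         mean_signal = x$mean_curve)
}

#' One-row summary of a metagene profile
#' @param x A `metagene_profile`.
#' @param ... Unused.
#' @return Tibble with gene counts and mean signal per segment.
#' @export
glance.metagene_profile <- function(x, ...) {
  seg_mean <- tapply(x$mean_curve, x$segment, mean)
  tibble(
    n_genes = x$n_genes,
    n_dropped = x$n_dropped,
    upstream_mean = unname(seg_mean["upstream"]),
    body_mean = unname(seg_mean["body"]),
    downstream_mean = unname(seg_mean["downstream"])
  )
}

#' Plot a metagene profile
#' @param object A `metagene_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  d <- tidy(object)
  n_flank <- sum(object$segment == "upstream")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$mean_signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(n_flank + 0.5, n_flank + object$body_bins + 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "TSS -> TES (scaled gene body with flanks)",
                  y = "mean signal",
                  title = sprintf("Metagene profile (%d genes)", object$n_genes)) +
    ggplot2::theme_minimal()
}
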