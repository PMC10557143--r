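# Internal helpers shared across modules.
#
# Canonical tibble shapes (all coordinates 0-based half-open, BED convention):
#   peaks:       chrom <chr>, start <int>, end <int>, name <chr>,
#                score <dbl>, summit <int>   (offset from start; -1 = unset)
#   genes:       chrom <chr>, start <int>, end <int>, gene_id <chr>,
#                score <dbl>, strand <chr in {+,-}>
#   chrom_sizes: chrom <chr>, size <int>
#   track:       chrom <chr>, start <int>, end <int>, value <dbl>
#                (sorted, non-overlapping per chromosome; gaps mean 0)

pc_abort <- function(msg, class = "peakcoloc_error", ...) {
  abort(msg, class = c(class, "peakcoloc_error"), ...)
}

pc_stopifnot_scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    pc_abort(sprintf("`%s` must be a single integer >= %d.", name, min),
             class = "peakcoloc_usage_error")
  }
  as.integer(x)
}

new_peaks <- function(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), summit = integer()) {
  tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = if (length(name)) as.character(name) else rep(".", length(chrom)),
    score = if (length(score)) as.numeric(score) else rep(0, length(chrom)),
    summit = if (length(summit)) as.integer(summit) else rep(-1L, length(chrom))
  )
}

validate_peaks <- function(peaks, arg = "peaks") {
  need <- c("chrom", "start", "end")
  if (!is.data.frame(peaks) || !all(need %in% names(peaks))) {
    pc_abort(sprintf("`%s` must be a data frame with chrom/start/end columns.", arg),
             class = "peakcoloc_usage_error")
  }
  peaks <- as_tibble(peaks)
  if (!"name" %in% names(peaks)) peaks$name <- "."
  if (!"score" %in% names(peaks)) peaks$score <- 0
  if (!"summit" %in% names(peaks)) peaks$summit <- -1L
  peaks$start <- as.integer(peaks$start)
  peaks$end <- as.integer(peaks$end)
  peaks$summit <- as.integer(peaks$summit)
  if (nrow(peaks)) {
    bad <- which(is.na(peaks$start) | is.na(peaks$end) | peaks$start < 0L |
                   peaks$start >= peaks$end)
    if (length(bad)) {
      pc_abort(sprintf("`%s`: invalid interval at row %d (need 0 <= start < end).",
                       arg, bad[1]), class = "peakcoloc_data_error")
    }
    w <- peaks$end - peaks$start
    bad <- which(!(peaks$summit == -1L | (peaks$summit >= 0L & peaks$summit < w)))
    if (length(bad)) {
      pc_abort(sprintf("`%s`: summit offset out of range at row %d.", arg, bad[1]),
               class = "peakcoloc_data_error")
    }
  }
  peaks
}

validate_genes <- function(genes, arg = "genes") {
  need <- c("chrom", "start", "end", "gene_id", "strand")
  if (!is.data.frame(genes) || !all(need %in% names(genes))) {
    pc_abort(sprintf("`%s` must have chrom/start/end/gene_id/strand columns.", arg),
             class = "peakcoloc_usage_error")
  }
  genes <- as_tibble(genes)
  if (!"score" %in% names(genes)) genes$score <- 0
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (nrow(genes)) {
    bad <- which(is.na(genes$start) | is.na(genes$end) | genes$start < 0L |
                   genes$start >= genes$end)
    if (length(bad)) {
      pc_abort(sprintf("`%s`: invalid transcript span at row %d.", arg, bad[1]),
               class = "peakcoloc_data_error")
    }
    bad <- which(!genes$strand %in% c("+", "-"))
    if (length(bad)) {
      pc_abort(sprintf("`%s`: strand must be '+' or '-' at row %d.", arg, bad[1]),
               class = "peakcoloc_data_error")
    }
  }
  genes[c("chrom", "start", "end", "gene_id", "score", "strand")]
}

validate_chrom_sizes <- function(chrom_sizes, arg = "chrom_sizes") {
  if (!is.data.frame(chrom_sizes) || !all(c("chrom", "size") %in% names(chrom_sizes))) {
    pc_abort(sprintf("`%s` must be a data frame with chrom and size columns.", arg),
             class = "peakcoloc_usage_error")
  }
  chrom_sizes <- as_tibble(chrom_sizes)
  chrom_sizes$size <- as.numeric(chrom_sizes$size)
  if (anyDuplicated(chrom_sizes$chrom)) {
    pc_abort(sprintf("`%s`: duplicate chromosome name '%s'.", arg,
                     chrom_sizes$chrom[duplicated(chrom_sizes$chrom)][1]),
             class = "peakcoloc_data_error")
  }
  if (nrow(chrom_sizes) && any(is.na(chrom_sizes$size) | chrom_sizes$size <= 0)) {
    pc_abort(sprintf("`%s`: chromosome lengths must be positive.", arg),
             class = "peakcoloc_data_error")
  }
  chrom_sizes
}

validate_track <- function(track, chrom_sizes = NULL, arg = "track") {
  need <- c("chrom", "start", "end", "value")
  if (!is.data.frame(track) || !all(need %in% names(track))) {
    pc_abort(sprintf("`%s` must have chrom/start/end/value columns.", arg),
             class = "peakcoloc_usage_error")
  }
  track <- as_tibble(track)[need]
  track$start <- as.integer(track$start)
  track$end <- as.integer(track$end)
  track$value <- as.numeric(track$value)
  if (nrow(track)) {
    if (any(is.na(track$start) | is.na(track$end) | track$start < 0L |
              track$start >= track$end)) {
      pc_abort(sprintf("`%s`: steps must satisfy 0 <= start < end.", arg),
               class = "peakcoloc_data_error")
    }
    if (any(!is.finite(track$value) | track$value < 0)) {
      pc_abort(sprintf("`%s`: step values must be finite and >= 0.", arg),
               class = "peakcoloc_data_error")
    }
    track <- arrange(track, .data$chrom, .data$start)
    same <- track$chrom[-1] == track$chrom[-nrow(track)]
    if (nrow(track) > 1 && any(same & track$start[-1] < track$end[-nrow(track)])) {
      i <- which(same & track$start[-1] < track$end[-nrow(track)])[1] + 1L
      pc_abort(sprintf("`%s`: overlapping steps on %s near position %d.",
                       arg, track$chrom[i], track$start[i]),
               class = "peakcoloc_data_error")
    }
    if (!is.null(chrom_sizes)) {
      chrom_sizes <- validate_chrom_sizes(chrom_sizes)
      sz <- setNames(chrom_sizes$size, chrom_sizes$chrom)
      unk <- setdiff(unique(track$chrom), names(sz))
      if (length(unk)) {
        pc_abort(sprintf("`%s`: unknown chromosome '%s'.", arg, unk[1]),
                 class = "peakcoloc_data_error")
      }
      if (any(track$end > sz[track$chrom])) {
        pc_abort(sprintf("`%s`: step beyond chromosome end.", arg),
                 class = "peakcoloc_data_error")
      }
    }
  }
  track
}

# 0-based half-open tibble -> 1-based closed GRanges
regions_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

gr_to_regions <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Region set algebra on 0-based half-open tibbles, via GenomicRanges.
regions_reduce <- function(x) {
  if (!nrow(x)) return(tibble(chrom = character(), start = integer(), end = integer()))
  gr_to_regions(GenomicRanges::reduce(regions_to_gr(x)))
}

# Overlap hits between two 0-based half-open tables, on a shared seqlevel
# universe (avoids spurious warnings when chromosome sets differ).
find_hits <- function(a, b) {
  lv <- union(unique(a$chrom), unique(b$chrom))
  gra <- GenomicRanges::GRanges(
    seqnames = factor(a$chrom, levels = lv),
    ranges = IRanges::IRanges(start = a$start + 1L, end = a$end))
  grb <- GenomicRanges::GRanges(
    seqnames = factor(b$chrom, levels = lv),
    ranges = IRanges::IRanges(start = b$start + 1L, end = b$end))
  GenomicRanges::findOverlaps(gra, grb)
}

# Put two region sets on a shared seqlevel universe so GRanges set ops work.
aligned_gr_pair <- function(x, y) {
  lv <- union(unique(x$chrom), unique(y$chrom))
  mk <- function(d) GenomicRanges::GRanges(
    seqnames = factor(d$chrom, levels = lv),
    ranges = IRanges::IRanges(start = d$start + 1L, end = d$end)
  )
  list(x = GenomicRanges::reduce(mk(x)), y = GenomicRanges::reduce(mk(y)))
}

regions_setdiff <- function(x, y) {
  if (!nrow(x)) return(tibble(chrom = character(), start = integer(), end = integer()))
  if (!nrow(y)) return(regions_reduce(x))
  p <- aligned_gr_pair(x, y)
  gr_to_regions(GenomicRanges::setdiff(p$x, p$y))
}

regions_intersect <- function(x, y) {
  if (!nrow(x) || !nrow(y)) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  p <- aligned_gr_pair(x, y)
  gr_to_regions(GenomicRanges::intersect(p$x, p$y))
}

genome_regions <- function(chrom_sizes) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  tibble(chrom = chrom_sizes$chrom, start = 0L, end = as.integer(chrom_sizes$size))
}
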