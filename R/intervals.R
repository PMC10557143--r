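# Interval-overlap engine. Two intervals overlap iff they are on the same
# chromosome and share at least one base: a.start < b.end and b.start < a.end
# (0-based half-open, so abutting intervals do NOT overlap). Queries are
# backed by GenomicRanges::findOverlaps; tests check the engine against a
# brute-force all-pairs scan.

#' Do two genomic intervals overlap?
#'
#' Vectorized over rows; shorter input recycled if it has one row. Overlap
#' requires >= 1 shared base on the same chromosome, so intervals that merely
#' abut (`a$end == b$start`) do not overlap.
#'
#' @param a,b Data frames with `chrom`, `start`, `end` (0-based half-open).
#' @return Logical vector.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' b <- tibble::tibble(chrom = "chr1", start = 200, end = 300)
#' intervals_overlap(a, b)  # FALSE: half-open abutment
#' @export
intervals_overlap <- function(a, b) {
  a <- validate_peaks(a, "a")
  b <- validate_peaks(b, "b")
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), ]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), ]
  if (nrow(a) != nrow(b)) {
    pc_abort("`a` and `b` must have the same number of rows (or one row).",
             class = "peakcoloc_usage_error")
  }
  a$chrom == b$chrom & a$start < b$end & b$start < a$end
}

#' Which rows of `a` overlap at least one interval in `b`?
#'
#' @param a,b Data frames with `chrom`, `start`, `end`.
#' @return Logical vector along the rows of `a`.
#' @export
overlap_membership <- function(a, b) {
  a <- validate_peaks(a, "a")
  b <- validate_peaks(b, "b")
  if (!nrow(a)) return(logical())
  if (!nrow(b)) return(rep(FALSE, nrow(a)))
  hits <- find_hits(a, b)
  out <- rep(FALSE, nrow(a))
  out[S4Vectors::queryHits(hits)] <- TRUE
  out
}

#' Report-first/unique intersection of two peak sets
#'
#' Returns each peak of `a` at most once, in `a`'s input order, iff it
#' overlaps at least one peak of `b` — the record-level semantics of
#' `bedtools intersect -wa -u` with the default 1-bp minimum overlap.
#' Duplicate records in `a` are reported independently; no deduplication.
#'
#' @param a,b Peak tibbles.
#' @return The overlapping subset of `a`, order preserved.
#' @export
intersect_report_a <- function(a, b) {
  a <- validate_peaks(a, "a")
  a[overlap_membership(a, b), , drop = FALSE]
}

#' Three-way co-occupancy counts
#'
#' Classifies each peak of `a` by whether it overlaps the R-loop set and the
#' G4 set independently (report-first/unique semantics against each), and
#' counts the joint classes — the numbers behind a three-set Venn diagram of
#' binding-site co-occupancy.
#'
#' @param a Query peak tibble (e.g. one protein's ChIP-seq peaks).
#' @param rloop,g4 Structure peak tibbles.
#' @return A one-row tibble: `n_peaks`, `n_rloop`, `n_g4`, `n_both`.
#' @export
three_way_cooccupancy <- function(a, rloop, g4) {
  a <- validate_peaks(a, "a")
  in_r <- overlap_membership(a, rloop)
  in_g <- overlap_membership(a, g4)
  tibble(
    n_peaks = nrow(a),
    n_rloop = sum(in_r),
    n_g4 = sum(in_g),
    n_both = sum(in_r & in_g)
  )
}
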