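#' Read a peak file (BED3, BED6 or ENCODE narrowPeak)
#'
#' Parses tab-separated peak records into a peak tibble. All coordinates are
#' kept 0-based half-open exactly as stored in the file. Lines starting with
#' `#`, `track` or `browser` are skipped; the number skipped is attached as
#' the `n_skipped` attribute. Gzip-compressed files are read transparently.
#'
#' Dialects:
#' * `bed3` — three columns; `name` is filled with `"."`, `score` with 0 and
#'   the summit offset with -1 (undefined).
#' * `bed6` — six columns (name, score, strand); strand is ignored for peaks.
#' * `narrowPeak` — ENCODE ten-column format; column 10 is the summit offset
#'   from the peak start (-1 when not called). signalValue/pValue/qValue are
#'   parsed for validation but not retained.
#'
#' @param path Path to the file (optionally `.gz`).
#' @param dialect One of `"narrowPeak"`, `"bed6"`, `"bed3"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `summit`, one row per data line, in file order.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200", f)
#' read_peaks(f, dialect = "bed3")
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "bed6", "bed3")) {
  dialect <- rlang::arg_match(dialect)
  fields <- parse_tab_file(path, min_fields = switch(dialect,
    bed3 = 3L, bed6 = 6L, narrowPeak = 10L))
  if (!length(fields$rows)) {
    out <- new_peaks()
    attr(out, "n_skipped") <- fields$n_skipped
    return(out)
  }
  chrom <- vapply(fields$rows, `[[`, "", 1L)
  start <- parse_int_field(fields, 2L, "start")
  end <- parse_int_field(fields, 3L, "end")
  check_coords(start, end, fields$lineno)
  n <- length(chrom)
  name <- if (dialect == "bed3") rep(".", n) else vapply(fields$rows, `[[`, "", 4L)
  score <- if (dialect == "bed3") rep(0, n) else parse_num_field(fields, 5L, "score")
  summit <- rep(-1L, n)
  if (dialect == "narrowPeak") {
    summit <- parse_int_field(fields, 10L, "summit offset")
    bad <- which(!(summit == -1L | (summit >= 0L & summit < end - start)))
    if (length(bad)) {
      pc_abort(sprintf("line %d: summit offset %d outside peak of width %d.",
                       fields$lineno[bad[1]], summit[bad[1]],
                       end[bad[1]] - start[bad[1]]),
               class = "peakcoloc_parse_error")
    }
  }
  out <- new_peaks(chrom, start, end, name, score, summit)
  attr(out, "n_skipped") <- fields$n_skipped
  out
}

#' Write peaks to a BED3/BED6/narrowPeak file
#'
#' Canonical formatting: tab-separated, no header, one record per row in
#' table order, so `write_peaks()` then [read_peaks()] is the identity.
#'
#' @param peaks A peak tibble (see [read_peaks()]).
#' @param path Output path.
#' @param dialect Output dialect; narrowPeak writes strand `"."`,
#'   signalValue 0 and p/q-values -1.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, dialect = c("narrowPeak", "bed6", "bed3")) {
  dialect <- rlang::arg_match(dialect)
  peaks <- validate_peaks(peaks)
  lines <- switch(dialect,
    bed3 = paste(peaks$chrom, peaks$start, peaks$end, sep = "\t"),
    bed6 = paste(peaks$chrom, peaks$start, peaks$end, peaks$name,
                 as.character(peaks$score), ".", sep = "\t"),
    narrowPeak = paste(peaks$chrom, peaks$start, peaks$end, peaks$name,
                       as.character(peaks$score), ".", "0", "-1", "-1",
                       peaks$summit, sep = "\t")
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a chrom.sizes file
#'
#' Two tab-separated columns: chromosome name and length in bp. Duplicate
#' names and non-positive lengths are errors.
#'
#' @param path Path to the file.
#' @return A tibble with columns `chrom` and `size`, in file order.
#' @export
read_chrom_sizes <- function(path) {
  fields <- parse_tab_file(path, min_fields = 2L)
  if (!length(fields$rows)) return(tibble(chrom = character(), size = numeric()))
  chrom <- vapply(fields$rows, `[[`, "", 1L)
  size <- parse_num_field(fields, 2L, "length")
  bad <- which(is.na(size) | size <= 0 | size != floor(size))
  if (length(bad)) {
    pc_abort(sprintf("line %d: chromosome length must be a positive integer.",
                     fields$lineno[bad[1]]), class = "peakcoloc_parse_error")
  }
  dup <- which(duplicated(chrom))
  if (length(dup)) {
    pc_abort(sprintf("line %d: duplicate chromosome name '%s'.",
                     fields$lineno[dup[1]], chrom[dup[1]]),
             class = "peakcoloc_parse_error")
  }
  tibble(chrom = chrom, size = size)
}

#' Write a chrom.sizes file
#' @param chrom_sizes Tibble with `chrom` and `size` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  chrom_sizes <- validate_chrom_sizes(chrom_sizes)
  readr::write_lines(
    paste(chrom_sizes$chrom, format(chrom_sizes$size, scientific = FALSE, trim = TRUE),
          sep = "\t"), path)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Four tab-separated columns: chrom, start, end, value. Steps are sorted per
#' chromosome on return. Overlapping steps are an error — no silent merging.
#' Gaps between steps mean signal 0.
#'
#' @param path Path to the bedGraph file.
#' @param chrom_sizes Optional chrom.sizes tibble; when given, steps beyond
#'   chromosome bounds or on unknown chromosomes are errors.
#' @return A track tibble (`chrom`, `start`, `end`, `value`).
#' @export
read_bedgraph <- function(path, chrom_sizes = NULL) {
  fields <- parse_tab_file(path, min_fields = 4L)
  if (!length(fields$rows)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  value = numeric()))
  }
  chrom <- vapply(fields$rows, `[[`, "", 1L)
  start <- parse_int_field(fields, 2L, "start")
  end <- parse_int_field(fields, 3L, "end")
  check_coords(start, end, fields$lineno)
  value <- parse_num_field(fields, 4L, "value")
  bad <- which(!is.finite(value) | value < 0)
  if (length(bad)) {
    pc_abort(sprintf("line %d: step value must be finite and >= 0.",
                     fields$lineno[bad[1]]), class = "peakcoloc_parse_error")
  }
  validate_track(tibble(chrom = chrom, start = start, end = end, value = value),
                 chrom_sizes = chrom_sizes, arg = basename(path))
}

#' Write a bedGraph coverage track
#' @param track A track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  track <- validate_track(track)
  readr::write_lines(
    paste(track$chrom, track$start, track$end, as.character(track$value),
          sep = "\t"), path)
  invisible(path)
}

#' Read gene models from a BED6 file
#'
#' Columns 4/5/6 are gene_id/score/strand. Strand must be `+` or `-`:
#' strand-less records (`"."`) are an error because every downstream use
#' (promoter windows, metagene orientation) is strand-aware.
#'
#' @param path Path to the BED6 file.
#' @return A tibble with columns `chrom`, `start`, `end`, `gene_id`, `score`,
#'   `strand`, in file order.
#' @export
read_gene_models <- function(path) {
  fields <- parse_tab_file(path, min_fields = 6L)
  if (!length(fields$rows)) {
    return(validate_genes(tibble(chrom = character(), start = integer(),
                                 end = integer(), gene_id = character(),
                                 score = numeric(), strand = character())))
  }
  chrom <- vapply(fields$rows, `[[`, "", 1L)
  start <- parse_int_field(fields, 2L, "start")
  end <- parse_int_field(fields, 3L, "end")
  check_coords(start, end, fields$lineno)
  gene_id <- vapply(fields$rows, `[[`, "", 4L)
  score <- parse_num_field(fields, 5L, "score")
  strand <- vapply(fields$rows, `[[`, "", 6L)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    pc_abort(sprintf("line %d: strand must be '+' or '-', got '%s'.",
                     fields$lineno[bad[1]], strand[bad[1]]),
             class = "peakcoloc_parse_error")
  }
  tibble(chrom = chrom, start = start, end = end, gene_id = gene_id,
         score = score, strand = strand)
}

#' Write gene models to a BED6 file
#' @param genes A gene-model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  genes <- validate_genes(genes)
  readr::write_lines(
    paste(genes$chrom, genes$start, genes$end, genes$gene_id,
          as.character(genes$score), genes$strand, sep = "\t"), path)
  invisible(path)
}

#' Normalize chromosome-name style
#'
#' Chromosome names are matched as exact strings everywhere in the package;
#' a `"1"` vs `"chr1"` mismatch silently yields zero overlaps with upstream
#' tools, so any renaming is explicit through this helper.
#'
#' @param x A tibble with a `chrom` column.
#' @param action `"strip-chr"` removes a leading `"chr"`, `"add-chr"`
#'   prepends it where absent, `"none"` returns `x` unchanged.
#' @return `x` with `chrom` rewritten.
#' @export
normalize_chrom_names <- function(x, action = c("none", "strip-chr", "add-chr")) {
  action <- rlang::arg_match(action)
  if (action == "none") return(x)
  if (action == "strip-chr") {
    x$chrom <- sub("^chr", "", x$chrom)
  } else {
    no <- !startsWith(x$chrom, "chr")
    x$chrom[no] <- paste0("chr", x$chrom[no])
  }
  x
}

# --- low-level line parsing -------------------------------------------------

parse_tab_file <- function(path, min_fields) {
  if (!file.exists(path)) {
    pc_abort(sprintf("file not found: %s", path), class = "peakcoloc_usage_error")
  }
  lines <- readr::read_lines(path)
  keep <- !(startsWith(lines, "#") | startsWith(lines, "track") |
              startsWith(lines, "browser") | lines == "")
  lineno <- which(keep)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- which(lengths(rows) < min_fields)
  if (length(short)) {
    pc_abort(sprintf("line %d: expected >= %d tab-separated fields, got %d.",
                     lineno[short[1]], min_fields, lengths(rows)[short[1]]),
             class = "peakcoloc_parse_error")
  }
  list(rows = rows, lineno = lineno, n_skipped = sum(!keep & lines != ""))
}

parse_int_field <- function(fields, col, what) {
  raw <- vapply(fields$rows, `[[`, "", col)
  val <- suppressWarnings(as.integer(raw))
  bad <- which(is.na(val) | raw != as.character(val))
  if (length(bad)) {
    pc_abort(sprintf("line %d: %s '%s' is not an integer.",
                     fields$lineno[bad[1]], what, raw[bad[1]]),
             class = "peakcoloc_parse_error")
  }
  val
}

parse_num_field <- function(fields, col, what) {
  raw <- vapply(fields$rows, `[[`, "", col)
  val <- suppressWarnings(as.numeric(raw))
  val[raw == "."] <- 0
  bad <- which(is.na(val))
  if (length(bad)) {
    pc_abort(sprintf("line %d: %s '%s' is not numeric.",
                     fields$lineno[bad[1]], what, raw[bad[1]]),
             class = "peakcoloc_parse_error")
  }
  val
}

check_coords <- function(start, end, lineno) {
  bad <- which(start < 0L | start >= end)
  if (length(bad)) {
    pc_abort(sprintf("line %d: invalid interval [%d, %d) (need 0 <= start < end).",
                     lineno[bad[1]], start[bad[1]], end[bad[1]]),
             class = "peakcoloc_parse_error")
  }
  invisible(NULL)
}
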