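# Independent oracles and fixture builders. Everything here is deliberately
# naive (all-pairs scans, per-bin loops) and shares no code with the package
# internals it checks.

# Brute-force all-pairs overlap membership: row i of `a` is TRUE iff some row
# of `b` is on the same chromosome and shares >= 1 base.
oracle_membership <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & a$start[i] < b$end & b$start < a$end[i])
  }, logical(1))
}

oracle_intersect_report_a <- function(a, b) {
  a[oracle_membership(a, b), , drop = FALSE]
}

oracle_three_way <- function(a, r, g) {
  in_r <- oracle_membership(a, r)
  in_g <- oracle_membership(a, g)
  c(n_peaks = nrow(a), n_rloop = sum(in_r), n_g4 = sum(in_g),
    n_both = sum(in_r & in_g))
}

# Closed-form Pearson correlation from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Length-weighted mean of a step-function track over [a, b) on one
# chromosome, by direct scan; gaps count as zero.
oracle_bin_mean <- function(track, chrom, a, b) {
  t <- track[track$chrom == chrom & track$start < b & track$end > a, ,
             drop = FALSE]
  if (!nrow(t)) return(0)
  sum(t$value * (pmin(t$end, b) - pmax(t$start, a))) / (b - a)
}

# Random peak set on the given chromosomes.
random_peaks <- function(n, chroms = c("chrA", "chrB"), max_pos = 10000,
                         max_width = 300) {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start, end = start + width,
    name = sprintf("p%d", seq_len(n)), score = 0, summit = -1L
  )
}

# Tiny deterministic genome/gene fixture used across annotation and profile
# tests.
tiny_genome <- function() tibble::tibble(chrom = c("chrA", "chrB"),
                                         size = c(1e6, 1e6))

tiny_genes <- function() tibble::tibble(
  chrom = c("chrA", "chrA", "chrB"),
  start = c(10000L, 50000L, 20000L),
  end = c(20000L, 70000L, 40000L),
  gene_id = c("g1", "g2", "g3"),
  score = 0,
  strand = c("+", "-", "+")
)

# Step track that is constant at `value` across both tiny chromosomes.
constant_track <- function(value = 2.5, sizes = tiny_genome()) {
  tibble::tibble(chrom = sizes$chrom, start = 0L,
                 end = as.integer(sizes$size), value = value)
}
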