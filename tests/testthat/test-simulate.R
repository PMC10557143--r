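# Generator invariants: determinism, feasibility errors and exact planting.

test_that("toy genome is deterministic and validates its arguments", {
  g <- make_genome(2, 1e7)
  expect_equal(g$chrom, c("chrS1", "chrS2"))
  expect_equal(g$size, c(1e7, 1e7))
  expect_equal(make_genome(2, 1e7), g)
  expect_equal(nrow(make_genome(1, 1e5)), 1L)  # minimal genome accepted
  expect_error(make_genome(0, 1e7), class = "peakcoloc_usage_error")
  expect_error(make_genome(1, 100), class = "peakcoloc_usage_error")
})

test_that("generated genes are non-overlapping, sorted and seed-stable", {
  sizes <- make_genome(2, 1e6)
  genes <- make_genes(sizes, n = 60, len_range = c(2000, 6000), seed = 5)
  expect_equal(nrow(genes), 60L)
  # pairwise non-overlap by the oracle: each gene overlaps only itself
  for (i in seq_len(60)) {
    expect_equal(sum(oracle_membership(genes[i, ], genes)), 1L)
  }
  expect_true(all(genes$end - genes$start >= 2000))
  expect_true(!is.unsorted(order(genes$chrom, genes$start)))
  expect_equal(make_genes(sizes, n = 60, len_range = c(2000, 6000), seed = 5),
               genes)
  expect_equal(nrow(make_genes(sizes, n = 0)), 0L)
  expect_error(make_genes(sizes, n = 1000, len_range = c(5000, 5000)),
               class = "peakcoloc_usage_error")  # infeasible density
})

test_that("structure peaks realize planted promoter and co-occurrence fractions exactly", {
  sizes <- make_genome(2, 5e6)
  genes <- make_genes(sizes, n = 100, seed = 9)
  promoters <- promoter_regions(genes, 1000, 500, sizes)
  pk <- make_structure_peaks(promoters, sizes, n = 400, promoter_frac = 0.7,
                             seed = 10)
  expect_equal(promoter_fraction(pk, promoters), 70)
  expect_equal(attr(pk, "n_promoter"), 280L)

  # promoter_frac = 1: every peak overlaps some promoter window
  all_prom <- make_structure_peaks(promoters, sizes, n = 100,
                                   promoter_frac = 1, seed = 11)
  expect_equal(promoter_fraction(all_prom, promoters), 100)

  # co-occurrence planted exactly; non-co-occurring peaks avoid the target
  g4 <- make_structure_peaks(promoters, sizes, n = 400, promoter_frac = 0.7,
                             cooccur_with = pk, cooccur_frac = 0.4, seed = 12)
  expect_equal(sum(oracle_membership(g4, pk)), 160L)
  # rho = 0: zero overlap with the target set
  g0 <- make_structure_peaks(promoters, sizes, n = 200, promoter_frac = 0.5,
                             cooccur_with = pk, cooccur_frac = 0, seed = 13)
  expect_equal(sum(oracle_membership(g0, pk)), 0L)
  # determinism
  expect_equal(make_structure_peaks(promoters, sizes, n = 400,
                                    promoter_frac = 0.7, seed = 10), pk)
})

test_that("TF sets realize their planted overlap counts and memberships exactly", {
  sizes <- make_genome(2, 5e6)
  genes <- make_genes(sizes, n = 100, seed = 19)
  promoters <- promoter_regions(genes, 1000, 500, sizes)
  rloop <- make_structure_peaks(promoters, sizes, n = 300, promoter_frac = 0.7,
                                seed = 20)
  g4 <- make_structure_peaks(promoters, sizes, n = 300, promoter_frac = 0.7,
                             cooccur_with = rloop, cooccur_frac = 0.5, seed = 21)
  tf <- make_tf_sets(rloop, g4, sizes, n_proteins = 8, n_peaks = 60, seed = 22)
  expect_equal(names(tf$tf_sets), tf$ledger$protein)
  for (i in seq_len(8)) {
    got_r <- oracle_membership(tf$tf_sets[[i]], rloop)
    got_g <- oracle_membership(tf$tf_sets[[i]], g4)
    expect_equal(sum(got_r), tf$ledger$n_rloop[i])
    expect_equal(sum(got_g), tf$ledger$n_g4[i])
    expect_equal(which(got_r), tf$ledger$members_rloop[[i]])
    expect_equal(which(got_g), tf$ledger$members_g4[[i]])
    expect_equal(sum(got_r & got_g), tf$ledger$n_both[i])
  }
  tf2 <- make_tf_sets(rloop, g4, sizes, n_proteins = 8, n_peaks = 60, seed = 22)
  expect_equal(tf2$ledger$f_rloop, tf$ledger$f_rloop)
  expect_equal(tf2$tf_sets, tf$tf_sets)
})

test_that("noiseless coverage equals its analytic truth; noise keeps it non-negative", {
  sizes <- make_genome(1, 2e5)
  anchors <- tibble::tibble(chrom = "chrS1", pos = c(50000L, 120000L))
  cov <- make_coverage(anchors, sizes, amplitude = 10, sigma = 150,
                       background = 2, noise_sd = 0, bin = 50)
  expect_identical(cov$track, cov$truth)
  mid <- (cov$truth$start + cov$truth$end) / 2
  near <- which(abs(mid - 50000) < 600)
  expect_equal(cov$truth$value[near],
               2 + 10 * exp(-(mid[near] - 50000)^2 / (2 * 150^2)),
               tolerance = 1e-12)
  far <- which(abs(mid - 50000) > 2000 & abs(mid - 120000) > 2000)
  expect_equal(cov$truth$value[far], rep(2, length(far)))

  noisy <- make_coverage(anchors, sizes, amplitude = 0, sigma = 150,
                         background = 0.1, noise_sd = 1, bin = 50, seed = 30)
  expect_true(all(noisy$track$value >= 0))

  # plateau levels land where the bin midpoint falls inside the region
  lv <- tibble::tibble(chrom = "chrS1", start = 1000L, end = 2000L, level = 4)
  pl <- make_coverage(NULL, sizes, amplitude = 0, sigma = 1, background = 1,
                      noise_sd = 0, bin = 50, region_levels = lv)
  expect_equal(pl$truth$value[pl$truth$start %in% seq(1000, 1950, 50)],
               rep(5, 20))
  expect_equal(pl$truth$value[pl$truth$start == 2000], 1)
})

test_that("a written scenario is self-consistent, clean to re-read and seed-stable", {
  dir1 <- withr::local_tempdir()
  scen <- simulate_scenario(dir1, seed = 3, n_proteins = 4, n_peaks = 40,
                            n_genes = 40, n_structure = 120,
                            n_chroms = 1, chrom_length = 2e6)
  # emitted files are valid inputs with zero warnings and zero skipped lines
  expect_no_warning({
    rl <- read_peaks(scen$paths$rloop, "narrowPeak")
    gg <- read_gene_models(scen$paths$genes)
    cs <- read_chrom_sizes(scen$paths$chrom_sizes)
    tr <- read_bedgraph(scen$paths$coverage, cs)
  })
  expect_equal(attr(rl, "n_skipped"), 0L)
  expect_equal(nrow(rl), 120L)
  expect_equal(nrow(gg), 40L)

  # ledger counts reproduced end-to-end by the screen (independent re-run)
  tf_files <- list.files(scen$paths$tf_dir, full.names = TRUE)
  tf_sets <- setNames(lapply(tf_files, read_peaks, dialect = "narrowPeak"),
                      sub("\\.narrowPeak$", "", basename(tf_files)))
  tab <- run_screen(tf_sets, rl, read_peaks(scen$paths$g4, "narrowPeak"))
  led <- scen$ledger$proteins
  expect_equal(tab$n_rloop, led$n_rloop)
  expect_equal(tab$n_g4, led$n_g4)
  expect_equal(tab$n_both, led$n_both)

  # byte-identical regeneration from the same seed
  dir2 <- withr::local_tempdir()
  simulate_scenario(dir2, seed = 3, n_proteins = 4, n_peaks = 40,
                    n_genes = 40, n_structure = 120,
                    n_chroms = 1, chrom_length = 2e6)
  rel <- list.files(dir1, recursive = TRUE)
  expect_equal(rel, list.files(dir2, recursive = TRUE))
  for (f in rel) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})
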