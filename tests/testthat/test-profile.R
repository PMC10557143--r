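# Aggregation profiles, metagene curves, densities and RPKM normalization.

test_that("peak_center uses the summit when defined, else the floored midpoint", {
  p <- tibble::tibble(chrom = "chrA",
                      start = c(100L, 100L, 100L),
                      end = c(200L, 200L, 201L),
                      name = ".", score = 0,
                      summit = c(50L, -1L, -1L))
  expect_equal(peak_center(p), c(150L, 150L, 150L))
})

test_that("a constant track gives a flat aggregation profile at its level", {
  sizes <- tiny_genome()
  track <- constant_track(2.5)
  anchors <- tibble::tibble(chrom = "chrA", pos = c(10000L, 50000L, 200000L))
  prof <- aggregate_profile(track, anchors, sizes, window = 2000, bin_size = 50)
  expect_equal(prof$mean_curve, rep(2.5, 80))
  expect_equal(dim(prof$values), c(3L, 80L))
})

test_that("a rectangular bump covering the central bins is recovered exactly", {
  sizes <- tiny_genome()
  # bump of height 4 over [9900, 10100): exactly the two central 100-bp bins
  track <- tibble::tibble(chrom = "chrA", start = 9900L, end = 10100L, value = 4)
  anchors <- tibble::tibble(chrom = "chrA", pos = 10000L)
  prof <- aggregate_profile(track, anchors, sizes, window = 1000, bin_size = 100)
  expect_equal(prof$mean_curve[10:11], c(4, 4))
  expect_equal(prof$mean_curve[-(10:11)], rep(0, 18))
})

test_that("bin values equal the per-bin oracle and aggregation is linear", {
  sizes <- tiny_genome()
  withr::with_seed(51, {
    starts <- sort(sample.int(19000, 400)) * 10L
    x <- tibble::tibble(chrom = "chrA", start = starts, end = starts + 10L,
                        value = runif(400) * 5)
    y <- x
    y$value <- runif(400) * 2
    anchors <- tibble::tibble(chrom = "chrA", pos = sample(5000:150000, 20))
  })
  px <- aggregate_profile(x, anchors, sizes, window = 1000, bin_size = 50)
  # per-bin oracle on a few anchors
  for (i in c(1, 7, 20)) {
    for (j in c(1, 13, 40)) {
      a <- anchors$pos[i] - 1000 + (j - 1) * 50
      expect_equal(px$values[i, j], oracle_bin_mean(x, "chrA", a, a + 50),
                   tolerance = 1e-12)
    }
  }
  # linearity: profile(2x + 3y) = 2 profile(x) + 3 profile(y)
  py <- aggregate_profile(y, anchors, sizes, window = 1000, bin_size = 50)
  z <- x
  z$value <- 2 * x$value + 3 * y$value
  pz <- aggregate_profile(z, anchors, sizes, window = 1000, bin_size = 50)
  expect_equal(pz$mean_curve, 2 * px$mean_curve + 3 * py$mean_curve,
               tolerance = 1e-12)
  # permutation invariance of anchors (mean unchanged)
  pshuf <- aggregate_profile(x, anchors[20:1, ], sizes, window = 1000,
                             bin_size = 50)
  expect_equal(sort(pshuf$mean_curve), sort(px$mean_curve))
  expect_equal(pshuf$mean_curve, px$mean_curve)
})

test_that("out-of-bounds anchors are dropped and counted, never zero-padded", {
  sizes <- tiny_genome()
  track <- constant_track(1)
  anchors <- tibble::tibble(chrom = "chrA", pos = c(500L, 10000L, 999900L))
  prof <- aggregate_profile(track, anchors, sizes, window = 2000, bin_size = 50)
  expect_equal(prof$n_anchors, 1L)
  expect_equal(prof$n_dropped, 2L)
  expect_equal(prof$n_anchors + prof$n_dropped, 3L)
  expect_equal(prof$mean_curve, rep(1, 80))  # no zero dilution from edges
  expect_error(
    aggregate_profile(track, tibble::tibble(chrom = "chrA", pos = 100L),
                      sizes, window = 2000, bin_size = 50),
    class = "peakcoloc_data_error")
  expect_error(
    aggregate_profile(track, anchors, sizes, window = 2000, bin_size = 300),
    class = "peakcoloc_usage_error")
})

test_that("metagene of a constant track is flat and strand mirroring is exact", {
  sizes <- tibble::tibble(chrom = c("chrA", "chrB"), size = c(1e6, 1e6))
  track <- constant_track(3, sizes)
  genes <- tibble::tibble(chrom = "chrA", start = 100000L, end = 110000L,
                          gene_id = "g1", score = 0, strand = "+")
  m <- metagene_profile(track, genes, sizes, flank = 2000, body_bins = 100,
                        flank_bin = 50)
  expect_equal(m$mean_curve, rep(3, 180))
  expect_equal(m$segment, rep(c("upstream", "body", "downstream"),
                              c(40, 100, 40)))

  # + gene with 100-bp steps of linearly increasing signal vs its exact
  # coordinate mirror on the other chromosome: curves identical bit-for-bit
  L <- 1e6
  steps <- tibble::tibble(chrom = "chrA",
                          start = 90000L + 100L * (0:299),
                          end = 90000L + 100L * (0:299) + 100L,
                          value = seq_len(300) / 7)
  mirror <- tibble::tibble(chrom = "chrB",
                           start = as.integer(L - steps$end),
                           end = as.integer(L - steps$start),
                           value = steps$value)
  gplus <- genes
  gminus <- tibble::tibble(chrom = "chrB", start = as.integer(L - 110000L),
                           end = as.integer(L - 100000L),
                           gene_id = "g1m", score = 0, strand = "-")
  both <- dplyr::bind_rows(steps, mirror)
  mp <- metagene_profile(both, gplus, sizes, 2000, 100, 50)
  mm <- metagene_profile(both, gminus, sizes, 2000, 100, 50)
  expect_identical(mp$mean_curve, mm$mean_curve)
  expect_true(any(diff(mp$mean_curve) != 0))  # non-trivial signal
})

test_that("metagene drops short or edge genes with an accounted count", {
  sizes <- tiny_genome()
  track <- constant_track(1)
  genes <- tibble::tibble(
    chrom = "chrA",
    start = c(100000L, 500L, 300000L),
    end = c(110000L, 560L, 300050L),
    gene_id = c("ok", "edge", "short"), score = 0,
    strand = "+"
  )
  m <- metagene_profile(track, genes, sizes, flank = 2000, body_bins = 100,
                        flank_bin = 50)
  expect_equal(m$n_genes, 1L)
  expect_equal(m$n_dropped, 2L)
  expect_error(metagene_profile(track, genes[2:3, ], sizes, 2000, 100, 50),
               class = "peakcoloc_data_error")
})

test_that("region density follows the formula and is split-invariant", {
  # 1-kb region holding 100 signal units in a track of total 1e6
  filler <- tibble::tibble(chrom = "chrA", start = 10000L, end = 1009998L,
                           value = 999800 / 999998)
  region_track <- tibble::tibble(chrom = "chrA", start = c(1000L, 5000L),
                                 end = c(2000L, 7000L), value = c(0.1, 0.05))
  track <- dplyr::bind_rows(region_track, filler)
  total <- track_total_signal(track)
  expect_equal(total, 1e6, tolerance = 1e-9)
  regions <- tibble::tibble(region_id = c("r1", "r2"),
                            class = c("promoter", "body"),
                            chrom = "chrA", start = c(1000L, 5000L),
                            end = c(2000L, 7000L))
  d <- region_density(track, regions, total_signal = 1e6)
  expect_equal(d$density, c(100, 50), tolerance = 1e-9)

  # splitting steps into finer pieces with identical totals changes nothing
  fine <- tibble::tibble(chrom = "chrA", start = 1000L + 100L * (0:9),
                         end = 1000L + 100L * (0:9) + 100L, value = 0.1)
  track2 <- dplyr::bind_rows(fine, track[-1, ])
  d2 <- region_density(track2, regions, total_signal = 1e6)
  expect_equal(d2$density, d$density, tolerance = 1e-12)
  expect_error(region_density(track, regions, total_signal = 0),
               class = "peakcoloc_usage_error")
})

test_that("RPKM normalization matches the formula and a naive counting oracle", {
  sizes <- tibble::tibble(chrom = "chrA", size = 10000)
  # 10 reads in one 100-bp bin; total scaled to 1e6 by the denominator
  reads <- tibble::tibble(chrom = "chrA", start = 150L + 0:9, end = 160L + 0:9)
  tr <- rpkm_normalize(reads, 100, sizes)
  bin2 <- tr$value[tr$start == 100]
  expect_equal(bin2, 10 / (100 / 1000) / (10 / 1e6))
  expect_equal(tr$value[tr$start == 5000], 0)

  withr::with_seed(61, {
    rstart <- sample.int(9900, 500)
    reads <- tibble::tibble(chrom = "chrA", start = rstart, end = rstart + 36L)
  })
  tr <- rpkm_normalize(reads, 250, sizes)
  # naive per-bin recount
  for (k in c(1, 10, 25, 40)) {
    a <- (k - 1) * 250
    cnt <- sum(reads$start < a + 250 & reads$end > a)
    expect_equal(tr$value[k], cnt / 0.25 / (500 / 1e6), tolerance = 1e-9)
  }
  expect_error(rpkm_normalize(reads[0, ], 100, sizes),
               class = "peakcoloc_usage_error")
})

test_that("profile objects expose tidy/glance/autoplot", {
  sizes <- tiny_genome()
  track <- constant_track(2)
  anchors <- tibble::tibble(chrom = "chrA", pos = c(10000L, 20000L, 30000L))
  prof <- aggregate_profile(track, anchors, sizes, 1000, 50)
  td <- tidy(prof)
  expect_equal(nrow(td), 40L)
  expect_equal(td$mean_signal, prof$mean_curve)
  expect_s3_class(autoplot(prof), "ggplot")
  g <- glance(prof)
  expect_equal(g$n_anchors, 3L)

  genes <- tibble::tibble(chrom = "chrA", start = 100000L, end = 110000L,
                          gene_id = "g", score = 0, strand = "+")
  m <- metagene_profile(track, genes, sizes, 1000, 50, 50)
  expect_equal(glance(m)$body_mean, 2)
  expect_s3_class(autoplot(m), "ggplot")
})
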