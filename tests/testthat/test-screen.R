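# Overlap percentages, the cross-protein correlation and candidate ranking.

test_that("overlap percentage follows the counting formula", {
  a <- tibble::tibble(chrom = "chrA", start = c(0L, 1000L, 2000L, 3000L),
                      end = c(50L, 1050L, 2050L, 3050L))
  expect_equal(overlap_percentage(a, a[1:2, ]), 50)
  expect_equal(overlap_percentage(a, a), 100)
  expect_equal(overlap_percentage(a, a[0, ]), 0)
  expect_error(overlap_percentage(a[0, ], a), class = "peakcoloc_usage_error")

  # constructed fixture: exactly 37 of 100 query peaks sit over the reference
  ref <- tibble::tibble(chrom = "chrA", start = 1000L * (1:37), end = 1000L * (1:37) + 100L)
  hit <- tibble::tibble(chrom = "chrA", start = 1000L * (1:37) + 50L,
                        end = 1000L * (1:37) + 150L)
  miss <- tibble::tibble(chrom = "chrA", start = 1000L * (38:100) + 500L,
                         end = 1000L * (38:100) + 600L)
  expect_equal(overlap_percentage(dplyr::bind_rows(hit, miss), ref), 37)
})

test_that("pearson_r matches the closed-form oracle and flags degeneracy", {
  withr::with_seed(7, {
    x <- runif(50) * 100
    y <- 0.8 * x + rnorm(50, 0, 5)
  })
  expect_equal(pearson_r(x, y), oracle_pearson(x, y), tolerance = 1e-12)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_warning(r <- pearson_r(rep(1, 5), x[1:5]),
                 class = "peakcoloc_degenerate_warning")
  expect_true(is.na(r))
  expect_error(pearson_r(x[1:2], y[1:2]), class = "peakcoloc_usage_error")
  expect_error(pearson_r(x, y[1:10]), class = "peakcoloc_usage_error")
})

test_that("run_screen reproduces planted per-protein counts", {
  # hand-planted fixture: three proteins with known overlap counts
  mk <- function(starts) tibble::tibble(chrom = "chrA", start = starts,
                                        end = starts + 100L)
  rloop <- mk(c(10000L, 30000L, 50000L))
  g4 <- mk(c(30000L, 70000L))
  tf <- list(
    # hits rloop at 10000/30000; hits g4 at 30000
    pA = mk(c(10050L, 30050L, 90000L, 95000L)),
    # hits g4 at 70000 only
    pB = mk(c(70050L, 99000L)),
    # hits nothing
    pC = mk(c(200000L, 300000L))
  )
  tab <- run_screen(tf, rloop, g4)
  expect_s3_class(tab, "screen_table")
  expect_equal(tab$protein, c("pA", "pB", "pC"))
  expect_equal(tab$n_rloop, c(2L, 0L, 0L))
  expect_equal(tab$n_g4, c(1L, 1L, 0L))
  expect_equal(tab$n_both, c(1L, 0L, 0L))
  expect_equal(tab$pct_rloop, c(50, 0, 0))
  expect_equal(tab$pct_g4, c(25, 50, 0))
  expect_equal(attr(tab, "pearson_r"),
               oracle_pearson(c(25, 50, 0), c(50, 0, 0)), tolerance = 1e-12)
})

test_that("screen is invariant to protein insertion order and handles edge cases", {
  withr::with_seed(21, {
    tf <- list(a = random_peaks(30), b = random_peaks(30), c = random_peaks(30))
    rloop <- random_peaks(60)
    g4 <- random_peaks(60)
  })
  t1 <- run_screen(tf, rloop, g4)
  t2 <- run_screen(rev(tf), rloop, g4)
  expect_equal(tidy(t1), tidy(t2))
  expect_equal(attr(t1, "pearson_r"), attr(t2, "pearson_r"))

  # protein against itself as both structures -> (100, 100)
  self <- suppressWarnings(run_screen(list(x = tf$a), tf$a, tf$a))
  expect_equal(self$pct_rloop, 100)
  expect_equal(self$pct_g4, 100)
  expect_true(is.na(attr(self, "pearson_r")))  # <3 records

  # empty TF set skipped with a classed warning, recorded
  expect_warning(
    t3 <- run_screen(c(tf, list(zz = tf$a[0, ])), rloop, g4),
    class = "peakcoloc_skip_warning"
  )
  expect_equal(attr(t3, "skipped"), "zz")
  expect_equal(nrow(t3), 3L)
  expect_error(suppressWarnings(run_screen(list(zz = tf$a[0, ]), rloop, g4)),
               class = "peakcoloc_usage_error")

  # enlarging a structure set never decreases any percentage
  withr::with_seed(22, extra <- random_peaks(40))
  t4 <- run_screen(tf, dplyr::bind_rows(rloop, extra), g4)
  expect_true(all(t4$pct_rloop >= t1$pct_rloop))
})

test_that("candidate ranking filters on both axes and sorts by the weaker one", {
  records <- tibble::tibble(
    protein = c("d", "a", "b", "c"),
    n_peaks = 100L,
    n_rloop = c(90L, 80L, 70L, 20L), pct_rloop = c(90, 80, 70, 20),
    n_g4 = c(50L, 85L, 75L, 90L), pct_g4 = c(50, 85, 75, 90),
    n_both = 0L
  )
  tab <- peakcoloc:::new_screen_table(records, pearson_r = NA_real_)
  ranked <- rank_candidates(tab, min_pct = 0)
  expect_equal(ranked$protein, c("a", "b", "d", "c"))  # by min(pct), desc
  ranked <- rank_candidates(tab, min_pct = 60)
  expect_equal(ranked$protein, c("a", "b"))
  # threshold 100 with one perfect protein keeps exactly that protein
  records$pct_rloop[1] <- records$pct_g4[1] <- 100
  tab <- peakcoloc:::new_screen_table(records, pearson_r = NA_real_)
  expect_equal(rank_candidates(tab, min_pct = 100)$protein, "d")
  # ties broken by protein name
  records$pct_rloop[] <- 50
  records$pct_g4[] <- 50
  tab <- peakcoloc:::new_screen_table(records, pearson_r = NA_real_)
  expect_equal(rank_candidates(tab, 0)$protein, c("a", "b", "c", "d"))
})

test_that("screen table TSV and broom-style accessors are consistent", {
  withr::with_seed(31, {
    tf <- list(a = random_peaks(40), b = random_peaks(40), c = random_peaks(40))
    tab <- run_screen(tf, random_peaks(80), random_peaks(80))
  })
  g <- glance(tab)
  expect_equal(g$n_proteins, 3L)
  expect_equal(g$pearson_r, attr(tab, "pearson_r"))
  td <- tidy(tab)
  expect_false(inherits(td, "screen_table"))
  expect_equal(nrow(td), 3L)

  f <- withr::local_tempfile(fileext = ".tsv")
  write_screen_table(tab, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# pearson_r\t", lines)))
  body <- utils::read.delim(text = lines[!startsWith(lines, "#")])
  expect_equal(body$protein, tab$protein)
  expect_equal(body$pct_rloop, round(tab$pct_rloop, 4))
  p <- autoplot(tab)
  expect_s3_class(p, "ggplot")
})
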