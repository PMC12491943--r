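one_contig <- function(L = 1000) seqs_tbl(c1 = strrep("A", L))

reads_at <- function(starts, len = 60L, contig = "c1") {
  tibble::tibble(read_id = sprintf("r%d", seq_along(starts)),
                 contig_id = contig, start = as.integer(starts),
                 end = as.integer(starts + len), strand = "+")
}

test_that("intersection requires at least one base of overlap (half-open)", {
  regions <- tibble::tibble(contig_id = "c1", start = 69L, end = 200L)
  expect_equal(observed_intersection(reads_at(10), regions)$n_intersecting,
               1L)
  regions$start <- 70L
  expect_equal(observed_intersection(reads_at(10), regions)$n_intersecting,
               0L)
  expect_error(observed_intersection(reads_at(integer(0)), regions),
               "empty read set")
})

test_that("observed intersection reports integer display percentages", {
  regions <- tibble::tibble(contig_id = "c1", start = 0L, end = 100L)
  obs <- observed_intersection(reads_at(c(0, 10, 200)), regions)
  expect_equal(obs$n_reads, 3L)
  expect_equal(obs$observed_fraction, 2 / 3)
  expect_equal(obs$percent, 67)
})

test_that("degenerate nulls: no regions give 0, tiling regions give 1", {
  target <- one_contig()
  reads <- reads_at(c(0, 100, 500))
  none <- permute_placements(reads, tibble::tibble(contig_id = character(0),
                                                   start = integer(0),
                                                   end = integer(0)),
                             target, n_perm = 20, seed = 1)
  expect_equal(none, rep(0, 20))
  all_reg <- tibble::tibble(contig_id = "c1", start = 0L, end = 1000L)
  expect_equal(permute_placements(reads, all_reg, target, n_perm = 20,
                                  seed = 1), rep(1, 20))
})

test_that("permutations are deterministic under a fixed seed", {
  withr::local_seed(40)
  target <- one_contig(5000)
  regions <- tibble::tibble(contig_id = "c1", start = c(100L, 3000L),
                            end = c(600L, 3500L))
  reads <- reads_at(sample(0:4940, 200, replace = TRUE))
  a <- permute_placements(reads, regions, target, n_perm = 50, seed = 214)
  b <- permute_placements(reads, regions, target, n_perm = 50, seed = 214)
  expect_identical(a, b)
  c <- permute_placements(reads, regions, target, n_perm = 50, seed = 215)
  expect_false(identical(a, c))
})

test_that("analytic expectation matches direct enumeration", {
  target <- one_contig(100)
  region <- tibble::tibble(contig_id = "c1", start = 50L, end = 60L)
  # read length 10: overlapping starts 41..59 of the 91 valid starts
  expect_equal(analytic_null_expectation(reads_at(0, len = 10), region,
                                         target), 19 / 91)
  whole <- tibble::tibble(contig_id = "c1", start = 0L, end = 100L)
  expect_equal(analytic_null_expectation(reads_at(0, len = 10), whole,
                                         target), 1)
  expect_equal(analytic_null_expectation(reads_at(0, len = 10),
                                         whole[0, ], target), 0)
})

test_that("analytic expectation exceeds the covered fraction for reads longer than 1", {
  withr::local_seed(41)
  target <- one_contig(2000)
  regions <- tibble::tibble(contig_id = "c1",
                            start = c(100L, 700L, 1500L),
                            end = c(250L, 900L, 1600L))
  covered_fraction <- region_bases(regions) / 2000
  e <- analytic_null_expectation(reads_at(0, len = 60), regions, target)
  expect_gt(e, covered_fraction)
})

test_that("permutation null mean agrees with the analytic oracle at 3 SE", {
  withr::local_seed(42)
  target <- one_contig(10000)
  regions <- tibble::tibble(contig_id = "c1",
                            start = c(500L, 4000L, 8000L),
                            end = c(1500L, 5000L, 8800L))
  reads <- reads_at(sample(0:9940, 500, replace = TRUE))
  nulls <- permute_placements(reads, regions, target, n_perm = 300,
                              seed = 7)
  expected <- analytic_null_expectation(reads, regions, target)
  se <- stats::sd(nulls) / sqrt(length(nulls))
  expect_lt(abs(mean(nulls) - expected), 3 * se)
})

test_that("the add-one estimator has the right floor, centre, and ceiling", {
  expect_equal(empirical_p(0.9, rep(0.5, 300)), 1 / 301)
  expect_equal(empirical_p(0.5, c(rep(0.6, 150), rep(0.4, 150))),
               151 / 301)
  expect_equal(empirical_p(0.1, rep(0.5, 300)), 1)
  # ties count against significance
  expect_equal(empirical_p(0.5, rep(0.5, 10)), 1)
  expect_error(empirical_p(0.5, numeric(0)), "empty")
})

test_that("empirical p is non-increasing in the observed fraction", {
  withr::local_seed(43)
  nulls <- runif(300)
  ps <- vapply(seq(0, 1, by = 0.05), empirical_p,
               numeric(1), null_fractions = nulls)
  expect_true(all(diff(ps) <= 0))
})

test_that("reads longer than their contig are excluded with a warning", {
  target <- seqs_tbl(c1 = strrep("A", 1000), tiny = strrep("A", 30))
  regions <- tibble::tibble(contig_id = "c1", start = 0L, end = 500L)
  reads <- dplyr::bind_rows(reads_at(c(0, 600)),
                            reads_at(0, contig = "tiny"))
  expect_warning(
    res <- enrichment_test(reads, regions, target, n_perm = 20),
    "excluded")
  expect_equal(res$n_reads, 2L)
})

test_that("enrichment_test returns a tidy-able object", {
  withr::local_seed(44)
  target <- one_contig(5000)
  regions <- tibble::tibble(contig_id = "c1", start = 1000L, end = 2500L)
  reads <- reads_at(sample(1000:2400, 150, replace = TRUE))
  res <- enrichment_test(reads, regions, target, n_perm = 100, seed = 3)
  expect_s3_class(res, "mm_enrichment")
  td <- tidy(res)
  expect_equal(td$n_reads, 150L)
  expect_equal(td$observed_fraction, 1)
  expect_equal(td$p.value, 1 / 101)
  expect_equal(res$empirical_p,
               empirical_p(res$observed_fraction, res$null_fractions))
  gl <- glance(res)
  expect_equal(gl$p.value, td$p.value)
  expect_s3_class(autoplot(res), "ggplot")
})
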