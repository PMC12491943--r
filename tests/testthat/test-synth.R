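test_that("host generation is deterministic with the requested composition", {
  h1 <- generate_host(2, c(1000, 2000), seed = 60)
  h2 <- generate_host(2, c(1000, 2000), seed = 60)
  expect_identical(h1, h2)
  expect_equal(sum(h1$length), 3000)
  expect_false(identical(h1$sequence, generate_host(2, c(1000, 2000),
                                                    seed = 61)$sequence))
  big <- generate_host(1, 100000, gc = 0.5, seed = 62)
  gc_obs <- stringr::str_count(big$sequence, "[GC]") / 100000
  expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / 100000))
  skewed <- generate_host(1, 100000, gc = 0.3, seed = 63)
  gc_skew <- stringr::str_count(skewed$sequence, "[GC]") / 100000
  expect_lt(abs(gc_skew - 0.3), 3 * sqrt(0.3 * 0.7 / 100000))
  expect_error(generate_host(1, 100, gc = 1.2), "gc")
})

test_that("planted inserts at divergence 0 copy the source verbatim", {
  host <- generate_host(2, 20000, seed = 64)
  src <- generate_sources(c("taxA", "taxB"), 10000, seed = 65)
  truth <- plant_inserts(host, src, n_inserts = 3, insert_length = 500,
                         seed = 66)
  expect_equal(nrow(truth$truth_regions), 3)
  for (i in 1:3) {
    tr <- truth$truth_regions[i, ]
    planted <- substr(
      truth$host$sequence[truth$host$contig_id == tr$contig_id],
      tr$start + 1, tr$end)
    original <- substr(
      src$sequence[src$taxon_label == tr$taxon_label],
      tr$source_start + 1, tr$source_start + 500)
    expect_equal(planted, original)
    expect_equal(tr$n_subs, 0L)
  }
})

test_that("recorded substitutions exactly match the planted divergence", {
  host <- generate_host(1, 30000, seed = 67)
  src <- generate_sources("taxA", 10000, seed = 68)
  truth <- plant_inserts(host, src, n_inserts = 4, insert_length = 1000,
                         divergence = 0.05, seed = 69)
  for (i in seq_len(nrow(truth$truth_regions))) {
    tr <- truth$truth_regions[i, ]
    planted <- strsplit(substr(
      truth$host$sequence[truth$host$contig_id == tr$contig_id],
      tr$start + 1, tr$end), "")[[1]]
    original <- strsplit(substr(
      src$sequence, tr$source_start + 1, tr$source_start + 1000), "")[[1]]
    expect_equal(sum(planted != original), tr$n_subs)
  }
  # observed substitution totals behave binomially around 50 per kb
  total <- sum(truth$truth_regions$n_subs)
  expect_lt(abs(total - 200), 3 * sqrt(4000 * 0.05 * 0.95))
})

test_that("copy_number plants a repeat family with disjoint truth regions", {
  truth <- multicopy_fixture(copies = 12)
  tr <- truth$truth_regions
  expect_equal(nrow(tr), 12)
  expect_equal(unique(tr$taxon_label), "Moritella_repeat")
  expect_equal(length(unique(tr$source_start)), 1)  # same fragment
  expect_equal(region_intersection_bases(tr, tr), region_bases(tr))
  ir <- IRanges::IRanges(tr$start + 1, tr$end)
  expect_equal(sum(IRanges::width(IRanges::reduce(ir, min.gapwidth = 0))),
               region_bases(tr))  # pairwise disjoint
})

test_that("plant_inserts fails cleanly when the host cannot fit the inserts", {
  host <- generate_host(1, 200, seed = 70)
  src <- generate_sources("taxA", 1000, seed = 71)
  expect_error(plant_inserts(host, src, n_inserts = 5, insert_length = 100,
                             seed = 72), "1000 attempts")
  expect_error(plant_inserts(host, src, insert_length = 59), ">= 60")
})

test_that("sampled reads honour inside_fraction extremes", {
  withr::local_seed(73)
  host <- generate_host(1, 10000, seed = 74)
  regions <- tibble::tibble(contig_id = host$contig_id, start = 2000L,
                            end = 5000L)
  inside <- sample_reads(host, regions, 300, inside_fraction = 1,
                         seed = 75)
  expect_equal(observed_intersection(inside, regions)$observed_fraction, 1)
  expect_equal(nrow(sample_reads(host, regions, 0)), 0)
  expect_error(sample_reads(host, regions[0, ], 10, inside_fraction = 0.5),
               "non-empty region set")
  expect_error(sample_reads(host[, ], regions, 10, read_length = 20000),
               "shortest contig")
})

test_that("uniform reads intersect at the analytic rate", {
  host <- generate_host(1, 20000, seed = 76)
  regions <- tibble::tibble(contig_id = host$contig_id,
                            start = c(1000L, 9000L), end = c(4000L, 12000L))
  reads <- sample_reads(host, regions, 1000, inside_fraction = 0, seed = 77)
  p <- analytic_null_expectation(reads, regions, host)
  obs <- observed_intersection(reads, regions)$observed_fraction
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 1000))
})

test_that("read sequences match their recorded placements", {
  host <- generate_host(2, c(500, 800), seed = 78)
  regions <- tibble::tibble(contig_id = host$contig_id[1], start = 100L,
                            end = 300L)
  reads <- sample_reads(host, regions, 50, inside_fraction = 0.5, seed = 79)
  for (i in sample(50, 10)) {
    expect_equal(reads$sequence[i], substr(
      host$sequence[host$contig_id == reads$contig_id[i]],
      reads$start[i] + 1, reads$end[i]))
  }
})

test_that("terminal damage toggle introduces only C-to-T changes", {
  withr::local_seed(80)
  host <- generate_host(1, 5000, seed = 81)
  clean <- sample_reads(host, tibble::tibble(contig_id = character(0),
                                             start = integer(0),
                                             end = integer(0)),
                        200, inside_fraction = 0, seed = 82)
  damaged <- sample_reads(host, tibble::tibble(contig_id = character(0),
                                               start = integer(0),
                                               end = integer(0)),
                          200, inside_fraction = 0, seed = 82,
                          damage_rate = 0.8)
  expect_equal(damaged$start, clean$start)
  diffs <- mapply(function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    which(ca != cb)
  }, clean$sequence, damaged$sequence, SIMPLIFY = FALSE)
  changed <- unlist(diffs)
  expect_true(all(changed <= 3))
  for (i in seq_len(nrow(clean))) {
    d <- diffs[[i]]
    if (length(d) > 0) {
      expect_true(all(substring(clean$sequence[i], d, d) == "C"))
      expect_true(all(substring(damaged$sequence[i], d, d) == "T"))
    }
  }
})
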