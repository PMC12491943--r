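aln_row <- function(contig, start, len = 60L, taxon = "taxA",
                    id = NULL) {
  if (is.null(id)) id <- make_read_id(taxon, "src", start)
  tibble::tibble(read_id = id, taxon_label = taxon, contig_id = contig,
                 start = as.integer(start), end = as.integer(start + len),
                 strand = "+", mismatches = 0L, rank = 1L)
}

test_that("overlapping and bookended intervals merge; gapped ones do not", {
  withr::local_seed(20)
  target <- seqs_tbl(c1 = random_seq(300))
  merged <- call_regions(dplyr::bind_rows(aln_row("c1", 5),
                                          aln_row("c1", 50)), target)
  expect_equal(merged[, c("start", "end", "n_reads")],
               tibble::tibble(start = 5L, end = 110L, n_reads = 2L))
  gapped <- call_regions(dplyr::bind_rows(aln_row("c1", 0),
                                          aln_row("c1", 70)), target)
  expect_equal(gapped$start, c(0L, 70L))
  expect_equal(gapped$end, c(60L, 130L))
  bookended <- call_regions(dplyr::bind_rows(aln_row("c1", 0),
                                             aln_row("c1", 60)), target)
  expect_equal(nrow(bookended), 1)  # depth >= 1 run with no zero gap
  expect_equal(bookended$end, 120L)
})

test_that("region boundaries have zero depth just outside", {
  withr::local_seed(21)
  target <- seqs_tbl(c1 = random_seq(400))
  aln <- dplyr::bind_rows(aln_row("c1", 10), aln_row("c1", 30),
                          aln_row("c1", 150))
  regions <- call_regions(aln, target)
  depth <- integer(400)
  for (i in seq_len(nrow(aln))) {
    span <- (aln$start[i] + 1):aln$end[i]
    depth[span] <- depth[span] + 1L
  }
  for (i in seq_len(nrow(regions))) {
    expect_true(all(depth[(regions$start[i] + 1):regions$end[i]] >= 1))
    if (regions$start[i] > 0) expect_equal(depth[regions$start[i]], 0L)
    if (regions$end[i] < 400) expect_equal(depth[regions$end[i] + 1], 0L)
  }
})

test_that("taxon counts partition n_reads; sample reads cover but do not count", {
  withr::local_seed(22)
  target <- seqs_tbl(c1 = random_seq(300))
  aln <- dplyr::bind_rows(
    aln_row("c1", 5, taxon = "taxB"),
    aln_row("c1", 20, taxon = "taxA"),
    aln_row("c1", 40, taxon = "taxB"),
    tibble::tibble(read_id = "sample_read_1", taxon_label = NA,
                   contig_id = "c1", start = 90L, end = 150L,
                   strand = "+", mismatches = 0L, rank = 1L)
  )
  regions <- call_regions(aln, target)
  expect_equal(nrow(regions), 1)  # sample read extends coverage run
  expect_equal(regions$end, 150L)
  expect_equal(regions$n_reads, 3L)  # sample read excluded
  expect_equal(regions$taxa[[1]],
               tibble::tibble(count = c(2L, 1L), taxon = c("taxB", "taxA")))
})

test_that("call_regions validates contigs and bounds", {
  target <- seqs_tbl(c1 = strrep("A", 100))
  expect_error(call_regions(aln_row("cX", 0), target), "cX")
  expect_error(call_regions(aln_row("c1", 50), target), "read")
  expect_equal(nrow(call_regions(aln_row("c1", 0)[0, ], target)), 0)
})

test_that("annotation keeps the top-k taxa with deterministic tie-breaks", {
  region <- tibble::tibble(
    contig_id = "c1", start = 127L, end = 246L, n_reads = 15L,
    taxa = list(tibble::tibble(count = c(3L, 3L, 5L, 2L, 1L, 1L),
                               taxon = c("B", "A", "C", "D", "F", "E"))))
  bed <- annotate_regions(region, organism = "org", ref_id = "ref",
                          top_taxa = 5)
  expect_equal(bed$length, 119L)
  t <- bed$taxa[[1]]
  expect_equal(t$taxon, c("C", "A", "B", "D", "E"))  # ties alphabetical
  expect_equal(t$count, c(5L, 3L, 3L, 2L, 1L))
  single <- region
  single$taxa <- list(tibble::tibble(count = 7L, taxon = "X"))
  expect_equal(nrow(annotate_regions(single)$taxa[[1]]), 1)
  expect_error(annotate_regions(region, top_taxa = 0), "top_taxa")
})

test_that("breadth of coverage is the covered-base fraction", {
  target <- seqs_tbl(c1 = strrep("A", 600), c2 = strrep("C", 400))
  regions <- tibble::tibble(contig_id = "c1", start = 0L, end = 119L)
  expect_equal(breadth_of_coverage(regions, target)$breadth, 0.119)
  expect_equal(breadth_of_coverage(regions[0, ], target)$breadth, 0)
  tiling <- tibble::tibble(contig_id = "c2", start = c(0L, 100L),
                           end = c(100L, 400L))
  per_contig <- breadth_of_coverage(tiling, target, by = "contig")
  expect_equal(per_contig$breadth[per_contig$contig_id == "c2"], 1)
  expect_equal(per_contig$breadth[per_contig$contig_id == "c1"], 0)
  overlapping <- tibble::tibble(contig_id = "c1", start = c(0L, 50L),
                                end = c(60L, 100L))
  expect_error(breadth_of_coverage(overlapping, target), "overlapping")
})

test_that("adding alignments never decreases breadth", {
  withr::local_seed(23)
  target <- seqs_tbl(c1 = random_seq(1000))
  alns <- dplyr::bind_rows(lapply(sample(0:940, 15), function(s) {
    aln_row("c1", s)
  }))
  breadths <- vapply(seq_len(nrow(alns)), function(k) {
    breadth_of_coverage(call_regions(alns[1:k, ], target), target)$breadth
  }, numeric(1))
  expect_true(all(diff(breadths) >= 0))
})

test_that("contig fractions capture constructed bimodality", {
  covered <- setNames(rep(strrep("A", 200), 100), sprintf("t%03d", 1:100))
  target <- seqs_tbl(covered)
  regions <- tibble::tibble(contig_id = sprintf("t%03d", 1:50),
                            start = 0L, end = 200L)
  cf <- contig_fractions(regions, target)
  expect_equal(cf$n_low, 50)
  expect_equal(cf$n_high, 50)
  expect_equal(sum(cf$histogram$count), 100)
  # single contig half covered: unimodal at 0.5
  half <- contig_fractions(tibble::tibble(contig_id = "t001", start = 0L,
                                          end = 100L),
                           target[1, ])
  expect_equal(half$fractions$fraction, 0.5)
  expect_equal(half$n_low + half$n_high, 0)
  # conditioning on contigs with mapped reads
  sub <- contig_fractions(regions, target,
                          contigs = sprintf("t%03d", 1:10))
  expect_equal(nrow(sub$fractions), 10)
  expect_equal(sub$n_high, 10)
})

test_that("genome-by-taxon table normalizes per taxon column", {
  counts <- tibble::tibble(
    assembly_id = c("g1", "g1", "g2"),
    taxon_label = c("taxA", "taxB", "taxA"),
    n = c(0, 5, 10))
  norm <- genome_taxon_table(counts)
  expect_equal(norm$taxA, c(0, 1))   # min-max
  expect_equal(norm$taxB, c(1, 0))   # absent taxon fills in as 0
  raw <- genome_taxon_table(counts, normalize = FALSE)
  expect_equal(raw$taxB, c(5, 0))
  single <- genome_taxon_table(counts[counts$assembly_id == "g1", ])
  expect_true(all(single[, -1] == 0))
  expect_error(genome_taxon_table(counts[0, ]), "nonzero")
  withr::local_seed(24)
  big <- tibble::tibble(assembly_id = rep(sprintf("g%d", 1:6), each = 4),
                        taxon_label = rep(c("a", "b", "c", "d"), 6),
                        n = sample(0:100, 24, replace = TRUE))
  vals <- as.matrix(genome_taxon_table(big)[, -1])
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("region plus complement partitions each contig", {
  withr::local_seed(25)
  target <- seqs_tbl(c1 = random_seq(500), c2 = random_seq(300))
  aln <- dplyr::bind_rows(aln_row("c1", 10), aln_row("c1", 200),
                          aln_row("c2", 0))
  regions <- call_regions(aln, target)
  comp <- complement_regions(regions, target)
  expect_equal(region_intersection_bases(regions, comp), 0)
  expect_equal(region_bases(regions) + region_bases(comp), 800)
})
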