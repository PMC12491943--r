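# Shared fixture builders and independent oracles for the test suite.

seqs_tbl <- function(...) {
  x <- c(...)
  tibble::tibble(contig_id = names(x), sequence = unname(x),
                 length = nchar(x))
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Substitute exactly n random positions of a sequence (always to a
# different base).
mutate_exact <- function(seq, n) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Base-level overlap oracle: total bases shared by two region sets
# (0-based half-open tibbles with contig_id, start, end).
region_intersection_bases <- function(a, b) {
  total <- 0
  for (cid in intersect(a$contig_id, b$contig_id)) {
    ia <- IRanges::IRanges(start = a$start[a$contig_id == cid] + 1L,
                           end = a$end[a$contig_id == cid])
    ib <- IRanges::IRanges(start = b$start[b$contig_id == cid] + 1L,
                           end = b$end[b$contig_id == cid])
    total <- total + sum(IRanges::width(IRanges::intersect(ia, ib)))
  }
  total
}

region_bases <- function(a) sum(a$end - a$start)

# Exhaustive canonical k-mer set of a sequence (independent of the C++
# sketching path); used as the Jaccard oracle.
canonical_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  rc <- micromask::revcomp(kmers)
  unique(pmin(kmers, rc))
}

# A deterministic planted-repeat fixture used by the saturation tests:
# one 600 bp source fragment planted as `copies` copies (identical by
# default: multicopy insertions of the same element).
multicopy_fixture <- function(copies = 12, divergence = 0, seed = 19) {
  host <- generate_host(1, 60000, seed = seed)
  src <- generate_sources("Moritella_repeat", 5000, seed = seed + 1)
  plant_inserts(host, src, n_inserts = 1, insert_length = 600,
                divergence = divergence, copy_number = copies,
                seed = seed + 2)
}
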