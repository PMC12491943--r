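#' Build a seed index over a target assembly
#'
#' Hashes every forward-strand seed-length k-mer of the target (uppercased;
#' seeds containing `N` are skipped). The default seed length of 15 bases
#' makes four non-overlapping seed tiles fit in a 60 bp read, so by the
#' pigeonhole principle any placement with at most 3 mismatches leaves at
#' least one tile exact and is guaranteed to be found.
#'
#' @param sequences target sequences tibble ([read_fasta()]).
#' @param seed seed (k-mer) length in bases, between 8 and 31.
#' @return an opaque index object of class `mm_index`.
#' @export
build_index <- function(sequences, seed = 15L) {
  check_sequences(sequences, "target")
  ptr <- cpp_build_index(sequences$contig_id, sequences$sequence,
                         as.integer(seed))
  structure(list(ptr = ptr, seed = as.integer(seed),
                 contig_id = sequences$contig_id,
                 contig_length = nchar(sequences$sequence)),
            class = "mm_index")
}

#' @export
print.mm_index <- function(x, ...) {
  info <- cpp_index_info(x$ptr)
  cat("<mm_index> seed", info$seed, "bp;", info$n_contigs, "contigs;",
      format(info$n_seeds, big.mark = ","), "distinct seeds\n")
  invisible(x)
}

#' Look up a seed in the index
#'
#' @param index an `mm_index`.
#' @param seed_seq a seed-length nucleotide string.
#' @return tibble of forward-strand occurrences (`contig_id`, 0-based `pos`).
#' @export
lookup_seed <- function(index, seed_seq) {
  as_tibble(cpp_lookup_seed(index$ptr, seed_seq)) %>%
    mutate(pos = as.integer(.data$pos))
}

#' Align reads to an indexed target
#'
#' Deterministic seed-and-extend placement emulating end-to-end short-read
#' alignment of near-identical sequence: candidate loci come from exact
#' seed hits of every non-overlapping seed tile (plus a tail-anchored tile)
#' of the read and of its reverse complement; each candidate is extended
#' ungapped over the full read length counting mismatches (`N` in the
#' target never matches). Placements with at most `max_mismatch` mismatches
#' are kept, deduplicated by (contig, start, strand), sorted by
#' (mismatches, contig_id, start, strand with `+` first), truncated to the
#' multimap cap, and ranked in that order. When the cap cuts into a group
#' of placements tied at the boundary mismatch count, the survivors are
#' picked cyclically from the tie group at a per-read deterministic offset
#' (a hash of the read sequence), so repeated runs are identical but
#' different reads drop different copies of a multicopy locus — the
#' behaviour that lets coverage of repeat families saturate as the cap
#' grows.
#'
#' @param reads a pseudo-read tibble ([fragment()]/[fragment_set()]), a
#'   tibble with `read_id` and `sequence`, or a character vector of read
#'   sequences (named or not).
#' @param index an `mm_index` from [build_index()].
#' @param max_mismatch maximum mismatches per placement (default 3, i.e. 5%
#'   of a 60 bp read).
#' @param multimap maximum placements retained per read (default 10).
#' @return an alignments tibble with columns `read_id`, `taxon_label`,
#'   `contig_id`, `start`, `end` (0-based half-open), `strand`,
#'   `mismatches`, `rank`.
#' @export
align_reads <- function(reads, index, max_mismatch = 3L, multimap = 10L) {
  if (!inherits(index, "mm_index")) abort("`index` must be an mm_index")
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    reads <- tibble(read_id = ids, sequence = unname(reads))
  }
  if (!all(c("read_id", "sequence") %in% names(reads))) {
    abort("`reads` must have `read_id` and `sequence` columns")
  }
  if (nrow(reads) == 0) return(empty_alignments())
  multimap <- if (is.finite(multimap)) as.integer(multimap) else
    .Machine$integer.max
  res <- cpp_align_batch(index$ptr, reads$sequence,
                         as.integer(max_mismatch), multimap)
  lens <- nchar(reads$sequence)
  tibble(
    read_id = reads$read_id[res$read],
    taxon_label = parse_taxon_label(reads$read_id[res$read]),
    contig_id = index$contig_id[res$contig],
    start = res$start,
    end = res$start + lens[res$read],
    strand = c("+", "-")[res$minus + 1L],
    mismatches = res$mismatches,
    rank = res$rank
  )
}

#' @rdname align_reads
#' @param read a single read sequence.
#' @export
align_read <- function(read, index, max_mismatch = 3L, multimap = 10L) {
  align_reads(stats::setNames(read, "read1"), index,
              max_mismatch = max_mismatch, multimap = multimap)
}

empty_alignments <- function() {
  tibble(read_id = character(0), taxon_label = character(0),
         contig_id = character(0), start = integer(0), end = integer(0),
         strand = character(0), mismatches = integer(0), rank = integer(0))
}

#' Brute-force alignment oracle
#'
#' Exhaustively tests every start position on both strands of the target by
#' direct Hamming comparison, returning the complete placement set with at
#' most `max_mismatch` mismatches, in the same deterministic order as
#' [align_reads()] but without the multimap truncation. Guarded to small
#' targets; use the indexed aligner for anything larger.
#'
#' @param read a single read sequence over `A,C,G,T`.
#' @param sequences target sequences tibble.
#' @param max_mismatch maximum mismatches per placement.
#' @return an alignments tibble (as [align_reads()], untruncated).
#' @export
oracle_align <- function(read, sequences, max_mismatch = 3L) {
  check_sequences(sequences, "target")
  if (sum(nchar(sequences$sequence)) > 1e6) {
    abort("target exceeds 1e6 bases; use build_index()/align_reads()")
  }
  read <- toupper(read)
  if (stringr::str_detect(read, "[^ACGT]")) {
    abort("read contains a non-ACGT base")
  }
  m <- nchar(read)
  qbytes <- list("+" = charToRaw(read), "-" = charToRaw(revcomp(read)))
  hits <- list()
  for (i in seq_len(nrow(sequences))) {
    tb <- charToRaw(toupper(sequences$sequence[i]))
    L <- length(tb)
    if (L < m) next
    starts <- 0:(L - m)
    for (strand in c("+", "-")) {
      q <- qbytes[[strand]]
      mism <- integer(length(starts))
      for (j in seq_len(m)) {
        mism <- mism + (tb[starts + j] != q[j])
      }
      keep <- mism <= max_mismatch
      if (any(keep)) {
        hits[[length(hits) + 1]] <- tibble(
          contig_id = sequences$contig_id[i],
          start = starts[keep],
          strand = strand,
          mismatches = mism[keep]
        )
      }
    }
  }
  out <- bind_rows(hits)
  if (nrow(out) == 0) return(empty_alignments())
  # byte-wise (radix) ordering matches the indexed aligner's tie-break
  ord <- order(out$mismatches, out$contig_id, out$start,
               match(out$strand, c("+", "-")), method = "radix")
  out[ord, ] %>%
    mutate(read_id = "read1", taxon_label = NA_character_,
           end = .data$start + m, rank = row_number()) %>%
    select("read_id", "taxon_label", "contig_id", "start", "end",
           "strand", "mismatches", "rank")
}
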