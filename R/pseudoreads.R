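#' Pseudo-read identifiers
#'
#' Pseudo-reads carry their provenance in the read id as
#' `taxon_label|source_contig|source_start`, which parses back losslessly
#' and lets per-region taxon attribution travel through alignment.
#'
#' @param taxon_label,source_contig,source_start id components.
#' @return character vector of read ids.
#' @export
make_read_id <- function(taxon_label, source_contig, source_start) {
  paste(taxon_label, source_contig, source_start, sep = "|")
}

#' @rdname make_read_id
#' @param read_id character vector of read ids.
#' @return for `parse_taxon_label()`, the taxon component, or `NA` for ids
#'   not in the pseudo-read format (e.g. sample reads).
#' @export
parse_taxon_label <- function(read_id) {
  parts <- stringr::str_split(read_id, stringr::fixed("|"))
  vapply(parts, function(p) {
    if (length(p) == 3 && nzchar(p[1])) p[1] else NA_character_
  }, character(1))
}

#' Fragment sequences into sliding-window pseudo-reads
#'
#' Cuts each input sequence into fixed-length windows (default 60 bp) at a
#' fixed step (default 10 bp), emulating short-read data from a reference
#' genome. Windows start at 0, `step`, 2\eqn{\times}`step`, ... while the
#' window still fits; sequences shorter than the window yield no reads. The
#' pre-filter window count for a sequence of length L is
#' floor((L - window) / step) + 1.
#'
#' @param sequences sequences tibble ([read_fasta()]); an optional
#'   `taxon_label` column labels each contig's source organism.
#' @param window window length in bases.
#' @param step step between window starts in bases.
#' @param drop_ambiguous drop windows containing any base outside
#'   `A,C,G,T` (the internal aligner is exact-alphabet).
#' @param tail_window also emit a final window anchored at L - `window`
#'   when (L - `window`) is not a multiple of `step` (off by default:
#'   strict sliding window).
#' @return a pseudo-read tibble with columns `read_id`, `taxon_label`,
#'   `source_contig`, `source_start`, `sequence`.
#' @examples
#' host <- generate_host(1, 1000, seed = 1)
#' nrow(fragment(host))  # floor((1000 - 60) / 10) + 1 = 95
#' @export
fragment <- function(sequences, window = 60L, step = 10L,
                     drop_ambiguous = TRUE, tail_window = FALSE) {
  check_sequences(sequences)
  if (step < 1 || step > window) {
    abort("`step` must satisfy 1 <= step <= window")
  }
  taxa <- if ("taxon_label" %in% names(sequences)) {
    sequences$taxon_label
  } else {
    rep(NA_character_, nrow(sequences))
  }
  out <- map(seq_len(nrow(sequences)), function(i) {
    seq_i <- sequences$sequence[i]
    L <- nchar(seq_i)
    if (L < window) return(NULL)
    starts <- seq.int(0L, L - window, by = step)
    if (tail_window && (L - window) %% step != 0L) {
      starts <- c(starts, L - window)
    }
    reads <- substring(seq_i, starts + 1L, starts + window)
    if (drop_ambiguous) {
      keep <- !stringr::str_detect(reads, "[^ACGT]")
      starts <- starts[keep]
      reads <- reads[keep]
    }
    if (length(starts) == 0) return(NULL)
    tibble(
      read_id = make_read_id(taxa[i], sequences$contig_id[i], starts),
      taxon_label = taxa[i],
      source_contig = sequences$contig_id[i],
      source_start = starts,
      sequence = reads
    )
  })
  empty <- tibble(read_id = character(0), taxon_label = character(0),
                  source_contig = character(0), source_start = integer(0),
                  sequence = character(0))
  bind_rows(c(list(empty), out))
}

#' Fragment a taxon-labelled genome collection
#'
#' Applies [fragment()] over a set of source genomes, each contig carrying
#' its taxon label. Duplicate (taxon, contig) pairs with identical sequence
#' are deduplicated; pairs with differing sequences are an error.
#'
#' @inheritParams fragment
#' @param sequences sequences tibble with a mandatory `taxon_label` column.
#' @return a pseudo-read tibble (see [fragment()]); summarise it with
#'   [taxon_read_counts()].
#' @export
fragment_set <- function(sequences, window = 60L, step = 10L,
                         drop_ambiguous = TRUE, tail_window = FALSE) {
  if (!"taxon_label" %in% names(sequences) ||
      anyNA(sequences$taxon_label)) {
    abort("every record must carry a `taxon_label`")
  }
  key <- paste(sequences$taxon_label, sequences$contig_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- sequences[key %in% key[duplicated(key)], ]
    n_seq <- dup %>%
      group_by(.data$taxon_label, .data$contig_id) %>%
      summarise(n = dplyr::n_distinct(.data$sequence), .groups = "drop")
    if (any(n_seq$n > 1)) {
      abort(paste0("duplicate (taxon, contig) pair with differing ",
                   "sequences: ", n_seq$taxon_label[n_seq$n > 1][1], " / ",
                   n_seq$contig_id[n_seq$n > 1][1]))
    }
    sequences <- sequences[!duplicated(key), ]
  }
  # contig ids need only be unique within a taxon here
  sequences <- mutate(sequences,
                      .orig_contig = .data$contig_id,
                      contig_id = paste(.data$taxon_label,
                                        .data$contig_id, sep = "\r"))
  reads <- fragment(sequences, window = window, step = step,
                    drop_ambiguous = drop_ambiguous,
                    tail_window = tail_window)
  reads %>%
    mutate(source_contig = stringr::str_split_i(.data$source_contig,
                                                stringr::fixed("\r"), 2),
           read_id = make_read_id(.data$taxon_label, .data$source_contig,
                                  .data$source_start))
}

#' Per-taxon pseudo-read counts and shares
#'
#' `taxon_read_counts()` tallies a pseudo-read tibble per taxon;
#' `taxon_shares()` adds each taxon's share of the total, as a fraction and
#' as a percentage rounded to one decimal (the display convention used when
#' quoting, e.g., the cyanobacterial share of a pseudo-read corpus).
#'
#' @param reads a pseudo-read tibble ([fragment_set()]).
#' @return a tibble with `taxon_label` and `n_reads` (and, for
#'   `taxon_shares()`, `share` and `percent`), sorted by decreasing count.
#' @export
taxon_read_counts <- function(reads) {
  reads %>%
    count(.data$taxon_label, name = "n_reads") %>%
    arrange(desc(.data$n_reads), .data$taxon_label)
}

#' @rdname taxon_read_counts
#' @param counts a per-taxon count tibble with columns `taxon_label` and
#'   `n_reads` (from `taxon_read_counts()`, or assembled from reported
#'   corpus totals).
#' @export
taxon_shares <- function(counts) {
  total <- sum(as.numeric(counts$n_reads))
  if (total <= 0) abort("total read count must be positive")
  counts %>%
    mutate(share = as.numeric(.data$n_reads) / total,
           percent = round(100 * .data$share, 1)) %>%
    arrange(desc(.data$n_reads), .data$taxon_label)
}
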