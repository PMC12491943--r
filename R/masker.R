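# Merge possibly-overlapping external region sets per contig (bookended
# intervals are NOT merged here; masking is insensitive to that).
merge_regions <- function(regions) {
  if (nrow(regions) == 0) return(regions[, c("contig_id", "start", "end")])
  out <- lapply(split(regions, regions$contig_id), function(r) {
    reg <- IRanges::reduce(IRanges::IRanges(start = r$start + 1L,
                                            end = r$end))
    tibble(contig_id = r$contig_id[1],
           start = IRanges::start(reg) - 1L,
           end = IRanges::end(reg))
  })
  out <- bind_rows(out)
  out[order(out$contig_id, out$start, method = "radix"), ]
}

check_regions_in_bounds <- function(regions, sequences) {
  lens <- contig_lengths(sequences)
  unknown <- setdiff(regions$contig_id, names(lens))
  if (length(unknown) > 0) {
    abort(paste0("region on unknown contig `", unknown[1], "`"))
  }
  oob <- regions$start < 0 | regions$end > lens[regions$contig_id] |
    regions$start >= regions$end
  if (any(oob)) {
    bad <- which(oob)[1]
    abort(paste0("region out of bounds: ", regions$contig_id[bad], ":",
                 regions$start[bad], "-", regions$end[bad]))
  }
  invisible(regions)
}

#' Mask microbial-like regions of an assembly
#'
#' Replaces exactly the bases inside the given regions: hard masking writes
#' `N`, soft masking lowercases. All other bases are byte-identical to the
#' input and sequence lengths never change, so downstream coordinates stay
#' valid. Overlapping input regions (e.g. from third-party BEDs) are merged
#' before masking. Masking is idempotent.
#'
#' @param sequences sequences tibble.
#' @param regions regions tibble (`contig_id`, `start`, `end`; 0-based
#'   half-open).
#' @param mode `"hard"` (default; k-mer profilers treat `N` as a hard
#'   break) or `"soft"`.
#' @return the sequences tibble with masked `sequence` values.
#' @examples
#' s <- tibble::tibble(contig_id = "c1", sequence = "ACGTACGTAC")
#' mask_fasta(s, tibble::tibble(contig_id = "c1", start = 2, end = 5))
#' @export
mask_fasta <- function(sequences, regions, mode = c("hard", "soft")) {
  mode <- match.arg(mode)
  check_sequences(sequences)
  regions <- merge_regions(regions)
  if (nrow(regions) > 0) check_regions_in_bounds(regions, sequences)
  masked <- sequences$sequence
  for (i in seq_len(nrow(regions))) {
    ci <- match(regions$contig_id[i], sequences$contig_id)
    raw <- charToRaw(masked[ci])
    span <- (regions$start[i] + 1L):regions$end[i]
    if (mode == "hard") {
      raw[span] <- charToRaw("N")
    } else {
      raw[span] <- charToRaw(tolower(rawToChar(raw[span])))
    }
    masked[ci] <- rawToChar(raw)
  }
  mutate(sequences, sequence = masked, length = nchar(masked))
}

#' Complement of a region set
#'
#' Per contig, the intervals covering exactly the bases *not* in the input
#' regions; input plus complement tile each contig exactly once. This is
#' the endogenous partition when the input is the microbial-like set.
#'
#' @inheritParams mask_fasta
#' @return a regions tibble (`contig_id`, `start`, `end`).
#' @export
complement_regions <- function(regions, sequences) {
  check_sequences(sequences)
  regions <- merge_regions(regions)
  if (nrow(regions) > 0) check_regions_in_bounds(regions, sequences)
  lens <- contig_lengths(sequences)
  out <- lapply(names(lens), function(cid) {
    L <- lens[[cid]]
    if (L == 0) return(NULL)
    r <- regions[regions$contig_id == cid, ]
    ir <- IRanges::IRanges(start = r$start + 1L, end = r$end)
    gaps <- IRanges::gaps(ir, start = 1L, end = L)
    if (length(gaps) == 0) return(NULL)
    tibble(contig_id = cid, start = IRanges::start(gaps) - 1L,
           end = IRanges::end(gaps))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(contig_id = character(0), start = integer(0),
                  end = integer(0)))
  }
  out[order(out$contig_id, out$start, method = "radix"), ]
}

#' Extract region sequences from an assembly
#'
#' One record per region, with the record id encoding the origin as
#' `contig:start-end` (0-based half-open, matching the BED dialect). Use
#' with [complement_regions()] to split an assembly into its exogenous and
#' endogenous partitions.
#'
#' @inheritParams mask_fasta
#' @param min_length drop regions shorter than this many bases.
#' @return a sequences tibble, one row per (retained) region.
#' @export
extract_fasta <- function(sequences, regions, min_length = 0L) {
  check_sequences(sequences)
  if (nrow(regions) == 0) {
    return(tibble(contig_id = character(0), sequence = character(0),
                  length = integer(0)))
  }
  check_regions_in_bounds(regions, sequences)
  regions <- filter(regions, .data$end - .data$start >= min_length)
  seqs <- map_chr(seq_len(nrow(regions)), function(i) {
    ci <- match(regions$contig_id[i], sequences$contig_id)
    substring(sequences$sequence[ci], regions$start[i] + 1L,
              regions$end[i])
  })
  tibble(
    contig_id = sprintf("%s:%d-%d", regions$contig_id, regions$start,
                        regions$end),
    sequence = seqs,
    length = nchar(seqs)
  )
}
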