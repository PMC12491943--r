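#' Reverse complement of nucleotide strings
#'
#' Case-preserving reverse complement; `N`/`n` map to themselves.
#'
#' @param x character vector of sequences over `A,C,G,T,N` (either case).
#' @return character vector of the same length.
#' @examples
#' revcomp("ACGTn")
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Validate a sequences tibble (contig_id + sequence columns).
check_sequences <- function(sequences, arg = "sequences") {
  if (!is.data.frame(sequences) ||
      !all(c("contig_id", "sequence") %in% names(sequences))) {
    abort(paste0("`", arg, "` must be a data frame with columns ",
                 "`contig_id` and `sequence`"))
  }
  if (anyDuplicated(sequences$contig_id)) {
    abort(paste0("duplicate contig_id in `", arg, "`"))
  }
  invisible(sequences)
}

# Named integer vector of contig lengths from a sequences tibble.
contig_lengths <- function(sequences) {
  setNames(nchar(sequences$sequence), sequences$contig_id)
}

# Per-contig cumulative count of region-covered bases: for contig of length L
# returns numeric vector P of length L + 1 with P[i + 1] = number of covered
# bases among positions [0, i). A read [s, s + len) overlaps a region iff
# P[s + len + 1] - P[s + 1] > 0. Returns a named list keyed by contig_id.
coverage_prefix <- function(regions, sequences) {
  lens <- contig_lengths(sequences)
  out <- lapply(lens, function(L) numeric(L + 1))
  if (nrow(regions) > 0) {
    by_contig <- split(regions, regions$contig_id)
    for (cid in names(by_contig)) {
      if (!cid %in% names(lens)) {
        abort(paste0("region on unknown contig `", cid, "`"))
      }
      L <- lens[[cid]]
      ind <- numeric(L)
      r <- by_contig[[cid]]
      if (any(r$start < 0 | r$end > L)) {
        abort(paste0("region out of bounds on contig `", cid, "`"))
      }
      for (i in seq_len(nrow(r))) {
        ind[(r$start[i] + 1):r$end[i]] <- 1
      }
      out[[cid]] <- c(0, cumsum(ind))
    }
  }
  out
}

# Regions tibble -> named list of IRanges (1-based closed), keyed by contig.
regions_to_iranges <- function(regions) {
  lapply(split(regions, regions$contig_id), function(r) {
    IRanges::IRanges(start = r$start + 1L, end = r$end)
  })
}
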