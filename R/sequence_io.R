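#' Read a FASTA file into a sequences tibble
#'
#' Parses multi-record, possibly line-wrapped FASTA. Case is preserved
#' (lowercase marks soft-masked bases); `U`/`u` are normalized to `T`/`t` to
#' tolerate RNA-alphabet deposits. The contig identifier is the first
#' whitespace-delimited token of the header line.
#'
#' @param path path to a FASTA file.
#' @param assembly_id,organism optional metadata recycled across records.
#' @return a tibble with columns `assembly_id`, `organism`, `contig_id`,
#'   `sequence`, `length`, one row per record in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGT", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, assembly_id = NA_character_,
                       organism = NA_character_) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    abort(paste0("malformed FASTA in ", path, ": ",
                                 conditionMessage(e)))
                  })
  if (length(set) == 0) abort(paste0("no sequences in ", path))
  ids <- stringr::str_split_i(names(set), "\\s+", 1)
  seqs <- as.character(set)
  bad <- stringr::str_detect(seqs, "[^ACGTNUacgtnu]")
  if (any(bad)) {
    abort(paste0("invalid nucleotide characters in contig `",
                 ids[which(bad)[1]], "`"))
  }
  seqs <- unname(chartr("Uu", "Tt", seqs))
  tibble(assembly_id = assembly_id, organism = organism,
         contig_id = ids, sequence = seqs, length = nchar(seqs))
}

#' Write a sequences tibble as FASTA
#'
#' Sequences are wrapped at 60 columns (the pseudo-read window length) and
#' case is preserved.
#'
#' @param sequences tibble with `contig_id` and `sequence` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  check_sequences(sequences)
  set <- Biostrings::BStringSet(setNames(sequences$sequence,
                                         sequences$contig_id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write microbial-like regions in the extended BED dialect
#'
#' Headerless TSV with columns ORGANISM, REFID, CONTIG, START, END, LENGTH,
#' NREADS, then one column per ranked taxon attribution formatted
#' `<count>_reads_<taxon>`. Coordinates are 0-based half-open so LENGTH is
#' exactly END minus START. Counts are written without thousands separators.
#'
#' @param rows tibble of annotated regions (see [annotate_regions()]) with
#'   columns `organism`, `ref_id`, `contig_id`, `start`, `end`, `length`,
#'   `n_reads` and a list-column `taxa` of tibbles with `count` and `taxon`.
#'   Rows must be sorted by (`contig_id`, `start`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(rows, path) {
  if (nrow(rows) > 0) {
    if (any(rows$start >= rows$end)) abort("BED rows must have start < end")
    if (any(rows$length != rows$end - rows$start)) {
      abort("BED row length must equal end - start")
    }
    ord <- order(rows$contig_id, rows$start)
    if (!identical(ord, seq_len(nrow(rows)))) {
      abort("BED rows must be sorted by (contig_id, start)")
    }
    lines <- vapply(seq_len(nrow(rows)), function(i) {
      taxa <- rows$taxa[[i]]
      taxon_fields <- if (!is.null(taxa) && nrow(taxa) > 0) {
        if (is.unsorted(rev(taxa$count))) {
          abort("taxon counts must be non-increasing")
        }
        sprintf("%d_reads_%s", taxa$count, taxa$taxon)
      } else {
        character(0)
      }
      paste(c(rows$organism[i], rows$ref_id[i], rows$contig_id[i],
              format(rows$start[i], scientific = FALSE),
              format(rows$end[i], scientific = FALSE),
              format(rows$length[i], scientific = FALSE),
              format(rows$n_reads[i], scientific = FALSE),
              taxon_fields),
            collapse = "\t")
    }, character(1))
  } else {
    lines <- character(0)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an extended (or plain) BED file
#'
#' Accepts the 7+ column extended dialect written by [write_bed()], or plain
#' 3-column BED (contig, start, end) as produced by third-party tools.
#'
#' @param path path to a headerless tab-separated BED file.
#' @return a tibble; for the extended dialect the columns of [write_bed()]
#'   including the `taxa` list-column, for 3-column input a tibble with
#'   `contig_id`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(organism = character(0), ref_id = character(0),
                  contig_id = character(0), start = integer(0),
                  end = integer(0), length = integer(0),
                  n_reads = integer(0), taxa = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1]])
  if (ncol1 == 3) {
    return(tibble(
      contig_id = map_chr(fields, 1),
      start = as.integer(map_chr(fields, 2)),
      end = as.integer(map_chr(fields, 3))
    ))
  }
  if (ncol1 < 7) abort("extended BED requires at least 7 columns")
  taxa <- map(fields, function(f) {
    tf <- f[-(1:7)]
    if (length(tf) == 0) {
      return(tibble(count = integer(0), taxon = character(0)))
    }
    m <- stringr::str_match(tf, "^([0-9]+)_reads_(.+)$")
    if (anyNA(m[, 1])) abort("malformed taxon field in extended BED")
    tibble(count = as.integer(m[, 2]), taxon = m[, 3])
  })
  tibble(
    organism = map_chr(fields, 1),
    ref_id = map_chr(fields, 2),
    contig_id = map_chr(fields, 3),
    start = as.integer(map_chr(fields, 4)),
    end = as.integer(map_chr(fields, 5)),
    length = as.integer(map_chr(fields, 6)),
    n_reads = as.integer(map_chr(fields, 7)),
    taxa = taxa
  )
}

# CIGAR -> reference-consumed length (M/D/N/=/X ops).
cigar_ref_length <- function(cigar) {
  ops <- stringr::str_match_all(cigar, "([0-9]+)([MIDNSHP=X])")
  vapply(ops, function(m) {
    sum(as.integer(m[m[, 3] %in% c("M", "D", "N", "=", "X"), 2]))
  }, numeric(1))
}

#' Read alignment placements from a text SAM file
#'
#' Ingestion path for externally produced alignments. Unmapped records (flag
#' bit 0x4) are dropped, the 1-based POS is converted to a 0-based start,
#' strand comes from flag bit 0x10, and the mismatch count is taken from the
#' `NM` tag when present (0 otherwise). Within each read, the primary record
#' gets rank 1 and secondary records (flag bit 0x100) are numbered in file
#' order.
#'
#' @param path path to a SAM file (text, `@`-prefixed headers then 11+
#'   column alignment lines).
#' @param sequences optional target sequences tibble; when given (or when
#'   the SAM carries `@SQ` headers) reference names are validated against it.
#' @return an alignments tibble with columns `read_id`, `taxon_label`,
#'   `contig_id`, `start`, `end`, `strand`, `mismatches`, `rank`.
#' @export
read_sam <- function(path, sequences = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  is_header <- startsWith(lines, "@")
  known <- NULL
  if (!is.null(sequences)) {
    check_sequences(sequences)
    known <- sequences$contig_id
  } else {
    sq <- lines[is_header & startsWith(lines, "@SQ")]
    if (length(sq) > 0) {
      known <- stringr::str_match(sq, "SN:([^\t]+)")[, 2]
    }
  }
  body_idx <- which(!is_header & nzchar(lines))
  rows <- vector("list", length(body_idx))
  for (i in seq_along(body_idx)) {
    ln <- body_idx[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) {
      abort(paste0("SAM line ", ln, ": fewer than 11 mandatory columns"))
    }
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next
    if (!is.null(known) && !f[3] %in% known) {
      abort(paste0("SAM line ", ln, ": reference `", f[3],
                   "` absent from target assembly"))
    }
    len <- if (f[10] != "*") nchar(f[10]) else cigar_ref_length(f[6])
    nm <- stringr::str_match(paste(f[-(1:11)], collapse = "\t"),
                             "NM:i:([0-9]+)")[, 2]
    start <- as.integer(f[4]) - 1L
    rows[[i]] <- tibble(
      read_id = f[1],
      contig_id = f[3],
      start = start,
      end = start + as.integer(len),
      strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
      mismatches = if (is.na(nm)) 0L else as.integer(nm),
      secondary = bitwAnd(flag, 256L) != 0L
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(read_id = character(0), taxon_label = character(0),
                  contig_id = character(0), start = integer(0),
                  end = integer(0), strand = character(0),
                  mismatches = integer(0), rank = integer(0)))
  }
  out %>%
    group_by(.data$read_id) %>%
    mutate(rank = order(order(.data$secondary, seq_len(n())))) %>%
    ungroup() %>%
    mutate(taxon_label = parse_taxon_label(.data$read_id)) %>%
    select("read_id", "taxon_label", "contig_id", "start", "end",
           "strand", "mismatches", "rank")
}

#' Write alignments as a text SAM file
#'
#' One line per retained placement: flag bit 0x10 for minus-strand hits,
#' 0x100 on ranks above 1, `NM` tag carrying the mismatch count, and `@SQ`
#' headers for every target contig.
#'
#' @param alignments alignments tibble (see [align_reads()]).
#' @param sequences target sequences tibble (for `@SQ` headers).
#' @param path output path.
#' @param read_seqs optional named character vector of read sequences keyed
#'   by `read_id`; when absent SEQ is written as `*`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, sequences, path, read_seqs = NULL) {
  check_sequences(sequences)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", sequences$contig_id,
                   nchar(sequences$sequence)))
  body <- character(0)
  if (nrow(alignments) > 0) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L) +
      ifelse(alignments$rank > 1L, 256L, 0L)
    len <- alignments$end - alignments$start
    seqf <- if (!is.null(read_seqs)) {
      s <- unname(read_seqs[alignments$read_id])
      ifelse(alignments$strand == "-", revcomp(s), s)
    } else {
      rep("*", nrow(alignments))
    }
    body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                    alignments$read_id, flag, alignments$contig_id,
                    alignments$start + 1L, len, seqf,
                    alignments$mismatches)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
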