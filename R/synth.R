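sample_bases <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a synthetic host assembly
#'
#' I.i.d. random nucleotides at a given GC content — a deliberately
#' repeat-free background so that detected regions can only come from
#' planted material.
#'
#' @param n_contigs number of contigs.
#' @param lengths contig lengths in bases (recycled to `n_contigs`).
#' @param gc GC fraction in (0, 1).
#' @param seed RNG seed.
#' @param prefix contig id prefix.
#' @return a sequences tibble.
#' @examples
#' generate_host(2, c(1000, 2000), seed = 1)
#' @export
generate_host <- function(n_contigs, lengths, gc = 0.5, seed = 1L,
                          prefix = "host") {
  if (gc <= 0 || gc >= 1) abort("`gc` must be strictly between 0 and 1")
  lengths <- rep_len(lengths, n_contigs)
  if (any(lengths < 1)) abort("contig lengths must be >= 1")
  withr::with_seed(seed, {
    seqs <- vapply(lengths, sample_bases, character(1), gc = gc)
  })
  tibble(contig_id = sprintf("%s_c%d", prefix, seq_len(n_contigs)),
         sequence = seqs, length = lengths)
}

#' Generate taxon-labelled source genomes
#'
#' Convenience wrapper producing one single-contig genome per taxon, each
#' with its own GC content so taxa are compositionally distinguishable.
#'
#' @param taxa character vector of taxon labels.
#' @param length genome length in bases (recycled).
#' @param gc GC fraction per taxon (recycled).
#' @param seed RNG seed.
#' @return a sequences tibble with a `taxon_label` column.
#' @export
generate_sources <- function(taxa, length = 20000L, gc = 0.5, seed = 2L) {
  length <- rep_len(length, base::length(taxa))
  gc <- rep_len(gc, base::length(taxa))
  withr::with_seed(seed, {
    seqs <- vapply(seq_along(taxa), function(i) {
      sample_bases(length[i], gc[i])
    }, character(1))
  })
  tibble(taxon_label = taxa,
         contig_id = paste0(taxa, "_genome"),
         sequence = seqs, length = length)
}

mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(list(sequence = seq, n_subs = 0L))
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  list(sequence = paste(ch, collapse = ""), n_subs = length(hit))
}

#' Plant contaminant inserts into a host assembly
#'
#' Copies random fragments of the source genomes into the host at
#' uniformly drawn non-overlapping positions, substituting each base
#' independently at the per-insert divergence rate, and records the exact
#' truth coordinates. `copy_number` plants the *same* source fragment
#' several times, each copy independently re-diverged — a small repeat
#' family, which is what makes multimapper retention matter.
#'
#' @param host host sequences tibble ([generate_host()]).
#' @param sources taxon-labelled source sequences tibble
#'   ([generate_sources()]).
#' @param n_inserts number of distinct source fragments to plant.
#' @param insert_length fragment length in bases (>= 60 so at least one
#'   pseudo-read window fits).
#' @param divergence per-base substitution rate applied to each planted
#'   copy.
#' @param copy_number copies planted per fragment.
#' @param seed RNG seed.
#' @return an object of class `mm_synthetic_truth`: list with `host` (the
#'   modified assembly), `sources`, and `truth_regions` (tibble with
#'   `contig_id`, `start`, `end`, `taxon_label`, `source_contig`,
#'   `source_start`, `insert`, `copy`, `n_subs`).
#' @export
plant_inserts <- function(host, sources, n_inserts = 4L,
                          insert_length = 5000L, divergence = 0,
                          copy_number = 1L, seed = 3L) {
  check_sequences(host, "host")
  if (insert_length < 60) abort("`insert_length` must be >= 60")
  if (!"taxon_label" %in% names(sources)) {
    abort("`sources` must carry a `taxon_label` column")
  }
  if (all(nchar(sources$sequence) < insert_length)) {
    abort("no source contig is long enough for `insert_length`")
  }
  withr::with_seed(seed, {
    host_seqs <- host$sequence
    lens <- nchar(host_seqs)
    occupied <- lapply(lens, function(L) IRanges::IRanges())
    truth <- list()
    for (ins in seq_len(n_inserts)) {
      eligible <- which(nchar(sources$sequence) >= insert_length)
      si <- eligible[sample.int(length(eligible), 1)]
      smax <- nchar(sources$sequence[si]) - insert_length
      sstart <- sample.int(smax + 1, 1) - 1L
      frag <- substring(sources$sequence[si], sstart + 1L,
                        sstart + insert_length)
      for (cp in seq_len(copy_number)) {
        placed <- FALSE
        for (attempt in seq_len(1000)) {
          hi <- sample.int(length(host_seqs), 1)
          if (lens[hi] < insert_length) next
          hstart <- sample.int(lens[hi] - insert_length + 1, 1) - 1L
          cand <- IRanges::IRanges(start = hstart + 1L,
                                   width = insert_length)
          if (length(IRanges::findOverlaps(cand, occupied[[hi]])) > 0) next
          mut <- mutate_sequence(frag, divergence)
          substr(host_seqs[hi], hstart + 1L,
                 hstart + insert_length) <- mut$sequence
          occupied[[hi]] <- c(occupied[[hi]], cand)
          truth[[length(truth) + 1]] <- tibble(
            contig_id = host$contig_id[hi],
            start = hstart, end = hstart + insert_length,
            taxon_label = sources$taxon_label[si],
            source_contig = sources$contig_id[si],
            source_start = sstart,
            insert = ins, copy = cp, n_subs = mut$n_subs
          )
          placed <- TRUE
          break
        }
        if (!placed) {
          abort("could not place all inserts disjointly after 1000 attempts")
        }
      }
    }
  })
  truth <- bind_rows(truth)
  truth <- truth[order(truth$contig_id, truth$start, method = "radix"), ]
  structure(list(
    host = mutate(host, sequence = host_seqs),
    sources = sources,
    truth_regions = truth
  ), class = "mm_synthetic_truth")
}

#' @export
print.mm_synthetic_truth <- function(x, ...) {
  cat("<mm_synthetic_truth>", nrow(x$host), "host contigs;",
      nrow(x$truth_regions), "planted inserts (",
      sum(x$truth_regions$end - x$truth_regions$start), "bases )\n")
  invisible(x)
}

#' Sample reads from a host assembly
#'
#' Draws fixed-length reads whose starts are, with probability
#' `inside_fraction`, uniform among all starts overlapping a region by at
#' least one base, and otherwise uniform among all valid starts — the
#' knob that emulates read sets enriched (or not) for microbial-like
#' regions. An optional ancient-DNA-style damage toggle applies terminal
#' C-to-T substitutions at the 5' end of each read.
#'
#' @param host sequences tibble.
#' @param regions regions tibble (may be empty when
#'   `inside_fraction = 0`).
#' @param n_reads number of reads.
#' @param read_length read length in bases.
#' @param inside_fraction fraction of reads forced to overlap a region.
#' @param seed RNG seed.
#' @param damage_rate probability of C-to-T substitution at each of the
#'   first 3 bases (default 0: no damage model).
#' @return a tibble with `read_id`, `contig_id`, `start`, `end`, `strand`,
#'   `sequence`.
#' @export
sample_reads <- function(host, regions, n_reads, read_length = 60L,
                         inside_fraction = 0, seed = 4L,
                         damage_rate = 0) {
  check_sequences(host, "host")
  if (inside_fraction < 0 || inside_fraction > 1) {
    abort("`inside_fraction` must be in [0, 1]")
  }
  if (n_reads == 0) {
    return(tibble(read_id = character(0), contig_id = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), sequence = character(0)))
  }
  lens <- contig_lengths(host)
  if (read_length > min(lens)) {
    abort("`read_length` exceeds the shortest contig")
  }
  # enumerate all valid (contig, start) pairs and which overlap a region
  prefix <- coverage_prefix(regions, host)
  all_starts <- bind_rows(lapply(names(lens), function(cid) {
    s <- 0:(lens[[cid]] - read_length)
    P <- prefix[[cid]]
    tibble(contig_id = cid, start = s,
           inside = P[s + read_length + 1] - P[s + 1] > 0)
  }))
  if (inside_fraction > 0 && !any(all_starts$inside)) {
    abort("`inside_fraction` > 0 requires a non-empty region set")
  }
  withr::with_seed(seed, {
    n_in <- round(n_reads * inside_fraction)
    pool_in <- which(all_starts$inside)
    pick <- c(
      if (n_in > 0) pool_in[sample.int(length(pool_in), n_in,
                                       replace = TRUE)],
      sample.int(nrow(all_starts), n_reads - n_in, replace = TRUE)
    )
    pick <- sample(pick)  # shuffle inside/outside ordering
    reads <- tibble(
      read_id = sprintf("sample_read_%d", seq_len(n_reads)),
      contig_id = all_starts$contig_id[pick],
      start = all_starts$start[pick],
      end = all_starts$start[pick] + read_length,
      strand = "+"
    )
    seqs <- map_chr(seq_len(n_reads), function(i) {
      ci <- match(reads$contig_id[i], host$contig_id)
      substring(host$sequence[ci], reads$start[i] + 1L, reads$end[i])
    })
    if (damage_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        for (p in 1:3) {
          if (substring(s, p, p) == "C" && runif(1) < damage_rate) {
            substr(s, p, p) <- "T"
          }
        }
        s
      }, character(1), USE.NAMES = FALSE)
    }
  })
  mutate(reads, sequence = seqs)
}
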