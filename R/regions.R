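#' Call microbial-like regions from alignments
#'
#' Merges the intervals of retained pseudo-read placements into maximal
#' runs of depth >= 1 (merge distance 0: overlapping and bookended
#' intervals join, runs separated by at least one zero-depth base stay
#' apart). Each region is annotated with its supporting-read count and the
#' per-taxon placement counts of alignments overlapping it by at least one
#' base. Placements whose read id does not parse as a pseudo-read (sample
#' reads) contribute to coverage but not to `n_reads` or taxon counts.
#'
#' @param alignments alignments tibble ([align_reads()] or [read_sam()]).
#' @param sequences target sequences tibble.
#' @return a regions tibble sorted by (`contig_id`, `start`) with columns
#'   `contig_id`, `start`, `end` (0-based half-open), `n_reads`, and a
#'   list-column `taxa` of per-taxon count tibbles (count-descending,
#'   ties alphabetical).
#' @export
call_regions <- function(alignments, sequences) {
  check_sequences(sequences, "target")
  if (nrow(alignments) == 0) return(empty_regions())
  lens <- contig_lengths(sequences)
  unknown <- setdiff(alignments$contig_id, names(lens))
  if (length(unknown) > 0) {
    abort(paste0("alignment on unknown contig `", unknown[1], "`"))
  }
  oob <- alignments$start < 0 |
    alignments$end > lens[alignments$contig_id]
  if (any(oob)) {
    bad <- which(oob)[1]
    abort(paste0("alignment of read `", alignments$read_id[bad],
                 "` at ", alignments$contig_id[bad], ":",
                 alignments$start[bad], "-", alignments$end[bad],
                 " exceeds contig bounds"))
  }
  out <- lapply(split(alignments, alignments$contig_id), function(a) {
    ir <- IRanges::IRanges(start = a$start + 1L, end = a$end)
    reg <- IRanges::reduce(ir)  # min.gapwidth = 1: bookended runs merge
    ov <- IRanges::findOverlaps(reg, ir, minoverlap = 1L)
    lab <- a$taxon_label[S4Vectors::subjectHits(ov)]
    grp <- S4Vectors::queryHits(ov)
    keep <- !is.na(lab)
    counts <- tibble(region = grp[keep], taxon = lab[keep]) %>%
      count(.data$region, .data$taxon, name = "count")
    taxa <- vector("list", length(reg))
    for (i in seq_along(taxa)) {
      taxa[[i]] <- tibble(count = integer(0), taxon = character(0))
    }
    for (g in split(counts, counts$region)) {
      ord <- order(-g$count, g$taxon, method = "radix")
      taxa[[g$region[1]]] <- tibble(count = g$count[ord],
                                    taxon = g$taxon[ord])
    }
    tibble(
      contig_id = a$contig_id[1],
      start = IRanges::start(reg) - 1L,
      end = IRanges::end(reg),
      n_reads = map_int(taxa, ~ sum(.x$count)),
      taxa = taxa
    )
  })
  out <- bind_rows(out)
  out[order(out$contig_id, out$start, method = "radix"), ]
}

empty_regions <- function() {
  tibble(contig_id = character(0), start = integer(0), end = integer(0),
         n_reads = integer(0), taxa = list())
}

#' Annotate regions as extended BED rows
#'
#' Produces one row per region in the extended BED schema: ORGANISM, REFID,
#' CONTIG, START, END, LENGTH, NREADS, then the `top_taxa` most abundant
#' source taxa as `<count>_reads_<taxon>` fields (counts non-increasing,
#' ties broken alphabetically).
#'
#' @param regions regions tibble from [call_regions()].
#' @param organism,ref_id assembly metadata written into every row.
#' @param top_taxa number of ranked taxon attributions to keep (default 5).
#' @return a BED-row tibble suitable for [write_bed()].
#' @export
annotate_regions <- function(regions, organism = NA_character_,
                             ref_id = NA_character_, top_taxa = 5L) {
  if (top_taxa < 1) abort("`top_taxa` must be >= 1")
  taxa <- map(regions$taxa, function(t) {
    if (is.null(t) || nrow(t) == 0) return(t)
    ord <- order(-t$count, t$taxon, method = "radix")
    t[utils::head(ord, top_taxa), ]
  })
  tibble(
    organism = organism,
    ref_id = ref_id,
    contig_id = regions$contig_id,
    start = regions$start,
    end = regions$end,
    length = regions$end - regions$start,
    n_reads = regions$n_reads,
    taxa = taxa
  )
}

#' Breadth of coverage of microbial-like regions
#'
#' Fraction of reference nucleotides covered at least once by aligned
#' pseudo-reads, i.e. total region bases over total assembly bases, at
#' assembly or per-contig resolution.
#'
#' @param regions regions tibble (disjoint per contig, as guaranteed by
#'   [call_regions()]).
#' @param sequences target sequences tibble.
#' @param by `"assembly"` for a single overall fraction, `"contig"` for
#'   one row per contig.
#' @return a tibble with `total_bases`, `covered_bases`, `breadth` (plus
#'   `contig_id` when `by = "contig"`).
#' @export
breadth_of_coverage <- function(regions, sequences,
                                by = c("assembly", "contig")) {
  by <- match.arg(by)
  check_sequences(sequences, "target")
  lens <- contig_lengths(sequences)
  covered <- setNames(numeric(length(lens)), names(lens))
  if (nrow(regions) > 0) {
    unknown <- setdiff(regions$contig_id, names(lens))
    if (length(unknown) > 0) {
      abort(paste0("region on unknown contig `", unknown[1], "`"))
    }
    for (cid in unique(regions$contig_id)) {
      r <- regions[regions$contig_id == cid, ]
      if (any(r$start < 0 | r$end > lens[[cid]])) {
        abort(paste0("region out of bounds on contig `", cid, "`"))
      }
      ir <- IRanges::IRanges(start = r$start + 1L, end = r$end)
      if (sum(IRanges::width(IRanges::reduce(ir, min.gapwidth = 0L))) <
          sum(r$end - r$start)) {
        abort(paste0("overlapping regions on contig `", cid, "`"))
      }
      covered[[cid]] <- sum(r$end - r$start)
    }
  }
  if (by == "assembly") {
    tibble(total_bases = sum(lens), covered_bases = sum(covered),
           breadth = if (sum(lens) > 0) sum(covered) / sum(lens) else 0)
  } else {
    tibble(contig_id = names(lens), total_bases = unname(lens),
           covered_bases = unname(covered),
           breadth = unname(ifelse(lens > 0, covered / lens, 0)))
  }
}

#' Per-contig microbial-like fraction distribution
#'
#' Computes the microbial-like fraction of every contig and summarises the
#' distribution: a histogram over `bins` equal-width bins of \[0, 1\] and
#' the counts of contigs at the two extremes (fraction <= `eps` and
#' >= 1 - `eps`), which detects the bimodal profile typical of assemblies
#' mixing clean host contigs with wholly contaminant contigs.
#'
#' @inheritParams breadth_of_coverage
#' @param bins number of histogram bins.
#' @param eps half-width for the mode counts at 0 and 1.
#' @param contigs optional character vector restricting the summary to a
#'   subset of contigs (e.g. contigs with at least one aligned sample read).
#' @return an object of class `mm_contig_fractions`: a list with
#'   `fractions` (per-contig tibble), `histogram` (bin tibble),
#'   `n_low`/`n_high` (mode counts) and `eps`. Has an [autoplot()] method.
#' @export
contig_fractions <- function(regions, sequences, bins = 100L, eps = 0.01,
                             contigs = NULL) {
  fr <- breadth_of_coverage(regions, sequences, by = "contig")
  if (!is.null(contigs)) fr <- filter(fr, .data$contig_id %in% contigs)
  breaks <- seq(0, 1, length.out = bins + 1L)
  bin <- pmin(findInterval(fr$breadth, breaks, rightmost.closed = TRUE),
              bins)
  hist <- tibble(bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
                 count = tabulate(bin, nbins = bins))
  structure(list(
    fractions = fr %>% rename(fraction = "breadth"),
    histogram = hist,
    n_low = sum(fr$breadth <= eps),
    n_high = sum(fr$breadth >= 1 - eps),
    eps = eps
  ), class = "mm_contig_fractions")
}

#' @export
print.mm_contig_fractions <- function(x, ...) {
  cat("<mm_contig_fractions>", nrow(x$fractions), "contigs;",
      x$n_low, "at fraction <=", x$eps, "and", x$n_high,
      "at fraction >=", 1 - x$eps, "\n")
  invisible(x)
}

#' @export
autoplot.mm_contig_fractions <- function(object, ...) {
  ggplot2::ggplot(object$fractions, ggplot2::aes(x = .data$fraction)) +
    ggplot2::geom_histogram(breaks = c(object$histogram$bin_left, 1),
                            fill = "grey30") +
    ggplot2::labs(x = "microbial-like fraction of contig",
                  y = "contigs") +
    ggplot2::theme_minimal()
}

#' @rdname contig_fractions
#' @param x an `mm_contig_fractions` object.
#' @param ... passed on to [autoplot()].
#' @export
plot_contig_fractions <- function(x, ...) autoplot(x, ...)

#' Genome-by-taxon abundance table
#'
#' Tabulates pseudo-read placement counts per (assembly, taxon) into a wide
#' assemblies-by-taxa table. With `normalize = TRUE` each taxon column is
#' min-max scaled to \[0, 1\] across assemblies (constant columns map to 0),
#' the scaling used for cross-assembly abundance heatmaps.
#'
#' @param counts long tibble with columns `assembly_id`, `taxon_label`,
#'   and `n` (placement counts), e.g. accumulated from the `taxa` columns
#'   of per-assembly region sets.
#' @param normalize min-max scale each taxon column.
#' @return a wide tibble, one row per assembly, one column per taxon.
#' @export
genome_taxon_table <- function(counts, normalize = TRUE) {
  if (nrow(counts) == 0 || all(counts$n == 0)) {
    abort("at least one assembly with nonzero counts is required")
  }
  wide <- counts %>%
    group_by(.data$assembly_id, .data$taxon_label) %>%
    summarise(n = sum(.data$n), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "taxon_label", values_from = "n",
                       values_fill = 0, names_sort = TRUE) %>%
    arrange(.data$assembly_id)
  if (normalize) {
    wide <- mutate(wide, dplyr::across(
      -"assembly_id",
      function(x) {
        rng <- range(x)
        if (rng[1] == rng[2]) rep(0, length(x))
        else (x - rng[1]) / (rng[2] - rng[1])
      }
    ))
  }
  wide
}

#' Heatmap of a genome-by-taxon abundance table
#'
#' @param table wide tibble from [genome_taxon_table()].
#' @return a ggplot object (tile heatmap, 0 lowest to 1 highest when the
#'   table is normalized).
#' @export
plot_taxon_heatmap <- function(table) {
  long <- tidyr::pivot_longer(table, -"assembly_id",
                              names_to = "taxon_label",
                              values_to = "abundance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$taxon_label,
                                     y = .data$assembly_id,
                                     fill = .data$abundance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "abundance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
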