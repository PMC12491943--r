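#' Workflow run configuration
#'
#' Bundles the tunable parameters of the detection workflow with their
#' defaults: 60 bp windows at a 10 bp step, up to 10 multimappers, top-5
#' taxon attributions and 300 permutations; seed length 15 and a mismatch
#' cap of 3 (5% of a 60 bp read) parameterise the internal aligner; the
#' RNG seed defaults to 214.
#'
#' @param window,step pseudo-read window length and step, bases.
#' @param multimap multimap cap per read.
#' @param max_mismatch mismatch cap per placement.
#' @param seed_length aligner seed length, bases.
#' @param top_taxa ranked taxon attributions per region.
#' @param n_perm permutations for the enrichment test.
#' @param mask_mode `"hard"` or `"soft"`.
#' @param rng_seed RNG seed.
#' @return a named list of class `mm_config`.
#' @export
run_config <- function(window = 60L, step = 10L, multimap = 10L,
                       max_mismatch = 3L, seed_length = 15L,
                       top_taxa = 5L, n_perm = 300L,
                       mask_mode = c("hard", "soft"), rng_seed = 214L) {
  mask_mode <- match.arg(mask_mode)
  if (step < 1 || step > window) abort("1 <= step <= window required")
  structure(list(window = as.integer(window), step = as.integer(step),
                 multimap = as.integer(multimap),
                 max_mismatch = as.integer(max_mismatch),
                 seed_length = as.integer(seed_length),
                 top_taxa = as.integer(top_taxa),
                 n_perm = as.integer(n_perm), mask_mode = mask_mode,
                 rng_seed = as.integer(rng_seed)),
            class = "mm_config")
}

#' Detect, annotate and mask microbial-like regions
#'
#' One-shot pipeline: fragment the source genomes into pseudo-reads, align
#' them to the target (or ingest externally produced SAM placements), merge
#' covered intervals into regions, annotate them with ranked taxon
#' attributions, compute breadth of coverage, and mask the target. When
#' `out_dir` is given, the extended BED, masked FASTA, per-contig breadth
#' TSV and a JSON run manifest are written there.
#'
#' @param target target sequences tibble, or path to a FASTA file.
#' @param sources taxon-labelled source sequences tibble, path to a FASTA
#'   file (taxon taken from the contig id), or `NULL` when `sam` is given.
#' @param sam optional path to a SAM file of pre-computed pseudo-read
#'   placements, bypassing the internal aligner.
#' @param config an [run_config()] list.
#' @param organism,ref_id assembly metadata for the BED output.
#' @param out_dir optional output directory.
#' @return an object of class `mm_detection`: list with `regions`,
#'   `bed` (annotated rows), `breadth`, `contig_breadth`, `masked`,
#'   `alignments` and `config`.
#' @export
detect <- function(target, sources = NULL, sam = NULL,
                   config = run_config(), organism = NA_character_,
                   ref_id = NA_character_, out_dir = NULL) {
  if (is.character(target)) target <- read_fasta(target)
  check_sequences(target, "target")
  if (is.null(sam)) {
    if (is.null(sources)) abort("either `sources` or `sam` is required")
    if (is.character(sources)) {
      sources <- read_fasta(sources) %>%
        mutate(taxon_label = .data$contig_id)
    }
    reads <- fragment_set(sources, window = config$window,
                          step = config$step)
    alignments <- if (nrow(reads) == 0) {
      empty_alignments()
    } else {
      idx <- build_index(target, seed = config$seed_length)
      align_reads(reads, idx, max_mismatch = config$max_mismatch,
                  multimap = config$multimap)
    }
  } else {
    alignments <- read_sam(sam, sequences = target)
  }
  regions <- call_regions(alignments, target)
  bed <- annotate_regions(regions, organism = organism, ref_id = ref_id,
                          top_taxa = config$top_taxa)
  res <- structure(list(
    regions = regions,
    bed = bed,
    breadth = breadth_of_coverage(regions, target),
    contig_breadth = breadth_of_coverage(regions, target, by = "contig"),
    masked = mask_fasta(target, regions, mode = config$mask_mode),
    alignments = alignments,
    config = config
  ), class = "mm_detection")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bed(bed, file.path(out_dir, "regions.bed"))
    write_fasta(res$masked, file.path(out_dir, "masked.fasta"))
    readr::write_tsv(res$contig_breadth,
                     file.path(out_dir, "contig_breadth.tsv"))
    manifest <- list(
      config = unclass(config),
      n_contigs = nrow(target),
      n_alignments = nrow(alignments),
      n_regions = nrow(regions),
      breadth = res$breadth$breadth,
      target_md5 = vapply(target$sequence,
                          function(s) digest_md5(s), character(1),
                          USE.NAMES = FALSE)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

digest_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

#' @export
print.mm_detection <- function(x, ...) {
  cat("<mm_detection>", nrow(x$regions), "microbial-like regions;",
      sprintf("breadth %.3f%%", 100 * x$breadth$breadth), "\n")
  invisible(x)
}

#' Validate sample reads against a region set
#'
#' Downstream validation: runs the intersection enrichment test of the
#' read placements against the microbial-like regions and summarises the
#' per-contig microbial-like fractions, optionally restricted to contigs
#' with at least one placed read.
#'
#' @param placements read placements tibble (`contig_id`, `start`, `end`),
#'   or path to a SAM or 6+-column BED file of placements.
#' @param regions regions tibble, or path to a BED file.
#' @param target target sequences tibble, or path to a FASTA file.
#' @param config an [run_config()] list.
#' @param mapped_contigs_only restrict contig fractions to contigs
#'   carrying at least one read placement.
#' @return list with `enrichment` (an `mm_enrichment`) and
#'   `contig_fractions` (an `mm_contig_fractions`).
#' @export
validate_reads <- function(placements, regions, target,
                           config = run_config(),
                           mapped_contigs_only = FALSE) {
  if (is.character(target)) target <- read_fasta(target)
  if (is.character(regions)) {
    if (!file.exists(regions)) {
      abort(paste0("region file not found: ", regions))
    }
    regions <- read_bed(regions)
  }
  if (is.character(placements)) {
    if (!file.exists(placements)) {
      abort(paste0("placement file not found: ", placements))
    }
    placements <- if (grepl("\\.sam$", placements, ignore.case = TRUE)) {
      filter(read_sam(placements, sequences = target), .data$rank == 1L)
    } else {
      read_placement_bed(placements)
    }
  }
  enr <- enrichment_test(placements, regions, target,
                         n_perm = config$n_perm, seed = config$rng_seed)
  contigs <- if (mapped_contigs_only) unique(placements$contig_id) else NULL
  list(enrichment = enr,
       contig_fractions = contig_fractions(regions, target,
                                           contigs = contigs))
}

# 6-column BED of read placements: contig, start, end, name, score, strand.
read_placement_bed <- function(path) {
  tb <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  if (ncol(tb) < 3) abort("placement BED needs at least 3 columns")
  out <- tibble(contig_id = as.character(tb[[1]]),
                start = as.integer(tb[[2]]), end = as.integer(tb[[3]]))
  out$read_id <- if (ncol(tb) >= 4) as.character(tb[[4]]) else
    sprintf("read_%d", seq_len(nrow(out)))
  out$strand <- if (ncol(tb) >= 6) as.character(tb[[6]]) else "+"
  out
}

#' Write read placements as 6-column BED
#'
#' @param placements placements tibble with `contig_id`, `start`, `end`,
#'   and optionally `read_id` and `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_placement_bed <- function(placements, path) {
  ids <- if ("read_id" %in% names(placements)) placements$read_id else
    sprintf("read_%d", seq_len(nrow(placements)))
  strand <- if ("strand" %in% names(placements)) placements$strand else "+"
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", placements$contig_id,
                     placements$start, placements$end, ids, strand),
             path)
  invisible(path)
}
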