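# Reads longer than their contig cannot be re-placed under the null; they
# are excluded from both observed and permuted counts, with a warning.
drop_oversized_reads <- function(placements, sequences) {
  lens <- contig_lengths(sequences)
  unknown <- setdiff(placements$contig_id, names(lens))
  if (length(unknown) > 0) {
    abort(paste0("placement on unknown contig `", unknown[1], "`"))
  }
  too_long <- (placements$end - placements$start) >
    lens[placements$contig_id]
  if (any(too_long)) {
    warn(paste0(sum(too_long), " read(s) longer than their contig were ",
                "excluded from the intersection test"))
    placements <- placements[!too_long, ]
  }
  placements
}

#' Observed read/region intersection
#'
#' Fraction of read placements that overlap any microbial-like region by at
#' least one base on the same contig (distance-0 closest-interval
#' semantics). Intervals are 0-based half-open, so a read ending where a
#' region starts does not intersect it.
#'
#' @param placements read placements tibble (`contig_id`, `start`, `end`;
#'   one row per read — primary placements only).
#' @param regions regions tibble (`contig_id`, `start`, `end`).
#' @return a one-row tibble with `n_reads`, `n_intersecting`,
#'   `observed_fraction`, and `percent` (the fraction as a percentage
#'   rounded to the integer, the display convention for these results).
#' @examples
#' reads <- tibble::tibble(contig_id = "c1", start = 10, end = 70)
#' regs <- tibble::tibble(contig_id = "c1", start = 69, end = 200)
#' observed_intersection(reads, regs)  # 1-base overlap counts
#' @export
observed_intersection <- function(placements, regions) {
  if (nrow(placements) == 0) abort("empty read set")
  hit <- reads_hit_regions(placements, regions)
  n <- nrow(placements)
  k <- sum(hit)
  tibble(n_reads = n, n_intersecting = k, observed_fraction = k / n,
         percent = round(100 * k / n))
}

# Logical vector: does each placement overlap >= 1 region base?
reads_hit_regions <- function(placements, regions) {
  hit <- logical(nrow(placements))
  if (nrow(regions) == 0) return(hit)
  reg_by_contig <- regions_to_iranges(regions)
  for (cid in unique(placements$contig_id)) {
    idx <- which(placements$contig_id == cid)
    reg <- reg_by_contig[[cid]]
    if (is.null(reg)) next
    ir <- IRanges::IRanges(start = placements$start[idx] + 1L,
                           end = placements$end[idx])
    hit[idx] <- IRanges::countOverlaps(ir, reg, minoverlap = 1L) > 0
  }
  hit
}

#' Permutation null for the intersection fraction
#'
#' Re-places every read uniformly at random within its own contig (start
#' drawn from the valid range 0 .. contig_length - read_length, keeping
#' contig assignment and read length fixed) and recomputes the
#' intersection fraction, `n_perm` times. Deterministic under `seed`.
#'
#' @inheritParams observed_intersection
#' @param sequences target sequences tibble (for contig lengths).
#' @param n_perm number of permutations (default 300).
#' @param seed RNG seed (default 214).
#' @return numeric vector of `n_perm` null intersection fractions.
#' @export
permute_placements <- function(placements, regions, sequences,
                               n_perm = 300L, seed = 214L) {
  placements <- drop_oversized_reads(placements, sequences)
  if (nrow(placements) == 0) abort("empty read set")
  prefix <- coverage_prefix(regions, sequences)
  lens <- contig_lengths(sequences)
  # flatten per-contig prefix sums into one vector with offsets
  offs <- c(0, cumsum(vapply(prefix, length, numeric(1))))
  big <- unlist(prefix, use.names = FALSE)
  ci <- match(placements$contig_id, names(prefix))
  off <- offs[ci]
  rlen <- placements$end - placements$start
  n_valid <- lens[placements$contig_id] - rlen + 1
  withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      s <- floor(runif(length(rlen)) * n_valid)  # 0-based starts
      mean(big[off + s + rlen + 1] - big[off + s + 1] > 0)
    }, numeric(1))
  })
}

#' Analytic expectation of the null intersection fraction
#'
#' Closed-form counterpart of [permute_placements()]: for each read the
#' overlap probability is the number of valid starts whose interval
#' overlaps at least one region base, over the number of valid starts,
#' computed by direct enumeration; the expectation is the mean over reads.
#'
#' @inheritParams permute_placements
#' @return expected intersection fraction in \[0, 1\].
#' @export
analytic_null_expectation <- function(placements, regions, sequences) {
  placements <- drop_oversized_reads(placements, sequences)
  if (nrow(placements) == 0) abort("empty read set")
  prefix <- coverage_prefix(regions, sequences)
  lens <- contig_lengths(sequences)
  key <- paste(placements$contig_id, placements$end - placements$start)
  probs <- vapply(split(seq_len(nrow(placements)), key), function(idx) {
    cid <- placements$contig_id[idx[1]]
    rlen <- placements$end[idx[1]] - placements$start[idx[1]]
    P <- prefix[[cid]]
    L <- lens[[cid]]
    s <- 0:(L - rlen)  # all valid starts
    sum(P[s + rlen + 1] - P[s + 1] > 0) / length(s)
  }, numeric(1))
  tally <- lengths(split(seq_len(nrow(placements)), key))
  sum(probs * tally) / sum(tally)
}

#' Empirical p-value of a permutation test
#'
#' Add-one estimator p = (1 + #\{null >= observed\}) / (1 + n_perm); ties
#' count against significance and p is never 0 (floor 1 / (n_perm + 1);
#' 1/301 with the default 300 permutations).
#'
#' @param observed_fraction observed intersection fraction.
#' @param null_fractions numeric vector of permuted fractions.
#' @return p-value in (0, 1\].
#' @export
empirical_p <- function(observed_fraction, null_fractions) {
  if (length(null_fractions) == 0) abort("`null_fractions` is empty")
  (1 + sum(null_fractions >= observed_fraction)) /
    (1 + length(null_fractions))
}

#' Read/region intersection enrichment test
#'
#' One-stop wrapper: observed intersection fraction, random-placement
#' permutation null, add-one empirical p-value, and the analytic null
#' expectation for reference.
#'
#' @inheritParams permute_placements
#' @return an object of class `mm_enrichment` with [tidy()], [glance()]
#'   and [autoplot()] methods.
#' @export
enrichment_test <- function(placements, regions, sequences,
                            n_perm = 300L, seed = 214L) {
  placements <- drop_oversized_reads(placements, sequences)
  obs <- observed_intersection(placements, regions)
  null_fr <- permute_placements(placements, regions, sequences,
                                n_perm = n_perm, seed = seed)
  structure(list(
    n_reads = obs$n_reads,
    n_intersecting = obs$n_intersecting,
    observed_fraction = obs$observed_fraction,
    null_fractions = null_fr,
    null_expectation = analytic_null_expectation(placements, regions,
                                                 sequences),
    empirical_p = empirical_p(obs$observed_fraction, null_fr),
    n_perm = as.integer(n_perm),
    seed = as.integer(seed)
  ), class = "mm_enrichment")
}

#' @export
print.mm_enrichment <- function(x, ...) {
  cat("<mm_enrichment>\n")
  cat(sprintf("  %d of %d reads intersect microbial-like regions (%d%%)\n",
              x$n_intersecting, x$n_reads,
              round(100 * x$observed_fraction)))
  cat(sprintf("  null: %.1f%% +/- %.1f%% over %d permutations (analytic %.1f%%)\n",
              100 * mean(x$null_fractions), 100 * stats::sd(x$null_fractions),
              x$n_perm, 100 * x$null_expectation))
  cat(sprintf("  empirical p = %.5g\n", x$empirical_p))
  invisible(x)
}

#' @rdname enrichment_test
#' @param x an `mm_enrichment` object.
#' @param ... unused.
#' @export
tidy.mm_enrichment <- function(x, ...) {
  tibble(
    n_reads = x$n_reads,
    n_intersecting = x$n_intersecting,
    observed_fraction = x$observed_fraction,
    null_mean = mean(x$null_fractions),
    null_sd = stats::sd(x$null_fractions),
    null_expectation = x$null_expectation,
    p.value = x$empirical_p,
    n_perm = x$n_perm,
    seed = x$seed
  )
}

#' @rdname enrichment_test
#' @export
glance.mm_enrichment <- function(x, ...) {
  tibble(observed_fraction = x$observed_fraction,
         null_mean = mean(x$null_fractions),
         p.value = x$empirical_p, n_perm = x$n_perm)
}

#' @rdname enrichment_test
#' @param object an `mm_enrichment` object.
#' @export
autoplot.mm_enrichment <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null_fractions),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed_fraction,
                        colour = "red", linewidth = 0.8) +
    ggplot2::labs(
      x = "intersection fraction",
      y = "permutations",
      title = sprintf("observed %.1f%% vs null (p = %.4g)",
                      100 * object$observed_fraction, object$empirical_p)
    ) +
    ggplot2::theme_minimal()
}
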