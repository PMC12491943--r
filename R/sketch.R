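#' MinHash sketch of a sequence set
#'
#' Bottom sketch of the hash values of the distinct canonical k-mers of
#' the input (canonical = lexicographic minimum of a k-mer and its reverse
#' complement; k-mers containing non-ACGT bases are skipped). The hash is
#' a fixed deterministic 64-bit mix, so sketches are reproducible across
#' runs and machines.
#'
#' @param sequences sequences tibble, or a character vector of sequences.
#' @param label sketch label (must be unique within a sketch collection).
#' @param k k-mer size in bases (default 21).
#' @param sketch_size number of smallest hashes retained (default 1000).
#' @return an object of class `mm_sketch`: list with `label`, `k`,
#'   `sketch_size` and the sorted `hashes`.
#' @export
sketch <- function(sequences, label, k = 21L, sketch_size = 1000L) {
  seqs <- if (is.data.frame(sequences)) sequences$sequence else sequences
  hashes <- cpp_sketch(seqs, as.integer(k), as.integer(sketch_size))
  if (length(hashes) == 0) abort("no valid k-mers")
  structure(list(label = label, k = as.integer(k),
                 sketch_size = as.integer(sketch_size), hashes = hashes),
            class = "mm_sketch")
}

#' @export
print.mm_sketch <- function(x, ...) {
  cat("<mm_sketch>", x$label, "- k =", x$k, ",", length(x$hashes),
      "of", x$sketch_size, "hashes\n")
  invisible(x)
}

#' Mash distance between two sketches
#'
#' The Jaccard index j of the two k-mer sets is estimated from the merged
#' bottom sketch (the s smallest hashes of the union, s = min(sketch_size,
#' union size)): j = (shared hashes among those s) / s. The distance is
#' d = -(1/k) * ln(2j / (1 + j)), with j = 0 mapped to the saturation
#' value 1. Identical sketches give d = 0.
#'
#' @param a,b `mm_sketch` objects with equal `k` and `sketch_size`.
#' @return a non-negative distance.
#' @examples
#' s1 <- sketch("ACGTACGGTTCAGGCATTACGGATCCATGGCAATCC", "a", k = 7,
#'              sketch_size = 20)
#' mash_distance(s1, s1)  # 0
#' @export
mash_distance <- function(a, b) {
  if (!inherits(a, "mm_sketch") || !inherits(b, "mm_sketch")) {
    abort("inputs must be mm_sketch objects")
  }
  if (a$k != b$k) abort("sketches have different k")
  if (a$sketch_size != b$sketch_size) {
    abort("sketches have different sketch_size")
  }
  u <- sort(unique(c(a$hashes, b$hashes)))
  s <- min(a$sketch_size, length(u))
  bottom <- u[seq_len(s)]
  shared <- sum(bottom %in% a$hashes & bottom %in% b$hashes)
  j <- shared / s
  if (j == 0) return(1)
  max(0, -log(2 * j / (1 + j)) / a$k)
}

#' Pairwise Mash distance matrix
#'
#' @param sketches list of `mm_sketch` objects with distinct labels and a
#'   common `k`.
#' @return a symmetric numeric matrix with zero diagonal, dimnames set to
#'   the sketch labels.
#' @export
distance_matrix <- function(sketches) {
  if (length(sketches) < 2) abort("need at least 2 sketches")
  labels <- map_chr(sketches, "label")
  if (anyDuplicated(labels)) abort("duplicate sketch labels")
  n <- length(sketches)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- mash_distance(sketches[[i]], sketches[[j]])
    }
  }
  d
}

#' Principal-coordinate embedding of a distance matrix
#'
#' Classical metric scaling (PCoA): double-centre -1/2 D^2, take the two
#' leading eigenvectors scaled by the square roots of their eigenvalues
#' (negative eigenvalues clamped to zero). The embedding is deterministic
#' up to axis sign; signs are fixed by making each axis's
#' largest-magnitude loading positive.
#'
#' @param d symmetric distance matrix with labelled rows.
#' @param groups optional named or matrix-ordered vector of group labels
#'   carried into the output (e.g. exogenous/endogenous).
#' @return an object of class `mm_embedding`: a tibble with `label`,
#'   `group`, `x`, `y` plus an `eig` attribute; has an [autoplot()] method.
#' @export
embed_distances <- function(d, groups = NULL) {
  if (!isTRUE(all.equal(d, t(d)))) abort("distance matrix must be symmetric")
  n <- nrow(d)
  if (all(d == 0)) {
    coords <- matrix(0, n, 2)
    eig <- c(0, 0)
  } else {
    mds <- cmdscale(d, k = min(2L, n - 1L), eig = TRUE)
    coords <- matrix(0, n, 2)
    if (ncol(mds$points) >= 1) coords[, 1] <- mds$points[, 1]
    if (ncol(mds$points) >= 2) coords[, 2] <- mds$points[, 2]
    eig <- mds$eig
  }
  for (ax in 1:2) {
    i <- which.max(abs(coords[, ax]))
    if (length(i) == 1 && coords[i, ax] < 0) coords[, ax] <- -coords[, ax]
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  grp <- if (is.null(groups)) {
    NA_character_
  } else if (!is.null(names(groups))) {
    unname(groups[labels])
  } else {
    groups
  }
  out <- tibble(label = labels, group = grp,
                x = coords[, 1], y = coords[, 2])
  attr(out, "eig") <- eig
  class(out) <- c("mm_embedding", class(out))
  out
}

#' @export
autoplot.mm_embedding <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y))
  p <- if (all(is.na(object$group))) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  }
  p + ggplot2::labs(x = "PCo1", y = "PCo2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname embed_distances
#' @param x an `mm_embedding` object.
#' @param ... passed to [autoplot()].
#' @export
plot_embedding <- function(x, ...) autoplot(x, ...)

#' Save or load sketches as TSV
#'
#' One row per sketch: label, k, sketch_size, comma-joined hash list.
#'
#' @param sketches list of `mm_sketch` objects.
#' @param path file path.
#' @return `write_sketches()` returns `path` invisibly; `read_sketches()`
#'   returns a list of `mm_sketch` objects.
#' @export
write_sketches <- function(sketches, path) {
  lines <- map_chr(sketches, function(s) {
    paste(s$label, s$k, s$sketch_size,
          paste(format(s$hashes, scientific = FALSE, trim = TRUE),
                collapse = ","),
          sep = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sketches
#' @export
read_sketches <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  map(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    structure(list(label = f[1], k = as.integer(f[2]),
                   sketch_size = as.integer(f[3]),
                   hashes = as.numeric(strsplit(f[4], ",")[[1]])),
              class = "mm_sketch")
  })
}
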