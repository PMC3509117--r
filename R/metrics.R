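#' Pairwise haplotype metrics
#'
#' Three elementwise comparisons between repeat-count vectors are used
#' throughout the package:
#'
#' * `"allele"` -- the number of loci at which two haplotypes differ. This is
#'   the default for mean pairwise differences within and between
#'   populations (the "number of pairwise differences" of standard haplotype
#'   software) and for AMOVA under an infinite-allele view of each locus.
#' * `"step"` -- the total number of single-repeat mutational steps,
#'   `sum(|a - b|)`. Used for network branch lengths, the rho statistic and
#'   mutational distances from a reference haplotype.
#' * `"squared"` -- the sum of squared repeat differences, `sum((a - b)^2)`.
#'   The stepwise-mutation-model metric behind Rst and the TD/ASD estimator.
#'
#' `hap_distance()` compares two haplotypes; `hap_distance_matrix()` returns
#' the full symmetric matrix over the rows of a haplotype table (or integer
#' matrix). Optional per-locus `weights` multiply each locus contribution.
#'
#' @param a,b Numeric vectors of repeat counts on a shared panel.
#' @param metric One of `"allele"`, `"step"`, `"squared"`.
#' @param weights Optional per-locus weights (default 1).
#' @return `hap_distance()`: a single non-negative number.
#' @examples
#' hap_distance(c(14, 23), c(14, 25), metric = "step")
#' @export
hap_distance <- function(a, b, metric = c("allele", "step", "squared"),
                         weights = NULL) {
  metric <- match.arg(metric)
  if (length(a) != length(b)) {
    abort("Haplotypes compared on different panels.")
  }
  w <- weights %||% rep(1, length(a))
  d <- abs(a - b)
  switch(metric,
    allele = sum(w * (d > 0)),
    step = sum(w * d),
    squared = sum(w * d^2)
  )
}

#' @rdname hap_distance
#' @param x Haplotype data frame or integer matrix (rows = haplotypes).
#' @param loci Optional locus columns when `x` is a data frame.
#' @return `hap_distance_matrix()`: an `n x n` symmetric numeric matrix.
#' @export
hap_distance_matrix <- function(x, metric = c("allele", "step", "squared"),
                                weights = NULL, loci = NULL) {
  metric <- match.arg(metric)
  m <- if (is.matrix(x)) x else hap_matrix(x, loci)
  n <- nrow(m)
  L <- ncol(m)
  w <- weights %||% rep(1, L)
  if (length(w) != L) abort("One weight per locus required.")
  out <- matrix(0, n, n)
  for (l in seq_len(L)) {
    d <- abs(outer(m[, l], m[, l], "-"))
    out <- out + w[l] * switch(metric,
      allele = (d > 0),
      step = d,
      squared = d^2
    )
  }
  out
}

# Distances of each row of m to a single reference haplotype.
dist_to_ref <- function(m, ref, metric, weights = NULL) {
  w <- weights %||% rep(1, ncol(m))
  d <- abs(sweep(m, 2, ref))
  v <- switch(metric,
    allele = (d > 0),
    step = d,
    squared = d^2
  )
  as.numeric(v %*% w)
}
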