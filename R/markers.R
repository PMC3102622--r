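#' Construct a marker map
#'
#' A marker map describes `L` ordered polymorphic sites: the number of
#' alleles `k_j` at each site and the recombination fraction `theta_j` of
#' each of the `L - 1` inter-locus intervals. Interval `j` sits between
#' locus `j` and locus `j + 1` (1-based), and every recombination fraction
#' must satisfy `0 <= theta <= 0.5`.
#'
#' @param n_alleles Integer vector of allele counts per locus, each `>= 2`.
#' @param theta Numeric vector of length `length(n_alleles) - 1` of
#'   recombination fractions in `[0, 0.5]`.
#' @return An object of class `"marker_map"`: a list with elements `L`,
#'   `n_alleles` and `theta`.
#' @examples
#' marker_map(c(2, 2, 2), theta = c(0.1, 0.25))
#' @export
marker_map <- function(n_alleles, theta = numeric(0)) {
  n_alleles <- as.integer(n_alleles)
  if (length(n_alleles) < 1) stop("a marker map needs at least one locus")
  if (any(is.na(n_alleles)) || any(n_alleles < 2)) {
    stop("allele counts must be integers >= 2")
  }
  theta <- as.numeric(theta)
  if (length(theta) != length(n_alleles) - 1L) {
    stop(sprintf("need %d recombination fractions for %d loci, got %d",
                 length(n_alleles) - 1L, length(n_alleles), length(theta)))
  }
  if (length(theta) > 0 && (any(is.na(theta)) || any(theta < 0) || any(theta > 0.5))) {
    stop("recombination fractions must lie in [0, 0.5]")
  }
  structure(list(L = length(n_alleles), n_alleles = n_alleles, theta = theta),
            class = "marker_map")
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("Marker map: %d loci, allele counts %s\n", x$L,
              paste(x$n_alleles, collapse = ",")))
  if (x$L > 1) {
    cat("theta:", paste(format(x$theta), collapse = " "), "\n")
  }
  invisible(x)
}
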