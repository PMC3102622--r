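#' Genotype and haplotype observation tables
#'
#' A genotype table stores, for each typed individual and locus, an
#' unordered pair of alleles (kept sorted so the smaller allele comes
#' first). A haplotype table stores two allele sequences per typed
#' individual; which sequence is maternal is unknown. An individual is
#' either typed at every locus or entirely untyped (untyped individuals are
#' simply absent from the table) -- partial missingness is rejected.
#'
#' @param alleles A 3-d array `n x L x 2` of positive integer alleles:
#'   `alleles[i, j, ]` is individual `i`'s allele pair (genotype) or the
#'   alleles of the two observed sequences (haplotype) at locus `j`.
#' @param ids Character vector of `n` individual identifiers (taken from
#'   `rownames(alleles)` when omitted).
#' @param map Optional [marker_map()] used to range-check alleles.
#' @return An object of class `"genotype_table"` or `"haplotype_table"`:
#'   the (sorted, for genotypes) array with `ids` as row names.
#' @examples
#' g <- genotype_table(array(c(2L, 1L, 1L, 2L), dim = c(1, 2, 2)), ids = "a")
#' g[1, , ]   # pairs stored smaller-first
#' @export
genotype_table <- function(alleles, ids = rownames(alleles), map = NULL) {
  arr <- check_allele_array(alleles, ids, map, "genotype")
  # store unordered pairs sorted, smaller allele first
  a1 <- pmin(arr[, , 1, drop = FALSE], arr[, , 2, drop = FALSE])
  a2 <- pmax(arr[, , 1, drop = FALSE], arr[, , 2, drop = FALSE])
  arr[, , 1] <- a1
  arr[, , 2] <- a2
  structure(arr, class = "genotype_table")
}

#' @rdname genotype_table
#' @export
haplotype_table <- function(alleles, ids = rownames(alleles), map = NULL) {
  arr <- check_allele_array(alleles, ids, map, "haplotype")
  structure(arr, class = "haplotype_table")
}

check_allele_array <- function(alleles, ids, map, what) {
  if (length(dim(alleles)) != 3 || dim(alleles)[3] != 2) {
    stop(what, " alleles must be an n x L x 2 array")
  }
  if (is.null(ids)) stop(what, " table needs individual identifiers")
  ids <- as.character(ids)
  if (length(ids) != dim(alleles)[1]) stop("ids do not match array rows")
  if (anyDuplicated(ids)) stop("duplicated individual in ", what, " table")
  storage.mode(alleles) <- "integer"
  if (any(is.na(alleles)) || any(alleles < 1)) {
    stop(what, " alleles must be positive integers (untyped individuals are omitted rows)")
  }
  if (!is.null(map)) {
    if (dim(alleles)[2] != map$L) {
      stop(sprintf("%s table has %d loci, marker map has %d",
                   what, dim(alleles)[2], map$L))
    }
    kmax <- matrix(rep(map$n_alleles, each = max(dim(alleles)[1], 1L)),
                   nrow = max(dim(alleles)[1], 1L))[seq_len(dim(alleles)[1]), ,
                                                    drop = FALSE]
    if (any(alleles[, , 1] > kmax) || any(alleles[, , 2] > kmax)) {
      bad <- which(alleles[, , 1] > kmax | alleles[, , 2] > kmax, arr.ind = TRUE)
      bad <- matrix(bad, ncol = 2)
      stop(sprintf("allele out of range for individual %s at locus %d",
                   ids[bad[1, 1]], bad[1, 2]))
    }
  }
  dimnames(alleles) <- list(ids, NULL, NULL)
  alleles
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table: %d individuals x %d loci\n",
              dim(x)[1], dim(x)[2]))
  invisible(x)
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("Haplotype table: %d individuals x %d loci\n",
              dim(x)[1], dim(x)[2]))
  invisible(x)
}

#' Identifiers of typed individuals
#'
#' @param x A genotype or haplotype table.
#' @return Character vector of typed individual identifiers.
#' @export
typed_ids <- function(x) {
  dimnames(x)[[1]]
}

#' Number of loci in an observation table
#' @param x A genotype or haplotype table.
#' @return Integer locus count.
#' @export
n_loci <- function(x) {
  dim(x)[2]
}

#' Collapse haplotypes to genotypes
#'
#' Drops the sequence structure of haplotype observations, keeping only the
#' unordered allele pair at each locus. The alleles are identical in the
#' two representations; only the linkage of alleles along each sequence is
#' lost.
#'
#' @param haps A [haplotype_table()].
#' @return A [genotype_table()] over the same individuals and loci.
#' @export
genotypes_from_haplotypes <- function(haps) {
  stopifnot(inherits(haps, "haplotype_table"))
  genotype_table(unclass(haps), ids = typed_ids(haps))
}

# Number of heterozygous loci of one individual's genotype row.
count_heterozygous <- function(genotypes, id) {
  sum(genotypes[id, , 1] != genotypes[id, , 2])
}
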