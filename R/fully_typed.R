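#' Trio likelihood on a 4-state HMM
#'
#' The transmission probability of a fully-haplotyped mother-father-child
#' trio, summed over the child's distinct orientations. For each
#' orientation, a forward pass runs over four hidden states -- the
#' maternal-side and paternal-side origin bits, i.e. which of each
#' parent's two observed sequences is being copied -- with initial weight
#' 1/4 per state, transition probability `theta_j` per changed bit, and
#' emission 1 exactly when the child's oriented alleles equal the selected
#' parental alleles. The parents' own orientations provably do not affect
#' the value (their haplotypes enter as unordered pairs) and are not
#' summed; founder priors are attached by [fully_typed_likelihood()], not
#' here.
#'
#' @param mother,father,child `2 x L` integer matrices, rows = the two
#'   observed haplotypes.
#' @param map A [marker_map()] with `L` loci.
#' @return A probability.
#' @examples
#' map <- marker_map(c(2, 2), theta = 0.25)
#' trio_likelihood(rbind(c(1,1), c(2,2)), rbind(c(1,1), c(1,1)),
#'                 rbind(c(1,2), c(1,1)), map)  # 0.125: one forced switch
#' @export
trio_likelihood <- function(mother, father, child, map) {
  check_trio(mother, father, child, map)
  total <- 0
  for (o in trio_orientations(child)) {
    cm <- child[o[1], ]
    cp <- child[o[2], ]
    # states (mb, pb) in {1,2}^2, mb varying fastest
    v <- rep(1 / 4, 4)
    for (j in seq_len(map$L)) {
      if (j > 1) {
        th <- map$theta[j - 1]
        v <- trio_step(v, th)
      }
      emit <- as.numeric(
        (mother[c(1, 2, 1, 2), j] == cm[j]) & (father[c(1, 1, 2, 2), j] == cp[j]))
      v <- v * emit
    }
    total <- total + sum(v)
  }
  total
}

trio_step <- function(v, th) {
  # independent binary channels on the maternal (fast) and paternal bit
  m <- matrix(v, 2, 2)
  m <- (1 - th) * m + th * m[2:1, ]
  m <- (1 - th) * m + th * m[, 2:1]
  as.vector(m)
}

trio_orientations <- function(child) {
  if (all(child[1, ] == child[2, ])) list(c(1, 2)) else list(c(1, 2), c(2, 1))
}

check_trio <- function(mother, father, child, map) {
  for (h in list(mother, father, child)) {
    if (!is.matrix(h) || nrow(h) != 2 || ncol(h) != map$L) {
      stop("trio haplotypes must be 2 x L matrices matching the marker map")
    }
  }
}

#' Minimum recombinations within one trio
#'
#' Minimum over the child's orientations of the number of sequence
#' switches needed in the maternal and paternal meioses, each found by a
#' two-state min-sum scan with unit switch cost (a state is admissible at
#' a locus iff the selected parental sequence carries the transmitted
#' allele).
#'
#' @inheritParams trio_likelihood
#' @return A non-negative integer.
#' @export
trio_min_recombinations <- function(mother, father, child, map) {
  check_trio(mother, father, child, map)
  best <- Inf
  for (o in trio_orientations(child)) {
    m <- meiosis_min_switches(mother, child[o[1], ])
    p <- meiosis_min_switches(father, child[o[2], ])
    best <- min(best, m + p)
  }
  if (is.infinite(best)) {
    stop("no orientation admits a compatible origin path for the trio", call. = FALSE)
  }
  as.integer(best)
}

meiosis_min_switches <- function(parent, transmitted) {
  cost <- c(0, 0)
  for (j in seq_along(transmitted)) {
    adm <- c(parent[1, j] == transmitted[j], parent[2, j] == transmitted[j])
    if (!any(adm)) return(Inf)
    if (j > 1) cost <- pmin(cost, rev(cost) + 1)
    cost[!adm] <- Inf
  }
  min(cost)
}

#' Likelihood of a fully-haplotyped pedigree in linear time
#'
#' When every individual is haplotyped, the pedigree likelihood decomposes
#' into conditionally independent trios: the product over founders of the
#' uniform founder-haplotype prior `prod_j (1/k_j)^2` (each founder
#' counted once) times the product over non-founders of
#' [trio_likelihood()]. One 4-state scan per trio gives `O(k * l)` time
#' for `k` non-founders and `l` loci. Agrees exactly with the general
#' inheritance HMM [likelihood()] on the same data.
#'
#' @param ped A [pedigree()] in which *every* individual is typed.
#' @param haps A [haplotype_table()] covering all of `ped$id`.
#' @param map A [marker_map()].
#' @return The likelihood as a scalar.
#' @export
fully_typed_likelihood <- function(ped, haps, map) {
  check_fully_typed(ped, haps)
  prior <- prod((1 / map$n_alleles)^2)^length(founders(ped))
  p <- prior
  for (i in nonfounders(ped)) {
    r <- match(i, ped$id)
    p <- p * trio_likelihood(hap_pair(haps, ped$mother[r]),
                             hap_pair(haps, ped$father[r]),
                             hap_pair(haps, i), map)
    if (p == 0) break
  }
  p
}

#' Minimum recombinations of a fully-haplotyped pedigree
#'
#' Sum of [trio_min_recombinations()] over the non-founders; each trio is
#' independent of the others. Agrees with the general
#' [min_recombination()] count on the same data.
#'
#' @inheritParams fully_typed_likelihood
#' @return A non-negative integer.
#' @export
fully_typed_min_recombination <- function(ped, haps, map) {
  check_fully_typed(ped, haps)
  total <- 0L
  for (i in nonfounders(ped)) {
    r <- match(i, ped$id)
    total <- total + trio_min_recombinations(hap_pair(haps, ped$mother[r]),
                                             hap_pair(haps, ped$father[r]),
                                             hap_pair(haps, i), map)
  }
  total
}

hap_pair <- function(haps, id) {
  rbind(haps[id, , 1], haps[id, , 2])
}

check_fully_typed <- function(ped, haps) {
  untyped <- setdiff(ped$id, typed_ids(haps))
  if (length(untyped) > 0) {
    stop("individuals without haplotype data (", paste(untyped, collapse = ", "),
         "): use the general inheritance HMM for partially typed pedigrees",
         call. = FALSE)
  }
  invisible(TRUE)
}
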