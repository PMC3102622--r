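#' Proxy haplotypes for one genotyped individual
#'
#' Builds the fixed haplotypes of the five proxy individuals (a spouse and
#' four full siblings) that force a genotyped individual's unordered
#' allele pairs through the rules of inheritance alone. The spouse `i0`
#' is homozygous all-ones; every child's first haplotype (inherited from
#' the spouse) is all ones; child `i1`'s second haplotype carries the
#' smaller genotype allele at every locus and `i2`'s the larger; children
#' `i3` and `i4` alternate, `i3` taking the smaller allele at the 1st,
#' 3rd, ... heterozygous locus and the larger at the 2nd, 4th, ..., with
#' `i4` complementary. The union of the children's alleles at each locus
#' therefore pins the parent's genotype, while the alternating pattern of
#' `i3`/`i4` forces two recombinations among the four children between
#' every pair of consecutive heterozygous loci.
#'
#' @param g An `L x 2` integer matrix of sorted allele pairs
#'   (`g[, 1] <= g[, 2]`), e.g. `genotypes[i, , ]` from a
#'   [genotype_table()].
#' @return A list of five `2 x L` matrices (`i0` .. `i4`), rows = the two
#'   haplotypes.
#' @examples
#' g <- cbind(c(1L, 1L, 1L), c(2L, 1L, 2L))  # heterozygous at loci 1, 3
#' proxy_haplotypes(g)$i3[2, ]  # 1 1 2: smaller allele at t1, larger at t2
#' @export
proxy_haplotypes <- function(g) {
  g <- matrix(as.integer(g), ncol = 2)
  if (any(g[, 1] > g[, 2])) {
    stop("genotype pairs must be sorted with the smaller allele first")
  }
  L <- nrow(g)
  het <- which(g[, 1] != g[, 2])
  ones <- rep(1L, L)
  i3 <- i4 <- g[, 1]
  if (length(het) > 0) {
    odd <- het[seq_along(het) %% 2 == 1L]
    even <- het[seq_along(het) %% 2 == 0L]
    i3[odd] <- g[odd, 1]
    i3[even] <- g[even, 2]
    i4[odd] <- g[odd, 2]
    i4[even] <- g[even, 1]
  }
  list(i0 = rbind(ones, ones),
       i1 = rbind(ones, g[, 1]),
       i2 = rbind(ones, g[, 2]),
       i3 = rbind(ones, i3),
       i4 = rbind(ones, i4))
}

#' Map a genotype problem to a haplotype problem
#'
#' For every genotyped individual `i`, adds a proxy family of five new
#' haplotyped individuals -- a founder spouse `i#0` and four children
#' `i#1` .. `i#4` of `i` and `i#0` -- carrying the [proxy_haplotypes()] of
#' `i`'s genotype. The result is a haplotype problem instance on exactly
#' `5|G| + |I|` individuals and `8|G| + |E|` edges in which only the
#' `5|G|` new individuals are typed; its minimum recombination count,
#' likelihood and maximum probability are related to those of the genotype
#' instance by [min_recomb_offset()] and [proxy_constant()].
#'
#' @param ped A [pedigree()].
#' @param genotypes A [genotype_table()] whose typed set is a subset of
#'   `ped$id`.
#' @return A list with elements `pedigree` (the enlarged pedigree),
#'   `haplotypes` (a [haplotype_table()] typing exactly the new
#'   individuals) and `families` (a list of `proxy_family` records with
#'   fields `parent`, `spouse`, `children`, `het_loci`, `hom_runs`, `T`).
#' @export
build_proxy_pedigree <- function(ped, genotypes) {
  assert_valid_pedigree(ped)
  G <- typed_ids(genotypes)
  if (!all(G %in% ped$id)) {
    stop("genotyped individuals absent from the pedigree: ",
         paste(setdiff(G, ped$id), collapse = ", "))
  }
  L <- n_loci(genotypes)
  new_id <- new_father <- new_mother <- character(0)
  hap_ids <- character(0)
  hap_rows <- list()
  families <- list()
  for (i in G) {
    ids5 <- paste0(i, "#", 0:4)
    clash <- intersect(ids5, c(ped$id, new_id))
    if (length(clash) > 0) {
      stop("proxy identifier collides with an existing individual: ",
           paste(clash, collapse = ", "))
    }
    haps <- proxy_haplotypes(genotypes[i, , ])
    new_id <- c(new_id, ids5)
    new_father <- c(new_father, NA, rep(i, 4))
    new_mother <- c(new_mother, NA, rep(ids5[1], 4))
    hap_ids <- c(hap_ids, ids5)
    hap_rows <- c(hap_rows, unname(haps))
    het <- which(genotypes[i, , 1] != genotypes[i, , 2])
    families[[i]] <- structure(list(
      parent = i, spouse = ids5[1], children = ids5[2:5],
      het_loci = het, T = length(het),
      hom_runs = hom_run_lengths(het, L)
    ), class = "proxy_family")
  }
  big <- pedigree(c(ped$id, new_id),
                  father = c(ped$father, new_father),
                  mother = c(ped$mother, new_mother))
  arr <- array(0L, dim = c(length(hap_ids), L, 2))
  for (r in seq_along(hap_rows)) {
    arr[r, , 1] <- hap_rows[[r]][1, ]
    arr[r, , 2] <- hap_rows[[r]][2, ]
  }
  haps <- haplotype_table(arr, ids = hap_ids)
  list(pedigree = big, haplotypes = haps, families = families)
}

# h_0 = loci before the first heterozygous locus; h_j = loci strictly
# between heterozygous loci t_j and t_{j+1}; h_T = loci after the last.
hom_run_lengths <- function(het, L) {
  if (length(het) == 0) return(L)
  bounds <- c(0L, het, L + 1L)
  diff(bounds) - 1L
}

#' Recombination-count offset of the proxy mapping
#'
#' The minimum recombination count of the mapped haplotype instance
#' exceeds that of the genotype instance by exactly `2 * (T_i - 1)` summed
#' over genotyped individuals, where `T_i` is the number of heterozygous
#' loci of individual `i`'s genotype: the alternating `i3`/`i4` pattern
#' costs two recombinations between each pair of consecutive heterozygous
#' loci, independent of how the parent's genotype is phased. A fully
#' homozygous parent (`T_i = 0`) forces no recombinations and contributes
#' 0 (the raw formula would give -2).
#'
#' @param genotypes A [genotype_table()].
#' @return A non-negative integer offset.
#' @export
min_recomb_offset <- function(genotypes) {
  ids <- typed_ids(genotypes)
  if (length(ids) == 0) return(0L)
  tt <- vapply(ids, function(i) count_heterozygous(genotypes, i), integer(1))
  as.integer(sum(2L * pmax(tt - 1L, 0L)))
}

#' Transition matrices of the 16-state transmission chain
#'
#' The chain runs over the 16 inheritance patterns of the four proxy
#' children's parent-side meioses. The full transition matrix has entries
#' `P[i, j] = theta^H(i,j) * (1 - theta)^(4 - H(i,j))` with `H` the
#' Hamming distance between 4-bit states; each `Qxxxx` equals `P` in the
#' column of state `xxxx` (bits ordered `i1 i2 i3 i4`, `i1` most
#' significant) and is zero elsewhere.
#'
#' At a heterozygous locus of the proxy parent the chain is constrained
#' to a single state determined by the parent's phase: `i1` and `i2`
#' always have opposite origin, and `i3` tracks `i1` at odd heterozygous
#' loci but `i2` at even ones (with `i4` opposite). The admissible
#' patterns therefore alternate between `0101` and `0110` (or, under the
#' complementary labeling of the parent's haplotypes, `1010` and `1001`)
#' -- two states at Hamming distance 2, which is what forces exactly two
#' recombinations among the four children between consecutive
#' heterozygous loci.
#'
#' @param theta Recombination fraction in `[0, 0.5]`.
#' @return A list with 16 x 16 matrices `P`, `Q0101`, `Q0110`, `Q1010`,
#'   `Q1001`.
#' @examples
#' m <- transmission_matrices(0.5)
#' all(m$P == 1 / 16)  # TRUE
#' @export
transmission_matrices <- function(theta) {
  if (length(theta) != 1 || is.na(theta) || theta < 0 || theta > 0.5) {
    stop("theta must lie in [0, 0.5]")
  }
  s <- 0:15
  H <- outer(s, s, function(a, b) popcount(bitwXor(a, b)))
  P <- theta^H * (1 - theta)^(4 - H)
  project <- function(state) {
    Q <- matrix(0, 16, 16)
    Q[, state + 1] <- P[, state + 1]
    Q
  }
  list(P = P, Q0101 = project(5L), Q0110 = project(6L),
       Q1010 = project(10L), Q1001 = project(9L))
}

#' Proxy-family transmission probability
#'
#' The probability mass that the 16-state transmission chain assigns to
#' the proxy children's haplotypes, as a function of the parent's genotype
#' and the marker map: a uniform 1/16 initial distribution is propagated
#' with the full matrix `P` across homozygous stretches and constrained to
#' the admissible pattern (alternately `0101` and `0110`; see
#' [transmission_matrices()]) at each heterozygous locus, and the
#' surviving mass is summed. Which haplotype of the parent is labeled
#' first is arbitrary, so the complementary pattern sequence
#' `1010`/`1001` gives the same value; `first_state` exists so tests can
#' assert that invariance. Interval-specific recombination fractions are
#' supported.
#'
#' For a fully heterozygous parent with interval fractions `theta_j` this
#' evaluates to `(1/16) * prod_j theta_j^2 (1 - theta_j)^2`; in
#' particular `p_t = 1/256` for two heterozygous loci at `theta = 0.5`,
#' and `p_t = 0` at `theta = 0` whenever `T >= 2`.
#'
#' The spouse-side meioses are summed out exactly (each contributes total
#' transition mass one) and the spouse's own founder prior is *not*
#' included here; see [proxy_constant()] for the full proportionality
#' constant of the mapping.
#'
#' @param family A `proxy_family` record from [build_proxy_pedigree()].
#' @param map A [marker_map()] for the same loci.
#' @param first_state State constrained at the first heterozygous locus
#'   (5 for `0101` or 10 for the complementary labeling `1010`); the
#'   states at subsequent heterozygous loci alternate with its
#'   Hamming-distance-2 partner (`0110` resp. `1001`).
#' @return A probability in `[0, 1]`; 1 when the parent is fully
#'   homozygous.
#' @export
transmission_probability <- function(family, map, first_state = 5L) {
  stopifnot(inherits(family, "proxy_family"))
  if (!first_state %in% c(5L, 10L)) {
    stop("first_state must be 5 (0101) or 10 (1010)")
  }
  if (map$L < max(c(family$het_loci, 1L))) {
    stop("marker map shorter than the proxy family's loci")
  }
  v <- rep(1 / 16, 16)
  het <- family$het_loci
  targets <- rep_len(c(first_state, bitwXor(first_state, 3L)), length(het))
  for (j in seq_len(map$L)) {
    if (j > 1) {
      v <- v %*% transmission_matrices(map$theta[j - 1])$P
      v <- as.vector(v)
    }
    hj <- match(j, het)
    if (!is.na(hj)) {
      keep <- v[targets[hj] + 1]
      v <- rep(0, 16)
      v[targets[hj] + 1] <- keep
    }
  }
  sum(v)
}

#' Proportionality constant of the proxy mapping
#'
#' For every phased assignment `x`, the haplotype probability in the
#' mapped instance equals the genotype-instance probability of `x`
#' restricted to the original individuals, times a constant per proxy
#' family that does not depend on `x`: the transmission probability of the
#' family's children multiplied by the all-ones spouse's founder prior
#' `prod_j (1/k_j)^2`. Likelihoods and maximum probabilities therefore
#' transfer between the two instances with coefficient
#' `prod_i proxy_constant(i)`.
#'
#' @inheritParams transmission_probability
#' @return A probability.
#' @seealso [verify_proportionality()]
#' @export
proxy_constant <- function(family, map) {
  transmission_probability(family, map) * prod((1 / map$n_alleles)^2)
}

#' Check the proxy-mapping proportionality numerically
#'
#' Computes the genotype-instance likelihood, the mapped haplotype
#' instance's likelihood, and the product of per-family
#' [proxy_constant()]s, and reports the relative error of
#' `L_hap = L_geno * prod(constants)`. Optionally also checks that the
#' restriction of the mapped instance's maximum-probability assignment to
#' the original individuals attains the genotype instance's maximum
#' probability.
#'
#' The per-assignment proportionality (see [proxy_constant()]) holds for
#' every phased assignment consistent with the genotypes, so the
#' likelihood identity is exact whenever each genotyped individual is
#' heterozygous at every locus. At a homozygous locus the proxy children
#' do not pin the parent's second allele -- the mapped instance also
#' admits assignments in which the parent is heterozygous there and all
#' four children draw the same parental haplotype -- so with homozygous
#' loci `ratio_error` is positive (the haplotype likelihood exceeds the
#' proportional value by that extra mass); this is a property of the
#' mapping itself, reported honestly rather than hidden.
#'
#' @inheritParams forward_backward
#' @param genotypes A [genotype_table()].
#' @param check_argmax Also compare maximum-probability assignments
#'   (exhaustive; tiny instances only).
#' @param max_candidates Passed to [max_probability()] when
#'   `check_argmax = TRUE`.
#' @return A list with `genotype_likelihood`, `haplotype_likelihood`,
#'   `product_constant`, `ratio_error`, `degenerate` (`TRUE` when both
#'   sides are 0, e.g. `theta = 0` with `T_i >= 2`), and, when requested,
#'   `argmax_agrees`.
#' @export
verify_proportionality <- function(ped, genotypes, map,
                                   max_states = 2^20,
                                   check_argmax = FALSE,
                                   max_candidates = 2^18) {
  mapped <- build_proxy_pedigree(ped, genotypes)
  lg <- as.numeric(likelihood(ped, map, genotypes, "genotype", max_states))
  lh <- as.numeric(likelihood(mapped$pedigree, map, mapped$haplotypes,
                              "haplotype", max_states))
  const <- prod(vapply(mapped$families, proxy_constant, numeric(1), map = map))
  expected <- lg * const
  degenerate <- expected == 0 && lh == 0
  ratio_error <- if (degenerate) 0 else abs(lh - expected) / expected
  out <- list(genotype_likelihood = lg, haplotype_likelihood = lh,
              product_constant = const, ratio_error = ratio_error,
              degenerate = degenerate)
  if (check_argmax && !degenerate) {
    mp_h <- max_probability(mapped$pedigree, map, mapped$haplotypes,
                            "haplotype", max_candidates)
    mp_g <- max_probability(ped, map, genotypes, "genotype", max_candidates)
    sub <- mp_h$assignment[ped$id, , , drop = FALSE]
    space_g <- build_hmm_space(ped, map, genotypes, "genotype", max_states)
    p_sub <- if (assignment_data_ok(space_g, sub) &&
                   all(vapply(seq_len(map$L), function(j) {
                     locus_data_ok(space_g, stats::setNames(sub[, j, 1], ped$id),
                                   stats::setNames(sub[, j, 2], ped$id), j)
                   }, logical(1)))) {
      assignment_probability(space_g, sub)
    } else {
      0
    }
    out$argmax_agrees <- isTRUE(abs(p_sub - mp_g$probability) <=
                                  1e-9 * max(mp_g$probability, .Machine$double.xmin))
    out$restricted_probability <- p_sub
    out$genotype_max_probability <- mp_g$probability
  }
  out
}
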