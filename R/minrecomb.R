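#' Minimum-recombination phasing
#'
#' Finds the minimum total number of recombinations over all phased
#' assignments and inheritance paths consistent with the observed data, by
#' a min-sum dynamic program over loci: nodes at locus `j` are hidden
#' states with non-zero emission, edge costs are the Hamming distances
#' between inheritance bit vectors (orientation changes are inadmissible
#' for haplotype data). Also returns one optimal hidden-state path and a
#' consistent phased assignment reconstructed from per-locus founder-allele
#' choices; among equal-cost predecessors, backtracking prefers the lowest
#' encoded state, so the witness is deterministic.
#'
#' @inheritParams forward_backward
#' @return An object of class `"min_recomb"`: a list with `count` (the
#'   minimum), `states` (integer inheritance-state encodings per locus),
#'   `orientation` (named 0/1 vector over typed individuals, haplotype
#'   data only), and `assignment` (an `|I| x L x 2` array of ordered
#'   maternal/paternal alleles).
#' @examples
#' # a forced recombination: the child's first haplotype mixes the
#' # mother's two homozygous haplotypes
#' ped <- pedigree(c("m", "f", "c"), c(NA, NA, "f"), c(NA, NA, "m"))
#' map <- marker_map(c(2, 2), theta = 0.1)
#' h <- haplotype_table(array(c(1L,1L,1L, 1L,1L,2L,   # hapA: locus 1, locus 2
#'                              2L,1L,1L, 2L,1L,1L),  # hapB: locus 1, locus 2
#'                            dim = c(3, 2, 2)), ids = c("m", "f", "c"))
#' min_recombination(ped, map, h, "haplotype")$count  # 1
#' @export
min_recombination <- function(ped, map, data,
                              data_kind = c("genotype", "haplotype"),
                              max_states = 2^20) {
  data_kind <- match.arg(data_kind)
  space <- build_hmm_space(ped, map, data, data_kind, max_states)
  E <- space$emissions
  L <- map$L
  S <- space$S
  feas <- E > 0

  empty <- which(colSums(feas) == 0)
  if (length(empty) > 0) {
    stop(sprintf("no feasible inheritance state at locus %d: data are Mendelian-inconsistent",
                 empty[1]), call. = FALSE)
  }

  perms <- state_bit_perms(space)
  minplus <- function(v) {
    for (p in perms) v <- pmin(v, v[p] + 1)
    v
  }

  C <- matrix(Inf, nrow = S, ncol = L)
  C[feas[, 1], 1] <- 0
  for (j in seq_len(L)[-1]) {
    v <- minplus(C[, j - 1])
    v[!feas[, j]] <- Inf
    if (all(is.infinite(v))) {
      stop(sprintf("no feasible inheritance path through locus %d", j), call. = FALSE)
    }
    C[, j] <- v
  }

  count <- min(C[, L])
  path <- integer(L)
  path[L] <- which.min(C[, L])
  if (L > 1) {
    for (j in rev(seq_len(L - 1))) {
      d <- full_state_distance(space, path[j + 1])
      path[j] <- which.min(C[, j] + d)
    }
  }

  inh <- (path - 1L) %% space$S_inh
  oi <- (path[1] - 1L) %/% space$S_inh + 1L
  orientation <- space$orientations[oi, ]

  assignment <- reconstruct_assignment(space, inh, oi)
  structure(list(count = as.integer(round(count)), states = inh,
                 orientation = if (space$kind == "haplotype") orientation else NULL,
                 assignment = assignment),
            class = "min_recomb")
}

#' @export
print.min_recomb <- function(x, ...) {
  cat(sprintf("Minimum recombinations: %d\n", x$count))
  invisible(x)
}

# Hamming distance from every full state to one target full state
# (Inf across orientation blocks).
full_state_distance <- function(space, target) {
  t_inh <- (target - 1L) %% space$S_inh
  t_block <- (target - 1L) %/% space$S_inh
  d_inh <- popcount(bitwXor(0:(space$S_inh - 1L), t_inh))
  if (space$n_orient == 1) return(d_inh)
  d <- rep(Inf, space$S)
  rows <- t_block * space$S_inh + seq_len(space$S_inh)
  d[rows] <- d_inh
  d
}

# Consistent phased assignment for a fixed state path: pick, per locus,
# the lexicographically smallest founder-slot assignment satisfying the
# data constraints (free slots take allele 1), then propagate through the
# slot maps.
reconstruct_assignment <- function(space, inh_states, orient_index) {
  ped <- space$ped
  L <- space$map$L
  x <- array(0L, dim = c(nrow(ped), L, 2), dimnames = list(ped$id, NULL, NULL))
  orientation <- space$orientations[orient_index, ]
  for (j in seq_len(L)) {
    a <- solve_founder_slots(space, inh_states[j] + 1L, j, orientation)
    col <- inh_states[j] + 1L
    x[, j, 1] <- a[space$mslot[, col]]
    x[, j, 2] <- a[space$pslot[, col]]
  }
  x
}

solve_founder_slots <- function(space, state_col, j, orientation) {
  k <- space$map$n_alleles[j]
  a <- rep(1L, space$n_slots)
  if (length(space$typed) == 0) return(a)
  if (space$kind == "haplotype") {
    for (i in space$typed) {
      o <- orientation[[i]]
      a[space$mslot[i, state_col]] <- space$data[i, j, 1 + o]
      a[space$pslot[i, state_col]] <- space$data[i, j, 2 - o]
    }
    return(a)
  }
  # genotype data: satisfy each connected component by enumeration
  cons <- lapply(space$typed, function(i) {
    list(s1 = space$mslot[i, state_col], s2 = space$pslot[i, state_col],
         g1 = space$data[i, j, 1], g2 = space$data[i, j, 2])
  })
  parent <- seq_len(space$n_slots)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (cn in cons) {
    p1 <- find(cn$s1); p2 <- find(cn$s2)
    if (p1 != p2) parent[p1] <- p2
  }
  comp <- vapply(seq_len(space$n_slots), find, integer(1))
  involved <- unique(unlist(lapply(cons, function(cn) c(cn$s1, cn$s2))))
  for (cid in unique(comp[involved])) {
    slots <- intersect(which(comp == cid), involved)
    ccons <- Filter(function(cn) comp[cn$s1] == cid, cons)
    A <- as.matrix(expand.grid(rep(list(seq_len(k)), length(slots)),
                               KEEP.OUT.ATTRS = FALSE))
    # order rows so the smallest assignment vector comes first
    A <- A[do.call(order, as.data.frame(A)), , drop = FALSE]
    ok <- rep(TRUE, nrow(A))
    for (cn in ccons) {
      i1 <- match(cn$s1, slots)
      i2 <- match(cn$s2, slots)
      if (cn$s1 == cn$s2) {
        ok <- ok & (cn$g1 == cn$g2) & (A[, i1] == cn$g1)
      } else {
        ok <- ok & ((A[, i1] == cn$g1 & A[, i2] == cn$g2) |
                      (A[, i1] == cn$g2 & A[, i2] == cn$g1))
      }
    }
    if (!any(ok)) stop("internal error: infeasible state on a feasible path")
    a[slots] <- A[which(ok)[1], ]
  }
  a
}
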