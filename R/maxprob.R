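#' Maximum-probability phasing (exhaustive)
#'
#' Finds a phased assignment `x*` maximizing `sum_s P[x | s] P[s]` over all
#' distinct phased assignments consistent with the observed data. The
#' problem is #P-hard in general, so this solver is exhaustive by design:
#' per-locus candidate phasings are enumerated from (inheritance state,
#' founder-allele assignment) pairs, combined across loci, and each
#' candidate's probability is computed as the product of the founder
#' priors and independent per-meiosis two-state chain sums. Ties are
#' broken by the lexicographically smallest encoding of `x` (individuals
#' in pedigree order, loci in order, maternal then paternal allele).
#'
#' @inheritParams forward_backward
#' @param max_candidates Cap on the number of per-locus and combined
#'   candidate phasings; exceeding it is a capacity error.
#' @return An object of class `"max_prob"`: a list with `assignment` (an
#'   `|I| x L x 2` array, or `NULL` for inconsistent data) and
#'   `probability`.
#' @export
max_probability <- function(ped, map, data,
                            data_kind = c("genotype", "haplotype"),
                            max_candidates = 2^18) {
  data_kind <- match.arg(data_kind)
  space <- build_hmm_space(ped, map, data, data_kind, max_states = 2^20)
  L <- map$L
  n <- nrow(ped)

  # distinct per-locus phasings x_j reachable from some (state, founder
  # assignment) pair, filtered by a per-locus data check
  per_locus <- vector("list", L)
  for (j in seq_len(L)) {
    k <- map$n_alleles[j]
    n_assign <- k^(2 * length(space$founders))
    if (as.double(space$S_inh) * n_assign > max_candidates) {
      stop("candidate cap exceeded: per-locus enumeration too large", call. = FALSE)
    }
    seen <- new.env(parent = emptyenv())
    cands <- list()
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), 2 * length(space$founders)),
                                  KEEP.OUT.ATTRS = FALSE))
    for (s in seq_len(space$S_inh)) {
      for (r in seq_len(nrow(grid))) {
        a <- unname(grid[r, ])
        xm <- a[space$mslot[, s]]
        xp <- a[space$pslot[, s]]
        names(xm) <- names(xp) <- space$ped$id
        if (!locus_data_ok(space, xm, xp, j)) next
        key <- paste(c(xm, xp), collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          cands[[length(cands) + 1L]] <- cbind(xm, xp)
        }
      }
    }
    if (length(cands) == 0) {
      return(structure(list(assignment = NULL, probability = 0), class = "max_prob"))
    }
    per_locus[[j]] <- cands
  }

  n_comb <- prod(vapply(per_locus, length, numeric(1)))
  if (n_comb > max_candidates) {
    stop("candidate cap exceeded: too many combined phasings", call. = FALSE)
  }

  best_p <- -1
  best_x <- NULL
  best_enc <- NULL
  idx <- rep(1L, L)
  sizes <- vapply(per_locus, length, integer(1))
  repeat {
    x <- array(0L, dim = c(n, L, 2), dimnames = list(ped$id, NULL, NULL))
    for (j in seq_len(L)) {
      x[, j, ] <- per_locus[[j]][[idx[j]]]
    }
    if (assignment_data_ok(space, x)) {
      p <- assignment_probability(space, x)
      if (p > 0) {
        enc <- as.vector(aperm(x, c(3, 2, 1)))  # maternal/paternal, locus, individual
        if (p > best_p * (1 + 1e-12) ||
            (p >= best_p * (1 - 1e-12) && !is.null(best_enc) &&
               lexicographically_less(enc, best_enc))) {
          best_p <- p
          best_x <- x
          best_enc <- enc
        }
      }
    }
    # advance the mixed-radix counter
    j <- 1L
    while (j <= L) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= sizes[j]) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > L) break
  }

  if (is.null(best_x)) {
    return(structure(list(assignment = NULL, probability = 0), class = "max_prob"))
  }
  structure(list(assignment = best_x, probability = best_p), class = "max_prob")
}

#' @export
print.max_prob <- function(x, ...) {
  cat(sprintf("Maximum-probability phasing: probability %g\n", x$probability))
  invisible(x)
}

lexicographically_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

# Per-locus necessary data check for a candidate (maternal, paternal)
# allele vector: genotype rows must match as unordered pairs; haplotype
# rows must match one of the orientations at this locus (canonical for
# founders). Cross-locus orientation constancy is checked later.
locus_data_ok <- function(space, xm, xp, j) {
  for (i in space$typed) {
    o1 <- data_pair(space, i, j, 0L)
    if (space$kind == "genotype") {
      if (!((xm[i] == o1[1] && xp[i] == o1[2]) ||
              (xm[i] == o1[2] && xp[i] == o1[1]))) return(FALSE)
    } else {
      canonical <- i %in% space$founders
      if (xm[i] == o1[1] && xp[i] == o1[2]) next
      if (!canonical && xm[i] == o1[2] && xp[i] == o1[1]) next
      return(FALSE)
    }
  }
  TRUE
}

data_pair <- function(space, i, j, o) {
  c(space$data[i, j, 1 + o], space$data[i, j, 2 - o])
}

# Full-assignment data check: for haplotype data every typed non-founder
# needs a single orientation valid across all loci; typed founders must
# match the canonical labeling (already enforced per locus).
assignment_data_ok <- function(space, x) {
  if (space$kind != "haplotype") return(TRUE)
  for (i in setdiff(space$typed, space$founders)) {
    ok0 <- all(x[i, , 1] == space$data[i, , 1] & x[i, , 2] == space$data[i, , 2])
    ok1 <- all(x[i, , 1] == space$data[i, , 2] & x[i, , 2] == space$data[i, , 1])
    if (!ok0 && !ok1) return(FALSE)
  }
  TRUE
}

# P[x] = founder priors x product over meioses of 2-state chain sums.
# The chain for one meiosis sums over its origin-bit path: initial weight
# 1/2 per bit value, switch probability theta_j between loci, and the bit
# is admissible at a locus iff the parent's corresponding allele equals
# the transmitted allele.
assignment_probability <- function(space, x) {
  map <- space$map
  ped <- space$ped
  prior <- prod((1 / map$n_alleles)^2)^length(space$founders)
  p <- prior
  mm <- meioses(ped)
  for (r in seq_len(nrow(mm))) {
    child <- mm$child[r]
    parent <- mm$parent[r]
    transmitted <- x[child, , if (mm$side[r] == "m") 1 else 2]
    v <- c(0.5, 0.5)
    for (j in seq_len(map$L)) {
      if (j > 1) {
        th <- map$theta[j - 1]
        v <- c((1 - th) * v[1] + th * v[2], th * v[1] + (1 - th) * v[2])
      }
      adm <- c(x[parent, j, 1] == transmitted[j], x[parent, j, 2] == transmitted[j])
      v[!adm] <- 0
    }
    p <- p * sum(v)
    if (p == 0) break
  }
  p
}
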