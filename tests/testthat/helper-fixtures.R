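# Shared pedigree builders, random instance generators and independent
# brute-force reference implementations for the test suite.

trio_ped <- function() {
  pedigree(c("m", "f", "c"), father = c("0", "0", "f"),
           mother = c("0", "0", "m"))
}

half_sib_ped <- function() {
  pedigree(c("f1", "m", "f2", "c1", "c2"),
           father = c("0", "0", "0", "f1", "f2"),
           mother = c("0", "0", "0", "m", "m"))
}

three_gen_ped <- function() {
  pedigree(c("gp1", "gp2", "p1", "p2", "c1"),
           father = c("0", "0", "gp2", "0", "p1"),
           mother = c("0", "0", "gp1", "0", "p2"))
}

# The six-individual example pedigree: founders 1, 2, 5; individuals 3
# and 4 children of 1 x 2; individual 6 the child of 4 x 5, hence a
# grandchild of 1 and 2. The three non-founders are genotyped.
figure1_ped <- function() {
  pedigree(as.character(1:6),
           father = c("0", "0", "2", "2", "0", "5"),
           mother = c("0", "0", "1", "1", "0", "4"))
}

figure1_genotyped <- function() c("3", "4", "6")

# Random pedigree on n individuals: each individual is, with probability
# `p_child`, the child of two earlier individuals (when at least two
# exist); ids are "i1".."in".
random_pedigree <- function(n, p_child = 0.7) {
  id <- paste0("i", seq_len(n))
  father <- mother <- rep(NA_character_, n)
  for (r in seq_len(n)) {
    if (r >= 3 && stats::runif(1) < p_child) {
      pa <- sample(r - 1L, 2L)
      father[r] <- id[pa[1]]
      mother[r] <- id[pa[2]]
    }
  }
  pedigree(id, father = father, mother = mother)
}

# Random uniform marker map with binary markers.
random_map <- function(L, theta_max = 0.5) {
  marker_map(rep(2L, L),
             theta = if (L > 1) stats::runif(L - 1, 0.05, theta_max) else numeric(0))
}

# Simulate consistent haplotypes for the whole pedigree by gene dropping.
random_truth <- function(ped, map, seed) {
  sc <- default_scenario(ped, seed = seed, loci = map$L,
                         theta_central = if (map$L > 1) map$theta[1] else 0.25)
  sc$map <- map
  sim_gene_drop(sc, 1)
}

# Force individual `i`'s simulated genotype heterozygous at every locus
# by flipping its second haplotype where needed (binary markers), then
# re-deriving a consistent full assignment is not needed: only `i` is
# typed in the instances using this helper.
all_het_genotype <- function(L) {
  g <- array(0L, dim = c(1, L, 2))
  g[1, , 1] <- 1L
  g[1, , 2] <- 2L
  g
}

# Independent minimum-recombination reference: enumerate the per-locus
# compatible inheritance-state sets by direct allele propagation over all
# founder-allele assignments (and haplotype orientations), then run a
# plain Viterbi-style min-sum over explicit states. Shares no code with
# min_recombination().
brute_min_recomb <- function(ped, map, data, data_kind) {
  fo <- founders(ped)
  nf <- nonfounders(ped)
  S <- 2L^(2L * length(nf))
  typed <- typed_ids(data)
  free_orient <- if (data_kind == "haplotype") {
    Filter(function(i) !(i %in% fo) && !all(data[i, , 1] == data[i, , 2]),
           typed)
  } else {
    character(0)
  }
  orient_grid <- if (length(free_orient) > 0) {
    g <- as.matrix(expand.grid(rep(list(0:1), length(free_orient)),
                               KEEP.OUT.ATTRS = FALSE))
    colnames(g) <- free_orient
    g
  } else {
    matrix(0L, nrow = 1, ncol = 0)
  }
  topo <- ped_topological_order_ref(ped)
  k2F <- 2L * length(fo)
  compatible <- function(s, j, orientation) {
    bits <- integer(2L * length(nf))
    if (length(nf) > 0) {
      bits <- as.integer(intToBits(s))[seq_len(2L * length(nf))]
    }
    grid <- as.matrix(expand.grid(rep(list(seq_len(map$n_alleles[j])), k2F),
                                  KEEP.OUT.ATTRS = FALSE))
    for (r in seq_len(nrow(grid))) {
      a <- grid[r, ]
      x <- matrix(0L, nrow = nrow(ped), ncol = 2, dimnames = list(ped$id, NULL))
      for (i in topo) {
        rr <- match(i, ped$id)
        if (i %in% fo) {
          fi <- match(i, fo)
          x[i, ] <- c(a[2 * fi - 1], a[2 * fi])
        } else {
          ni <- match(i, nf)
          x[i, 1] <- x[ped$mother[rr], 1 + bits[2 * ni - 1]]
          x[i, 2] <- x[ped$father[rr], 1 + bits[2 * ni]]
        }
      }
      ok <- TRUE
      for (i in typed) {
        obs <- data[i, j, ]
        if (data_kind == "genotype") {
          if (!identical(sort(as.integer(x[i, ])), sort(as.integer(obs)))) {
            ok <- FALSE
            break
          }
        } else {
          o <- if (i %in% free_orient) orientation[[i]] else 0L
          want <- if (o == 0) obs else rev(obs)
          if (x[i, 1] != want[1] || x[i, 2] != want[2]) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
  best <- Inf
  for (oi in seq_len(nrow(orient_grid))) {
    orientation <- orient_grid[oi, ]
    ok <- matrix(FALSE, nrow = S, ncol = map$L)
    for (s in 0:(S - 1L)) {
      for (j in seq_len(map$L)) ok[s + 1, j] <- compatible(s, j, orientation)
    }
    if (any(colSums(ok) == 0)) next
    cost <- ifelse(ok[, 1], 0, Inf)
    for (j in seq_len(map$L)[-1]) {
      new_cost <- rep(Inf, S)
      for (s in 0:(S - 1L)) {
        if (!ok[s + 1, j]) next
        trans <- vapply(0:(S - 1L), function(t) {
          sum(as.integer(intToBits(bitwXor(s, t)))[seq_len(2L * length(nf))])
        }, numeric(1))
        new_cost[s + 1] <- min(cost + trans)
      }
      cost <- new_cost
    }
    best <- min(best, min(cost))
  }
  best
}

# Minimal topological sort used only by the reference implementations.
ped_topological_order_ref <- function(ped) {
  remaining <- ped$id
  placed <- character(0)
  while (length(remaining) > 0) {
    ready <- Filter(function(i) {
      r <- match(i, ped$id)
      (is.na(ped$father[r]) ||
         ped$father[r] %in% placed) &&
        (is.na(ped$mother[r]) || ped$mother[r] %in% placed)
    }, remaining)
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

# Genotype table with one typed individual.
single_genotype_table <- function(id, g, map) {
  dimnames(g) <- list(id, NULL, NULL)
  genotype_table(g, ids = id, map = map)
}
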