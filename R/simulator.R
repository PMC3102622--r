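#' Simulation scenario around a recombination breakpoint
#'
#' The default scenario places 40 biallelic SNPs in two tightly linked
#' blocks of 20 on either side of a strong recombination breakpoint with
#' `theta = 0.25`; all other intervals get `theta_tight` (default 0.01).
#' Founder haplotypes come from a synthetic pool drawn i.i.d. per locus
#' from uniform (or supplied) allele frequencies -- a stand-in for a panel
#' of population haplotypes, reproducing linkage structure only through
#' the map, not through founder linkage disequilibrium.
#'
#' @param ped A [pedigree()].
#' @param seed Integer seed; the scenario and every replicate derived from
#'   it are reproducible functions of this seed.
#' @param loci Number of biallelic loci (the breakpoint sits mid-map).
#' @param theta_central Recombination fraction of the central interval.
#' @param theta_tight Recombination fraction of all other intervals.
#' @param pool_size Number of founder haplotypes to draw (default: exactly
#'   two per founder).
#' @param allele_freqs Optional allele-frequency vector passed to
#'   [generate_founder_pool()].
#' @param replicates Replicate count carried along for bookkeeping.
#' @return An object of class `"sim_scenario"`: a list with `ped`, `map`,
#'   `pool`, `seed`, `replicates` and `central_interval`.
#' @export
default_scenario <- function(ped, seed, loci = 40, theta_central = 0.25,
                             theta_tight = 0.01, pool_size = NULL,
                             allele_freqs = NULL, replicates = 1) {
  assert_valid_pedigree(ped)
  central <- as.integer(floor(loci / 2))
  theta <- rep(theta_tight, loci - 1)
  theta[central] <- theta_central
  map <- marker_map(rep(2L, loci), theta)
  if (is.null(pool_size)) pool_size <- 2L * length(founders(ped))
  pool <- generate_founder_pool(pool_size, map, seed, allele_freqs)
  structure(list(ped = ped, map = map, pool = pool, seed = as.integer(seed),
                 replicates = as.integer(replicates),
                 central_interval = central),
            class = "sim_scenario")
}

#' Synthetic founder haplotype pool
#'
#' Draws `n` haplotypes of length `map$L`, sampling each locus
#' independently from the given allele frequencies (uniform over the
#' `k_j` alleles by default). Deterministic given the seed; the caller's
#' random-number state is left untouched.
#'
#' @param n Number of haplotypes, at least two per founder of the pedigree
#'   they will seed.
#' @param map A [marker_map()].
#' @param seed Integer seed.
#' @param allele_freqs `NULL` for uniform, or a numeric vector of
#'   frequencies recycled across loci (length `max(k_j)`).
#' @return An `n x L` integer matrix, one haplotype per row.
#' @examples
#' pool <- generate_founder_pool(6, marker_map(rep(2, 5), rep(0.1, 4)), seed = 1)
#' dim(pool)  # 6 x 5
#' @export
generate_founder_pool <- function(n, map, seed, allele_freqs = NULL) {
  if (n < 2) stop("the founder pool needs at least two haplotypes")
  with_local_seed(seed, {
    pool <- matrix(0L, nrow = n, ncol = map$L)
    for (j in seq_len(map$L)) {
      k <- map$n_alleles[j]
      prob <- if (is.null(allele_freqs)) rep(1 / k, k) else allele_freqs[seq_len(k)]
      pool[, j] <- sample.int(k, n, replace = TRUE, prob = prob)
    }
    pool
  })
}

#' Gene-dropping simulation
#'
#' Simulates one replicate of inheritance on the scenario's pedigree:
#' founders receive pool haplotypes in order (two each, no reuse); each
#' meiosis picks a parental haplotype uniformly at the first locus and
#' switches haplotype between adjacent loci with probability `theta_j`;
#' children copy the selected parental allele. The per-meiosis origin-bit
#' paths and the true per-interval recombination counts (Hamming distance
#' between consecutive inheritance states) are recorded, and the derived
#' genotype table holds the unordered pairs of the simulated haplotypes.
#'
#' Each replicate uses its own generator seeded from the scenario seed and
#' the replicate index, so any replicate is reproducible in isolation.
#'
#' @param scenario A [default_scenario()] (or hand-built `sim_scenario`).
#' @param replicate Replicate index (1-based).
#' @param theta_is_stay_prob Treat `theta_j` as the probability of
#'   *staying* on the same parental haplotype instead of switching (the
#'   complementary convention); off by default.
#' @return An object of class `"sim_result"`: a list with `haplotypes` (a
#'   [haplotype_table()] for all individuals, hapA = maternal),
#'   `genotypes`, `inheritance` (meiosis x locus 0/1 origin-bit matrix,
#'   rows named `child:m` / `child:p`), `true_recomb` (per-interval
#'   counts) and `replicate`.
#' @export
sim_gene_drop <- function(scenario, replicate = 1, theta_is_stay_prob = FALSE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  ped <- scenario$ped
  map <- scenario$map
  fo <- founders(ped)
  if (nrow(scenario$pool) < 2 * length(fo)) {
    stop("founder pool exhausted: need two haplotypes per founder", call. = FALSE)
  }
  with_local_seed(replicate_seed(scenario$seed, replicate), {
    L <- map$L
    hap <- array(0L, dim = c(nrow(ped), L, 2),
                 dimnames = list(ped$id, NULL, NULL))
    for (f in seq_along(fo)) {
      hap[fo[f], , 1] <- scenario$pool[2 * f - 1, ]
      hap[fo[f], , 2] <- scenario$pool[2 * f, ]
    }
    mm <- meioses(ped)
    bits <- matrix(0L, nrow = nrow(mm), ncol = L,
                   dimnames = list(paste(mm$child, mm$side, sep = ":"), NULL))
    for (i in ped_topological_order(ped)) {
      rows <- which(mm$child == i)
      if (length(rows) == 0) next
      for (r in rows) {
        parent <- mm$parent[r]
        b <- integer(L)
        b[1] <- sample(0:1, 1)
        if (L > 1) {
          u <- stats::runif(L - 1)
          switch_prob <- if (theta_is_stay_prob) 1 - map$theta else map$theta
          flips <- as.integer(u < switch_prob)
          b <- cumsum(c(b[1], flips)) %% 2L
        }
        bits[r, ] <- b
        side <- if (mm$side[r] == "m") 1 else 2
        sel <- cbind(seq_len(L), b + 1L)
        hap[i, , side] <- hap[parent, , ][sel]
      }
    }
    true_recomb <- if (L > 1) {
      colSums(matrix(bits[, -1, drop = FALSE] != bits[, -L, drop = FALSE],
                     nrow = nrow(bits)))
    } else {
      integer(0)
    }
    haps <- haplotype_table(hap, ids = ped$id, map = map)
    structure(list(haplotypes = haps,
                   genotypes = genotypes_from_haplotypes(haps),
                   inheritance = bits,
                   true_recomb = as.integer(true_recomb),
                   scenario = scenario, replicate = as.integer(replicate)),
              class = "sim_result")
  })
}

#' Remove untyped individuals from simulated data
#'
#' Masks the given individuals in both the genotype and the haplotype
#' view of one simulated replicate. The two returned tables share the same
#' typed set and identical underlying alleles; only the sequence structure
#' differs.
#'
#' @param result A [sim_gene_drop()] result.
#' @param untyped Character vector of individuals to drop (subset of the
#'   pedigree).
#' @return A list with masked `genotypes` and `haplotypes` tables.
#' @export
mask_data <- function(result, untyped = character(0)) {
  stopifnot(inherits(result, "sim_result"))
  ids <- typed_ids(result$haplotypes)
  if (!all(untyped %in% ids)) {
    stop("unknown individuals in untyped set: ",
         paste(setdiff(untyped, ids), collapse = ", "))
  }
  keep <- setdiff(ids, untyped)
  sub <- function(tab, ctor) {
    arr <- unclass(tab)[keep, , , drop = FALSE]
    ctor(arr, ids = keep)
  }
  list(genotypes = sub(result$genotypes, genotype_table),
       haplotypes = sub(result$haplotypes, haplotype_table))
}

# Independent, reproducible seed per replicate (kept below 2^31).
replicate_seed <- function(seed, replicate) {
  as.integer((as.double(seed) + 1000003 * as.double(replicate)) %% 2147483629)
}

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
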