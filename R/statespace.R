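# Hidden state space for the inheritance-vector HMMs.
#
# Hidden states are inheritance vectors (2 bits per non-founder meiosis,
# see meioses()) for genotype data, and inheritance vectors crossed with
# haplotype orientations for haplotype data. Orientation bits are carried
# only where they are identifiable as distinct phased assignments:
#  * typed non-founders whose two observed sequences differ carry one bit
#    (0 = hapA maternal);
#  * typed non-founders with identical sequences have a single distinct
#    phasing, so no bit;
#  * typed founders get the canonical labeling hapA = maternal: their own
#    maternal/paternal labels are not pinned by any earlier generation, so
#    the two labelings are the same unordered founder assignment and are
#    counted once (the founder prior is exchangeable).
# This makes the haplotype likelihood a sum over *distinct* phased
# assignments, and is what makes it agree with the trio-decomposition
# likelihood for fully-haplotyped pedigrees.
#
# Emissions at a locus sum the uniform founder-allele prior over all
# founder-slot assignments compatible with the state and the observed
# data: each founder contributes two "slots" (its maternal and paternal
# haplotype allele); every individual's maternal/paternal allele traces
# back through the inheritance bits to one slot; typed individuals then
# impose pair constraints (genotype) or forced alleles (haplotype) on
# those slots. Free slots sum to one; constrained groups contribute
# (#satisfying assignments) / k^(#slots in group).

build_hmm_space <- function(ped, map, data,
                            data_kind = c("genotype", "haplotype"),
                            max_states = 2^20) {
  data_kind <- match.arg(data_kind)
  assert_valid_pedigree(ped)
  if (n_loci(data) != map$L) {
    stop("observation table and marker map disagree on the number of loci")
  }
  if (!all(typed_ids(data) %in% ped$id)) {
    stop("typed individuals absent from the pedigree: ",
         paste(setdiff(typed_ids(data), ped$id), collapse = ", "))
  }
  fo <- founders(ped)
  nf <- nonfounders(ped)
  n_bits <- 2L * length(nf)
  if (n_bits > 30 || 2^n_bits > max_states) {
    stop("state-space cap exceeded: ", n_bits, " meiosis bits (",
         format(2^n_bits, scientific = TRUE), " inheritance states) over the ",
         "max_states limit of ", max_states, call. = FALSE)
  }
  S_inh <- bitwShiftL(1L, n_bits)

  # founder slots: founder f (in founder order) owns slots 2f-1, 2f
  slot_of <- stats::setNames(seq(1L, by = 2L, length.out = length(fo)), fo)
  n_slots <- 2L * length(fo)

  # maternal/paternal source slot of every individual, per inheritance state
  topo <- ped_topological_order(ped)
  states <- 0:(S_inh - 1L)
  mslot <- pslot <- matrix(0L, nrow = nrow(ped), ncol = S_inh,
                           dimnames = list(ped$id, NULL))
  bit_of <- stats::setNames(seq(0L, by = 2L, length.out = length(nf)), nf)
  for (i in topo) {
    r <- match(i, ped$id)
    if (i %in% fo) {
      mslot[i, ] <- slot_of[[i]]
      pslot[i, ] <- slot_of[[i]] + 1L
    } else {
      mb <- state_bit(states, bit_of[[i]])
      pb <- state_bit(states, bit_of[[i]] + 1L)
      mo <- ped$mother[r]
      fa <- ped$father[r]
      mslot[i, ] <- ifelse(mb == 0L, mslot[mo, ], pslot[mo, ])
      pslot[i, ] <- ifelse(pb == 0L, mslot[fa, ], pslot[fa, ])
    }
  }

  typed <- typed_ids(data)
  if (data_kind == "haplotype") {
    orientations <- enumerate_orientations(ped, map, data)
  } else {
    orientations <- matrix(0L, nrow = 1, ncol = length(typed),
                           dimnames = list(NULL, typed))
  }
  n_orient <- nrow(orientations)
  S <- as.double(S_inh) * n_orient
  if (S > max_states) {
    stop(sprintf("state-space cap exceeded: %d inheritance states x %d orientations > %d",
                 S_inh, n_orient, max_states))
  }

  space <- list(
    kind = data_kind, ped = ped, map = map, data = data,
    founders = fo, nonfounders = nf, n_bits = n_bits,
    S_inh = S_inh, n_orient = n_orient, S = as.integer(S),
    orientations = orientations, slot_of = slot_of, n_slots = n_slots,
    mslot = mslot, pslot = pslot, bit_of = bit_of, typed = typed
  )
  space$emissions <- compute_emissions(space)
  space
}

# Orientation vectors (one row per configuration, columns = typed ids).
# A typed individual's bit is free only when it is a non-founder with
# distinct observed sequences; per-individual infeasible orientations
# (required parental allele absent from a typed parent at some locus) are
# pruned -- an exact individual-level necessary condition.
enumerate_orientations <- function(ped, map, data) {
  typed <- typed_ids(data)
  fo <- founders(ped)
  choice <- list()
  for (i in typed) {
    if (i %in% fo || all(data[i, , 1] == data[i, , 2])) {
      choice[[i]] <- 0L
      next
    }
    r <- match(i, ped$id)
    ok <- logical(2)
    for (o in 0:1) {
      mseq <- data[i, , 1 + o]
      pseq <- data[i, , 2 - o]
      ok[o + 1] <- orientation_feasible(mseq, ped$mother[r], data) &&
        orientation_feasible(pseq, ped$father[r], data)
    }
    choice[[i]] <- if (any(ok)) (0:1)[ok] else 0:1
  }
  if (length(typed) == 0) return(matrix(0L, nrow = 1, ncol = 0))
  grid <- expand.grid(choice, KEEP.OUT.ATTRS = FALSE)
  out <- as.matrix(grid)
  storage.mode(out) <- "integer"
  colnames(out) <- typed
  out
}

orientation_feasible <- function(child_seq, parent, data) {
  if (!(parent %in% typed_ids(data))) return(TRUE)
  all(child_seq == data[parent, , 1] | child_seq == data[parent, , 2])
}

# Emission matrix: S x L (inheritance index varies fastest within each
# orientation block).
compute_emissions <- function(space) {
  L <- space$map$L
  E <- matrix(0, nrow = space$S, ncol = L)
  if (space$kind == "haplotype") {
    for (oi in seq_len(space$n_orient)) {
      rows <- (oi - 1L) * space$S_inh + seq_len(space$S_inh)
      for (j in seq_len(L)) {
        E[rows, j] <- haplotype_emission_block(space, space$orientations[oi, ], j)
      }
    }
  } else {
    keys <- genotype_state_keys(space)
    for (j in seq_len(L)) {
      vals <- vapply(keys$reps, function(s) {
        genotype_emission_state(space, s, j)
      }, numeric(1))
      E[, j] <- vals[keys$index]
    }
  }
  E
}

# Group inheritance states by the slot mapping they induce on typed
# individuals; emissions only depend on that mapping.
genotype_state_keys <- function(space) {
  if (length(space$typed) == 0) {
    return(list(index = rep(1L, space$S_inh), reps = 1L))
  }
  M <- rbind(space$mslot[space$typed, , drop = FALSE],
             space$pslot[space$typed, , drop = FALSE])
  key <- do.call(paste, c(as.data.frame(t(M)), sep = "."))
  index <- match(key, unique(key))
  reps <- which(!duplicated(index))
  list(index = index, reps = reps)
}

# Exact emission for one inheritance state (genotype data): partition the
# constrained slots into connected components and count satisfying
# founder-allele assignments by enumeration.
genotype_emission_state <- function(space, state_col, j) {
  k <- space$map$n_alleles[j]
  cons <- lapply(space$typed, function(i) {
    list(s1 = space$mslot[i, state_col], s2 = space$pslot[i, state_col],
         g1 = space$data[i, j, 1], g2 = space$data[i, j, 2])
  })
  if (length(cons) == 0) return(1)
  # union-find over slots
  parent <- seq_len(space$n_slots)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (cn in cons) {
    a <- find(cn$s1); b <- find(cn$s2)
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(space$n_slots), find, integer(1))
  involved <- unique(unlist(lapply(cons, function(cn) c(cn$s1, cn$s2))))
  total <- 1
  for (cid in unique(comp[involved])) {
    slots <- intersect(which(comp == cid), involved)
    ccons <- Filter(function(cn) comp[cn$s1] == cid, cons)
    if (length(slots) > 12) stop("state-space cap exceeded in emission enumeration")
    A <- as.matrix(expand.grid(rep(list(seq_len(k)), length(slots)),
                               KEEP.OUT.ATTRS = FALSE))
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
    total <- total * sum(ok) / k^length(slots)
    if (total == 0) break
  }
  total
}

# Vectorized emission over all inheritance states for one orientation
# configuration (haplotype data): all constraints are forced alleles on
# slots, so track per-slot requirements and detect conflicts.
haplotype_emission_block <- function(space, orientation, j) {
  S <- space$S_inh
  k <- space$map$n_alleles[j]
  if (length(space$typed) == 0) return(rep(1, S))
  req <- matrix(0L, nrow = S, ncol = space$n_slots)
  conflict <- rep(FALSE, S)
  seqS <- seq_len(S)
  for (i in space$typed) {
    o <- orientation[[i]]
    am <- space$data[i, j, 1 + o]
    ap <- space$data[i, j, 2 - o]
    for (side in 1:2) {
      slots <- if (side == 1) space$mslot[i, ] else space$pslot[i, ]
      a <- if (side == 1) am else ap
      idx <- cbind(seqS, slots)
      cur <- req[idx]
      conflict <- conflict | (cur != 0L & cur != a)
      req[idx] <- a
    }
  }
  count <- rowSums(req != 0L)
  e <- k^(-count)
  e[conflict] <- 0
  e
}

# Index permutations realizing a flip of each meiosis bit, over the full
# (orientation x inheritance) state vector.
state_bit_perms <- function(space) {
  lapply(seq_len(space$n_bits) - 1L, function(b) {
    p <- bitwXor(0:(space$S_inh - 1L), bitwShiftL(1L, b)) + 1L
    if (space$n_orient == 1) return(p)
    rep(p, space$n_orient) +
      rep((seq_len(space$n_orient) - 1L) * space$S_inh, each = space$S_inh)
  })
}
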