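#' Brute-force pedigree likelihood (test oracle)
#'
#' Computes the likelihood by literal enumeration: every inheritance-state
#' path is listed explicitly, and at each locus the uniform founder-allele
#' prior is summed over all `k^(2|F|)` founder assignments, with
#' compatibility decided by directly propagating alleles down the pedigree
#' and comparing against the observed data. For haplotype data the
#' enumeration additionally loops over the per-individual orientations of
#' typed non-founders with distinct sequences (typed founders keep the
#' canonical hapA-maternal labeling, so each distinct phased assignment is
#' counted once).
#'
#' This deliberately shares no machinery with [forward_backward()]; it
#' exists to validate it on tiny instances and is guarded by a size cap.
#'
#' @inheritParams forward_backward
#' @param max_paths Cap on the number of enumerated state paths.
#' @return The likelihood as a scalar.
#' @export
brute_force_likelihood <- function(ped, map, data,
                                   data_kind = c("genotype", "haplotype"),
                                   max_paths = 2^20) {
  data_kind <- match.arg(data_kind)
  assert_valid_pedigree(ped)
  fo <- founders(ped)
  nf <- nonfounders(ped)
  L <- map$L
  S <- bitwShiftL(1L, 2L * length(nf))
  if (as.double(S)^L > max_paths) {
    stop("size guard: brute-force enumeration too large", call. = FALSE)
  }

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

  topo <- ped_topological_order(ped)
  k2F <- 2L * length(fo)

  # per-locus, per-state founder-prior mass, for one orientation
  locus_mass <- function(s, j, orientation) {
    k <- map$n_alleles[j]
    bits <- decode_inheritance_state(s, ped)
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), k2F),
                                  KEEP.OUT.ATTRS = FALSE))
    n_ok <- 0L
    for (r in seq_len(nrow(grid))) {
      a <- grid[r, ]
      x <- matrix(0L, nrow = nrow(ped), ncol = 2, dimnames = list(ped$id, NULL))
      for (i in topo) {
        rr <- match(i, ped$id)
        if (i %in% fo) {
          fi <- match(i, fo)
          x[i, ] <- c(a[2 * fi - 1], a[2 * fi])
        } else {
          x[i, 1] <- x[ped$mother[rr], 1 + bits[i, "m"]]
          x[i, 2] <- x[ped$father[rr], 1 + bits[i, "p"]]
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
          o <- if (i %in% fo) 0L else if (i %in% free_orient) orientation[[i]] else 0L
          want <- if (o == 0) obs else rev(obs)
          if (x[i, 1] != want[1] || x[i, 2] != want[2]) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) n_ok <- n_ok + 1L
    }
    n_ok / k^k2F
  }

  total <- 0
  paths <- as.matrix(expand.grid(rep(list(0:(S - 1L)), L),
                                 KEEP.OUT.ATTRS = FALSE))
  for (oi in seq_len(nrow(orient_grid))) {
    orientation <- orient_grid[oi, ]
    EM <- matrix(0, nrow = S, ncol = L)
    for (s in 0:(S - 1L)) {
      for (j in seq_len(L)) {
        EM[s + 1, j] <- locus_mass(s, j, orientation)
      }
    }
    for (r in seq_len(nrow(paths))) {
      p <- 1 / S
      for (j in seq_len(L)) {
        p <- p * EM[paths[r, j] + 1, j]
        if (p == 0) break
        if (j > 1) {
          d <- state_hamming(paths[r, j - 1], paths[r, j])
          th <- map$theta[j - 1]
          p <- p * th^d * (1 - th)^(2 * length(nf) - d)
        }
      }
      total <- total + p
    }
  }
  total
}
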