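#' Forward-backward algorithm over inheritance vectors
#'
#' Runs the scaled forward-backward algorithm on the hidden Markov model
#' whose hidden states are inheritance vectors (genotype data) or
#' inheritance vectors crossed with haplotype orientations (haplotype
#' data), with transition probability `theta^d * (1 - theta)^(n_meioses - d)`
#' for `d` flipped meiosis bits (orientation changes are forbidden), and
#' emissions that sum the uniform `1/k_j` founder-allele prior over
#' assignments compatible with the state and the observed data. Each
#' inheritance vector has prior probability `1 / 2^(2 * n_nonfounders)` at
#' the first locus; orientations carry no additional prior weight, so the
#' likelihood is a sum over distinct phased assignments.
#'
#' Mendelian-inconsistent data yield likelihood 0 together with a
#' diagnostic naming the earliest offending locus.
#'
#' @param ped A [pedigree()].
#' @param map A [marker_map()].
#' @param data A [genotype_table()] or [haplotype_table()].
#' @param data_kind `"genotype"` or `"haplotype"`.
#' @param max_states Cap on the hidden state count; exceeding it is an
#'   error, never a silent approximation.
#' @return An object of class `"pedigree_fb"`: a list with elements
#'   `likelihood`, `loglik`, `posterior` (an `S x L` matrix of per-locus
#'   state posteriors), `diagnostic` (`NULL` or a message), plus the scaled
#'   forward/backward quantities needed by [recombination_distribution()]
#'   and [pairwise_posterior()].
#' @seealso [likelihood()], [recombination_distribution()]
#' @export
forward_backward <- function(ped, map, data,
                             data_kind = c("genotype", "haplotype"),
                             max_states = 2^20) {
  data_kind <- match.arg(data_kind)
  space <- build_hmm_space(ped, map, data, data_kind, max_states)
  E <- space$emissions
  L <- map$L
  S <- space$S
  perms <- state_bit_perms(space)

  zero_locus <- which(colSums(E) == 0)
  if (length(zero_locus) > 0) {
    return(fb_zero(space, sprintf(
      "data are Mendelian-inconsistent: no compatible inheritance state at locus %d",
      zero_locus[1])))
  }

  transform <- function(v, theta) {
    for (p in perms) v <- (1 - theta) * v + theta * v[p]
    v
  }

  f <- matrix(0, nrow = S, ncol = L)
  scales <- numeric(L)
  v <- rep(1 / space$S_inh, S) * E[, 1]
  scales[1] <- sum(v)
  f[, 1] <- v / scales[1]
  for (j in seq_len(L)[-1]) {
    v <- transform(f[, j - 1], map$theta[j - 1]) * E[, j]
    scales[j] <- sum(v)
    if (scales[j] == 0) {
      return(fb_zero(space, sprintf(
        "data are Mendelian-inconsistent: no positive-probability path through locus %d", j)))
    }
    f[, j] <- v / scales[j]
  }

  b <- matrix(0, nrow = S, ncol = L)
  bscales <- numeric(L)
  b[, L] <- 1
  bscales[L] <- 1
  if (L > 1) {
    for (j in rev(seq_len(L - 1))) {
      w <- transform(b[, j + 1] * E[, j + 1], map$theta[j])
      bscales[j] <- sum(w)
      b[, j] <- w / bscales[j]
    }
  }

  post <- f * b
  post <- sweep(post, 2, colSums(post), "/")

  loglik <- sum(log(scales))
  structure(list(
    space = space, likelihood = exp(loglik), loglik = loglik,
    posterior = post, f = f, b = b, scales = scales, bscales = bscales,
    diagnostic = NULL
  ), class = "pedigree_fb")
}

fb_zero <- function(space, msg) {
  structure(list(space = space, likelihood = 0, loglik = -Inf,
                 posterior = NULL, f = NULL, b = NULL,
                 scales = NULL, bscales = NULL, diagnostic = msg),
            class = "pedigree_fb")
}

#' @export
print.pedigree_fb <- function(x, ...) {
  cat(sprintf("Inheritance HMM (%s data): %d states x %d loci\n",
              x$space$kind, x$space$S, x$space$map$L))
  cat(sprintf("log-likelihood: %g\n", x$loglik))
  if (!is.null(x$diagnostic)) cat("note:", x$diagnostic, "\n")
  invisible(x)
}

#' Pedigree likelihood
#'
#' The probability of the observed genotype or haplotype data, summed over
#' all unobserved phased assignments and inheritance paths.
#'
#' @inheritParams forward_backward
#' @return The likelihood as a scalar, with attributes `loglik` and (for
#'   inconsistent data) `diagnostic`.
#' @examples
#' trio <- pedigree(c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"))
#' map <- marker_map(2)
#' g <- genotype_table(array(1L, dim = c(3, 1, 2)), ids = c("f", "m", "c"))
#' likelihood(trio, map, g, "genotype")  # 1/16
#' @export
likelihood <- function(ped, map, data,
                       data_kind = c("genotype", "haplotype"),
                       max_states = 2^20) {
  fb <- forward_backward(ped, map, data, data_kind, max_states)
  structure(fb$likelihood, loglik = fb$loglik, diagnostic = fb$diagnostic)
}

#' Posterior distribution of the recombination count in one interval
#'
#' Computes the posterior probability mass function of the total number of
#' recombinations (over all meioses in the pedigree) occurring in the
#' interval between locus `interval` and locus `interval + 1`, under the
#' fitted inheritance HMM.
#'
#' @param fb A [forward_backward()] result.
#' @param interval 1-based interval index in `1..L-1`.
#' @return An object of class `"recomb_distribution"`: a list with the
#'   `interval` and `pmf`, a named vector over counts `0..n_meioses`.
#' @export
recombination_distribution <- function(fb, interval) {
  stopifnot(inherits(fb, "pedigree_fb"))
  space <- fb$space
  L <- space$map$L
  if (L < 2) stop("the marker map has no inter-locus interval")
  if (interval < 1 || interval > L - 1) {
    stop(sprintf("interval must lie in 1..%d", L - 1))
  }
  if (!is.null(fb$diagnostic)) {
    stop("recombination distribution unavailable: ", fb$diagnostic)
  }
  nb <- space$n_bits
  theta <- space$map$theta[interval]
  perms <- state_bit_perms(space)
  # W[, r+1] accumulates forward mass reaching each state with exactly r
  # recombinations across the interval's meioses.
  W <- matrix(0, nrow = space$S, ncol = nb + 1)
  W[, 1] <- fb$f[, interval]
  for (p in perms) {
    W2 <- (1 - theta) * W
    if (nb > 0) {
      W2[, 2:(nb + 1)] <- W2[, 2:(nb + 1)] + theta * W[p, 1:nb, drop = FALSE]
    }
    W <- W2
  }
  tail_w <- fb$space$emissions[, interval + 1] * fb$b[, interval + 1]
  pmf <- as.vector(crossprod(W, tail_w))
  pmf <- pmf / sum(pmf)
  names(pmf) <- 0:nb
  structure(list(interval = interval, pmf = pmf),
            class = "recomb_distribution")
}

#' @export
print.recomb_distribution <- function(x, ...) {
  cat(sprintf("Recombination-count posterior, interval %d:\n", x$interval))
  print(round(x$pmf, 6))
  invisible(x)
}

#' Pairwise state posterior for one interval
#'
#' Joint posterior over the hidden states at the two loci flanking an
#' interval. Intended for small state spaces (diagnostics and tests);
#' [recombination_distribution()] avoids materializing this matrix.
#'
#' @inheritParams recombination_distribution
#' @param max_states Refuse to materialize matrices larger than
#'   `max_states^2`.
#' @return An `S x S` matrix summing to 1; rows index the state at locus
#'   `interval`, columns the state at `interval + 1`.
#' @export
pairwise_posterior <- function(fb, interval, max_states = 4096) {
  stopifnot(inherits(fb, "pedigree_fb"))
  space <- fb$space
  if (space$S > max_states) {
    stop("state-space cap exceeded for explicit pairwise posteriors")
  }
  if (!is.null(fb$diagnostic)) {
    stop("pairwise posterior unavailable: ", fb$diagnostic)
  }
  L <- space$map$L
  if (L < 2 || interval < 1 || interval > L - 1) {
    stop(sprintf("interval must lie in 1..%d", L - 1))
  }
  theta <- space$map$theta[interval]
  Tm <- transition_matrix(space, theta)
  M <- outer(fb$f[, interval],
             fb$space$emissions[, interval + 1] * fb$b[, interval + 1]) * Tm
  M / sum(M)
}

# Explicit transition matrix over the full state space (small spaces only).
transition_matrix <- function(space, theta) {
  inh <- 0:(space$S_inh - 1L)
  D <- outer(inh, inh, function(a, b) popcount(bitwXor(a, b)))
  Tm <- theta^D * (1 - theta)^(space$n_bits - D)
  if (space$n_orient > 1) {
    Z <- matrix(0, space$n_orient, space$n_orient)
    diag(Z) <- 1
    Tm <- kronecker(Z, Tm)
  }
  Tm
}

#' Transition probability between two hidden states
#'
#' `theta^d * (1 - theta)^(n_meioses - d)` where `d` is the Hamming
#' distance between the inheritance bit vectors; for haplotype data,
#' transitions between states with different orientations have
#' probability zero.
#'
#' @param space A state space as stored in a [forward_backward()] result
#'   (`fb$space`).
#' @param state_a,state_b Integer inheritance-state encodings.
#' @param theta Recombination fraction of the interval.
#' @param orient_a,orient_b Orientation configuration indices (1-based),
#'   for haplotype spaces.
#' @return A probability.
#' @export
transition_probability <- function(space, state_a, state_b, theta,
                                   orient_a = 1L, orient_b = 1L) {
  if (orient_a != orient_b) return(0)
  d <- popcount(bitwXor(as.integer(state_a), as.integer(state_b)))
  theta^d * (1 - theta)^(space$n_bits - d)
}

#' Emission probability of a hidden state at one locus
#'
#' @inheritParams transition_probability
#' @param state Integer inheritance-state encoding.
#' @param locus 1-based locus index.
#' @param orient Orientation configuration index (1-based), for haplotype
#'   spaces.
#' @return The founder-allele-prior-weighted probability of the observed
#'   data at `locus` given the hidden state.
#' @export
emission_probability <- function(space, state, locus, orient = 1L) {
  space$emissions[(orient - 1L) * space$S_inh + as.integer(state) + 1L, locus]
}

# Vectorized population count for non-negative integers < 2^30.
popcount <- local({
  tab <- NULL
  function(x) {
    if (is.null(tab)) {
      t0 <- integer(65536)
      for (b in 0:15) t0 <- t0 + bitwAnd(bitwShiftR(0:65535, b), 1L)
      tab <<- t0
    }
    tab[bitwAnd(x, 65535L) + 1L] + tab[bitwShiftR(x, 16L) + 1L]
  }
})
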