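#' Meiosis indexing for a pedigree
#'
#' Every non-founder has two meioses: one maternal (the allele received
#' from the mother) and one paternal. An inheritance state assigns each
#' meiosis one bit: `0` means the transmitted allele has grand-maternal
#' origin (the parent's own maternal allele), `1` grand-paternal. States
#' are encoded as integers in `[0, 2^(2 * n_nonfounders))`, with the
#' maternal bit of the first non-founder (pedigree row order) as the least
#' significant bit, followed by its paternal bit, and so on.
#'
#' @param ped A [pedigree()].
#' @return A data frame with one row per meiosis: columns `child`,
#'   `parent`, `side` (`"m"`/`"p"`) and `bit` (0-based bit position).
#' @export
meioses <- function(ped) {
  nf <- nonfounders(ped)
  rows <- match(nf, ped$id)
  data.frame(
    child = rep(nf, each = 2),
    parent = as.vector(rbind(ped$mother[rows], ped$father[rows])),
    side = rep(c("m", "p"), length(nf)),
    bit = seq_len(2 * length(nf)) - 1L,
    stringsAsFactors = FALSE
  )
}

# Extract bit `pos` (0-based) from non-negative integer states (vectorized).
state_bit <- function(state, pos) {
  bitwAnd(bitwShiftR(as.integer(state), pos), 1L)
}

# Decode an inheritance state into a named matrix of bits:
# rows = non-founders, columns = c("m", "p").
decode_inheritance_state <- function(state, ped) {
  nf <- nonfounders(ped)
  m <- matrix(state_bit(state, seq(0L, by = 2L, length.out = length(nf))),
              ncol = 1)
  p <- matrix(state_bit(state, seq(1L, by = 2L, length.out = length(nf))),
              ncol = 1)
  out <- cbind(m, p)
  dimnames(out) <- list(nf, c("m", "p"))
  out
}

# Hamming distance between two inheritance-state encodings.
state_hamming <- function(a, b) {
  x <- bitwXor(as.integer(a), as.integer(b))
  n <- 0L
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

#' Mendelian and data compatibility at one locus
#'
#' Evaluates the product of the per-individual compatibility indicators
#' `C[i, j]` at a single locus: every non-founder's ordered
#' (maternal, paternal) alleles must equal the parental alleles selected by
#' the inheritance state, and every typed individual's ordered alleles must
#' match the observed data -- as an unordered pair for genotype data, or as
#' the observed sequences under the given orientation for haplotype data
#' (orientation bit `0` assigns observed sequence `hapA` maternal origin).
#'
#' @param x_slice Integer matrix `|I| x 2` of ordered
#'   (maternal, paternal) alleles at the locus; row names are individual
#'   identifiers covering the whole pedigree.
#' @param state Integer inheritance-state encoding (see [meioses()]).
#' @param ped A [pedigree()].
#' @param data A genotype or haplotype table.
#' @param data_kind `"genotype"` or `"haplotype"`.
#' @param locus 1-based locus index into `data`.
#' @param orientation Named integer (0/1) vector over typed individuals;
#'   required iff `data_kind = "haplotype"`.
#' @return `TRUE` iff all compatibility indicators are 1.
#' @export
is_compatible <- function(x_slice, state, ped, data,
                          data_kind = c("genotype", "haplotype"),
                          locus = 1L, orientation = NULL) {
  data_kind <- match.arg(data_kind)
  if (is.null(rownames(x_slice)) || !all(ped$id %in% rownames(x_slice))) {
    stop("x_slice must cover every pedigree individual (named rows)")
  }
  if (data_kind == "haplotype" && is.null(orientation)) {
    stop("haplotype data requires an orientation")
  }
  bits <- decode_inheritance_state(state, ped)
  for (i in nonfounders(ped)) {
    r <- match(i, ped$id)
    mo <- ped$mother[r]
    fa <- ped$father[r]
    if (x_slice[i, 1] != x_slice[mo, 1 + bits[i, "m"]]) return(FALSE)
    if (x_slice[i, 2] != x_slice[fa, 1 + bits[i, "p"]]) return(FALSE)
  }
  for (i in typed_ids(data)) {
    obs <- data[i, locus, ]
    if (data_kind == "genotype") {
      if (!identical(sort(as.integer(x_slice[i, ])), sort(as.integer(obs)))) {
        return(FALSE)
      }
    } else {
      o <- orientation[[i]]
      want <- if (o == 0) obs else rev(obs)
      if (x_slice[i, 1] != want[1] || x_slice[i, 2] != want[2]) return(FALSE)
    }
  }
  TRUE
}
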