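#' Construct a pedigree
#'
#' A pedigree is a directed acyclic graph of individuals in which every
#' individual has either zero recorded parents (a *founder*) or exactly two.
#' Edges run from parent to child, so a pedigree with `n` individuals and
#' `f` founders has exactly `2 * (n - f)` edges.
#'
#' The constructor performs only structural coercion; use
#' [validate_pedigree()] to obtain a report of invariant violations, or rely
#' on [read_dataset()] which validates on ingest.
#'
#' @param id Character vector of unique individual identifiers.
#' @param father,mother Character vectors of parental identifiers, `NA` (or
#'   `"0"`) for founders. An individual must have both parents recorded or
#'   neither.
#' @return An object of class `"pedigree"`: a data frame with columns `id`,
#'   `father`, `mother`.
#' @seealso [founders()], [validate_pedigree()], [read_pedigree()]
#' @examples
#' trio <- pedigree(c("f", "m", "c"), father = c(NA, NA, "f"),
#'                  mother = c(NA, NA, "m"))
#' founders(trio)
#' @export
pedigree <- function(id, father = NA_character_, mother = NA_character_) {
  id <- as.character(id)
  father <- as.character(father)
  mother <- as.character(mother)
  n <- length(id)
  father <- rep_len(father, n)
  mother <- rep_len(mother, n)
  father[!is.na(father) & father == "0"] <- NA_character_
  mother[!is.na(mother) & mother == "0"] <- NA_character_
  ped <- data.frame(id = id, father = father, mother = mother,
                    stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals (%d founders, %d non-founders)\n",
              nrow(x), length(founders(x)), length(nonfounders(x))))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Founders and non-founders of a pedigree
#'
#' @param ped A [pedigree()].
#' @return Character vector of identifiers, in pedigree row order.
#' @export
founders <- function(ped) {
  ped$id[is.na(ped$father) & is.na(ped$mother)]
}

#' @rdname founders
#' @export
nonfounders <- function(ped) {
  ped$id[!(is.na(ped$father) & is.na(ped$mother))]
}

#' Parent-to-child edge list
#'
#' @param ped A [pedigree()].
#' @return Data frame with columns `parent`, `child`; two rows per
#'   non-founder.
#' @export
ped_edges <- function(ped) {
  nf <- !(is.na(ped$father) & is.na(ped$mother))
  data.frame(
    parent = c(ped$father[nf], ped$mother[nf]),
    child = c(ped$id[nf], ped$id[nf]),
    stringsAsFactors = FALSE
  )
}

# Kahn topological order over parent -> child edges; returns ids, parents
# before children.  NULL when the relation is cyclic.
ped_topological_order <- function(ped) {
  ids <- ped$id
  indeg <- integer(length(ids))
  names(indeg) <- ids
  parents <- list()
  for (r in seq_len(nrow(ped))) {
    for (p in c(ped$father[r], ped$mother[r])) {
      if (!is.na(p) && p %in% ids) {
        indeg[[ped$id[r]]] <- indeg[[ped$id[r]]] + 1L
      }
    }
  }
  order_out <- character(0)
  queue <- ids[indeg[ids] == 0L]
  indeg_work <- indeg
  child_of <- split(
    rep(ped$id, 2L),
    f = factor(c(ped$father, ped$mother), levels = ids)
  )
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    order_out <- c(order_out, v)
    for (ch in child_of[[v]]) {
      indeg_work[[ch]] <- indeg_work[[ch]] - 1L
      if (indeg_work[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) != length(ids)) return(NULL)
  order_out
}

#' Validate pedigree invariants
#'
#' Checks the structural invariants of a pedigree: unique identifiers, both
#' or neither parent recorded, parents present in the pedigree, distinct
#' mother and father, and acyclicity of the parent-child relation. Each
#' violation is reported as a human-readable string naming the individuals
#' involved. This function reports and never raises.
#'
#' @param ped A [pedigree()].
#' @return Character vector of violation descriptions; empty iff the
#'   pedigree is valid.
#' @examples
#' bad <- pedigree(c("a", "b"), father = c("b", NA), mother = c("b", NA))
#' validate_pedigree(bad)
#' @export
validate_pedigree <- function(ped) {
  violations <- character(0)
  dup <- unique(ped$id[duplicated(ped$id)])
  if (length(dup) > 0) {
    violations <- c(violations,
                    sprintf("duplicated identifier: %s", dup))
  }
  one_parent <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(one_parent)) {
    violations <- c(violations,
                    sprintf("individual %s has exactly one recorded parent",
                            ped$id[one_parent]))
  }
  for (col in c("father", "mother")) {
    missing_parent <- !is.na(ped[[col]]) & !(ped[[col]] %in% ped$id)
    if (any(missing_parent)) {
      violations <- c(violations,
                      sprintf("individual %s lists unknown %s %s",
                              ped$id[missing_parent], col,
                              ped[[col]][missing_parent]))
    }
  }
  same <- !is.na(ped$father) & !is.na(ped$mother) & ped$father == ped$mother
  if (any(same)) {
    violations <- c(violations,
                    sprintf("individual %s has identical mother and father (%s)",
                            ped$id[same], ped$father[same]))
  }
  if (length(violations) == 0 && is.null(ped_topological_order(ped))) {
    violations <- c(violations,
                    "parent-child relation is cyclic (some individual is its own ancestor)")
  }
  violations
}

# Stop with a validation error when a pedigree is invalid.
assert_valid_pedigree <- function(ped) {
  v <- validate_pedigree(ped)
  if (length(v) > 0) {
    stop("invalid pedigree:\n", paste("  -", v, collapse = "\n"), call. = FALSE)
  }
  invisible(ped)
}
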