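#' Read and write pedigree analysis files
#'
#' Four whitespace/tab-delimited plain-text dialects are supported:
#' \describe{
#'   \item{pedigree}{One row per individual, `id father mother`, with `0`
#'     standing for "no parent" (founders are `id 0 0`). Lines starting
#'     with `#` are comments.}
#'   \item{marker map}{TSV with header `locus k theta_next`; loci are
#'     numbered from 1 and `theta_next` on the last row is `NA`.}
#'   \item{genotypes}{TSV, one row per typed individual:
#'     `id a1_1 a2_1 a1_2 a2_2 ...` (two columns per locus).}
#'   \item{haplotypes}{TSV, two rows per typed individual:
#'     `id hapA allele_1 ... allele_L` then `id hapB ...`.}
#' }
#' Allele `0` marks missing data and is only legal as an entirely missing
#' row, which is equivalent to omitting the row; partially missing rows are
#' a data error.
#'
#' @param path File path.
#' @param map A [marker_map()] used to check locus counts and allele ranges.
#' @return `read_pedigree()` a [pedigree()]; `read_marker_map()` a
#'   [marker_map()]; `read_genotype_table()` a [genotype_table()];
#'   `read_haplotype_table()` a [haplotype_table()].
#' @name pedigree_io
NULL

# Tokenized non-comment lines with original line numbers.
read_tokens <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(tokens = strsplit(trimws(lines[keep]), "\\s+"),
       lineno = which(keep))
}

parse_error <- function(path, lineno, msg) {
  stop(sprintf("%s:%d: %s", path, lineno, msg), call. = FALSE)
}

as_int_fields <- function(fields, path, lineno) {
  vals <- suppressWarnings(as.integer(fields))
  if (any(is.na(vals))) {
    parse_error(path, lineno,
                sprintf("expected integer fields, got '%s'",
                        paste(fields, collapse = " ")))
  }
  vals
}

#' @rdname pedigree_io
#' @export
read_pedigree <- function(path) {
  tk <- read_tokens(path)
  n <- length(tk$tokens)
  id <- father <- mother <- character(n)
  for (i in seq_len(n)) {
    f <- tk$tokens[[i]]
    if (length(f) != 3) {
      parse_error(path, tk$lineno[i],
                  sprintf("pedigree rows have 3 fields (id father mother), got %d",
                          length(f)))
    }
    id[i] <- f[1]
    father[i] <- f[2]
    mother[i] <- f[3]
  }
  ped <- pedigree(id, father, mother)
  assert_valid_pedigree(ped)
  ped
}

#' @rdname pedigree_io
#' @param ped A [pedigree()].
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$father[is.na(out$father)] <- "0"
  out$mother[is.na(out$mother)] <- "0"
  writeLines(c("# id father mother",
               paste(out$id, out$father, out$mother)), path)
  invisible(path)
}

#' @rdname pedigree_io
#' @export
read_marker_map <- function(path) {
  tk <- read_tokens(path)
  if (length(tk$tokens) < 2) parse_error(path, 1L, "marker file needs a header and at least one locus row")
  header <- tk$tokens[[1]]
  if (!identical(tolower(header), c("locus", "k", "theta_next"))) {
    parse_error(path, tk$lineno[1], "marker file header must be 'locus k theta_next'")
  }
  n <- length(tk$tokens) - 1L
  k <- integer(n)
  theta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    f <- tk$tokens[[i + 1L]]
    ln <- tk$lineno[i + 1L]
    if (length(f) != 3) parse_error(path, ln, "marker rows have 3 fields")
    locus <- as_int_fields(f[1], path, ln)
    if (locus != i) parse_error(path, ln, sprintf("expected locus %d, got %s", i, f[1]))
    k[i] <- as_int_fields(f[2], path, ln)
    if (toupper(f[3]) != "NA") {
      th <- suppressWarnings(as.numeric(f[3]))
      if (is.na(th)) parse_error(path, ln, sprintf("bad theta_next '%s'", f[3]))
      theta[i] <- th
    }
  }
  if (!is.na(theta[n])) {
    parse_error(path, tk$lineno[n + 1L], "theta_next on the last locus row must be NA")
  }
  if (n > 1 && any(is.na(theta[-n]))) {
    bad <- which(is.na(theta[-n]))[1]
    parse_error(path, tk$lineno[bad + 1L], "theta_next may only be NA on the last row")
  }
  marker_map(k, theta[-n])
}

#' @rdname pedigree_io
#' @export
write_marker_map <- function(map, path) {
  theta <- c(format(map$theta, digits = 17), "NA")
  writeLines(c("locus\tk\ttheta_next",
               paste(seq_len(map$L), map$n_alleles, theta, sep = "\t")),
             path)
  invisible(path)
}

#' @rdname pedigree_io
#' @export
read_genotype_table <- function(path, map) {
  tk <- read_tokens(path)
  rows <- list()
  ids <- character(0)
  for (i in seq_along(tk$tokens)) {
    f <- tk$tokens[[i]]
    ln <- tk$lineno[i]
    if (length(f) != 1 + 2 * map$L) {
      parse_error(path, ln,
                  sprintf("genotype rows have %d fields (id + 2 per locus), got %d",
                          1 + 2 * map$L, length(f)))
    }
    vals <- as_int_fields(f[-1], path, ln)
    if (all(vals == 0L)) next  # fully-missing row == untyped individual
    if (any(vals == 0L)) {
      parse_error(path, ln,
                  sprintf("individual %s is partially missing; individuals must be typed at all loci or omitted",
                          f[1]))
    }
    ids <- c(ids, f[1])
    rows[[length(rows) + 1L]] <- vals
  }
  arr <- array(0L, dim = c(length(ids), map$L, 2))
  for (i in seq_along(rows)) {
    m <- matrix(rows[[i]], ncol = 2, byrow = TRUE)  # row j = (a1_j, a2_j)
    arr[i, , 1] <- m[, 1]
    arr[i, , 2] <- m[, 2]
  }
  genotype_table(arr, ids = ids, map = map)
}

#' @rdname pedigree_io
#' @param genotypes A [genotype_table()].
#' @export
write_genotype_table <- function(genotypes, path) {
  ids <- typed_ids(genotypes)
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], as.vector(rbind(genotypes[i, , 1], genotypes[i, , 2]))),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pedigree_io
#' @export
read_haplotype_table <- function(path, map) {
  tk <- read_tokens(path)
  if (length(tk$tokens) %% 2 != 0) {
    parse_error(path, tk$lineno[length(tk$lineno)],
                "haplotype files have two rows (hapA, hapB) per individual")
  }
  n <- length(tk$tokens) %/% 2
  ids <- character(0)
  rows <- list()
  for (i in seq_len(n)) {
    fa <- tk$tokens[[2 * i - 1]]
    fb <- tk$tokens[[2 * i]]
    lna <- tk$lineno[2 * i - 1]
    lnb <- tk$lineno[2 * i]
    for (f in list(fa, fb)) {
      if (length(f) != 2 + map$L) {
        parse_error(path, lna,
                    sprintf("haplotype rows have %d fields (id hapA/hapB + one per locus), got %d",
                            2 + map$L, length(f)))
      }
    }
    if (fa[1] != fb[1] || tolower(fa[2]) != "hapa" || tolower(fb[2]) != "hapb") {
      parse_error(path, lna,
                  sprintf("expected paired rows '%s hapA ...' then '%s hapB ...'", fa[1], fa[1]))
    }
    va <- as_int_fields(fa[-(1:2)], path, lna)
    vb <- as_int_fields(fb[-(1:2)], path, lnb)
    if (all(va == 0L) && all(vb == 0L)) next
    if (any(va == 0L) || any(vb == 0L)) {
      parse_error(path, lna,
                  sprintf("individual %s is partially missing; individuals must be typed at all loci or omitted",
                          fa[1]))
    }
    ids <- c(ids, fa[1])
    rows[[length(rows) + 1L]] <- rbind(va, vb)
  }
  arr <- array(0L, dim = c(length(ids), map$L, 2))
  for (i in seq_along(rows)) {
    arr[i, , 1] <- rows[[i]][1, ]
    arr[i, , 2] <- rows[[i]][2, ]
  }
  haplotype_table(arr, ids = ids, map = map)
}

#' @rdname pedigree_io
#' @param haps A [haplotype_table()].
#' @export
write_haplotype_table <- function(haps, path) {
  ids <- typed_ids(haps)
  lines <- character(0)
  for (i in seq_along(ids)) {
    lines <- c(lines,
               paste(c(ids[i], "hapA", haps[i, , 1]), collapse = "\t"),
               paste(c(ids[i], "hapB", haps[i, , 2]), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a complete dataset
#'
#' Reads and cross-validates a pedigree file, a marker map, and either a
#' genotype or a haplotype file. Typed individuals are exactly the rows
#' present in the data file, and must be a subset of the pedigree.
#'
#' @inheritParams pedigree_io
#' @param pedigree_path,marker_path,data_path File paths.
#' @param data_kind `"genotype"` or `"haplotype"`.
#' @return A list with elements `pedigree`, `map` and `data` (a genotype or
#'   haplotype table).
#' @export
read_dataset <- function(pedigree_path, marker_path, data_path,
                         data_kind = c("genotype", "haplotype")) {
  data_kind <- match.arg(data_kind)
  ped <- read_pedigree(pedigree_path)
  map <- read_marker_map(marker_path)
  data <- if (data_kind == "genotype") {
    read_genotype_table(data_path, map)
  } else {
    read_haplotype_table(data_path, map)
  }
  unknown <- setdiff(typed_ids(data), ped$id)
  if (length(unknown) > 0) {
    stop("typed individuals absent from the pedigree: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  list(pedigree = ped, map = map, data = data)
}
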