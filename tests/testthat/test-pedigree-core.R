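test_that("pedigree constructor normalizes parents and orders fields", {
  ped <- trio_ped()
  expect_s3_class(ped, "pedigree")
  expect_identical(ped$id, c("m", "f", "c"))
  expect_true(all(is.na(ped$father[1:2])))
  expect_identical(ped$father[3], "f")
  expect_identical(founders(ped), c("m", "f"))
  expect_identical(nonfounders(ped), "c")
})

test_that("pedigree accepts '0' and NA interchangeably for missing parents", {
  p1 <- pedigree(c("a", "b"), father = c("0", NA), mother = c(NA, "0"))
  expect_true(all(is.na(p1$father)))
  expect_true(all(is.na(p1$mother)))
})

test_that("edge count law |E| = 2(|I| - |F|) holds on random pedigrees", {
  set.seed(11)
  for (trial in 1:20) {
    ped <- random_pedigree(sample(1:12, 1))
    expect_identical(nrow(ped_edges(ped)),
                     2L * (nrow(ped) - length(founders(ped))))
  }
})

test_that("topological order places parents before children", {
  set.seed(12)
  for (trial in 1:10) {
    ped <- random_pedigree(10)
    topo <- ped_topological_order(ped)
    pos <- match(ped$id, topo)
    for (r in seq_len(nrow(ped))) {
      if (!is.na(ped$father[r])) {
        expect_lt(pos[match(ped$father[r], ped$id)], pos[r])
        expect_lt(pos[match(ped$mother[r], ped$id)], pos[r])
      }
    }
  }
})

test_that("validate_pedigree reports defects without raising", {
  probs <- validate_pedigree(pedigree(c("a", "a")))
  expect_true(any(grepl("duplicate", probs, ignore.case = TRUE)))

  one_parent <- pedigree(c("a", "b"), father = c(NA, "a"), mother = c(NA, NA))
  expect_true(length(validate_pedigree(one_parent)) > 0)

  # a two-individual ancestral cycle with otherwise well-formed rows
  cyc <- pedigree(c("a", "b", "c"),
                  father = c("b", "a", NA), mother = c("c", "c", NA))
  expect_true(any(grepl("cycl", validate_pedigree(cyc), ignore.case = TRUE)))
  expect_error(pedhap:::assert_valid_pedigree(cyc))
})

test_that("self-parenthood (father == mother) is reported", {
  selfp <- pedigree(c("a", "b"), father = c(NA, "a"), mother = c(NA, "a"))
  expect_true(length(validate_pedigree(selfp)) > 0)
})

test_that("meioses enumerates two meioses per non-founder, maternal first", {
  ped <- half_sib_ped()
  mm <- meioses(ped)
  expect_identical(nrow(mm), 4L)
  expect_identical(mm$child, c("c1", "c1", "c2", "c2"))
  expect_identical(mm$side, c("m", "p", "m", "p"))
  expect_identical(mm$parent[1], "m")
  expect_identical(mm$parent[2], "f1")
})

test_that("marker_map validates alleles and recombination fractions", {
  map <- marker_map(c(2L, 3L, 2L), theta = c(0.1, 0.5))
  expect_identical(map$L, 3L)
  expect_error(marker_map(c(1L, 2L), theta = 0.1), "allele")
  expect_error(marker_map(c(2L, 2L), theta = 0.6))
  expect_error(marker_map(c(2L, 2L), theta = c(0.1, 0.2)))
})

test_that("genotype_table sorts pairs and rejects out-of-range alleles", {
  map <- marker_map(c(2L, 2L), theta = 0.1)
  g <- array(c(2L, 1L, 1L, 2L), dim = c(1, 2, 2))
  gt <- single_genotype_table("x", g, map)
  expect_true(all(gt[, , 1] <= gt[, , 2]))
  g_bad <- array(3L, dim = c(1, 2, 2))
  expect_error(single_genotype_table("x", g_bad, map))
})

test_that("genotypes_from_haplotypes drops phase", {
  map <- marker_map(c(2L, 2L), theta = 0.1)
  h <- array(c(2L, 2L, 1L, 1L), dim = c(1, 2, 2), dimnames = list("x", NULL, NULL))
  ht <- haplotype_table(h, ids = "x", map = map)
  gt <- genotypes_from_haplotypes(ht)
  expect_identical(as.integer(gt["x", 1, ]), c(1L, 2L))
  expect_identical(count_heterozygous(gt, "x"), 2L)
})

test_that("pedigree and marker files round-trip through the text dialects", {
  dir <- withr::local_tempdir()
  ped <- figure1_ped()
  pf <- file.path(dir, "ped.txt")
  write_pedigree(ped, pf)
  expect_identical(read_pedigree(pf)$id, ped$id)
  expect_identical(read_pedigree(pf)$father, ped$father)

  map <- marker_map(c(2L, 3L), theta = 0.25)
  mf <- file.path(dir, "map.tsv")
  write_marker_map(map, mf)
  map2 <- read_marker_map(mf)
  expect_identical(map2$n_alleles, map$n_alleles)
  expect_equal(map2$theta, map$theta)
})

test_that("genotype and haplotype files round-trip, with 0 rows as untyped", {
  dir <- withr::local_tempdir()
  map <- marker_map(c(2L, 2L), theta = 0.3)
  sim <- random_truth(half_sib_ped(), map, seed = 5)

  gf <- file.path(dir, "geno.tsv")
  write_genotype_table(sim$genotypes, gf)
  gt <- read_genotype_table(gf, map)
  expect_identical(sort(typed_ids(gt)), sort(typed_ids(sim$genotypes)))
  for (i in typed_ids(gt)) expect_identical(gt[i, , ], sim$genotypes[i, , ])

  hf <- file.path(dir, "hap.tsv")
  write_haplotype_table(sim$haplotypes, hf)
  ht <- read_haplotype_table(hf, map)
  for (i in typed_ids(ht)) expect_identical(ht[i, , ], sim$haplotypes[i, , ])
})

test_that("parse errors carry line numbers and file context", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.txt")
  writeLines(c("# comment", "a 0 0", "b a"), f)
  expect_error(read_pedigree(f), "bad\\.txt:3")
})

test_that("partially-zero genotype rows are rejected, fully-zero rows untyped", {
  dir <- withr::local_tempdir()
  map <- marker_map(c(2L, 2L), theta = 0.1)
  f <- file.path(dir, "geno.tsv")
  writeLines(c("a\t1\t2\t1\t1", "b\t0\t0\t0\t0"), f)
  gt <- read_genotype_table(f, map)
  expect_identical(typed_ids(gt), "a")
  writeLines(c("a\t1\t0\t1\t1"), f)
  expect_error(read_genotype_table(f, map))
})
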