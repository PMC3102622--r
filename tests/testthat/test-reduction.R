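test_that("proxy haplotypes follow the alternating construction", {
  g <- cbind(c(1L, 1L, 1L, 1L), c(2L, 1L, 2L, 2L))  # het at loci 1, 3, 4
  px <- proxy_haplotypes(g)
  expect_true(all(px$i0 == 1L))
  expect_identical(px$i1[2, ], g[, 1])
  expect_identical(px$i2[2, ], g[, 2])
  # i3: smaller at 1st and 3rd het locus, larger at 2nd
  expect_identical(px$i3[2, ], c(1L, 1L, 2L, 1L))
  expect_identical(px$i4[2, ], c(2L, 1L, 1L, 2L))
  # every child's first haplotype comes from the all-ones spouse
  for (k in paste0("i", 1:4)) expect_true(all(px[[k]][1, ] == 1L))
  # between them, i1/i2 and i3/i4 carry the genotype at every locus
  expect_identical(t(apply(rbind(px$i3[2, ], px$i4[2, ]), 2, sort)), unname(g))
  expect_error(proxy_haplotypes(cbind(2L, 1L)), "sorted")
})

test_that("mapped pedigree obeys the size law 5|G|+|I|, 8|G|+|E|", {
  set.seed(21)
  for (n in 1:12) {
    ped <- random_pedigree(n)
    L <- 3L
    map <- random_map(L)
    ids <- sample(ped$id, sample(seq_len(n), 1))
    g <- array(sample(1:2, length(ids) * L * 2, TRUE), c(length(ids), L, 2),
               dimnames = list(ids, NULL, NULL))
    gt <- genotype_table(g, ids = ids, map = map)
    red <- build_proxy_pedigree(ped, gt)
    expect_identical(nrow(red$pedigree), 5L * length(ids) + n)
    expect_identical(nrow(ped_edges(red$pedigree)),
                     8L * length(ids) + nrow(ped_edges(ped)))
    expect_identical(sort(typed_ids(red$haplotypes)),
                     sort(as.character(outer(ids, 0:4, paste, sep = "#"))))
    expect_equal(length(validate_pedigree(red$pedigree)), 0)
  }
})

test_that("proxy identifier collisions are an error", {
  ped <- pedigree(c("a", "a#0"), father = c(NA, NA), mother = c(NA, NA))
  map <- marker_map(2L, theta = numeric(0))
  gt <- single_genotype_table("a", array(1L, c(1, 1, 2)), map)
  expect_error(build_proxy_pedigree(ped, gt), "collide")
})

test_that("min_recomb_offset clamps T = 0 and sums 2(T - 1)", {
  map <- marker_map(rep(2L, 4), theta = rep(0.1, 3))
  g <- array(0L, c(2, 4, 2), dimnames = list(c("a", "b"), NULL, NULL))
  g["a", , 1] <- c(1L, 1L, 1L, 1L); g["a", , 2] <- c(2L, 2L, 2L, 1L)  # T = 3
  g["b", , 1] <- c(1L, 1L, 1L, 1L); g["b", , 2] <- c(1L, 1L, 1L, 1L)  # T = 0
  gt <- genotype_table(g, ids = c("a", "b"), map = map)
  expect_identical(min_recomb_offset(gt), 4L)
  empty <- genotype_table(array(0L, c(0, 4, 2)), ids = character(0), map = map)
  expect_identical(min_recomb_offset(empty), 0L)
})

test_that("transmission matrices have the stated structure", {
  m0 <- transmission_matrices(0)
  expect_equal(m0$P, diag(16))
  m5 <- transmission_matrices(0.5)
  expect_true(all(m5$P == 1 / 16))
  th <- 0.3
  m <- transmission_matrices(th)
  expect_true(all(abs(rowSums(m$P) - 1) < 1e-12))
  # entry between complementary 4-bit states is theta^4
  expect_equal(m$P[6 + 1, 9 + 1], th^4)
  # Q matrices are single columns of P
  expect_equal(m$Q0101[, 5 + 1], m$P[, 5 + 1])
  expect_true(all(m$Q0101[, -(5 + 1)] == 0))
  expect_equal(m$Q0110[, 6 + 1], m$P[, 6 + 1])
  expect_error(transmission_matrices(0.6))
})

test_that("transmission probability matches its closed form and pins", {
  ped <- pedigree("1")
  # fully heterozygous parent: p_t = 1/16 * prod theta^2 (1-theta)^2
  for (L in 2:4) {
    theta <- seq(0.1, 0.4, length.out = L - 1)
    map <- marker_map(rep(2L, L), theta = theta)
    gt <- single_genotype_table("1", all_het_genotype(L), map)
    fam <- build_proxy_pedigree(ped, gt)$families[[1]]
    expect_equal(transmission_probability(fam, map),
                 (1 / 16) * prod(theta^2 * (1 - theta)^2))
  }
  # pinned values
  map2 <- marker_map(c(2L, 2L), theta = 0.5)
  gt2 <- single_genotype_table("1", all_het_genotype(2L), map2)
  fam2 <- build_proxy_pedigree(ped, gt2)$families[[1]]
  expect_equal(transmission_probability(fam2, map2), 1 / 256)
  map0 <- marker_map(c(2L, 2L), theta = 0)
  expect_equal(transmission_probability(fam2, map0), 0)
  # fully homozygous parent: p_t = 1
  ghom <- array(1L, c(1, 3, 2))
  map3 <- marker_map(rep(2L, 3), theta = c(0.2, 0.3))
  fam3 <- build_proxy_pedigree(ped, single_genotype_table("1", ghom, map3))$families[[1]]
  expect_equal(transmission_probability(fam3, map3), 1)
  # label swap invariance
  expect_equal(transmission_probability(fam2, map2, first_state = 5L),
               transmission_probability(fam2, map2, first_state = 10L))
  expect_error(transmission_probability(fam2, map2, first_state = 6L))
})

test_that("p_t is monotone non-increasing in T at fixed theta and L", {
  ped <- pedigree("1")
  L <- 5L
  map <- marker_map(rep(2L, L), theta = rep(0.2, L - 1))
  values <- vapply(0:L, function(T) {
    g <- array(1L, c(1, L, 2))
    if (T > 0) g[1, seq_len(T), 2] <- 2L
    fam <- build_proxy_pedigree(ped, single_genotype_table("1", g, map))$families[[1]]
    transmission_probability(fam, map)
  }, numeric(1))
  expect_true(all(diff(values) <= 1e-15))
})

test_that("proof recursion: each heterozygous step costs exactly 2, for every phasing", {
  for (T in 1:4) {
    L <- T + 1L
    map <- marker_map(rep(2L, L), theta = rep(0.3, L - 1))
    g <- array(1L, c(1, L, 2))
    g[1, seq_len(T), 2] <- 2L
    het <- seq_len(T)
    px <- proxy_haplotypes(matrix(g[1, , ], ncol = 2))
    kids <- lapply(px[paste0("i", 1:4)], function(h) h[2, ])
    # every one of the 2^(T-1) distinct phasings of the parent
    phasings <- as.matrix(expand.grid(rep(list(0:1), max(T - 1, 0))))
    for (r in seq_len(nrow(phasings))) {
      hap1 <- g[1, , 1]
      hap2 <- g[1, , 2]
      flip <- c(0L, phasings[r, ])
      phase <- cumsum(flip) %% 2L  # phase switch indicator per het locus
      for (k in seq_along(het)) {
        if (phase[k] == 1L) {
          tmp <- hap1[het[k]]; hap1[het[k]] <- hap2[het[k]]; hap2[het[k]] <- tmp
        }
      }
      parent <- rbind(hap1, hap2)
      total <- sum(vapply(kids, function(child)
        pedhap:::meiosis_min_switches(parent, child), numeric(1)))
      expect_identical(as.integer(total), 2L * (T - 1L))
    }
  }
})

test_that("Lemma 1: mapped min-recombination equals genotype count plus offset", {
  set.seed(31)
  done <- 0
  while (done < 12) {
    n <- sample(2:4, 1)
    ped <- random_pedigree(n)
    L <- sample(2:4, 1)
    map <- random_map(L)
    sim <- random_truth(ped, map, seed = done + 100)
    gid <- sample(ped$id, 1)
    masked <- mask_data(sim, setdiff(ped$id, gid))
    rg <- min_recombination(ped, map, masked$genotypes, "genotype")$count
    red <- build_proxy_pedigree(ped, masked$genotypes)
    rh <- min_recombination(red$pedigree, map, red$haplotypes, "haplotype")$count
    expect_identical(rh, rg + min_recomb_offset(masked$genotypes))
    done <- done + 1
  }
})

test_that("Lemma 2 conditional identity holds for every consistent phasing", {
  # parent also haplotyped in both instances; ratio equals proxy_constant
  # regardless of phasing, including homozygous runs
  ped <- pedigree("1")
  map <- marker_map(rep(2L, 4), theta = c(0.1, 0.25, 0.4))
  g <- array(0L, c(1, 4, 2))
  g[1, , 1] <- c(1L, 1L, 1L, 1L)
  g[1, , 2] <- c(2L, 1L, 1L, 2L)  # het at 1 and 4, homozygous run between
  gt <- single_genotype_table("1", g, map)
  red <- build_proxy_pedigree(ped, gt)
  const <- proxy_constant(red$families[[1]], map)
  for (phase in 0:1) {
    h <- array(0L, c(1, 4, 2), dimnames = list("1", NULL, NULL))
    if (phase == 0) {
      h[1, , 1] <- c(1L, 1L, 1L, 1L); h[1, , 2] <- c(2L, 1L, 1L, 2L)
    } else {
      h[1, , 1] <- c(1L, 1L, 1L, 2L); h[1, , 2] <- c(2L, 1L, 1L, 1L)
    }
    ht <- haplotype_table(h, ids = "1", map = map)
    lg <- as.numeric(likelihood(ped, map, ht, "haplotype"))
    arr <- unclass(red$haplotypes)
    big <- array(0L, dim = c(6, 4, 2),
                 dimnames = list(c("1", typed_ids(red$haplotypes)), NULL, NULL))
    big[1, , ] <- h[1, , ]
    big[2:6, , ] <- arr
    bht <- haplotype_table(big, ids = rownames(big), map = map)
    lh <- as.numeric(likelihood(red$pedigree, map, bht, "haplotype"))
    expect_equal(lh / lg, const, tolerance = 1e-12)
  }
})

test_that("Corollary 3: likelihood proportional on all-heterozygous instances", {
  set.seed(41)
  peds <- list(pedigree("1"), trio_ped())
  for (trial in 1:8) {
    ped <- peds[[1 + trial %% 2]]
    gid <- if (nrow(ped) == 1) "1" else "c"
    L <- sample(2:3, 1)
    map <- random_map(L)
    g <- all_het_genotype(L)
    gt <- single_genotype_table(gid, g, map)
    vp <- verify_proportionality(ped, gt, map)
    expect_false(vp$degenerate)
    expect_lt(vp$ratio_error, 1e-9)
  }
})

test_that("Corollary 3 argmax agreement on all-heterozygous instances", {
  map <- marker_map(c(2L, 2L), theta = 0.2)
  gt <- single_genotype_table("c", all_het_genotype(2L), map)
  vp <- verify_proportionality(trio_ped(), gt, map, check_argmax = TRUE)
  expect_lt(vp$ratio_error, 1e-9)
  expect_true(vp$argmax_agrees)
})

test_that("degenerate case theta = 0 with T >= 2 reports both sides zero", {
  ped <- pedigree("1")
  map <- marker_map(c(2L, 2L), theta = 0)
  gt <- single_genotype_table("1", all_het_genotype(2L), map)
  vp <- verify_proportionality(ped, gt, map)
  expect_true(vp$degenerate)
  expect_identical(vp$ratio_error, 0)
})

test_that("homozygous loci leak extra mass into the mapped instance", {
  # the documented limitation of the unconditional Corollary-3 identity:
  # a single homozygous locus on a lone founder gives L_hap = 9/128
  # against a proportional value of 8/128
  ped <- pedigree("1")
  map <- marker_map(2L, theta = numeric(0))
  g <- array(1L, c(1, 1, 2))
  gt <- single_genotype_table("1", g, map)
  vp <- verify_proportionality(ped, gt, map)
  expect_equal(vp$haplotype_likelihood, 9 / 128)
  expect_equal(vp$genotype_likelihood * vp$product_constant, 8 / 128)
  expect_gt(vp$haplotype_likelihood,
            vp$genotype_likelihood * vp$product_constant)
})
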