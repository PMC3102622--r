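test_that("forward-backward equals brute-force enumeration on tiny instances", {
  set.seed(51)
  done <- 0
  while (done < 10) {
    ped <- trio_ped()
    L <- sample(2:3, 1)
    map <- random_map(L)
    sim <- random_truth(ped, map, seed = 500 + done)
    untyped <- sample(ped$id, sample(0:2, 1))
    masked <- mask_data(sim, untyped)
    for (kind in c("genotype", "haplotype")) {
      data <- if (kind == "genotype") masked$genotypes else masked$haplotypes
      fb <- forward_backward(ped, map, data, kind)
      bf <- brute_force_likelihood(ped, map, data, kind)
      expect_equal(fb$likelihood, bf, tolerance = 1e-12)
    }
    done <- done + 1
  }
})

test_that("forward-backward agrees with the oracle on a two-child pedigree", {
  set.seed(52)
  ped <- half_sib_ped()
  map <- random_map(2L)
  sim <- random_truth(ped, map, seed = 99)
  masked <- mask_data(sim, c("f2", "m"))
  for (kind in c("genotype", "haplotype")) {
    data <- if (kind == "genotype") masked$genotypes else masked$haplotypes
    fb <- forward_backward(ped, map, data, kind)
    bf <- brute_force_likelihood(ped, map, data, kind)
    expect_equal(fb$likelihood, bf, tolerance = 1e-12)
  }
})

test_that("likelihood of a dataless pedigree is 1 and posteriors are uniform", {
  ped <- trio_ped()
  map <- marker_map(rep(2L, 3), theta = c(0.1, 0.3))
  empty <- genotype_table(array(0L, c(0, 3, 2)), ids = character(0), map = map)
  fb <- forward_backward(ped, map, empty, "genotype")
  expect_equal(fb$likelihood, 1)
  expect_true(all(abs(fb$posterior - 1 / nrow(fb$posterior)) < 1e-12))
})

test_that("posterior columns are normalized and consistent with marginals", {
  set.seed(53)
  map <- random_map(3L)
  sim <- random_truth(half_sib_ped(), map, seed = 7)
  fb <- forward_backward(half_sib_ped(), map, sim$genotypes, "genotype")
  expect_true(all(abs(colSums(fb$posterior) - 1) < 1e-10))
  # pairwise posterior marginalizes to the single-locus posteriors
  pp <- pairwise_posterior(fb, interval = 1)
  expect_equal(rowSums(pp), fb$posterior[, 1], tolerance = 1e-10)
  expect_equal(colSums(pp), fb$posterior[, 2], tolerance = 1e-10)
})

test_that("recombination distribution is a pmf that matches the pairwise posterior", {
  set.seed(54)
  map <- random_map(2L)
  ped <- half_sib_ped()
  sim <- random_truth(ped, map, seed = 8)
  fb <- forward_backward(ped, map, sim$genotypes, "genotype")
  dist <- recombination_distribution(fb, 1)
  expect_equal(sum(dist$pmf), 1, tolerance = 1e-12)
  expect_identical(names(dist$pmf), as.character(0:4))
  # reference from the explicit joint posterior
  pp <- pairwise_posterior(fb, 1)
  S <- nrow(pp)
  nbits <- 4L
  ref <- numeric(nbits + 1)
  for (a in 0:(S - 1)) {
    for (b in 0:(S - 1)) {
      d <- pedhap:::state_hamming(a, b)
      ref[d + 1] <- ref[d + 1] + pp[a %% S + 1, b %% S + 1]
    }
  }
  expect_equal(unname(dist$pmf), ref, tolerance = 1e-10)
})

test_that("with no data the recombination count is Binomial(n_bits, theta)", {
  ped <- half_sib_ped()
  for (th in c(0.1, 0.5)) {
    map <- marker_map(c(2L, 2L), theta = th)
    empty <- genotype_table(array(0L, c(0, 2, 2)), ids = character(0), map = map)
    fb <- forward_backward(ped, map, empty, "genotype")
    dist <- recombination_distribution(fb, 1)
    expect_equal(unname(dist$pmf), dbinom(0:4, 4, th), tolerance = 1e-12)
  }
})

test_that("zero-likelihood data yields a diagnostic naming a locus", {
  ped <- trio_ped()
  map <- marker_map(2L, theta = numeric(0))
  g <- array(0L, c(2, 1, 2), dimnames = list(c("m", "c"), NULL, NULL))
  g["m", 1, ] <- c(1L, 1L)
  g["c", 1, ] <- c(2L, 2L)  # impossible: child shares no allele with mother
  gt <- genotype_table(g, ids = c("m", "c"), map = map)
  fb <- forward_backward(ped, map, gt, "genotype")
  expect_equal(fb$likelihood, 0)
  expect_match(fb$diagnostic, "locus 1")
})

test_that("transition matrix and accessors are consistent", {
  ped <- trio_ped()
  map <- marker_map(c(2L, 2L), theta = 0.2)
  empty <- genotype_table(array(0L, c(0, 2, 2)), ids = character(0), map = map)
  fb <- forward_backward(ped, map, empty, "genotype")
  space <- fb$space
  tm <- pedhap:::transition_matrix(space, 0.2)
  expect_true(all(abs(rowSums(tm) - 1) < 1e-12))
  expect_equal(tm[1, 1], 0.8^2)
  expect_equal(transition_probability(space, 0L, 3L, 0.2), 0.2^2)
  expect_equal(transition_probability(space, 0L, 1L, 0.2), 0.2 * 0.8)
  expect_equal(emission_probability(space, 0L, 1L), 1)
})

test_that("genotype likelihood is invariant to haplotype phase of the input", {
  # two haplotype tables with the same genotypes give identical genotype
  # likelihoods after phase is dropped
  set.seed(55)
  map <- random_map(3L)
  sim <- random_truth(trio_ped(), map, seed = 13)
  gt <- genotypes_from_haplotypes(sim$haplotypes)
  fb1 <- forward_backward(trio_ped(), map, gt, "genotype")
  # swap the two haplotypes of every individual: same genotypes
  arr <- unclass(sim$haplotypes)[, , c(2, 1), drop = FALSE]
  ht2 <- haplotype_table(arr, ids = typed_ids(sim$haplotypes), map = map)
  gt2 <- genotypes_from_haplotypes(ht2)
  fb2 <- forward_backward(trio_ped(), map, gt2, "genotype")
  expect_equal(fb1$likelihood, fb2$likelihood, tolerance = 1e-14)
})

test_that("haplotype data is never more likely than its genotype projection", {
  set.seed(56)
  for (trial in 1:5) {
    map <- random_map(2L)
    sim <- random_truth(trio_ped(), map, seed = 60 + trial)
    lh <- as.numeric(likelihood(trio_ped(), map, sim$haplotypes, "haplotype"))
    lg <- as.numeric(likelihood(trio_ped(), map,
                                genotypes_from_haplotypes(sim$haplotypes),
                                "genotype"))
    expect_lte(lh, lg + 1e-15)
    expect_gt(lh, 0)
  }
})

test_that("state-space cap raises a capacity error instead of allocating", {
  ped <- random_pedigree(40, p_child = 1)
  map <- marker_map(2L, theta = numeric(0))
  empty <- genotype_table(array(0L, c(0, 1, 2)), ids = character(0), map = map)
  expect_error(forward_backward(ped, map, empty, "genotype", max_states = 2^10),
               "cap")
})
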