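test_that("observed heterozygosity counts heterozygotes per locus", {
  hom <- make_dataset(list(P = list(geno_mat(c("146/146", "148/148")))))
  expect_equal(observed_heterozygosity(hom, "P")$mean, 0)
  het <- make_dataset(list(P = list(geno_mat(c("146/148", "146/150")))))
  expect_equal(observed_heterozygosity(het, "P")$mean, 1)
  mix <- make_dataset(list(P = list(geno_mat(c("146/148", "146/150", "146/148",
                                               "146/146", "148/148")))))
  expect_equal(observed_heterozygosity(mix, "P")$mean, 0.6)
})

test_that("unbiased expected heterozygosity matches the small-sample formula", {
  mono <- make_dataset(list(P = list(geno_mat(c("146/146", "146/146")))))
  expect_equal(expected_heterozygosity(mono, "P")$mean, 0)
  # n = 5 individuals, allele counts 6 and 4 of 10 genes:
  # (10/9) * (1 - 0.6^2 - 0.4^2) = 0.53333
  ds <- make_dataset(list(P = list(geno_mat(c("146/146", "146/146", "146/148",
                                              "148/148", "148/146")))))
  expect_equal(expected_heterozygosity(ds, "P")$mean, (10 / 9) * (1 - 0.36 - 0.16),
               tolerance = 1e-12)
  # two alleles at 0.5: estimate converges to 0.5 from above as n grows
  big <- make_dataset(list(P = list(geno_mat(rep(c("146/148"), 500)))))
  expect_equal(expected_heterozygosity(big, "P")$mean, 0.5, tolerance = 2e-3)
  # fewer than 2 typed individuals -> flagged NA
  tiny <- make_dataset(list(P = list(geno_mat("146/148"))))
  expect_true(is.na(expected_heterozygosity(tiny, "P")$per_locus[[1]]))
})

test_that("rarefied allelic richness equals exhaustive subset enumeration", {
  # g = N returns the observed allele count; monomorphic locus gives 1
  ds <- make_dataset(list(P = list(geno_mat(c("146/148", "150/146", "146/146")))))
  expect_equal(allelic_richness(ds, "P", g = 3)$mean, 3)
  mono <- make_dataset(list(P = list(geno_mat(c("146/146", "146/146", "146/146",
                                                "146/146", "146/146")))))
  expect_equal(allelic_richness(mono, "P", g = 5)$mean, 1)
  # N = 6 individuals, allele copy counts {7, 4, 1}: brute force over all
  # C(12, 2g) gene subsets
  g6 <- geno_mat(c("146/146", "146/146", "146/148", "146/148", "148/148",
                   "146/150"))
  ds6 <- make_dataset(list(P = list(g6)))
  for (g in c(2, 3, 5)) {
    expect_equal(allelic_richness(ds6, "P", g = g)$mean,
                 rarefaction_enum(c(7, 4, 1), g), tolerance = 1e-10)
  }
  # monotone non-decreasing in g, up to the observed count at g = N
  ar <- vapply(1:6, function(g) allelic_richness(ds6, "P", g = g)$mean, 0)
  expect_true(all(diff(ar) >= -1e-12))
  expect_equal(ar[6], 3)
})

test_that("HWE Markov-chain test matches complete enumeration on small tables", {
  # perfect-HWE configuration: the modal table has probability-ordering p = 1
  g <- c(rep("146/146", 25), rep("146/148", 50), rep("148/148", 25))
  ds <- make_dataset(list(P = list(geno_mat(g))))
  res <- hwe_exact_test(ds, "P", 1, dememorization = 2000, batches = 20,
                        iterations_per_batch = 2000, seed = 1)
  expect_gt(res$p, 0.97)
  # small two-allele tables against full enumeration
  cases <- list(c(2, 1, 2), c(1, 4, 1), c(3, 0, 2), c(2, 2, 2))
  for (cs in cases) {
    g <- c(rep("146/146", cs[1]), rep("146/148", cs[2]), rep("148/148", cs[3]))
    ds <- make_dataset(list(P = list(geno_mat(g))))
    res <- hwe_exact_test(ds, "P", 1, dememorization = 2000, batches = 20,
                          iterations_per_batch = 3000, seed = 42)
    expect_equal(res$p, hwe_enum_p(cs[1], cs[2], cs[3]),
                 tolerance = max(0.03, 4 * res$se))
  }
  # an all-heterozygote sample of n = 20 is a gross HWE violation
  g <- rep("146/148", 20)
  res <- hwe_exact_test(make_dataset(list(P = list(geno_mat(g)))), "P", 1,
                        dememorization = 2000, batches = 20,
                        iterations_per_batch = 2000, seed = 3)
  expect_lt(res$p, 0.01)
  # monomorphic locus is undefined
  mono <- make_dataset(list(P = list(geno_mat(rep("146/146", 5)))))
  expect_true(is.na(hwe_exact_test(mono, "P", 1, 100, 5, 100)$p))
})

test_that("LD permutation test flags duplicated loci and rejects n_perm = 0", {
  set.seed(5)
  g1 <- geno_mat(sprintf("%d/%d", sample(c(146, 148, 150), 30, TRUE),
                         sample(c(146, 148, 150), 30, TRUE)))
  ds <- make_dataset(list(P = list(g1, g1)))   # locus 2 duplicates locus 1
  res <- ld_permutation_test(ds, "P", c(1, 2), n_perm = 199, seed = 1)
  expect_lte(res$p, 1 / 200 + 1e-12)
  expect_error(ld_permutation_test(ds, "P", c(1, 2), n_perm = 0), "n_perm")
  # monomorphic locus -> NA
  mono <- geno_mat(rep("146/146", 30))
  ds2 <- make_dataset(list(P = list(g1, mono)))
  expect_true(is.na(ld_permutation_test(ds2, "P", c(1, 2), n_perm = 99)$p))
})

test_that("LD permutation test holds its nominal type-I error under the null", {
  set.seed(11)
  rej <- 0; nrep <- 200
  for (i in seq_len(nrep)) {
    g1 <- geno_mat(sprintf("%d/%d", sample(c(146, 148), 25, TRUE),
                           sample(c(146, 148), 25, TRUE)))
    g2 <- geno_mat(sprintf("%d/%d", sample(c(200, 202), 25, TRUE),
                           sample(c(200, 202), 25, TRUE)))
    p <- ld_permutation_test(make_dataset(list(P = list(g1, g2))), "P",
                             c(1, 2), n_perm = 99)$p
    if (!is.na(p) && p <= 0.05) rej <- rej + 1
  }
  # binomial 99.9% envelope around 0.05 at 200 replicates (permutation p is
  # discrete and slightly conservative)
  expect_lt(rej / nrep, 0.05 + 3.3 * sqrt(0.05 * 0.95 / nrep))
})

test_that("sequential Bonferroni follows Holm's step-down rule", {
  expect_equal(sequential_bonferroni(numeric(0)), logical(0))
  expect_equal(sequential_bonferroni(0.04, alpha = 0.05), TRUE)
  expect_equal(sequential_bonferroni(c(0.001, 0.04), alpha = 0.05), c(TRUE, TRUE))
  expect_equal(sequential_bonferroni(c(0.03, 0.04), alpha = 0.05), c(FALSE, FALSE))
  expect_equal(sequential_bonferroni(rep(1, 5)), rep(FALSE, 5))
  expect_error(sequential_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("partial correlation recovers known partial structure", {
  set.seed(21)
  n <- 10000
  z <- rnorm(n)
  # x and y correlated only through z: partial correlation given z is rho
  rho <- 0.4
  x <- 0.8 * z + rnorm(n)
  y <- 0.8 * z + rho * (x - 0.8 * z) + sqrt(1 - rho^2) * rnorm(n)
  pc <- partial_correlation(y, x, z)
  expect_equal(pc$r, rho, tolerance = 0.02)
  expect_lt(pc$p, 1e-6)
  # control uncorrelated with both: partial r ~ simple r
  w <- rnorm(n)
  expect_equal(partial_correlation(y, x, w)$r, cor(y, x), tolerance = 0.02)
  # degenerate: y identical to the control
  expect_error(partial_correlation(z, x, z), "residual variance")
  expect_error(partial_correlation(rep(1, 10), rnorm(10)), "constant")
})
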