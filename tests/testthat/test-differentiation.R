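# independent Weir-Cockerham arithmetic for one biallelic locus, two pops
wc_theta_oracle <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2; N <- n1 + n2; nbar <- N / r
  nc <- (N - (n1^2 + n2^2) / N) / (r - 1)
  comp <- function(pA1, pA2, hA1, hA2) {
    pbar <- (n1 * pA1 + n2 * pA2) / N
    s2 <- (n1 * (pA1 - pbar)^2 + n2 * (pA2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * hA1 + n2 * hA2) / N
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 -
                                  hbar * (2 * nbar - 1) / (4 * nbar))
    c(a, a + b + hbar / 2)
  }
  tot <- comp(p1, p2, h1, h2) + comp(1 - p1, 1 - p2, h1, h2)
  tot[1] / tot[2]
}

test_that("Weir-Cockerham theta behaves at the boundary cases", {
  set.seed(41)
  gs <- sprintf("%d/%d", sample(c(146, 148, 150), 50, TRUE),
                sample(c(146, 148, 150), 50, TRUE))
  same <- make_dataset(list(A = list(geno_mat(gs)), B = list(geno_mat(gs))))
  expect_lt(abs(wc_fst(same, pairwise = FALSE)$theta), 0.02)
  fixed <- make_dataset(list(A = list(geno_mat(rep("146/146", 10))),
                             B = list(geno_mat(rep("148/148", 10)))))
  expect_equal(wc_fst(fixed, pairwise = FALSE)$theta, 1)
})

test_that("Weir-Cockerham theta matches hand-computed variance components", {
  # pop1: 8 AA + 2 AB (A: 18, B: 2); pop2: 1 AA + 4 AB + 5 BB (A: 6, B: 14)
  p1g <- c(rep("146/146", 8), rep("146/148", 2))
  p2g <- c("146/146", rep("146/148", 4), rep("148/148", 5))
  ds <- make_dataset(list(P1 = list(geno_mat(p1g)), P2 = list(geno_mat(p2g))))
  got <- wc_fst(ds)$theta
  want <- wc_theta_oracle(10, 10, 0.9, 0.3, 0.2, 0.4)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(wc_fst(ds)$pairwise["P1", "P2"], want, tolerance = 1e-12)
})

test_that("R_ST reproduces a direct one-way ANOVA on repeat counts", {
  fixed <- make_dataset(list(A = list(geno_mat(rep("20/20", 8))),
                             B = list(geno_mat(rep("40/40", 8)))),
                        motif_length = 2L)
  expect_equal(rst(fixed, pairwise = FALSE)$rst, 1)
  set.seed(42)
  gs <- sprintf("%d/%d", 2 * sample(10:20, 40, TRUE), 2 * sample(10:20, 40, TRUE))
  same <- make_dataset(list(A = list(geno_mat(gs)), B = list(geno_mat(gs))))
  expect_lt(abs(rst(same, pairwise = FALSE)$rst), 0.02)
  # 3-population toy vs variance components from the classic ANOVA identity
  g1 <- geno_mat(c("20/22", "20/20", "22/24"))
  g2 <- geno_mat(c("24/24", "26/24", "24/22"))
  g3 <- geno_mat(c("30/30", "28/30", "30/32"))
  ds <- make_dataset(list(A = list(g1), B = list(g2), C = list(g3)))
  y <- c(t(g1)) / 2; grp <- rep(1:3, each = 6)
  y <- c(c(t(g1)), c(t(g2)), c(t(g3))) / 2
  fit <- stats::aov(y ~ factor(grp))
  ms <- summary(fit)[[1]]$`Mean Sq`
  n0 <- (18 - (3 * 36) / 18) / 2          # equal sizes: 6 genes per group
  s2a <- (ms[1] - ms[2]) / n0
  expect_equal(rst(ds, pairwise = FALSE)$rst, s2a / (s2a + ms[2]),
               tolerance = 1e-10)
  # monomorphic in size -> NA
  mono <- make_dataset(list(A = list(geno_mat(rep("20/20", 4))),
                            B = list(geno_mat(rep("20/20", 4)))))
  expect_true(is.na(rst(mono, pairwise = FALSE)$rst))
})

test_that("allele-size permutation preserves R_ST when sizes are exchangeable", {
  # equal-spaced sizes with equal frequencies: permuting two equally frequent
  # size labels leaves the distribution unchanged
  g <- geno_mat(c("20/20", "22/22", "20/22", "20/20", "22/22", "20/22"))
  ds <- make_dataset(list(A = list(g), B = list(g[c(2, 1, 3, 5, 4, 6), ])))
  res <- suppressWarnings(allele_size_permutation_test(ds, n_perm = 50, seed = 1))
  # two states with identical frequency: every bijection yields the same R_ST
  expect_equal(res$mean_rst_perm, res$rst_obs, tolerance = 1e-12)
  expect_equal(res$p, 1)
})

test_that("allele-size permutation test is calibrated under frequency-only divergence", {
  # drift-only null: allele states get arbitrary sizes, no stepwise memory
  set.seed(43)
  nrep <- 120
  pvals <- numeric(nrep)
  sizes <- 2 * c(10, 14, 11, 17, 12, 15)
  for (i in seq_len(nrep)) {
    mk <- function() {
      p <- as.vector(stats::rmultinom(1, 60, rep(1, 6))) + 1
      geno_mat(sprintf("%d/%d", sample(sizes, 20, TRUE, prob = p),
                       sample(sizes, 20, TRUE, prob = p)))
    }
    ds <- make_dataset(list(A = list(mk()), B = list(mk())))
    pvals[i] <- allele_size_permutation_test(ds, n_perm = 119)$p
  }
  rej <- mean(pvals <= 0.05)
  expect_lt(rej, 0.05 + 3.3 * sqrt(0.05 * 0.95 / nrep))
  # and detectably anticonservative nowhere: p-values span the unit interval
  expect_gt(mean(pvals > 0.5), 0.25)
})

test_that("the permutation test detects stepwise divergence (power)", {
  set.seed(44)
  hits <- 0; nrep <- 20
  ev <- data.frame(time = 3000, kind = "merge", a = 2, b = 1)
  sc <- demographic_scenario(c(A = 400, B = 400), ev, c(A = 25, B = 25))
  mm <- mutation_model(motif_lengths = rep(2, 8), mean_rate = 5e-4, pgsm = 0,
                       rate_shape = Inf, n_states = 60, range_lo = 10)
  for (i in seq_len(nrep)) {
    ds <- simulate_genotypes(sc, mm)
    if (allele_size_permutation_test(ds, n_perm = 119)$p <= 0.05) hits <- hits + 1
  }
  expect_gt(hits / nrep, 0.5)
})

test_that("mean permuted R_ST approximates the frequency-based differentiation", {
  set.seed(45)
  # drift-only data: R_STperm should sit near theta, not near R_STobs
  mk <- function(p) geno_mat(sprintf("%d/%d",
                                     2 * sample(10:15, 60, TRUE, prob = p),
                                     2 * sample(10:15, 60, TRUE, prob = p)))
  p1 <- c(4, 1, 3, 2, 1, 1); p2 <- c(1, 3, 1, 2, 4, 1)
  ds <- make_dataset(list(A = list(mk(p1)), B = list(mk(p2))))
  res <- allele_size_permutation_test(ds, n_perm = 400, seed = 9)
  theta <- wc_fst(ds, pairwise = FALSE)$theta
  expect_lt(abs(res$mean_rst_perm - theta), 0.06)
})

test_that("Rousset distance, delta-mu^2, Garza M and D_AS follow their closed forms", {
  expect_equal(rousset_distance(0), 0)
  expect_equal(rousset_distance(0.2), 0.25)
  expect_equal(rousset_distance(0.5), 1.0)
  expect_warning(rousset_distance(1), "infinite")

  same <- make_dataset(list(A = list(geno_mat(c("20/22", "22/24"))),
                            B = list(geno_mat(c("20/22", "22/24")))))
  expect_equal(delta_mu2(same, c("A", "B"))$mean, 0)
  # means 10 and 12 repeats -> 4
  ds <- make_dataset(list(A = list(geno_mat(c("20/20", "20/20"))),
                          B = list(geno_mat(c("24/24", "24/24")))))
  expect_equal(delta_mu2(ds, c("A", "B"))$mean, 4)
  mix <- make_dataset(list(A = list(geno_mat(c("20/24", "20/20"))),
                           B = list(geno_mat(c("26/28", "30/24")))))
  expect_equal(delta_mu2(mix, c("A", "B"))$mean, (10.5 - 13.5)^2)

  g <- make_dataset(list(P = list(geno_mat(c("16/18", "20/16")))))
  expect_equal(garza_m(g, "P")$mean, 3 / 3)        # alleles {8, 9, 10}
  g2 <- make_dataset(list(P = list(geno_mat(c("16/16", "20/20")))))
  expect_equal(garza_m(g2, "P")$mean, 2 / 3)       # alleles {8, 10}
  mono <- make_dataset(list(P = list(geno_mat(c("16/16")))))
  expect_equal(garza_m(mono, "P")$mean, 1)

  idpop <- make_dataset(list(A = list(geno_mat(c("20/20"))),
                             B = list(geno_mat(c("20/20")))))
  expect_equal(shared_allele_distance(idpop, c("A", "B")), 0)
  disj <- make_dataset(list(A = list(geno_mat(c("20/20", "20/22"))),
                            B = list(geno_mat(c("30/30", "32/30")))))
  expect_equal(shared_allele_distance(disj, c("A", "B")), 1)
  # hand count: (20,22) vs (20,20) shares 1 of 2; (20,22) vs (22,24) shares 1
  toy <- make_dataset(list(A = list(geno_mat(c("20/22"))),
                           B = list(geno_mat(c("20/20", "22/24")))))
  expect_equal(shared_allele_distance(toy, c("A", "B")), 1 - mean(c(0.5, 0.5)))
})
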