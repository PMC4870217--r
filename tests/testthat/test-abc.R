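# the default five analysis demes, at reduced sample sizes for speed
small_pop_config <- list(sample_sizes = c(South = 15, McKinley = 8,
                                          MariposaNelder = 8,
                                          TuolumneMerced = 6, Calaveras = 8))

test_that("summary vector: degenerate and invariance cases", {
  mono <- make_dataset(list(A = list(geno_mat(rep("20/20", 4))),
                            B = list(geno_mat(rep("20/20", 4)))))
  sv <- summary_vector(mono)
  expect_equal(unname(sv[c("kA_A", "kA_B")]), c(1, 1))
  expect_equal(unname(sv[c("HE_A", "HE_B", "VAR_A", "VAR_B")]), rep(0, 4))
  expect_equal(unname(sv["DMU_A.B"]), 0)
  # permuting individual order leaves the vector unchanged
  set.seed(71)
  sc <- demographic_scenario(c(A = 200, B = 150),
                             data.frame(time = 100, kind = "merge", a = 2, b = 1),
                             c(A = 12, B = 10))
  ds <- simulate_genotypes(sc, mutation_model(motif_lengths = rep(2, 5),
                                              mean_rate = 5e-4, pgsm = 0.2),
                           seed = 72)
  perm <- sample(length(ds$ind))
  ds2 <- msat_dataset(ds$alleles[perm, , , drop = FALSE], ds$ind[perm],
                      ds$pop[perm], ds$loci)
  expect_equal(summary_vector(ds), summary_vector(ds2))
  # a deme in the partition with no sampled population is an error
  expect_error(summary_vector(ds, partition = c(A = "x", B = "x", Z = "y")),
               "empty deme")
})

test_that("R summary vector agrees with the simulator's internal statistics", {
  set.seed(73)
  sc <- build_scenario("simultaneous_divergence",
                       c(N1 = 2000, N2 = 300, N3 = 200, N4 = 400, N5 = 250,
                         N_div = 1000, N_anc = 9000, t_div1 = 80, t_anc = 4000),
                       list(sample_sizes = c(South = 25, McKinley = 10,
                                             MariposaNelder = 10,
                                             TuolumneMerced = 8, Calaveras = 12)))
  mm <- mutation_model(mean_rate = 5e-4, pgsm = 0.2)
  ds <- simulate_genotypes(sc, mm, seed = 74)
  sv_r <- summary_vector(ds)
  genes <- matrix(NA_integer_, 2 * length(ds$ind), nrow(ds$loci))
  ru <- repeat_units(ds)
  for (l in seq_len(nrow(ds$loci))) {
    genes[seq(1, nrow(genes), 2), l] <- ru[, l, 1]
    genes[seq(2, nrow(genes), 2), l] <- ru[, l, 2]
  }
  pop_idx <- match(ds$pop, unique(ds$pop))
  sv_cpp <- msatabc:::cpp_dataset_stats(genes, pop_idx, 5, TRUE)
  expect_equal(unname(sv_r), sv_cpp[seq_along(sv_r)], tolerance = 1e-10)
  # holdout block agrees with the R holdout vector
  hv_r <- holdout_vector(ds)
  expect_equal(unname(hv_r), sv_cpp[-seq_along(sv_r)], tolerance = 1e-10)
})

test_that("reference tables have the promised shape and are seed-reproducible", {
  kinds <- c("simultaneous_divergence", "ancient_divergence")
  t1 <- build_reference_table(kinds, n_per_scenario = 100, seed = 7,
                              pop_config = small_pop_config)
  expect_equal(nrow(t1$stats), 200)
  expect_equal(as.vector(table(t1$scenario)), c(100, 100))
  expect_false(anyNA(t1$stats))
  t2 <- build_reference_table(kinds, n_per_scenario = 100, seed = 7,
                              pop_config = small_pop_config)
  expect_identical(t1$stats, t2$stats)
  expect_identical(t1$params, t2$params)
  expect_error(build_reference_table(kinds, n_per_scenario = 10, seed = 1),
               ">= 100")
})

test_that("reference-table summary means match direct simulation under a point prior", {
  pt <- list(N1 = c(1000, 1000.001), N2 = c(200, 200.001), N3 = c(200, 200.001),
             N4 = c(200, 200.001), N5 = c(200, 200.001),
             N_div = c(800, 800.001), N_anc = c(5000, 5000.001),
             t_div1 = c(100, 100.001), t_anc = c(2000, 2000.001))
  spec <- prior_spec("simultaneous_divergence", overrides = pt)
  mm <- mutation_model(mean_rate = 5e-4, pgsm = 0.2)
  pc <- list(sample_sizes = c(South = 20, McKinley = 10, MariposaNelder = 10,
                              TuolumneMerced = 10, Calaveras = 10))
  tab <- build_reference_table("simultaneous_divergence",
                               priors = list(simultaneous_divergence = spec),
                               n_per_scenario = 300, seed = 8, pop_config = pc,
                               mut_model = mm)
  set.seed(9)
  direct <- replicate(300, {
    sc <- build_scenario("simultaneous_divergence",
                         vapply(pt, `[`, 0, 1), pc)
    st <- msatabc:::cpp_dataset_stats(
      msatabc:::.sim_gene_matrix(sc, msatabc:::.realize_mutation(mm)),
      rep(1:5, pc$sample_sizes), 5, FALSE)
    st[6]    # mean gene diversity of the southern deme
  })
  expect_equal(mean(tab$stats[, "HE_South"]), mean(direct), tolerance = 0.03)
})

test_that("scenario choice separates the separable and ties the identical", {
  kinds <- c("simultaneous_divergence", "ancient_divergence")
  # far-apart mutation regimes make the two scenarios trivially separable in
  # diversity space: old split + big ancestral N vs recent split
  t1 <- build_reference_table(kinds, n_per_scenario = 600, seed = 11,
                              pop_config = small_pop_config)
  obs <- t1$stats[5, ]    # a simultaneous_divergence row
  mc <- model_choice_logistic(t1, obs, tolerance = 0.1)
  expect_s3_class(mc, "abc_model_choice")
  expect_equal(sum(mc$posterior$prob), 1, tolerance = 1e-6)
  expect_true(all(mc$posterior$prob >= 0))
  # duplicated scenario: probabilities must split evenly
  t2 <- t1
  S1 <- t1$stats[t1$scenario == 1, ]
  t2$stats <- rbind(S1, S1)
  t2$scenario <- rep(1:2, each = nrow(S1))
  t2$params <- list(t1$params[[1]], t1$params[[1]])
  mc2 <- model_choice_logistic(t2, obs, tolerance = 0.1)
  expect_equal(mc2$posterior$prob, c(0.5, 0.5), tolerance = 0.1)
  # tolerance floor
  expect_error(model_choice_logistic(t1, obs, tolerance = 0.01), ">= 50")
})

test_that("logistic and rejection scenario-choice estimates agree when separation is clear", {
  kinds <- c("simultaneous_divergence", "ancient_divergence")
  tab <- build_reference_table(kinds, n_per_scenario = 600, seed = 12,
                               pop_config = small_pop_config)
  obs <- tab$stats[10, ]
  mc_log <- model_choice_logistic(tab, obs, tolerance = 0.1)
  ret <- msatabc:::.abc_retain(tab$stats, obs, 0.1)
  scen <- tab$scenario[ret$idx]
  rej <- vapply(1:2, function(k) sum(ret$w[scen == k]) / sum(ret$w), 0)
  expect_lt(max(abs(mc_log$posterior$prob - rej)), 0.1)
})

test_that("parameter estimation: prior limit, boundedness, adjustment", {
  spec <- prior_spec("simultaneous_divergence")
  tab <- build_reference_table("simultaneous_divergence", n_per_scenario = 400,
                               seed = 13, pop_config = small_pop_config)
  obs <- tab$stats[1, ]
  # tolerance 1 without adjustment: the posterior is the prior
  pe_prior <- estimate_parameters(tab, obs, 1, tolerance = 1, adjust = FALSE)
  for (pn in c("N1", "t_div1", "t_anc")) {
    b <- spec$params[spec$params$name == pn, ]
    expect_equal(pe_prior$estimates$median[pe_prior$estimates$parameter == pn],
                 (b$min + b$max) / 2, tolerance = 0.1 * (b$max - b$min))
  }
  # adjusted estimates never escape the prior support
  pe <- estimate_parameters(tab, obs, 1, tolerance = 0.15)
  expect_true(pe$adjusted)
  for (i in seq_len(nrow(spec$params))) {
    pn <- spec$params$name[i]
    col <- pe$posterior_sample[, pn]
    expect_true(all(col >= spec$params$min[i] - 1e-6))
    expect_true(all(col <= spec$params$max[i] + 1e-6))
  }
  est <- pe$estimates
  expect_true(all(est$lower <= est$median & est$median <= est$upper))
})

test_that("RMAE matches closed forms and a numerical-integration oracle", {
  pf <- data.frame(parameter = "a", truth = c(2, 4, 8), estimate = c(2, 4, 8))
  expect_equal(unname(rmae(pf)["a"]), 0)
  pf2 <- data.frame(parameter = "a", truth = c(2, 4), estimate = c(4, 8))
  expect_equal(unname(rmae(pf2)["a"]), 1)
  # estimator = prior median m of U[a, b]: RMAE = median of |m - th| / th
  a <- 100; b <- 1000; m <- (a + b) / 2
  set.seed(14)
  th <- runif(2e5, a, b)
  want <- median(abs(m - th) / th)
  pf3 <- data.frame(parameter = "x", truth = th, estimate = m)
  expect_equal(unname(rmae(pf3)["x"]), want, tolerance = 1e-12)
  # numerical check of the same quantity by quadrature on the cdf
  f <- function(c) {
    # P(|m - th|/th <= c) for th ~ U[a, b]
    lo <- m / (1 + c); hi <- if (c < 1) m / (1 - c) else Inf
    (min(hi, b) - max(lo, a)) / (b - a)
  }
  cstar <- uniroot(function(c) f(c) - 0.5, c(1e-6, 10))$root
  expect_equal(want, cstar, tolerance = 0.01)
  # zero truths are excluded and counted
  pf4 <- data.frame(parameter = "a", truth = c(0, 2), estimate = c(1, 3))
  expect_equal(attr(rmae(pf4), "n_excluded"), 1)
})

test_that("error-rate evaluation behaves at the symmetric and bounded extremes", {
  kinds <- c("simultaneous_divergence", "ancient_divergence")
  tab <- build_reference_table(kinds, n_per_scenario = 300, seed = 15,
                               pop_config = small_pop_config)
  ce <- suppressWarnings(
    confidence_evaluation(tab, "simultaneous_divergence", n_pseudo = 10,
                          tolerance = 0.2, seed = 16))
  expect_true(ce$type1 >= 0 && ce$type1 <= 1)
  expect_true(ce$type2 >= 0 && ce$type2 <= 1)
  expect_equal(nrow(ce$details), 20)
  # indistinguishable reference rows: the focal scenario's posterior
  # probability collapses to ~1/2 on every pseudo-dataset
  t2 <- tab
  t2$stats[t2$scenario == 2, ] <- t2$stats[t2$scenario == 1, ]
  t2$params[[2]] <- t2$params[[1]]
  ce2 <- suppressWarnings(
    confidence_evaluation(t2, "simultaneous_divergence", n_pseudo = 14,
                          tolerance = 0.2, seed = 17))
  expect_equal(mean(ce2$details$p_focal), 0.5, tolerance = 0.1)
})

test_that("posterior-predictive checks flag misfit and pass self-fit", {
  tab <- build_reference_table("simultaneous_divergence", n_per_scenario = 400,
                               seed = 18, pop_config = small_pop_config)
  set.seed(19)
  # observed data drawn from the fitted model family
  spec <- tab$priors[[1]]
  th <- sample_priors(spec)
  sc <- build_scenario("simultaneous_divergence", th, tab$pop_config)
  ds <- simulate_genotypes(sc, mutation_model(mean_rate = 5e-4, pgsm = 0.2))
  obs <- summary_vector(ds)
  hold <- holdout_vector(ds)
  fit <- estimate_parameters(tab, obs, 1, tolerance = 0.15)
  pp <- model_check(fit, tab, hold, n = 150, seed = 20)
  expect_true(all(pp >= 0 & pp <= 1))
  expect_equal(length(pp), length(hold))
  # self-fit: the bulk of holdout statistics are not extreme
  expect_gt(mean(pp > 0.02 & pp < 0.98), 0.6)
  # gross misfit: monomorphic observed data against a variable model
  npair <- 10
  mono_hold <- hold
  mono_hold[] <- c(1, rep(1, npair), rep(0, npair), rep(0, npair))
  pp2 <- model_check(fit, tab, mono_hold, n = 150, seed = 21)
  expect_lt(min(pp2), 0.05)
})
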