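## Generators for datasets with the sampling structure the analysis
## assumes: open-pollinated half-sib families from a clonal seed orchard,
## and pseudo-observed datasets simulated under a known demographic truth.

#' Orchard sampling design
#'
#' Describes seed collections from a clonal orchard: for each grove, a
#' number of mother trees and open-pollinated seedlings per mother. Mothers
#' are drawn from the grove allele frequencies; each seedling receives one
#' Mendelian maternal gamete and one paternal gamete from the grove pollen
#' pool (panmictic within grove). Seedlings of the same mother are half
#' sibs unless selfing occurs.
#'
#' @param groves data.frame with columns `name`, `n_mothers`,
#'   `seedlings_per_mother`.
#' @param n_alleles alleles per locus for the frequency spec (default 10,
#'   uniform frequencies).
#' @param selfing_rate probability a seedling's paternal gamete comes from
#'   its own mother (default 0).
#' @return object of class `orchard_design`.
#' @export
orchard_design <- function(groves, n_alleles = 10, selfing_rate = 0) {
  stopifnot(all(c("name", "n_mothers", "seedlings_per_mother") %in% names(groves)))
  if (any(groves$n_mothers < 1) || any(groves$seedlings_per_mother < 1))
    stop("n_mothers and seedlings_per_mother must be >= 1")
  if (n_alleles < 2) stop("degenerate allele-frequency spec: need >= 2 alleles")
  structure(list(groves = groves, n_alleles = n_alleles,
                 selfing_rate = selfing_rate),
            class = "orchard_design")
}

#' Generate an orchard dataset with its true pedigree
#'
#' @param design an [orchard_design()].
#' @param n_loci number of loci (all dinucleotide; allele sizes
#'   `2 * (10 + allele index)` bp).
#' @param seed optional integer seed.
#' @return list with `dataset` (an [msat_dataset()], `family` holding the
#'   mother id), `pedigree` (data.frame individual/population/mother) and
#'   `true_r` (matrix of expected relatedness: 0.25 within a half-sib
#'   family, 0 otherwise).
#' @export
generate_orchard <- function(design, n_loci = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ka <- design$n_alleles
  sizes_bp <- 2L * (10L + seq_len(ka))       # dinucleotide ladder
  ind <- character(); popv <- character(); fam <- character()
  rows <- list()
  for (g in seq_len(nrow(design$groves))) {
    gv <- design$groves[g, ]
    # mother genotypes: n_mothers x loci x 2 allele indices
    mom <- array(sample.int(ka, gv$n_mothers * n_loci * 2, replace = TRUE),
                 dim = c(gv$n_mothers, n_loci, 2))
    for (m in seq_len(gv$n_mothers)) {
      for (s in seq_len(gv$seedlings_per_mother)) {
        mat <- vapply(seq_len(n_loci),
                      function(l) mom[m, l, sample.int(2, 1)], 0L)
        if (stats::runif(1) < design$selfing_rate) {
          pat <- vapply(seq_len(n_loci),
                        function(l) mom[m, l, sample.int(2, 1)], 0L)
        } else {
          pat <- sample.int(ka, n_loci, replace = TRUE)   # grove pollen pool
        }
        ind <- c(ind, sprintf("%s_m%02d_s%02d", gv$name, m, s))
        popv <- c(popv, gv$name)
        fam <- c(fam, sprintf("%s_m%02d", gv$name, m))
        rows[[length(rows) + 1]] <- cbind(sizes_bp[mat], sizes_bp[pat])
      }
    }
  }
  n <- length(ind)
  alleles <- array(NA_integer_, dim = c(n, n_loci, 2))
  for (i in seq_len(n)) alleles[i, , ] <- rows[[i]]
  ds <- msat_dataset(alleles, ind, popv,
                     locus_def(sprintf("SL%02d", seq_len(n_loci)), 2L),
                     family = fam)
  true_r <- matrix(0, n, n, dimnames = list(ind, ind))
  same_fam <- outer(fam, fam, "==")
  true_r[same_fam] <- 0.25
  diag(true_r) <- NA
  list(dataset = ds,
       pedigree = data.frame(individual_id = ind, population_id = popv,
                             mother = fam, stringsAsFactors = FALSE),
       true_r = true_r)
}

# Table 2 posterior medians used as the default pseudo-observed truth.
DEFAULT_TRUTH <- c(N1 = 5380, N2 = 480, N3 = 284, N4 = 592, N5 = 329,
                   N_div = 1870, N_anc = 23000, t_div1 = 68, t_anc = 7610)

#' Generate a pseudo-observed dataset with recorded truth
#'
#' Wraps [simulate_genotypes()] for recovery tests: the generating
#' parameters are returned alongside the dataset. The default truth is the
#' simultaneous-divergence posterior-median configuration (southern pool
#' N1 = 5380; northern demes in the hundreds; divergence from N_div = 1870
#' at 68 generations; ancestral decline from N_anc = 23000 at 7610
#' generations).
#'
#' @param truth_params named parameter vector (default `DEFAULT_TRUTH`).
#' @param scenario_kind scenario kind (default simultaneous divergence).
#' @param sample_sizes named diploid sample sizes per deme (default mirrors
#'   the grove pooling: southern ~200, northern demes 16-50).
#' @param mut_model a [mutation_model()]; defaults to a fixed mid-range
#'   model (mean rate 5e-4, P = 0.22) rather than hyper-prior draws.
#' @param seed optional integer seed.
#' @param prior_check warn when the truth lies outside the default priors.
#' @return list with `dataset`, `truth`, `scenario`.
#' @export
generate_pseudo_observed <- function(truth_params = DEFAULT_TRUTH,
                                     scenario_kind = "simultaneous_divergence",
                                     sample_sizes = DEFAULT_SAMPLES,
                                     mut_model = mutation_model(mean_rate = 5e-4,
                                                                pgsm = 0.22),
                                     seed = NULL, prior_check = TRUE) {
  if (prior_check) {
    spec <- prior_spec(scenario_kind)
    pr <- spec$params
    common <- intersect(names(truth_params), pr$name)
    lo <- stats::setNames(pr$min, pr$name)[common]
    hi <- stats::setNames(pr$max, pr$name)[common]
    out <- truth_params[common] < lo | truth_params[common] > hi
    if (any(out))
      warning("truth outside default priors: ", paste(common[out], collapse = ", "))
  }
  sc <- build_scenario(scenario_kind, truth_params,
                       list(sample_sizes = sample_sizes))
  ds <- simulate_genotypes(sc, mut_model, seed = seed)
  list(dataset = ds, truth = truth_params, scenario = sc)
}
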