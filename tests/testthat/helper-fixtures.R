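# Shared fixtures and independent oracles used across the suite.

# Build a dataset from a list of per-population genotype arrays.
# genos: named list (population -> list of n x 2 matrices, one per locus,
# allele sizes in bp; NA rows = missing genotype).
make_dataset <- function(genos, motif_length = 2L, offset = 0L) {
  pops <- names(genos)
  L <- length(genos[[1]])
  n_per <- vapply(genos, function(g) nrow(g[[1]]), 0L)
  n <- sum(n_per)
  alleles <- array(NA_integer_, dim = c(n, L, 2))
  ind <- character(n); popv <- character(n)
  row <- 1
  for (p in pops) {
    for (i in seq_len(n_per[[p]])) {
      for (l in seq_len(L)) alleles[row, l, ] <- genos[[p]][[l]][i, ]
      ind[row] <- paste0(p, "_", i); popv[row] <- p
      row <- row + 1
    }
  }
  msat_dataset(alleles, ind, popv,
               locus_def(paste0("loc", seq_len(L)), motif_length, offset = offset))
}

# single-locus two-population helper: per pop a vector of "a/b" genotypes
geno_mat <- function(strings) {
  do.call(rbind, lapply(strsplit(strings, "/"), as.integer))
}

# --- rarefaction oracle: exhaustive enumeration over gene subsets --------
rarefaction_enum <- function(allele_counts, g) {
  genes <- rep(seq_along(allele_counts), allele_counts)
  subs <- utils::combn(length(genes), 2 * g)
  mean(apply(subs, 2, function(ix) length(unique(genes[ix]))))
}

# --- HWE exact-test oracle: full enumeration for 2 alleles ---------------
# Levene conditional distribution of the heterozygote count given allele
# counts; probability-ordering p-value.
hwe_enum_p <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logw <- vapply(hs, function(h) {
    aa <- (nA - h) / 2; bb <- n - aa - h
    if (aa < 0 || bb < 0) return(-Inf)
    h * log(2) - lfactorial(aa) - lfactorial(h) - lfactorial(bb)
  }, 0)
  w <- exp(logw - max(logw))
  pr <- w / sum(w)
  obs <- which(hs == nAa)
  sum(pr[pr <= pr[obs] + 1e-12])
}

# --- Mendelian pair simulators for relatedness calibration ---------------
# returns a dataset of n_pairs pairs with the requested relationship plus
# enough unrelated individuals to stabilize allele frequencies
sim_related_pairs <- function(n_pairs, relationship = c("parent_offspring",
                                                        "unrelated"),
                              n_loci = 20, k_alleles = 10) {
  relationship <- match.arg(relationship)
  draw <- function() sample.int(k_alleles, 1)
  sizes <- 2L * (10L + seq_len(k_alleles))
  n <- 2 * n_pairs
  alleles <- array(NA_integer_, dim = c(n, n_loci, 2))
  for (p in seq_len(n_pairs)) {
    for (l in seq_len(n_loci)) {
      g1 <- c(draw(), draw())
      g2 <- if (relationship == "parent_offspring")
        c(g1[sample.int(2, 1)], draw()) else c(draw(), draw())
      alleles[2 * p - 1, l, ] <- sizes[g1]
      alleles[2 * p, l, ] <- sizes[g2]
    }
  }
  ids <- sprintf("i%04d", seq_len(n))
  ds <- msat_dataset(alleles, ids, rep("P1", n),
                     locus_def(paste0("loc", seq_len(n_loci)), 2L))
  list(dataset = ds,
       pair_idx = cbind(seq(1, n, by = 2), seq(2, n, by = 2)))
}

# mean relatedness over the designated pairs
mean_pair_r <- function(rmat, pair_idx) {
  mean(rmat[pair_idx], na.rm = TRUE)
}

grove_meta_path <- function() {
  system.file("extdata", "grove_meta.csv", package = "msatabc")
}

# small GENEPOP fixture text (2 populations, 2 loci, 3-digit coding)
genepop_fixture <- function() {
  c("toy dataset",
    "locA",
    "locB",
    "POP",
    "north1 ,  146148 210210",
    "north2 ,  146146 210213",
    "POP",
    "south1 ,  148148 213213",
    "south2 ,  146148 000000")
}
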