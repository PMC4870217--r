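## Per-population diversity statistics, HWE / LD tests, multiple-testing
## correction and partial correlations.

# allele count vector at one locus for a set of rows (pairwise deletion)
.allele_counts <- function(dataset, locus, rows) {
  a <- dataset$alleles[rows, locus, , drop = FALSE]
  a <- as.vector(a)
  a <- a[!is.na(a)]
  if (!length(a)) return(integer(0))
  table(a)
}

#' Observed heterozygosity per locus
#'
#' Fraction of typed individuals that are heterozygous, per locus, with the
#' across-locus mean. Individuals missing at a locus are dropped for that
#' locus only.
#'
#' @param dataset an [msat_dataset()].
#' @param population population id.
#' @return list with `per_locus` (named numeric, NA when no data) and `mean`.
#' @export
observed_heterozygosity <- function(dataset, population) {
  rows <- which(dataset$pop == population)
  L <- nrow(dataset$loci)
  per <- setNames(rep(NA_real_, L), dataset$loci$name)
  for (l in seq_len(L)) {
    g <- dataset$alleles[rows, l, , drop = FALSE]
    ok <- !is.na(g[, 1, 1])
    if (!any(ok)) next
    per[l] <- mean(g[ok, 1, 1] != g[ok, 1, 2])
  }
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Unbiased expected heterozygosity (Nei gene diversity) per locus
#'
#' `H_E = 2n/(2n-1) * (1 - sum p_i^2)` with `n` typed diploid individuals at
#' the locus. Loci with fewer than 2 typed individuals are flagged NA.
#'
#' @inheritParams observed_heterozygosity
#' @return list with `per_locus` and `mean`.
#' @export
expected_heterozygosity <- function(dataset, population) {
  rows <- which(dataset$pop == population)
  L <- nrow(dataset$loci)
  per <- setNames(rep(NA_real_, L), dataset$loci$name)
  for (l in seq_len(L)) {
    cnt <- .allele_counts(dataset, l, rows)
    ng <- sum(cnt)                      # gene copies = 2n
    if (ng < 4) next                    # n < 2 diploid individuals
    p <- cnt / ng
    per[l] <- (ng / (ng - 1)) * (1 - sum(p^2))
  }
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a subsample of `g` diploid
#' individuals (`2g` gene copies), by hypergeometric rarefaction:
#' `A_R(g) = sum_i [1 - choose(2N - N_i, 2g) / choose(2N, 2g)]`
#' over alleles with `N_i` copies among the `2N` sampled genes. Loci with
#' fewer than `g` typed individuals are excluded and flagged NA.
#'
#' @inheritParams observed_heterozygosity
#' @param g rarefaction sample size in diploid individuals (default 5).
#' @return list with `per_locus` and `mean`.
#' @export
allelic_richness <- function(dataset, population, g = 5) {
  rows <- which(dataset$pop == population)
  L <- nrow(dataset$loci)
  per <- setNames(rep(NA_real_, L), dataset$loci$name)
  for (l in seq_len(L)) {
    cnt <- .allele_counts(dataset, l, rows)
    ng <- sum(cnt)
    if (ng < 2 * g) next
    per[l] <- sum(1 - exp(lchoose(ng - cnt, 2 * g) - lchoose(ng, 2 * g)))
  }
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Markov-chain exact test of Hardy-Weinberg equilibrium
#'
#' Markov-chain estimate of the exact-test probability under the
#' probability-ordering criterion: the p-value is the probability, under the
#' conditional (Levene) distribution of genotype tables given allele counts,
#' of tables no more probable than the observed one. The chain swaps allele
#' copies between random individuals' gene slots; on slot-labelled arrays
#' this random-transposition walk is uniform, and a uniform array draw
#' induces exactly the Levene distribution on tables (each table owns
#' `n! 2^H / prod(n_ij!)` arrays), so every swap is accepted. The estimate
#' and its Monte-Carlo standard error come from batch means.
#'
#' @inheritParams observed_heterozygosity
#' @param locus locus name or index.
#' @param dememorization burn-in steps (default 10000).
#' @param batches number of batches (default 1000).
#' @param iterations_per_batch steps per batch (default 10000).
#' @param seed optional integer seed.
#' @return list with `p`, `se`, `n_alleles`, `n` (typed individuals); `p` is
#'   NA for monomorphic loci or fewer than 3 typed individuals.
#' @export
hwe_exact_test <- function(dataset, population, locus,
                           dememorization = 10000, batches = 1000,
                           iterations_per_batch = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- which(dataset$pop == population)
  g <- dataset$alleles[rows, locus, , drop = TRUE]
  if (is.null(dim(g))) g <- matrix(g, ncol = 2)
  g <- g[!is.na(g[, 1]), , drop = FALSE]
  n <- nrow(g)
  lev <- sort(unique(as.vector(g)))
  k <- length(lev)
  if (k < 2 || n < 3)
    return(list(p = NA_real_, se = NA_real_, n_alleles = k, n = n))
  gi <- matrix(match(g, lev), ncol = 2)
  gi <- cbind(pmin(gi[, 1], gi[, 2]), pmax(gi[, 1], gi[, 2]))
  cnt <- matrix(0L, k, k)
  for (i in seq_len(n)) cnt[gi[i, 1], gi[i, 2]] <- cnt[gi[i, 1], gi[i, 2]] + 1L
  score <- function(cm) {
    h <- sum(cm) - sum(diag(cm))
    h * log(2) - sum(lfactorial(cm[upper.tri(cm, diag = TRUE)]))
  }
  s_obs <- score(cnt)
  s_cur <- s_obs
  step <- function() {
    ij <- sample.int(n, 2)
    c1 <- sample.int(2, 1); c2 <- sample.int(2, 1)
    a <- gi[ij[1], c1]; b <- gi[ij[1], 3 - c1]
    c_ <- gi[ij[2], c2]; d <- gi[ij[2], 3 - c2]
    if (a == c_) return(FALSE)            # no-op swap
    rm1 <- sort(c(a, b)); rm2 <- sort(c(c_, d))
    ad1 <- sort(c(c_, b)); ad2 <- sort(c(a, d))
    delta <- 0
    dec <- function(p) {
      v <- cnt[p[1], p[2]]
      delta <<- delta + lfactorial(v) - lfactorial(v - 1L)
      cnt[p[1], p[2]] <<- v - 1L
      if (p[1] != p[2]) delta <<- delta - log(2)
    }
    inc <- function(p) {
      v <- cnt[p[1], p[2]]
      delta <<- delta + lfactorial(v) - lfactorial(v + 1L)
      cnt[p[1], p[2]] <<- v + 1L
      if (p[1] != p[2]) delta <<- delta + log(2)
    }
    dec(rm1); dec(rm2); inc(ad1); inc(ad2)
    gi[ij[1], ] <<- ad1; gi[ij[2], ] <<- ad2
    s_cur <<- s_cur + delta
    TRUE
  }
  for (t in seq_len(dememorization)) step()
  bm <- numeric(batches)
  tol <- 1e-9
  for (b in seq_len(batches)) {
    hit <- 0L
    for (t in seq_len(iterations_per_batch)) {
      step()
      if (s_cur <= s_obs + tol) hit <- hit + 1L
    }
    bm[b] <- hit / iterations_per_batch
  }
  list(p = mean(bm), se = stats::sd(bm) / sqrt(batches), n_alleles = k, n = n)
}

#' Genotypic linkage-disequilibrium permutation test
#'
#' Log-likelihood-ratio (G) statistic of association between the genotype
#' classes of two loci, with significance from permuting one locus's
#' genotypes across individuals. `p = (1 + #{G_perm >= G_obs}) / (1 + n_perm)`.
#'
#' @inheritParams observed_heterozygosity
#' @param locus_pair length-2 vector of locus names or indices.
#' @param n_perm number of permutations (must be >= 1).
#' @param seed optional integer seed.
#' @return list with `p`, `G_obs`, `n` shared typed individuals; `p` NA when
#'   either locus is monomorphic in the population.
#' @export
ld_permutation_test <- function(dataset, population, locus_pair, n_perm = 1000,
                                seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rows <- which(dataset$pop == population)
  g1 <- dataset$alleles[rows, locus_pair[1], , drop = TRUE]
  g2 <- dataset$alleles[rows, locus_pair[2], , drop = TRUE]
  if (is.null(dim(g1))) { g1 <- matrix(g1, ncol = 2); g2 <- matrix(g2, ncol = 2) }
  ok <- !is.na(g1[, 1]) & !is.na(g2[, 1])
  if (sum(ok) < 5) stop("fewer than 5 shared typed individuals")
  lab <- function(g) paste(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]), sep = "/")
  x <- lab(g1[ok, , drop = FALSE]); y <- lab(g2[ok, , drop = FALSE])
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(p = NA_real_, G_obs = NA_real_, n = sum(ok)))
  gstat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    nz <- tab > 0
    2 * sum(tab[nz] * log(tab[nz] / e[nz]))
  }
  G_obs <- gstat(x, y)
  hits <- 0L
  for (b in seq_len(n_perm)) if (gstat(x, sample(y)) >= G_obs - 1e-12) hits <- hits + 1L
  list(p = (1 + hits) / (1 + n_perm), G_obs = G_obs, n = sum(ok))
}

#' Sequential Bonferroni (Holm) correction
#'
#' Holm's step-down procedure: order p-values ascending and reject while
#' `p_(i) <= alpha / (m - i + 1)`, stopping at the first failure.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise error rate (default 0.05).
#' @return logical vector of rejection flags, in the input order.
#' @export
sequential_bonferroni <- function(p_values, alpha = 0.05) {
  if (!length(p_values)) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "holm") <= alpha
}

#' Partial correlation with a t-based p-value
#'
#' Pearson partial correlation via the residual method: `y` and `x` are each
#' regressed on the control variables and the residuals correlated. The
#' two-sided p-value uses `t = r * sqrt((n - k - 2) / (1 - r^2))` with
#' `df = n - k - 2` for `k` controls.
#'
#' @param y,x numeric vectors.
#' @param controls numeric vector, matrix or data.frame of control
#'   variables (NULL for a simple correlation).
#' @return list with `r`, `p`, `df`.
#' @export
partial_correlation <- function(y, x, controls = NULL) {
  n <- length(y)
  if (length(x) != n) stop("y and x must have equal length")
  if (stats::sd(y) == 0 || stats::sd(x) == 0) stop("constant variable")
  if (is.null(controls)) {
    k <- 0
    ry <- y - mean(y); rx <- x - mean(x)
  } else {
    Z <- as.matrix(controls)
    if (any(apply(Z, 2, stats::sd) == 0)) stop("constant control variable")
    k <- ncol(Z)
    if (n < k + 3) stop("need at least k + 3 observations")
    qz <- qr(cbind(1, Z))
    ry <- qr.resid(qz, y)
    rx <- qr.resid(qz, x)
  }
  if (stats::sd(ry) < 1e-12 || stats::sd(rx) < 1e-12)
    stop("zero residual variance after controlling")
  r <- stats::cor(as.vector(ry), as.vector(rx))
  df <- n - k - 2
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Per-population diversity table
#'
#' Convenience wrapper assembling sample size, rarefied allelic richness,
#' unbiased expected heterozygosity and observed heterozygosity per
#' population (across-locus means), in the layout of a standard grove table.
#'
#' @param dataset an [msat_dataset()].
#' @param g rarefaction size in diploid individuals (default 5).
#' @return data.frame with columns `population_id`, `n`, `A_R`, `H_E`, `H_O`.
#' @export
diversity_table <- function(dataset, g = 5) {
  pops <- unique(dataset$pop)
  out <- lapply(pops, function(p) {
    n <- sum(dataset$pop == p)
    data.frame(population_id = p, n = n,
               A_R = allelic_richness(dataset, p, g)$mean,
               H_E = expected_heterozygosity(dataset, p)$mean,
               H_O = observed_heterozygosity(dataset, p)$mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
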