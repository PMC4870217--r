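## F-statistics, allele-size based R_ST, the allele-size permutation test
## for phylogeographic signal, and pairwise distance statistics.

# resolve a population -> group mapping into a per-individual group factor
.group_of <- function(dataset, grouping = NULL) {
  if (is.null(grouping)) return(factor(dataset$pop))
  if (is.null(names(grouping))) stop("grouping must be named by population_id")
  g <- grouping[dataset$pop]
  if (anyNA(g)) stop("populations missing from grouping: ",
                     paste(unique(dataset$pop[is.na(g)]), collapse = ", "))
  factor(unname(g))
}

# Weir-Cockerham variance components at one locus; returns c(a, abc) sums
.wc_locus <- function(A, grp) {
  ok <- !is.na(A[, 1])
  A <- A[ok, , drop = FALSE]; grp <- droplevels(grp[ok])
  nt <- table(grp)
  keep <- names(nt)[nt >= 2]
  if (length(keep) < 2) return(c(0, 0))
  sel <- grp %in% keep
  A <- A[sel, , drop = FALSE]; grp <- droplevels(grp[sel])
  r <- nlevels(grp)
  ni <- as.numeric(table(grp))
  N <- sum(ni); nbar <- N / r
  nc <- (N - sum(ni^2) / N) / (r - 1)
  alleles <- sort(unique(as.vector(A)))
  if (length(alleles) < 2) return(c(0, 0))
  a_sum <- 0; abc_sum <- 0
  gi <- as.integer(grp)
  for (u in alleles) {
    copies <- (A[, 1] == u) + (A[, 2] == u)
    p_i <- tapply(copies, gi, sum) / (2 * ni)
    h_i <- tapply(copies == 1, gi, mean)
    pbar <- sum(ni * p_i) / N
    s2 <- sum(ni * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * h_i) / N
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    c_ <- hbar / 2
    a_sum <- a_sum + a
    abc_sum <- abc_sum + a + b + c_
  }
  c(a_sum, abc_sum)
}

#' Weir-Cockerham F_ST (theta)
#'
#' Variance-component estimator of theta, loci combined by summing
#' components. Populations (or groups) with fewer than 2 typed individuals
#' at a locus are excluded from that locus.
#'
#' @param dataset an [msat_dataset()].
#' @param grouping optional named character vector mapping population ids to
#'   group labels; default treats each population as its own group.
#' @param pairwise also compute the matrix of pairwise theta (default TRUE).
#' @return list with `theta` (global), and when requested `pairwise`
#'   (symmetric matrix, zero diagonal).
#' @export
wc_fst <- function(dataset, grouping = NULL, pairwise = TRUE) {
  grp <- .group_of(dataset, grouping)
  L <- nrow(dataset$loci)
  comp_for <- function(keep_levels) {
    tot <- c(0, 0)
    for (l in seq_len(L)) {
      A <- dataset$alleles[, l, , drop = TRUE]
      if (is.null(dim(A))) A <- matrix(A, ncol = 2)
      sel <- grp %in% keep_levels
      tot <- tot + .wc_locus(A[sel, , drop = FALSE], factor(grp[sel], levels = keep_levels))
    }
    if (tot[2] == 0) NA_real_ else tot[1] / tot[2]
  }
  levs <- levels(grp)
  out <- list(theta = comp_for(levs))
  if (pairwise && length(levs) > 1) {
    M <- matrix(0, length(levs), length(levs), dimnames = list(levs, levs))
    for (i in seq_along(levs)[-length(levs)]) for (j in (i + 1):length(levs)) {
      M[i, j] <- M[j, i] <- comp_for(levs[c(i, j)])
    }
    out$pairwise <- M
  }
  out
}

# Per-locus data for size-based ANOVA: count matrix (groups x states) and
# per-state sizes in repeat units.
.rst_locus_data <- function(dataset, l, grp) {
  A <- dataset$alleles[, l, , drop = TRUE]
  if (is.null(dim(A))) A <- matrix(A, ncol = 2)
  ok <- !is.na(A[, 1])
  if (!any(ok)) return(NULL)
  sizes_bp <- as.vector(A[ok, ])
  g2 <- rep(grp[ok], 2)
  states <- sort(unique(sizes_bp))
  C <- table(factor(g2, levels = levels(grp)), factor(sizes_bp, levels = states))
  C <- matrix(as.numeric(C), nrow = nlevels(grp))
  sz <- (states - dataset$loci$offset[l]) / dataset$loci$motif_length[l]
  list(C = C, sizes = sz)
}

# variance components (sigma2_among, MSW) from count matrix + state sizes
.rst_components <- function(C, sizes) {
  m <- rowSums(C)
  use <- m >= 2
  C <- C[use, , drop = FALSE]; m <- m[use]
  r <- nrow(C)
  if (r < 2) return(c(0, 0))
  M <- sum(m)
  ybar_i <- as.vector(C %*% sizes) / m
  ybar <- sum(C %*% sizes) / M
  ss_i <- as.vector(C %*% sizes^2) - m * ybar_i^2
  MSW <- sum(ss_i) / (M - r)
  MSA <- sum(m * (ybar_i - ybar)^2) / (r - 1)
  nc <- (M - sum(m^2) / M) / (r - 1)
  c((MSA - MSW) / nc, MSW)
}

#' Slatkin's R_ST from allele sizes
#'
#' Allele-size analogue of F_ST: a one-way ANOVA of allele size (in repeat
#' units) on population groups at the gene-copy level;
#' `R_ST = sigma2_among / (sigma2_among + sigma2_within)`, loci combined by
#' summing variance components.
#'
#' @inheritParams wc_fst
#' @return list with `rst` (global; NA if the dataset is monomorphic in
#'   size) and optionally `pairwise`.
#' @export
rst <- function(dataset, grouping = NULL, pairwise = TRUE) {
  grp <- .group_of(dataset, grouping)
  L <- nrow(dataset$loci)
  dat <- lapply(seq_len(L), .rst_locus_data, dataset = dataset, grp = grp)
  rst_from <- function(rows_keep) {
    tot <- c(0, 0)
    for (d in dat) {
      if (is.null(d)) next
      tot <- tot + .rst_components(d$C[rows_keep, , drop = FALSE], d$sizes)
    }
    if (tot[1] + tot[2] <= 0) NA_real_ else tot[1] / (tot[1] + tot[2])
  }
  levs <- levels(grp)
  out <- list(rst = rst_from(seq_along(levs)))
  if (pairwise && length(levs) > 1) {
    M <- matrix(0, length(levs), length(levs), dimnames = list(levs, levs))
    for (i in seq_along(levs)[-length(levs)]) for (j in (i + 1):length(levs)) {
      M[i, j] <- M[j, i] <- rst_from(c(i, j))
    }
    out$pairwise <- M
  }
  out
}

#' Allele-size permutation test for phylogeographic signal
#'
#' Permutes the size labels among the distinct observed allele states within
#' each locus (a bijection of sizes over states, preserving all allele
#' frequencies) and recomputes R_ST. This erases stepwise-mutation memory
#' while retaining frequency differentiation, so the permuted R_ST behaves
#' like an F_ST estimate; an observed R_ST in the upper tail indicates
#' divergence carried by allele size (mutational, phylogeographic signal).
#'
#' @inheritParams wc_fst
#' @param n_perm number of permutations (default 20000; a warning is issued
#'   below 100).
#' @param seed optional integer seed.
#' @return list with `rst_obs`, `mean_rst_perm`, `p`
#'   (`Pr(R_STperm >= R_STobs)`, one-tailed, with +1 correction), `n_perm`,
#'   `seed`.
#' @export
allele_size_permutation_test <- function(dataset, grouping = NULL,
                                         n_perm = 20000, seed = NULL) {
  if (n_perm < 100) warning("n_perm < 100: p-value will be unstable")
  if (!is.null(seed)) set.seed(seed)
  grp <- .group_of(dataset, grouping)
  L <- nrow(dataset$loci)
  dat <- lapply(seq_len(L), .rst_locus_data, dataset = dataset, grp = grp)
  dat <- dat[!vapply(dat, is.null, TRUE)]
  rst_of <- function(size_list) {
    tot <- c(0, 0)
    for (i in seq_along(dat)) tot <- tot + .rst_components(dat[[i]]$C, size_list[[i]])
    if (tot[1] + tot[2] <= 0) NA_real_ else tot[1] / (tot[1] + tot[2])
  }
  obs <- rst_of(lapply(dat, `[[`, "sizes"))
  if (is.na(obs)) stop("R_ST undefined: dataset monomorphic in allele size")
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm[b] <- rst_of(lapply(dat, function(d) sample(d$sizes)))
  }
  hits <- sum(perm >= obs - 1e-12)
  list(rst_obs = obs, mean_rst_perm = mean(perm),
       p = (1 + hits) / (1 + n_perm), n_perm = n_perm, seed = seed)
}

#' Rousset's genetic distance
#'
#' Elementwise `F_ST / (1 - F_ST)`; entries at fixation (`F_ST = 1`) map to
#' `Inf` with a warning.
#'
#' @param fst scalar, vector or matrix of F_ST values (< 1).
#' @return transformed object of the same shape.
#' @export
rousset_distance <- function(fst) {
  if (any(fst == 1, na.rm = TRUE)) warning("F_ST = 1: infinite Rousset distance")
  fst / (1 - fst)
}

#' Goldstein's delta-mu-squared between two populations
#'
#' Squared difference of mean allele size (repeat units) per locus, plus the
#' across-locus mean. Loci untyped in either population are skipped.
#'
#' @param dataset an [msat_dataset()].
#' @param pop_pair length-2 vector of population ids.
#' @return list with `per_locus` and `mean`.
#' @export
delta_mu2 <- function(dataset, pop_pair) {
  ru <- repeat_units(dataset)
  L <- nrow(dataset$loci)
  per <- setNames(rep(NA_real_, L), dataset$loci$name)
  for (l in seq_len(L)) {
    m <- vapply(pop_pair, function(p) {
      v <- as.vector(ru[dataset$pop == p, l, ])
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, 0)
    if (!anyNA(m)) per[l] <- (m[1] - m[2])^2
  }
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Garza-Williamson M ratio
#'
#' `M = k / (r + 1)` per locus, with `k` the allele count and `r` the allele
#' size range in repeat units; depressed by bottlenecks (lost allele states
#' shrink `k` faster than `r`).
#'
#' @inheritParams observed_heterozygosity
#' @return list with `per_locus` and `mean`.
#' @export
garza_m <- function(dataset, population) {
  ru <- repeat_units(dataset)
  rows <- which(dataset$pop == population)
  L <- nrow(dataset$loci)
  per <- setNames(rep(NA_real_, L), dataset$loci$name)
  for (l in seq_len(L)) {
    v <- as.vector(ru[rows, l, ])
    v <- v[!is.na(v)]
    if (!length(v)) next
    per[l] <- length(unique(v)) / (max(v) - min(v) + 1)
  }
  list(per_locus = per, mean = mean(per, na.rm = TRUE))
}

#' Shared-allele distance between two populations
#'
#' `D_AS = 1 - mean_{x in A, y in B} ps(x, y)`, where `ps` is the proportion
#' of shared alleles between two individuals averaged over loci typed in
#' both (at one locus: the overlap of the two genotypes' allele multisets,
#' divided by 2).
#'
#' @inheritParams delta_mu2
#' @return scalar in `[0, 1]`.
#' @export
shared_allele_distance <- function(dataset, pop_pair) {
  ia <- which(dataset$pop == pop_pair[1])
  ib <- which(dataset$pop == pop_pair[2])
  if (!length(ia) || !length(ib)) stop("empty population")
  L <- nrow(dataset$loci)
  tot <- 0; npair <- 0
  for (x in ia) for (y in ib) {
    s <- 0; nl <- 0
    for (l in seq_len(L)) {
      gx <- dataset$alleles[x, l, ]; gy <- dataset$alleles[y, l, ]
      if (is.na(gx[1]) || is.na(gy[1])) next
      shared <- sum(pmin(table(factor(gx, levels = unique(c(gx, gy)))),
                         table(factor(gy, levels = unique(c(gx, gy))))))
      s <- s + shared / 2
      nl <- nl + 1
    }
    if (nl > 0) { tot <- tot + s / nl; npair <- npair + 1 }
  }
  1 - tot / npair
}
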