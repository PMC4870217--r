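## Lynch-Ritland pairwise relatedness and iterative kin pruning.

#' Lynch-Ritland pairwise relatedness matrix
#'
#' For reference individual x with alleles (a, b) and proband y with alleles
#' (c, d), the single-locus estimate is
#' \deqn{r = \frac{p_a(\delta_{bc}+\delta_{bd}) + p_b(\delta_{ac}+\delta_{ad})
#'   - 4 p_a p_b}{(1+\delta_{ab})(p_a+p_b) - 4 p_a p_b}}
#' with \eqn{\delta} Kronecker deltas and allele frequencies `p` computed over the
#' full dataset. Loci are combined by the Lynch-Ritland information weights
#' (the denominator divided by `2 p_a p_b`), and each unordered pair's
#' estimate is the arithmetic mean of the two reference choices.
#'
#' Loci that are uninformative for a given reference (zero denominator, e.g.
#' a heterozygote for two alleles both at frequency 0.5) are dropped from
#' that reference's weighted mean, as are loci missing in either individual.
#'
#' @param dataset an [msat_dataset()].
#' @return symmetric n x n matrix of relatedness estimates with NA diagonal;
#'   entries are NA for pairs sharing no usable locus.
#' @export
lynch_ritland_matrix <- function(dataset) {
  n <- length(dataset$ind)
  L <- nrow(dataset$loci)
  num <- matrix(0, n, n)   # sum_l w_l * r_l  (x = row = reference)
  den <- matrix(0, n, n)   # sum_l w_l
  for (l in seq_len(L)) {
    A <- dataset$alleles[, l, , drop = TRUE]
    if (is.null(dim(A))) A <- matrix(A, ncol = 2)
    typed <- !is.na(A[, 1])
    av <- as.vector(A[typed, ])
    frq <- table(av) / length(av)
    if (length(frq) < 2) next
    pa <- rep(NA_real_, n); pb <- rep(NA_real_, n)
    pa[typed] <- as.numeric(frq[as.character(A[typed, 1])])
    pb[typed] <- as.numeric(frq[as.character(A[typed, 2])])
    hom <- A[, 1] == A[, 2]
    dl <- (1 + as.numeric(hom)) * (pa + pb) - 4 * pa * pb
    wl <- dl / (2 * pa * pb)
    usable <- typed & is.finite(wl) & dl > 1e-12
    # pairwise delta terms: rows are reference x, cols proband y
    e11 <- outer(A[, 1], A[, 1], "==")
    e12 <- outer(A[, 1], A[, 2], "==")
    e21 <- outer(A[, 2], A[, 1], "==")
    e22 <- outer(A[, 2], A[, 2], "==")
    # numerator for x as reference: a = A[x,1], b = A[x,2]; c,d = proband
    numer <- pa * (e21 + e22) + pb * (e11 + e12) - 4 * pa * pb
    rl <- numer / dl
    ok <- outer(usable, typed, "&")
    contrib_n <- ifelse(ok, wl * rl, 0)
    contrib_d <- ifelse(ok, wl, 0)
    contrib_n[is.na(contrib_n)] <- 0
    contrib_d[is.na(contrib_d)] <- 0
    num <- num + contrib_n
    den <- den + contrib_d
  }
  directed <- num / den
  directed[den == 0] <- NA
  r <- (directed + t(directed)) / 2
  diag(r) <- NA
  dimnames(r) <- list(dataset$ind, dataset$ind)
  r
}

#' Iterative kin pruning of a relatedness matrix
#'
#' Individuals are ranked by the number of pairwise comparisons in which
#' they exceed the relatedness threshold; the highest-ranked individual is
#' removed, ranks are recomputed, and the procedure repeats until no pair
#' exceeds the threshold. Pairs wholly inside an exempt population are never
#' counted (nor required to be resolved).
#'
#' Rank ties are broken deterministically: higher mean relatedness over the
#' individual's above-threshold pairs first, then lexicographically smaller
#' id.
#'
#' @param rmat symmetric relatedness matrix with individual ids as dimnames
#'   (e.g. from [lynch_ritland_matrix()]).
#' @param threshold pairs with relatedness above this value count as kin (strict
#'   inequality; default 0.25, the half-sib expectation).
#' @param pop optional character vector of population ids (same order as
#'   `rmat` rows); required when `exempt_populations` is non-empty.
#' @param exempt_populations populations whose within-population pairs are
#'   exempt from pruning.
#' @return list with `kept` (character ids) and `removed` (data.frame with
#'   columns `id`, `rank` at removal).
#' @export
prune_related <- function(rmat, threshold = 0.25, pop = NULL,
                          exempt_populations = character()) {
  if (!isSymmetric(unname(ifelse(is.na(rmat), 0, rmat))))
    stop("relatedness matrix must be symmetric")
  ids <- rownames(rmat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(rmat)))
  count_mat <- !is.na(rmat) & rmat > threshold
  diag(count_mat) <- FALSE
  if (length(exempt_populations)) {
    if (is.null(pop)) stop("pop required with exempt_populations")
    ex <- pop %in% exempt_populations
    exempt_pair <- outer(ex, ex, "&") & outer(pop, pop, "==")
    count_mat[exempt_pair] <- FALSE
  }
  alive <- rep(TRUE, length(ids))
  removed <- list()
  repeat {
    cm <- count_mat & outer(alive, alive, "&")
    ranks <- rowSums(cm)
    if (max(ranks) == 0) break
    cand <- which(ranks == max(ranks))
    if (length(cand) > 1) {
      meanr <- vapply(cand, function(i) mean(rmat[i, cm[i, ]], na.rm = TRUE), 0)
      cand <- cand[meanr == max(meanr)]
      if (length(cand) > 1) cand <- cand[order(ids[cand])][1]
    }
    i <- cand[1]
    removed[[length(removed) + 1]] <- data.frame(id = ids[i], rank = ranks[i],
                                                 stringsAsFactors = FALSE)
    alive[i] <- FALSE
  }
  list(kept = ids[alive],
       removed = if (length(removed)) do.call(rbind, removed)
       else data.frame(id = character(), rank = integer()))
}

#' Prune a dataset to a kin-free sample
#'
#' Convenience wrapper: computes the Lynch-Ritland matrix, prunes, and
#' returns the reduced dataset together with the removal log.
#'
#' @param dataset an [msat_dataset()].
#' @inheritParams prune_related
#' @return list with `dataset` (pruned), `kept`, `removed`, `rmat`.
#' @export
prune_dataset <- function(dataset, threshold = 0.25,
                          exempt_populations = character()) {
  rmat <- lynch_ritland_matrix(dataset)
  pr <- prune_related(rmat, threshold = threshold, pop = dataset$pop,
                      exempt_populations = exempt_populations)
  list(dataset = subset_dataset(dataset, ind = pr$kept),
       kept = pr$kept, removed = pr$removed, rmat = rmat)
}
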