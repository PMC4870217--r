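## Geographic / indicator distance matrices and (partial) Mantel tests of
## isolation by distance.

#' Great-circle distance matrix between population centroids
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param meta population metadata from [read_population_meta()].
#' @return symmetric matrix of distances in km, populations as dimnames;
#'   attribute `kind = "geographic"`.
#' @export
great_circle_matrix <- function(meta) {
  if (anyNA(meta$latitude) || anyNA(meta$longitude)) stop("missing coordinates")
  n <- nrow(meta)
  xy <- cbind(meta$longitude, meta$latitude)
  M <- matrix(0, n, n, dimnames = list(meta$population_id, meta$population_id))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j) {
    d <- geosphere::distHaversine(xy[i, ], xy[j, ], r = 6371000) / 1000
    M[i, j] <- M[j, i] <- d
  }
  attr(M, "kind") <- "geographic"
  M
}

#' Binary indicator matrix from a group assignment
#'
#' Pairwise comparisons are coded 0 when both populations belong to the same
#' group and 1 when they belong to different groups.
#'
#' @param meta population metadata (uses `population_id`).
#' @param group_assignment named character vector mapping population ids to
#'   group labels; defaults to `meta$group_label`.
#' @return symmetric 0/1 matrix, zero diagonal; attribute `kind = "indicator"`.
#' @export
indicator_matrix <- function(meta, group_assignment = NULL) {
  if (is.null(group_assignment))
    group_assignment <- setNames(meta$group_label, meta$population_id)
  g <- group_assignment[meta$population_id]
  if (anyNA(g)) stop("unassigned population(s): ",
                     paste(meta$population_id[is.na(g)], collapse = ", "))
  M <- 1 - outer(g, g, "==") * 1
  dimnames(M) <- list(meta$population_id, meta$population_id)
  diag(M) <- 0
  attr(M, "kind") <- "indicator"
  M
}

.upper <- function(M) M[upper.tri(M)]

#' Mantel test
#'
#' Pearson correlation of the off-diagonal upper triangles of two symmetric
#' matrices, with significance from simultaneous row/column permutation of
#' the second matrix. The tail is directional: `tail = "greater"` tests
#' `Pr(r_perm >= r_obs)` and `"less"` the opposite; `"two.sided"` doubles
#' the smaller tail.
#'
#' @param A,B conformable symmetric matrices.
#' @param n_perm number of permutations (default 30000).
#' @param seed optional integer seed.
#' @param log_transform_B apply `log` to the off-diagonal entries of `B`
#'   (e.g. log geographic distance); zero distances are an error.
#' @param tail `"greater"`, `"less"` or `"two.sided"`.
#' @return list with `r`, `p`, `n_perm`, `tail`.
#' @export
mantel_test <- function(A, B, n_perm = 30000, seed = NULL,
                        log_transform_B = FALSE, tail = "greater") {
  stopifnot(all(dim(A) == dim(B)))
  if (!is.null(seed)) set.seed(seed)
  if (log_transform_B) {
    if (any(.upper(B) <= 0)) stop("log transform of non-positive distance")
    Bt <- B
    Bt[upper.tri(Bt) | lower.tri(Bt)] <- log(B[upper.tri(B) | lower.tri(B)])
    B <- Bt
  }
  va <- .upper(A)
  if (stats::sd(va) == 0 || stats::sd(.upper(B)) == 0)
    stop("zero variance in a distance triangle")
  r_obs <- stats::cor(va, .upper(B))
  n <- nrow(A)
  rp <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    o <- sample.int(n)
    rp[b] <- stats::cor(va, .upper(B[o, o]))
  }
  p_ge <- (1 + sum(rp >= r_obs - 1e-12)) / (1 + n_perm)
  p_le <- (1 + sum(rp <= r_obs + 1e-12)) / (1 + n_perm)
  p <- switch(tail,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)),
              stop("unknown tail"))
  list(r = r_obs, p = p, n_perm = n_perm, tail = tail)
}

#' Partial Mantel test
#'
#' Correlation of `A` and `B` after removing the linear effect of `C` from
#' both triangles; significance by permutation of the residuals of `A | C`
#' (residual matrix rows/columns permuted jointly, Legendre's method).
#'
#' @inheritParams mantel_test
#' @param C control matrix.
#' @return list with `r`, `p`, `n_perm`, `tail`.
#' @export
partial_mantel_test <- function(A, B, C, n_perm = 10000, seed = NULL,
                                tail = "greater") {
  stopifnot(all(dim(A) == dim(B)), all(dim(A) == dim(C)))
  if (!is.null(seed)) set.seed(seed)
  va <- .upper(A); vb <- .upper(B); vc <- .upper(C)
  if (stats::sd(vc) == 0) stop("control matrix has zero variance")
  if (abs(stats::cor(vb, vc)) > 1 - 1e-10)
    stop("control matrix perfectly collinear with B")
  resid_of <- function(v) stats::residuals(stats::lm(v ~ vc))
  ra <- resid_of(va); rb <- resid_of(vb)
  r_obs <- stats::cor(ra, rb)
  # square residual matrix of A|C for joint row/column permutation
  n <- nrow(A)
  RA <- matrix(0, n, n)
  RA[upper.tri(RA)] <- ra
  RA <- RA + t(RA)
  rp <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    o <- sample.int(n)
    rap <- .upper(RA[o, o])
    rp[b] <- stats::cor(stats::residuals(stats::lm(rap ~ vc)), rb)
  }
  p_ge <- (1 + sum(rp >= r_obs - 1e-12)) / (1 + n_perm)
  p_le <- (1 + sum(rp <= r_obs + 1e-12)) / (1 + n_perm)
  p <- switch(tail,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)),
              stop("unknown tail"))
  list(r = r_obs, p = p, n_perm = n_perm, tail = tail)
}

#' Drop populations below a minimum sample size
#'
#' @param dataset an [msat_dataset()].
#' @param min_n minimum number of sampled individuals (default 10).
#' @return list with `dataset` (reduced) and `removed` (data.frame of
#'   population id and sample size).
#' @export
filter_small_populations <- function(dataset, min_n = 10) {
  sizes <- table(dataset$pop)
  drop <- names(sizes)[sizes < min_n]
  if (length(drop) == length(sizes)) stop("all populations below min_n")
  keep <- setdiff(names(sizes), drop)
  ds <- if (length(drop)) subset_dataset(dataset, pop = keep) else dataset
  list(dataset = ds,
       removed = data.frame(population_id = drop,
                            n = as.integer(sizes[drop]),
                            stringsAsFactors = FALSE))
}
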