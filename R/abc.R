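## Approximate Bayesian computation: summary statistics, reference tables,
## scenario choice by local multinomial logistic regression, parameter
## estimation by local linear regression, and validation machinery.

.stat_names <- function(demes, holdout = FALSE) {
  P <- length(demes)
  pr <- utils::combn(P, 2)
  pairs <- paste0(demes[pr[1, ]], ".", demes[pr[2, ]])
  nm <- c(paste0("kA_", demes), paste0("HE_", demes), paste0("VAR_", demes),
          paste0("FST_", pairs), paste0("DMU_", pairs))
  if (holdout)
    nm <- c(nm, "GWM", paste0("KPOOL_", pairs), paste0("VPOOL_", pairs),
            paste0("DAS_", pairs))
  nm
}

# collapse a dataset onto analysis demes (drops unassigned populations)
.deme_dataset <- function(dataset, partition) {
  demes <- partition[dataset$pop]
  keep <- !is.na(demes)
  msat_dataset(dataset$alleles[keep, , , drop = FALSE], dataset$ind[keep],
               unname(demes[keep]), dataset$loci, family = dataset$family[keep])
}

#' ABC summary-statistic vector of a dataset
#'
#' Fixed ordering contract over the analysis demes: per-deme mean allele
#' count, per-deme mean unbiased gene diversity, per-deme mean allele-size
#' variance (repeat units), then pairwise Weir-Cockerham F_ST and pairwise
#' delta-mu-squared, pairs in lexicographic deme order.
#'
#' @param dataset an [msat_dataset()].
#' @param partition named character vector mapping population ids to deme
#'   labels (NULL: populations are the demes). Deme order follows first
#'   appearance in `partition`.
#' @return named numeric vector of length `3P + 2 * choose(P, 2)`.
#' @export
summary_vector <- function(dataset, partition = NULL) {
  if (is.null(partition)) {
    demes <- unique(dataset$pop)
    ds <- dataset
  } else {
    demes <- unique(unname(partition))
    ds <- .deme_dataset(dataset, partition)
  }
  if (!all(demes %in% ds$pop)) stop("empty deme in partition")
  ru <- repeat_units(ds)
  L <- nrow(ds$loci)
  P <- length(demes)
  kA <- He <- Va <- numeric(P)
  for (d in seq_len(P)) {
    rows <- which(ds$pop == demes[d])
    if (!length(rows)) stop("empty deme: ", demes[d])
    kl <- hl <- vl <- rep(NA_real_, L)
    for (l in seq_len(L)) {
      v <- as.vector(ru[rows, l, ])
      v <- v[!is.na(v)]
      if (length(v) < 2) next
      kl[l] <- length(unique(v))
      p <- table(v) / length(v)
      hl[l] <- (length(v) / (length(v) - 1)) * (1 - sum(p^2))
      vl[l] <- stats::var(v)
    }
    kA[d] <- mean(kl, na.rm = TRUE)
    He[d] <- mean(hl, na.rm = TRUE)
    Va[d] <- mean(vl, na.rm = TRUE)
  }
  pr <- utils::combn(P, 2)
  fst <- dmu <- numeric(ncol(pr))
  for (k in seq_len(ncol(pr))) {
    pair <- demes[pr[, k]]
    sub <- subset_dataset(ds, pop = pair)
    th <- wc_fst(sub, pairwise = FALSE)$theta
    fst[k] <- if (is.na(th)) 0 else th
    dmu[k] <- delta_mu2(ds, pair)$mean
  }
  stats::setNames(c(kA, He, Va, fst, dmu), .stat_names(demes))
}

#' Holdout summary statistics for posterior-predictive model checking
#'
#' Statistics deliberately disjoint from [summary_vector()]: global mean
#' Garza-Williamson M (over demes and loci), and per deme pair the pooled
#' two-sample mean allele count, pooled mean allele-size variance, and
#' shared-allele distance.
#'
#' @inheritParams summary_vector
#' @return named numeric vector of length `1 + 3 * choose(P, 2)`.
#' @export
holdout_vector <- function(dataset, partition = NULL) {
  if (is.null(partition)) {
    demes <- unique(dataset$pop); ds <- dataset
  } else {
    demes <- unique(unname(partition)); ds <- .deme_dataset(dataset, partition)
  }
  ru <- repeat_units(ds)
  L <- nrow(ds$loci)
  P <- length(demes)
  gw <- unlist(lapply(demes, function(d) garza_m(ds, d)$per_locus))
  pr <- utils::combn(P, 2)
  kp <- vp <- das <- numeric(ncol(pr))
  for (k in seq_len(ncol(pr))) {
    pair <- demes[pr[, k]]
    rows <- which(ds$pop %in% pair)
    kl <- vl <- rep(NA_real_, L)
    for (l in seq_len(L)) {
      v <- as.vector(ru[rows, l, ])
      v <- v[!is.na(v)]
      if (length(v) < 2) next
      kl[l] <- length(unique(v))
      vl[l] <- stats::var(v)
    }
    kp[k] <- mean(kl, na.rm = TRUE)
    vp[k] <- mean(vl, na.rm = TRUE)
    das[k] <- shared_allele_distance(ds, pair)
  }
  stats::setNames(c(mean(gw, na.rm = TRUE), kp, vp, das),
                  .stat_names(demes, holdout = TRUE)[-seq_len(3 * P + 2 * ncol(pr))])
}

# parameter bounds (for logit transforms) of a scenario's parameter columns
.param_bounds <- function(spec, mut_model) {
  b <- rbind(as.matrix(spec$params[, c("min", "max")]))
  rownames(b) <- spec$params$name
  G <- mut_model$n_groups
  hy <- rbind(matrix(mut_model$mean_rate_bounds, G, 2, byrow = TRUE),
              matrix(mut_model$pgsm_bounds, G, 2, byrow = TRUE))
  rownames(hy) <- c(paste0("mean_rate", seq_len(G)), paste0("pgsm", seq_len(G)))
  rbind(b, hy)
}

#' Build an ABC reference table by prior-predictive simulation
#'
#' For each scenario kind: draw parameters from the priors, build the
#' scenario, simulate a dataset of the configured sample sizes under the
#' mutation model (hyper-parameters redrawn per dataset), and record the
#' summary-statistic vector.
#'
#' @param kinds character vector of scenario kinds (see [build_scenario()]).
#' @param priors named list of [prior_spec()] objects (names = kinds);
#'   NULL uses the default spec for each kind.
#' @param n_per_scenario simulations per scenario (>= 100).
#' @param seed integer seed.
#' @param pop_config optional list with `deme_names`, `sample_sizes`.
#' @param mut_model a [mutation_model()].
#' @param workers number of worker processes (forked); 1 = serial.
#' @return object of class `abc_reftable`: list with `kinds`, `scenario`
#'   (integer index per row), `stats` (matrix), `params` (list of matrices,
#'   one per kind), `bounds` (per kind), `priors`, `pop_config`,
#'   `mut_model`, `seed`.
#' @export
build_reference_table <- function(kinds, priors = NULL, n_per_scenario = 1000,
                                  seed = 1, pop_config = NULL,
                                  mut_model = mutation_model(), workers = 1) {
  if (n_per_scenario < 100) stop("n_per_scenario must be >= 100")
  if (is.null(priors)) priors <- stats::setNames(lapply(kinds, prior_spec), kinds)
  demes <- if (!is.null(pop_config$deme_names)) pop_config$deme_names else DEFAULT_DEMES
  ss <- if (!is.null(pop_config$sample_sizes)) pop_config$sample_sizes else DEFAULT_SAMPLES
  pop_idx <- rep(seq_along(demes), ss)
  snames <- .stat_names(demes)
  one_block <- function(k, block_seed) {
    set.seed(block_seed)
    spec <- priors[[kinds[k]]]
    stats_m <- matrix(NA_real_, n_per_scenario, length(snames))
    params_m <- NULL
    fails <- 0
    i <- 1
    while (i <= n_per_scenario) {
      th <- sample_priors(spec)
      res <- tryCatch({
        sc <- build_scenario(kinds[k], th, pop_config)
        real <- .realize_mutation(mut_model)
        genes <- .sim_gene_matrix(sc, real)
        list(st = cpp_dataset_stats(genes, pop_idx, length(demes), FALSE),
             pv = c(th, real$hyper))
      }, error = function(e) NULL)
      if (is.null(res)) {
        fails <- fails + 1
        if (fails > 0.01 * n_per_scenario + 10)
          stop("simulation failure rate above 1% for scenario ", kinds[k])
        next
      }
      if (is.null(params_m))
        params_m <- matrix(NA_real_, n_per_scenario, length(res$pv),
                           dimnames = list(NULL, names(res$pv)))
      stats_m[i, ] <- res$st
      params_m[i, ] <- res$pv
      i <- i + 1
    }
    colnames(stats_m) <- snames
    list(stats = stats_m, params = params_m)
  }
  set.seed(seed)
  block_seeds <- sample.int(2^31 - 2, length(kinds))
  blocks <- if (workers > 1) {
    parallel::mcmapply(one_block, seq_along(kinds), block_seeds,
                       SIMPLIFY = FALSE, mc.cores = workers)
  } else {
    mapply(one_block, seq_along(kinds), block_seeds, SIMPLIFY = FALSE)
  }
  structure(list(kinds = kinds,
                 scenario = rep(seq_along(kinds), each = n_per_scenario),
                 stats = do.call(rbind, lapply(blocks, `[[`, "stats")),
                 params = lapply(blocks, `[[`, "params"),
                 bounds = lapply(kinds, function(k) .param_bounds(priors[[k]], mut_model)),
                 priors = priors, pop_config = list(deme_names = demes, sample_sizes = ss),
                 mut_model = mut_model, n_per_scenario = n_per_scenario,
                 seed = seed),
            class = "abc_reftable")
}

#' @export
print.abc_reftable <- function(x, ...) {
  cat("abc_reftable:", length(x$scenario), "simulations,",
      length(x$kinds), "scenarios (", paste(x$kinds, collapse = ", "), ")\n")
  invisible(x)
}

#' Persist / load a reference table as CSV plus a JSON sidecar
#'
#' @param table an `abc_reftable`.
#' @param path base path (writes `<path>.csv` and `<path>.json`).
#' @return base path, invisibly.
#' @export
write_reference_table <- function(table, path) {
  wide <- data.frame(scenario = table$kinds[table$scenario], table$stats,
                     check.names = FALSE)
  utils::write.csv(wide, paste0(path, ".csv"), row.names = FALSE)
  for (k in seq_along(table$kinds))
    utils::write.csv(as.data.frame(table$params[[k]]),
                     paste0(path, "_params_", table$kinds[k], ".csv"),
                     row.names = FALSE)
  jsonlite::write_json(list(kinds = table$kinds, seed = table$seed,
                            n_per_scenario = table$n_per_scenario,
                            deme_names = table$pop_config$deme_names,
                            sample_sizes = unname(table$pop_config$sample_sizes)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

# robust standardization scales from the pooled reference table
.robust_scale <- function(stats_m) {
  med <- apply(stats_m, 2, stats::median)
  madv <- apply(stats_m, 2, stats::mad)
  madv[madv < 1e-12] <- NA   # uninformative columns are dropped from distances
  list(center = med, scale = madv)
}

.abc_retain <- function(stats_m, observed, tolerance) {
  sc <- .robust_scale(stats_m)
  use <- which(!is.na(sc$scale))
  Z <- sweep(sweep(stats_m[, use, drop = FALSE], 2, sc$center[use]),
             2, sc$scale[use], "/")
  zo <- (observed[use] - sc$center[use]) / sc$scale[use]
  d <- sqrt(rowSums(sweep(Z, 2, zo)^2))
  n_ret <- max(1L, ceiling(tolerance * nrow(stats_m)))
  idx <- order(d)[seq_len(n_ret)]
  dmax <- max(d[idx])
  w <- if (dmax > 0) 1 - (d[idx] / dmax)^2 else rep(1, n_ret)
  w[w <= 0] <- min(w[w > 0], 1e-8)
  list(idx = idx, w = w, Z = Z[idx, , drop = FALSE], zo = zo, d = d)
}

#' ABC scenario choice by local multinomial logistic regression
#'
#' Summaries are standardized by the reference table's median and MAD, the
#' `tolerance` fraction of simulations closest to the observed vector (in
#' Euclidean distance) is retained with Epanechnikov weights, and a
#' multinomial logistic regression of scenario label on the standardized
#' summary deviations is evaluated at the observed point (deviation zero).
#' Confidence limits come from the regression's asymptotic covariance
#' (parametric draws of the coefficients). If a scenario is absent from the
#' retained set, the weighted rejection-count estimate is returned instead,
#' flagged as `method = "rejection"`.
#'
#' @param table an `abc_reftable`.
#' @param observed named numeric vector from [summary_vector()].
#' @param tolerance fraction of simulations retained (default 0.01);
#'   `tolerance * nrow >= 50` is required.
#' @param n_ci_draws coefficient draws for the confidence limits.
#' @return object of class `abc_model_choice`: data.frame `posterior` with
#'   columns `scenario`, `prob`, `lower`, `upper`; plus `method`,
#'   `tolerance`, `n_retained`.
#' @export
model_choice_logistic <- function(table, observed, tolerance = 0.01,
                                  n_ci_draws = 200) {
  n <- nrow(table$stats)
  if (tolerance * n < 50)
    stop("tolerance * rows must be >= 50 (got ", tolerance * n, ")")
  ret <- .abc_retain(table$stats, observed, tolerance)
  scen <- factor(table$kinds[table$scenario[ret$idx]], levels = table$kinds)
  K <- length(table$kinds)
  probs <- rep(0, K); lower <- rep(0, K); upper <- rep(1, K)
  if (any(tabulate(scen, K) == 0) || K == 1) {
    wt <- tapply(ret$w, scen, sum, default = 0)
    probs <- as.numeric(wt / sum(wt))
    method <- "rejection"
    # binomial-style limits on the weighted counts
    ess <- sum(ret$w)^2 / sum(ret$w^2)
    se <- sqrt(pmax(probs * (1 - probs) / ess, 0))
    lower <- pmax(0, probs - 1.96 * se); upper <- pmin(1, probs + 1.96 * se)
  } else {
    df <- data.frame(scen = scen, ret$Z, check.names = FALSE)
    fit <- nnet::multinom(scen ~ ., data = df, weights = ret$w, trace = FALSE,
                          MaxNWts = 5000, maxit = 400)
    at0 <- as.data.frame(matrix(ret$zo, 1, dimnames = list(NULL, colnames(ret$Z))))
    probs <- as.numeric(stats::predict(fit, newdata = at0, type = "probs"))
    if (length(probs) == 1) probs <- c(1 - probs, probs)  # K = 2 case
    method <- "logistic"
    ci <- tryCatch({
      cf <- stats::coef(fit)
      if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
      vc <- stats::vcov(fit)
      Lc <- tryCatch(chol(vc + diag(1e-10, nrow(vc))), error = function(e) NULL)
      if (is.null(Lc)) NULL else {
        x0 <- c(1, ret$zo)
        draws <- matrix(NA_real_, n_ci_draws, K)
        cfv <- as.vector(t(cf))
        for (b in seq_len(n_ci_draws)) {
          z <- cfv + as.vector(t(Lc) %*% stats::rnorm(length(cfv)))
          cb <- matrix(z, nrow = nrow(cf), byrow = TRUE)
          eta <- c(0, as.vector(cb %*% x0))
          draws[b, ] <- exp(eta - max(eta)) / sum(exp(eta - max(eta)))
        }
        list(lower = apply(draws, 2, stats::quantile, 0.025),
             upper = apply(draws, 2, stats::quantile, 0.975))
      }
    }, error = function(e) NULL)
    if (!is.null(ci)) { lower <- ci$lower; upper <- ci$upper }
    else { lower <- rep(NA_real_, K); upper <- rep(NA_real_, K) }
  }
  structure(list(posterior = data.frame(scenario = table$kinds, prob = probs,
                                        lower = lower, upper = upper,
                                        stringsAsFactors = FALSE),
                 method = method, tolerance = tolerance,
                 n_retained = length(ret$idx)),
            class = "abc_model_choice")
}

#' @export
print.abc_model_choice <- function(x, ...) {
  cat("ABC scenario choice (", x$method, ", ", x$n_retained, " retained)\n",
      sep = "")
  print(x$posterior, row.names = FALSE, digits = 3)
  invisible(x)
}

.wquantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], 0)
}

#' ABC parameter estimation by local linear regression
#'
#' Beaumont-style adjustment: parameters of the retained simulations of one
#' scenario are logit-transformed onto their prior bounds, regressed
#' (weighted) on the standardized summary deviations, shifted to the
#' observed point by subtracting the fitted linear trend, back-transformed
#' and summarized by weighted quantiles. The logit transform guarantees the
#' adjusted draws stay inside the prior support.
#'
#' @param table an `abc_reftable`.
#' @param observed named numeric vector from [summary_vector()].
#' @param scenario scenario kind (or index) whose parameters to estimate.
#' @param tolerance fraction of that scenario's simulations retained.
#' @param adjust apply the regression adjustment (default TRUE; FALSE gives
#'   the plain rejection posterior).
#' @return object of class `abc_param_estimate`: data.frame `estimates`
#'   with `parameter`, `median`, `lower`, `upper` (2.5/97.5% quantiles);
#'   plus the weighted `posterior_sample` matrix, `weights`, `adjusted`
#'   flag.
#' @export
estimate_parameters <- function(table, observed, scenario, tolerance = 0.01,
                                adjust = TRUE) {
  k <- if (is.character(scenario)) match(scenario, table$kinds) else scenario
  if (is.na(k)) stop("unknown scenario")
  rows <- which(table$scenario == k)
  ret <- .abc_retain(table$stats[rows, , drop = FALSE], observed, tolerance)
  P <- table$params[[k]][ret$idx, , drop = FALSE]
  bounds <- table$bounds[[k]]
  bn <- rownames(bounds)
  # align bounds to parameter columns (hyper names carry group suffixes)
  bmat <- t(vapply(colnames(P), function(nm) {
    j <- match(nm, bn)
    if (is.na(j)) j <- match(sub("[0-9]+$", "", nm), sub("[0-9]+$", "", bn))
    bounds[j, ]
  }, c(0, 0)))
  eps <- 1e-10
  to_logit <- function(x, a, b) {
    z <- pmin(pmax((x - a) / (b - a), eps), 1 - eps)
    log(z / (1 - z))
  }
  from_logit <- function(y, a, b) a + (b - a) / (1 + exp(-y))
  adj <- P
  adjusted_flag <- FALSE
  if (adjust) {
    X <- sweep(ret$Z, 2, ret$zo)   # deviations; observed point at 0
    ok <- TRUE
    for (j in seq_len(ncol(P))) {
      y <- to_logit(P[, j], bmat[j, 1], bmat[j, 2])
      fit <- tryCatch(stats::lm.wfit(cbind(1, X), y, ret$w),
                      error = function(e) NULL)
      if (is.null(fit) || anyNA(fit$coefficients[1])) { ok <- FALSE; break }
      beta <- fit$coefficients[-1]
      beta[is.na(beta)] <- 0
      ystar <- y - as.vector(X %*% beta)
      adj[, j] <- from_logit(ystar, bmat[j, 1], bmat[j, 2])
    }
    adjusted_flag <- ok
    if (!ok) adj <- P   # singular design: fall back to rejection posterior
  }
  est <- data.frame(parameter = colnames(P),
                    median = apply(adj, 2, function(v) .wquantile(v, ret$w, 0.5)),
                    lower = apply(adj, 2, function(v) .wquantile(v, ret$w, 0.025)),
                    upper = apply(adj, 2, function(v) .wquantile(v, ret$w, 0.975)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(estimates = est, posterior_sample = adj, weights = ret$w,
                 scenario = table$kinds[k], adjusted = adjusted_flag,
                 tolerance = tolerance),
            class = "abc_param_estimate")
}

#' @export
print.abc_param_estimate <- function(x, ...) {
  cat("ABC parameter estimates, scenario ", x$scenario,
      if (!x$adjusted) " (unadjusted rejection posterior)", "\n", sep = "")
  print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Type I / type II error of ABC scenario choice on pseudo-observed data
#'
#' Simulates pseudo-observed datasets with known parameters drawn from the
#' priors: type I is the fraction of datasets simulated under the focal
#' scenario for which the focal scenario does not attain the highest
#' posterior probability; type II is the fraction of datasets simulated
#' under competing scenarios for which it does.
#'
#' @param table an `abc_reftable` (provides priors, scenarios, design).
#' @param focal focal scenario kind.
#' @param n_pseudo pseudo-observed datasets per side (default 500; a
#'   warning is issued below 20).
#' @param tolerance model-choice tolerance.
#' @param seed integer seed.
#' @return list with `type1`, `type2`, and a `details` data.frame (true
#'   scenario, selected scenario, focal posterior probability).
#' @export
confidence_evaluation <- function(table, focal, n_pseudo = 500,
                                  tolerance = 0.01, seed = 1) {
  if (n_pseudo < 20) warning("n_pseudo < 20: error rates will be unstable")
  set.seed(seed)
  kinds <- table$kinds
  if (!focal %in% kinds) stop("focal scenario not in table")
  competitors <- setdiff(kinds, focal)
  truth <- c(rep(focal, n_pseudo),
             rep(competitors, length.out = n_pseudo))
  sel <- character(length(truth)); pfocal <- numeric(length(truth))
  demes <- table$pop_config$deme_names
  pop_idx <- rep(seq_along(demes), table$pop_config$sample_sizes)
  for (i in seq_along(truth)) {
    th <- sample_priors(table$priors[[truth[i]]])
    sc <- build_scenario(truth[i], th, table$pop_config)
    real <- .realize_mutation(table$mut_model)
    st <- cpp_dataset_stats(.sim_gene_matrix(sc, real), pop_idx,
                            length(demes), FALSE)
    names(st) <- colnames(table$stats)
    mc <- model_choice_logistic(table, st, tolerance)
    sel[i] <- mc$posterior$scenario[which.max(mc$posterior$prob)]
    pfocal[i] <- mc$posterior$prob[mc$posterior$scenario == focal]
  }
  under_focal <- truth == focal
  list(type1 = mean(sel[under_focal] != focal),
       type2 = mean(sel[!under_focal] == focal),
       details = data.frame(truth = truth, selected = sel,
                            p_focal = pfocal, stringsAsFactors = FALSE))
}

#' Relative median absolute error of parameter estimates
#'
#' `RMAE = median over datasets of |estimate - truth| / truth`, one value
#' per parameter. Datasets with zero truth are excluded and flagged.
#'
#' @param pseudo_fits data.frame with columns `parameter`, `truth`,
#'   `estimate` (one row per parameter per pseudo-observed dataset).
#' @return named numeric vector of RMAE per parameter; attribute
#'   `n_excluded` counts zero-truth exclusions.
#' @export
rmae <- function(pseudo_fits) {
  zero <- pseudo_fits$truth == 0
  d <- pseudo_fits[!zero, , drop = FALSE]
  out <- tapply(abs(d$estimate - d$truth) / abs(d$truth), d$parameter,
                stats::median)
  out <- out[unique(pseudo_fits$parameter)]
  attr(out, "n_excluded") <- sum(zero)
  out
}

#' Posterior-predictive model checking on holdout statistics
#'
#' Draws parameter vectors from the fitted posterior sample (weighted),
#' simulates datasets, and locates each observed holdout statistic within
#' its posterior-predictive distribution. Reported per statistic is the
#' lower-tail probability `(1 + #{sim <= obs}) / (n + 1)`; values near 0 or
#' 1 indicate misfit.
#'
#' @param fitted an `abc_param_estimate` for the chosen scenario.
#' @param table the `abc_reftable` the fit came from.
#' @param observed_holdout named vector from [holdout_vector()].
#' @param n number of posterior-predictive simulations (default 10000).
#' @param seed integer seed.
#' @return named numeric vector of tail probabilities.
#' @export
model_check <- function(fitted, table, observed_holdout, n = 10000, seed = 1) {
  set.seed(seed)
  kind <- fitted$scenario
  spec <- table$priors[[kind]]
  demes <- table$pop_config$deme_names
  pop_idx <- rep(seq_along(demes), table$pop_config$sample_sizes)
  post <- fitted$posterior_sample
  wp <- fitted$weights / sum(fitted$weights)
  mm <- table$mut_model
  G <- mm$n_groups
  sims <- matrix(NA_real_, n, length(observed_holdout))
  npair <- choose(length(demes), 2)
  holdout_cols <- function(st) st[(length(st) - 3 * npair):length(st)]
  i <- 1; guard <- 0
  while (i <= n) {
    row <- post[sample.int(nrow(post), 1, prob = wp), ]
    th <- row[spec$params$name]
    cond_ok <- all(vapply(spec$conditions,
                          function(cc) isTRUE(eval(parse(text = cc), as.list(th))), TRUE))
    if (!cond_ok) {
      guard <- guard + 1
      if (guard > 50 * n) stop("posterior sample violates scenario conditions")
      next
    }
    mm_i <- mutation_model(motif_lengths = mm$motif_lengths,
                           mean_rate = unname(row[paste0("mean_rate", seq_len(G))]),
                           pgsm = unname(row[paste0("pgsm", seq_len(G))]),
                           rate_shape = mm$rate_shape,
                           n_states = mm$hi - mm$lo + 1, range_lo = mm$lo)
    sc <- build_scenario(kind, th, table$pop_config)
    real <- .realize_mutation(mm_i)
    st <- cpp_dataset_stats(.sim_gene_matrix(sc, real), pop_idx,
                            length(demes), TRUE)
    sims[i, ] <- holdout_cols(st)
    i <- i + 1
  }
  p <- vapply(seq_along(observed_holdout), function(j)
    (1 + sum(sims[, j] <= observed_holdout[j])) / (n + 1), 0)
  stats::setNames(p, names(observed_holdout))
}
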