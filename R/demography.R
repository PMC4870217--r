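## Demographic scenarios, prior specifications, the coalescent simulator
## wrapper, and generation-time conversions.

DEFAULT_DEMES <- c("South", "McKinley", "MariposaNelder", "TuolumneMerced",
                   "Calaveras")
DEFAULT_SAMPLES <- c(South = 200L, McKinley = 19L, MariposaNelder = 44L,
                     TuolumneMerced = 16L, Calaveras = 50L)

#' Low-level demographic scenario
#'
#' A set of demes with current diploid effective sizes and an ordered
#' backward-time event list. Events (times in generations before present):
#' `merge` moves all lineages of deme `a` into deme `b`; `size_change` sets
#' deme `a`'s size to `b` for all older times. A forward-time founder
#' bottleneck is encoded as a `size_change` to the founder size shortly
#' before (backward of) the colonization merge.
#'
#' @param deme_sizes named numeric vector of current diploid sizes (>= 2).
#' @param events data.frame with columns `time`, `kind` ("merge" or
#'   "size_change"), `a`, `b` (deme indices; for `size_change`, `b` is the
#'   new size).
#' @param sample_sizes named integer vector of diploid individuals sampled
#'   per deme.
#' @param kind optional scenario label.
#' @param params optional named parameter vector kept for provenance.
#' @return object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(deme_sizes, events, sample_sizes,
                                 kind = "custom", params = NULL) {
  D <- length(deme_sizes)
  if (is.null(names(deme_sizes))) names(deme_sizes) <- paste0("deme", seq_len(D))
  if (any(deme_sizes < 2)) stop("deme sizes must be >= 2")
  if (nrow(events)) {
    if (any(events$time < 0)) stop("event times must be non-negative")
    o <- order(events$time, seq_len(nrow(events)))
    events <- events[o, , drop = FALSE]
    szl <- events$b[events$kind == "size_change"]
    if (any(szl < 2)) stop("sizes in size_change events must be >= 2")
  }
  sample_sizes <- sample_sizes[names(deme_sizes)]
  sample_sizes[is.na(sample_sizes)] <- 0L
  # structural coalescence check: demes holding samples must merge to one
  active <- which(sample_sizes > 0)
  if (length(active) > 1) {
    cur <- as.list(seq_len(D))
    for (r in which(events$kind == "merge")) {
      a <- events$a[r]; b <- events$b[r]
      cur[[b]] <- union(cur[[b]], cur[[a]]); cur[[a]] <- integer(0)
    }
    holders <- Filter(function(s) any(s %in% active), cur)
    if (length(holders) > 1)
      stop("non-coalescing event structure: sampled demes never share an ancestor")
  }
  structure(list(deme_names = names(deme_sizes),
                 deme_sizes = unname(deme_sizes),
                 events = events,
                 sample_sizes = unname(as.integer(sample_sizes)),
                 kind = kind, params = params),
            class = "demographic_scenario")
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat("demographic_scenario (", x$kind, "): ", length(x$deme_sizes),
      " demes, ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

# events as the numeric matrix the C++ simulator consumes
.events_matrix <- function(scenario) {
  ev <- scenario$events
  if (!nrow(ev)) return(matrix(0, 0, 4))
  cbind(ev$time, ifelse(ev$kind == "merge", 0, 1), ev$a, ev$b)
}

SCENARIO_KINDS <- c("stepping_stone", "mass_colonization",
                    "simultaneous_divergence", "ancient_divergence")

#' Build one of the four competing divergence scenarios
#'
#' Five demes (southern groves pooled, McKinley, Mariposa+Nelder,
#' Tuolumne+Merced, the Calaveras pair) with current sizes `N1..N5`.
#' `stepping_stone`: the south colonizes McKinley at `t_col1` (the oldest
#' event, forward in time first), which seeds Mariposa+Nelder, then
#' Tuolumne+Merced, then Calaveras, each colonization followed by a founder
#' bottleneck (`founder_N` for `bn_duration` generations).
#' `mass_colonization`: all four northern demes are founded from the south
#' at `t_col1`, with bottlenecks. `simultaneous_divergence`: all five demes
#' split at `t_div1` from a population of size `N_div` that itself had
#' declined from an ancestral size `N_anc` at `t_anc`.
#' `ancient_divergence`: the same structure with a deep-past split time
#' `t_div2`. In every scenario the terminal ancestral deme changes to size
#' `N_anc` at `t_anc`, which must predate all splits.
#'
#' @param kind one of `"stepping_stone"`, `"mass_colonization"`,
#'   `"simultaneous_divergence"`, `"ancient_divergence"`.
#' @param params named vector: `N1..N5`, `N_anc`, `t_anc`, plus per kind
#'   `t_col1..t_col4`/`founder_N`/`bn_duration` (stepping stone), `t_col1`/
#'   `founder_N`/`bn_duration` (mass colonization), `t_div1`/`N_div`
#'   (simultaneous divergence) or `t_div2`/`N_div` (ancient divergence).
#' @param pop_config optional list with `deme_names` and `sample_sizes`.
#' @return a [demographic_scenario()].
#' @export
build_scenario <- function(kind, params, pop_config = NULL) {
  kind <- match.arg(kind, SCENARIO_KINDS)
  p <- as.list(params)
  demes <- if (!is.null(pop_config$deme_names)) pop_config$deme_names else DEFAULT_DEMES
  ss <- if (!is.null(pop_config$sample_sizes)) pop_config$sample_sizes else DEFAULT_SAMPLES
  sizes <- setNames(as.numeric(p[paste0("N", 1:5)]), demes)
  ev <- list()
  add <- function(time, kind_, a, b)
    ev[[length(ev) + 1]] <<- data.frame(time = time, kind = kind_, a = a, b = b)
  if (kind == "stepping_stone") {
    tc <- as.numeric(p[c("t_col1", "t_col2", "t_col3", "t_col4")])
    if (!(tc[1] > tc[2] && tc[2] > tc[3] && tc[3] > tc[4]))
      stop("condition violated: colonization times must satisfy t_col1 > t_col2 > t_col3 > t_col4")
    if (p$bn_duration >= tc[4])
      stop("condition violated: bn_duration must be shorter than the most recent colonization time")
    if (p$t_anc <= tc[1]) stop("condition violated: t_anc must predate all colonizations")
    # forward chain: 1 -> 2 at t_col1 (oldest), 2 -> 3, 3 -> 4, 4 -> 5 at
    # t_col4 (most recent); backward, each colonized deme merges into its
    # source, preceded by its founder bottleneck window
    for (i in 1:4) {
      d_col <- i + 1
      add(tc[i] - p$bn_duration, "size_change", d_col, p$founder_N)
      add(tc[i], "merge", d_col, i)
    }
  } else if (kind == "mass_colonization") {
    if (p$bn_duration >= p$t_col1)
      stop("condition violated: bn_duration must be shorter than t_col1")
    if (p$t_anc <= p$t_col1) stop("condition violated: t_anc must predate t_col1")
    for (d in 2:5) {
      add(p$t_col1 - p$bn_duration, "size_change", d, p$founder_N)
      add(p$t_col1, "merge", d, 1)
    }
  } else {
    tdiv <- if (kind == "simultaneous_divergence") p$t_div1 else p$t_div2
    if (is.null(tdiv)) stop("missing divergence time")
    if (p$t_anc <= tdiv) stop("condition violated: t_anc must predate the divergence")
    for (d in 2:5) add(tdiv, "merge", d, 1)
    add(tdiv, "size_change", 1, p$N_div)
  }
  add(p$t_anc, "size_change", 1, p$N_anc)
  demographic_scenario(sizes, do.call(rbind, ev), ss, kind = kind,
                       params = unlist(p))
}

#' Uniform prior specification for a scenario kind
#'
#' Default bounds: `N1` in `[100, 10000]`, `N2..N5` in `[10, 1000]`,
#' `N_div` in `[100, 10000]`, `N_anc` in `[100, 100000]`, recent
#' colonization/divergence times in `[10, 1000]` generations, `t_div2` in
#' `[1000, 10000]`, `t_anc` in `[100, 10000]`, `founder_N` in `[2, 100]`,
#' `bn_duration` in `[1, 50]`; conditions make `t_anc` predate all splits,
#' order stepping-stone colonizations, and keep bottlenecks shorter than the
#' youngest colonization. All bounds are overridable.
#'
#' @param kind scenario kind (see [build_scenario()]).
#' @param overrides optional named list of `c(min, max)` bounds.
#' @return object of class `prior_spec`: list with `kind`, `params`
#'   (data.frame name/min/max) and `conditions` (character predicates).
#' @export
prior_spec <- function(kind, overrides = NULL) {
  kind <- match.arg(kind, SCENARIO_KINDS)
  b <- list(N1 = c(100, 10000), N2 = c(10, 1000), N3 = c(10, 1000),
            N4 = c(10, 1000), N5 = c(10, 1000), N_anc = c(100, 1e5),
            t_anc = c(100, 10000))
  if (kind == "stepping_stone") {
    b <- c(b, list(t_col1 = c(10, 1000), t_col2 = c(10, 1000),
                   t_col3 = c(10, 1000), t_col4 = c(10, 1000),
                   founder_N = c(2, 100), bn_duration = c(1, 50)))
    cond <- c("t_col1 > t_col2", "t_col2 > t_col3", "t_col3 > t_col4",
              "bn_duration < t_col4", "t_anc > t_col1")
  } else if (kind == "mass_colonization") {
    b <- c(b, list(t_col1 = c(10, 1000), founder_N = c(2, 100),
                   bn_duration = c(1, 50)))
    cond <- c("bn_duration < t_col1", "t_anc > t_col1")
  } else if (kind == "simultaneous_divergence") {
    b <- c(b, list(t_div1 = c(10, 1000), N_div = c(100, 10000)))
    cond <- "t_anc > t_div1"
  } else {
    b <- c(b, list(t_div2 = c(1000, 10000), N_div = c(100, 10000)))
    cond <- "t_anc > t_div2"
  }
  if (!is.null(overrides)) for (nm in names(overrides)) b[[nm]] <- overrides[[nm]]
  params <- data.frame(name = names(b),
                       min = vapply(b, `[`, 0, 1),
                       max = vapply(b, `[`, 0, 2),
                       row.names = NULL, stringsAsFactors = FALSE)
  if (any(params$min >= params$max)) stop("prior bounds: min must be < max")
  structure(list(kind = kind, params = params, conditions = cond),
            class = "prior_spec")
}

#' Draw a parameter vector from a prior specification
#'
#' Independent uniforms with rejection sampling until all inter-parameter
#' conditions hold.
#'
#' @param spec a [prior_spec()].
#' @param max_reject abort after this many consecutive rejections (the spec
#'   is then deemed unsatisfiable).
#' @return named numeric parameter vector.
#' @export
sample_priors <- function(spec, max_reject = 1e5) {
  pr <- spec$params
  for (i in seq_len(max_reject + 1)) {
    x <- stats::runif(nrow(pr), pr$min, pr$max)
    names(x) <- pr$name
    env <- as.list(x)
    ok <- all(vapply(spec$conditions,
                     function(cc) isTRUE(eval(parse(text = cc), env)), TRUE))
    if (ok) return(x)
  }
  stop("unsatisfiable prior specification: ", max_reject, " rejections")
}

#' Generalized stepwise mutation model for a microsatellite panel
#'
#' Loci are grouped by motif length (all dinucleotide loci in one group, the
#' trinucleotide locus in another). Each group has a mean mutation rate per
#' generation and a geometric step parameter `P` (`P = 0` is the strict
#' one-step SMM); per-locus rates scatter about the group mean as a Gamma
#' with shape `rate_shape`. Allele sizes live on a bounded ladder of
#' `n_states` contiguous repeat counts, enforced by reflection. Leaving
#' `mean_rate` / `pgsm` as `NULL` makes them hyper-parameters drawn
#' uniformly from `mean_rate_bounds` / `pgsm_bounds` at simulation time (one
#' draw per group per dataset), the prior-predictive behaviour the ABC layer
#' uses.
#'
#' @param motif_lengths integer vector of per-locus motif lengths (defines
#'   the groups; default ten dinucleotide loci and one trinucleotide locus).
#' @param mean_rate per-group mean rate (single value recycled), or NULL.
#' @param pgsm per-group geometric parameter in `[0, 1)`, or NULL.
#' @param mean_rate_bounds,pgsm_bounds hyper-prior bounds.
#' @param rate_shape Gamma shape for per-locus rate scatter; `Inf` means all
#'   loci share the group mean exactly.
#' @param n_states number of allowed repeat states (default 40).
#' @param range_lo smallest repeat count on the ladder (default 10).
#' @return object of class `mutation_model`.
#' @export
mutation_model <- function(motif_lengths = c(rep(2L, 10), 3L),
                           mean_rate = NULL, pgsm = NULL,
                           mean_rate_bounds = c(1e-4, 1e-3),
                           pgsm_bounds = c(0.1, 0.3),
                           rate_shape = 2, n_states = 40, range_lo = 10) {
  if (!is.null(pgsm) && any(pgsm < 0 | pgsm >= 1)) stop("pgsm must be in [0, 1)")
  if (!is.null(mean_rate) && any(mean_rate <= 0)) stop("mean_rate must be > 0")
  structure(list(motif_lengths = as.integer(motif_lengths),
                 groups = match(motif_lengths, sort(unique(motif_lengths))),
                 n_groups = length(unique(motif_lengths)),
                 mean_rate = mean_rate, pgsm = pgsm,
                 mean_rate_bounds = mean_rate_bounds,
                 pgsm_bounds = pgsm_bounds,
                 rate_shape = rate_shape,
                 lo = as.integer(range_lo),
                 hi = as.integer(range_lo + n_states - 1)),
            class = "mutation_model")
}

# Draw the concrete per-locus rates / P for one simulated dataset.
.realize_mutation <- function(mm) {
  G <- mm$n_groups
  mr <- mm$mean_rate
  if (is.null(mr)) mr <- stats::runif(G, mm$mean_rate_bounds[1], mm$mean_rate_bounds[2])
  mr <- rep_len(mr, G)
  pg <- mm$pgsm
  if (is.null(pg)) pg <- stats::runif(G, mm$pgsm_bounds[1], mm$pgsm_bounds[2])
  pg <- rep_len(pg, G)
  L <- length(mm$motif_lengths)
  rate <- numeric(L)
  for (l in seq_len(L)) {
    m <- mr[mm$groups[l]]
    rate[l] <- if (is.finite(mm$rate_shape))
      stats::rgamma(1, shape = mm$rate_shape, rate = mm$rate_shape / m) else m
  }
  list(rate = rate, pgsm = pg[mm$groups], lo = mm$lo, hi = mm$hi,
       root = as.integer(floor((mm$lo + mm$hi) / 2)),
       hyper = c(mean_rate = mr, pgsm = pg))
}

# gene-copy matrix (2n x L, repeat units) for one simulated dataset
.sim_gene_matrix <- function(scenario, real) {
  cpp_sim_dataset(2L * scenario$sample_sizes, scenario$deme_sizes,
                  .events_matrix(scenario), real$rate, real$pgsm,
                  real$lo, real$hi, real$root)
}

#' Simulate a genotype dataset under a demographic scenario
#'
#' Runs the continuous-time coalescent per locus (exponential waiting times,
#' piecewise-constant deme sizes, backward-time merges) and drops GSM
#' mutations on the branches as Poisson events; gene copies are paired into
#' diploid individuals. Allele sizes are reported in bp
#' (`repeat count x motif length`).
#'
#' @param scenario a [demographic_scenario()].
#' @param mut_model a [mutation_model()].
#' @param seed optional integer seed.
#' @return an [msat_dataset()] with the scenario's demes as populations.
#' @export
simulate_genotypes <- function(scenario, mut_model = mutation_model(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(scenario$sample_sizes < 1 & scenario$sample_sizes != 0))
    stop("sample sizes must be >= 1 (or 0 to skip a deme)")
  real <- .realize_mutation(mut_model)
  genes <- .sim_gene_matrix(scenario, real)
  n_ind <- nrow(genes) / 2
  L <- ncol(genes)
  motif <- mut_model$motif_lengths
  alleles <- array(NA_integer_, dim = c(n_ind, L, 2))
  for (l in seq_len(L)) {
    alleles[, l, 1] <- genes[seq(1, 2 * n_ind, by = 2), l] * motif[l]
    alleles[, l, 2] <- genes[seq(2, 2 * n_ind, by = 2), l] * motif[l]
  }
  pops <- rep(scenario$deme_names, scenario$sample_sizes)
  ids <- paste0(pops, "_", unlist(lapply(scenario$sample_sizes[scenario$sample_sizes > 0],
                                         seq_len)))
  loci <- locus_def(sprintf("L%02d_%s", seq_len(L), ifelse(motif == 2, "di", "tri")),
                    motif_length = motif)
  msat_dataset(alleles, ids, pops, loci)
}

#' Mean pairwise coalescence times and tree lengths (diagnostic)
#'
#' Simulates genealogies only (no mutation) and returns tree height and
#' total branch length per replicate; used to verify the simulator against
#' coalescent theory (`E[TMRCA] = 2N` for a pair, total length
#' `4N sum 1/i`).
#'
#' @param scenario a [demographic_scenario()].
#' @param reps number of replicates.
#' @param seed optional integer seed.
#' @return data.frame with columns `height`, `length`.
#' @export
simulate_tmrca <- function(scenario, reps = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- cpp_sim_tmrca(2L * scenario$sample_sizes, scenario$deme_sizes,
                     .events_matrix(scenario), reps)
  data.frame(height = m[, 1], length = m[, 2])
}

#' Generation time by the Lande life-history formula
#'
#' `T = alpha + s / (lambda - s)` with `alpha` the age at sexual maturity in
#' years, `s` the adult survival term and `lambda` the population growth
#' term (about 1 for a stable population). Requires `lambda > s`.
#'
#' @param alpha age at sexual maturity (years).
#' @param s survival term.
#' @param lambda growth term (default 1).
#' @return generation time in years.
#' @export
generation_time <- function(alpha, s, lambda = 1) {
  if (any(lambda <= s)) stop("lambda must exceed s")
  alpha + s / (lambda - s)
}

#' Convert generations to absolute time
#'
#' @param g time in generations (>= 0).
#' @param T_years generation time in years.
#' @return list with `years`, `kya`, `Mya`.
#' @export
generations_to_years <- function(g, T_years) {
  if (any(g < 0)) stop("g must be >= 0")
  y <- g * T_years
  list(years = y, kya = y / 1000, Mya = y / 1e6)
}
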