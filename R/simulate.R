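#' Simulation configuration for trio count data
#'
#' Describes a synthetic trio RNA-seq experiment: two hybrid/parent trios
#' under WW, WD and RW with three replicates reproduce the 54-library
#' design the pipeline targets. Counts are negative binomial with variance
#' `mu + alpha * mu^2`; each gene carries a per-trio inheritance mode and a
#' shared condition-response direction as ground truth.
#'
#' Mode construction on the WW baseline `b` (log2 expected counts), with
#' `D = effect_log2fc` and parent split `hi = 2^(b + D/2)`,
#' `lo = 2^(b - D/2)`:
#' additive -> hybrid = (P1 + P2)/2 on the linear scale; high/low dominance
#' -> hybrid = max/min(P1, P2); overdominant -> hybrid = max(P1, P2) * 2^D
#' with both parents at `2^b`; underdominant -> hybrid = min(P1, P2) / 2^D;
#' PAV I -> both parents expressed, hybrid mean exactly 0; PAV II -> one
#' parent expressed only; PAV III -> hybrid only; PAV IV -> hybrid plus one
#' parent. `up_WD` multiplies every WD mean by `2^D`, `down_WD` divides;
#' with probability `reset_prob` a responding gene's RW mean reverts to its
#' WW mean, otherwise it stays at the WD level.
#'
#' @param n_genes number of genes.
#' @param trios named list of trio specs, each a named character vector
#'   `c(hybrid=, parent1=, parent2=)` of genotype display ids.
#' @param conditions ordered subset of `c("WW","WD","RW")`.
#' @param n_replicates replicates per cell (>= 2).
#' @param lib_size_mean expected reads per library.
#' @param lib_size_cv coefficient of variation of library sizes.
#' @param dispersion NB dispersion alpha (> 0; variance `mu + alpha mu^2`).
#' @param mode_proportions simplex over the nine mode labels.
#' @param response_proportions simplex over `c(up_WD, down_WD, null)`.
#' @param reset_prob probability that a responding gene's RW mean reverts
#'   to the WW mean (default 0.6).
#' @param effect_log2fc magnitude of mode and response effects (log2).
#' @param baseline_logmean_range range of the WW baseline log2 mean.
#' @param seed integer seed driving per-gene substreams.
#' @param shared_modes draw one mode per gene applied to every trio
#'   (default FALSE: independent per-trio draws).
#' @param response_coupling `"independent"` (default: response drawn from
#'   `response_proportions`) or `"dominance"`: overdominant genes respond
#'   `up_WD`, underdominant genes `down_WD`, all others are null — the
#'   construction used to benchmark conserved dominance-overlap recovery.
#'   `"dominance"` requires `shared_modes = TRUE`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       trios = list(
                         AB = c(hybrid = "AB", parent1 = "AA", parent2 = "BB"),
                         CD = c(hybrid = "CD", parent1 = "CC", parent2 = "DD")),
                       conditions = c("WW", "WD", "RW"),
                       n_replicates = 3,
                       lib_size_mean = 1.5e6,
                       lib_size_cv = 0.1,
                       dispersion = 0.05,
                       mode_proportions = c(
                         additive = 0.40, high_dom = 0.15, low_dom = 0.15,
                         overdominant = 0.08, underdominant = 0.08,
                         pav_I = 0.03, pav_II = 0.04, pav_III = 0.03,
                         pav_IV = 0.04),
                       response_proportions = c(up_WD = 0.25, down_WD = 0.25,
                                                null = 0.50),
                       reset_prob = 0.6,
                       effect_log2fc = 2,
                       baseline_logmean_range = c(4, 12),
                       seed = 1,
                       shared_modes = FALSE,
                       response_coupling = c("independent", "dominance")) {
  response_coupling <- match.arg(response_coupling)
  if (response_coupling == "dominance" && !shared_modes)
    stop("response_coupling='dominance' requires shared_modes=TRUE")
  mode_labels <- c("additive", "high_dom", "low_dom", "overdominant",
                   "underdominant", "pav_I", "pav_II", "pav_III", "pav_IV")
  if (n_genes < 1) stop("zero genes")
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (!all(conditions %in% valid_conditions)) stop("invalid condition label")
  if (!setequal(names(mode_proportions), mode_labels) ||
      abs(sum(mode_proportions) - 1) > 1e-8 || any(mode_proportions < 0))
    stop("mode_proportions must be a simplex over the nine mode labels")
  if (!setequal(names(response_proportions), c("up_WD", "down_WD", "null")) ||
      abs(sum(response_proportions) - 1) > 1e-8 || any(response_proportions < 0))
    stop("response_proportions must be a simplex over up_WD/down_WD/null")
  if (reset_prob < 0 || reset_prob > 1) stop("reset_prob must be in [0, 1]")
  if (effect_log2fc <= 0) stop("effect_log2fc must be positive")
  structure(list(
    n_genes = as.integer(n_genes), trios = trios, conditions = conditions,
    n_replicates = as.integer(n_replicates), lib_size_mean = lib_size_mean,
    lib_size_cv = lib_size_cv, dispersion = dispersion,
    mode_proportions = mode_proportions[mode_labels],
    response_proportions = response_proportions[c("up_WD", "down_WD", "null")],
    reset_prob = reset_prob, effect_log2fc = effect_log2fc,
    baseline_logmean_range = baseline_logmean_range, seed = as.integer(seed),
    shared_modes = isTRUE(shared_modes),
    response_coupling = response_coupling),
    class = "sim_config")
}

# deterministic per-gene substream seed; independent of gene order
substream_seed <- function(seed, index) {
  as.integer((as.double(seed %% 100000L) * 1000003 + index) %% 2147483647)
}

# linear-scale (p1, p2, f1) WW means for one mode.
# swap flips which parent carries the high/expressed allele.
mode_ww_means <- function(mode, b, D, swap) {
  B <- 2^b; hi <- 2^(b + D / 2); lo <- 2^(b - D / 2)
  m <- switch(mode,
    additive      = c(hi, lo, (hi + lo) / 2),
    high_dom      = c(hi, lo, hi),
    low_dom       = c(hi, lo, lo),
    overdominant  = c(B, B, B * 2^D),
    underdominant = c(B, B, B / 2^D),
    pav_I         = c(B, B, 0),
    pav_II        = c(B, 0, 0),
    pav_III       = c(0, 0, B),
    pav_IV        = c(B, 0, B),
    stop("unknown mode: ", mode))
  if (swap) m[1:2] <- m[2:1]
  stats::setNames(m, c("parent1", "parent2", "hybrid"))
}

#' Simulate trio count data with ground truth
#'
#' Draws NB counts for the design in `config` and returns both the
#' expression set and the generating truth (per-gene mode per trio,
#' response direction, reset flag, and true means per role x condition).
#' Deterministic given `config$seed`; each gene uses its own RNG substream
#' so results do not depend on gene order.
#'
#' @param config a [sim_config()].
#' @return list with elements `es` (a `TrioExpressionSet`) and `truth`
#'   (class `SimTruth`: `genes` data.frame and `means` data.frame of true
#'   `mu` per gene x trio x role x condition).
#' @export
simulate_trios <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  gene_ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  trio_ids <- names(cfg$trios)
  roles <- c("hybrid", "parent1", "parent2")

  # per-gene generating parameters (substream 2g)
  n_tr <- length(trio_ids)
  baseline <- numeric(cfg$n_genes)
  modes <- matrix("", cfg$n_genes, n_tr, dimnames = list(gene_ids, trio_ids))
  swaps <- matrix(FALSE, cfg$n_genes, n_tr)
  response <- character(cfg$n_genes)
  reset <- logical(cfg$n_genes)
  mode_labels <- names(cfg$mode_proportions)
  resp_labels <- c("up", "down", "null")
  for (g in seq_len(cfg$n_genes)) {
    set.seed(substream_seed(cfg$seed, 2 * g))
    baseline[g] <- stats::runif(1, cfg$baseline_logmean_range[1],
                                cfg$baseline_logmean_range[2])
    modes[g, ] <- if (cfg$shared_modes)
      rep(sample(mode_labels, 1, prob = cfg$mode_proportions), n_tr)
    else sample(mode_labels, n_tr, replace = TRUE, prob = cfg$mode_proportions)
    swaps[g, ] <- stats::runif(n_tr) < 0.5
    response[g] <- if (cfg$response_coupling == "dominance")
      switch(modes[g, 1], overdominant = "up", underdominant = "down", "null")
    else sample(resp_labels, 1,
                prob = c(cfg$response_proportions[["up_WD"]],
                         cfg$response_proportions[["down_WD"]],
                         cfg$response_proportions[["null"]]))
    reset[g] <- response[g] != "null" && stats::runif(1) < cfg$reset_prob
  }

  # true means per gene x trio x role x condition
  D <- cfg$effect_log2fc
  mu <- array(0, dim = c(cfg$n_genes, n_tr, 3, length(cfg$conditions)),
              dimnames = list(gene_ids, trio_ids, roles, cfg$conditions))
  for (g in seq_len(cfg$n_genes)) {
    resp_mult <- switch(response[g], up = 2^D, down = 2^-D, null = 1)
    for (t in seq_len(n_tr)) {
      ww <- mode_ww_means(modes[g, t], baseline[g], D, swaps[g, t])
      for (cond in cfg$conditions) {
        mult <- if (cond == "WW") 1
                else if (cond == "WD") resp_mult
                else if (reset[g] || response[g] == "null") 1 else resp_mult
        mu[g, t, , cond] <- ww[roles] * mult
      }
    }
  }

  # sample sheet
  sheet <- expand.grid(replicate = seq_len(cfg$n_replicates),
                       condition = cfg$conditions, role = roles,
                       trio_id = trio_ids, stringsAsFactors = FALSE)
  geno <- mapply(function(tr, ro) cfg$trios[[tr]][[ro]],
                 sheet$trio_id, sheet$role)
  sheet$sample_id <- paste(geno, sheet$condition, sheet$replicate, sep = "_")
  sheet <- sheet[, c("sample_id", "trio_id", "role", "condition", "replicate")]

  # library-size factors (substream 0): lognormal with mean 1, given CV,
  # then scaled so each library's expected total is lib_size_mean
  set.seed(substream_seed(cfg$seed, 0L))
  sigma <- sqrt(log(1 + cfg$lib_size_cv^2))
  f <- stats::rlnorm(nrow(sheet), meanlog = -sigma^2 / 2, sdlog = sigma)
  exp_tot <- vapply(seq_len(nrow(sheet)), function(j) {
    sum(mu[, sheet$trio_id[j], sheet$role[j], sheet$condition[j]])
  }, 0)
  s <- f * cfg$lib_size_mean / exp_tot

  # counts (substream 2g + 1)
  counts <- matrix(0, cfg$n_genes, nrow(sheet),
                   dimnames = list(gene_ids, sheet$sample_id))
  size <- 1 / cfg$dispersion
  mu_col_idx <- cbind(match(sheet$trio_id, trio_ids),
                      match(sheet$role, roles),
                      match(sheet$condition, cfg$conditions))
  for (g in seq_len(cfg$n_genes)) {
    set.seed(substream_seed(cfg$seed, 2 * g + 1))
    mug <- mu[cbind(g, mu_col_idx)] * s
    counts[g, ] <- stats::rnbinom(nrow(sheet), mu = mug, size = size)
  }

  es <- trio_expression_set(counts, sheet)
  genes <- do.call(rbind, lapply(seq_len(n_tr), function(t) {
    data.frame(gene_id = gene_ids, trio_id = trio_ids[t],
               mode = modes[, t], response = response, reset = reset,
               baseline_log2 = baseline, stringsAsFactors = FALSE,
               row.names = NULL)
  }))
  means <- as.data.frame.table(mu, responseName = "mu",
                               stringsAsFactors = FALSE)
  names(means) <- c("gene_id", "trio_id", "role", "condition", "mu")
  truth <- structure(list(genes = genes, means = means,
                          lib_factors = stats::setNames(s, sheet$sample_id),
                          config = cfg),
                     class = "SimTruth")
  list(es = es, truth = truth)
}

#' Simulate replicated phenotype measurements
#'
#' Draws normal replicates (truncated at zero by resampling) around given
#' genotype means for each condition — the synthetic analog of ear and
#' kernel trait tables used for heterosis indices.
#'
#' @param trait_specs list of specs, each a list with elements `trait`
#'   (name), `genotypes` (named character vector `c(hybrid=, parent1=,
#'   parent2=)`), `means` (named list per condition of numeric vectors
#'   `c(hybrid=, parent1=, parent2=)` of positive means), `sd`
#'   (replicate standard deviation, >= 0) and `n_rep` (>= 2).
#' @param seed integer seed.
#' @return a `PhenotypeTable` data.frame.
#' @export
simulate_phenotypes <- function(trait_specs, seed = 1) {
  rows <- list()
  for (i in seq_along(trait_specs)) {
    ts <- trait_specs[[i]]
    if (is.null(ts$n_rep) || ts$n_rep < 2) stop("n_rep must be >= 2")
    if (is.null(ts$sd) || ts$sd < 0) stop("sd must be >= 0")
    set.seed(substream_seed(seed, i))
    for (cond in names(ts$means)) {
      mm <- ts$means[[cond]]
      if (any(mm <= 0)) stop("non-positive phenotype mean")
      for (role in names(ts$genotypes)) {
        m <- mm[[role]]
        vals <- stats::rnorm(ts$n_rep, m, ts$sd)
        while (any(vals <= 0))
          vals[vals <= 0] <- stats::rnorm(sum(vals <= 0), m, ts$sd)
        rows[[length(rows) + 1]] <- data.frame(
          trait = ts$trait, genotype_id = ts$genotypes[[role]],
          condition = cond, replicate = seq_len(ts$n_rep), value = vals,
          stringsAsFactors = FALSE)
      }
    }
  }
  validate_phenotypes(do.call(rbind, rows))
}

#' Simulate a term annotation with known enrichment
#'
#' Builds an `AnnotationMap` over the simulated gene universe in which a
#' fraction of terms is deliberately packed with genes of one truth class
#' (an inheritance mode in the first trio, or a response direction) while
#' the remaining terms draw genes uniformly. The packing record is attached
#' as attribute `sim_truth` for recovery testing.
#'
#' @param truth a `SimTruth` from [simulate_trios()].
#' @param n_terms number of terms (0 gives an empty map).
#' @param enriched_fraction fraction of terms packed with one class.
#' @param seed integer seed.
#' @param term_size mean term size (Poisson, shifted by 5).
#' @param packing fraction of a packed term drawn from its class (default 0.8).
#' @return an [annotation_map()]; empty-universe-safe.
#' @export
simulate_annotation <- function(truth, n_terms = 50, enriched_fraction = 0.2,
                                seed = 1, term_size = 30, packing = 0.8) {
  stopifnot(inherits(truth, "SimTruth"))
  if (n_terms == 0) {
    am <- annotation_map(stats::setNames(list(), character()))
    attr(am, "sim_truth") <- data.frame(term_id = character(),
                                        class = character())
    return(am)
  }
  universe <- unique(truth$genes$gene_id)
  first_trio <- truth$genes$trio_id[1]
  g1 <- truth$genes[truth$genes$trio_id == first_trio, ]
  classes <- list()
  for (m in unique(g1$mode)) classes[[paste0("mode:", m)]] <- g1$gene_id[g1$mode == m]
  for (r in c("up", "down")) {
    gs <- unique(truth$genes$gene_id[truth$genes$response == r])
    if (length(gs)) classes[[paste0("response:", r)]] <- gs
  }
  set.seed(substream_seed(seed, 97L))
  n_enriched <- round(n_terms * enriched_fraction)
  terms <- list(); rec <- character(n_terms)
  for (i in seq_len(n_terms)) {
    k <- 5 + stats::rpois(1, term_size - 5)
    k <- min(k, length(universe))
    if (i <= n_enriched && length(classes)) {
      cl <- sample(names(classes), 1)
      pool <- classes[[cl]]
      n_in <- min(length(pool), round(packing * k))
      genes <- c(sample(pool, n_in),
                 sample(setdiff(universe, pool), k - n_in))
      rec[i] <- cl
    } else {
      genes <- sample(universe, k)
      rec[i] <- "uniform"
    }
    terms[[sprintf("T%04d", i)]] <- unique(genes)
  }
  am <- annotation_map(terms)
  attr(am, "sim_truth") <- data.frame(term_id = names(terms), class = rec,
                                      stringsAsFactors = FALSE)
  am
}
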