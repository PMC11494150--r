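#' Median-of-ratios size factors
#'
#' Library-size normalisation factors computed as the median across genes of
#' each sample's ratio to the per-gene geometric-mean reference, rescaled so
#' that the factors have geometric mean 1. Genes with a zero count in any
#' sample drop out of the reference; if no gene is expressed in every
#' sample the function falls back to total-count scaling and records a
#' warning.
#'
#' @param counts non-negative matrix, genes x samples.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    warning("no gene expressed in all samples; falling back to total-count scaling")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(tot)))
    return(stats::setNames(sf, colnames(counts)))
  }
  m <- counts[all_pos, , drop = FALSE]
  ref <- exp(rowMeans(log(m)))
  sf <- apply(m / ref, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' FPKM from counts and gene lengths
#'
#' `fpkm[g, j] = counts[g, j] * 1e9 / (length_g * N_j)` where `N_j` is the
#' sample's library size: the raw column total (`raw_total`) or the column
#' total after median-of-ratios normalisation (`normalized_total`).
#'
#' @param counts genes x samples matrix.
#' @param gene_lengths named vector of union-exon lengths (bp) covering
#'   every gene in `counts`.
#' @param size_basis library-size definition, see above.
#' @return FPKM matrix of the same shape.
#' @export
fpkm <- function(counts, gene_lengths,
                 size_basis = c("raw_total", "normalized_total")) {
  size_basis <- match.arg(size_basis)
  counts <- as.matrix(counts)
  len <- gene_lengths[rownames(counts)]
  if (any(is.na(len)))
    stop("missing length for counted gene(s): ",
         paste(utils::head(rownames(counts)[is.na(len)]), collapse = ", "))
  N <- if (size_basis == "raw_total") colSums(counts)
       else colSums(sweep(counts, 2, size_factors(counts), "/"))
  out <- counts * 1e9 / outer(as.numeric(len), as.numeric(N))
  dimnames(out) <- dimnames(counts)
  out
}

#' Pearson correlation between samples
#'
#' Replicate-consistency QC: pairwise Pearson correlation of samples on
#' `log2(x + 1)`-transformed expression (FPKM when available, otherwise
#' normalised counts).
#'
#' @param expr genes x samples expression matrix (linear scale).
#' @param log2_transform apply `log2(x + 1)` first (default TRUE).
#' @return symmetric samples x samples correlation matrix with unit diagonal.
#' @export
replicate_correlation <- function(expr, log2_transform = TRUE) {
  x <- as.matrix(expr)
  if (log2_transform) x <- log2(x + 1)
  r <- stats::cor(x, method = "pearson")
  diag(r) <- 1
  r
}

#' Define a two-cell contrast
#'
#' A contrast compares the mean expression of one design cell (trio, role,
#' condition) against another, e.g. the hybrid's WD vs WW cells.
#'
#' @param name label carried into results.
#' @param num,den character vectors `c(trio, role, condition)` for the
#'   numerator and denominator cells.
#' @return list of class `Contrast`.
#' @export
contrast <- function(name, num, den) {
  stopifnot(length(num) == 3, length(den) == 3)
  if (identical(unname(num), unname(den))) stop("numerator equals denominator")
  structure(list(name = name,
                 num = stats::setNames(unname(num), c("trio", "role", "condition")),
                 den = stats::setNames(unname(den), c("trio", "role", "condition"))),
            class = "Contrast")
}

# dispersion by method of moments on normalised counts.
# x1, x0: genes x reps matrices. Returns per-gene alpha (unfloored, may be
# negative/NA) for per-gene mode and a single pooled value for shared mode.
mom_dispersion <- function(x1, x0) {
  per_group <- function(x) {
    n <- ncol(x)
    m <- rowMeans(x)
    v <- rowSums((x - m)^2) / (n - 1)
    a <- (v - m) / m^2
    a[m <= 0] <- NA_real_
    list(a = a, w = n - 1)
  }
  g1 <- per_group(x1); g0 <- per_group(x0)
  w1 <- ifelse(is.na(g1$a), 0, g1$w)
  w0 <- ifelse(is.na(g0$a), 0, g0$w)
  num <- ifelse(is.na(g1$a), 0, g1$a) * w1 + ifelse(is.na(g0$a), 0, g0$a) * w0
  den <- w1 + w0
  a <- ifelse(den > 0, num / den, NA_real_)
  a
}

ALPHA_FLOOR <- 1e-8

# core NB Wald machinery on two normalised-count matrices (genes x reps).
# Returns a data.frame without fdr/call.
nb_wald <- function(x1, x0, alpha_mode = "shared_mom", alpha_fixed = NULL) {
  stopifnot(nrow(x1) == nrow(x0))
  n1 <- ncol(x1); n0 <- ncol(x0)
  if (n1 < 2 || n0 < 2) stop("need >= 2 replicates per side")
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  a_gene <- mom_dispersion(x1, x0)
  alpha <- switch(alpha_mode,
    shared_mom = rep(max(ALPHA_FLOOR, mean(a_gene, na.rm = TRUE)), length(m1)),
    per_gene_mom = pmax(ALPHA_FLOOR, ifelse(is.na(a_gene), ALPHA_FLOOR, a_gene)),
    fixed = {
      if (is.null(alpha_fixed) || alpha_fixed <= 0)
        stop("alpha_mode='fixed' requires a positive alpha_fixed")
      rep(alpha_fixed, length(m1))
    },
    stop("unknown alpha_mode: ", alpha_mode))
  # pseudo-mean floor of 0.5 inside the log when a side is all-zero
  m1f <- ifelse(m1 == 0, 0.5, m1)
  m0f <- ifelse(m0 == 0, 0.5, m0)
  log2fc <- log2(m1f / m0f)
  se_ln <- sqrt((1 / m1f + alpha) / n1 + (1 / m0f + alpha) / n0)
  z <- log(m1f / m0f) / se_ln
  p <- 2 * stats::pnorm(-abs(z))
  both_zero <- m1 == 0 & m0 == 0
  log2fc[both_zero] <- 0
  p[both_zero] <- 1
  data.frame(gene_id = rownames(x1),
             base_mean = (m1 + m0) / 2,
             log2fc = log2fc,
             se_log2fc = se_ln / log(2),
             p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Negative-binomial Wald differential-expression test
#'
#' Per gene: group means are estimated on median-of-ratios-normalised
#' counts; the NB dispersion (variance = mu + alpha * mu^2) comes from a
#' method-of-moments estimate, either pooled across genes (`shared_mom`,
#' default), per gene (`per_gene_mom`) or fixed by the caller; the Wald
#' statistic on the log fold change uses the delta-method standard error
#' and a two-sided normal reference. Genes with all-zero counts in both
#' groups get `p = 1`, `log2fc = 0`; a pseudo-mean floor of 0.5 normalised
#' counts enters the log when exactly one side is all-zero. No dispersion
#' shrinkage is applied.
#'
#' @param es a `TrioExpressionSet`.
#' @param ctr a [contrast()].
#' @param alpha_mode `"shared_mom"`, `"per_gene_mom"` or `"fixed"`.
#' @param alpha_fixed dispersion value when `alpha_mode = "fixed"`.
#' @param sf optional precomputed size factors for all samples of `es`.
#' @return data.frame of class `DEResult` with columns `gene_id`,
#'   `base_mean`, `log2fc`, `se_log2fc`, `p_value` and a `contrast`
#'   attribute; `fdr`/`call` are added by [call_de()].
#' @export
nb_test <- function(es, ctr, alpha_mode = c("shared_mom", "per_gene_mom", "fixed"),
                    alpha_fixed = NULL, sf = NULL) {
  stopifnot(inherits(es, "TrioExpressionSet"), inherits(ctr, "Contrast"))
  alpha_mode <- match.arg(alpha_mode)
  if (is.null(sf)) sf <- size_factors(es$counts)
  norm <- sweep(es$counts, 2, sf, "/")
  s1 <- cell_samples(es$sheet, ctr$num["trio"], ctr$num["role"], ctr$num["condition"])
  s0 <- cell_samples(es$sheet, ctr$den["trio"], ctr$den["role"], ctr$den["condition"])
  if (length(s1) < 2 || length(s0) < 2)
    stop("contrast cell missing or under-replicated: ", ctr$name)
  res <- nb_wald(norm[, s1, drop = FALSE], norm[, s0, drop = FALSE],
                 alpha_mode = alpha_mode, alpha_fixed = alpha_fixed)
  attr(res, "contrast") <- ctr
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values numeric vector of p-values.
#' @return vector of FDR values in `[0, 1]`, same order as input.
#' @export
bh_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "BH")
}

#' Apply the fold-change / FDR calling rule
#'
#' A gene is called `up` iff `log2fc > log2(fc_threshold)` and
#' `fdr < fdr_threshold`, `down` symmetrically, otherwise `ns`. Defaults
#' encode the |fold change| > 2 at FDR < 5% rule. BH correction is applied
#' across the genes of the supplied result (one contrast = one family).
#'
#' @param results `DEResult` data.frame from [nb_test()].
#' @param fc_threshold linear fold-change gate (default 2).
#' @param fdr_threshold FDR gate (default 0.05).
#' @return the input with `fdr` and `call` columns added.
#' @export
call_de <- function(results, fc_threshold = 2, fdr_threshold = 0.05) {
  stopifnot(is.data.frame(results), all(c("log2fc", "p_value") %in% names(results)))
  results$fdr <- bh_adjust(results$p_value)
  lfc_gate <- log2(fc_threshold)
  results$call <- ifelse(results$log2fc > lfc_gate & results$fdr < fdr_threshold, "up",
                  ifelse(results$log2fc < -lfc_gate & results$fdr < fdr_threshold, "down",
                         "ns"))
  results
}

#' Standard condition contrasts for every genotype of a trio design
#'
#' Builds the WD-vs-WW (`phase = "drought"`) or RW-vs-WD
#' (`phase = "rewatering"`) contrast for each (trio, role) in the sheet —
#' the six pairwise comparisons of a two-trio design.
#'
#' @param sheet a validated sample sheet.
#' @param phase `"drought"` or `"rewatering"`.
#' @param genotype_labels optional named map from `"trio.role"` to a display
#'   genotype id used in contrast names.
#' @return named list of [contrast()] objects.
#' @export
condition_contrasts <- function(sheet, phase = c("drought", "rewatering"),
                                genotype_labels = NULL) {
  phase <- match.arg(phase)
  cc <- if (phase == "drought") c("WD", "WW") else c("RW", "WD")
  cells <- unique(sheet[, c("trio_id", "role")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    tr <- cells$trio_id[i]; ro <- cells$role[i]
    key <- paste(tr, ro, sep = ".")
    lab <- if (!is.null(genotype_labels) && key %in% names(genotype_labels))
      genotype_labels[[key]] else key
    nm <- paste0(lab, "_", cc[1], "_vs_", cc[2])
    out[[nm]] <- contrast(nm, c(tr, ro, cc[1]), c(tr, ro, cc[2]))
  }
  out
}
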