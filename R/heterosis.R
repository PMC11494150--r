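#' Mid-parent and high-parent heterosis indices
#'
#' From replicated trait values of a hybrid and its two parents under one
#' condition: `MP = (P1_mean + P2_mean)/2`, `HP = max(P1_mean, P2_mean)`,
#' `MPH(%) = 100 * (F1_mean - MP)/MP`, `HPH(%) = 100 * (F1_mean - HP)/HP`.
#' For all-positive means `MPH >= HPH` always holds (HP >= MP). Two-sided
#' Welch t-tests compare the hybrid replicates against the mid-parent
#' pseudo-replicates (per-replicate parent-pair means, the default) or the
#' pooled parent values, and against the higher parent's replicates.
#'
#' @param pheno a `PhenotypeTable` (see [read_phenotypes()]).
#' @param trio named character vector `c(hybrid=, parent1=, parent2=)` of
#'   genotype ids.
#' @param condition condition label.
#' @param trait trait name.
#' @param mp_test `"paired_mp"` (per-replicate parent means; requires equal
#'   replicate counts in the parents) or `"pooled"` (all parent values as
#'   one group).
#' @return one-row data.frame of class `HeterosisResult`.
#' @export
heterosis_indices <- function(pheno, trio, condition, trait,
                              mp_test = c("paired_mp", "pooled")) {
  mp_test <- match.arg(mp_test)
  vals <- function(geno) {
    v <- pheno$value[pheno$genotype_id == geno & pheno$condition == condition &
                     pheno$trait == trait]
    if (length(v) == 0) stop("missing genotype ", geno, " for ", trait,
                             " under ", condition)
    if (length(v) < 2) stop("need >= 2 replicates for ", geno)
    v
  }
  f1 <- vals(trio[["hybrid"]])
  p1 <- vals(trio[["parent1"]])
  p2 <- vals(trio[["parent2"]])
  means <- c(F1 = mean(f1), P1 = mean(p1), P2 = mean(p2))
  if (any(means <= 0)) stop("non-positive mean; heterosis ratio undefined")
  MP <- (means[["P1"]] + means[["P2"]]) / 2
  HP <- max(means[["P1"]], means[["P2"]])
  hp_vals <- if (means[["P1"]] >= means[["P2"]]) p1 else p2
  mp_group <- if (mp_test == "paired_mp") {
    if (length(p1) != length(p2))
      stop("paired_mp requires equal parent replicate counts")
    (p1 + p2) / 2
  } else c(p1, p2)
  p_mp <- welch_p(f1, mp_group)
  p_hp <- welch_p(f1, hp_vals)
  res <- data.frame(
    trait = trait, trio_id = paste(trio, collapse = "/"),
    condition = condition,
    F1_mean = means[["F1"]], P1_mean = means[["P1"]], P2_mean = means[["P2"]],
    MP = MP, HP = HP,
    MPH_pct = 100 * (means[["F1"]] - MP) / MP,
    HPH_pct = 100 * (means[["F1"]] - HP) / HP,
    p_vs_MP = p_mp, p_vs_HP = p_hp,
    stringsAsFactors = FALSE)
  class(res) <- c("HeterosisResult", "data.frame")
  res
}

# Welch two-sided p; degenerate zero-variance groups: p = 1 when the
# groups are identical in mean, NA otherwise (t undefined)
welch_p <- function(x, y) {
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else NA_real_)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Condition effect on a trait
#'
#' Percent change of the WD mean relative to the WW mean for one genotype,
#' with a two-sided Welch t-test. A negative value is a drought-induced
#' decrease (e.g. -48.6 = a 48.6% drop).
#'
#' @param pheno a `PhenotypeTable`.
#' @param genotype genotype id.
#' @param trait trait name.
#' @return list with `percent_change` and `p_value`.
#' @export
condition_effect <- function(pheno, genotype, trait) {
  v <- function(cond) {
    x <- pheno$value[pheno$genotype_id == genotype & pheno$trait == trait &
                     pheno$condition == cond]
    if (length(x) < 2) stop("need >= 2 replicates under ", cond)
    x
  }
  ww <- v("WW"); wd <- v("WD")
  list(percent_change = 100 * (mean(wd) - mean(ww)) / mean(ww),
       p_value = welch_p(wd, ww))
}
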