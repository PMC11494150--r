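#' Expression-detection flag from replicate values
#'
#' A gene is "expressed" in a design cell when at least `min_reps`
#' replicates reach `tau` (FPKM or normalised counts). This operationalises
#' the exact-zero presence/absence predicates, which are fragile under
#' sampling noise.
#'
#' @param replicate_values non-negative numeric vector.
#' @param tau detection threshold (default 1).
#' @param min_reps minimum number of replicates at or above `tau` (default 2).
#' @return logical scalar.
#' @export
expressed_flag <- function(replicate_values, tau = 1, min_reps = 2) {
  sum(replicate_values >= tau) >= min_reps
}

#' PAV type from the three presence flags
#'
#' Presence/absence variation over the (hybrid, parent1, parent2) triple:
#' type I = both parents expressed, hybrid silent; II = exactly one parent
#' expressed, hybrid silent; III = hybrid only; IV = hybrid plus exactly one
#' parent; V = all three expressed. The all-silent row is not a PAV type
#' and returns `NA` (reported separately as `not_detected` by
#' [classify_all()]).
#'
#' @param f1,p1,p2 logical vectors (recycled to common length).
#' @return character vector of `"I"`..`"V"` or `NA`.
#' @export
classify_pav <- function(f1, p1, p2) {
  n <- max(length(f1), length(p1), length(p2))
  f1 <- rep_len(f1, n); p1 <- rep_len(p1, n); p2 <- rep_len(p2, n)
  np <- p1 + p2
  out <- rep(NA_character_, n)
  out[!f1 & np == 2] <- "I"
  out[!f1 & np == 1] <- "II"
  out[f1 & np == 0] <- "III"
  out[f1 & np == 1] <- "IV"
  out[f1 & np == 2] <- "V"
  out
}

#' Inheritance mode from pairwise tri-state comparisons
#'
#' Classifies a type-V gene from the outcomes of four tests, each reduced
#' to a tri-state (`higher` / `equal` / `lower`, where `equal` means "not
#' significantly different" under the global fold-change/FDR rule):
#' hybrid vs parent1, hybrid vs parent2, hybrid vs mid-parent value, and
#' parent1 vs parent2. The additive test is evaluated first; the
#' nonadditive subrules follow in order (overdominant, underdominant, high
#' dominance, low dominance), first match wins; anything else (e.g.
#' partial dominance strictly between the parents but away from the
#' mid-parent) is `other`.
#'
#' @param f1_vs_p1,f1_vs_p2,f1_vs_mpv,p1_vs_p2 character vectors over
#'   `c("higher","equal","lower")`, recycled to common length.
#'   `p1_vs_p2 = "higher"` means parent1 exceeds parent2.
#' @return character vector of modes: `additive`, `overdominant`,
#'   `underdominant`, `high_dominance`, `low_dominance` or `other`.
#' @export
classify_mode <- function(f1_vs_p1, f1_vs_p2, f1_vs_mpv, p1_vs_p2) {
  tri <- c("higher", "equal", "lower")
  n <- max(length(f1_vs_p1), length(f1_vs_p2), length(f1_vs_mpv), length(p1_vs_p2))
  a <- rep_len(f1_vs_mpv, n); b <- rep_len(f1_vs_p1, n)
  c_ <- rep_len(f1_vs_p2, n); d <- rep_len(p1_vs_p2, n)
  if (!all(c(a, b, c_, d) %in% tri)) stop("tri-state must be higher/equal/lower")
  out <- rep("other", n)
  high <- (b == "equal" & d == "higher") | (c_ == "equal" & d == "lower")
  low  <- (b == "equal" & d == "lower")  | (c_ == "equal" & d == "higher")
  out[low] <- "low_dominance"
  out[high] <- "high_dominance"           # listed before low; wins ties
  out[b == "lower" & c_ == "lower"] <- "underdominant"
  out[b == "higher" & c_ == "higher"] <- "overdominant"
  out[a == "equal"] <- "additive"         # additive test evaluated first
  out
}

# reduce a called DE result to tri-states: up -> higher, down -> lower,
# ns -> equal
de_tristate <- function(called) {
  ifelse(called$call == "up", "higher",
         ifelse(called$call == "down", "lower", "equal"))
}

#' Hybrid vs mid-parent NB test
#'
#' Builds a mid-parent pseudo-group by averaging the two parents'
#' normalised replicate values pairwise (replicates paired by replicate
#' number, so each pseudo-replicate is `(P1_r + P2_r)/2`) and applies the
#' NB Wald machinery hybrid vs pseudo-group. Intended for type-V genes;
#' BH correction is applied by the caller across the family of tests of
#' one trio x condition.
#'
#' @param es a `TrioExpressionSet`.
#' @param trio,condition design cell.
#' @param genes optional subset of gene ids (default all).
#' @inheritParams nb_test
#' @return `DEResult` data.frame (no fdr/call).
#' @export
midparent_test <- function(es, trio, condition,
                           genes = NULL,
                           alpha_mode = c("shared_mom", "per_gene_mom", "fixed"),
                           alpha_fixed = NULL, sf = NULL) {
  stopifnot(inherits(es, "TrioExpressionSet"))
  alpha_mode <- match.arg(alpha_mode)
  if (is.null(sf)) sf <- size_factors(es$counts)
  norm <- sweep(es$counts, 2, sf, "/")
  if (!is.null(genes)) norm <- norm[genes, , drop = FALSE]
  sh <- es$sheet
  pick <- function(role) {
    sub <- sh[sh$trio_id == trio & sh$role == role & sh$condition == condition, ]
    sub <- sub[order(sub$replicate), ]
    norm[, sub$sample_id, drop = FALSE]
  }
  xf <- pick("hybrid"); x1 <- pick("parent1"); x2 <- pick("parent2")
  nr <- min(ncol(x1), ncol(x2))
  if (nr < 2 || ncol(xf) < 2) stop("contrast cell missing or under-replicated")
  xmp <- (x1[, seq_len(nr), drop = FALSE] + x2[, seq_len(nr), drop = FALSE]) / 2
  res <- nb_wald(xf, xmp, alpha_mode = alpha_mode, alpha_fixed = alpha_fixed)
  attr(res, "contrast") <- contrast(
    paste0(trio, "_", condition, "_F1_vs_MPV"),
    c(trio, "hybrid", condition), c(trio, "midparent", condition))
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Union of hybrid-specific (type III) and overdominant genes
#'
#' Type-III genes (expressed in the hybrid only) behave as overdominant and
#' are merged with the type-V overdominant class. The two inputs are
#' disjoint by construction (III excludes V), so the union size is the
#' exact sum.
#'
#' @param calls data.frame of inheritance calls from [classify_all()].
#' @return named list per `trio.condition` of merged gene-id vectors.
#' @export
merged_overdominant <- function(calls) {
  key <- paste(calls$trio_id, calls$condition, sep = ".")
  sel <- calls$pav_type == "III" |
    (calls$pav_type == "V" & calls$mode == "overdominant")
  split(calls$gene_id[sel], key[sel])
}

#' Classify every gene x trio x condition
#'
#' Full inheritance classification: detection flags per role
#' ([expressed_flag()] on FPKM when present, otherwise on
#' median-of-ratios-normalised counts), PAV typing ([classify_pav()]), and
#' for type-V genes the four NB Wald tests (hybrid vs each parent, parents
#' against each other, hybrid vs mid-parent pseudo-group), each BH-corrected
#' within its own family (one test x trio x condition), reduced to
#' tri-states at the fold-change/FDR thresholds and mapped through
#' [classify_mode()].
#'
#' @param es a `TrioExpressionSet`.
#' @param tau,min_reps detection rule parameters, see [expressed_flag()].
#' @param fc_threshold,fdr_threshold calling rule, see [call_de()].
#' @inheritParams nb_test
#' @return data.frame of class `InheritanceCalls` with one row per
#'   gene x trio x condition: `pav_type` (`I`..`V` or `not_detected`),
#'   `mode` (`not_applicable` outside type V), the four evidence
#'   tri-states, and `merged_overdominant` flag
#'   (`pav_type == "III" | mode == "overdominant"`).
#' @export
classify_all <- function(es, tau = 1, min_reps = 2,
                         fc_threshold = 2, fdr_threshold = 0.05,
                         alpha_mode = c("shared_mom", "per_gene_mom", "fixed"),
                         alpha_fixed = NULL) {
  stopifnot(inherits(es, "TrioExpressionSet"))
  alpha_mode <- match.arg(alpha_mode)
  sf <- size_factors(es$counts)
  norm <- sweep(es$counts, 2, sf, "/")
  expr <- if (!is.null(es$fpkm)) es$fpkm else norm
  sh <- es$sheet
  genes <- rownames(es$counts)
  out <- list()
  for (tr in unique(sh$trio_id)) {
    for (cond in unique(sh$condition[sh$trio_id == tr])) {
      flags <- sapply(c("hybrid", "parent1", "parent2"), function(role) {
        ids <- cell_samples(sh, tr, role, cond)
        apply(expr[, ids, drop = FALSE], 1, expressed_flag,
              tau = tau, min_reps = min_reps)
      })
      pav <- classify_pav(flags[, "hybrid"], flags[, "parent1"], flags[, "parent2"])
      pav[is.na(pav)] <- "not_detected"
      mode <- rep("not_applicable", length(genes))
      tri <- matrix(NA_character_, length(genes), 4,
                    dimnames = list(genes, c("f1_vs_p1", "f1_vs_p2",
                                             "f1_vs_mpv", "p1_vs_p2")))
      v_genes <- genes[pav == "V"]
      if (length(v_genes) >= 1) {
        sub <- function(role) {
          ids <- cell_samples(sh, tr, role, cond)
          ids <- ids[order(sh$replicate[match(ids, sh$sample_id)])]
          norm[v_genes, ids, drop = FALSE]
        }
        xf <- sub("hybrid"); x1 <- sub("parent1"); x2 <- sub("parent2")
        nr <- min(ncol(x1), ncol(x2))
        xmp <- (x1[, seq_len(nr), drop = FALSE] +
                x2[, seq_len(nr), drop = FALSE]) / 2
        fam <- list(
          f1_vs_p1 = nb_wald(xf, x1, alpha_mode, alpha_fixed),
          f1_vs_p2 = nb_wald(xf, x2, alpha_mode, alpha_fixed),
          f1_vs_mpv = nb_wald(xf, xmp, alpha_mode, alpha_fixed),
          p1_vs_p2 = nb_wald(x1, x2, alpha_mode, alpha_fixed))
        for (nm in names(fam)) {
          called <- call_de(fam[[nm]], fc_threshold, fdr_threshold)
          tri[v_genes, nm] <- de_tristate(called)
        }
        mode[pav == "V"] <- classify_mode(tri[v_genes, "f1_vs_p1"],
                                          tri[v_genes, "f1_vs_p2"],
                                          tri[v_genes, "f1_vs_mpv"],
                                          tri[v_genes, "p1_vs_p2"])
      }
      out[[paste(tr, cond, sep = ".")]] <- data.frame(
        gene_id = genes, trio_id = tr, condition = cond,
        pav_type = pav, mode = mode,
        f1_vs_p1 = tri[, 1], f1_vs_p2 = tri[, 2],
        f1_vs_mpv = tri[, 3], p1_vs_p2 = tri[, 4],
        merged_overdominant = pav == "III" | mode == "overdominant",
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  class(calls) <- c("InheritanceCalls", "data.frame")
  calls
}

#' Per-condition bookkeeping of inheritance calls
#'
#' Counts of PAV types and, within type V, of each expression mode, per
#' trio x condition — the tabular analog of the class-size bar charts used
#' to report these analyses.
#'
#' @param calls data.frame from [classify_all()].
#' @return data.frame of counts per trio, condition, pav_type and mode.
#' @export
inheritance_summary <- function(calls) {
  agg <- stats::aggregate(list(n = calls$gene_id),
                          by = list(trio_id = calls$trio_id,
                                    condition = calls$condition,
                                    pav_type = calls$pav_type,
                                    mode = calls$mode),
                          FUN = length)
  agg[order(agg$trio_id, agg$condition, agg$pav_type, agg$mode), ]
}
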