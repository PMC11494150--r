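#' Named gene sets with provenance
#'
#' A `ResponseSets` object is a named collection of directional gene sets
#' (DRG/RRG per genotype, the conserved CDRG/CRRG intersections, common
#' over/under-dominant sets and the derived DODG/DUDG/RODG/RUDG overlaps).
#' Every derived set records the operation and parent sets that produced
#' it, so membership can be re-derived and audited.
#'
#' @return empty `ResponseSets` container.
#' @export
response_sets <- function() {
  structure(list(sets = list()), class = "ResponseSets")
}

#' @export
print.ResponseSets <- function(x, ...) {
  cat("ResponseSets with", length(x$sets), "sets\n")
  for (nm in names(x$sets)) {
    s <- x$sets[[nm]]
    cat(sprintf("  %-28s %6d genes  [%s] %s\n", nm, length(s$genes),
                s$direction, s$provenance$op))
  }
  invisible(x)
}

#' Add a leaf gene set
#'
#' @param rs a `ResponseSets`.
#' @param name set name.
#' @param genes character vector of gene ids.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @param op provenance operation label (default `"leaf"`).
#' @param parents parent set names (empty for leaves).
#' @export
rs_add <- function(rs, name, genes, direction = "both",
                   op = "leaf", parents = character()) {
  stopifnot(inherits(rs, "ResponseSets"),
            direction %in% c("up", "down", "both"))
  rs$sets[[name]] <- list(genes = sort(unique(as.character(genes))),
                          direction = direction,
                          provenance = list(op = op, parents = parents))
  rs
}

#' Derive a set by recorded set algebra
#'
#' Computes `intersect`, `union` or `setdiff` over existing sets (in
#' order, left-folded) and records the operation as provenance.
#'
#' @inheritParams rs_add
#' @param op one of `"intersect"`, `"union"`, `"setdiff"`.
#' @param parents names of existing sets, applied left to right.
#' @export
rs_derive <- function(rs, name, op, parents, direction = "both") {
  stopifnot(inherits(rs, "ResponseSets"), op %in% c("intersect", "union", "setdiff"))
  missing <- setdiff(parents, names(rs$sets))
  if (length(missing)) stop("unknown parent set(s): ", paste(missing, collapse = ", "))
  genes <- apply_set_op(op, lapply(rs$sets[parents], `[[`, "genes"))
  rs$sets[[name]] <- list(genes = sort(genes), direction = direction,
                          provenance = list(op = op, parents = parents))
  rs
}

apply_set_op <- function(op, gene_lists) {
  Reduce(match.fun(op), gene_lists)
}

#' @rdname rs_add
#' @export
rs_get <- function(rs, name) {
  if (is.null(rs$sets[[name]])) stop("unknown set: ", name)
  rs$sets[[name]]$genes
}

#' Audit provenance of all derived sets
#'
#' Recomputes every non-leaf set from its recorded parents and checks that
#' the stored membership is reproduced exactly.
#'
#' @param rs a `ResponseSets`.
#' @return logical vector named by set (TRUE = re-derives identically;
#'   leaves are trivially TRUE).
#' @export
rs_audit <- function(rs) {
  stopifnot(inherits(rs, "ResponseSets"))
  vapply(names(rs$sets), function(nm) {
    s <- rs$sets[[nm]]
    if (!s$provenance$op %in% c("intersect", "union", "setdiff")) return(TRUE)
    redone <- sort(apply_set_op(s$provenance$op,
                                lapply(rs$sets[s$provenance$parents], `[[`, "genes")))
    identical(redone, s$genes)
  }, TRUE)
}

#' Directional response gene sets from a called DE result
#'
#' The drought phase uses the WD-vs-WW contrast, the re-watering phase the
#' RW-vs-WD contrast; the up and down sets are simply the `up`/`down`
#' calls of the supplied result.
#'
#' @param de_called `DEResult` data.frame with a `call` column
#'   (see [call_de()]).
#' @return list with character vectors `up` and `down`.
#' @export
response_genes <- function(de_called) {
  stopifnot(is.data.frame(de_called), "call" %in% names(de_called))
  list(up = sort(de_called$gene_id[de_called$call == "up"]),
       down = sort(de_called$gene_id[de_called$call == "down"]))
}

#' Conserved (shared) genes between two sets
#'
#' Plain intersection on gene ids. Direction stratification is achieved by
#' intersecting matching direction sets (up with up, down with down), the
#' default throughout the pipeline; passing direction-agnostic unions
#' reproduces a plain ID intersection.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return sorted character vector.
#' @export
conserved <- function(set_a, set_b) {
  sort(intersect(set_a, set_b))
}

#' Headline overlaps of conserved response and dominance sets
#'
#' DODG = upregulated conserved drought-response genes that are common
#' overdominant genes under WD; DUDG = downregulated conserved
#' drought-response genes that are common underdominant genes under WD;
#' RODG / RUDG are the re-watering analogs built from CRRGs and the common
#' dominance sets under RW.
#'
#' @param conserved_up,conserved_down CDRG (phase `"drought"`) or CRRG
#'   (phase `"rewatering"`) direction sets.
#' @param common_overdominant,common_underdominant dominance sets shared by
#'   both hybrids under the phase's stressed condition (WD or RW).
#' @param phase `"drought"` or `"rewatering"`.
#' @return named list of the two sets (`DODG`/`DUDG` or `RODG`/`RUDG`).
#' @export
conserved_dominance_overlap <- function(conserved_up, conserved_down,
                                        common_overdominant,
                                        common_underdominant,
                                        phase = c("drought", "rewatering")) {
  phase <- match.arg(phase)
  nms <- if (phase == "drought") c("DODG", "DUDG") else c("RODG", "RUDG")
  out <- list(sort(intersect(conserved_up, common_overdominant)),
              sort(intersect(conserved_down, common_underdominant)))
  stats::setNames(out, nms)
}

#' Reset / persistence bookkeeping after re-watering
#'
#' Partitions each drought-response direction set by whether re-watering
#' reversed it: `reset_up_down = drg_up` intersected with `rrg_down`,
#' `persistent_up` the remainder (and symmetrically for the down set).
#' Fractions are relative to the DRG set sizes.
#'
#' @param drg_up,drg_down,rrg_up,rrg_down character vectors of gene ids.
#' @return data.frame with columns `category`, `n`, `fraction`.
#' @export
reset_accounting <- function(drg_up, drg_down, rrg_up, rrg_down) {
  ru <- intersect(drg_up, rrg_down)
  rd <- intersect(drg_down, rrg_up)
  pu <- setdiff(drg_up, rrg_down)
  pd <- setdiff(drg_down, rrg_up)
  frac <- function(k, n) if (n == 0) NA_real_ else k / n
  data.frame(
    category = c("reset_up_down", "reset_down_up", "persistent_up", "persistent_down"),
    n = c(length(ru), length(rd), length(pu), length(pd)),
    fraction = c(frac(length(ru), length(drg_up)),
                 frac(length(rd), length(drg_down)),
                 frac(length(pu), length(drg_up)),
                 frac(length(pd), length(drg_down))),
    stringsAsFactors = FALSE)
}

#' Assemble the full response-set collection for a two-hybrid design
#'
#' Runs the set algebra of the analysis end to end with provenance: per
#' hybrid DRG/RRG direction sets from the supplied called DE results,
#' direction-stratified conserved sets (CDRG/CRRG), common over- and
#' under-dominant genes between the hybrids under WD and RW (type-III
#' merged into overdominant via [merged_overdominant()]), the four
#' headline overlaps (DODG/DUDG/RODG/RUDG) and the reset/persistent
#' partitions of the conserved drought sets.
#'
#' @param de_drought,de_rewatering named lists (by trio id) of called
#'   hybrid DE results for WD-vs-WW and RW-vs-WD.
#' @param calls inheritance calls from [classify_all()].
#' @param trios character vector of the two trio ids (defaults to the
#'   names of `de_drought`).
#' @return a `ResponseSets` with all named sets; audit with [rs_audit()].
#' @export
build_response_sets <- function(de_drought, de_rewatering, calls,
                                trios = names(de_drought)) {
  stopifnot(length(trios) == 2)
  rs <- response_sets()
  for (tr in trios) {
    dr <- response_genes(de_drought[[tr]])
    rw <- response_genes(de_rewatering[[tr]])
    rs <- rs_add(rs, paste0("DRG_up_", tr), dr$up, "up", op = "de_call")
    rs <- rs_add(rs, paste0("DRG_down_", tr), dr$down, "down", op = "de_call")
    rs <- rs_add(rs, paste0("RRG_up_", tr), rw$up, "up", op = "de_call")
    rs <- rs_add(rs, paste0("RRG_down_", tr), rw$down, "down", op = "de_call")
  }
  for (dirn in c("up", "down")) {
    rs <- rs_derive(rs, paste0("CDRG_", dirn), "intersect",
                    paste0("DRG_", dirn, "_", trios), dirn)
    rs <- rs_derive(rs, paste0("CRRG_", dirn), "intersect",
                    paste0("RRG_", dirn, "_", trios), dirn)
  }
  mo <- merged_overdominant(calls)
  for (cond in c("WD", "RW")) {
    for (tr in trios) {
      key <- paste(tr, cond, sep = ".")
      rs <- rs_add(rs, paste0("overdominant_", cond, "_", tr),
                   if (is.null(mo[[key]])) character() else mo[[key]],
                   "both", op = "inheritance_call")
      und <- calls$gene_id[calls$trio_id == tr & calls$condition == cond &
                           calls$mode == "underdominant"]
      rs <- rs_add(rs, paste0("underdominant_", cond, "_", tr), und,
                   "both", op = "inheritance_call")
    }
    rs <- rs_derive(rs, paste0("common_overdominant_", cond), "intersect",
                    paste0("overdominant_", cond, "_", trios))
    rs <- rs_derive(rs, paste0("common_underdominant_", cond), "intersect",
                    paste0("underdominant_", cond, "_", trios))
  }
  rs <- rs_derive(rs, "DODG", "intersect",
                  c("CDRG_up", "common_overdominant_WD"), "up")
  rs <- rs_derive(rs, "DUDG", "intersect",
                  c("CDRG_down", "common_underdominant_WD"), "down")
  rs <- rs_derive(rs, "RODG", "intersect",
                  c("CRRG_up", "common_overdominant_RW"), "up")
  rs <- rs_derive(rs, "RUDG", "intersect",
                  c("CRRG_down", "common_underdominant_RW"), "down")
  rs <- rs_derive(rs, "reset_up_down", "intersect", c("CDRG_up", "CRRG_down"), "both")
  rs <- rs_derive(rs, "reset_down_up", "intersect", c("CDRG_down", "CRRG_up"), "both")
  rs <- rs_derive(rs, "persistent_up", "setdiff", c("CDRG_up", "CRRG_down"), "up")
  rs <- rs_derive(rs, "persistent_down", "setdiff", c("CDRG_down", "CRRG_up"), "down")
  rs
}
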