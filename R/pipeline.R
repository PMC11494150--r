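# helpers mapping simulator truth labels to classifier output labels
truth_to_call_label <- function(mode) {
  map <- c(additive = "additive", high_dom = "high_dominance",
           low_dom = "low_dominance", overdominant = "overdominant",
           underdominant = "underdominant",
           pav_I = "pav_I", pav_II = "pav_II", pav_III = "pav_III",
           pav_IV = "pav_IV")
  unname(map[mode])
}

call_label <- function(calls) {
  ifelse(calls$pav_type %in% c("I", "II", "III", "IV"),
         paste0("pav_", calls$pav_type),
         ifelse(calls$pav_type == "V", calls$mode, "not_detected"))
}

#' Confusion matrix of classified vs generating labels
#'
#' Joins inheritance calls of one condition against the simulator truth
#' and tabulates generating label (rows) by called label (columns), with
#' per-class sensitivity (diagonal fraction of each truth row).
#'
#' @param calls data.frame from [classify_all()].
#' @param truth `SimTruth` from [simulate_trios()].
#' @param condition condition at which to compare (default `"WW"`, where
#'   mode construction is not overlaid by a condition response).
#' @return list with `table` (confusion matrix) and `sensitivity`
#'   (named vector per truth class).
#' @export
mode_confusion <- function(calls, truth, condition = "WW") {
  cc <- calls[calls$condition == condition, ]
  key <- paste(cc$gene_id, cc$trio_id)
  tkey <- paste(truth$genes$gene_id, truth$genes$trio_id)
  tr_label <- truth_to_call_label(truth$genes$mode[match(key, tkey)])
  cl_label <- call_label(cc)
  tab <- table(truth = tr_label, called = cl_label)
  sens <- vapply(rownames(tab), function(lab) {
    tot <- sum(tab[lab, ])
    if (tot == 0) return(NA_real_)
    hit <- if (lab %in% colnames(tab)) tab[lab, lab] else 0
    hit / tot
  }, 0)
  list(table = tab, sensitivity = sens)
}

#' Read a pipeline configuration from YAML
#'
#' The file mirrors the argument structure of [run_pipeline()]: a `sim`
#' section with [sim_config()] fields, an optional `thresholds` section
#' (`tau`, `min_reps`, `fc`, `fdr`), optional `phenotypes` trait specs and
#' an optional `annotation` section (`n_terms`, `enriched_fraction`).
#'
#' @param path YAML file path.
#' @return config list suitable for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$sim$trios))
    cfg$sim$trios <- lapply(cfg$sim$trios, unlist)
  if (!is.null(cfg$sim$mode_proportions))
    cfg$sim$mode_proportions <- unlist(cfg$sim$mode_proportions)
  if (!is.null(cfg$sim$response_proportions))
    cfg$sim$response_proportions <- unlist(cfg$sim$response_proportions)
  if (!is.null(cfg$sim$baseline_logmean_range))
    cfg$sim$baseline_logmean_range <- as.numeric(cfg$sim$baseline_logmean_range)
  cfg
}

#' Run the full analysis chain on a simulated design
#'
#' Orchestrates simulate -> differential expression (WD vs WW and RW vs WD
#' for every genotype) -> inheritance classification -> response-set
#' algebra (conserved sets, dominance overlaps, reset accounting) ->
#' optional heterosis indices -> optional enrichment, and returns one
#' machine-readable report with a truth-comparison block. Deterministic
#' given the config seed; when `out_dir` is supplied all stage TSVs are
#' written together with an md5 manifest.
#'
#' @param config list with elements `sim` (arguments to [sim_config()]),
#'   optional `thresholds` (`tau`, `min_reps`, `fc`, `fdr`), optional
#'   `phenotypes` (trait specs for [simulate_phenotypes()]) and optional
#'   `annotation` (`n_terms`, `enriched_fraction` for
#'   [simulate_annotation()]).
#' @param out_dir optional output directory.
#' @return list of class `RunReport`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  th <- utils::modifyList(list(tau = 1, min_reps = 2, fc = 2, fdr = 0.05),
                          config$thresholds %||% list())
  scfg <- do.call(sim_config, config$sim %||% list())
  sim <- simulate_trios(scfg)
  es <- sim$es

  sf <- size_factors(es$counts)
  labels <- unlist(lapply(names(scfg$trios), function(tr)
    stats::setNames(scfg$trios[[tr]],
                    paste(tr, names(scfg$trios[[tr]]), sep = "."))))
  de <- list()
  for (phase in c("drought", "rewatering")) {
    ctrs <- condition_contrasts(es$sheet, phase, genotype_labels = labels)
    de[[phase]] <- lapply(ctrs, function(ctr)
      call_de(nb_test(es, ctr, sf = sf), th$fc, th$fdr))
  }
  de_counts <- lapply(de, function(phase_res)
    lapply(phase_res, function(r) as.list(table(r$call))))

  calls <- classify_all(es, tau = th$tau, min_reps = th$min_reps,
                        fc_threshold = th$fc, fdr_threshold = th$fdr)
  inh_summary <- inheritance_summary(calls)

  trios <- names(scfg$trios)
  hybrid_de <- function(phase) {
    out <- list()
    for (tr in trios) {
      nm <- grep(paste0("^", scfg$trios[[tr]][["hybrid"]], "_"),
                 names(de[[phase]]), value = TRUE)
      out[[tr]] <- de[[phase]][[nm]]
    }
    out
  }
  rs <- build_response_sets(hybrid_de("drought"), hybrid_de("rewatering"),
                            calls, trios = trios)
  set_sizes <- vapply(rs$sets, function(s) length(s$genes), 1L)
  reset_tab <- reset_accounting(rs_get(rs, "CDRG_up"), rs_get(rs, "CDRG_down"),
                                rs_get(rs, "CRRG_up"), rs_get(rs, "CRRG_down"))

  report <- list(
    config = list(sim = unclass(scfg)[setdiff(names(scfg), "trios")],
                  trios = scfg$trios, thresholds = th),
    de_counts = de_counts,
    inheritance_summary = inh_summary,
    set_sizes = as.list(set_sizes),
    reset_accounting = reset_tab,
    audit = list(sets_rederive = all(rs_audit(rs))))

  if (!is.null(config$phenotypes)) {
    ph <- simulate_phenotypes(config$phenotypes, seed = scfg$seed)
    het <- list()
    for (ts in config$phenotypes) {
      for (cond in names(ts$means)) {
        het[[length(het) + 1]] <-
          heterosis_indices(ph, ts$genotypes, cond, ts$trait)
      }
    }
    report$heterosis <- do.call(rbind, het)
  }

  if (!is.null(config$annotation)) {
    ann <- do.call(simulate_annotation,
                   c(list(truth = sim$truth, seed = scfg$seed),
                     config$annotation))
    if (length(ann$terms)) {
      universe <- rownames(es$counts)
      enr <- enrich(rs_get(rs, "CDRG_up"), ann, universe)
      report$enrichment_top <- utils::head(enr, 10)
    }
  }

  conf <- mode_confusion(calls, sim$truth, condition = "WW")
  report$truth_comparison <- list(
    sensitivity = as.list(conf$sensitivity),
    confusion = as.data.frame.matrix(conf$table))

  class(report) <- c("RunReport", "list")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_counts(es, file.path(out_dir, "counts.tsv"),
                 file.path(out_dir, "samples.tsv"))
    utils::write.table(calls, file.path(out_dir, "inheritance_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gene_sets(rs, file.path(out_dir, "gene_sets.tsv"))
    utils::write.table(sim$truth$genes, file.path(out_dir, "sim_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_run_report(report, file.path(out_dir, "report.json"))
    files <- setdiff(list.files(out_dir), "manifest.tsv")
    manifest <- data.frame(file = files,
                           md5 = unname(tools::md5sum(file.path(out_dir, files))),
                           stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$manifest <- manifest
  }
  report
}

#' Write a run report as JSON
#'
#' @param report a `RunReport` from [run_pipeline()].
#' @param path output path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, force = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
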