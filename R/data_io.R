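#' Build a validated trio expression set
#'
#' Container for gene-level counts of one or more (hybrid, parent1, parent2)
#' trios profiled across watering conditions. Columns of `counts` must match
#' the rows of `sheet` one-to-one and in the same order.
#'
#' @param counts non-negative integer matrix, genes x samples, with gene ids
#'   as rownames and sample ids as colnames.
#' @param sheet data.frame with columns `sample_id`, `trio_id`, `role`
#'   (one of `hybrid`, `parent1`, `parent2`), `condition` (one of `WW`,
#'   `WD`, `RW`) and `replicate` (positive integer).
#' @param fpkm optional FPKM matrix of the same shape as `counts`; supplied
#'   together with `gene_lengths` (or computed later with [fpkm()]).
#' @param gene_lengths optional named vector of union-exon lengths in bp.
#' @return An object of class `TrioExpressionSet`: a list with elements
#'   `counts`, `sheet`, `fpkm`, `gene_lengths`.
#' @export
trio_expression_set <- function(counts, sheet, fpkm = NULL, gene_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must carry gene ids as rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene_id in counts")
  if (!is.numeric(counts) || any(is.na(counts))) stop("counts must be numeric with no NA")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  sheet <- validate_sample_sheet(sheet)
  if (ncol(counts) != nrow(sheet))
    stop("counts has ", ncol(counts), " columns but sheet has ", nrow(sheet), " rows")
  missing <- setdiff(sheet$sample_id, colnames(counts))
  if (length(missing))
    stop("design mismatch: sheet sample(s) absent from counts matrix: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(colnames(counts), sheet$sample_id)
  if (length(extra))
    stop("design mismatch: counts column(s) absent from sheet: ",
         paste(extra, collapse = ", "))
  counts <- counts[, sheet$sample_id, drop = FALSE]
  if (!is.null(fpkm)) {
    fpkm <- as.matrix(fpkm)
    stopifnot(identical(dim(fpkm), dim(counts)))
    fpkm <- fpkm[, sheet$sample_id, drop = FALSE]
  }
  if (!is.null(gene_lengths)) {
    gene_lengths <- gene_lengths[rownames(counts)]
    if (any(is.na(gene_lengths)))
      stop("missing gene length for: ",
           paste(rownames(counts)[is.na(gene_lengths)][1:5], collapse = ", "))
  }
  structure(list(counts = counts, sheet = sheet, fpkm = fpkm,
                 gene_lengths = gene_lengths),
            class = "TrioExpressionSet")
}

#' @export
print.TrioExpressionSet <- function(x, ...) {
  cat("TrioExpressionSet:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  trios:     ", paste(unique(x$sheet$trio_id), collapse = ", "), "\n")
  cat("  conditions:", paste(unique(x$sheet$condition), collapse = ", "), "\n")
  cat("  fpkm:      ", if (is.null(x$fpkm)) "absent" else "present", "\n")
  invisible(x)
}

valid_roles <- c("hybrid", "parent1", "parent2")
valid_conditions <- c("WW", "WD", "RW")

validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "trio_id", "role", "condition", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  sheet <- as.data.frame(sheet)[, need]
  sheet[] <- lapply(sheet, function(z) if (is.factor(z)) as.character(z) else z)
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sheet")
  if (!all(sheet$role %in% valid_roles))
    stop("role must be one of: ", paste(valid_roles, collapse = ", "))
  if (!all(sheet$condition %in% valid_conditions))
    stop("condition must be one of: ", paste(valid_conditions, collapse = ", "))
  sheet$replicate <- as.integer(sheet$replicate)
  if (any(is.na(sheet$replicate)) || any(sheet$replicate < 1))
    stop("replicate must be a positive integer")
  for (tr in unique(sheet$trio_id)) {
    roles <- unique(sheet$role[sheet$trio_id == tr])
    miss <- setdiff(valid_roles, roles)
    if (length(miss))
      stop("trio ", tr, " lacks role(s): ", paste(miss, collapse = ", "))
  }
  rownames(sheet) <- NULL
  sheet
}

#' Read a counts matrix and its sample sheet
#'
#' The counts file is a TSV with a `gene_id` first column and one column per
#' sample (an HTSeq-count style wide matrix); the sheet is a TSV with the
#' sample-sheet columns. The returned object's columns follow the sheet's
#' row order; any mismatch between the two files is an error, never a silent
#' reordering.
#'
#' @param path path to the counts TSV.
#' @param sheet_path path to the sample sheet TSV.
#' @return A [trio_expression_set()].
#' @export
read_counts <- function(path, sheet_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("counts file needs a gene_id column plus samples")
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids)) stop("duplicate gene_id in counts file")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("invalid count: non-numeric value in counts file")
  if (any(is.na(m)) || any(m != floor(m)) || any(m < 0))
    stop("invalid count: counts must be non-negative integers")
  storage.mode(m) <- "double"
  rownames(m) <- gene_ids
  sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE)
  trio_expression_set(m, sheet)
}

#' Write a trio expression set to disk
#'
#' Inverse of [read_counts()]: writes the counts matrix (gene_id first
#' column) and the sample sheet as two TSVs.
#'
#' @param es a `TrioExpressionSet`.
#' @param path,sheet_path output paths for the counts and sheet TSVs.
#' @export
write_counts <- function(es, path, sheet_path) {
  stopifnot(inherits(es, "TrioExpressionSet"))
  df <- data.frame(gene_id = rownames(es$counts), es$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(es$sheet, sheet_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Union-exon gene lengths from a GTF
#'
#' Computes, for every gene with exon features, the total length of the
#' union of its exon intervals (GTF coordinates are 1-based closed). These
#' are the lengths used for FPKM normalisation.
#'
#' @param path path to a GTF file whose exon features carry `gene_id`
#'   attributes.
#' @return Named integer vector of lengths in bp.
#' @export
gene_lengths_from_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[!is.na(gr$type) & gr$type == "exon"]
  if (length(ex) == 0) stop("GTF contains no exon features")
  if (is.null(ex$gene_id) || any(is.na(ex$gene_id)))
    stop("exon feature without gene_id attribute")
  genes_seen <- unique(gr$gene_id[!is.na(gr$gene_id)])
  no_exon <- setdiff(genes_seen, unique(ex$gene_id))
  if (length(no_exon))
    stop("gene(s) with no exon features: ", paste(no_exon, collapse = ", "))
  grl <- GenomicRanges::reduce(S4Vectors::split(ex, ex$gene_id))
  lens <- sum(GenomicRanges::width(grl))
  lens <- stats::setNames(as.integer(lens), names(lens))
  lens
}

#' Read a phenotype table
#'
#' Long-format TSV with columns `trait`, `genotype_id`, `condition`,
#' `replicate`, `value`. All values must be positive (heterosis indices are
#' ratios); missing replicates are rejected, not imputed.
#'
#' @param path path to the TSV.
#' @return data.frame of class `PhenotypeTable`.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_phenotypes(ph)
}

validate_phenotypes <- function(ph) {
  need <- c("trait", "genotype_id", "condition", "replicate", "value")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  ph <- as.data.frame(ph)[, need]
  if (any(is.na(ph$value))) stop("missing phenotype value (NA) rejected")
  if (any(ph$value <= 0)) stop("phenotype values must be positive")
  if (!all(ph$condition %in% valid_conditions))
    stop("phenotype condition must be one of: ", paste(valid_conditions, collapse = ", "))
  class(ph) <- c("PhenotypeTable", "data.frame")
  ph
}

#' Write / read named gene sets
#'
#' Gene sets travel as a two-column TSV (`set_name`, `gene_id`). An empty
#' set contributes no rows and is restored as an empty set if it is listed
#' in `empty_sets` on write (stored in a `# empty:` header comment).
#'
#' @param sets a `ResponseSets` object (see [response_sets()]) or a named
#'   list of character vectors.
#' @param path output path.
#' @export
write_gene_sets <- function(sets, path) {
  if (inherits(sets, "ResponseSets")) sets <- lapply(sets$sets, `[[`, "genes")
  stopifnot(is.list(sets), !is.null(names(sets)))
  empty <- names(sets)[vapply(sets, length, 1L) == 0]
  con <- file(path, "w")
  on.exit(close(con))
  if (length(empty)) writeLines(paste0("# empty: ", paste(empty, collapse = ",")), con)
  df <- data.frame(
    set_name = rep(names(sets), vapply(sets, length, 1L)),
    gene_id = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_gene_sets
#' @param schema optional character vector of allowed set names; unknown
#'   names on read become an error when supplied.
#' @return `read_gene_sets` returns a named list of character vectors.
#' @export
read_gene_sets <- function(path, schema = NULL) {
  first <- readLines(path, n = 1)
  empty <- character()
  skip <- 0
  if (startsWith(first, "# empty:")) {
    empty <- strsplit(trimws(sub("# empty:", "", first)), ",")[[1]]
    skip <- 1
  }
  df <- utils::read.delim(path, skip = skip, stringsAsFactors = FALSE)
  sets <- split(df$gene_id, df$set_name)
  for (nm in empty) if (is.null(sets[[nm]])) sets[[nm]] <- character()
  if (!is.null(schema)) {
    unknown <- setdiff(names(sets), schema)
    if (length(unknown))
      stop("unknown set name(s): ", paste(unknown, collapse = ", "))
  }
  lapply(sets, as.character)
}

#' Build an annotation map for enrichment
#'
#' A GMT-style term-to-genes mapping. Empty terms are rejected.
#'
#' @param terms named list, term_id -> character vector of gene ids.
#' @param term_names optional named character vector of descriptions.
#' @return object of class `AnnotationMap`.
#' @export
annotation_map <- function(terms, term_names = NULL) {
  stopifnot(is.list(terms))
  if (length(terms) && is.null(names(terms))) stop("terms must be named by term_id")
  if (any(vapply(terms, length, 1L) == 0)) stop("empty term gene set")
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (is.null(term_names))
    term_names <- stats::setNames(names(terms), names(terms))
  structure(list(terms = terms, term_names = term_names[names(terms)]),
            class = "AnnotationMap")
}

#' Read / write GMT annotation files
#'
#' Standard GMT: one term per line, tab-separated
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @return [annotation_map()] object.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3
  if (any(bad)) stop("malformed GMT line (fewer than 3 fields)")
  ids <- vapply(parts, `[[`, "", 1)
  descs <- vapply(parts, `[[`, "", 2)
  terms <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  annotation_map(terms, stats::setNames(descs, ids))
}

#' @rdname read_gmt
#' @param annotation an `AnnotationMap`.
#' @export
write_gmt <- function(annotation, path) {
  stopifnot(inherits(annotation, "AnnotationMap"))
  lines <- vapply(names(annotation$terms), function(id) {
    paste(c(id, annotation$term_names[[id]], annotation$terms[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(NULL)
}

# sample ids spanning one (trio, role, condition) cell, in sheet order
cell_samples <- function(sheet, trio, role, condition) {
  sheet$sample_id[sheet$trio_id == trio & sheet$role == role &
                  sheet$condition == condition]
}
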