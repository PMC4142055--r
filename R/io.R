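# Plain-text interchange: tab-separated tables with header rows, GMT gene
# sets, JSON truth/manifest files. Probe and sample ids are opaque strings.

#' Read an expression TSV (first column probe id, one column per sample)
#' @param path file path.
#' @return genes x samples numeric matrix with dimnames.
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("expression TSV needs probe id plus sample columns",
                         call. = FALSE)
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids)) stop("duplicate probe ids in expression TSV",
                               call. = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression TSV
#' @param expr genes x samples matrix.
#' @param path output path.
#' @export
write_expression_tsv <- function(expr, path) {
  d <- data.frame(probe_id = rownames(expr), expr, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trait TSV (sample_id, value)
#' @param path file path.
#' @return Named numeric vector.
#' @export
read_trait_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(d[[2L]]), as.character(d[[1L]]))
}

#' Write a trait TSV
#' @param trait named numeric vector.
#' @param path output path.
#' @export
write_trait_tsv <- function(trait, path) {
  utils::write.table(
    data.frame(sample_id = names(trait), value = as.numeric(trait)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype TSV (sample_id, one column per marker, codes 0/1/2)
#' @param path file path.
#' @return samples x markers integer matrix.
#' @export
read_genotype_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(!m %in% 0:2)) stop("genotype codes must be 0, 1 or 2", call. = FALSE)
  rownames(m) <- as.character(d[[1L]])
  m
}

#' Write a genotype TSV
#' @param genotypes samples x markers matrix.
#' @param path output path.
#' @export
write_genotype_tsv <- function(genotypes, path) {
  d <- data.frame(sample_id = rownames(genotypes), genotypes,
                  check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard tab-separated gene-set format: set name, description, then one
#' gene per field.
#'
#' @param path file path.
#' @return Named list of character vectors, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(ln, 1, 40),
                             call. = FALSE)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) stop("empty gene set: ", f[1L], call. = FALSE)
    sets[[f[1L]]] <- genes
    descs[f[1L]] <- f[2L]
  }
  attr(sets, "description") <- descs
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions)) {
      descriptions[[nm]]
    } else {
      "na"
    }
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write simulation ground truth as JSON
#' @param truth truth list from [simulate_network_expression()].
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  # named vectors must become JSON objects, not name-less arrays
  truth$true_module_label <- as.list(truth$true_module_label)
  truth$trait_values <- as.list(truth$trait_values)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read simulation ground truth JSON
#' @param path file path.
#' @return The truth list; `true_module_label` is a named character vector.
#' @export
read_truth_json <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$true_module_label <- unlist(truth$true_module_label)
  truth$trait_values <- unlist(truth$trait_values)
  truth$causal_gene_ids <- as.character(truth$causal_gene_ids)
  truth$reactive_gene_ids <- as.character(truth$reactive_gene_ids)
  truth
}

#' Read a probe annotation TSV
#' @param path TSV with columns probe_id, gene_symbol, entrez_id and
#'   optionally chromosome, mb.
#' @return data.frame.
#' @export
read_annotation_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_symbol", "entrez_id")
  if (!all(need %in% names(d))) {
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Write a simulated study to a directory of pipeline inputs
#'
#' Emits expression, trait, genotype and annotation TSVs plus the truth
#' JSON, the file layout the pipeline driver consumes.
#'
#' @param sim result of [simulate_network_expression()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(sim$expr, file.path(dir, "expression.tsv"))
  write_trait_tsv(sim$trait, file.path(dir, "trait.tsv"))
  write_genotype_tsv(sim$genotypes, file.path(dir, "genotypes.tsv"))
  utils::write.table(sim$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth_json(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
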