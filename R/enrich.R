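#' Hypergeometric gene-set enrichment of a module
#'
#' One-sided upper-tail hypergeometric (Fisher) test of the overlap between
#' a module's genes and a gene set, against a stated background universe.
#' Identifiers are upper-cased before matching; set members outside the
#' background are ignored. Fold enrichment is `(k/m) / (K/N)` with k the
#' overlap, m the set size in background, K the module size and N the
#' background size.
#'
#' @param module_genes character vector of module gene identifiers.
#' @param gene_set character vector (one set), or a named list of sets.
#' @param background character vector, the test universe; must contain all
#'   module genes.
#' @return data.frame (set, k, m, K, N, fold_enrichment, p_value), one row
#'   per set.
#' @export
hypergeometric_enrichment <- function(module_genes, gene_set, background) {
  background <- unique(toupper(background))
  if (length(background) == 0) stop("empty background", call. = FALSE)
  module_genes <- unique(toupper(module_genes))
  if (!all(module_genes %in% background)) {
    stop("background must contain every module gene", call. = FALSE)
  }
  if (!is.list(gene_set)) gene_set <- list(set = gene_set)
  if (is.null(names(gene_set))) names(gene_set) <- paste0("set", seq_along(gene_set))
  n_bg <- length(background)
  k_mod <- length(module_genes)
  rows <- lapply(names(gene_set), function(nm) {
    set <- intersect(unique(toupper(gene_set[[nm]])), background)
    m <- length(set)
    k <- length(intersect(set, module_genes))
    p <- if (m == 0) 1 else
      stats::phyper(k - 1L, m, n_bg - m, k_mod, lower.tail = FALSE)
    fold <- if (m == 0 || k_mod == 0) NA_real_ else (k / m) / (k_mod / n_bg)
    data.frame(set = nm, k = k, m = m, K = k_mod, N = n_bg,
               fold_enrichment = fold, p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Enrichment of every module against every gene set
#'
#' Runs [hypergeometric_enrichment()] for each (module, set) pair and
#' attaches a BH FDR across all tests.
#'
#' @param module_members named list: module -> character vector of gene ids.
#' @param gene_sets named list of gene sets (e.g. from [read_gmt()]).
#' @param background test universe.
#' @return data.frame with columns module, set, k, m, K, N,
#'   fold_enrichment, p_value, fdr.
#' @export
enrich_modules <- function(module_members, gene_sets, background) {
  rows <- lapply(names(module_members), function(mod) {
    r <- hypergeometric_enrichment(module_members[[mod]], gene_sets, background)
    cbind(module = mod, r, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}

#' Cluster enrichment score
#'
#' Summarises a cluster of annotation terms as minus the log10 of the
#' geometric mean of the terms' unadjusted p-values (equivalently, the mean
#' of -log10 p).
#'
#' @param p_values unadjusted term p-values; all must be > 0.
#' @return Single numeric score.
#' @export
cluster_enrichment_score <- function(p_values) {
  if (length(p_values) == 0) stop("no p-values supplied", call. = FALSE)
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  mean(-log10(p_values))
}

#' Collapse probes to unique gene symbols
#'
#' Keeps one probe per gene symbol - the one with the highest whole-network
#' connectivity - so contingency tables never double-count a gene.
#'
#' @param annotation data.frame with columns probe_id and gene_symbol.
#' @param k_total named connectivity vector (names = probe ids); when `NULL`
#'   the first probe per symbol is kept.
#' @return Subset of `annotation`, one row per symbol.
#' @export
collapse_probes <- function(annotation, k_total = NULL) {
  stopifnot(all(c("probe_id", "gene_symbol") %in% names(annotation)))
  if (is.null(k_total)) {
    annotation[!duplicated(toupper(annotation$gene_symbol)), , drop = FALSE]
  } else {
    k <- k_total[annotation$probe_id]
    k[is.na(k)] <- -Inf
    ord <- order(toupper(annotation$gene_symbol), -k)
    a <- annotation[ord, , drop = FALSE]
    a[!duplicated(toupper(a$gene_symbol)), , drop = FALSE]
  }
}
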