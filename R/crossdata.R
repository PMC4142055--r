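#' Map external probes to network modules by Entrez id
#'
#' Every external probe whose Entrez id matches a network gene inherits that
#' gene's module. Entrez ids that map to network probes in more than one
#' module are conflicting; their external probes are dropped and flagged.
#' Unmatched probes are dropped with a count.
#'
#' @param network_annot data.frame with columns probe_id, entrez_id, module.
#' @param external_annot data.frame with columns probe_id, entrez_id.
#' @return List of class `entrez_mapping`: `mapping` (data.frame probe_id,
#'   entrez_id, module), `n_unmatched`, `conflicting_entrez`.
#' @export
map_by_entrez <- function(network_annot, external_annot) {
  stopifnot(all(c("probe_id", "entrez_id", "module") %in% names(network_annot)),
            all(c("probe_id", "entrez_id") %in% names(external_annot)))
  net <- unique(network_annot[, c("entrez_id", "module")])
  conflicts <- unique(net$entrez_id[duplicated(net$entrez_id)])
  if (length(conflicts)) {
    warning(sprintf("%d Entrez id(s) map to multiple modules; dropped",
                    length(conflicts)), call. = FALSE)
    net <- net[!net$entrez_id %in% conflicts, , drop = FALSE]
  }
  idx <- match(external_annot$entrez_id, net$entrez_id)
  matched <- !is.na(idx)
  n_unmatched <- sum(!matched)
  if (!any(matched)) warning("no external probes matched the network",
                             call. = FALSE)
  mapping <- data.frame(
    probe_id = external_annot$probe_id[matched],
    entrez_id = external_annot$entrez_id[matched],
    module = net$module[idx[matched]],
    stringsAsFactors = FALSE
  )
  structure(list(mapping = mapping, n_unmatched = n_unmatched,
                 conflicting_entrez = conflicts),
            class = "entrez_mapping")
}

#' Per-module expression difference between two groups
#'
#' Fold change per probe is the difference of group mean log2 values
#' (group 2 minus group 1). Each module's fold change is the mean over its
#' mapped probes, and its significance is a two-sided two-sample t-test of
#' the module probes' per-probe differences against the background (grey, or
#' all other mapped probes when no grey probes exist).
#'
#' @param external_expr probes x samples log2 matrix of the second dataset.
#' @param group_labels factor/character with exactly two levels, one entry
#'   per sample; differences are level 2 minus level 1.
#' @param mapping an `entrez_mapping` (or its `mapping` data.frame).
#' @param alpha significance level for the flag (default 0.05).
#' @return data.frame (module, n_probes, mean_log2_diff, t_statistic,
#'   p_value, significant).
#' @export
module_group_difference <- function(external_expr, group_labels, mapping,
                                    alpha = 0.05) {
  if (inherits(mapping, "entrez_mapping")) mapping <- mapping$mapping
  group_labels <- as.factor(group_labels)
  if (nlevels(group_labels) != 2L) stop("exactly two groups required",
                                        call. = FALSE)
  if (any(table(group_labels) < 2L)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  g1 <- group_labels == levels(group_labels)[1L]
  probes <- intersect(mapping$probe_id, rownames(external_expr))
  if (length(probes) == 0) stop("no mapped probes in expression matrix",
                                call. = FALSE)
  mapping <- mapping[match(probes, mapping$probe_id), , drop = FALSE]
  x <- external_expr[probes, , drop = FALSE]
  diffs <- rowMeans(x[, !g1, drop = FALSE]) - rowMeans(x[, g1, drop = FALSE])

  mods <- unique(mapping$module)
  bg_mods <- if ("grey" %in% mods) "grey" else character(0)
  rows <- lapply(setdiff(mods, "grey"), function(m) {
    in_mod <- mapping$module == m
    bg <- if (length(bg_mods)) mapping$module %in% bg_mods else !in_mod
    d_mod <- diffs[in_mod]
    d_bg <- diffs[bg]
    tt <- if (length(d_mod) >= 2L && length(d_bg) >= 2L &&
              (stats::sd(d_mod) > 0 || stats::sd(d_bg) > 0)) {
      stats::t.test(d_mod, d_bg)
    } else {
      NULL
    }
    data.frame(module = m, n_probes = sum(in_mod),
               mean_log2_diff = mean(d_mod),
               t_statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p_value = if (is.null(tt)) NA_real_ else tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out[order(out$p_value), , drop = FALSE]
}

#' Paired per-gene differential expression
#'
#' For paired designs (e.g. one lesion and one intact sample per subject):
#' per-gene mean within-pair difference (first matrix minus second) and the
#' two-sided paired t-test p-value. Genes whose within-pair differences have
#' zero variance are flagged degenerate with `p_value = NA`.
#'
#' @param expr_a,expr_b genes x subjects matrices with identical dimnames
#'   (columns are subjects, paired positionally).
#' @param genes optional subset of gene ids to test.
#' @return data.frame (gene, mean_difference, t_statistic, p_value,
#'   degenerate).
#' @export
paired_gene_difference <- function(expr_a, expr_b, genes = rownames(expr_a)) {
  if (!identical(dim(expr_a), dim(expr_b))) {
    stop("paired matrices must have identical dimensions", call. = FALSE)
  }
  if (!is.null(colnames(expr_a)) && !is.null(colnames(expr_b)) &&
      !identical(colnames(expr_a), colnames(expr_b))) {
    stop("subjects are not paired: column names differ", call. = FALSE)
  }
  if (ncol(expr_a) < 3L) stop("need at least 3 pairs", call. = FALSE)
  genes <- intersect(genes, rownames(expr_a))
  if (length(genes) == 0) stop("no requested genes present", call. = FALSE)
  rows <- lapply(genes, function(g) {
    d <- expr_a[g, ] - expr_b[g, ]
    degenerate <- stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1)
    if (degenerate) {
      data.frame(gene = g, mean_difference = mean(d), t_statistic = NA_real_,
                 p_value = if (all(abs(d) < 1e-12)) 1 else NA_real_,
                 degenerate = degenerate, stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(d)
      data.frame(gene = g, mean_difference = mean(d),
                 t_statistic = unname(tt$statistic), p_value = tt$p.value,
                 degenerate = degenerate, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
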