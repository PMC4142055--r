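#' Gene significance for a quantitative trait
#'
#' GS of a gene is the absolute Pearson correlation between its expression
#' and the trait, computed over samples where both are present.
#'
#' @param expr genes x samples expression matrix.
#' @param trait numeric trait vector, one value per sample (names matched to
#'   columns of `expr` when present).
#' @return Named numeric vector of GS values in \[0, 1\].
#' @export
gene_significance <- function(expr, trait) {
  if (!is.null(names(trait)) && !is.null(colnames(expr))) {
    if (!all(colnames(expr) %in% names(trait))) {
      stop("trait is missing values for some samples", call. = FALSE)
    }
    trait <- trait[colnames(expr)]
  }
  if (length(trait) != ncol(expr)) {
    stop("trait length must match sample count", call. = FALSE)
  }
  if (sum(is.finite(trait)) < 4L) {
    stop("trait must be finite for at least 4 samples", call. = FALSE)
  }
  if (stats::sd(trait, na.rm = TRUE) == 0) {
    stop("trait is constant", call. = FALSE)
  }
  gs <- abs(as.numeric(stats::cor(t(expr), trait,
                                  use = "pairwise.complete.obs")))
  stats::setNames(gs, rownames(expr))
}

#' Module significance
#'
#' MS of a module is the arithmetic mean of its members' gene significance.
#' Grey (unassigned) genes are reported as their own row, flagged so they are
#' never called significant.
#'
#' @param gs named GS vector from [gene_significance()].
#' @param labels named module labels covering `gs`.
#' @return data.frame (module, n_genes, ms, is_grey) sorted by decreasing MS.
#' @export
module_significance <- function(gs, labels) {
  labels <- labels[names(gs)]
  if (anyNA(labels)) stop("labels must cover all GS entries", call. = FALSE)
  mods <- unique(labels)
  empty <- setdiff(mods, labels)
  if (length(empty)) warning("skipping empty module(s)", call. = FALSE)
  ms <- tapply(gs, labels, mean)
  out <- data.frame(
    module = names(ms),
    n_genes = as.integer(table(labels)[names(ms)]),
    ms = as.numeric(ms),
    is_grey = names(ms) == "grey",
    stringsAsFactors = FALSE
  )
  out[order(-out$ms), , drop = FALSE]
}

#' Permutation threshold for module significance
#'
#' Builds the null distribution of MS by repeatedly sampling `set_size` GS
#' values without replacement from the observed GS vector and recording the
#' mean; the threshold is the requested empirical quantile of those means. A
#' module is called significant when its MS reaches the threshold.
#'
#' @param gs observed GS vector.
#' @param set_size genes per null set (default 400).
#' @param n_sets number of null sets (default 10000).
#' @param quantile one-sided quantile for the threshold (default 0.95).
#' @param seed optional integer seed.
#' @return List of class `ms_threshold`: `threshold`, `null_means`
#'   (summary), `set_size`, `n_sets`, `quantile`, `seed`.
#' @export
ms_permutation_threshold <- function(gs, set_size = 400L, n_sets = 10000L,
                                     quantile = 0.95, seed = NULL) {
  set_size <- .check_count(set_size, "set_size")
  n_sets <- .check_count(n_sets, "n_sets")
  .check_fraction(quantile, "quantile")
  gs <- gs[is.finite(gs)]
  if (set_size > length(gs)) {
    stop("'set_size' exceeds the number of GS values", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  means <- vapply(seq_len(n_sets),
                  function(i) mean(sample(gs, set_size)), numeric(1))
  thr <- as.numeric(stats::quantile(means, probs = quantile, names = FALSE))
  structure(list(
    threshold = thr,
    null_means = summary(means),
    set_size = set_size, n_sets = n_sets, quantile = quantile, seed = seed
  ), class = "ms_threshold")
}

#' @export
print.ms_threshold <- function(x, ...) {
  cat(sprintf("MS permutation threshold: %.4f (%d sets of %d, quantile %.2f)\n",
              x$threshold, x$n_sets, x$set_size, x$quantile))
  invisible(x)
}

#' Trait association of genes and modules
#'
#' Convenience wrapper: GS, MS, permutation threshold, and the significance
#' call per module.
#'
#' @param expr genes x samples expression matrix.
#' @param trait trait vector.
#' @param labels named module labels.
#' @param set_size,n_sets,quantile,seed passed to
#'   [ms_permutation_threshold()].
#' @return Object of class `trait_association`: `gs`, `ms` (with
#'   `significant` column), `threshold` object, `significant_modules`.
#' @export
trait_association <- function(expr, trait, labels, set_size = 400L,
                              n_sets = 10000L, quantile = 0.95, seed = NULL) {
  gs <- gene_significance(expr, trait)
  set_size <- min(set_size, length(gs))
  ms <- module_significance(gs, labels)
  thr <- ms_permutation_threshold(gs, set_size, n_sets, quantile, seed)
  ms$significant <- !ms$is_grey & ms$ms >= thr$threshold
  structure(list(
    gs = gs, ms = ms, threshold = thr,
    significant_modules = ms$module[ms$significant]
  ), class = "trait_association")
}

#' @export
print.trait_association <- function(x, ...) {
  print(x$threshold)
  print(x$ms, row.names = FALSE, digits = 3)
  invisible(x)
}
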