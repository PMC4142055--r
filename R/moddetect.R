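#' Average-linkage dendrogram of TOM dissimilarity
#'
#' @param diss square symmetric dissimilarity matrix with zero diagonal.
#' @return An `hclust` object.
#' @export
hierarchical_dendrogram <- function(diss) {
  .check_square_symmetric(diss, "diss")
  if (any(abs(diag(diss)) > 1e-10)) {
    stop("dissimilarity diagonal must be zero", call. = FALSE)
  }
  stats::hclust(stats::as.dist(diss), method = "average")
}

#' Two-stage branch cut of the gene dendrogram
#'
#' Stage 1 cuts the average-linkage tree at `cut_height`; branches with at
#' least `min_module_size` leaves become modules, everything else is
#' provisionally unassigned ("grey"). Stage 2 reassigns each grey gene to the
#' module minimising its mean dissimilarity to module members, but only when
#' that mean is below both the gene's mean dissimilarity to all non-module
#' genes and `cut_height`; otherwise the gene stays grey. Modules are named
#' by size rank using the conventional colour sequence (turquoise, blue,
#' brown, ...).
#'
#' @param dendro `hclust` object from [hierarchical_dendrogram()].
#' @param diss the dissimilarity matrix the tree was built from.
#' @param cut_height static cut height in (0, 1] (default 0.97).
#' @param min_module_size minimum branch size to form a module (default 50).
#' @param hybrid_assign run stage 2 (default TRUE).
#' @return Named character vector of module labels ("grey" = unassigned).
#' @export
dynamic_cut <- function(dendro, diss, cut_height = 0.97, min_module_size = 50L,
                        hybrid_assign = TRUE) {
  stopifnot(inherits(dendro, "hclust"))
  .check_fraction(cut_height, "cut_height", 0, 1, open = FALSE)
  if (cut_height == 0) stop("'cut_height' must be positive", call. = FALSE)
  min_module_size <- .check_count(min_module_size, "min_module_size")
  n <- length(dendro$order)
  ids <- if (!is.null(dendro$labels)) dendro$labels else as.character(seq_len(n))

  if (min_module_size > n) {
    warning("minimum module size exceeds gene count; all genes unassigned",
            call. = FALSE)
    return(stats::setNames(rep("grey", n), ids))
  }

  branch <- stats::cutree(dendro, h = cut_height)
  sizes <- table(branch)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- rep("grey", n)
  names(labels) <- ids

  if (length(keep) > 0) {
    # size-rank colour naming
    ord <- keep[order(sizes[as.character(keep)], decreasing = TRUE)]
    cols <- module_color_names(length(ord))
    for (i in seq_along(ord)) labels[branch == ord[i]] <- cols[i]
  }

  if (hybrid_assign && length(keep) > 0 && any(labels == "grey")) {
    mods <- setdiff(unique(labels), "grey")
    grey_idx <- which(labels == "grey")
    member_idx <- lapply(mods, function(m) which(labels == m))
    names(member_idx) <- mods
    for (g in grey_idx) {
      d_mod <- vapply(member_idx, function(ix) mean(diss[g, ix]), numeric(1))
      best <- which.min(d_mod)
      ix <- member_idx[[best]]
      out_ix <- setdiff(seq_len(n), c(ix, g))
      d_out <- if (length(out_ix)) mean(diss[g, out_ix]) else Inf
      if (d_mod[best] < d_out && d_mod[best] < cut_height) {
        labels[g] <- mods[best]
      }
    }
  }
  labels
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' standardized member expression: genes are scaled to zero mean and unit
#' variance across samples, the first right-singular direction over samples
#' is extracted, scaled to unit variance, and sign-fixed so it correlates
#' positively with the module's mean standardized expression profile.
#' Constant genes are excluded from the decomposition with a warning.
#'
#' @param expr genes x samples expression matrix.
#' @param labels named module labels covering the rows of `expr`.
#' @return List of class `module_eigengenes`: `eigengenes` (modules x
#'   samples, unit variance rows) and `variance_explained` (share of total
#'   variance carried by the first component).
#' @export
module_eigengene <- function(expr, labels) {
  labels <- labels[rownames(expr)]
  if (anyNA(labels)) stop("labels must cover all rows of 'expr'", call. = FALSE)
  mods <- setdiff(unique(labels), "grey")
  if (length(mods) == 0) stop("no modules to summarise", call. = FALSE)
  me <- matrix(NA_real_, nrow = length(mods), ncol = ncol(expr),
               dimnames = list(mods, colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    x <- expr[labels == m, , drop = FALSE]
    sds <- apply(x, 1L, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("module %s: excluding %d constant gene(s) from PCA",
                      m, sum(sds == 0)), call. = FALSE)
      x <- x[sds > 0, , drop = FALSE]
    }
    if (nrow(x) < 2L) stop(sprintf("module %s has < 2 usable genes", m),
                           call. = FALSE)
    xs <- t(scale(t(x)))
    sv <- svd(xs, nu = 0, nv = 1)
    e <- as.numeric(scale(sv$v[, 1L]))
    if (stats::cor(e, colMeans(xs)) < 0) e <- -e
    me[m, ] <- e
    ve[m] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = me, variance_explained = ve),
            class = "module_eigengenes")
}

#' Module membership (kME)
#'
#' Pearson correlation of each gene's expression with each module eigengene.
#' High kME with the gene's own module marks hub genes.
#'
#' @param expr genes x samples expression matrix.
#' @param eigengenes a [module_eigengene()] result or its eigengene matrix.
#' @return Matrix genes x modules of correlations in \[-1, 1\].
#' @export
kme <- function(expr, eigengenes) {
  if (inherits(eigengenes, "module_eigengenes")) {
    eigengenes <- eigengenes$eigengenes
  }
  stats::cor(t(expr), t(eigengenes))
}

#' Hub genes of a module
#'
#' Ranks member genes of one module by kME with its own eigengene.
#'
#' @param kme_table genes x modules kME matrix.
#' @param labels named module labels.
#' @param module module name.
#' @param n number of hubs to return (default 10).
#' @return data.frame (probe_id, kme) sorted decreasing.
#' @export
hub_genes <- function(kme_table, labels, module, n = 10L) {
  members <- names(labels)[labels == module]
  if (length(members) == 0) stop("unknown or empty module", call. = FALSE)
  v <- kme_table[members, module]
  v <- sort(v, decreasing = TRUE)
  utils::head(data.frame(probe_id = names(v), kme = unname(v),
                         stringsAsFactors = FALSE), n)
}

#' Detect modules on a built network
#'
#' Runs the dendrogram, the two-stage cut, eigengenes and kME in one step.
#'
#' @param network a `coexpression_network` from [build_network()].
#' @param expr the expression matrix the network was built from.
#' @param cut_height,min_module_size,hybrid_assign passed to [dynamic_cut()].
#' @return Object of class `module_set`: `labels`, `dendrogram`,
#'   `eigengenes`, `variance_explained`, `kme`, `cut_height`,
#'   `min_module_size`.
#' @export
detect_modules <- function(network, expr, cut_height = 0.97,
                           min_module_size = 50L, hybrid_assign = TRUE) {
  stopifnot(inherits(network, "coexpression_network"))
  dendro <- hierarchical_dendrogram(network$diss)
  labels <- dynamic_cut(dendro, network$diss, cut_height, min_module_size,
                        hybrid_assign)
  if (all(labels == "grey")) {
    me <- NULL
    km <- NULL
    ve <- numeric(0)
  } else {
    eg <- module_eigengene(expr, labels)
    me <- eg$eigengenes
    ve <- eg$variance_explained
    km <- kme(expr, me)
  }
  structure(list(
    labels = labels, dendrogram = dendro, eigengenes = me,
    variance_explained = ve, kme = km, cut_height = cut_height,
    min_module_size = as.integer(min_module_size)
  ), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  tab <- sort(table(x$labels), decreasing = TRUE)
  grey <- if ("grey" %in% names(tab)) tab[["grey"]] else 0L
  tab <- tab[names(tab) != "grey"]
  cat(sprintf("Module set: %d modules, %d genes assigned, %d grey\n",
              length(tab), sum(tab), grey))
  cat(sprintf("cut height %.2f, minimum module size %d\n",
              x$cut_height, x$min_module_size))
  if (length(tab)) print(tab)
  invisible(x)
}

#' @export
plot.module_set <- function(x, ...) {
  plot(x$dendrogram, labels = FALSE, hang = -1,
       main = "Gene dendrogram (TOM dissimilarity)",
       xlab = "", sub = "", ...)
  graphics::abline(h = x$cut_height, col = 2, lty = 2)
  invisible(x)
}
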