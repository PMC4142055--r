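#' Pairwise Pearson correlation matrix of genes
#'
#' Correlates every pair of gene rows across samples using pairwise-complete
#' observations. Zero-variance rows cannot be correlated; they are excluded
#' with a warning and recorded in the `excluded` attribute rather than
#' silently dropped. Pairs sharing fewer than `min_obs` finite observations
#' get r = 0.
#'
#' @param expr numeric matrix, genes x samples (rownames are probe ids).
#' @param min_obs minimum shared finite observations per pair (default 3).
#' @return Symmetric correlation matrix over the retained genes, with
#'   attribute `excluded` naming any dropped zero-variance rows.
#' @export
correlation_matrix <- function(expr, min_obs = 3L) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("'expr' must be a numeric matrix", call. = FALSE)
  }
  if (ncol(expr) < 4L) stop("need at least 4 samples", call. = FALSE)
  v <- apply(expr, 1L, stats::var, na.rm = TRUE)
  bad <- !is.finite(v) | v == 0
  excluded <- rownames(expr)[bad]
  if (any(bad)) {
    warning(sprintf("excluding %d zero-variance row(s): %s", sum(bad),
                    paste(utils::head(excluded, 5L), collapse = ", ")),
            call. = FALSE)
    expr <- expr[!bad, , drop = FALSE]
  }
  r <- stats::cor(t(expr), use = "pairwise.complete.obs")
  if (anyNA(expr)) {
    shared <- tcrossprod(!is.na(expr))
    r[shared < min_obs] <- 0
  }
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  attr(r, "excluded") <- excluded
  r
}

#' Soft-threshold adjacency from a correlation matrix
#'
#' Unsigned weighted-network adjacency `a_ij = |r_ij|^beta`; the diagonal is
#' set to 1.
#'
#' @param corr symmetric Pearson correlation matrix.
#' @param beta integer soft-threshold power >= 1 (default 8).
#' @return Adjacency matrix in \[0, 1\].
#' @export
adjacency_from_correlation <- function(corr, beta = 8L) {
  .check_square_symmetric(corr, "corr")
  beta <- .check_count(beta, "beta")
  a <- abs(corr)^beta
  diag(a) <- 1
  a
}

#' Whole-network connectivity
#'
#' `k_i = sum_{j != i} a_ij`, the sum of a gene's connection strengths to all
#' other network genes.
#'
#' @param adjacency adjacency matrix (diagonal ignored).
#' @return Named numeric vector of k.total per gene.
#' @export
connectivity <- function(adjacency) {
  .check_square_symmetric(adjacency, "adjacency")
  rowSums(adjacency) - diag(adjacency)
}

# Scale-free topology fit: bin log10(k) into equal-occupancy bins, estimate
# the density of k per bin, and regress log10(density) on log10(mean k).
# Returns signed R^2 = -sign(slope) * R^2 (positive when frequency falls
# with connectivity, the scale-free signature), or NA when degenerate.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < n_bins || stats::sd(k) == 0) {
    return(list(signed_r2 = NA_real_, slope = NA_real_))
  }
  lk <- log10(k)
  breaks <- unique(stats::quantile(lk, probs = seq(0, 1, length.out = n_bins + 1L),
                                   names = FALSE))
  if (length(breaks) < 4L) return(list(signed_r2 = NA_real_, slope = NA_real_))
  bin <- cut(lk, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = nlevels(bin))
  widths <- diff(10^breaks)      # bin widths on the k scale
  dens <- counts / (length(k) * widths)
  xk <- tapply(k, bin, mean)
  keep <- counts > 0 & dens > 0 & is.finite(xk)
  if (sum(keep) < 3L) return(list(signed_r2 = NA_real_, slope = NA_real_))
  x <- log10(xk[keep])
  y <- log10(dens[keep])
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[["x"]]
  list(signed_r2 = -sign(slope) * r2, slope = slope)
}

#' Scan soft-threshold powers by the scale-free topology criterion
#'
#' For each candidate power, builds the unsigned adjacency, computes the
#' connectivity distribution, and measures how well it follows a power law:
#' log10(k) is split into 10 equal-occupancy bins, the empirical density of k
#' per bin is regressed on log10(mean k) in log-log space, and the fit is
#' summarised as the signed index `-sign(slope) * R^2`. The chosen power is
#' the smallest with signed R^2 >= `r2_cut`; if none qualifies, the power
#' with maximal signed R^2.
#'
#' @param corr correlation matrix.
#' @param candidate_powers integer powers to scan.
#' @param r2_cut required signed scale-free fit index (default 0.85).
#' @param n_bins number of connectivity bins (default 10).
#' @return Object of class `soft_threshold_scan`: data.frame `scan` (power,
#'   signed_r2, slope, mean_k, median_k, max_k) and `chosen_power`.
#' @export
pick_soft_threshold <- function(corr,
                                candidate_powers = c(1:10, 12L, 14L, 16L, 18L, 20L),
                                r2_cut = 0.85, n_bins = 10L) {
  .check_square_symmetric(corr, "corr")
  if (length(candidate_powers) == 0) {
    stop("'candidate_powers' must be non-empty", call. = FALSE)
  }
  candidate_powers <- sort(unique(vapply(candidate_powers, .check_count,
                                         integer(1), name = "candidate_powers")))
  rows <- lapply(candidate_powers, function(p) {
    a <- adjacency_from_correlation(corr, p)
    k <- connectivity(a)
    fit <- scale_free_fit(k, n_bins = n_bins)
    data.frame(power = p, signed_r2 = fit$signed_r2, slope = fit$slope,
               mean_k = mean(k), median_k = stats::median(k), max_k = max(k))
  })
  scan <- do.call(rbind, rows)
  ok <- !is.na(scan$signed_r2)
  if (!any(ok)) {
    chosen <- NA_integer_
  } else if (any(scan$signed_r2[ok] >= r2_cut)) {
    chosen <- min(scan$power[ok][scan$signed_r2[ok] >= r2_cut])
  } else {
    chosen <- scan$power[ok][which.max(scan$signed_r2[ok])]
  }
  structure(list(scan = scan, chosen_power = chosen, r2_cut = r2_cut),
            class = "soft_threshold_scan")
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat("Soft-threshold scan (scale-free topology criterion)\n")
  print(x$scan, row.names = FALSE, digits = 3)
  cat(sprintf("Chosen power: %s (signed R^2 cut %.2f)\n",
              ifelse(is.na(x$chosen_power), "none", x$chosen_power), x$r2_cut))
  invisible(x)
}

#' @export
plot.soft_threshold_scan <- function(x, ...) {
  ok <- !is.na(x$scan$signed_r2)
  plot(x$scan$power[ok], x$scan$signed_r2[ok], type = "b",
       xlab = "soft-threshold power", ylab = "signed scale-free fit R^2",
       ylim = c(min(0, x$scan$signed_r2[ok]), 1), ...)
  graphics::abline(h = x$r2_cut, lty = 2)
  if (!is.na(x$chosen_power)) graphics::abline(v = x$chosen_power, col = 2, lty = 3)
  invisible(x)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_{u != i,j} a_iu a_uj` and `k` the adjacency row sums excluding
#' the diagonal; `TOM_ii = 1`. The dissimilarity is `1 - TOM`.
#'
#' @param adjacency symmetric adjacency matrix in \[0, 1\], unit diagonal.
#' @return List with `tom` (similarity) and `diss` (1 - TOM) matrices.
#' @export
tom_matrix <- function(adjacency) {
  .check_square_symmetric(adjacency, "adjacency")
  if (any(adjacency < 0 | adjacency > 1)) {
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  }
  a <- adjacency
  diag(a) <- 0
  l <- a %*% a             # (u != i,j) terms only: zero diagonal kills u = i, j
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2  # symmetrize away rounding asymmetry
  list(tom = tom, diss = 1 - tom)
}

#' Build the full weighted co-expression network
#'
#' Convenience constructor: correlation, soft-threshold scan, adjacency at
#' the chosen (or fixed) power, TOM, and connectivity, bundled as a classed
#' object.
#'
#' @param expr genes x samples expression matrix.
#' @param beta fixed soft-threshold power; `NULL` to use the scan's choice.
#'   The scan is always recorded.
#' @param candidate_powers,r2_cut passed to [pick_soft_threshold()].
#' @return Object of class `coexpression_network` with elements `beta`,
#'   `adjacency`, `tom`, `diss`, `k_total`, `scan`, `probe_ids`.
#' @export
build_network <- function(expr, beta = 8L,
                          candidate_powers = c(1:10, 12L, 14L, 16L, 18L, 20L),
                          r2_cut = 0.85) {
  r <- correlation_matrix(expr)
  scan <- pick_soft_threshold(r, candidate_powers, r2_cut)
  if (is.null(beta)) {
    beta <- scan$chosen_power
    if (is.na(beta)) stop("soft-threshold scan degenerate; supply 'beta'",
                          call. = FALSE)
  }
  a <- adjacency_from_correlation(r, beta)
  tm <- tom_matrix(a)
  structure(list(
    beta = as.integer(beta), adjacency = a, tom = tm$tom, diss = tm$diss,
    k_total = connectivity(a), scan = scan, probe_ids = rownames(a)
  ), class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("Weighted co-expression network: %d genes, beta = %d\n",
              length(x$probe_ids), x$beta))
  cat(sprintf("k.total: mean %.2f, max %.2f; scan-chosen power: %s\n",
              mean(x$k_total), max(x$k_total),
              ifelse(is.na(x$scan$chosen_power), "none", x$scan$chosen_power)))
  invisible(x)
}
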