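# Single-marker structural-equation edge orienting.
#
# Three models for the triple (marker M, gene G, trait T), each a recursive
# path model imposing exactly one vanishing partial correlation:
#   causal      M -> G -> T   (rho(M,T | G) = 0)
#   reactive    M -> T -> G   (rho(M,G | T) = 0)
#   independent G <- M -> T   (rho(G,T | M) = 0)
# Each model is scored by its Gaussian maximum-likelihood goodness of fit:
# the model-implied covariance is the sample correlation matrix with the
# non-adjacent entry replaced by the product of the two adjacent ones (the ML
# solution for a recursive chain on standardized variables), and
# chi^2 = (n - 1) * F_ML with 1 degree of freedom.

.neo_models <- c("causal", "reactive", "independent")

# implied correlation matrix for one model; S has dimnames M, G, T
.neo_implied <- function(S, model) {
  Sig <- S
  set2 <- function(i, j, v) {
    Sig[i, j] <<- v
    Sig[j, i] <<- v
  }
  switch(model,
    causal = set2("M", "T", S["M", "G"] * S["G", "T"]),
    reactive = set2("M", "G", S["M", "T"] * S["T", "G"]),
    independent = set2("G", "T", S["G", "M"] * S["M", "T"]),
    stop("unknown model")
  )
  Sig
}

# ML discrepancy F = log det(Sigma) - log det(S) + tr(S Sigma^-1) - p
.neo_discrepancy <- function(S, Sig) {
  p <- nrow(S)
  d_s <- det(S)
  d_sig <- det(Sig)
  if (d_s <= 0 || d_sig <= 0) return(NA_real_)
  log(d_sig) - log(d_s) + sum(diag(S %*% solve(Sig))) - p
}

#' Fit the three single-marker SEMs for one gene
#'
#' Standardizes marker (additive 0/1/2 codes), gene expression and trait,
#' fits the causal, reactive and independent models by Gaussian maximum
#' likelihood on the implied 3x3 covariance, and scores them by the chi-square
#' goodness-of-fit p-value (df = 1), RMSEA
#' `sqrt(max((chi2 - df) / (df * (n - 1)), 0))`, and the LEO score
#' `log10(p_causal) - log10(max(p_reactive, p_independent))`. A positive LEO
#' supports the causal orientation; 0.3 corresponds to a roughly two-fold
#' fit-probability ratio. If the causal model ties the best alternative the
#' LEO is 0 and the best model is reported as "ambiguous".
#'
#' @param marker numeric marker codes (0/1/2), one per sample.
#' @param gene numeric gene expression vector.
#' @param trait numeric trait vector.
#' @param gene_id optional identifier carried into the result.
#' @return Object of class `neo_fit`: `fits` (data.frame, one row per model:
#'   chi_square, df, model_p, rmsea), `leo_nb`, `best_model`, `n`, `gene_id`.
#' @export
neo_single_marker <- function(marker, gene, trait, gene_id = NA_character_) {
  ok <- is.finite(marker) & is.finite(gene) & is.finite(trait)
  if (sum(ok) < 10L) stop("need at least 10 complete cases", call. = FALSE)
  m <- marker[ok]; g <- gene[ok]; tr <- trait[ok]
  if (stats::sd(m) == 0) stop("marker is constant", call. = FALSE)
  if (stats::sd(g) == 0 || stats::sd(tr) == 0) {
    stop("gene and trait must be non-constant", call. = FALSE)
  }
  n <- sum(ok)
  X <- cbind(M = .standardize(m), G = .standardize(g), T = .standardize(tr))
  S <- stats::cor(X)
  if (det(S) <= 1e-12) stop("singular sample covariance", call. = FALSE)

  fits <- do.call(rbind, lapply(.neo_models, function(mod) {
    Fml <- .neo_discrepancy(S, .neo_implied(S, mod))
    chi2 <- max((n - 1) * Fml, 0)
    data.frame(model = mod, chi_square = chi2, df = 1L,
               model_p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
               rmsea = sqrt(max((chi2 - 1) / (n - 1), 0)),
               stringsAsFactors = FALSE)
  }))

  p_causal <- fits$model_p[fits$model == "causal"]
  p_alt <- max(fits$model_p[fits$model != "causal"])
  best <- fits$model[which.max(fits$model_p)]
  if (p_causal == p_alt) {
    leo <- 0
    best <- "ambiguous"
  } else {
    leo <- log10(p_causal) - log10(p_alt)
  }
  structure(list(fits = fits, leo_nb = leo, best_model = best, n = n,
                 gene_id = gene_id),
            class = "neo_fit")
}

#' @export
print.neo_fit <- function(x, ...) {
  cat(sprintf("Single-marker SEM edge orienting%s (n = %d)\n",
              if (!is.na(x$gene_id)) paste0(" for ", x$gene_id) else "", x$n))
  print(x$fits, row.names = FALSE, digits = 4)
  cat(sprintf("LEO.NB = %.3f; best model: %s\n", x$leo_nb, x$best_model))
  invisible(x)
}

#' @export
summary.neo_fit <- function(object, ...) {
  rc <- object$fits[object$fits$model == "causal", ]
  cat(sprintf(
    "LEO.NB %.3f (best: %s); causal-model chi^2 %.3f (p %.3g), RMSEA %.3f\n",
    object$leo_nb, object$best_model, rc$chi_square, rc$model_p, rc$rmsea))
  invisible(object)
}

#' Screen module genes as causal candidates
#'
#' Fits the three single-marker SEMs for every candidate gene against a
#' common marker and outcome, and flags candidates whose LEO score exceeds
#' `leo_threshold` with causal-model RMSEA at most `rmsea_threshold`. The
#' outcome may be the clinical trait or a designated gene's expression (that
#' gene is then excluded from the candidates). Genes whose fit fails (e.g. a
#' singular covariance) are kept in the table with NA statistics and noted.
#'
#' @param expr genes x samples expression matrix (typically restricted to
#'   one module).
#' @param marker numeric marker codes per sample.
#' @param outcome numeric trait vector, or a single gene id present in
#'   `expr`.
#' @param candidates gene ids to screen (default: all rows of `expr`).
#' @param leo_threshold LEO score required to flag a candidate (default 0.3).
#' @param rmsea_threshold maximum causal-model RMSEA to flag (default 0.05).
#' @return Object of class `neo_screen`: data.frame sorted by decreasing
#'   LEO with per-model chi-square/p/RMSEA, `leo_nb`, `best_model`,
#'   `flagged`.
#' @export
screen_candidates <- function(expr, marker, outcome,
                              candidates = rownames(expr),
                              leo_threshold = 0.3, rmsea_threshold = 0.05) {
  if (is.character(outcome)) {
    if (length(outcome) != 1L || !outcome %in% rownames(expr)) {
      stop("outcome gene not found in expression matrix", call. = FALSE)
    }
    candidates <- setdiff(candidates, outcome)
    outcome_vec <- expr[outcome, ]
  } else {
    outcome_vec <- outcome
  }
  if (length(candidates) == 0) stop("no candidate genes", call. = FALSE)
  missing <- setdiff(candidates, rownames(expr))
  if (length(missing)) {
    stop("candidates absent from expression matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(candidates, function(gid) {
    fit <- tryCatch(neo_single_marker(marker, expr[gid, ], outcome_vec, gid),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      message(sprintf("NEO fit failed for %s: %s", gid, conditionMessage(fit)))
      return(data.frame(
        gene = gid, chi2_causal = NA_real_, p_causal = NA_real_,
        rmsea_causal = NA_real_, chi2_reactive = NA_real_,
        p_reactive = NA_real_, rmsea_reactive = NA_real_,
        chi2_independent = NA_real_, p_independent = NA_real_,
        rmsea_independent = NA_real_, leo_nb = NA_real_,
        best_model = NA_character_, flagged = FALSE, stringsAsFactors = FALSE))
    }
    f <- fit$fits
    g <- function(mod, col) f[f$model == mod, col]
    data.frame(
      gene = gid,
      chi2_causal = g("causal", "chi_square"),
      p_causal = g("causal", "model_p"),
      rmsea_causal = g("causal", "rmsea"),
      chi2_reactive = g("reactive", "chi_square"),
      p_reactive = g("reactive", "model_p"),
      rmsea_reactive = g("reactive", "rmsea"),
      chi2_independent = g("independent", "chi_square"),
      p_independent = g("independent", "model_p"),
      rmsea_independent = g("independent", "rmsea"),
      leo_nb = fit$leo_nb, best_model = fit$best_model,
      flagged = is.finite(fit$leo_nb) && fit$leo_nb > leo_threshold &&
        g("causal", "rmsea") <= rmsea_threshold,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$leo_nb, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(table = out, leo_threshold = leo_threshold,
                 rmsea_threshold = rmsea_threshold),
            class = "neo_screen")
}

#' @export
print.neo_screen <- function(x, ...) {
  cat(sprintf(
    "NEO single-marker screen: %d candidates, %d flagged (LEO > %.2f, RMSEA <= %.2f)\n",
    nrow(x$table), sum(x$table$flagged, na.rm = TRUE),
    x$leo_threshold, x$rmsea_threshold))
  cols <- c("gene", "leo_nb", "p_causal", "rmsea_causal", "best_model", "flagged")
  print(utils::head(x$table[, cols], 10L), row.names = FALSE, digits = 3)
  invisible(x)
}
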