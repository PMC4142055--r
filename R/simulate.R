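#' Simulation settings for an F2-intercross expression study
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' Defaults emulate the study design the package targets: an F2 mouse
#' intercross of about 90 animals, a few thousand liver probes organised in
#' correlated modules of unequal size, one module linked to a quantitative
#' lesion trait through a marker -> gene -> trait causal chain, and a set of
#' trait-reactive genes.
#'
#' @param n_samples number of F2 animals (default 90).
#' @param module_sizes integer vector of planted module sizes; the first
#'   module hosts the causal chain gene.
#' @param within_module_cor target pairwise correlation inside each module,
#'   in (0, 1); recycled across modules.
#' @param n_background_genes number of unstructured noise genes.
#' @param n_markers number of independent F2 markers (codes 0/1/2).
#' @param a1 standardized path coefficient marker -> causal gene; when
#'   modules are planted, `a1^2 + within_module_cor` must stay below 1 so
#'   the chain gene can keep its module's correlation structure.
#' @param a2 standardized path coefficient causal gene -> trait, in [0, 1).
#' @param n_reactive_genes number of genes downstream of the trait.
#' @param b standardized path coefficient trait -> reactive gene, in [0, 1).
#' @param noise_sd scale of the idiosyncratic noise on ordinary module genes
#'   and background genes (1 keeps within-module correlation at
#'   `within_module_cor`).
#' @param seed integer seed fixing every random draw.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 90,
                       module_sizes = c(500, 300, 200, 150, 100),
                       within_module_cor = 0.7,
                       n_background_genes = 750,
                       n_markers = 1,
                       a1 = 0.5,
                       a2 = 0.5,
                       n_reactive_genes = 20,
                       b = 0.5,
                       noise_sd = 1,
                       seed = 1L) {
  n_samples <- .check_count(n_samples, "n_samples")
  if (length(module_sizes) > 0) {
    module_sizes <- vapply(module_sizes, .check_count, integer(1),
                           name = "module_sizes")
  } else {
    module_sizes <- integer(0)
  }
  if (length(module_sizes) == 0 && n_background_genes == 0 &&
      n_reactive_genes == 0) {
    stop("simulation must contain at least one gene", call. = FALSE)
  }
  within_module_cor <- .check_fraction(within_module_cor, "within_module_cor")
  within_module_cor <- rep_len(within_module_cor, length(module_sizes))
  n_background_genes <- .check_count(n_background_genes, "n_background_genes",
                                     min = 0L)
  n_markers <- .check_count(n_markers, "n_markers")
  n_reactive_genes <- .check_count(n_reactive_genes, "n_reactive_genes",
                                   min = 0L)
  for (p in c(a1 = a1, a2 = a2, b = b)) {
    if (!is.finite(p)) stop("path coefficients must be finite", call. = FALSE)
  }
  if (abs(a1) >= 1 || abs(a2) >= 1 || abs(b) >= 1) {
    stop("standardized path coefficients must have absolute value < 1",
         call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("'noise_sd' must be a non-negative number", call. = FALSE)
  }
  if (length(module_sizes) > 0 && a1 != 0 &&
      a1^2 + within_module_cor[1L] >= 1) {
    stop("a1^2 + within_module_cor of the first module must be < 1 ",
         "(the chain gene carries both the marker effect and its module ",
         "factor)", call. = FALSE)
  }
  structure(list(
    n_samples = n_samples, module_sizes = module_sizes,
    within_module_cor = within_module_cor,
    n_background_genes = n_background_genes, n_markers = n_markers,
    a1 = a1, a2 = a2, n_reactive_genes = n_reactive_genes, b = b,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate F2-intercross genotypes
#'
#' Each marker is drawn independently per animal with genotype codes 0, 1, 2
#' at the Mendelian F2 frequencies 1/4, 1/2, 1/4.
#'
#' @param n_samples number of animals.
#' @param n_markers number of markers.
#' @param seed optional integer seed; if `NULL` the current RNG state is used.
#' @return Integer matrix (samples x markers) with dimnames.
#' @export
simulate_f2_genotypes <- function(n_samples, n_markers = 1, seed = NULL) {
  n_samples <- .check_count(n_samples, "n_samples")
  n_markers <- .check_count(n_markers, "n_markers")
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(stats::rbinom(n_samples * n_markers, size = 2L, prob = 0.5),
              nrow = n_samples, ncol = n_markers)
  dimnames(g) <- list(sprintf("sample_%03d", seq_len(n_samples)),
                      sprintf("marker_%d", seq_len(n_markers)))
  g
}

#' Simulate an expression study with planted modules and a causal chain
#'
#' Generates a probes x samples log2-scale expression matrix, a quantitative
#' trait, F2 marker genotypes, and the ground truth needed to score every
#' downstream stage. Module genes load on one latent factor per module
#' (`sqrt(w) * factor + noise_sd * sqrt(1 - w) * eps`), so with `noise_sd = 1`
#' the expected within-module pairwise correlation is `w`. The first gene of
#' the first module is the chain gene G built as
#' `sqrt(w) * factor + a1 * M + sqrt(1 - w - a1^2) * eps` with M the
#' standardized additive marker code, so G keeps the module's correlation
#' with its peers while carrying the marker effect; the trait is
#' `a2 * std(G) + sqrt(1 - a2^2) * eps`, so cor(marker, trait) is close to
#' `a1 * a2` and the marker-trait partial correlation given G vanishes.
#' Reactive genes are `b * std(trait) + sqrt(1 - b^2) * eps`; background genes
#' are independent noise. Each gene gets its own baseline intensity near 8 to
#' mimic log2 array data (correlations are unaffected).
#'
#' @param config a [sim_config()].
#' @return A list with elements `expr` (genes x samples matrix),
#'   `annotation` (data.frame: probe_id, gene_symbol, entrez_id, chromosome,
#'   mb), `trait` (named numeric vector), `genotypes` (samples x markers),
#'   and `truth` (list: true_module_label, causal_gene_ids,
#'   reactive_gene_ids, marker_id, trait_values).
#' @export
simulate_network_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  sizes <- config$module_sizes
  w <- config$within_module_cor
  n_mod_genes <- sum(sizes)
  n_genes <- n_mod_genes + config$n_background_genes + config$n_reactive_genes
  if (n_genes == 0) stop("no genes to simulate", call. = FALSE)

  genotypes <- simulate_f2_genotypes(n, config$n_markers)
  marker_id <- colnames(genotypes)[1L]
  m_raw <- genotypes[, 1L]
  m_std <- if (stats::sd(m_raw) > 0) .standardize(m_raw) else rep(0, n)

  sample_ids <- rownames(genotypes)
  expr <- matrix(NA_real_, nrow = n_genes, ncol = n,
                 dimnames = list(sprintf("probe_%04d", seq_len(n_genes)),
                                 sample_ids))
  labels <- character(n_genes)

  row <- 0L
  chain_gene <- NA_character_
  chain_values <- NULL
  for (mi in seq_along(sizes)) {
    f <- stats::rnorm(n)
    for (gi in seq_len(sizes[mi])) {
      row <- row + 1L
      labels[row] <- paste0("module_", mi)
      if (mi == 1L && gi == 1L) {
        # chain gene: marker effect plus its module's factor, unit variance
        g <- sqrt(w[mi]) * f + config$a1 * m_std +
          sqrt(max(1 - w[mi] - config$a1^2, 0)) * stats::rnorm(n)
        chain_gene <- rownames(expr)[row]
        chain_values <- g
        expr[row, ] <- g
      } else {
        expr[row, ] <- sqrt(w[mi]) * f +
          config$noise_sd * sqrt(1 - w[mi]) * stats::rnorm(n)
      }
    }
  }

  if (is.null(chain_values)) {
    # no modules planted: the trait is driven by the marker alone
    chain_values <- m_std
  }
  trait <- config$a2 * .standardize(chain_values) +
    sqrt(1 - config$a2^2) * stats::rnorm(n)
  names(trait) <- sample_ids
  t_std <- .standardize(trait)

  if (config$n_background_genes > 0) {
    for (gi in seq_len(config$n_background_genes)) {
      row <- row + 1L
      labels[row] <- "background"
      expr[row, ] <- config$noise_sd * stats::rnorm(n)
    }
  }
  reactive_ids <- character(0)
  if (config$n_reactive_genes > 0) {
    for (gi in seq_len(config$n_reactive_genes)) {
      row <- row + 1L
      labels[row] <- "background"
      reactive_ids <- c(reactive_ids, rownames(expr)[row])
      expr[row, ] <- config$b * t_std +
        sqrt(1 - config$b^2) * stats::rnorm(n)
    }
  }

  baseline <- stats::rnorm(n_genes, mean = 8, sd = 1)
  expr <- expr + baseline

  names(labels) <- rownames(expr)
  causal_ids <- if (!is.na(chain_gene) && config$a1 != 0 && config$a2 != 0) {
    chain_gene
  } else {
    character(0)
  }

  annotation <- data.frame(
    probe_id = rownames(expr),
    gene_symbol = sprintf("Gene%04d", seq_len(n_genes)),
    entrez_id = 100000L + seq_len(n_genes),
    chromosome = as.character(1L + (seq_len(n_genes) - 1L) %% 19L),
    mb = round(stats::runif(n_genes, 3, 180), 3),
    stringsAsFactors = FALSE
  )

  list(
    expr = expr,
    annotation = annotation,
    trait = trait,
    genotypes = genotypes,
    truth = list(
      true_module_label = labels,
      causal_gene_ids = causal_ids,
      reactive_gene_ids = reactive_ids,
      marker_id = marker_id,
      trait_values = trait
    )
  )
}
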