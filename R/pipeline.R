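#' Pipeline configuration
#'
#' Assembles and validates the settings of the end-to-end analysis. File
#' paths may be `NULL` when the corresponding stage is skipped (enrichment
#' needs `gmt_file`; causal orienting needs `genotype_file` and `marker`).
#'
#' @param expr_file expression TSV path.
#' @param trait_file trait TSV path.
#' @param genotype_file optional genotype TSV path.
#' @param annotation_file optional probe annotation TSV path.
#' @param gmt_file optional GMT gene-set path.
#' @param marker marker column name for the SEM screen (default: first
#'   marker in the genotype file).
#' @param beta soft-threshold power (default 8).
#' @param cut_height,min_module_size branch-cut settings (defaults 0.97, 50).
#' @param set_size,n_sets,ms_quantile permutation-null settings (defaults
#'   400, 10000, 0.95).
#' @param leo_threshold,rmsea_threshold SEM flag thresholds (defaults 0.3,
#'   0.05).
#' @param edge_weight_threshold TOM weight cut for graph export (default
#'   0.02; unsigned beta = 8 TOM values are small, e.g. about 0.06 between
#'   genes correlated at 0.7).
#' @param seed integer seed for every random step.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expr_file, trait_file,
                            genotype_file = NULL, annotation_file = NULL,
                            gmt_file = NULL, marker = NULL,
                            beta = 8L, cut_height = 0.97,
                            min_module_size = 50L, set_size = 400L,
                            n_sets = 10000L, ms_quantile = 0.95,
                            leo_threshold = 0.3, rmsea_threshold = 0.05,
                            edge_weight_threshold = 0.02, seed = 1L) {
  cfg <- list(
    expr_file = expr_file, trait_file = trait_file,
    genotype_file = genotype_file, annotation_file = annotation_file,
    gmt_file = gmt_file, marker = marker,
    beta = .check_count(beta, "beta"),
    cut_height = .check_fraction(cut_height, "cut_height", 0, 1, open = FALSE),
    min_module_size = .check_count(min_module_size, "min_module_size"),
    set_size = .check_count(set_size, "set_size"),
    n_sets = .check_count(n_sets, "n_sets"),
    ms_quantile = .check_fraction(ms_quantile, "ms_quantile"),
    leo_threshold = leo_threshold,
    rmsea_threshold = .check_fraction(rmsea_threshold, "rmsea_threshold",
                                      0, 1, open = FALSE),
    edge_weight_threshold = .check_fraction(edge_weight_threshold,
                                            "edge_weight_threshold",
                                            0, 1, open = FALSE),
    seed = as.integer(seed)
  )
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' File paths in the configuration are resolved relative to the config
#' file's directory.
#'
#' @param path YAML (.yaml/.yml) or JSON config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  for (f in c("expr_file", "trait_file", "genotype_file", "annotation_file",
              "gmt_file")) {
    if (!is.null(raw[[f]]) && !grepl("^/", raw[[f]])) {
      raw[[f]] <- file.path(base, raw[[f]])
    }
  }
  do.call(pipeline_config, raw)
}

# fixed-format numeric tables so identical results give identical bytes
.write_result_tsv <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1)) & !vapply(d, is.integer, logical(1))
  d[num] <- lapply(d[num], function(x) sprintf("%.10g", x))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full co-expression analysis pipeline
#'
#' Validates inputs, then runs: network construction (correlation,
#' soft-threshold scan, adjacency at the configured power, TOM,
#' connectivity), module detection, trait association with the permutation
#' MS threshold, optional gene-set enrichment, and the optional single-marker
#' SEM screen of the most trait-significant module. Results are written as
#' TSV tables plus a JSON manifest recording the configuration, seed, row
#' counts and package version; the adjacency/TOM arrays are saved as an RDS
#' container with a JSON sidecar of probe ids.
#'
#' @param config a [pipeline_config()] (or path readable by
#'   [read_pipeline_config()]).
#' @param out_dir output directory.
#' @param keep_network save the adjacency/TOM container (default TRUE).
#' @return Object of class `coexnet_run` bundling all stage results.
#' @export
run_pipeline <- function(config, out_dir, keep_network = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  # validation first: every referenced input must exist before any compute
  for (f in c("expr_file", "trait_file", "genotype_file", "annotation_file",
              "gmt_file")) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("input file not found (%s): %s", f, p), call. = FALSE)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  expr <- read_expression_tsv(config$expr_file)
  trait <- read_trait_tsv(config$trait_file)
  annot <- if (!is.null(config$annotation_file)) {
    read_annotation_tsv(config$annotation_file)
  } else {
    NULL
  }
  say("stage input: %d probes x %d samples", nrow(expr), ncol(expr))

  set.seed(config$seed)
  net <- build_network(expr, beta = config$beta)
  say("stage network: beta %d, scan-chosen power %s", net$beta,
      ifelse(is.na(net$scan$chosen_power), "none", net$scan$chosen_power))

  mods <- detect_modules(net, expr, cut_height = config$cut_height,
                         min_module_size = config$min_module_size)
  n_mod <- length(setdiff(unique(mods$labels), "grey"))
  say("stage modules: %d modules, %d grey genes", n_mod,
      sum(mods$labels == "grey"))

  assoc <- trait_association(expr, trait, mods$labels,
                             set_size = config$set_size,
                             n_sets = config$n_sets,
                             quantile = config$ms_quantile,
                             seed = config$seed)
  say("stage trait: MS threshold %.4f, significant: %s", assoc$threshold$threshold,
      if (length(assoc$significant_modules)) {
        paste(assoc$significant_modules, collapse = ", ")
      } else {
        "none"
      })

  enrichment <- NULL
  if (!is.null(config$gmt_file)) {
    sets <- read_gmt(config$gmt_file)
    if (!is.null(annot)) {
      coll <- collapse_probes(annot, net$k_total)
      sym <- stats::setNames(coll$gene_symbol, coll$probe_id)
      members <- split(stats::na.omit(sym[names(mods$labels)]),
                       mods$labels[names(stats::na.omit(sym[names(mods$labels)]))])
      background <- unname(sym)
    } else {
      members <- split(names(mods$labels), mods$labels)
      background <- names(mods$labels)
    }
    members <- members[setdiff(names(members), "grey")]
    enrichment <- enrich_modules(members, sets, background)
    say("stage enrich: %d tests, min FDR %.3g", nrow(enrichment),
        min(enrichment$fdr))
  }

  neo <- NULL
  if (!is.null(config$genotype_file)) {
    geno <- read_genotype_tsv(config$genotype_file)
    geno <- geno[colnames(expr), , drop = FALSE]
    marker <- if (is.null(config$marker)) colnames(geno)[1L] else config$marker
    if (!marker %in% colnames(geno)) {
      stop("marker not found in genotype file: ", marker, call. = FALSE)
    }
    target <- assoc$significant_modules
    target <- target[1L]
    if (length(target) == 0 || is.na(target)) {
      say("stage neo: skipped (no significant module)")
    } else {
      cand <- names(mods$labels)[mods$labels == target]
      neo <- screen_candidates(expr[cand, , drop = FALSE], geno[, marker],
                               trait[colnames(expr)],
                               leo_threshold = config$leo_threshold,
                               rmsea_threshold = config$rmsea_threshold)
      say("stage neo: module %s, %d candidates, %d flagged", target,
          nrow(neo$table), sum(neo$table$flagged, na.rm = TRUE))
    }
  }

  # ---- outputs ----
  assign_tab <- data.frame(
    probe_id = names(mods$labels), module = unname(mods$labels),
    k_total = unname(net$k_total[names(mods$labels)]),
    gs = unname(assoc$gs[names(mods$labels)]),
    stringsAsFactors = FALSE
  )
  if (!is.null(mods$kme)) {
    own <- rep(NA_real_, length(mods$labels))
    nz <- mods$labels != "grey"
    own[nz] <- mods$kme[cbind(names(mods$labels)[nz], mods$labels[nz])]
    assign_tab$kme_own_module <- own
  }
  if (!is.null(annot)) {
    assign_tab$gene_symbol <-
      annot$gene_symbol[match(assign_tab$probe_id, annot$probe_id)]
  }
  .write_result_tsv(assign_tab, file.path(out_dir, "modules.tsv"))
  if (!is.null(mods$eigengenes)) {
    eg <- data.frame(module = rownames(mods$eigengenes), mods$eigengenes,
                     check.names = FALSE, stringsAsFactors = FALSE)
    .write_result_tsv(eg, file.path(out_dir, "eigengenes.tsv"))
  }
  .write_result_tsv(net$scan$scan, file.path(out_dir, "soft_threshold_scan.tsv"))
  .write_result_tsv(assoc$ms, file.path(out_dir, "module_significance.tsv"))
  if (!is.null(enrichment)) {
    .write_result_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
  }
  if (!is.null(neo)) {
    .write_result_tsv(neo$table, file.path(out_dir, "neo.tsv"))
  }
  edges <- export_graph(net, mods$labels,
                        weight_threshold = config$edge_weight_threshold,
                        path_prefix = file.path(out_dir, "network"))
  if (keep_network) {
    saveRDS(list(adjacency = net$adjacency, tom = net$tom), # nolint
            file.path(out_dir, "network_arrays.rds"))
    jsonlite::write_json(list(probe_ids = net$probe_ids, beta = net$beta),
                         file.path(out_dir, "network_arrays.json"),
                         auto_unbox = TRUE)
  }

  manifest <- list(
    package = "coexnet",
    version = as.character(utils::packageVersion("coexnet")),
    seed = config$seed,
    config = unclass(config),
    n_probes = nrow(expr), n_samples = ncol(expr),
    n_modules = n_mod,
    ms_threshold = assoc$threshold$threshold,
    significant_modules = as.list(assoc$significant_modules),
    flagged_causal_genes = if (!is.null(neo)) {
      as.list(neo$table$gene[which(neo$table$flagged)])
    } else {
      list()
    },
    n_edges_exported = nrow(edges),
    rows = list(modules = nrow(assign_tab),
                module_significance = nrow(assoc$ms),
                enrichment = if (is.null(enrichment)) 0L else nrow(enrichment),
                neo = if (is.null(neo)) 0L else nrow(neo$table)),
    log = log_lines
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(
    config = config, network = net, modules = mods, trait_association = assoc,
    enrichment = enrichment, neo = neo, manifest = manifest,
    out_dir = out_dir
  ), class = "coexnet_run")
}

#' @export
print.coexnet_run <- function(x, ...) {
  cat("Co-expression pipeline run\n")
  print(x$network)
  print(x$modules)
  print(x$trait_association$threshold)
  cat(sprintf("significant module(s): %s\n",
              if (length(x$trait_association$significant_modules)) {
                paste(x$trait_association$significant_modules, collapse = ", ")
              } else {
                "none"
              }))
  if (!is.null(x$neo)) print(x$neo)
  invisible(x)
}

#' @export
summary.coexnet_run <- function(object, ...) {
  print(object)
  if (!is.null(object$enrichment)) {
    cat("top enrichment rows:\n")
    print(utils::head(object$enrichment, 5L), row.names = FALSE, digits = 3)
  }
  invisible(object)
}

#' Export the network for graph viewers
#'
#' Writes an undirected edge list (gene1, gene2, TOM weight) filtered at a
#' weight threshold, and a GraphML file with module and k.total node
#' attributes readable by Cytoscape.
#'
#' @param network a `coexpression_network`.
#' @param labels named module labels (optional).
#' @param weight_threshold minimum TOM weight for an edge to be kept.
#' @param path_prefix if non-NULL, writes `<prefix>_edges.tsv` and
#'   `<prefix>.graphml`.
#' @return data.frame of kept edges, invisibly when files are written.
#' @export
export_graph <- function(network, labels = NULL, weight_threshold = 0.1,
                         path_prefix = NULL) {
  stopifnot(inherits(network, "coexpression_network"))
  if (weight_threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  tom <- network$tom
  ids <- network$probe_ids
  keep <- which(upper.tri(tom) & tom >= weight_threshold, arr.ind = TRUE)
  edges <- data.frame(
    gene1 = ids[keep[, 1L]], gene2 = ids[keep[, 2L]],
    weight = tom[keep], stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$gene1, edges$gene2), , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0) {
    warning("weight threshold excludes all edges", call. = FALSE)
  }
  if (!is.null(path_prefix)) {
    .write_result_tsv(edges, paste0(path_prefix, "_edges.tsv"))
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(
        name = ids,
        module = if (is.null(labels)) "unassigned" else unname(labels[ids]),
        k_total = unname(network$k_total[ids]),
        stringsAsFactors = FALSE
      )
    )
    igraph::write_graph(g, paste0(path_prefix, ".graphml"), format = "graphml")
    return(invisible(edges))
  }
  edges
}
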