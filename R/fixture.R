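#' Prepare the packaged demo study
#'
#' Simulates the study described by the packaged fixture configuration (an
#' F2 intercross with planted modules, a causal chain and reactive genes),
#' writes the pipeline input files (expression, trait, genotypes, annotation,
#' truth JSON) into `dir`, and also writes a small GMT with one synthetic
#' signature planted inside the first module (plus some background genes) so
#' the enrichment stage has something to find.
#'
#' @param dir directory to populate.
#' @param config_file YAML fixture description; defaults to the packaged one.
#' @return List: `config` (a ready [pipeline_config()]), `sim` (the
#'   simulation, including truth), `gmt_file`.
#' @export
prepare_demo_study <- function(dir,
                               config_file = system.file("extdata",
                                                         "fixture_config.yaml",
                                                         package = "coexnet")) {
  fx <- yaml::read_yaml(config_file)
  sim_cfg <- do.call(sim_config, fx$simulation)
  sim <- simulate_network_expression(sim_cfg)
  write_simulation(sim, dir)

  # plant a signature: member symbols of the first module plus background
  ann <- sim$annotation
  labels <- sim$truth$true_module_label
  first_mod <- labels[labels != "background"][1L]
  mod_sym <- ann$gene_symbol[match(names(labels)[labels == first_mod],
                                   ann$probe_id)]
  bg_sym <- ann$gene_symbol[match(names(labels)[labels == "background"],
                                  ann$probe_id)]
  sig <- c(utils::head(mod_sym, fx$signature$n_module_genes),
           utils::head(bg_sym, fx$signature$n_background_genes))
  gmt_file <- file.path(dir, "signature.gmt")
  write_gmt(list(planted_signature = sig), gmt_file,
            descriptions = c(planted_signature = "synthetic planted signature"))

  cfg <- do.call(pipeline_config, c(
    list(expr_file = file.path(dir, "expression.tsv"),
         trait_file = file.path(dir, "trait.tsv"),
         genotype_file = file.path(dir, "genotypes.tsv"),
         annotation_file = file.path(dir, "annotation.tsv"),
         gmt_file = gmt_file,
         seed = sim_cfg$seed),
    fx$pipeline
  ))
  list(config = cfg, sim = sim, gmt_file = gmt_file)
}
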