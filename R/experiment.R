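# Seeded simulate-and-mine experiment: the package's own end-to-end
# validation harness.

#' Run a multi-species simulate-and-mine experiment
#'
#' Draws element templates, simulates `n_species` pseudo-species of
#' `n_genomes` genomes each with planted copies, mines them with
#' [run_tcme_pipeline()] using a reference library built from the same
#' templates, and scores the recovered elements against the ground-truth
#' ledger.
#'
#' @param n_species number of pseudo-species.
#' @param n_genomes genomes per species.
#' @param genome_length genome length in nt.
#' @param divergence per-site substitution rate of planted copies.
#' @param truncation_fraction,decay_fraction see [tcme_simulate()].
#' @param copy_number per-subgroup Poisson means (default 0.8 each).
#' @param seed integer master seed; all stage seeds derive from it.
#' @param run_phylogeny forwarded to [tcme_config()].
#' @param bootstrap_replicates forwarded to [tcme_config()].
#' @return list with `result` (a `tcme_result`), `ledger`, `templates`,
#'   `metrics` (from [recovery_metrics()]).
#' @export
tcme_experiment <- function(n_species = 6L, n_genomes = 20L,
                            genome_length = 500000L, divergence = 0.02,
                            truncation_fraction = 0.15,
                            decay_fraction = 0.15,
                            copy_number = NULL,
                            seed = 1L, run_phylogeny = FALSE,
                            bootstrap_replicates = 1000L) {
  species <- paste("Synthetica",
                   c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                     "eta", "theta", "iota", "kappa")[seq_len(n_species)])
  templates <- tcme_templates(seed = derive_seed(seed, "templates"))
  reference <- tcme_reference(templates)
  genomes <- list()
  ledgers <- list()
  for (i in seq_along(species)) {
    sim <- tcme_simulate(
      templates, n_genomes = n_genomes, genome_length = genome_length,
      divergence = divergence, truncation_fraction = truncation_fraction,
      decay_fraction = decay_fraction, copy_number = copy_number,
      species = species[i],
      seed = derive_seed(seed, paste0("sim", i)))
    g <- sim$genomes
    l <- sim$ledger
    tag <- sprintf("sp%d_", i)
    g$genome_id <- paste0(tag, g$genome_id)
    l$genome_id <- paste0(tag, l$genome_id)
    genomes[[i]] <- g
    ledgers[[i]] <- l
  }
  genomes <- dplyr::bind_rows(genomes)
  ledger <- dplyr::bind_rows(ledgers)
  cfg <- tcme_config(seed = derive_seed(seed, "pipeline"),
                     run_phylogeny = run_phylogeny,
                     bootstrap_replicates = bootstrap_replicates)
  result <- run_tcme_pipeline(genomes, reference = reference, config = cfg)
  metrics <- recovery_metrics(result$elements, ledger)
  list(result = result, ledger = ledger, templates = templates,
       metrics = metrics)
}
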