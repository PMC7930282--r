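# cached synthetic studies and pipeline runs shared across test files
.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(config = generator_config(seed = 7L)) {
  key <- paste0("sim_", digest_key(config))
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_venom_study(config)
  .sim_cache[[key]]
}

cached_pipeline <- function(config = generator_config(seed = 7L)) {
  key <- paste0("pipe_", digest_key(config))
  if (is.null(.sim_cache[[key]])) {
    sim <- cached_sim(config)
    .sim_cache[[key]] <- run_venom_pipeline(
      sim$contigs, sim$annotations, sim$peptides, sim$reference,
      counts = sim$counts, ontology = sim$ontology)
  }
  .sim_cache[[key]]
}

digest_key <- function(config) paste(unlist(config), collapse = "_")
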