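# small simulated datasets shared across test files

tiny_config <- function(n_cells = 300, seed = 42, ...) {
  sim_config(n_cells = n_cells, seed = seed, ...)
}

# run the full analysis quietly (boundary-tie warnings from integer ADT
# counts are expected)
quiet_analyze <- function(sim, params = pipeline_config()) {
  suppressWarnings(analyze_repertoire(sim$vdj, sim$counts, sim$meta,
                                      params))
}
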