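# Shared fixtures: one default condition/parameter set, and a cache so that
# expensive simulation batches are run once and reused across test blocks.

the_cond <- experimental_conditions()
the_params <- synapse_params(the_cond)

.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# fast engine controls for tests where long equilibration is irrelevant
fast_ctrl <- list(warmup_det = 20, warmup_stoch = 1)
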