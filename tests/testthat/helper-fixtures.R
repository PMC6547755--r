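# Shared fixtures: seeded random states, parameter draws and small lattices.
fx <- generate_fixtures(n_states = 12, n_params = 12, n_lattices = 3,
                        M = 20, N = 5, L = 8, seed = 424242)

# shorthand parameter sets used across files
params_sync <- function(...) pgg_params(..., mechanism = "synchronous")
params_async <- function(...) pgg_params(..., mechanism = "asynchronous")
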