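# Shared fixtures, built in code.

hi_cell <- function(n = 500, b3 = 0.2, ...) {
  design_cell(n = n, b3 = b3, reliability = "high", ...)
}

hi_spec <- function(n = 500, b3 = 0.2, ...) {
  make_population_spec(hi_cell(n = n, b3 = b3, ...))
}

# five-case fixture for likelihood oracles
tiny_data <- function(seed = 42) {
  generate_dataset(hi_spec(), n = 5, seed = seed)
}
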