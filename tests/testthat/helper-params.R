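# Parameter tweaks used across tests (internal-style helpers kept out of
# the package API).

.set_stimulus_off <- function(params) {
  params$value[match("S0", params$name)] <- 0
  params
}

.set_value <- function(params, name, value) {
  params$value[match(name, params$name)] <- value
  params
}

# set named parameters to exactly zero (apply_override only scales by
# positive factors)
.zero_params <- function(params, names) {
  for (nm in names) params$value[match(nm, params$name)] <- 0
  params
}
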