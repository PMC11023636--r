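# small fast parameter set shared across solver tests; retraction event
# process deliberately short so test horizons stay cheap
test_params <- function(...) {
  p <- model_params()
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  validate_model_params(p)
  structure(p, class = "model_params")
}

# uniform density field helper
uniform_field <- function(value, n = 32) {
  density_field(matrix(value, n + 1, n + 1), h = 1 / n)
}
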