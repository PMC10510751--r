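# Shared parameter sets (loading is deterministic but not free; reuse).
PARAMS_PZ <- load_parameter_set(alphabet_mode("DNA-PZ"))
PARAMS_DNA <- load_parameter_set(alphabet_mode("canonical-DNA"))

random_pz_string <- function(n, alphabet = c("A", "C", "G", "T", "P", "Z")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
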