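# short sessions used across tests; all fixtures are generated in code

short_active <- function(n_laps = 3, ...) {
  preset_protocol("novel_active", n_laps = n_laps, ...)
}

# closed-form dendritic nonlinearity, written independently of g_dend()
g_dend_oracle <- function(I, a1 = 4 / 3, a2 = 2 / 3, I0 = 2.5) {
  lin <- tanh(I / I0)
  a1 * ifelse(lin > 0, lin, 0) + a2 * (tanh(2 * (I - I0)) + 1) / 2
}
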