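# shared fixtures: the packaged base case and cheap derived objects
base_params <- load_parameter_table()

# parameter set with every distribution degenerate at its base value
fixed_params <- local({
  p <- base_params
  p$distribution <- "fixed"
  p$ui_low <- p$base
  p$ui_high <- p$base
  p
})

# deterministic no-disease-mortality variant used by bookkeeping checks
no_mortality_params <- local({
  p <- base_params
  p$base[p$name == "bg_mort"] <- 0
  p$ui_low[p$name == "bg_mort"] <- 0
  for (nm in paste0("surv5_crc", 1:4)) p <- set_param(p, nm, 1)
  for (nm in c("utility_general", "utility_aa", paste0("utility_crc", 1:4))) {
    p <- set_param(p, nm, 1)
  }
  p <- set_param(p, "discount_rate", 0)
  p
})
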