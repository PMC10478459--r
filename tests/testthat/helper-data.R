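# Small simulated datasets shared across tests.

tiny_cfg <- function(..., seed = 1) {
  defaults <- list(n_lines = 24, n_markers = 120, n_features = 30,
                   years = c("Y1", "Y2"), locations = "Loc",
                   lines_per_trial = c(8, 12), second_appearance_prop = 0.3,
                   plots_per_batch = 20, seed = seed)
  do.call(sim_config, modifyList(defaults, list(...)))
}

# variance set for a pure-GBLUP generative model (no metabolomic signal)
gblup_truth <- c(alpha = 0, g1 = 0.5, l1 = 0.2, ig1 = 0.3, il1 = 0.2,
                 t1 = 0.15, e1 = 0.6)
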