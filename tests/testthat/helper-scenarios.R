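# shared simulation fixtures, built in code at test time

sustained_scenario <- function(read_interval = 0.5) {
  kinetic_scenario(onset_rate = log(2) / 1.5, baseline_duration = 5,
                   read_interval = read_interval, total_duration = 35)
}

# one full-ish agonist plus one partial agonist on one pathway
single_pathway_params <- function() {
  dplyr::bind_rows(
    ligand_params("reference", "cAMP", Em = 100, log_tau = 0.7, log_KA = -8.5),
    ligand_params("analog", "cAMP", Em = 100, log_tau = 0.2, log_KA = -8.5)
  )
}

# run one simulated two-pathway bias study and return the analog's summary row
run_bias_study <- function(dd_true = 0.5, seed = 1L, n_blocks = 5,
                           cv = 0.05, block_sd = 0.1) {
  nm <- noise_model(cv, 1, block_sd, seed = seed)
  cr <- simulate_cr_study(bias_scenario_params(dd_true),
                          n_blocks = n_blocks, noise = nm)
  res <- suppressMessages(bias_analysis(cr, "reference", "cAMP"))
  tibble::as_tibble(res)[tibble::as_tibble(res)$ligand == "analog", ]
}
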