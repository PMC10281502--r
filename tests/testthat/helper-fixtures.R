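# Shared fixtures: identity-scale parameters for hand-checkable arithmetic,
# the default truth bundle, and a small sampler config for quick MCMC runs.

identity_params <- function() {
  composition_params(
    structural = structural_params(alpha_lU0 = 0, beta_lU1 = 3,
                                   beta_lU2 = 0, sd_lU = 0.1,
                                   alpha_lKnU0 = 0, beta_lKnU1 = 3,
                                   sd_lKnU = 0.1),
    allocation = storage_allocation_params(alpha_POu = 0, beta_POu = 0,
                                           phi1 = 10),
    adipose_lipid = adipose_lipid_params(alpha_F = 0, alpha_M = 0,
                                         beta = 0, phi2 = 10),
    adipose_protein = adipose_protein_params(alpha = 0, beta = 0,
                                             phi3 = 10),
    smi = smi_params(b_sma = 3, L0 = 1))
}

truth_params <- default_truth_params()

quick_cfg <- function(seed, chains = 2, warmup = 400, sampling = 500) {
  sampler_config(chains = chains, warmup_iterations = warmup,
                 sampling_iterations = sampling, seed = seed)
}

random_bears <- function(n, seed, params = truth_params) {
  set.seed(seed)
  # draw condition above the structural floor so every bear is feasible
  L <- runif(n, 1.0, 2.5)
  smi_t <- runif(n, 130, 220)
  data.frame(id = sprintf("X%04d", seq_len(n)),
             sex = sample(c("F", "M"), n, replace = TRUE),
             length = L,
             mass = smi_t * (L / params$smi$L0)^params$smi$b_sma)
}
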