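# Shared fixtures: small seeded cohorts and random fasting samples.

small_cohort <- function(n = 300, seed = 1, target = 0.75, mc = 20000) {
  simulate_cohort(simulation_config(
    n_subjects = n, seed = seed,
    target_pearson_quicki_mlbm = target,
    calibration_mc_size = mc))
}

# tie-free random fasting samples on the QUICKI-valid domain (G0 * I0 > 1)
random_fasting <- function(n, seed) {
  set.seed(seed)
  data.frame(glucose = runif(n, 3, 12), insulin = runif(n, 2, 40))
}
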