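## shared fixtures: small parameter sets and designs used across tests

widr <- preset_parameters("widr")

## a mild treatment parameter set for fast stochastic checks
tiny_tp <- tp_parameters(B = 0.3, D0 = 0.1, k0 = 0.8, a = 0.5, t0 = 0,
                         S0 = 0, lambda_variant = "linear", k = 0.004,
                         Dp = 0.05, f0 = 0)

tiny_params <- mcld_parameters(b = 0.3, d = 0.1, mu_s = 0, mu_p = 0,
                               tp = tiny_tp, dose = 5, dt = 0.05)

tiny_design <- experiment_design(n_plates = 1, wells_per_plate = 24,
                                 seed_cells_per_well = 50,
                                 expansion_target_cells = 500,
                                 T_treat = 40, T_obs = 30,
                                 early_cutoff_days = 10,
                                 late_cutoff_days = 20,
                                 colony_detection_threshold = 20,
                                 persister_read_day = 10)

## random TP parameter draws for property-style loops
random_tp <- function(rng_seed) {
  set.seed(rng_seed)
  tp_parameters(
    B = runif(1, 0.2, 0.8), D0 = runif(1, 0, 0.2),
    k0 = runif(1, 0.5, 2), a = runif(1, 0.1, 1),
    t0 = runif(1, 0, 2), S0 = runif(1, 0, 0.5),
    lambda_variant = sample(c("constant", "linear", "saturating"), 1),
    lambda0 = runif(1, 0, 0.1), k = runif(1, 0, 0.02),
    Dp = runif(1, 0.01, 0.1), f0 = runif(1, 0, 0.2))
}
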