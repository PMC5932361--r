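# Shared fixtures: everything is generated in code, no stored data.

defaults <- default_parameters()

# short-horizon scenarios for tests that only probe the drop/recovery phase
bomb_short <- function(horizon = 120, step = 0.1) {
  hydrolysis_scenario("bomb", horizon = horizon, output_step = step)
}
sustained_short <- function(horizon = 300, step = 0.5) {
  hydrolysis_scenario("sustained", horizon = horizon, output_step = step)
}

# randomized-but-valid parameter sets for property tests
random_params <- function(n = 10, seed = 421) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    model_parameters(
      i3g = runif(1, 10, 500),
      myr = enzyme_kinetics("M", runif(1, 0.01, 30), runif(1, 0.01, 50),
                            runif(1, 20, 800)),
      nit = enzyme_kinetics("N", runif(1, 0.01, 5), runif(1, 0.001, 0.1),
                            runif(1, 1000, 40000)),
      beta = runif(1),
      tir1_total = 10^runif(1, -6, -4),
      binding_iaa = binding_parameters(runif(1, 1, 50)),
      binding_ant = binding_parameters(runif(1, 1, 50)),
      tau_ian = runif(1, 0.01, 0.5),
      tau_iaa = runif(1, 1e-3, 0.1),
      tau_ant = runif(1, 0.01, 0.5),
      theta = runif(1, 1e-6, 1e-3)
    )
  })
}

# synthetic piecewise-linear TIR1:IAA trace for metric unit tests
synthetic_traj <- function(time, tir1_iaa) {
  tibble::tibble(time = time, ian = 0, ant = 0, iaa = 0,
                 tir1_iaa = tir1_iaa, tir1_ant = 0)
}
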