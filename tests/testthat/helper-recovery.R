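# Large parameter-recovery run: 40 participants x 100 trials per cell,
# default generator conditions, fixed seed. Cached because several checks
# read different aspects of the same simulation.
recovery_run <- function() {
  cached_run("recovery", function() {
    spec <- generator_spec(n_participants = 40, trials_per_cell = 100)
    suppressWarnings(
      recovery_experiment(spec, seed = 1234, config = run_config()))
  })
}
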