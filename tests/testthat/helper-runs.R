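# Shared simulation runs, computed once per test session and reused across
# tests that probe different properties of the same study-scale dataset.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, fun) {
  if (!exists(name, envir = .run_cache))
    assign(name, fun(), envir = .run_cache)
  get(name, envir = .run_cache)
}

# study-scale run: 8 participants x 3 SAT x 2 lexicality x 105 trials/cell
# (5040 trials), default generator conditions, fixed seed
study_run <- function() {
  cached_run("study", function() {
    spec <- generator_spec(n_participants = 8, trials_per_cell = 105)
    res <- suppressWarnings(
      recovery_experiment(spec, seed = 100, config = run_config()))
    res$merged <- merge(res$trials, res$truth,
                        by = c("participant", "trial"),
                        suffixes = c("", ".true"))
    res$spec <- spec
    res
  })
}

# small end-to-end run used by pipeline / curve tests
small_run <- function() {
  cached_run("small", function() {
    spec <- generator_spec(n_participants = 2, trials_per_cell = 12)
    ds <- generate_dataset(spec, seed = 5)
    res <- suppressWarnings(run_pipeline(ds$recordings, ds$events))
    list(spec = spec, ds = ds, res = res)
  })
}
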