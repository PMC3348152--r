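# The default synthetic study conditions used by the acceptance checks:
# 8 fields x 64 colonies = 512 colonies, 9 hourly frames. Computed once and
# cached for the whole test run.
.scenario_cache <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.scenario_cache$run)) {
    t0 <- proc.time()
    fields <- default_scenario(n_fields = 8, seed = 2024)
    run <- run_growth_pipeline(fields, 0:8)
    run$elapsed <- (proc.time() - t0)[["elapsed"]]
    run$n_colonies <- sum(vapply(fields, function(f) length(f$colonies),
                                 numeric(1)))
    .scenario_cache$run <- run
  }
  .scenario_cache$run
}

shock_run <- function() {
  if (is.null(.scenario_cache$shock)) {
    fields <- shock_scenario(n_fields = 4, seed = 2024)
    .scenario_cache$shock <- run_survival_pipeline(
      fields, pre_times = 0:5, post_times = 0:16, shift = c(3.2, -1.7))
  }
  .scenario_cache$shock
}
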