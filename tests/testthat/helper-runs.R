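# Shared scenario runs, computed once per test session and reused across
# test files (the model is deterministic, so caching is safe).
.run_cache <- new.env(parent = emptyenv())

cached_sim <- function(name, expr) {
  if (!exists(name, envir = .run_cache))
    assign(name, force(expr), envir = .run_cache)
  get(name, envir = .run_cache)
}

run_scenario <- function(gap, gel, dose, days) {
  simulate_healing(scenario(gap_mm = gap, gel_present = gel,
                            bmp2_dose_ug = dose, horizon_days = days))
}

sim_5ug <- function() cached_sim("s_5ug", run_scenario(8, TRUE, 5, 84))
sim_gel_only <- function() cached_sim("s_gel0", run_scenario(8, TRUE, 0, 84))
sim_empty <- function() cached_sim("s_empty", run_scenario(8, FALSE, 0, 84))
sim_2mm <- function() cached_sim("s_2mm", run_scenario(2, FALSE, 0, 42))

sim_dose <- function(dose) {
  if (dose == 0) return(sim_gel_only())
  if (dose == 5) return(sim_5ug())
  cached_sim(paste0("s_dose_", dose), run_scenario(8, TRUE, dose, 84))
}
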