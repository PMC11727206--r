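# Lazily computed study results shared by the benchmark-reproduction tests.
# The settings are the study conditions themselves (U[-3,3] covariates,
# xtilde-driven models, balanced designs, 1000 replications; the p = 10,
# n = 2000 grid point runs at 250 replications).

.study_cache <- new.env(parent = emptyenv())

study_cached <- function(key, maker) {
  if (is.null(.study_cache[[key]])) .study_cache[[key]] <- maker()
  .study_cache[[key]]
}

study_c1_main <- function() {
  study_cached("c1_main", function() {
    run_study(sim_config(
      n = 1000, p = 5, law = "uniform", model = "C1",
      designs = list(cre = design_spec("cre"), mode = design_spec("mode")),
      replications = 1000, seed = 20240101
    ))
  })
}

study_c2_main <- function() {
  study_cached("c2_main", function() {
    run_study(sim_config(
      n = 1000, p = 5, law = "uniform", model = "C2",
      designs = list(cre = design_spec("cre")),
      replications = 1000, seed = 20240102
    ))
  })
}

study_c3_small <- function() {
  study_cached("c3_small", function() {
    run_study(sim_config(
      n = 250, p = 5, law = "uniform", model = "C3",
      designs = list(cre = design_spec("cre")),
      replications = 1000, seed = 20240103
    ))
  })
}

study_c1_p10 <- function() {
  study_cached("c1_p10", function() {
    run_study(sim_config(
      n = 2000, p = 10, law = "uniform", model = "C1",
      designs = list(cre = design_spec("cre"), mode = design_spec("mode")),
      replications = 250, seed = 20240104
    ))
  })
}

summary_row <- function(study, design) {
  study$summary[study$summary$design == design, , drop = FALSE]
}
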