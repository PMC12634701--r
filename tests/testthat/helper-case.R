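# Shared fixtures: default case, joints, and memoized protocol runs for the
# heavy comparative tests.

default_case_profile <- function() {
  sagittal_profile(PI = 60, PT = 49, TK = 50, LL = -12, body_mass = 60)
}

default_case_model <- function() build_spine(default_case_profile())

.run_cache <- new.env(parent = emptyenv())

# full five-scenario protocol runs at default settings (computed once)
protocol_runs <- function() {
  if (is.null(.run_cache$runs)) {
    model <- default_case_model()
    joints <- default_joint_table()
    scs <- rod_scenarios()
    .run_cache$runs <- lapply(scs, function(sc)
      run_protocol(model, joints, sc))
  }
  .run_cache$runs
}

scenario_order <- c("constant_6.0", "stepped_6.0_5.0", "bezier_6.0_5.5_5.0",
                    "constant_5.5", "bezier_5.5_5.0_4.75")
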