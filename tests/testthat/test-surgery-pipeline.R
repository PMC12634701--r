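test_that("surgical plan validates its span and derives junction sets", {
  plan <- surgical_plan()
  expect_equal(plan$instrumented, c("T10", "T11", "T12", "L1", "L2", "L3",
                                    "L4", "L5", "S1"))
  expect_equal(plan$screw_levels, setdiff(plan$instrumented, "L3"))
  expect_equal(plan$pso_junctions, c("L2-L3", "L3-L4"))
  expect_false(any(plan$pso_junctions %in% plan$facetectomy_junctions))
  expect_error(surgical_plan(pso_level = "T5"), "inside")
  expect_error(surgical_plan(flexion_angle = 0), "> 0")
  expect_error(surgical_plan(uiv = "L5", liv = "T10"), "span")
})

test_that("rod contour interpolates the planned screw heads", {
  m <- default_case_model()
  plan <- surgical_plan()
  ct <- make_rod_contour(m, plan$screw_levels, n_el = 4)
  expect_equal(ct$tie_levels[1], "S1")  # distal end first
  expect_equal(length(ct$tie_nodes), 8)
  # knot nodes coincide with the head points
  po <- m$poses
  for (k in seq_along(ct$tie_levels)) {
    i <- match(ct$tie_levels[k], po$level)
    th <- po$theta[i] * pi / 180
    head <- c(po$x[i], po$z[i]) +
      rodspine:::.rot(th) %*% c(-45, 0)
    node <- ct$tie_nodes[k]
    expect_equal(c(ct$nodes$x[node], ct$nodes$z[node]), drop(head),
                 tolerance = 1e-9)
  }
  # landmarks are ordered along the rod and include the zone boundaries
  lm <- ct$landmarks
  expect_true(all(c("L1-L2", "T11-T12", "end") %in% names(lm)))
  expect_true(all(diff(lm[names(lm) != "end"]) > 0))
})

test_that("contour identical to the in-situ spine gives near-zero forces", {
  m <- default_case_model()
  j <- default_joint_table()
  plan <- surgical_plan()
  settings <- solve_settings(load_steps = 4)
  ct <- make_rod_contour(m, plan$screw_levels, n_el = 4)
  asm <- assemble(m, j, scenario = rod_scenarios()$constant_6.0,
                  contour = ct, settings = settings)
  rest <- setNames(m$junctions$rest_angle, m$junctions$junction)
  red <- reduce_and_lock(asm, asm$q0, j, rest, plan, settings = settings)
  expect_lt(max(red$state$screws$force), 1)
  # poses essentially unchanged (null reduction)
  expect_equal(red$q[seq_len(54)], asm$q0[seq_len(54)], tolerance = 1e-3)
  # PSO junctions are fused afterwards
  expect_equal(red$joints[["L2-L3"]]$state, "fused")
  expect_equal(red$joints[["L3-L4"]]$state, "fused")
})

test_that("standing-prone-standing is reversible in the elastic regime", {
  m <- default_case_model()
  j <- default_joint_table()
  settings <- solve_settings()
  cal <- rodspine:::.calibrate_standing(m, j, settings)
  q_stand <- cal$result$q
  prone <- prone_transition(m, j, cal$rest, q_start = q_stand,
                            settings = settings)
  asm <- assemble(m, j, rest_angles = cal$rest, settings = settings)
  back <- solve_static(asm, q0 = prone$q, gravity = "follower",
                       settings = settings)
  expect_equal(back$q, q_stand, tolerance = 1e-4)
})

test_that("staged protocol reproduces the expected stage structure", {
  runs <- protocol_runs()
  run <- runs$constant_6.0
  expect_s3_class(run, "stage_states")
  expect_equal(names(run$stages),
               c("preop_standing", "prone", "released", "instrumented",
                 "postop_standing", "flexed"))
  # calibrated pre-op standing reproduces the radiographic profile
  expect_equal(run$stages$preop_standing$profile$TK, 50, tolerance = 0.1)
  expect_equal(run$stages$preop_standing$profile$LL, -12, tolerance = 0.1)
  # prone unloading: TK decreases, signed lordosis increases
  expect_lt(run$stages$prone$profile$TK, run$stages$preop_standing$profile$TK)
  expect_gt(run$stages$prone$profile$LL, run$stages$preop_standing$profile$LL)
  # every stage satisfies solver equilibrium: screw gaps bounded
  expect_lt(max(run$stages$flexed$screws$gap), 2)
  # the flexed stage satisfies the imposed T1 constraint
  th_flex <- run$stages$flexed$poses$theta[1]
  th_stand <- run$stages$postop_standing$poses$theta[1]
  expect_equal(th_stand - th_flex, run$plan$flexion_angle, tolerance = 1e-6)
})

test_that("post-operative lordosis lands on the plan for every scenario", {
  runs <- protocol_runs()
  ll <- vapply(runs, function(r) r$stages$postop_standing$profile$LL,
               numeric(1))
  expect_true(all(abs(ll - runs[[1]]$plan$target_LL) <= 2))
  expect_lte(diff(range(ll)), 2)
})

test_that("only the rod profile differs between scenario runs", {
  runs <- protocol_runs()
  ref <- runs[[1]]
  for (run in runs[-1]) {
    expect_identical(run$plan, ref$plan)
    expect_identical(run$wedge, ref$wedge)
    expect_identical(run$assembly$rod$contour$nodes,
                     ref$assembly$rod$contour$nodes)
    expect_identical(run$rest_angles, ref$rest_angles)
  }
  profs <- lapply(runs, function(r) r$scenario$profile)
  expect_length(unique(vapply(profs, function(p) p$kind, character(1))), 3)
})

test_that("stepped rod concentrates more stress at the step than the bezier", {
  runs <- protocol_runs()
  s_step <- peak_rod_stress_near(runs$stepped_6.0_5.0, "T11-T12")
  s_bez <- peak_rod_stress_near(runs$bezier_6.0_5.5_5.0, "T11-T12")
  expect_gt(s_step, s_bez)
  # stress profile is recorded for every element with the local diameter
  rod <- runs$stepped_6.0_5.0$stages$flexed$rod
  expect_true(all(rod$sigma_outer >= 0))
  expect_setequal(round(unique(rod$d), 2), c(6, 5))
})
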