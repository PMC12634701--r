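test_that("DOF bookkeeping and rigid-body-mode detection", {
  m <- default_case_model()
  j <- default_joint_table()
  asm <- assemble(m, j)
  # 18 rigid bodies x 3 DOF, sacrum/pelvis fixed
  expect_equal(asm$ndof, 54)
  expect_equal(n_free_dof(asm), 51)
  expect_error(assemble(m, j, fix_base = FALSE), "rigid-body mode")
  # instrumented: rod nodes appear and tie count equals screw count
  plan <- surgical_plan()
  ct <- make_rod_contour(m, plan$screw_levels, n_el = 4)
  asm2 <- assemble(m, j, scenario = rod_scenarios()$constant_6.0,
                   contour = ct)
  expect_length(asm2$ties, length(plan$screw_levels))
  expect_equal(asm2$ndof, 54 + 3 * nrow(ct$nodes))
  expect_error(assemble(m, j, scenario = rod_scenarios()$constant_6.0),
               "contour")
})

test_that("joint spring element force is the exact energy gradient", {
  kx <- 260; ky <- 1200
  mfn <- function(phi) 5e4 * phi + 2e4 * sinh(3 * phi)
  efn <- function(phi) 5e4 * phi^2 / 2 + 2e4 * cosh(3 * phi) / 3
  rA <- c(2, -12); rB <- c(-3, 14); rest <- 0.05
  energy <- function(q) {
    RA <- rodspine:::.rot(q[3]); RB <- rodspine:::.rot(q[6])
    dl <- crossprod(RB, (q[1:2] + RA %*% rA) - (q[4:5] + RB %*% rB))
    0.5 * kx * dl[1]^2 + 0.5 * ky * dl[2]^2 + efn(q[3] - q[6] - rest)
  }
  q <- c(5, 300, 0.3, -2, 260, 0.18)
  g <- rodspine:::.spring_g(q[1:3], q[4:6], rA, rB, kx, ky, mfn, rest)
  h <- 1e-6
  for (k in 1:6) {
    qp <- q; qm <- q; qp[k] <- qp[k] + h; qm[k] <- qm[k] - h
    expect_equal(g[k], (energy(qp) - energy(qm)) / (2 * h),
                 tolerance = 1e-5)
  }
  # analytic tangent matches finite differences of the force
  tfn <- function(phi) 5e4 + 6e4 * cosh(3 * phi)
  K <- rodspine:::.spring_K(q[1:3], q[4:6], rA, rB, kx, ky, tfn, rest)
  for (k in 1:6) {
    qp <- q; qm <- q; qp[k] <- qp[k] + h; qm[k] <- qm[k] - h
    fd <- (rodspine:::.spring_g(qp[1:3], qp[4:6], rA, rB, kx, ky, mfn, rest) -
           rodspine:::.spring_g(qm[1:3], qm[4:6], rA, rB, kx, ky, mfn, rest)) /
      (2 * h)
    expect_equal(K[, k], fd, tolerance = 1e-4)
  }
})

test_that("elastic cantilever matches PL^3/3EI within 1% at 8 elements", {
  EI <- 113000 * section_inertia(6)
  r <- rod_cantilever(100, 6, tip_force = 10, n_el = 8)
  expect_equal(r$tip_deflection, 10 * 100^3 / (3 * EI), tolerance = 0.01)
  expect_false(r$plastic)
  # tip-moment load: rotation ML/EI, deflection ML^2/2EI
  r2 <- rod_cantilever(100, 6, tip_moment = 5000, n_el = 8)
  expect_equal(r2$tip_rotation, 5000 * 100 / EI, tolerance = 0.01)
  expect_equal(r2$tip_deflection, 5000 * 100^2 / (2 * EI), tolerance = 0.01)
})

test_that("mesh refinement halves-or-better the cantilever error", {
  # pure tip moment, geometrically nonlinear (tip rotation ~0.2 rad);
  # error measured against a fine-mesh reference
  ref <- rod_cantilever(100, 6, tip_moment = 15000, n_el = 64)$tip_deflection
  err <- vapply(c(2, 4, 8), function(n)
    abs(rod_cantilever(100, 6, tip_moment = 15000, n_el = n)$tip_deflection -
        ref), numeric(1))
  expect_lte(err[2], err[1] / 2 + 1e-12)
  expect_lte(err[3], err[2] / 2 + 1e-12)
})

test_that("loading past first yield leaves residual rotation after unload", {
  # My for d=6 is about 20.1 N.m; load to 25 N.m and remove it
  r <- rod_cantilever(100, 6, tip_moment = 25000, n_el = 8, unload = TRUE)
  expect_true(r$plastic)
  expect_gt(abs(r$tip_rotation_unloaded), 1e-3)
  # elastic load-unload returns to zero
  re <- rod_cantilever(100, 6, tip_moment = 10000, n_el = 8, unload = TRUE)
  expect_false(re$plastic)
  expect_lt(abs(re$tip_rotation_unloaded), 1e-8)
})

test_that("zero load gives zero displacement and zero internal forces", {
  m <- default_case_model()
  asm <- assemble(m, default_joint_table())
  res <- solve_static(asm, gravity = "none",
                      settings = solve_settings(load_steps = 1))
  expect_equal(res$q, asm$q0, tolerance = 1e-9)
  sys <- rodspine:::.system_forces(asm, res$q, want_K = FALSE,
                                   collect = TRUE)
  expect_true(all(abs(sys$joint_info$moment) < 1e-9))
})

test_that("follower load on a straight vertical spine is plain gravity", {
  p <- sagittal_profile(PI = 40, PT = 40, TK = 0, LL = 0)
  m <- build_spine(p, upper_thoracic_wedge = 0, thoracolumbar_wedge = 0)
  asm <- assemble(m, default_joint_table())
  expect_true(all(abs(m$poses$theta) < 1e-12))
  Ff <- follower_gravity(asm, mode = "follower")
  Fv <- follower_gravity(asm, mode = "vertical")
  expect_equal(Ff, Fv, tolerance = 1e-12)
  # standing under gravity keeps the straight spine moment-free
  res <- solve_static(asm, gravity = "follower")
  st <- rodspine:::.system_forces(asm, res$q, want_K = FALSE, collect = TRUE)
  expect_lt(max(abs(st$joint_info$moment)), 1e-6)
})

test_that("follower force transmitted at the sacrum is g * supported mass", {
  m <- default_case_model()
  asm <- assemble(m, default_joint_table())
  for (qv in list(asm$q0, asm$q0 + rep(c(5, -3, 0.03), 18))) {
    F <- follower_gravity(asm, qv)
    tot <- c(sum(F[seq(1, 52, 3)]), sum(F[seq(2, 53, 3)]))
    W <- 9.81 * sum(m$mass_fraction * m$body_mass)
    expect_equal(sqrt(sum(tot^2)), W, tolerance = 1e-9)
  }
})

test_that("follower gravity bends the curved spine less than vertical", {
  # balanced alignment at a sub-critical mass: an osteo-ligamentous spine
  # buckles under larger dead vertical loads, which is exactly why the
  # follower path is used
  p <- sagittal_profile(PI = 50, PT = 12, TK = 35, LL = 50, body_mass = 6)
  m <- build_spine(p)
  j <- default_joint_table()
  asm <- assemble(m, j)
  peak <- function(gr) {
    res <- solve_static(asm, gravity = gr)
    max(abs(rodspine:::.system_forces(asm, res$q, want_K = FALSE,
                                      collect = TRUE)$joint_info$moment))
  }
  expect_lt(peak("follower"), peak("vertical"))
})

test_that("elastic solution is path-independent in the number of steps", {
  m <- default_case_model()
  j <- default_joint_table()
  asm <- assemble(m, j)
  r1 <- solve_static(asm, gravity = "follower",
                     settings = solve_settings(load_steps = 1))
  r10 <- solve_static(asm, gravity = "follower",
                      settings = solve_settings(load_steps = 10))
  expect_equal(r1$q, r10$q, tolerance = 1e-6)
})

test_that("global equilibrium: reactions balance applied loads to 1e-8", {
  m <- default_case_model()
  asm <- assemble(m, default_joint_table())
  res <- solve_static(asm, gravity = "follower",
                      settings = solve_settings(tol = 1e-11, tol_abs = 1e-8))
  q <- res$q
  Fext <- follower_gravity(asm, q)
  R <- rodspine:::.system_forces(asm, q, want_K = FALSE)$R
  # the support (fixed sacrum/pelvis) must carry the whole applied load:
  # reaction force = internal force at the fixed DOFs
  W <- sqrt(sum(Fext^2))
  expect_lt(abs(R[52] + sum(Fext[seq(1, 52, 3)])) / W, 1e-8)
  expect_lt(abs(R[53] + sum(Fext[seq(2, 53, 3)])) / W, 1e-8)
})

test_that("imposed T1 rotation: null case and kinematic bookkeeping", {
  m <- default_case_model()
  j <- default_joint_table()
  asm <- assemble(m, j)
  stand <- solve_static(asm, gravity = "follower")
  th1 <- stand$q[3] * 180 / pi
  # theta = standing value -> unchanged solution
  r0 <- solve_static(asm, q0 = stand$q, gravity = "follower",
                     gravity_ramp = FALSE,
                     prescribed = impose_rotation(asm, "T1", th1))
  expect_equal(r0$q, stand$q, tolerance = 1e-6)
  # 10-degree forward rotation: junction rotations telescope to the imposed
  # change (the base is fixed)
  r10 <- solve_static(asm, q0 = stand$q, gravity = "follower",
                      gravity_ramp = FALSE,
                      prescribed = impose_rotation(asm, "T1", th1 - 10))
  rel_change <- (r10$q[seq(3, 54, 3)] - stand$q[seq(3, 54, 3)]) * 180 / pi
  expect_equal(sum(-diff(rel_change)), -10 - 0, tolerance = 1e-9)
  # every FSU flexes
  dro <- -diff(rel_change)  # per-junction change, cranial to caudal
  expect_true(all(dro < 0))
  expect_error(impose_rotation(asm, "S1", 0), "fixed")
  expect_error(impose_rotation(asm, "C7", 0), "unknown")
})
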