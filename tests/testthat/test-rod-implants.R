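test_that("circular section formulas", {
  expect_equal(section_inertia(6), pi * 6^4 / 64)
  expect_equal(signif(section_inertia(6), 4), 63.62)
  expect_equal(section_area(6), pi * 9)
  expect_equal(section_inertia(6) / section_inertia(5), (6 / 5)^4)
  expect_equal((6 / 5)^4, 2.0736)
  expect_error(section_inertia(0), "> 0")
  expect_error(section_area(-1), "> 0")
  # d -> 0 limit
  expect_lt(section_inertia(1e-4), 1e-15)
})

test_that("fiber discretization reproduces area exactly and inertia to 0.5%", {
  for (d in c(4.75, 5.5, 6)) {
    fs <- fiber_section(d, 32)
    expect_equal(sum(fs$A), section_area(d), tolerance = 1e-12)
    expect_equal(sum(fs$y^2 * fs$A), section_inertia(d), tolerance = 0.005)
    expect_equal(sum(fs$y * fs$A), 0, tolerance = 1e-9)
  }
})

test_that("elastic fiber response matches E I kappa within 0.5%", {
  mat <- rod_material()
  fs <- fiber_section(6, 32)
  EI <- mat$E * section_inertia(6)
  for (k in c(1e-5, 1e-4, 5e-4)) {
    expect_equal(moment_curvature(fs, mat, k), EI * k, tolerance = 0.005)
  }
  expect_equal(moment_curvature(fs, mat, 1e-4), 718.9, tolerance = 0.005)
})

test_that("first yield and plastic limit moments of the 6 mm section", {
  fs <- fiber_section(6, 64)
  mat <- rod_material()
  My <- 950 * section_inertia(6) / 3  # sigma_y I / c = 20146 N.mm
  # just below first-yield curvature the response is elastic
  ky <- My / (mat$E * section_inertia(6))
  expect_equal(moment_curvature(fs, mat, 0.98 * ky), 0.98 * My,
               tolerance = 0.01)
  expect_equal(My / 1000, 20.1, tolerance = 0.01)
  # elastic-perfectly-plastic limit: sigma_y d^3/6
  epp <- rod_material(sigma_y = 950, sigma_u = 950.0001, eps_u = 0.5)
  Mp <- 950 * 6^3 / 6
  expect_equal(Mp, 34200)
  expect_equal(moment_curvature(fiber_section(6, 32), epp, 0.05), Mp,
               tolerance = 0.01)
})

test_that("moment-curvature is odd; hysteresis only after yield", {
  fs <- fiber_section(6, 32)
  mat <- rod_material()
  ks <- c(1e-4, 5e-3)
  expect_equal(moment_curvature(fs, mat, -ks), -moment_curvature(fs, mat, ks))
  # elastic load-unload leaves no state; plastic excursion does
  el <- section_response(fs, mat, 0, 1e-4)
  expect_false(el$plastic)
  expect_true(all(el$state$alpha == 0))
  pl <- section_response(fs, mat, 0, 5e-3)
  expect_true(pl$plastic)
  expect_true(any(pl$state$alpha > 0))
  # unloading from the plastic state is elastic with residual moment offset
  un <- section_response(fs, mat, 0, 0, state = pl$state)
  expect_gt(abs(un$M), 0)
  # fiber stress never exceeds the ultimate strength
  expect_lte(pl$sigma_outer, mat$sigma_u + 1e-9)
})

test_that("rupture flag raises past ultimate elongation without crashing", {
  fs <- fiber_section(6, 16)
  mat <- rod_material()
  r <- section_response(fs, mat, 0, 0.05)  # outer strain ~0.15 > eps_u
  expect_true(r$rupture)
  expect_lte(r$sigma_outer, mat$sigma_u + 1e-9)
})

test_that("material constructor validates the multilinear law", {
  m <- rod_material()
  expect_equal(m$hardening$stress, c(0, 950, 1180))
  expect_equal(m$hardening$strain[2], 950 / 113000)
  # first segment slope = E
  expect_equal(diff(m$hardening$stress[1:2]) / diff(m$hardening$strain[1:2]),
               m$E)
  expect_true(all(diff(m$hardening$stress) >= 0))
  expect_error(rod_material(sigma_y = 1200, sigma_u = 1000), "sigma_y")
})

landmarks <- c("L1-L2" = 150, "T11-T12" = 280, end = 400)

test_that("diameter profiles evaluate as specified", {
  expect_equal(diameter_at(constant_profile(6), c(0, 123, 400), landmarks),
               rep(6, 3))
  stp <- stepped_profile(6, 5, "T11-T12")
  expect_equal(diameter_at(stp, c(0, 279.9, 280), landmarks), c(6, 6, 6))
  expect_equal(diameter_at(stp, c(280.1, 400), landmarks), c(5, 5))
  bez <- bezier_profile(c(6, 5.5, 5), c("L1-L2", "T11-T12"), transition = 20)
  # plateau values at zone midpoints
  expect_equal(diameter_at(bez, c(75, 215, 340), landmarks), c(6, 5.5, 5))
  expect_error(diameter_at(bez, 401, landmarks), "outside")
  expect_error(diameter_at(bez, 100), "landmark")
})

test_that("bezier transition is C1, monotone and bounded", {
  bez <- bezier_profile(c(6, 5.5, 5), c("L1-L2", "T11-T12"), transition = 20)
  s <- seq(0, 400, by = 0.05)
  d <- diameter_at(bez, s, landmarks)
  expect_true(all(d <= 6 & d >= 5))
  expect_true(all(diff(d) <= 1e-12))  # monotone non-increasing profile
  # first derivative continuous (no jump beyond curvature-scale changes)
  dd <- diff(d) / diff(s)
  expect_lt(max(abs(diff(dd))), 0.01 * max(abs(dd)) + 1e-8)
  expect_true(all(is.finite(dd)))
})

test_that("the five scenarios carry the printed diameters and EI order", {
  scs <- rod_scenarios()
  expect_named(scs, scenario_order)
  expect_equal(scs$constant_6.0$profile$diameters, 6.0)
  expect_equal(scs$constant_5.5$profile$diameters, 5.5)
  expect_equal(scs$stepped_6.0_5.0$profile$diameters, c(6.0, 5.0))
  expect_equal(scs$stepped_6.0_5.0$profile$boundaries, "T11-T12")
  expect_equal(scs$bezier_6.0_5.5_5.0$profile$diameters, c(6.0, 5.5, 5.0))
  expect_equal(scs$bezier_5.5_5.0_4.75$profile$diameters, c(5.5, 5.0, 4.75))
  expect_equal(scs$bezier_6.0_5.5_5.0$profile$boundaries,
               c("L1-L2", "T11-T12"))
  # length-averaged flexural rigidity ordering over a representative span
  ei <- vapply(scs, mean_flexural_rigidity, numeric(1),
               landmarks = landmarks)
  expect_equal(order(ei, decreasing = TRUE), seq_len(5))
})
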