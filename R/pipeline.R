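# Staged surgical protocol: pre-operative standing, prone transition,
# posterior releases (facetectomies + PSO wedge), rod reduction and
# locking, return to standing under follower gravity, and 10-degree
# flexion. One run per rod scenario; only the rod section profile differs
# between runs.

#' Surgical plan
#'
#' @param uiv,liv upper and lower instrumented vertebrae (screws at every
#'   level in between except the PSO level).
#' @param pso_level pedicle-subtraction-osteotomy level (inside the
#'   instrumented span); modelled as a rest-angle wedge split across the
#'   two adjacent junctions, fused after compression.
#' @param facetectomy_factor flexion-stiffness multiplier for released
#'   facet joints.
#' @param pso_wedge_cap largest admissible wedge, degrees.
#' @param target_LL,target_TK planned post-operative lordosis/kyphosis
#'   (degrees) used to shape the rod contour.
#' @param flexion_angle forward rotation imposed at T1 for the flexion
#'   stage, degrees (> 0).
#' @param head_offset posterior offset of the screw head from the vertebral
#'   centroid, mm.
#' @return List of class `surgical_plan`.
#' @export
surgical_plan <- function(uiv = "T10", liv = "S1", pso_level = "L3",
                          facetectomy_factor = 0.5, pso_wedge_cap = 35,
                          target_LL = 48, target_TK = 36.5,
                          flexion_angle = 10, head_offset = 45) {
  lv <- .levels
  iu <- match(uiv, lv); il <- match(liv, lv); ip <- match(pso_level, lv)
  if (is.na(iu) || is.na(il) || iu >= il) .stopf("invalid instrumented span")
  if (is.na(ip) || ip <= iu || ip >= il)
    .stopf("PSO level must lie strictly inside the instrumented span")
  if (flexion_angle <= 0) .stopf("flexion angle must be > 0")
  instrumented <- lv[iu:il]
  span_junctions <- .junctions[iu:(il - 1)]
  pso_junctions <- c(.junction_of(lv[ip - 1], lv[ip]),
                     .junction_of(lv[ip], lv[ip + 1]))
  structure(
    list(uiv = uiv, liv = liv, pso_level = pso_level,
         instrumented = instrumented,
         screw_levels = setdiff(instrumented, pso_level),
         facetectomy_junctions = setdiff(span_junctions, pso_junctions),
         pso_junctions = pso_junctions,
         facetectomy_factor = facetectomy_factor,
         pso_wedge_cap = pso_wedge_cap,
         target_LL = target_LL, target_TK = target_TK,
         flexion_angle = flexion_angle, head_offset = head_offset),
    class = "surgical_plan")
}

#' Rod contour through planned screw-head positions
#'
#' Builds the planned post-operative spine, places screw heads at a
#' posterior offset from each instrumented centroid, and passes a natural
#' cubic spline through them (chord-length parameterized). The same
#' contour is shared by all scenarios.
#'
#' @param planned_model [build_spine()] model of the planned post-operative
#'   shape.
#' @param screw_levels instrumented levels carrying screws, cranial to
#'   caudal.
#' @param head_offset posterior head offset, mm.
#' @param n_el beam elements per inter-screw segment.
#' @return List of class `rod_contour`: node table (x, z, theta, s), tie
#'   node indices and levels, junction arc-length landmarks.
#' @export
make_rod_contour <- function(planned_model, screw_levels, head_offset = 45,
                             n_el = 8) {
  po <- planned_model$poses
  idx <- match(screw_levels, po$level)
  if (anyNA(idx)) .stopf("unknown screw level")
  # distal (sacral) end first so arc length runs distal -> proximal
  idx <- rev(idx[order(idx)])
  heads <- t(vapply(idx, function(i) {
    th <- po$theta[i] * .deg2rad
    c(po$x[i], po$z[i]) + .rot(th) %*% c(-head_offset, 0)
  }, numeric(2)))
  u <- c(0, cumsum(sqrt(rowSums(diff(heads)^2))))
  fx <- stats::splinefun(u, heads[, 1], method = "natural")
  fz <- stats::splinefun(u, heads[, 2], method = "natural")
  nseg <- length(idx) - 1
  us <- unique(unlist(lapply(seq_len(nseg), function(k)
    seq(u[k], u[k + 1], length.out = n_el + 1))))
  nodes <- data.frame(
    x = fx(us), z = fz(us),
    theta = atan2(fz(us, deriv = 1), fx(us, deriv = 1)),
    s = us)
  tie_nodes <- match(u, us)
  tie_levels <- po$level[idx]
  landmarks <- numeric(nseg)
  names(landmarks) <- vapply(seq_len(nseg), function(k)
    .junction_of(po$level[idx[k + 1]], po$level[idx[k]]), character(1))
  for (k in seq_len(nseg)) landmarks[k] <- (u[k] + u[k + 1]) / 2
  landmarks <- c(landmarks, end = u[length(u)])
  structure(
    list(nodes = nodes, tie_nodes = tie_nodes, tie_levels = tie_levels,
         tie_theta_planned = po$theta[idx] * .deg2rad,
         head_local = c(-head_offset, 0), landmarks = landmarks,
         planned_model = planned_model),
    class = "rod_contour")
}

# package a converged state into a stage report
.stage_state <- function(stage, asm, q, tie_ramp = 1) {
  info <- .system_forces(asm, q, tie_ramp = tie_ramp, want_K = FALSE,
                         collect = TRUE)
  nb <- asm$nb
  poses <- data.frame(
    level = names(asm$bidx),
    x = q[3 * seq_len(nb) - 2], z = q[3 * seq_len(nb) - 1],
    theta = q[3 * seq_len(nb)] * .rad2deg,
    body_height = asm$model$poses$body_height,
    stringsAsFactors = FALSE)
  st <- structure(
    list(stage = stage, poses = poses, q = q,
         joints = info$joint_info, rod = info$rod_info,
         screws = info$tie_info, model = asm$model),
    class = "stage_state")
  st$profile <- measure_profile(st)
  st
}

#' @export
print.stage_state <- function(x, ...) {
  cat(sprintf("Stage '%s': TK %.1f | LL %.1f deg\n", x$stage,
              x$profile$TK, x$profile$LL))
  invisible(x)
}

# calibrate joint rest angles so the gravity-loaded standing shape
# reproduces the built (radiographic) geometry
.calibrate_standing <- function(model, joints, settings, iters = 3) {
  rest <- stats::setNames(model$junctions$rest_angle,
                          model$junctions$junction)
  target <- rest
  res <- NULL
  for (i in seq_len(iters)) {
    asm <- assemble(model, joints, rest_angles = rest, settings = settings)
    res <- solve_static(asm, gravity = "follower", settings = settings)
    q <- res$q
    rel <- vapply(seq_len(nrow(model$junctions)), function(k) {
      iA <- asm$bidx[[model$junctions$upper[k]]]
      iB <- asm$bidx[[model$junctions$lower[k]]]
      (q[3 * iA] - q[3 * iB]) * .rad2deg
    }, numeric(1))
    rest <- rest + (target - rel)
  }
  list(rest = rest, result = res, assembly = res$assembly)
}

#' Prone transition
#'
#' Removes gravity (supported prone positioning modelled as unloading): the
#' spine relaxes toward the joint rest angles. For a kyphotic case this
#' decreases TK and increases signed LL relative to loaded standing.
#'
#' @param model,joints,rest_angles,settings model, joint set and calibrated
#'   rest angles as used for the standing solve.
#' @param q_start state to relax from (the standing solution).
#' @return A `stage_state`.
#' @export
prone_transition <- function(model, joints, rest_angles, q_start = NULL,
                             settings = solve_settings()) {
  asm <- assemble(model, joints, rest_angles = rest_angles,
                  settings = settings)
  if (is.null(q_start)) q_start <- asm$q0
  res <- solve_static(asm, q0 = q_start, gravity = "none",
                      settings = settings)
  .stage_state("prone", asm, res$q)
}

# update joint laws inside an existing assembly without losing rod state
.refresh_joints <- function(asm, joints, rest_angles) {
  asm$joints <- joints
  for (k in seq_along(asm$jels)) {
    j <- asm$jels[[k]]$junction
    law <- joints[[j]]
    asm$jels[[k]]$law <- law
    asm$jels[[k]]$rest <- (rest_angles[[j]] + law$rest_angle) * .deg2rad
  }
  asm
}

#' Rod reduction and locking
#'
#' Starting from the released prone state, ramps the screw-tie stiffness so
#' the spine is drawn to the rod contour (displacement-controlled
#' reduction), closes the PSO wedge, locks the ties and fuses the PSO
#' junctions. Rod plastic state developed during reduction is retained.
#'
#' @param asm instrumented [assemble()]d system (rod + ties).
#' @param q_start combined state: released body poses, rod at contour.
#' @param joints joint set in the released state.
#' @param rest_angles calibrated geometric rest angles.
#' @param plan a [surgical_plan()].
#' @param settings a [solve_settings()].
#' @param max_gap largest admissible residual tie gap after locking, mm.
#' @param lock_factor tie stiffness multiplier applied at set-screw
#'   locking.
#' @return List: `state` (a `stage_state`), `assembly` (with committed
#'   plastic state and fused PSO junctions), `joints` (fused set).
#' @export
reduce_and_lock <- function(asm, q_start, joints, rest_angles, plan,
                            settings = solve_settings(), max_gap = 2,
                            lock_factor = 5) {
  # record the initial head-to-rod mismatch per tie: the reduction is
  # displacement-controlled, closing this gap over the load steps
  nd0 <- asm$rod$node_dof0
  for (k in seq_along(asm$ties)) {
    tk <- asm$ties[[k]]
    ia <- nd0 + (3 * tk$node - 2):(3 * tk$node)
    ib <- (3 * tk$body - 2):(3 * tk$body)
    RB <- .rot(q_start[ib[3]])
    pA <- q_start[ia[1:2]]
    pB <- q_start[ib[1:2]] + RB %*% tk$r_head
    asm$ties[[k]]$dl0 <- drop(crossprod(RB, pA - pB))
    asm$ties[[k]]$phi0 <- q_start[ia[3]] - q_start[ib[3]] - tk$rest
  }
  res <- solve_static(asm, q0 = q_start, gravity = "none", tie_ramp = TRUE,
                      settings = settings)
  asm <- res$assembly
  # set screws locked: stiffen the head connections
  asm$tie_stiffness <- asm$tie_stiffness * lock_factor
  asm$tie_rot_stiffness <- asm$tie_rot_stiffness * lock_factor
  # compression complete: fuse the osteotomy rigidly at the achieved
  # (compressed) angle, so fusion itself introduces no moment jump
  for (j in plan$pso_junctions) {
    k <- match(j, vapply(asm$jels, `[[`, character(1), "junction"))
    el <- asm$jels[[k]]
    rel_deg <- (res$q[3 * el$iA] - res$q[3 * el$iB]) * .rad2deg
    joints[[j]] <- apply_modifier(joints[[j]], fusion())
    joints[[j]]$rest_angle <- rel_deg - rest_angles[[j]]
  }
  asm <- .refresh_joints(asm, joints, rest_angles)
  res <- solve_static(asm, q0 = res$q, gravity = "none",
                      settings = solve_settings(
                        load_steps = 1, tol = settings$tol,
                        tol_abs = settings$tol_abs,
                        max_iter = settings$max_iter,
                        elements_per_segment = settings$elements_per_segment,
                        n_fibers = settings$n_fibers))
  st <- .stage_state("instrumented", res$assembly, res$q)
  if (max(st$screws$gap) > max_gap)
    .stopf("tie target unreachable: residual screw gap %.2f mm at %s",
           max(st$screws$gap), st$screws$level[which.max(st$screws$gap)])
  list(state = st, assembly = res$assembly, joints = joints, q = res$q)
}

#' Run the full staged protocol for one rod scenario
#'
#' Stages: `preop_standing` (follower gravity, joint rest angles calibrated
#' so the standing shape reproduces the radiographic profile), `prone`
#' (unloaded), `released` (facetectomies and PSO wedge, applied
#' incrementally), `instrumented` (rod reduction, locking, PSO fusion),
#' `postop_standing` (follower gravity) and `flexed` (imposed forward
#' rotation at T1). Each stage starts from the previous converged state.
#'
#' The PSO wedge is the planned lordosis change capped at
#' `plan$pso_wedge_cap`; residual correction is delivered by the
#' displacement-controlled reduction to the shared rod contour.
#'
#' @param model a [build_spine()] model.
#' @param joints named list of intact [joint_law()]s.
#' @param scenario a `rod_scenario` from [rod_scenarios()].
#' @param plan a [surgical_plan()].
#' @param settings a [solve_settings()].
#' @return List of class `stage_states`: `stages` (named `stage_state`
#'   list), `scenario`, `plan`, `wedge` (degrees), final `assembly`.
#' @export
run_protocol <- function(model, joints, scenario, plan = surgical_plan(),
                         settings = solve_settings()) {
  ## 1. pre-operative standing (calibrated)
  cal <- .calibrate_standing(model, joints, settings)
  rest <- cal$rest
  preop <- .stage_state("preop_standing", cal$assembly, cal$result$q)

  ## 2. prone
  prone <- prone_transition(model, joints, rest, q_start = preop$q,
                            settings = settings)

  ## 3. releases: facetectomies, then the PSO wedge applied incrementally
  jrel <- joints
  for (j in plan$facetectomy_junctions)
    jrel[[j]] <- apply_modifier(jrel[[j]], facetectomy(plan$facetectomy_factor))
  wedge <- max(0, min(plan$pso_wedge_cap,
                      plan$target_LL - prone$profile$LL))
  q <- prone$q
  nsub <- min(5, settings$load_steps)
  relaxed <- NULL
  for (f in seq_len(nsub) / nsub) {
    jstep <- jrel
    for (j in plan$pso_junctions)
      jstep[[j]] <- apply_modifier(jstep[[j]], pso_wedge(wedge * f / 2))
    asm <- assemble(model, jstep, rest_angles = rest, settings = settings)
    res <- solve_static(asm, q0 = q, gravity = "none",
                        settings = solve_settings(
                          load_steps = 1, tol = settings$tol,
                          tol_abs = settings$tol_abs,
                          max_iter = settings$max_iter))
    q <- res$q
    relaxed <- res
  }
  jrel <- jstep
  released <- .stage_state("released", relaxed$assembly, q)

  ## 4. instrumentation: shared contour from the planned shape
  planned_profile <- sagittal_profile(
    PI = model$profile$PI, PT = model$profile$PT,
    TK = plan$target_TK, LL = plan$target_LL,
    body_mass = model$profile$body_mass)
  planned_model <- build_spine(planned_profile, model$anthropometry)
  contour <- make_rod_contour(planned_model, plan$screw_levels,
                              head_offset = plan$head_offset,
                              n_el = settings$elements_per_segment)
  asm <- assemble(model, jrel, scenario = scenario, contour = contour,
                  rest_angles = rest, settings = settings)
  q_start <- asm$q0
  q_start[seq_len(3 * asm$nb)] <- q[seq_len(3 * asm$nb)]
  red <- reduce_and_lock(asm, q_start, jrel, rest, plan, settings)
  instrumented <- red$state

  ## 5. post-operative standing
  res5 <- solve_static(red$assembly, q0 = red$q, gravity = "follower",
                       settings = settings)
  postop <- .stage_state("postop_standing", res5$assembly, res5$q)

  ## 6. flexion: forward rotation imposed at T1, gravity maintained
  th_t1 <- postop$poses$theta[postop$poses$level == "T1"]
  presc <- impose_rotation(res5$assembly, "T1",
                           th_t1 - plan$flexion_angle)
  res6 <- solve_static(res5$assembly, q0 = res5$q, gravity = "follower",
                       gravity_ramp = FALSE, prescribed = presc,
                       settings = settings)
  flexed <- .stage_state("flexed", res6$assembly, res6$q)

  structure(
    list(stages = list(preop_standing = preop, prone = prone,
                       released = released, instrumented = instrumented,
                       postop_standing = postop, flexed = flexed),
         scenario = scenario, plan = plan, wedge = wedge,
         rest_angles = rest, assembly = res6$assembly),
    class = "stage_states")
}

#' @export
print.stage_states <- function(x, ...) {
  cat(sprintf("Protocol run, scenario %s (PSO wedge %.1f deg)\n",
              x$scenario$name, x$wedge))
  for (s in x$stages)
    cat(sprintf("  %-16s TK %6.1f  LL %6.1f\n", s$stage,
                s$profile$TK, s$profile$LL))
  invisible(x)
}
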