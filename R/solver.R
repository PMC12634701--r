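# Nonlinear static equilibrium of the coupled system: rigid vertebrae
# (3 DOF each: x, z, theta), nonlinear FSU joint springs, elastoplastic
# corotational beam elements for the rods, and pedicle-screw tie springs.
#
# Internal units: mm, N, N.mm, radians. The sacrum/pelvis body is fixed.

.S2 <- matrix(c(0, 1, -1, 0), 2, 2)  # 90-degree rotation (d/dtheta of R)

#' Solver settings
#'
#' @param load_steps number of increments per stage (>= 1).
#' @param tol relative residual tolerance (force residual over reference
#'   load norm).
#' @param tol_abs absolute residual floor, N: the step is accepted once the
#'   residual norm falls below `max(tol * reference, tol_abs)` (rigid fused
#'   couplings leave a small round-off force floor).
#' @param max_iter Newton iteration cap per load step.
#' @param line_search enable backtracking when a full Newton step grows the
#'   residual.
#' @param elements_per_segment beam elements per instrumented segment.
#' @param n_fibers fibers per rod section.
#' @return List of class `solve_settings`.
#' @export
solve_settings <- function(load_steps = 10, tol = 1e-6, tol_abs = 1e-3,
                           max_iter = 50,
                           line_search = TRUE, elements_per_segment = 8,
                           n_fibers = 32) {
  if (tol <= 0 || load_steps < 1) .stopf("tolerance must be > 0 and steps >= 1")
  structure(list(load_steps = as.integer(load_steps), tol = tol,
                 tol_abs = tol_abs,
                 max_iter = as.integer(max_iter), line_search = line_search,
                 elements_per_segment = as.integer(elements_per_segment),
                 n_fibers = as.integer(n_fibers)),
            class = "solve_settings")
}

## ---- generic 3-DOF spring element (FSU joints and screw ties) ----------

# qA, qB: (x, z, theta[rad]) of the two bodies; rA, rB local attachment
# offsets; kx (shear, along the B endplate tangent), ky (axial); moment_fn:
# torque (N.mm) as a function of relative rotation (rad) minus rest.
.spring_g <- function(qA, qB, rA, rB, kx, ky, moment_fn, rest) {
  RA <- .rot(qA[3]); RB <- .rot(qB[3])
  pA <- qA[1:2] + RA %*% rA
  pB <- qB[1:2] + RB %*% rB
  dl <- crossprod(RB, pA - pB)  # R(-thetaB) (pA - pB)
  f <- c(kx * dl[1], ky * dl[2])
  phi <- qA[3] - qB[3] - rest
  M <- moment_fn(phi)
  dldthA <- .S2 %*% .rot(qA[3] - qB[3]) %*% rA
  dldthB <- -.S2 %*% (dl + rB)
  g <- numeric(6)
  g[1:2] <- RB %*% f
  g[3] <- sum(f * dldthA) + M
  g[4:5] <- -(RB %*% f)
  g[6] <- sum(f * dldthB) - M
  g
}

# exact tangent of .spring_g; tangent_fn(phi) = dM/dphi (N.mm/rad)
.spring_K <- function(qA, qB, rA, rB, kx, ky, tangent_fn, rest) {
  RA <- .rot(qA[3]); RB <- .rot(qB[3]); RBt <- t(RB)
  pA <- qA[1:2] + RA %*% rA
  pB <- qB[1:2] + RB %*% rB
  dl <- drop(crossprod(RB, pA - pB))
  Kd <- diag(c(kx, ky), 2)
  f <- c(kx * dl[1], ky * dl[2])
  w <- drop(.rot(qA[3] - qB[3]) %*% rA)
  a1 <- drop(.S2 %*% w)             # d dl / d thetaA
  vB <- drop(-.S2 %*% (dl + rB))    # d dl / d thetaB
  Mp <- tangent_fn(qA[3] - qB[3] - rest)
  Sf <- drop(.S2 %*% f)
  K <- matrix(0, 6, 6)
  blk <- RB %*% Kd
  K[1:2, 1:2] <- blk %*% RBt
  K[1:2, 3] <- blk %*% a1
  K[1:2, 4:5] <- -blk %*% RBt
  K[1:2, 6] <- blk %*% vB + .S2 %*% RB %*% f
  r3 <- drop(Kd %*% a1)
  K[3, 1:2] <- drop(r3 %*% RBt)
  K[3, 3] <- sum(a1 * r3) - sum(f * w) + Mp
  K[3, 4:5] <- -drop(r3 %*% RBt)
  K[3, 6] <- sum(r3 * vB) + sum(f * w) - Mp
  K[4:5, ] <- -K[1:2, ]
  r6 <- drop(Kd %*% vB) + Sf
  K[6, 1:2] <- drop(r6 %*% RBt)
  K[6, 3] <- sum(r6 * a1) - Mp
  K[6, 4:5] <- -drop(r6 %*% RBt)
  K[6, 6] <- sum(r6 * vB) + Mp
  K
}

## ---- corotational elastoplastic beam element ---------------------------

.gauss2 <- c(0.5 - 0.5 / sqrt(3), 0.5 + 0.5 / sqrt(3))

# el: list(L0, beta0, t0 (length-2 initial node rotations), fibers,
# material, state (list of 2 per-gauss states)). qi, qj: nodal (x,z,theta).
.beam_eval <- function(el, qi, qj) {
  dx <- qj[1] - qi[1]; dz <- qj[2] - qi[2]
  Ln <- sqrt(dx^2 + dz^2)
  beta <- atan2(dz, dx)
  # keep the rigid rotation continuous with respect to the initial chord
  db <- beta - el$beta0
  if (db > pi) db <- db - 2 * pi else if (db < -pi) db <- db + 2 * pi
  tb <- c((qi[3] - el$t0[1]) - db, (qj[3] - el$t0[2]) - db)
  eps0 <- (Ln - el$L0) / el$L0
  L0 <- el$L0
  Fu <- 0; Mv <- c(0, 0)
  kl <- matrix(0, 3, 3)
  states <- vector("list", 2)
  sig_out <- numeric(2); Mg <- numeric(2); Ng <- numeric(2)
  plastic <- FALSE; rupture <- FALSE
  for (g in 1:2) {
    xi <- .gauss2[g]
    B <- c(6 * xi - 4, 6 * xi - 2) / L0
    kap <- sum(B * tb)
    r <- section_response(el$fibers, el$material, eps0, kap, el$state[[g]])
    W <- L0 / 2
    Fu <- Fu + W * r$N / L0
    Mv <- Mv + W * r$M * B
    kl[1, 1] <- kl[1, 1] + W * r$EA / L0^2
    kl[1, 2:3] <- kl[1, 2:3] + W * r$ES * B / L0
    kl[2:3, 2:3] <- kl[2:3, 2:3] + W * r$EI * outer(B, B)
    states[[g]] <- r$state
    sig_out[g] <- r$sigma_outer
    Mg[g] <- r$M; Ng[g] <- r$N
    plastic <- plastic || r$plastic
    rupture <- rupture || r$rupture
  }
  kl[2:3, 1] <- kl[1, 2:3]
  c_ <- cos(beta); s_ <- sin(beta)
  rvec <- c(-c_, -s_, 0, c_, s_, 0)
  zvec <- c(s_, -c_, 0, -s_, c_, 0)
  Tm <- rbind(rvec,
              c(0, 0, 1, 0, 0, 0) - zvec / Ln,
              c(0, 0, 0, 0, 0, 1) - zvec / Ln)
  floc <- c(Fu, Mv)
  g6 <- drop(crossprod(Tm, floc))
  Kg <- crossprod(Tm, kl %*% Tm) +
    Fu / Ln * tcrossprod(zvec) +
    (Mv[1] + Mv[2]) / Ln^2 * (tcrossprod(rvec, zvec) + tcrossprod(zvec, rvec))
  list(g = g6, K = Kg, states = states, sigma_outer = sig_out,
       M = Mg, N = Ng, plastic = plastic, rupture = rupture,
       theta_bar = tb, eps0 = eps0)
}

## ---- assembly ----------------------------------------------------------

#' Assemble the coupled spine/instrumentation system
#'
#' Builds the DOF map (3 per vertebra T1..S1, the sacrum/pelvis body
#' fixed), the joint spring elements (one per junction, attached at disc
#' centres), and -- when a rod scenario and contour are supplied -- the rod
#' beam mesh and pedicle-screw tie elements.
#'
#' @param model a [build_spine()] model.
#' @param joints named list of [joint_law()] per junction (e.g.
#'   [default_joint_table()]), possibly surgically modified.
#' @param scenario optional `rod_scenario` (see [rod_scenarios()]).
#' @param contour optional rod contour from [make_rod_contour()]; required
#'   with a scenario.
#' @param rest_angles optional named vector of geometric joint rest angles
#'   (degrees, `theta_upper - theta_lower`); defaults to the built wedges.
#'   A joint law's own `rest_angle` (surgical wedge) is added on top.
#' @param settings a [solve_settings()].
#' @param fix_base keep the sacrum/pelvis fixed (the physical model);
#'   `FALSE` is only meaningful to demonstrate rigid-body-mode detection.
#' @param tie_stiffness,tie_rot_stiffness screw tie stiffness during
#'   reduction, N/mm and N.mm/rad (bilateral pair lumped in the sagittal
#'   plane); [reduce_and_lock()] stiffens the ties by its lock factor once
#'   the set screws are locked.
#' @return An object of class `spine_assembly`.
#' @export
assemble <- function(model, joints, scenario = NULL, contour = NULL,
                     rest_angles = NULL, settings = solve_settings(),
                     fix_base = TRUE,
                     tie_stiffness = 2000, tie_rot_stiffness = 1e6) {
  if (!fix_base)
    .stopf("unconstrained rigid-body mode: global translation/rotation of the whole spine (pelvis fixation removed)")
  lv <- model$poses$level
  nb <- length(lv)
  bidx <- stats::setNames(seq_len(nb), lv)
  q0 <- numeric(3 * nb)
  for (i in seq_len(nb)) {
    q0[3 * i - 2] <- model$poses$x[i]
    q0[3 * i - 1] <- model$poses$z[i]
    q0[3 * i] <- model$poses$theta[i] * .deg2rad
  }
  if (is.null(rest_angles))
    rest_angles <- stats::setNames(model$junctions$rest_angle,
                                   model$junctions$junction)

  jels <- lapply(seq_len(nrow(model$junctions)), function(k) {
    jrow <- model$junctions[k, ]
    law <- joints[[jrow$junction]]
    if (is.null(law)) .stopf("no joint law for junction %s", jrow$junction)
    iA <- bidx[[jrow$upper]]; iB <- bidx[[jrow$lower]]
    pj <- c(jrow$px, jrow$pz)
    thA <- model$poses$theta[iA] * .deg2rad
    thB <- model$poses$theta[iB] * .deg2rad
    rA <- crossprod(.rot(thA), pj - c(model$poses$x[iA], model$poses$z[iA]))
    rB <- crossprod(.rot(thB), pj - c(model$poses$x[iB], model$poses$z[iB]))
    rest <- (rest_angles[[jrow$junction]] + law$rest_angle) * .deg2rad
    list(junction = jrow$junction, iA = iA, iB = iB,
         rA = drop(rA), rB = drop(rB),
         kx = law$shear, ky = law$axial, rest = rest, law = law)
  })

  asm <- structure(
    list(model = model, joints = joints, bidx = bidx, nb = nb,
         q0 = q0, jels = jels, rod = NULL, ties = NULL,
         ndof = 3 * nb,
         fixed = c(3 * bidx[["S1"]] - 2, 3 * bidx[["S1"]] - 1,
                   3 * bidx[["S1"]]),
         tie_stiffness = tie_stiffness,
         tie_rot_stiffness = tie_rot_stiffness,
         settings = settings),
    class = "spine_assembly")

  if (!is.null(scenario)) {
    if (is.null(contour)) .stopf("a rod scenario requires a contour")
    nn <- nrow(contour$nodes)
    node_dof0 <- 3 * nb
    asm$ndof <- 3 * nb + 3 * nn
    q0r <- numeric(3 * nn)
    for (j in seq_len(nn)) {
      q0r[3 * j - 2] <- contour$nodes$x[j]
      q0r[3 * j - 1] <- contour$nodes$z[j]
      q0r[3 * j] <- contour$nodes$theta[j]
    }
    asm$q0 <- c(q0, q0r)
    nf <- settings$n_fibers
    els <- vector("list", nn - 1)
    for (e in seq_len(nn - 1)) {
      p1 <- c(contour$nodes$x[e], contour$nodes$z[e])
      p2 <- c(contour$nodes$x[e + 1], contour$nodes$z[e + 1])
      L0 <- sqrt(sum((p2 - p1)^2))
      s_mid <- (contour$nodes$s[e] + contour$nodes$s[e + 1]) / 2
      d <- diameter_at(scenario$profile, s_mid, contour$landmarks)
      els[[e]] <- list(
        n1 = e, n2 = e + 1, L0 = L0, beta0 = atan2(p2[2] - p1[2], p2[1] - p1[1]),
        t0 = c(contour$nodes$theta[e], contour$nodes$theta[e + 1]),
        fibers = fiber_section(d, nf), material = scenario$material,
        d = d, s_mid = s_mid,
        state = list(NULL, NULL))
    }
    ties <- lapply(seq_along(contour$tie_nodes), function(k) {
      lvk <- contour$tie_levels[k]
      ib <- bidx[[lvk]]
      list(level = lvk, node = contour$tie_nodes[k], body = ib,
           r_head = contour$head_local,
           rest = contour$nodes$theta[contour$tie_nodes[k]] -
             contour$tie_theta_planned[k],
           dl0 = c(0, 0), phi0 = 0)
    })
    asm$rod <- list(scenario = scenario, contour = contour, elements = els,
                    nodes = contour$nodes, node_dof0 = node_dof0)
    asm$ties <- ties
  }
  asm
}

#' Follower-load gravity
#'
#' Distributes body weight along the deformed spine: with cumulative
#' supported weight `P_i` above junction `i` and `t_i` the caudal unit
#' tangent between adjacent centroids, vertebra `i` receives
#' `P_i t_i - P_(i-1) t_(i-1)` at its centroid. The forces telescope so the
#' load transmitted at the sacrum has magnitude `g * sum(m)` in any
#' posture; on a straight vertical spine the scheme reduces exactly to
#' plain vertical gravity. The load is configuration-dependent (the
#' tangents follow the deformation); `jacobian = TRUE` also returns its
#' derivative with respect to the state, which [solve_static()] folds into
#' the tangent so the compressive path tracks the spine continuously (an
#' osteo-ligamentous spine is unstable under direction-frozen gravity).
#'
#' @param assembly a [assemble()]d system.
#' @param q state vector (defaults to the assembly reference state).
#' @param mode `"follower"` or `"vertical"` (plain gravity).
#' @param g gravitational acceleration, m/s^2.
#' @param jacobian also return `J = dF/dq` (dense).
#' @return External load vector (length `ndof`), N and N.mm; with
#'   `jacobian = TRUE` a list `F`, `J`.
#' @export
follower_gravity <- function(assembly, q = assembly$q0,
                             mode = c("follower", "vertical"), g = 9.81,
                             jacobian = FALSE) {
  mode <- match.arg(mode)
  nb <- assembly$nb
  w <- assembly$model$mass_fraction * assembly$model$body_mass * g
  F <- numeric(assembly$ndof)
  if (mode == "vertical") {
    for (i in seq_len(nb)) F[3 * i - 1] <- F[3 * i - 1] - w[i]
    if (jacobian) return(list(F = F, J = NULL))
    return(F)
  }
  cx <- q[3 * seq_len(nb) - 2]; cz <- q[3 * seq_len(nb) - 1]
  P <- cumsum(w)
  J <- if (jacobian) matrix(0, assembly$ndof, assembly$ndof) else NULL
  for (i in seq_len(nb - 1)) {
    u <- c(cx[i + 1] - cx[i], cz[i + 1] - cz[i])
    L <- sqrt(sum(u^2))
    tv <- u / L
    # junction i: +P_i t_i on body i, -P_i t_i on body i+1
    ri <- c(3 * i - 2, 3 * i - 1)
    rj <- c(3 * i + 1, 3 * i + 2)
    F[ri] <- F[ri] + P[i] * tv
    # the reaction at the terminal junction enters the fixed sacrum/pelvis
    # (the load path out of the spine), not the modelled body set
    if (i + 1 < nb) F[rj] <- F[rj] - P[i] * tv
    if (jacobian) {
      M <- P[i] / L * (diag(2) - tcrossprod(tv))  # d(P t)/dc_{i+1}
      J[ri, rj] <- J[ri, rj] + M
      J[ri, ri] <- J[ri, ri] - M
      J[rj, rj] <- J[rj, rj] - M
      J[rj, ri] <- J[rj, ri] + M
    }
  }
  if (jacobian) list(F = F, J = J) else F
}

# internal forces and tangent of the full system at state q
.system_forces <- function(asm, q, tie_ramp = 1, want_K = TRUE,
                           collect = FALSE) {
  n <- asm$ndof
  R <- numeric(n)
  K <- if (want_K) matrix(0, n, n) else NULL
  jinfo <- NULL; rinfo <- NULL; tinfo <- NULL
  if (collect) jinfo <- vector("list", length(asm$jels))

  for (k in seq_along(asm$jels)) {
    el <- asm$jels[[k]]
    ia <- (3 * el$iA - 2):(3 * el$iA)
    ib <- (3 * el$iB - 2):(3 * el$iB)
    law <- el$law
    mfn <- function(phi) 1000 * joint_moment(law, phi * .rad2deg, warn = FALSE)
    tfn <- function(phi) 1000 * .rad2deg *
      tangent_stiffness(law, phi * .rad2deg)
    g6 <- .spring_g(q[ia], q[ib], el$rA, el$rB, el$kx, el$ky, mfn, el$rest)
    idx <- c(ia, ib)
    R[idx] <- R[idx] + g6
    if (want_K)
      K[idx, idx] <- K[idx, idx] +
        .spring_K(q[ia], q[ib], el$rA, el$rB, el$kx, el$ky, tfn, el$rest)
    if (collect) {
      phi <- q[ia[3]] - q[ib[3]] - el$rest
      jinfo[[k]] <- data.frame(
        junction = el$junction, rotation = phi * .rad2deg,
        moment = joint_moment(law, phi * .rad2deg, warn = FALSE),
        state = law$state, stringsAsFactors = FALSE)
    }
  }

  if (!is.null(asm$rod)) {
    nd0 <- asm$rod$node_dof0
    if (collect) rinfo <- vector("list", length(asm$rod$elements))
    for (e in seq_along(asm$rod$elements)) {
      el <- asm$rod$elements[[e]]
      i1 <- nd0 + (3 * el$n1 - 2):(3 * el$n1)
      i2 <- nd0 + (3 * el$n2 - 2):(3 * el$n2)
      be <- .beam_eval(el, q[i1], q[i2])
      idx <- c(i1, i2)
      R[idx] <- R[idx] + be$g
      if (want_K) K[idx, idx] <- K[idx, idx] + be$K
      if (collect)
        rinfo[[e]] <- data.frame(
          element = e, s = el$s_mid, d = el$d,
          M = max(abs(be$M)) / 1000, N = max(abs(be$N)),
          sigma_outer = max(be$sigma_outer),
          plastic = be$plastic, rupture = be$rupture)
    }
    # displacement-controlled reduction: the tie rest gap shrinks from the
    # initial head-to-rod mismatch (tie_ramp = 0) to zero (tie_ramp = 1)
    # at full tie stiffness
    kt <- asm$tie_stiffness
    kr <- asm$tie_rot_stiffness
    shift <- 1 - tie_ramp
    if (collect) tinfo <- vector("list", length(asm$ties))
    for (k in seq_along(asm$ties)) {
      tk <- asm$ties[[k]]
      ia <- nd0 + (3 * tk$node - 2):(3 * tk$node)
      ib <- (3 * tk$body - 2):(3 * tk$body)
      rBe <- tk$r_head + shift * tk$dl0
      reste <- tk$rest + shift * tk$phi0
      mfn <- function(phi) kr * phi
      tfn <- function(phi) kr
      g6 <- .spring_g(q[ia], q[ib], c(0, 0), rBe, kt, kt, mfn, reste)
      idx <- c(ia, ib)
      R[idx] <- R[idx] + g6
      if (want_K)
        K[idx, idx] <- K[idx, idx] +
          .spring_K(q[ia], q[ib], c(0, 0), rBe, kt, kt, tfn, reste)
      if (collect) {
        fvec <- g6[1:2]
        gap <- sqrt(sum(fvec^2)) / max(kt, 1e-12)
        tinfo[[k]] <- data.frame(
          level = tk$level, fx = fvec[1], fz = fvec[2],
          force = sqrt(sum(fvec^2)), gap = gap, stringsAsFactors = FALSE)
      }
    }
  }
  out <- list(R = R, K = K)
  if (collect) {
    out$joint_info <- do.call(rbind, jinfo)
    out$rod_info <- if (!is.null(rinfo)) do.call(rbind, rinfo)
    out$tie_info <- if (!is.null(tinfo)) do.call(rbind, tinfo)
  }
  out
}

# commit beam plastic states at state q
.commit_plastic <- function(asm, q) {
  if (is.null(asm$rod)) return(asm)
  nd0 <- asm$rod$node_dof0
  for (e in seq_along(asm$rod$elements)) {
    el <- asm$rod$elements[[e]]
    i1 <- nd0 + (3 * el$n1 - 2):(3 * el$n1)
    i2 <- nd0 + (3 * el$n2 - 2):(3 * el$n2)
    be <- .beam_eval(el, q[i1], q[i2])
    asm$rod$elements[[e]]$state <- be$states
  }
  asm
}

#' Solve static equilibrium under staged loading
#'
#' Incremental Newton solution: external loads (and prescribed DOF values)
#' are ramped over `load_steps`; follower gravity is re-oriented along the
#' deformed inter-vertebral tangents at the start of each step; rod plastic
#' state is committed path-dependently after each converged step.
#'
#' @param assembly a [assemble()]d system.
#' @param q0 starting state (defaults to the assembly reference).
#' @param gravity `"none"`, `"follower"` or `"vertical"`.
#' @param prescribed named numeric vector of prescribed DOF values
#'   (names = DOF indices), ramped from their starting values.
#' @param tie_ramp ramp screw-tie stiffness with the load factor (rod
#'   reduction stage).
#' @param extra_load fixed external load vector added to gravity (ramped).
#' @param gravity_ramp ramp gravity with the load factor (`FALSE` keeps it
#'   at full magnitude throughout, e.g. while ramping an imposed rotation
#'   from an already-loaded state).
#' @param settings a [solve_settings()]; defaults to the assembly's.
#' @return List of class `solve_result`: final state `q`, updated
#'   `assembly` (committed plastic state), convergence diagnostics.
#' @export
solve_static <- function(assembly, q0 = assembly$q0,
                         gravity = c("none", "follower", "vertical"),
                         prescribed = NULL, tie_ramp = FALSE,
                         extra_load = NULL, gravity_ramp = TRUE,
                         settings = assembly$settings) {
  gravity <- match.arg(gravity)
  n <- assembly$ndof
  q <- q0
  fixed <- assembly$fixed
  presc_idx <- if (length(prescribed)) as.integer(names(prescribed)) else integer(0)
  presc_start <- q[presc_idx]
  free <- setdiff(seq_len(n), c(fixed, presc_idx))
  hist <- list()
  nsteps <- settings$load_steps
  gmode <- if (gravity == "vertical") "vertical" else "follower"
  for (step in seq_len(nsteps)) {
    lam <- step / nsteps
    glam <- if (gravity_ramp) lam else 1
    ramp <- if (tie_ramp) lam else 1
    q[presc_idx] <- presc_start + lam * (prescribed - presc_start)
    # residual with configuration-dependent gravity
    resid <- function(qv, want_K = TRUE) {
      sys <- .system_forces(assembly, qv, tie_ramp = ramp, want_K = want_K)
      if (gravity == "none") {
        Fe <- numeric(n); Jg <- NULL
      } else {
        gr <- follower_gravity(assembly, qv, mode = gmode, jacobian = want_K)
        if (want_K) { Fe <- gr$F * glam; Jg <- gr$J }
        else { Fe <- gr * glam; Jg <- NULL }
      }
      if (!is.null(extra_load)) Fe <- Fe + extra_load * lam
      K <- sys$K
      if (want_K && !is.null(Jg)) K <- K - glam * Jg
      list(res = sys$R - Fe, K = K, ref = max(sqrt(sum(Fe^2)), 1))
    }
    conv <- FALSE
    for (it in seq_len(settings$max_iter)) {
      rr <- resid(q)
      rn <- sqrt(sum(rr$res[free]^2))
      ref <- rr$ref
      if (rn <= max(settings$tol * ref, settings$tol_abs)) { conv <- TRUE; break }
      dq <- tryCatch(
        solve(rr$K[free, free, drop = FALSE], -rr$res[free]),
        error = function(e) .stopf("singular system at step %d: %s", step,
                                   conditionMessage(e)))
      alpha <- 1
      repeat {
        qt <- q; qt[free] <- qt[free] + alpha * dq
        rtn <- sqrt(sum(resid(qt, want_K = FALSE)$res[free]^2))
        if (!settings$line_search || rtn < rn || alpha < 1 / 4096) break
        alpha <- alpha / 2
      }
      q <- qt
    }
    if (!conv) {
      rr <- resid(q)
      rn <- sqrt(sum(rr$res[free]^2))
      if (rn > max(settings$tol * rr$ref, settings$tol_abs) * 100)
        .stopf("non-convergence at load step %d/%d (relative residual %.3e)",
               step, nsteps, rn / rr$ref)
    }
    assembly <- .commit_plastic(assembly, q)
    rn_final <- sqrt(sum(resid(q, want_K = FALSE)$res[free]^2))
    hist[[step]] <- c(step = step, iters = it, residual = rn_final / ref)
  }
  structure(list(q = q, assembly = assembly,
                 gravity = gravity, tie_ramp = if (tie_ramp) 1 else NULL,
                 diagnostics = do.call(rbind, hist)),
            class = "solve_result")
}

#' Prescribe a sagittal rotation at a level
#'
#' Returns a named prescribed-DOF vector fixing the sagittal rotation of
#' `level` at `angle` degrees (absolute orientation); translations of the
#' level remain free. Pass the result to [solve_static()].
#'
#' @param assembly a [assemble()]d system.
#' @param level vertebral level, e.g. `"T1"`.
#' @param angle target absolute orientation, degrees.
#' @return Named numeric vector (DOF index -> value in radians).
#' @export
impose_rotation <- function(assembly, level, angle) {
  if (!level %in% names(assembly$bidx)) .stopf("unknown level %s", level)
  dof <- 3 * assembly$bidx[[level]]
  if (dof %in% assembly$fixed)
    .stopf("conflicting constraint: rotation of %s is already fixed", level)
  stats::setNames(angle * .deg2rad, dof)
}

#' Count free degrees of freedom
#' @param assembly a [assemble()]d system.
#' @return Integer.
#' @export
n_free_dof <- function(assembly) assembly$ndof - length(assembly$fixed)

#' Cantilever rod bench test
#'
#' Solves a straight horizontal rod clamped at one end with a transverse
#' tip force and/or tip moment, using the same corotational elastoplastic
#' beam elements as the spine assembly. Intended for mechanics
#' verification (Euler-Bernoulli closed forms, plastic residuals).
#'
#' @param L rod length, mm.
#' @param d diameter, mm.
#' @param tip_force transverse tip load, N (positive = +z).
#' @param tip_moment tip moment, N.mm.
#' @param n_el number of elements.
#' @param material a [rod_material()].
#' @param unload also return the state after removing the load (elastic
#'   unloading; nonzero residuals indicate plasticity).
#' @param settings a [solve_settings()].
#' @return List: `tip_deflection` (mm), `tip_rotation` (rad), `plastic`,
#'   and with `unload = TRUE` the residual `tip_deflection_unloaded`,
#'   `tip_rotation_unloaded`.
#' @export
rod_cantilever <- function(L, d, tip_force = 0, tip_moment = 0, n_el = 8,
                           material = rod_material(), unload = FALSE,
                           settings = solve_settings()) {
  nn <- n_el + 1
  xs <- seq(0, L, length.out = nn)
  els <- lapply(seq_len(n_el), function(e)
    list(n1 = e, n2 = e + 1, L0 = xs[e + 1] - xs[e], beta0 = 0,
         t0 = c(0, 0), fibers = fiber_section(d, settings$n_fibers),
         material = material, state = list(NULL, NULL)))
  q <- as.numeric(rbind(xs, 0, 0))
  free <- 4:(3 * nn)
  forces <- function(q, want_K = TRUE) {
    n <- length(q)
    R <- numeric(n)
    K <- if (want_K) matrix(0, n, n) else NULL
    for (el in els) {
      i1 <- (3 * el$n1 - 2):(3 * el$n1); i2 <- (3 * el$n2 - 2):(3 * el$n2)
      be <- .beam_eval(el, q[i1], q[i2])
      idx <- c(i1, i2)
      R[idx] <- R[idx] + be$g
      if (want_K) K[idx, idx] <- K[idx, idx] + be$K
    }
    list(R = R, K = K)
  }
  run_to <- function(q, Fz0, M0, Fz, M) {
    for (step in seq_len(settings$load_steps)) {
      lam <- step / settings$load_steps
      Fe <- numeric(3 * nn)
      Fe[3 * nn - 1] <- Fz0 + (Fz - Fz0) * lam
      Fe[3 * nn] <- M0 + (M - M0) * lam
      ref <- max(sqrt(sum(Fe^2)), 1)
      for (it in seq_len(settings$max_iter)) {
        sys <- forces(q)
        res <- sys$R - Fe
        if (sqrt(sum(res[free]^2)) <= settings$tol * ref) break
        q[free] <- q[free] + solve(sys$K[free, free], -res[free])
      }
      # commit plastic state
      for (e in seq_len(n_el)) {
        i1 <- (3 * e - 2):(3 * e); i2 <- (3 * e + 1):(3 * e + 3)
        els[[e]]$state <<- .beam_eval(els[[e]], q[i1], q[i2])$states
      }
    }
    q
  }
  q <- run_to(q, 0, 0, tip_force, tip_moment)
  plastic <- any(vapply(els, function(el)
    any(vapply(el$state, function(s) !is.null(s) && any(s$alpha > 0),
               logical(1))), logical(1)))
  out <- list(tip_deflection = q[3 * nn - 1],
              tip_rotation = q[3 * nn],
              plastic = plastic)
  if (unload) {
    q <- run_to(q, tip_force, tip_moment, 0, 0)
    out$tip_deflection_unloaded <- q[3 * nn - 1]
    out$tip_rotation_unloaded <- q[3 * nn]
  }
  out
}
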