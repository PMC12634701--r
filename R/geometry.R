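# Parametric sagittal spine geometry: synthesis from radiographic parameters
# and measurement of those parameters from any model or solved state.

#' Sagittal radiographic profile
#'
#' Bundle of the standard sagittal parameters describing a patient:
#' pelvic incidence (PI), pelvic tilt (PT), sacral slope (SS = PI - PT),
#' T4-T12 thoracic kyphosis (TK, positive = kyphosis), L1-S1 lumbar lordosis
#' (LL, positive = lordosis), a scalar coronal lumbar Cobb (report only) and
#' body mass.
#'
#' Convention: angles in degrees; x anterior-positive, z cranial-positive,
#' rotations counter-clockwise positive viewed from the patient's left.
#'
#' @param PI pelvic incidence, degrees (20-100).
#' @param PT pelvic tilt, degrees.
#' @param TK T4-T12 kyphosis Cobb angle, degrees (positive = kyphotic).
#' @param LL L1-S1 lordosis Cobb angle, degrees (positive = lordotic).
#' @param lumbar_cobb_coronal scalar coronal Cobb report, degrees.
#' @param body_mass body mass, kg (> 0).
#' @return An object of class `sagittal_profile`.
#' @export
sagittal_profile <- function(PI, PT, TK, LL, lumbar_cobb_coronal = 0,
                             body_mass = 60) {
  SS <- PI - PT
  if (!is.finite(PI) || PI < 20 || PI > 100)
    .stopf("PI must lie in [20, 100] degrees (got %s)", PI)
  if (body_mass <= 0) .stopf("body_mass must be > 0")
  if (abs(PI - (PT + SS)) > 0.1)
    .stopf("PI = PT + SS violated by more than 0.1 degree")
  structure(
    list(PI = PI, PT = PT, SS = SS, TK = TK, LL = LL,
         lumbar_cobb_coronal = lumbar_cobb_coronal, body_mass = body_mass),
    class = "sagittal_profile")
}

#' @export
print.sagittal_profile <- function(x, ...) {
  cat(sprintf(
    "Sagittal profile: PI %.1f | PT %.1f | SS %.1f | TK %.1f | LL %.1f | mass %.1f kg\n",
    x$PI, x$PT, x$SS, x$TK, x$LL, x$body_mass))
  invisible(x)
}

#' Default anthropometry table
#'
#' Average-adult vertebral body heights, disc heights and per-level mass
#' fractions (head/neck and arms lumped at T1), uniformly scalable. Mass
#' fractions follow standard segmental anthropometry; the summed supported
#' fraction at the sacrum is about 0.59 of body mass.
#'
#' @param scale uniform scale factor applied to all heights.
#' @return data.frame with columns `level`, `body_height`, `disc_below`,
#'   `mass_fraction` (heights in mm; `disc_below` is the disc at the junction
#'   between `level` and the next caudal level, NA for S1).
#' @export
default_anthropometry <- function(scale = 1) {
  path <- system.file("extdata", "anthropometry_default.csv",
                      package = "rodspine", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$body_height <- tab$body_height * scale
  tab$disc_below <- tab$disc_below * scale
  tab
}

# Per-junction apportionment fractions of the aggregate Cobb angles.
# Thoracic kyphosis is distributed over the 8 junctions T4-T5 .. T11-T12
# with a mid-thoracic apex; lumbar lordosis over L1-L2 .. L5-S1 weighted
# caudally (normative: about two thirds of lordosis arises at L4-S1).
.tk_junctions <- c("T4-T5", "T5-T6", "T6-T7", "T7-T8", "T8-T9", "T9-T10",
                   "T10-T11", "T11-T12")
.tk_fractions <- c(0.09, 0.11, 0.13, 0.15, 0.15, 0.14, 0.12, 0.11)
.ll_junctions <- c("L1-L2", "L2-L3", "L3-L4", "L4-L5", "L5-S1")
.ll_fractions <- c(0.10, 0.14, 0.20, 0.26, 0.30)

#' Build a sagittal spine model from a radiographic profile
#'
#' Synthesizes rigid-vertebra sagittal geometry (T1..S1 plus fixed pelvis)
#' whose measured radiographic parameters reproduce the requested profile.
#' The aggregate TK and LL Cobb angles are apportioned to junction wedges
#' using normative per-level fractions; junctions outside the T4-T12 and
#' L1-S1 ranges receive small default wedges.
#'
#' @param profile a [sagittal_profile()].
#' @param anthropometry per-level heights/mass table, see
#'   [default_anthropometry()].
#' @param upper_thoracic_wedge wedge (degrees) at each junction above T4-T5
#'   (kyphotic continuation; negative = kyphotic).
#' @param thoracolumbar_wedge wedge (degrees) at T12-L1.
#' @param sacrum_offset distance (mm) from the femoral-head axis to the
#'   centre of the superior S1 endplate.
#' @param max_wedge largest admissible per-junction wedge magnitude, degrees.
#' @return An object of class `spine_model`: vertebral poses, disc heights,
#'   mass fractions, junction rest angles and the generating profile.
#' @export
build_spine <- function(profile, anthropometry = default_anthropometry(),
                        upper_thoracic_wedge = -2, thoracolumbar_wedge = 0,
                        sacrum_offset = 70, max_wedge = 25) {
  stopifnot(inherits(profile, "sagittal_profile"))
  lv <- .levels
  if (!all(lv %in% anthropometry$level))
    .stopf("anthropometry must cover levels T1..S1")
  an <- anthropometry[match(lv, anthropometry$level), ]
  if (any(an$body_height <= 0)) .stopf("body heights must be > 0")

  # junction wedges w_j = theta_upper - theta_lower
  w <- stats::setNames(numeric(length(.junctions)), .junctions)
  w[.tk_junctions] <- -profile$TK * .tk_fractions
  w[.ll_junctions] <- profile$LL * .ll_fractions
  w[c("T1-T2", "T2-T3", "T3-T4")] <- upper_thoracic_wedge
  w["T12-L1"] <- thoracolumbar_wedge
  bad <- names(w)[abs(w) > max_wedge]
  if (length(bad))
    .stopf("requested angles unreachable: junction wedge exceeds %g deg at %s",
           max_wedge, paste(bad, collapse = ", "))

  # orientations, caudal to cranial
  # the sacral endplate tilts anterior-down by the sacral slope
  theta <- stats::setNames(numeric(length(lv)), lv)
  theta["S1"] <- -profile$SS
  for (i in rev(seq_along(.junctions))) {
    up <- .levels[i]; lo <- .levels[i + 1]
    theta[up] <- theta[lo] + w[.junctions[i]]
  }

  # walk positions up from the sacral endplate
  fh <- c(0, 0)  # femoral head axis
  pt_r <- profile$PT * .deg2rad
  sup <- fh + sacrum_offset * c(-sin(pt_r), cos(pt_r))  # S1 superior endplate
  cx <- cz <- stats::setNames(numeric(length(lv)), lv)
  jx <- jz <- stats::setNames(numeric(length(.junctions)), .junctions)
  h <- stats::setNames(an$body_height, lv)
  cS1 <- sup - h["S1"] / 2 * .normal(theta["S1"])
  cx["S1"] <- cS1[1]; cz["S1"] <- cS1[2]
  disc <- stats::setNames(an$disc_below[-length(lv)], .junctions)
  if (any(!is.finite(disc)) || any(disc <= 0))
    .stopf("disc heights must be finite and > 0")
  p <- sup
  for (i in rev(seq_along(.junctions))) {
    up <- .levels[i]; lo <- .levels[i + 1]; j <- .junctions[i]
    nmid <- .normal((theta[up] + theta[lo]) / 2)
    jc <- p + disc[j] / 2 * nmid        # disc (joint) centre
    jx[j] <- jc[1]; jz[j] <- jc[2]
    inf <- p + disc[j] * nmid           # inferior endplate of upper vertebra
    cc <- inf + h[up] / 2 * .normal(theta[up])
    cx[up] <- cc[1]; cz[up] <- cc[2]
    p <- inf + h[up] * .normal(theta[up])  # superior endplate of upper
  }

  poses <- data.frame(level = lv, x = unname(cx), z = unname(cz),
                      theta = unname(theta), body_height = unname(h),
                      stringsAsFactors = FALSE)
  junctions <- data.frame(
    junction = .junctions,
    upper = .levels[-length(lv)], lower = .levels[-1],
    rest_angle = unname(w), px = unname(jx), pz = unname(jz),
    stringsAsFactors = FALSE)

  model <- structure(
    list(poses = poses, junctions = junctions,
         disc_heights = disc,
         mass_fraction = stats::setNames(an$mass_fraction, lv),
         body_mass = profile$body_mass,
         fh = fh, sacrum_offset = sacrum_offset,
         anthropometry = an,
         profile = profile),
    class = "spine_model")
  meas <- measure_profile(model)
  if (abs(meas$TK - profile$TK) > 0.5 || abs(meas$LL - profile$LL) > 0.5)
    .stopf("internal error: built geometry does not reproduce TK/LL")
  model
}

#' @export
print.spine_model <- function(x, ...) {
  m <- measure_profile(x)
  cat(sprintf("Sagittal spine model (%d vertebrae + pelvis)\n",
              nrow(x$poses)))
  cat(sprintf("  measured: TK %.1f | LL %.1f | PI %.1f | PT %.1f\n",
              m$TK, m$LL, m$PI, m$PT))
  invisible(x)
}

#' Measure the sagittal radiographic profile of a model or solved state
#'
#' TK is the Cobb angle between the superior T4 and inferior T12 endplates;
#' LL the Cobb angle between the superior L1 and superior S1 endplates
#' (kyphosis positive TK, lordosis positive LL). PT and PI are measured from
#' the femoral-head axis and the sacral endplate; the pelvis is fixed, so
#' they change only through the stored pelvic pose.
#'
#' @param x a `spine_model` or a `stage_state`.
#' @param ... unused.
#' @return A [sagittal_profile()] of measured values.
#' @export
measure_profile <- function(x, ...) UseMethod("measure_profile")

.measure_from_poses <- function(poses, fh, sacrum_offset, body_mass,
                                coronal = 0) {
  th <- stats::setNames(poses$theta, poses$level)
  TK <- th[["T12"]] - th[["T4"]]
  LL <- th[["L1"]] - th[["S1"]]
  # superior S1 endplate centre from the S1 pose
  hS1 <- poses$body_height[poses$level == "S1"]
  cS1 <- c(poses$x[poses$level == "S1"], poses$z[poses$level == "S1"])
  sup <- cS1 + hS1 / 2 * .normal(th[["S1"]])
  v <- sup - fh
  PT <- atan2(-v[1], v[2]) * .rad2deg
  SS <- -th[["S1"]]
  sagittal_profile(PI = PT + SS, PT = PT, TK = TK, LL = LL,
                   lumbar_cobb_coronal = coronal, body_mass = body_mass)
}

#' @rdname measure_profile
#' @export
measure_profile.spine_model <- function(x, ...) {
  .measure_from_poses(x$poses, x$fh, x$sacrum_offset, x$body_mass,
                      x$profile$lumbar_cobb_coronal)
}

#' @rdname measure_profile
#' @export
measure_profile.stage_state <- function(x, ...) {
  .measure_from_poses(x$poses, x$model$fh, x$model$sacrum_offset,
                      x$model$body_mass,
                      x$model$profile$lumbar_cobb_coronal)
}

#' Pelvic incidence to lumbar lordosis mismatch
#'
#' @param profile a [sagittal_profile()] (or anything with PI and LL fields).
#' @return PI - LL in degrees.
#' @export
pi_ll_mismatch <- function(profile) profile$PI - profile$LL

#' Post-operative pelvic tilt target
#'
#' Two published planning rules: the Le Huec regression
#' `PT = 0.44 * PI - 11.4` and the Schwab threshold `PT < 20` degrees
#' (returned as the 20-degree upper bound).
#'
#' @param PI pelvic incidence, degrees.
#' @param rule `"lehuec"` or `"schwab"`.
#' @return Target (or bound on) pelvic tilt, degrees.
#' @export
target_pt <- function(PI, rule = c("lehuec", "schwab")) {
  rule <- match.arg(rule)
  if (!is.finite(PI)) .stopf("PI must be finite")
  switch(rule, lehuec = 0.44 * PI - 11.4, schwab = 20)
}

#' Export model geometry as CSV
#'
#' Writes one row per vertebra: level, x (mm), z (mm), theta (deg),
#' body_height (mm).
#' @param model a `spine_model` or `stage_state`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geometry_csv <- function(model, path) {
  poses <- model$poses
  names(poses) <- c("level", "x_mm", "z_mm", "theta_deg", "body_height_mm")
  utils::write.csv(poses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
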