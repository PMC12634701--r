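# Nonlinear constitutive law for each functional spinal unit (FSU) and its
# surgical-state modifiers (rib-cage stiffening, facetectomy, osteotomy
# wedge, fusion).
#
# Flexion/extension moment-rotation: M(theta) = kappa * f * (k0*theta +
# c*sinh(theta/theta_ref)) -- a smooth, odd, monotonically stiffening curve.
# Beyond the physiologic range the curve continues linearly with the
# boundary tangent (extrapolation is flagged with a warning). Shear and
# axial directions are linear springs; the full 6x6 joint reduces to 3x3
# in the sagittal plane.

.fused_k <- 1e6  # N.m/deg: rigid coupling for fused joints

#' Construct an intervertebral joint law
#'
#' @param junction junction label, e.g. `"L4-L5"`.
#' @param k0 neutral-zone flexion stiffness, N.m/degree.
#' @param c stiffening amplitude, N.m.
#' @param theta_ref stiffening reference rotation, degrees.
#' @param kappa rib-cage stiffening multiplier (>= 1; > 1 only for thoracic
#'   junctions).
#' @param shear,axial linear translational stiffnesses, N/mm.
#' @param range physiologic rotation range, degrees; the moment curve is
#'   linearly continued beyond `+-range`.
#' @param rom_lo,rom_hi calibration corridor bounds: rotation (degrees)
#'   expected under a pure 7.5 N.m flexion moment.
#' @return An object of class `joint_law`.
#' @export
joint_law <- function(junction, k0, c, theta_ref, kappa = 1,
                      shear = 260, axial = 1200, range = 15,
                      rom_lo = NA, rom_hi = NA) {
  if (k0 <= 0 || c < 0 || theta_ref <= 0) .stopf("invalid joint curve parameters")
  if (kappa < 1) .stopf("kappa must be >= 1")
  lower <- sub(".*-", "", junction)
  if (kappa > 1 && !grepl("^T", lower))
    .stopf("rib-cage multiplier kappa > 1 is only admissible for thoracic junctions")
  structure(
    list(junction = junction, k0 = k0, c = c, theta_ref = theta_ref,
         kappa = kappa, shear = shear, axial = axial, range = range,
         rom_lo = rom_lo, rom_hi = rom_hi,
         stiffness_factor = 1, rest_angle = 0, state = "intact"),
    class = "joint_law")
}

.base_curve <- function(law, theta) {
  k0 <- law$k0; cc <- law$c; tr <- law$theta_ref; rg <- law$range
  inside <- abs(theta) <= rg
  out <- numeric(length(theta))
  out[inside] <- k0 * theta[inside] + cc * sinh(theta[inside] / tr)
  if (any(!inside)) {
    s <- sign(theta[!inside])
    m_rg <- k0 * rg + cc * sinh(rg / tr)
    k_rg <- k0 + cc / tr * cosh(rg / tr)
    out[!inside] <- s * m_rg + k_rg * (theta[!inside] - s * rg)
  }
  out
}

.base_tangent <- function(law, theta) {
  th <- pmin(pmax(theta, -law$range), law$range)
  law$k0 + law$c / law$theta_ref * cosh(th / law$theta_ref)
}

#' Joint flexion moment at a given rotation
#'
#' Rotation is measured from the joint rest angle (rest-angle handling is
#' the caller's concern; surgical wedges shift the rest angle via
#' [apply_modifier()]). Rotations beyond the physiologic `range` trigger a
#' warning and the curve continues linearly.
#'
#' @param law a [joint_law()].
#' @param theta rotation(s), degrees.
#' @param warn warn on extrapolation beyond the physiologic range.
#' @return Moment(s), N.m.
#' @export
joint_moment <- function(law, theta, warn = TRUE) {
  if (law$state == "fused") return(.fused_k * theta)
  if (warn && any(abs(theta) > law$range))
    warning(sprintf("joint %s rotation beyond physiologic range (+-%g deg); linear extrapolation",
                    law$junction, law$range))
  law$kappa * law$stiffness_factor * .base_curve(law, theta)
}

#' Tangent flexion stiffness of a joint law
#'
#' Derivative of [joint_moment()] with respect to rotation; strictly
#' positive everywhere.
#'
#' @inheritParams joint_moment
#' @return Stiffness(es), N.m/degree.
#' @export
tangent_stiffness <- function(law, theta) {
  if (law$state == "fused") return(rep(.fused_k, length(theta)))
  law$kappa * law$stiffness_factor * .base_tangent(law, theta)
}

#' Surgical joint-state modifiers
#'
#' `facetectomy()` scales the flexion stiffness (default factor 0.5);
#' `pso_wedge()` shifts the joint rest angle by a wedge angle (degrees,
#' positive closes into lordosis) and marks the joint osteotomized;
#' `fusion()` makes the joint rigid.
#'
#' @param factor flexion stiffness multiplier in (0, 1].
#' @param angle wedge angle, degrees.
#' @return A `joint_modifier` object, to be applied with [apply_modifier()].
#' @export
facetectomy <- function(factor = 0.5) {
  if (factor <= 0 || factor > 1) .stopf("facetectomy factor must be in (0, 1]")
  structure(list(kind = "facetectomy", factor = factor), class = "joint_modifier")
}

#' @rdname facetectomy
#' @export
pso_wedge <- function(angle) {
  structure(list(kind = "pso_wedge", angle = angle), class = "joint_modifier")
}

#' @rdname facetectomy
#' @export
fusion <- function() structure(list(kind = "fusion"), class = "joint_modifier")

#' Apply a surgical modifier to a joint law
#'
#' Facetectomy multiplies the flexion stiffness by its factor; a wedge
#' osteotomy shifts the rest angle; fusion couples the joint rigidly.
#' Modifying a fused joint is an error.
#'
#' @param law a [joint_law()].
#' @param mod a modifier from [facetectomy()], [pso_wedge()] or [fusion()].
#' @return The modified `joint_law`.
#' @export
apply_modifier <- function(law, mod) {
  stopifnot(inherits(law, "joint_law"), inherits(mod, "joint_modifier"))
  if (law$state == "fused")
    .stopf("joint %s is fused; no further modification possible", law$junction)
  switch(mod$kind,
    facetectomy = {
      law$stiffness_factor <- law$stiffness_factor * mod$factor
      if (law$state == "intact") law$state <- "facetectomized"
    },
    pso_wedge = {
      # positive wedge closes posteriorly into lordosis: the upper
      # vertebra extends relative to the lower one, so the rest relative
      # angle (theta_upper - theta_lower) increases
      law$rest_angle <- law$rest_angle + mod$angle
      law$state <- "osteotomized"
    },
    fusion = {
      law$state <- "fused"
    },
    .stopf("unknown modifier kind '%s'", mod$kind))
  law
}

#' Default per-junction joint laws
#'
#' Seventeen junction laws (T1-T2 .. L5-S1) read from the packaged corridor
#' table. Thoracic junctions carry a rib-cage stiffening multiplier
#' kappa > 1; thoracolumbar and lumbar junctions have kappa = 1. The
#' corridor parameters are representative of published cadaveric flexion
#' data (a lumbar FSU rotates about 5 degrees under a pure 7.5 N.m flexion
#' moment); absolute outputs that depend on them should be interpreted
#' through rank and ratio comparisons.
#'
#' @return Named list of [joint_law()] objects, one per junction.
#' @export
default_joint_table <- function() {
  path <- system.file("extdata", "joint_laws_default.csv",
                      package = "rodspine", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  laws <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    joint_law(r$junction, k0 = r$k0, c = r$c, theta_ref = r$theta_ref,
              kappa = r$kappa, shear = r$shear, axial = r$axial,
              rom_lo = r$rom_lo, rom_hi = r$rom_hi)
  })
  stats::setNames(laws, tab$junction)
}

#' Joint strain energy
#'
#' Integral of the flexion moment from 0 to `theta` (numeric quadrature);
#' non-negative and convex for the monotone stiffening curve.
#' @inheritParams joint_moment
#' @return Energy, N.m.deg.
#' @export
joint_energy <- function(law, theta) {
  vapply(theta, function(t1) {
    if (t1 == 0) return(0)
    stats::integrate(function(u) joint_moment(law, u, warn = FALSE),
                     0, t1)$value
  }, numeric(1))
}
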