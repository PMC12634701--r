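#' @keywords internal
"_PACKAGE"

# Canonical level ordering, cranial to caudal. The sacrum (S1) is modelled as
# one rigid body with the pelvis, which is fixed in space.
.levels <- c(paste0("T", 1:12), paste0("L", 1:5), "S1")
.junctions <- paste(.levels[-length(.levels)], .levels[-1], sep = "-")

#' Vertebral levels and junction labels
#'
#' `spine_levels()` returns the modelled levels in cranial-to-caudal order
#' (T1..T12, L1..L5, S1). `spine_junctions()` returns the 17 intervertebral
#' junction labels ("T1-T2" .. "L5-S1").
#' @return Character vector.
#' @export
spine_levels <- function() .levels

#' @rdname spine_levels
#' @export
spine_junctions <- function() .junctions

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

# endplate normal (cranial) and tangent (anterior) for an endplate rotated
# theta degrees counter-clockwise (viewed from the patient's left;
# x anterior, z cranial)
.normal <- function(theta_deg) {
  a <- theta_deg * .deg2rad
  c(-sin(a), cos(a))
}
.tangent <- function(theta_deg) {
  a <- theta_deg * .deg2rad
  c(cos(a), sin(a))
}

.rot <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)

# round half away from zero (reported newtons are printed as integers)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.junction_of <- function(upper, lower) paste(upper, lower, sep = "-")
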