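# Published benchmark tables for the five rod scenarios (validated
# patient-specific simulation study, flexion loading): intervertebral
# sagittal moments per junction and bilateral screw force magnitudes per
# level. NA marks junctions/levels across the PSO, which are not reported.
# These serve as fixture inputs to the metrics module.

.scenario_names <- c("constant_6.0", "stepped_6.0_5.0", "bezier_6.0_5.5_5.0",
                     "constant_5.5", "bezier_5.5_5.0_4.75")

#' Benchmark intervertebral moment table
#'
#' Intervertebral sagittal moments (N.m) under 10-degree flexion for the
#' five rod scenarios, per junction from T1-T2 to L5-S1, from the
#' reference simulation study of the default case (UIV = T10, PSO = L3).
#'
#' @return A `moment_table`: data.frame with `junction` plus one column per
#'   scenario; attributes `uiv` and `uiv_plus1` name the annotated rows.
#' @export
reference_moment_table <- function() {
  tab <- data.frame(
    junction = .junctions,
    constant_6.0        = c(8.7, 8.7, 8.8, 8.9, 9.0, 9.0, 9.0, 9.0, 9.0,
                            4.5, 4.3, 5.4, 2.5, NA, NA, 2.6, 10.9),
    stepped_6.0_5.0     = c(8.4, 8.5, 8.5, 8.6, 8.7, 8.7, 8.7, 8.7, 8.7,
                            6.5, 3.4, 5.8, 2.1, NA, NA, 2.6, 10.7),
    bezier_6.0_5.5_5.0  = c(8.1, 8.1, 8.2, 8.3, 8.4, 8.4, 8.4, 8.4, 8.4,
                            6.6, 2.5, 4.0, 2.3, NA, NA, 2.1, 10.7),
    constant_5.5        = c(7.9, 7.9, 8.0, 8.1, 8.1, 8.2, 8.2, 8.2, 8.2,
                            5.5, 4.4, 4.3, 2.1, NA, NA, 3.0, 10.3),
    bezier_5.5_5.0_4.75 = c(7.1, 7.2, 7.2, 7.3, 7.4, 7.5, 7.5, 7.5, 7.5,
                            5.5, 1.6, 3.0, 1.9, NA, NA, 2.4, 9.5),
    stringsAsFactors = FALSE, check.names = FALSE)
  as_moment_table(tab, uiv_junction = "T10-T11")
}

#' Benchmark screw force table
#'
#' Left/right pedicle screw force magnitudes (N) under 10-degree flexion
#' for the five rod scenarios, per instrumented level (no screws at the
#' PSO level).
#'
#' @return A `screw_table`: data.frame with `level` plus `<scenario>.left`
#'   and `<scenario>.right` columns; attribute `uiv`.
#' @export
reference_screw_table <- function() {
  lv <- c("T10", "T11", "T12", "L1", "L2", "L3", "L4", "L5", "S1")
  vals <- list(
    constant_6.0        = list(left = c(359, 145, 206, 183, 238, NA, 181, 1354, 1111),
                               right = c(628, 233, 574, 180, 120, NA, 148, 965, 918)),
    stepped_6.0_5.0     = list(left = c(292, 152, 220, 423, 340, NA, 170, 1283, 1053),
                               right = c(485, 167, 613, 251, 213, NA, 145, 930, 890)),
    bezier_6.0_5.5_5.0  = list(left = c(278, 131, 208, 193, 216, NA, 156, 1202, 1004),
                               right = c(446, 151, 620, 232, 147, NA, 221, 1084, 964)),
    constant_5.5        = list(left = c(232, 231, 442, 109, 203, NA, 151, 1112, 918),
                               right = c(430, 214, 522, 145, 93, NA, 114, 772, 752)),
    bezier_5.5_5.0_4.75 = list(left = c(211, 162, 193, 180, 206, NA, 160, 1061, 867),
                               right = c(330, 190, 530, 243, 156, NA, 131, 763, 719)))
  tab <- data.frame(level = lv, stringsAsFactors = FALSE)
  for (sc in names(vals)) {
    tab[[paste0(sc, ".left")]] <- vals[[sc]]$left
    tab[[paste0(sc, ".right")]] <- vals[[sc]]$right
  }
  as_screw_table(tab, uiv = "T10")
}
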