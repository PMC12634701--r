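# Outcome metrics: intervertebral moment tables, screw force tables,
# range-of-motion summaries, offloading percentages and load-transition
# smoothness, computed from protocol stage states or from externally
# supplied (benchmark) tables.

#' Moment and screw tables
#'
#' `as_moment_table()` tags a data.frame (column `junction` plus one numeric
#' column per scenario, N.m) with UIV annotations. `as_screw_table()` tags
#' a per-level table with `<scenario>.left` / `<scenario>.right` force
#' columns (N). Reported newtons are rounded half-away-from-zero to
#' integers.
#'
#' @param x data.frame as described.
#' @param uiv_junction the UIV junction label (row immediately below is the
#'   first instrumented junction; the row above is UIV+1).
#' @param uiv the upper instrumented vertebra.
#' @return The annotated table.
#' @export
as_moment_table <- function(x, uiv_junction) {
  stopifnot("junction" %in% names(x))
  i <- match(uiv_junction, x$junction)
  if (is.na(i) || i < 2) .stopf("UIV junction not found (or has no row above)")
  structure(x, uiv = uiv_junction, uiv_plus1 = x$junction[i - 1],
            class = c("moment_table", "data.frame"))
}

#' @rdname as_moment_table
#' @export
as_screw_table <- function(x, uiv) {
  stopifnot("level" %in% names(x))
  if (!uiv %in% x$level) .stopf("UIV level not found")
  structure(x, uiv = uiv, class = c("screw_table", "data.frame"))
}

.scenarios_of <- function(table) {
  if (inherits(table, "moment_table")) setdiff(names(table), "junction")
  else unique(sub("\\.(left|right)$", "",
                  setdiff(names(table), "level")))
}

#' Intervertebral moment table from protocol runs
#'
#' One column per scenario: the magnitude of the sagittal moment carried by
#' each functional spinal unit in the flexed stage. Junctions across the
#' PSO are reported but flagged for exclusion from comparative metrics
#' (attribute `excluded`).
#'
#' @param runs named list of [run_protocol()] results (names = scenarios).
#' @param stage stage to read (default `"flexed"`).
#' @return A `moment_table`.
#' @export
moment_table <- function(runs, stage = "flexed") {
  stopifnot(length(runs) >= 1)
  out <- data.frame(junction = .junctions, stringsAsFactors = FALSE)
  for (nm in names(runs)) {
    st <- runs[[nm]]$stages[[stage]]
    if (is.null(st)) .stopf("stage '%s' missing for scenario %s", stage, nm)
    out[[nm]] <- abs(st$joints$moment)[match(.junctions, st$joints$junction)]
  }
  plan <- runs[[1]]$plan
  uivj <- .junctions[match(plan$uiv, .levels)]
  tab <- as_moment_table(out, uiv_junction = uivj)
  attr(tab, "excluded") <- plan$pso_junctions
  tab
}

#' Screw force table from protocol runs
#'
#' The sagittal model lumps the bilateral screw pair into one tie; the
#' per-screw force is half the tie force magnitude, reported identically
#' left and right.
#'
#' @inheritParams moment_table
#' @return A `screw_table`.
#' @export
screw_force_table <- function(runs, stage = "flexed") {
  plan <- runs[[1]]$plan
  lv <- plan$instrumented
  out <- data.frame(level = lv, stringsAsFactors = FALSE)
  for (nm in names(runs)) {
    st <- runs[[nm]]$stages[[stage]]
    f <- st$screws$force[match(lv, st$screws$level)] / 2
    out[[paste0(nm, ".left")]] <- f
    out[[paste0(nm, ".right")]] <- f
  }
  as_screw_table(out, uiv = plan$uiv)
}

#' Moment at the first junction above the instrumentation (UIV+1)
#'
#' @param table a `moment_table`.
#' @param scenario scenario column name.
#' @return Moment, N.m.
#' @export
uiv_plus1_moment <- function(table, scenario) {
  if (!scenario %in% names(table)) .stopf("unknown scenario '%s'", scenario)
  v <- table[[scenario]][match(attr(table, "uiv_plus1"), table$junction)]
  if (is.na(v)) .stopf("UIV+1 moment is NA for scenario '%s'", scenario)
  v
}

#' Percent reduction relative to a reference
#'
#' `100 * (reference - value) / reference`; the reference must be positive.
#'
#' @param reference reference (stiffest-construct) value.
#' @param value compared value.
#' @return Percent reduction (negative if `value > reference`).
#' @export
percent_reduction <- function(reference, value) {
  if (any(reference <= 0)) .stopf("reference must be > 0")
  100 * (reference - value) / reference
}

#' Mean construct force for a scenario
#'
#' Arithmetic mean of all non-NA left and right screw force magnitudes,
#' rounded half-away-from-zero to integer newtons.
#'
#' @param table a `screw_table`.
#' @param scenario scenario name.
#' @return Mean construct force, N (integer).
#' @export
mean_construct_force <- function(table, scenario) {
  cols <- paste0(scenario, c(".left", ".right"))
  if (!all(cols %in% names(table))) .stopf("unknown scenario '%s'", scenario)
  v <- unlist(table[cols], use.names = FALSE)
  if (all(is.na(v))) .stopf("all screw forces are NA for '%s'", scenario)
  .round_half_away(mean(v, na.rm = TRUE))
}

#' Screw force at the upper instrumented vertebra
#'
#' Mean of the left and right screw force magnitudes at the UIV, rounded
#' half-away-from-zero to integer newtons.
#'
#' @inheritParams mean_construct_force
#' @param uiv level (defaults to the table's annotation).
#' @return Force, N (integer).
#' @export
uiv_screw_force <- function(table, scenario, uiv = attr(table, "uiv")) {
  cols <- paste0(scenario, c(".left", ".right"))
  if (!all(cols %in% names(table))) .stopf("unknown scenario '%s'", scenario)
  i <- match(uiv, table$level)
  if (is.na(i)) .stopf("level %s not in table", uiv)
  v <- c(table[[cols[1]]][i], table[[cols[2]]][i])
  if (anyNA(v)) .stopf("UIV screw force is NA for '%s'", scenario)
  .round_half_away(mean(v))
}

#' Per-junction range of motion between two stages
#'
#' Absolute change in inter-vertebral relative rotation between the
#' standing and flexed solutions, degrees.
#'
#' @param run a [run_protocol()] result.
#' @param from,to stage names.
#' @return data.frame: junction, rom (degrees), instrumented flag.
#' @export
rom_summary <- function(run, from = "postop_standing", to = "flexed") {
  a <- run$stages[[from]]$joints
  b <- run$stages[[to]]$joints
  stopifnot(!is.null(a), !is.null(b))
  rom <- abs(b$rotation[match(.junctions, b$junction)] -
             a$rotation[match(.junctions, a$junction)])
  plan <- run$plan
  span <- .junctions[match(plan$uiv, .levels):(match(plan$liv, .levels) - 1)]
  data.frame(junction = .junctions, rom = rom,
             instrumented = .junctions %in% span,
             stringsAsFactors = FALSE)
}

#' Load-transition smoothness at the proximal junction
#'
#' Operationalizes "smoother load transition" as the maximum absolute
#' moment difference between adjacent junction rows from UIV+1 down to
#' UIV-2 (four rows, three differences; NA rows are skipped). Lower is
#' smoother; a constant column scores 0.
#'
#' @param table a `moment_table`.
#' @param scenario scenario name.
#' @return Smoothness score, N.m (non-negative).
#' @export
transition_smoothness <- function(table, scenario) {
  if (!scenario %in% names(table)) .stopf("unknown scenario '%s'", scenario)
  i1 <- match(attr(table, "uiv_plus1"), table$junction)
  rows <- i1:min(i1 + 3, nrow(table))
  v <- table[[scenario]][rows]
  v <- v[!is.na(v)]
  if (length(v) < 2) return(0)
  max(abs(diff(v)))
}

#' Comparison summary across scenarios
#'
#' Per scenario: UIV+1 moment, UIV screw force, mean construct force,
#' transition smoothness, and percent reductions relative to a reference
#' scenario (default the constant 6.0 mm rod, the stiffest construct).
#'
#' @param mtab a `moment_table`.
#' @param stab a `screw_table`.
#' @param reference reference scenario name.
#' @return data.frame, one row per scenario.
#' @export
comparison_summary <- function(mtab, stab, reference = "constant_6.0") {
  sc <- .scenarios_of(mtab)
  if (!reference %in% sc) .stopf("reference scenario '%s' absent", reference)
  m1 <- vapply(sc, uiv_plus1_moment, numeric(1), table = mtab)
  fu <- vapply(sc, uiv_screw_force, numeric(1), table = stab)
  fm <- vapply(sc, mean_construct_force, numeric(1), table = stab)
  sm <- vapply(sc, transition_smoothness, numeric(1), table = mtab)
  data.frame(
    scenario = sc,
    uiv_plus1_moment = m1,
    uiv_screw_force = fu,
    mean_construct_force = fm,
    transition_smoothness = sm,
    moment_reduction_pct = percent_reduction(m1[[reference]], m1),
    uiv_screw_reduction_pct = percent_reduction(fu[[reference]], fu),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Peak outer-fiber rod stress near a junction
#'
#' Largest outer-fiber stress magnitude among rod elements whose midpoint
#' lies within one inter-screw segment of the named junction's arc
#' position.
#'
#' @param run a [run_protocol()] result.
#' @param junction junction label (must be an inter-screw landmark).
#' @param stage stage to read.
#' @return Stress, MPa.
#' @export
peak_rod_stress_near <- function(run, junction, stage = "postop_standing") {
  st <- run$stages[[stage]]
  lm <- run$assembly$rod$contour$landmarks
  if (!junction %in% names(lm)) .stopf("junction %s is not a rod landmark", junction)
  s0 <- lm[[junction]]
  # one inter-screw segment on either side
  seglen <- mean(diff(sort(unname(lm[names(lm) != "end"]))))
  sel <- abs(st$rod$s - s0) <= seglen
  max(st$rod$sigma_outer[sel])
}

#' Write/read a metrics table as CSV
#'
#' Scenario names form the header; units are embedded in the file via a
#' `# units:` comment line.
#' @param table a `moment_table` or `screw_table`.
#' @param path file path.
#' @return `path` invisibly (write); the annotated table (read).
#' @export
write_table_csv <- function(table, path) {
  units <- if (inherits(table, "moment_table")) "N.m" else "N"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s; uiv: %s", units,
                     attr(table, "uiv")), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_table_csv
#' @param kind `"moment"` or `"screw"`.
#' @param uiv UIV annotation (junction label for moment tables, level for
#'   screw tables).
#' @export
read_table_csv <- function(path, kind = c("moment", "screw"), uiv = NULL) {
  kind <- match.arg(kind)
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1 else 0
  if (is.null(uiv) && skip == 1)
    uiv <- sub(".*uiv: *", "", first)
  x <- utils::read.csv(path, skip = skip, stringsAsFactors = FALSE,
                       check.names = FALSE)
  if (kind == "moment") as_moment_table(x, uiv_junction = uiv)
  else as_screw_table(x, uiv = uiv)
}
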