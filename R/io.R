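# Configuration, fixture generation and result serialization.
# All physical quantities are serialized in N, mm, N.m, degrees and kg.

.config_defaults <- function() {
  list(
    patient = list(PI = 60, PT = 49, TK = 50, LL = -12,
                   lumbar_cobb_coronal = 3, body_mass = 60),
    plan = list(uiv = "T10", liv = "S1", pso_level = "L3",
                facetectomy_factor = 0.5, pso_wedge_cap = 35,
                target_LL = 48, target_TK = 36.5, flexion_angle = 10,
                head_offset = 45),
    solver = list(load_steps = 10, tol = 1e-6, max_iter = 50,
                  elements_per_segment = 8, n_fibers = 32),
    seed = 1,
    output_dir = "results")
}

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration (patient descriptor, surgical plan,
#' solver settings, seed, output directory), fills defaults for missing
#' keys and rejects unknown ones. An empty file yields the defaults-only
#' configuration. The packaged default case is at
#' `system.file("extdata", "case_default.yaml", package = "rodspine")`.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return List of class `run_config` with elements `profile`
#'   ([sagittal_profile()]), `plan` ([surgical_plan()]), `settings`
#'   ([solve_settings()]), `seed`, `output_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defs <- .config_defaults()
  bad <- setdiff(names(raw), names(defs))
  if (length(bad))
    .stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  for (grp in c("patient", "plan", "solver")) {
    sub <- raw[[grp]]
    if (is.null(sub)) next
    badk <- setdiff(names(sub), names(defs[[grp]]))
    if (length(badk))
      .stopf("unknown keys in '%s': %s", grp, paste(badk, collapse = ", "))
    defs[[grp]][names(sub)] <- sub
  }
  if (!is.null(raw$seed)) defs$seed <- raw$seed
  if (!is.null(raw$output_dir)) defs$output_dir <- raw$output_dir
  p <- defs$patient
  profile <- sagittal_profile(PI = p$PI, PT = p$PT, TK = p$TK, LL = p$LL,
                              lumbar_cobb_coronal = p$lumbar_cobb_coronal,
                              body_mass = p$body_mass)
  pl <- defs$plan
  plan <- surgical_plan(uiv = pl$uiv, liv = pl$liv,
                        pso_level = pl$pso_level,
                        facetectomy_factor = pl$facetectomy_factor,
                        pso_wedge_cap = pl$pso_wedge_cap,
                        target_LL = pl$target_LL, target_TK = pl$target_TK,
                        flexion_angle = pl$flexion_angle,
                        head_offset = pl$head_offset)
  sv <- defs$solver
  settings <- solve_settings(load_steps = sv$load_steps, tol = sv$tol,
                             max_iter = sv$max_iter,
                             elements_per_segment = sv$elements_per_segment,
                             n_fibers = sv$n_fibers)
  structure(list(profile = profile, plan = plan, settings = settings,
                 seed = defs$seed, output_dir = defs$output_dir),
            class = "run_config")
}

#' Write fixture files
#'
#' Writes the benchmark moment and screw-force tables and the default case
#' configuration to `outdir`: `reference_flexion_moments.csv`,
#' `reference_screw_forces.csv`, `case_default.yaml`. Re-running produces
#' byte-identical files.
#'
#' @param outdir writable directory (created if needed).
#' @return Character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(outdir, "reference_flexion_moments.csv")
  p2 <- file.path(outdir, "reference_screw_forces.csv")
  p3 <- file.path(outdir, "case_default.yaml")
  write_table_csv(reference_moment_table(), p1)
  write_table_csv(reference_screw_table(), p2)
  file.copy(system.file("extdata", "case_default.yaml",
                        package = "rodspine", mustWork = TRUE),
            p3, overwrite = TRUE)
  invisible(c(p1, p2, p3))
}

#' Run the staged protocol for a set of scenarios
#'
#' Convenience wrapper: builds the spine and joint set from a
#' configuration and runs [run_protocol()] per scenario.
#'
#' @param config a [load_config()] result (or path to a config file).
#' @param scenarios scenario names (subset of `names(rod_scenarios())`) or
#'   `"all"`.
#' @param quiet suppress progress messages.
#' @return Named list of [run_protocol()] results.
#' @export
simulate_case <- function(config, scenarios = "all", quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  all_sc <- rod_scenarios()
  if (identical(scenarios, "all")) scenarios <- names(all_sc)
  unknown <- setdiff(scenarios, names(all_sc))
  if (length(unknown))
    .stopf("unknown scenario(s) %s; valid names: %s",
           paste(unknown, collapse = ", "),
           paste(names(all_sc), collapse = ", "))
  model <- build_spine(config$profile)
  joints <- default_joint_table()
  out <- list()
  for (nm in scenarios) {
    if (!quiet) message("scenario ", nm)
    out[[nm]] <- run_protocol(model, joints, all_sc[[nm]],
                              plan = config$plan,
                              settings = config$settings)
  }
  out
}

#' Write protocol results to CSV
#'
#' Per scenario: stage profiles and, for the flexed stage, joint moments,
#' screw forces and the rod stress profile; plus a combined comparison
#' summary and a JSON manifest (scenarios, seed, package version).
#'
#' @param runs named list of [run_protocol()] results.
#' @param outdir output directory.
#' @param seed seed recorded in the manifest.
#' @return `outdir`, invisibly.
#' @export
write_results <- function(runs, outdir, seed = NA) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(runs)) {
    run <- runs[[nm]]
    prof <- do.call(rbind, lapply(run$stages, function(s)
      data.frame(stage = s$stage, TK_deg = s$profile$TK,
                 LL_deg = s$profile$LL, PI_deg = s$profile$PI,
                 PT_deg = s$profile$PT)))
    utils::write.csv(prof, file.path(outdir, paste0(nm, "_stages.csv")),
                     row.names = FALSE)
    fx <- run$stages$flexed
    utils::write.csv(fx$joints,
                     file.path(outdir, paste0(nm, "_joint_moments_Nm.csv")),
                     row.names = FALSE)
    utils::write.csv(fx$screws,
                     file.path(outdir, paste0(nm, "_screw_forces_N.csv")),
                     row.names = FALSE)
    utils::write.csv(fx$rod,
                     file.path(outdir, paste0(nm, "_rod_stress_MPa.csv")),
                     row.names = FALSE)
  }
  mtab <- moment_table(runs)
  stab <- screw_force_table(runs)
  write_table_csv(mtab, file.path(outdir, "flexion_moments.csv"))
  write_table_csv(stab, file.path(outdir, "screw_forces.csv"))
  ref <- if ("constant_6.0" %in% names(runs)) "constant_6.0" else names(runs)[1]
  utils::write.csv(comparison_summary(mtab, stab, reference = ref),
                   file.path(outdir, "comparison_summary.csv"),
                   row.names = FALSE)
  manifest <- list(scenarios = names(runs), seed = seed,
                   package = "rodspine",
                   version = as.character(utils::packageVersion("rodspine")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
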