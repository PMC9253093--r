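#' Validate a pipeline run configuration
#'
#' @param config list (or path to a JSON file) with fields: `out_dir`
#'   (required), `seed`, `stages` (subset of the stage names, default all),
#'   `morphotypes`, `n_linear`, `n_yaw`, `duration`, `conch_step_deg`,
#'   `densities` (named overrides for [density_table()]), `trial_dir`
#'   (existing trials to analyze instead of fresh fixtures).
#' @return The validated config with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$out_dir)) stop("config field 'out_dir' is required")
  defaults <- list(seed = 1L, stages = pipeline_stages(),
                   morphotypes = names(morphotype_params()),
                   n_linear = 9L, n_yaw = 15L, duration = 12,
                   conch_step_deg = 3, densities = list(),
                   trial_dir = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  bad <- setdiff(config$stages, pipeline_stages())
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(config$morphotypes, names(morphotype_params()))
  if (length(bad)) stop("unknown morphotype(s): ", paste(bad, collapse = ", "))
  if (!is.null(config$trial_dir) && !dir.exists(config$trial_dir))
    stop("trial_dir does not exist: ", config$trial_dir)
  config
}

#' @rdname validate_run_config
#' @export
pipeline_stages <- function() {
  c("make-fixtures", "generate-conch", "hydrostatics", "design-robot",
    "analyze-trials", "fit-drag", "stats", "report")
}

#' Run the analysis pipeline end-to-end
#'
#' Executes the requested stages in order: simulate fixture trials, generate
#' the demonstration conchs and their morphospace placements, solve their
#' hydrostatics (scaled to the ~1 kg robot displaced mass), solve the
#' demonstration robot mass budget, extract kinematics from every trial,
#' fit coasting drag coefficients, run the group statistics, and write an
#' aggregate report. All outputs are files under `out_dir`; a manifest
#' records the package version, seeds and per-file digests.
#'
#' @param config see [validate_run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "conchydro",
                   version = as.character(utils::packageVersion("conchydro")),
                   seed = config$seed, stages = list())
  wr <- function(x, rel) {
    path <- file.path(config$out_dir, rel)
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
    path
  }
  finish_stage <- function(name, files) {
    manifest$stages[[name]] <<- list(
      files = as.list(stats::setNames(
        as.character(tools::md5sum(files)), basename(files))))
    write_manifest()
  }
  write_manifest <- function()
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    ok <- tryCatch({
      fn()
      TRUE
    }, error = function(e) {
      manifest$stages[[name]] <<- list(error = conditionMessage(e))
      write_manifest()
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    invisible(ok)
  }
  dens <- do.call(density_table, config$densities)
  trial_dir <- config$trial_dir

  run_stage("make-fixtures", function() {
    fdir <- file.path(config$out_dir, "fixtures")
    make_fixture_suite(fdir, seed = config$seed,
                       n_linear = config$n_linear, n_yaw = config$n_yaw,
                       morphotypes = config$morphotypes,
                       duration = config$duration)
    if (is.null(trial_dir)) trial_dir <<- fdir
    finish_stage("make-fixtures", file.path(fdir, "manifest.json"))
  })

  specs <- demo_conch_specs(step_deg = config$conch_step_deg)
  models <- NULL
  run_stage("generate-conch", function() {
    models <<- lapply(specs, conch_model)
    files <- character(0)
    for (nm in names(models)) {
      p <- file.path(config$out_dir, paste0("conch_", nm, ".obj"))
      write_mesh(models[[nm]]$water_displaced, p)
      files <- c(files, p)
    }
    morpho <- lapply(specs, function(s) {
      ms <- conch_measurements(s)
      as.list(westermann_coordinates(ms$D, ms$U, ms$ah, ms$ab, W = ms$W))
    })
    files <- c(files, wr(morpho, "morphospace.json"))
    finish_stage("generate-conch", files)
  })

  hydro <- NULL
  run_stage("hydrostatics", function() {
    if (is.null(models)) models <<- lapply(specs, conch_model)
    hydro <<- lapply(models, function(m) {
      sc <- scale_to_displaced_mass(m, 982, dens)
      h <- hydrostatics(sc$model, dens)
      c(h[c("phi", "liquid_fraction", "attainable", "St",
            "apertural_angle", "thrust_angle", "total_mass",
            "displaced_mass")],
        list(B = h$B, M = h$M, scale_factor = sc$factor,
             note = "phi is the gas fraction as the fill formula evaluates; liquid_fraction = 1 - phi"))
    })
    finish_stage("hydrostatics", wr(hydro, "hydrostatics.json"))
  })

  run_stage("design-robot", function() {
    bud <- solve_mass_budget(demo_mass_budget())
    out <- list(displaced_mass = bud$displaced_mass,
                target_M = bud$target_M,
                petg_mass = budget_component(bud, "PETG")$mass,
                petg_center = budget_component(bud, "PETG")$center,
                recomputed_center = budget_center(bud),
                components = lapply(bud$components, unclass))
    finish_stage("design-robot", wr(out, "robot_budget.json"))
  })

  kin <- NULL
  run_stage("analyze-trials", function() {
    if (is.null(trial_dir))
      stop("no trials: run make-fixtures or set trial_dir")
    kin <<- analyze_trial_dir(trial_dir)
    finish_stage("analyze-trials", wr(kin, "kinematics.json"))
  })

  run_stage("fit-drag", function() {
    if (is.null(trial_dir))
      stop("no trials: run make-fixtures or set trial_dir")
    params <- morphotype_params()
    files <- list.files(trial_dir, pattern = "_linear_.*\\.csv$",
                        full.names = TRUE)
    fits <- lapply(files, function(f) {
      nm <- sub("_linear.*", "", basename(f))
      p <- params[[nm]]
      fit <- tryCatch(
        fit_drag_coefficient(read_trial(f), frontal_area = p$frontal_area,
                             effective_mass = p$mass *
                               (1 + p$added_mass_coefficient),
                             fluid_density = p$fluid_density),
        error = function(e) list(error = conditionMessage(e)))
      c(list(trial = basename(f), morphotype = nm),
        fit[intersect(names(fit), c("Cd", "k", "v0", "r_squared", "n",
                                    "convention", "error"))])
    })
    finish_stage("fit-drag", wr(fits, "drag_fits.json"))
  })

  run_stage("stats", function() {
    if (is.null(kin)) stop("stats stage needs analyze-trials results")
    out <- list()
    lin <- kin$linear
    if (length(unique(lin$morphotype)) >= 2) {
      gh <- welch_anova_games_howell(lin$peak_velocity, lin$morphotype)
      out$peak_velocity <- list(anova = gh$anova, pairwise = gh$pairwise)
    }
    yaw <- kin$yaw
    if (length(unique(yaw$morphotype)) >= 2) {
      gh <- welch_anova_games_howell(yaw$peak_omega, yaw$morphotype)
      out$peak_omega <- list(anova = gh$anova, pairwise = gh$pairwise)
    }
    finish_stage("stats", wr(out, "stats.json"))
  })

  run_stage("report", function() {
    report <- list(
      note = paste("speeds reported in cm/s and accelerations in cm/s^2;",
                   "chamber fill quoted as liquid fraction"),
      kinematics_summary = if (!is.null(kin)) {
        lin <- kin$linear
        lapply(split(lin, lin$morphotype), function(d) list(
          n = nrow(d),
          mean_accel_cm_s2 = mean(d$accel_cm_s2),
          mean_peak_velocity_cm_s = mean(d$peak_velocity) * 100,
          mean_coasting_distance_cm = mean(d$coasting_distance) * 100,
          mean_duration_s = mean(d$duration)))
      },
      yaw_summary = if (!is.null(kin)) {
        lapply(split(kin$yaw, kin$yaw$morphotype), function(d) list(
          n = nrow(d),
          mean_peak_omega_deg_s = mean(d$peak_omega),
          mean_revolutions = mean(d$revolutions)))
      },
      hydrostatics = hydro)
    finish_stage("report", wr(report, "report.json"))
  })

  write_manifest()
  invisible(manifest)
}

#' Analyze every trial CSV in a directory
#'
#' @param dir directory of trial CSVs named `<morphotype>_<kind>_<nn>.csv`.
#' @return List of two data.frames, `linear` and `yaw`, one row per trial.
#' @export
analyze_trial_dir <- function(dir) {
  lin_files <- list.files(dir, pattern = "_linear_.*\\.csv$",
                          full.names = TRUE)
  yaw_files <- list.files(dir, pattern = "_yaw_.*\\.csv$", full.names = TRUE)
  lin <- do.call(rbind, lapply(lin_files, function(f) {
    tr <- read_trial(f)
    s <- trial_summary(tr)
    acc <- fit_acceleration(tr)
    data.frame(trial = basename(f),
               morphotype = sub("_linear.*", "", basename(f)),
               peak_velocity = s$peak_velocity,
               coasting_distance = s$coasting_distance,
               duration = s$duration,
               accel_cm_s2 = acc$slope_cm_s2,
               accel_r2 = acc$r_squared)
  }))
  yaw <- do.call(rbind, lapply(yaw_files, function(f) {
    tr <- read_trial(f)
    y <- yaw_series(tr)
    data.frame(trial = basename(f),
               morphotype = sub("_yaw.*", "", basename(f)),
               net_angle = y$net_angle[length(y$net_angle)],
               revolutions = y$revolutions,
               peak_omega = y$peak_omega)
  }))
  list(linear = lin, yaw = yaw)
}
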