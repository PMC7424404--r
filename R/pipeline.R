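#' Study configuration
#'
#' Bundles every knob of the synthetic SAC study: cohort sizes (default 18
#' patients with the first 9 forming the calibration subset, as in the
#' retrospective cohort), the generating growth law and ground-truth material
#' model, measurement noise, the baseline (literature) material model, the
#' DoE parameter box, spring catalog, time points and seeds.
#'
#' @param seed master seed; all stage seeds are derived from it
#' @param n_cohort cohort size
#' @param n_calibration size of the calibration subset (first patients)
#' @param growth_n size of the unoperated growth cohort
#' @param truth ground-truth [material_model()] of the generator
#' @param growth generating \code{growth_model}
#' @param baseline literature [material_model()] used for the first batch
#' @param box [parameter_box()] for the DoE
#' @param noise [noise_spec()]
#' @param catalog spring catalog
#' @param times opening time points (days; insertion, FU1, FU2)
#' @param nominal nominal maximum spring opening (mm)
#' @param angular_resolution patient mesh resolution
#' @param n_substeps viscoelastic integration substeps
#' @param n_distance_samples surface-distance sample count for the rescaling
#'   validation
#' @param ci_band_frac cranial-index measurement plane height as a fraction
#'   of head height (the biparietal width is read above this plane, clear of
#'   the constrained model base)
#' @param out_dir optional output directory for CSV/JSON artifacts
#' @return list of class \code{study_config}
#' @export
study_config <- function(seed = 1L, n_cohort = 18L, n_calibration = 9L,
                         growth_n = 24L, truth = truth_materials(),
                         growth = default_growth_model(),
                         baseline = literature_materials(),
                         box = parameter_box(), noise = noise_spec(),
                         catalog = spring_catalog(), times = c(0, 1, 28),
                         nominal = 60, angular_resolution = 28L,
                         n_substeps = 60L, n_distance_samples = 4000L,
                         ci_band_frac = 0.4, out_dir = NULL) {
  if (n_calibration > n_cohort) stop("calibration subset cannot exceed the cohort")
  cfg <- as.list(environment())
  class(cfg) <- "study_config"
  cfg
}

#' Read a study configuration from YAML
#'
#' Scalar fields override the defaults of [study_config()]; material models
#' and the parameter box can be given as nested maps (e.g.
#' \code{truth: {E_B: 600, E_s: 20, alpha_tau: 10, alpha_G: 1.1}}).
#'
#' @param path YAML file
#' @return a \code{study_config}
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("seed", "n_cohort", "n_calibration", "growth_n", "times",
              "nominal", "angular_resolution", "n_substeps",
              "n_distance_samples", "ci_band_frac", "out_dir")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  for (f in c("truth", "baseline")) {
    if (!is.null(y[[f]])) args[[f]] <- do.call(material_model, y[[f]])
  }
  if (!is.null(y$growth)) args$growth <- growth_model(y$growth$a, y$growth$b)
  if (!is.null(y$noise)) args$noise <- do.call(noise_spec, y$noise)
  do.call(study_config, args)
}

.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 97 + k * 1009) %% 2147483647)
}

.stage <- function(name, expr, verbose = TRUE) {
  if (verbose) message(sprintf("[%s] %s ...", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Cranial index of a head mesh in the measurement band
#'
#' Reads OFD/BPD above a measurement plane placed at a fraction of the head
#' height, so that the biparietal width is measured on the free parietal
#' wall rather than on the constrained base ring of the model.
#'
#' @param mesh a calvarium [tet_mesh()] (possibly deformed)
#' @param band_frac measurement plane height / head height
#' @return CI in percent
#' @export
head_ci <- function(mesh, band_frac = 0.4) {
  surf <- mesh_surface(mesh)
  cranial_index(surf, base_z = band_frac * max(surf$vertices[, 3]))$CI_pct
}

#' Calibrate the material model of one patient
#'
#' Runs the face-centered CCD forward simulations on the patient's model,
#' fits one quadratic response surface per normalized opening (insertion,
#' FU1, FU2) and optimizes the four material parameters against the
#' patient's measured openings.
#'
#' @param fm the patient's [fem_model()] (operated, rescaled mesh)
#' @param springs springs list (see [patient_springs()])
#' @param measured measured [opening_timeline()] of the patient
#' @param box [parameter_box()]
#' @param template [material_model()] supplying the fixed structural
#'   settings (Poisson ratios, Prony series)
#' @param nominal nominal opening (mm)
#' @param n_substeps integration substeps
#' @param seed optimizer multi-start seed
#' @return list with \code{optimum} (\code{optimized_material}),
#'   \code{surfaces}, \code{design}, \code{responses} (percent openings)
#' @export
calibrate_patient <- function(fm, springs, measured, box = parameter_box(),
                              template = material_model(), nominal = 60,
                              n_substeps = 60L, seed = 1L) {
  design <- ccd_design(box)
  times <- measured$times
  responses <- t(vapply(seq_len(nrow(design)), function(i) {
    mats <- materials_from_params(unlist(design[i, ]), template)
    fw <- forward_openings(fm, mats, springs, times = times,
                           nominal = nominal, n_substeps = n_substeps)
    normalize_opening(fw$timeline$mm, nominal)
  }, numeric(length(times))))
  colnames(responses) <- c("OP_IO", "OP_FU1", "OP_FU2")[seq_len(ncol(responses))]
  surfaces <- fit_response_surface(design, responses, box)
  targets <- normalize_opening(measured$mm, nominal)
  evaluate <- function(par) {
    mats <- materials_from_params(par, template)
    fw <- forward_openings(fm, mats, springs, times = times,
                           nominal = nominal, n_substeps = n_substeps)
    normalize_opening(fw$timeline$mm, nominal)
  }
  optimum <- optimize_materials(surfaces, targets, box, seed = seed,
                                evaluate = evaluate)
  list(optimum = optimum, surfaces = surfaces, design = design,
       responses = responses)
}

#' Run the full synthetic SAC study
#'
#' Executes the whole workflow: growth-cohort generation and growth-curve
#' fit; synthetic patient cohort with measured openings; per-patient
#' CT-to-surgery rescaling (validated by surface RMSE against the true
#' at-surgery anatomy); first simulation batch with literature materials;
#' DoE + response-surface calibration on the calibration subset (which never
#' sees the held-out patients' measurements); population averaging;
#' re-simulation of all patients with the optimized material model; and
#' prediction-error / cranial-index reporting.
#'
#' @param config a [study_config()]
#' @param cohort optionally, a pregenerated cohort (must match
#'   \code{config$n_cohort}); by default the cohort is generated from the
#'   config seed
#' @param verbose print stage progress
#' @return a \code{sac_study} report: see the elements \code{growth_fit},
#'   \code{population} (optimized material parameters, mean and SD),
#'   \code{sensitivity} (mean local sensitivities, outputs x factors),
#'   \code{errors} (per-time summaries for baseline and optimized models),
#'   \code{ci} (cohort cranial-index trajectory), \code{rescaling}
#'   (RMSE with and without growth rescaling)
#' @export
run_study <- function(config = study_config(), cohort = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  times <- config$times
  tmpl <- config$baseline

  growth_points <- .stage("growth cohort", generate_growth_points(
    config$growth_n, config$growth, config$noise$volume_sd_mm3,
    seed = .derive_seed(config$seed, 1)), verbose)
  growth_fit <- fit_growth_curve(growth_points)

  if (is.null(cohort)) {
    cohort <- .stage("patient cohort", generate_cohort(
      config$n_cohort, config$growth, config$truth, config$noise,
      seed = .derive_seed(config$seed, 2), catalog = config$catalog,
      times = times, angular_resolution = config$angular_resolution,
      n_substeps = config$n_substeps), verbose)
  }
  if (length(cohort) != config$n_cohort) stop("cohort size does not match config")
  for (r in cohort) {
    if (!all(r$spring_models %in% names(config$catalog))) {
      stop("cohort references spring models missing from the catalog")
    }
  }
  n <- length(cohort)
  calib_idx <- seq_len(config$n_calibration)

  patients <- .stage("geometry + rescaling", lapply(seq_len(n), function(i) {
    rec <- cohort[[i]]
    mesh_CT <- patient_mesh(rec, rec$V_CT_mm3)
    V_hat <- rescale_volume(growth_fit, rec$V_CT_mm3, rec$age_CT_months,
                            rec$age_SAC_months)
    mesh_hat <- rescale_mesh(mesh_CT, rec$V_CT_mm3, V_hat)
    operated <- apply_surgery(mesh_hat, rec$plan)
    list(rec = rec, mesh_CT = mesh_CT, mesh_hat = mesh_hat,
         operated = operated, V_hat = V_hat,
         fm = fem_model(operated, tmpl$nu_B, tmpl$nu_s),
         springs = patient_springs(rec, config$catalog))
  }), verbose)

  rescaling <- .stage("rescaling validation", {
    rows <- lapply(patients[calib_idx], function(p) {
      true_surf <- mesh_surface(patient_mesh(p$rec, p$rec$V_SAC_true_mm3))
      cmp <- function(m) {
        reg <- icp_register(mesh_surface(m)$vertices, true_surf,
                            max_iter = 10L, tol = 1e-8)
        s <- mesh_surface(m); s$vertices <- reg$transformed
        surface_distance(s, true_surf, config$n_distance_samples,
                         seed = .derive_seed(config$seed, 3))$rmse_mm
      }
      c(raw = cmp(p$mesh_CT), rescaled = cmp(p$mesh_hat))
    })
    do.call(rbind, rows)
  }, verbose)

  fw_R <- .stage("baseline simulations", lapply(patients, function(p) {
    forward_openings(p$fm, config$baseline, p$springs, times = times,
                     provenance = "R", nominal = config$nominal,
                     n_substeps = config$n_substeps)
  }), verbose)

  calib <- .stage("DoE calibration", lapply(patients[calib_idx], function(p) {
    calibrate_patient(p$fm, p$springs, p$rec$measured_openings,
                      box = config$box, template = tmpl,
                      nominal = config$nominal,
                      n_substeps = config$n_substeps,
                      seed = .derive_seed(config$seed, 4))
  }), verbose)
  optima <- lapply(calib, `[[`, "optimum")
  population <- aggregate_population(optima, config$box)
  sens <- Reduce(`+`, lapply(calib, function(cl) {
    local_sensitivity(cl$surfaces, config$box)
  })) / length(calib)
  opt_materials <- materials_from_params(population$mean, tmpl)

  fw_OPT <- .stage("optimized simulations", lapply(patients, function(p) {
    forward_openings(p$fm, opt_materials, p$springs, times = times,
                     provenance = "OPT", nominal = config$nominal,
                     n_substeps = config$n_substeps)
  }), verbose)

  err <- function(fws) {
    e <- t(vapply(seq_len(n), function(i) {
      prediction_error(fws[[i]]$timeline, cohort[[i]]$measured_openings)
    }, numeric(length(times))))
    colnames(e) <- c("IO", "FU1", "FU2")[seq_len(length(times))]
    e
  }
  errors_R <- err(fw_R)
  errors_OPT <- err(fw_OPT)

  ci <- .stage("cranial index", {
    tr <- t(vapply(seq_len(n), function(i) {
      p <- patients[[i]]
      pre <- head_ci(p$operated, config$ci_band_frac)
      fu <- vapply(times[-1], function(tt) {
        head_ci(deformed_mesh(p$operated, fw_OPT[[i]]$sim, tt),
                config$ci_band_frac)
      }, numeric(1))
      c(PRE = pre, FU1 = fu[1], FU2 = fu[2])
    }, numeric(3)))
    tr
  }, verbose)

  report <- structure(list(
    config = config, growth_points = growth_points, growth_fit = growth_fit,
    cohort = cohort, population = population, sensitivity = sens,
    optima = optima,
    errors = list(R = errors_R, OPT = errors_OPT,
                  summary_R = summarize_errors(errors_R),
                  summary_OPT = summarize_errors(errors_OPT)),
    openings = list(R = fw_R, OPT = fw_OPT),
    ci = ci, rescaling = rescaling), class = "sac_study")

  if (!is.null(config$out_dir)) .write_study_outputs(report, config$out_dir)
  report
}

#' @export
print.sac_study <- function(x, ...) {
  cat(sprintf("<sac_study> %d patients (%d calibrated)\n",
              length(x$cohort), length(x$optima)))
  cat(sprintf("  growth fit: b = %.1f, R^2 = %.3f\n",
              x$growth_fit$b, x$growth_fit$r_squared))
  cat("  population material (mean +/- SD):\n")
  for (nm in names(x$population$mean)) {
    cat(sprintf("    %-10s %.4g +/- %.3g\n", nm, x$population$mean[nm],
                x$population$sd[nm]))
  }
  cat("  prediction error, percent points (baseline -> optimized):\n")
  for (j in seq_len(nrow(x$errors$summary_R))) {
    cat(sprintf("    %-4s %5.1f +/- %.1f  ->  %5.1f +/- %.1f\n",
                x$errors$summary_R$time[j],
                x$errors$summary_R$mean[j], x$errors$summary_R$sd[j],
                x$errors$summary_OPT$mean[j], x$errors$summary_OPT$sd[j]))
  }
  cat(sprintf("  cranial index: %.1f -> %.1f -> %.1f %%\n",
              mean(x$ci[, 1]), mean(x$ci[, 2]), mean(x$ci[, 3])))
  invisible(x)
}

.write_study_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_csv(report$cohort, file.path(out_dir, "cohort.csv"))
  n <- length(report$cohort)
  times <- report$config$times
  long <- do.call(rbind, lapply(seq_len(n), function(i) {
    rec <- report$cohort[[i]]
    rows <- function(tl, prov) {
      data.frame(patient_id = rec$patient_id, time_days = times,
                 provenance = prov, opening_mm = tl$mm,
                 opening_pct = normalize_opening(tl$mm, tl$nominal))
    }
    rbind(rows(rec$measured_openings, "M"),
          rows(report$openings$R[[i]]$timeline, "R"),
          rows(report$openings$OPT[[i]]$timeline, "OPT"))
  }))
  utils::write.csv(long, file.path(out_dir, "openings.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(a = report$growth_fit$a, b = report$growth_fit$b,
                            r_squared = report$growth_fit$r_squared),
                       file.path(out_dir, "growth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(mean = as.list(report$population$mean),
                            sd = as.list(report$population$sd)),
                       file.path(out_dir, "population_material.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    prediction_error = list(R = report$errors$summary_R,
                            OPT = report$errors$summary_OPT),
    cranial_index = list(mean = colMeans(report$ci),
                         sd = apply(report$ci, 2, stats::sd)),
    rescaling_rmse_mm = list(raw = mean(report$rescaling[, "raw"]),
                             rescaled = mean(report$rescaling[, "rescaled"]))),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
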