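#' Measurement-noise specification of the synthetic cohort
#'
#' @param opening_sd_mm Gaussian noise on measured spring openings (mm);
#'   default 1 mm, the reading precision of a sterile ruler / follow-up
#'   X-ray measurement
#' @param volume_sd_mm3 Gaussian noise on the control volumes around the
#'   growth law (mm^3); the default puts the growth-curve fit in the
#'   low-90s percent R^2 regime typical of this population
#' @return list of class \code{noise_spec}
#' @export
noise_spec <- function(opening_sd_mm = 1, volume_sd_mm3 = 40) {
  if (opening_sd_mm < 0 || volume_sd_mm3 < 0) stop("noise SDs must be non-negative")
  structure(list(opening_sd_mm = opening_sd_mm, volume_sd_mm3 = volume_sd_mm3),
            class = "noise_spec")
}

#' Ground-truth material model of the synthetic population
#'
#' The generating parameters of the synthetic cohort: a stiffer-than-baseline
#' bone (E_B = 600 MPa), mildly stronger relaxation (alpha_G = 1.1) and a
#' slowed relaxation time scale (alpha_tau = 10), all inside the calibration
#' parameter box.
#' @return a [material_model()]
#' @export
truth_materials <- function() {
  material_model(E_B = 600, E_s = 20, alpha_G = 1.1, alpha_tau = 10)
}

# control volume (cohort scale, mm^3) that corresponds to the reference-size
# calvarium mesh; only volume ratios enter the geometry
.V_REF <- 1000

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate (age, volume) points of an unoperated growth cohort
#'
#' Ages follow the unoperated-population distribution (mean 4.0, SD 1.3
#' months); volumes follow the logarithmic growth law plus Gaussian noise.
#'
#' @param n number of patients (default 24)
#' @param model generating \code{growth_model}
#' @param volume_sd_mm3 volume noise SD
#' @param seed RNG seed
#' @return data.frame with \code{age_months}, \code{volume_mm3}
#' @export
generate_growth_points <- function(n = 24L, model = default_growth_model(),
                                   volume_sd_mm3 = 40, seed = 1L) {
  with_local_seed(seed, {
    age <- .rtrunc_norm(n, 4.0, 1.3, 1.4, 8.0)
    vol <- predict_volume(model, age) + stats::rnorm(n, 0, volume_sd_mm3)
    data.frame(age_months = age, volume_mm3 = vol)
  })
}

#' Build the calvarium mesh of a cohort record at a given control volume
#'
#' Generates the patient's reference-shape calvarium and scales it
#' isotropically so its control volume corresponds to \code{V} on the cohort
#' volume scale.
#'
#' @param record a cohort record from [generate_cohort()]
#' @param V control volume (cohort scale, mm^3)
#' @param operated apply the record's surgical plan
#' @return a [tet_mesh()]
#' @export
patient_mesh <- function(record, V, operated = FALSE) {
  m <- generate_calvarium(record$calv_params)
  m <- scale_mesh(m, (V / .V_REF)^(1 / 3))
  if (operated) m <- apply_surgery(m, record$plan)
  m
}

#' Spring set-up of a cohort record
#' @param record a cohort record
#' @param catalog spring catalog (named list of [spring_spec()])
#' @return springs list for [solve_quasistatic()]
#' @export
patient_springs <- function(record, catalog = spring_catalog()) {
  ant <- catalog[[record$spring_models[1]]]
  post <- catalog[[record$spring_models[2]]]
  if (is.null(ant) || is.null(post)) {
    stop("spring model not in catalog: ", paste(record$spring_models, collapse = "/"))
  }
  list(list(spec = ant, sets = c("ant_groove_L", "ant_groove_R")),
       list(spec = post, sets = c("post_groove_L", "post_groove_R")))
}

#' Forward simulation of a patient: averaged spring openings
#'
#' Runs the quasi-static viscoelastic simulation and returns the
#' anterior/posterior-averaged opening timeline.
#'
#' @param model [fem_model()] (or operated [tet_mesh()]) of the patient
#' @param materials a [material_model()]
#' @param springs springs list (see [patient_springs()])
#' @param times output times (days)
#' @param provenance provenance tag of the returned timeline
#' @param nominal nominal maximum spring opening (mm)
#' @param ... passed to [solve_quasistatic()]
#' @return list with \code{timeline} (averaged [opening_timeline()]) and
#'   \code{sim} (the full \code{sac_sim})
#' @export
forward_openings <- function(model, materials, springs, times = c(0, 1, 28),
                             provenance = "R", nominal = 60, ...) {
  sim <- solve_quasistatic(model, materials, springs, times = times, ...)
  per <- lapply(seq_along(springs), function(i) {
    opening_timeline(sim$openings[i, ], times, provenance, nominal)
  })
  tl <- if (length(per) == 2L) average_springs(per[[1]], per[[2]]) else per[[1]]
  list(timeline = tl, sim = sim, per_spring = per)
}

#' Generate a synthetic SAC cohort
#'
#' Each record emulates one patient of the study: ages at CT and at surgery,
#' a noisy control volume on the growth curve, a scaphocephalic calvarium
#' shape (cephalic index ~70%), a surgical plan and spring pair, and
#' "measured" spring openings produced by running the forward viscoelastic
#' model on the patient's true at-surgery geometry under the ground-truth
#' material model, plus measurement noise.  The output is a pure function of
#' the arguments and the seed.
#'
#' @param n number of patients
#' @param growth generating \code{growth_model}
#' @param truth ground-truth [material_model()]
#' @param noise a [noise_spec()]
#' @param seed RNG seed
#' @param catalog spring catalog
#' @param times opening measurement times (days)
#' @param angular_resolution mesh resolution of the patient calvaria
#' @param n_substeps time-integration substeps of the forward simulations
#' @return list of cohort records (class \code{sac_cohort}); each record
#'   carries ids, ages, volumes, shape/plan parameters and the measured
#'   [opening_timeline()]
#' @export
generate_cohort <- function(n = 18L, growth = default_growth_model(),
                            truth = truth_materials(), noise = noise_spec(),
                            seed = 1L, catalog = spring_catalog(),
                            times = c(0, 1, 28), angular_resolution = 28L,
                            n_substeps = 60L) {
  if (n < 1L) stop("cohort size must be >= 1")
  draws <- with_local_seed(seed, {
    data.frame(
      age_SAC = .rtrunc_norm(n, 5.5, 1.0, 3.0, 8.0),
      gap = .rtrunc_norm(n, 1.8, 1.0, 0.3, 4.0),
      dV = stats::rnorm(n, 0, noise$volume_sd_mm3),
      CI = .rtrunc_norm(n, 70.6, 3.0, 64, 76),
      A = .rtrunc_norm(n, 25, 3, 18, 32),
      P = .rtrunc_norm(n, 60, 5, 48, 72),
      LAT = .rtrunc_norm(n, 85, 5, 75, 95),
      spring_draw = stats::runif(n),
      e_open = I(matrix(stats::rnorm(n * 2L * length(times), 0, noise$opening_sd_mm),
                        nrow = n)))
  })
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    d <- draws[i, ]
    age_CT <- max(1.0, d$age_SAC - d$gap)
    V_CT <- predict_volume(growth, age_CT) + d$dV
    V_SAC <- rescale_volume(growth, V_CT, age_CT, d$age_SAC)
    springs <- if (d$spring_draw < 0.5) c("S12", "S12")
      else if (d$spring_draw < 0.75) c("S14", "S14")
      else if (d$spring_draw < 0.9) c("S14", "S12")
      else c("S12", "S10")
    calv <- calvarium_params(OFD_mm = 140, BPD_mm = 140 * d$CI / 100,
                             height_mm = 78,
                             angular_resolution = angular_resolution)
    # lateral cut position follows the head width; osteotomy length is
    # clamped to the patient's coronal-to-occiput extent
    scale_i <- (V_SAC / .V_REF)^(1 / 3)
    bpd_i <- calv$BPD_mm * scale_i
    a_i <- calv$OFD_mm / 2 * scale_i
    x_hi_i <- calv$coronal_frac * a_i - calv$suture_width_mm * scale_i / 2
    lat_max <- x_hi_i + 0.92 * a_i
    P_i <- min(max(d$P, d$A + 10), lat_max - 8)
    rec <- list(patient_id = sprintf("P%02d", i),
                age_CT_months = age_CT, age_SAC_months = d$age_SAC,
                V_CT_mm3 = V_CT, V_SAC_true_mm3 = V_SAC,
                spring_models = springs, calv_params = calv)
    # if a plan is geometrically infeasible on this anatomy (detached
    # segment, grooves touching a cut), nudge it deterministically, as a
    # surgeon would adjust cut positions intra-operatively
    mesh <- NULL
    for (jit in 0:4) {
      plan <- surgical_plan(A_mm = d$A + 0.9 * jit,
                            P_mm = min(P_i - 1.1 * jit, lat_max - 8),
                            LAT_mm = max(min(d$LAT, lat_max), P_i + 8),
                            osteotomy_offset_mm = max(18, 0.205 * bpd_i) + 1.2 * jit)
      rec$plan <- plan
      mesh <- tryCatch(patient_mesh(rec, V_SAC, operated = TRUE),
                       error = function(e) NULL)
      if (!is.null(mesh)) break
    }
    if (is.null(mesh)) {
      stop(sprintf("could not realize a feasible surgical plan for patient %s", rec$patient_id))
    }
    fw <- forward_openings(fem_model(mesh, truth$nu_B, truth$nu_s), truth,
                           patient_springs(rec, catalog), times = times,
                           provenance = "M", n_substeps = n_substeps)
    # each spring is read separately (ruler at insertion, X-ray at follow-up)
    # and the two noisy readings are averaged per time point
    e <- matrix(as.numeric(d$e_open), nrow = 2L, byrow = TRUE)
    ant <- pmax(fw$per_spring[[1]]$mm + e[1, ], 0)
    post <- pmax(fw$per_spring[[2]]$mm + e[2, ], 0)
    rec$measured_openings <- opening_timeline((ant + post) / 2, times, "M")
    rec$measured_per_spring <- list(ant = ant, post = post)
    rec$true_openings <- fw$timeline$mm
    cohort[[i]] <- rec
  }
  class(cohort) <- c("sac_cohort", "list")
  cohort
}

#' @export
print.sac_cohort <- function(x, ...) {
  cat(sprintf("<sac_cohort> %d patients\n", length(x)))
  print(utils::head(cohort_table(x), 6))
  if (length(x) > 6) cat("  ...\n")
  invisible(x)
}
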