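#' Calvarial material model
#'
#' Isotropic linear elasticity (bone and suture moduli, Poisson ratios) plus
#' a Prony-series stress relaxation law with population scale factors.  The
#' normalized relaxation function is
#' \deqn{g(t) = \alpha_\infty + \sum_i \alpha_i e^{-t/\tau_i}}
#' with \eqn{\alpha_\infty + \sum_i \alpha_i = 1}.  Two dimensionless
#' population scale constants adapt the adult-literature series to the
#' paediatric calvarium: \code{alpha_G} scales the relative moduli
#' (\eqn{\alpha_i' = \alpha_G \alpha_i}) and \code{alpha_tau} scales the time
#' constants (\eqn{\tau_i' = \alpha_\tau \tau_i}).  The long-term modulus is
#' recomputed as \eqn{1 - \sum_i \alpha_G \alpha_i} so that \eqn{g(0) = 1}
#' for any \code{alpha_G} (the instantaneous modulus keeps its meaning).
#'
#' @param E_B bone Young's modulus (MPa)
#' @param E_s suture Young's modulus (MPa)
#' @param nu_B,nu_s Poisson ratios (literature defaults; the paper's source
#'   values are not printed)
#' @param prony data frame with columns \code{alpha} (relative moduli) and
#'   \code{tau} (time constants, days); the default single-term series
#'   (alpha = 0.5, tau = 0.4 days) puts the coupled spring/structure
#'   relaxation times in the day-to-month window where follow-up-1 openings
#'   respond to \code{alpha_tau} and follow-up-2 openings to \code{alpha_G}
#' @param alpha_G relaxation-modulus scale (>= 1 here; upper-bounded so the
#'   scaled long-term modulus stays positive)
#' @param alpha_tau relaxation-time scale (> 0)
#' @return list of class \code{material_model}
#' @export
material_model <- function(E_B = 421, E_s = 16, nu_B = 0.22, nu_s = 0.45,
                           prony = data.frame(alpha = 0.5, tau = 0.4),
                           alpha_G = 1, alpha_tau = 1) {
  m <- list(E_B = E_B, E_s = E_s, nu_B = nu_B, nu_s = nu_s,
            prony = as.data.frame(prony), alpha_G = alpha_G,
            alpha_tau = alpha_tau)
  class(m) <- "material_model"
  .check_materials(m)
  m
}

.check_materials <- function(m) {
  if (m$E_B <= 0 || m$E_s <= 0) stop("Young's moduli must be positive")
  if (any(m$nu_B >= 0.5, m$nu_s >= 0.5, m$nu_B < 0, m$nu_s < 0)) {
    stop("Poisson ratios must lie in [0, 0.5)")
  }
  if (!all(c("alpha", "tau") %in% names(m$prony))) {
    stop("prony must have columns 'alpha' and 'tau'")
  }
  if (any(m$prony$tau <= 0)) stop("Prony time constants must be positive")
  if (any(m$prony$alpha < 0)) stop("Prony relative moduli must be non-negative")
  if (m$alpha_tau <= 0) stop("alpha_tau must be positive")
  if (m$alpha_G * sum(m$prony$alpha) >= 1) {
    stop("scaled relative moduli alpha_G * sum(alpha_i) must stay below 1 (positive long-term modulus)")
  }
  invisible(TRUE)
}

#' @export
print.material_model <- function(x, ...) {
  cat(sprintf("<material_model> E_B = %.4g MPa, E_s = %.4g MPa, nu = (%.2f, %.2f)\n",
              x$E_B, x$E_s, x$nu_B, x$nu_s))
  cat(sprintf("  Prony: %s; alpha_G = %.4g, alpha_tau = %.4g, g(inf) = %.4g\n",
              paste(sprintf("(%.3g, %.3g d)", x$prony$alpha, x$prony$tau), collapse = " + "),
              x$alpha_G, x$alpha_tau, relaxation_factor(x, Inf)))
  invisible(x)
}

#' Normalized relaxation factor g(t)
#'
#' Evaluates the scaled Prony relaxation
#' \deqn{g(t) = \left(1 - \sum_i \alpha_G\alpha_i\right)
#'   + \sum_i \alpha_G \alpha_i \, e^{-t/(\alpha_\tau \tau_i)}}
#' so that g(0) = 1 exactly.
#'
#' @param materials a [material_model()]
#' @param t time in days (vectorized, t >= 0; \code{Inf} gives the long-term
#'   modulus fraction)
#' @return dimensionless relaxation factor(s)
#' @export
relaxation_factor <- function(materials, t) {
  .check_materials(materials)
  if (any(t < 0)) stop("t must be non-negative")
  ai <- materials$alpha_G * materials$prony$alpha
  ti <- materials$alpha_tau * materials$prony$tau
  vapply(t, function(tt) {
    (1 - sum(ai)) + sum(ai * exp(-tt / ti))
  }, numeric(1))
}

#' Spring distractor specification
#'
#' The implanted springs are linear compression springs characterized by a
#' stiffness and an unloaded (free) length; force k * (L0 - d) pushes the
#' groove rims apart while the current opening d is below the free length.
#' The catalog values are synthetic stand-ins on the scale of clinical
#' cranioplasty distractors (the experimental constants are published
#' elsewhere, not in this model's sources).
#'
#' @param name model label (e.g. "S12")
#' @param stiffness N/mm (> 0)
#' @param free_length unloaded opening, mm (> 0); defaults to the 60 mm
#'   nominal maximum spring opening
#' @return list of class \code{spring_spec}
#' @export
spring_spec <- function(name = "S12", stiffness = 0.3, free_length = 60) {
  if (stiffness < 0) stop("spring stiffness must be non-negative")
  if (free_length <= 0) stop("spring free length must be positive")
  structure(list(name = name, stiffness = stiffness, free_length = free_length),
            class = "spring_spec")
}

#' Default spring catalog (S10/S12/S14)
#' @return named list of [spring_spec()]s
#' @export
spring_catalog <- function() {
  list(S10 = spring_spec("S10", stiffness = 0.50),
       S12 = spring_spec("S12", stiffness = 0.60),
       S14 = spring_spec("S14", stiffness = 0.70))
}

#' Literature (baseline) material model
#'
#' Baseline parameter set used for the first batch of simulations before any
#' population calibration: E_B = 421 MPa, E_s = 16 MPa, alpha_tau = 1,
#' alpha_G = 1.
#' @return a [material_model()]
#' @export
literature_materials <- function() material_model(E_B = 421, E_s = 16,
                                                  alpha_G = 1, alpha_tau = 1)
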