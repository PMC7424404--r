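#' Fit the logarithmic calvarial growth curve
#'
#' Least-squares fit of the supraorbital calvarial control volume against
#' log-transformed age, \eqn{V = a + b \log(\mathrm{age} + 1)} (natural
#' logarithm; the fitted model is base-invariant once b absorbs the base).
#'
#' @param points data frame or matrix with columns \code{age_months} and
#'   \code{volume_mm3} (at least 2 rows, ages >= 0, not all identical)
#' @return list of class \code{growth_model} with elements \code{a}
#'   (intercept, mm^3), \code{b} (growth rate, mm^3 per log-month) and
#'   \code{r_squared}.  For a zero-variance response (constant volumes)
#'   \code{r_squared} is defined as 1 by convention.
#' @export
fit_growth_curve <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("age_months", "volume_mm3") %in% names(points))) {
    names(points)[1:2] <- c("age_months", "volume_mm3")
  }
  age <- points$age_months
  vol <- points$volume_mm3
  if (length(age) < 2L) stop("need at least 2 points to fit the growth curve")
  if (any(age < 0)) stop("ages must be non-negative")
  x <- log(age + 1)
  if (max(x) - min(x) < 1e-12) stop("singular fit: all ages identical")
  fit <- stats::lm.fit(cbind(1, x), vol)
  coefs <- fit$coefficients
  ss_tot <- sum((vol - mean(vol))^2)
  r2 <- if (ss_tot < .Machine$double.eps * max(1, sum(vol^2))) 1 else {
    1 - sum(fit$residuals^2) / ss_tot
  }
  structure(list(a = unname(coefs[1]), b = unname(coefs[2]), r_squared = r2),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model> V = %.4g + %.4g * log(age + 1)  (R^2 = %.3f)\n",
              x$a, x$b, x$r_squared))
  invisible(x)
}

#' Build a growth model from known coefficients
#' @param a intercept (mm^3)
#' @param b growth rate (mm^3 per log-month)
#' @return a \code{growth_model}
#' @export
growth_model <- function(a, b) {
  structure(list(a = a, b = b, r_squared = NA_real_), class = "growth_model")
}

#' Default calvarial growth law of the synthetic population
#'
#' Coefficients anchored to printed endpoint volumes of an unoperated
#' sagittal-craniosynostosis cohort: 640 mm^3 at 1.7 months and 1184 mm^3 at
#' 7.2 months, giving b = 544 / (log(8.2) - log(2.7)).
#' @return a \code{growth_model}
#' @export
default_growth_model <- function() {
  b <- 544 / (log(8.2) - log(2.7))
  growth_model(a = 640 - b * log(2.7), b = b)
}

#' Predicted control volume at an age
#' @param model a \code{growth_model}
#' @param age_months age (months, >= 0)
#' @return volume in mm^3
#' @export
predict_volume <- function(model, age_months) {
  if (any(age_months < 0)) stop("ages must be non-negative")
  model$a + model$b * log(age_months + 1)
}

#' Rescale a control volume from scan age to surgery age
#'
#' \eqn{V_{SAC} = V_{CT} + b \log\frac{1 + age_{SAC}}{1 + age_{CT}}}; only
#' the growth rate b enters (the intercept cancels).  Exactly transitive:
#' rescaling age1 -> age2 -> age3 equals age1 -> age3.
#'
#' @param model a \code{growth_model}
#' @param V_CT control volume at scan (mm^3)
#' @param age_CT age at scan (months)
#' @param age_SAC age at surgery (months)
#' @return rescaled volume V_SAC (mm^3)
#' @export
rescale_volume <- function(model, V_CT, age_CT, age_SAC) {
  if (any(c(age_CT, age_SAC) < 0)) stop("ages must be non-negative")
  V_CT + model$b * (log(1 + age_SAC) - log(1 + age_CT))
}

#' Isotropically rescale a mesh to a target control volume
#'
#' Applies the linear scale factor \eqn{(V_{SAC}/V_{CT})^{1/3}} about the
#' centroid of the base plane.  Topology, labels and node sets are unchanged;
#' shape (and hence cranial index) is preserved.
#'
#' @param mesh a [tet_mesh()]
#' @param V_CT control volume associated with the mesh (mm^3, > 0)
#' @param V_SAC target control volume (mm^3, > 0)
#' @return the rescaled mesh
#' @export
rescale_mesh <- function(mesh, V_CT, V_SAC) {
  if (!is.finite(V_CT) || !is.finite(V_SAC) || V_CT <= 0 || V_SAC <= 0) {
    stop("volumes must be positive")
  }
  scale_mesh(mesh, (V_SAC / V_CT)^(1 / 3))
}
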