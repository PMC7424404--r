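#' Spring opening timeline
#'
#' Openings at insertion (IO), first follow-up (FU1, ~1 day) and second
#' follow-up (FU2, ~1 month), in mm, with a provenance tag: \code{"M"}
#' (measured), \code{"R"} (reference/literature-material simulation) or
#' \code{"OPT"} (optimized-material simulation).
#'
#' @param mm numeric vector of openings (mm), one per time point
#' @param times time points in days (default c(0, 1, 28))
#' @param provenance one of "M", "R", "OPT"
#' @param nominal nominal maximum spring opening used for normalization (mm)
#' @return list of class \code{opening_timeline}
#' @export
opening_timeline <- function(mm, times = c(0, 1, 28), provenance = c("M", "R", "OPT"),
                             nominal = 60) {
  provenance <- match.arg(provenance)
  if (length(mm) != length(times)) stop("mm and times must have equal length")
  if (any(mm < 0)) stop("openings must be non-negative")
  structure(list(times = times, mm = as.numeric(mm), nominal = nominal,
                 provenance = provenance),
            class = "opening_timeline")
}

#' @export
print.opening_timeline <- function(x, ...) {
  cat(sprintf("<opening_timeline> [%s] %s\n", x$provenance,
              paste(sprintf("t=%gd: %.2f mm (%.1f%%)", x$times, x$mm,
                            normalize_opening(x$mm, x$nominal)), collapse = ", ")))
  invisible(x)
}

#' Normalize a spring opening to percent of the nominal maximum
#'
#' @param opening_mm opening(s) in mm (>= 0)
#' @param nominal nominal maximum spring opening (mm, default 60)
#' @return percentage(s) of the nominal opening
#' @export
normalize_opening <- function(opening_mm, nominal = 60) {
  if (nominal <= 0) stop("nominal opening must be positive")
  if (any(opening_mm < 0)) stop("openings must be non-negative")
  opening_mm / nominal * 100
}

#' Average anterior and posterior spring timelines
#'
#' Per-time arithmetic mean of two timelines with matching time points and
#' provenance (averaging commutes with normalization).
#'
#' @param anterior,posterior [opening_timeline()]s
#' @return averaged [opening_timeline()]
#' @export
average_springs <- function(anterior, posterior) {
  stopifnot(inherits(anterior, "opening_timeline"),
            inherits(posterior, "opening_timeline"))
  if (!isTRUE(all.equal(anterior$times, posterior$times))) {
    stop("timelines have mismatched time points")
  }
  if (anterior$provenance != posterior$provenance) {
    stop("cannot average timelines of different provenance")
  }
  opening_timeline((anterior$mm + posterior$mm) / 2, anterior$times,
                   anterior$provenance, anterior$nominal)
}

#' Signed prediction error in percent points
#'
#' simulated% - measured% per time point, on the nominal-opening percent
#' scale (the Bland-Altman scale used for cohort reporting).
#'
#' @param simulated simulated [opening_timeline()] (provenance R or OPT)
#' @param measured measured [opening_timeline()] (provenance M)
#' @return numeric vector of signed errors (percent points), named by time
#' @export
prediction_error <- function(simulated, measured) {
  if (!isTRUE(all.equal(simulated$times, measured$times))) {
    stop("timelines have mismatched time points")
  }
  e <- normalize_opening(simulated$mm, simulated$nominal) -
    normalize_opening(measured$mm, measured$nominal)
  names(e) <- paste0("t", simulated$times)
  e
}

#' Cohort summary of prediction errors
#' @param errors matrix (patients x time points) of signed percent errors
#' @return data.frame with mean and SD per time point
#' @export
summarize_errors <- function(errors) {
  errors <- as.matrix(errors)
  data.frame(time = colnames(errors) %||% seq_len(ncol(errors)),
             mean = colMeans(errors),
             sd = apply(errors, 2, stats::sd),
             mean_abs = colMeans(abs(errors)),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
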