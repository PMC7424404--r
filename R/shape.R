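#' Offset a surface along vertex normals (scalp reconstruction)
#'
#' Displaces every vertex along its area-weighted vertex normal by a fixed
#' patient-specific amount, recreating the scalp surface from the outer skull
#' surface.  A warning (not a failure) is raised when the offset exceeds the
#' local feature size enough that self-intersection is likely.
#'
#' @param surface a closed, outward-oriented [tri_surface()]
#' @param offset_mm offset distance (mm, >= 0)
#' @return the offset [tri_surface()]
#' @export
offset_scalp <- function(surface, offset_mm) {
  if (offset_mm < 0) stop("offset must be non-negative")
  cr <- .tri_cross(surface)                 # face normal * 2*area
  vn <- matrix(0, nrow(surface$vertices), 3)
  for (j in 1:3) {
    idx <- surface$faces[, j]
    for (cc in 1:3) {
      acc <- rowsum(cr[, cc], idx)
      vn[as.integer(rownames(acc)), cc] <- vn[as.integer(rownames(acc)), cc] + acc
    }
  }
  nrm <- sqrt(rowSums(vn^2))
  if (any(nrm < 1e-12)) warning("degenerate vertex normals; offset may self-intersect")
  vn <- vn / pmax(nrm, 1e-12)
  tri_surface(surface$vertices + offset_mm * vn, surface$faces, surface$meta)
}

.rigid_fit <- function(moving, target) {
  mc <- colMeans(moving); tc <- colMeans(target)
  H <- crossprod(sweep(moving, 2, mc), sweep(target, 2, tc))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(tc - R %*% mc))
}

#' Rigid ICP registration
#'
#' Iterative closest point: alternates nearest-neighbour correspondence
#' (point-to-point against a point set, or point-to-nearest-surface-point
#' against a triangulated surface) with the least-squares rigid alignment
#' (rotation from the SVD of the cross-covariance, translation from the
#' centroids).  The RMSE sequence is non-increasing; iteration stops when
#' its decrease falls below \code{tol}.
#'
#' @param moving point set (n x 3 matrix) or [tri_surface()] (its vertices
#'   are used)
#' @param fixed point set or [tri_surface()] (surface enables
#'   point-to-surface correspondence)
#' @param max_iter iteration cap
#' @param tol absolute tolerance on the RMSE decrease (mm)
#' @return list with \code{R} (3 x 3 rotation), \code{t} (translation),
#'   \code{transformed} points, \code{rmse} (final), \code{rmse_history}
#' @export
icp_register <- function(moving, fixed, max_iter = 50L, tol = 1e-10) {
  mv <- if (inherits(moving, "tri_surface")) moving$vertices else as.matrix(moving)
  if (nrow(mv) < 3) stop("registration needs at least 3 moving points")
  fixed_surface <- inherits(fixed, "tri_surface") && nrow(fixed$faces) > 0
  fx <- if (inherits(fixed, "tri_surface")) fixed$vertices else as.matrix(fixed)
  if (nrow(fx) < 3) stop("registration needs at least 3 fixed points")
  if (min(svd(sweep(mv, 2, colMeans(mv)))$d) < 1e-9 * max(abs(mv))) {
    stop("degenerate (collinear) moving point set")
  }
  R <- diag(3); tt <- numeric(3)
  cur <- mv
  hist <- numeric(0)
  for (it in seq_len(max_iter)) {
    target <- if (fixed_surface) {
      cp <- cpp_closest_mesh(cur, fixed$vertices, fixed$faces)
      cp$points
    } else {
      nn <- cpp_nn(cur, fx)
      fx[nn$idx, , drop = FALSE]
    }
    rmse <- sqrt(mean(rowSums((cur - target)^2)))
    hist <- c(hist, rmse)
    if (it > 1 && (hist[it - 1] - rmse) < tol) break
    ft <- .rigid_fit(cur, target)
    cur <- sweep(cur %*% t(ft$R), 2, ft$t, `+`)
    R <- ft$R %*% R
    tt <- as.numeric(ft$R %*% tt) + ft$t
  }
  list(R = R, t = tt, transformed = cur, rmse = hist[length(hist)],
       rmse_history = hist)
}

#' Surface-to-surface distance statistics
#'
#' Samples points uniformly (area-weighted) on surface \code{a} and measures
#' the unsigned distance to the nearest point of surface \code{b}.
#'
#' @param a source [tri_surface()] (sampled)
#' @param b target [tri_surface()]
#' @param n_samples number of sample points
#' @param threshold_mm distance threshold for the percent-below statistic
#'   (default 2 mm, the accepted planning accuracy threshold)
#' @param seed sampling seed
#' @return list of class \code{shape_comparison}: \code{rmse_mm},
#'   \code{mean_mm}, \code{pct_below} (percent of samples under the
#'   threshold), \code{threshold_mm}, \code{distances}
#' @export
surface_distance <- function(a, b, n_samples = 10000L, threshold_mm = 2, seed = 1L) {
  if (!nrow(a$faces) || !nrow(b$faces)) stop("empty surface")
  pts <- sample_surface_points(a, n_samples, seed = seed)
  d <- cpp_closest_mesh(pts, b$vertices, b$faces)$dist
  structure(list(rmse_mm = sqrt(mean(d^2)), mean_mm = mean(d),
                 pct_below = mean(d < threshold_mm) * 100,
                 threshold_mm = threshold_mm, distances = d),
            class = "shape_comparison")
}

#' @export
print.shape_comparison <- function(x, ...) {
  cat(sprintf("<shape_comparison> RMSE %.3f mm, mean %.3f mm, %.1f%% below %g mm\n",
              x$rmse_mm, x$mean_mm, x$pct_below, x$threshold_mm))
  invisible(x)
}

#' Cranial index of a head surface
#'
#' OFD is the maximal anteroposterior (x) extent and BPD the maximal lateral
#' (y) extent of the surface above the base plane; CI = 100 * BPD / OFD, the
#' standard cephalic index (scaphocephalic shapes fall below ~80%).  The
#' surface must be in the canonical frame (x anteroposterior, y lateral,
#' z up, base at z = 0).
#'
#' @param surface a [tri_surface()]
#' @param base_z vertices below this height are ignored (default 0 with a
#'   small tolerance)
#' @return list of class \code{cranial_index_report} with \code{OFD_mm},
#'   \code{BPD_mm}, \code{CI_pct}
#' @export
cranial_index <- function(surface, base_z = 0) {
  v <- surface$vertices
  v <- v[v[, 3] >= base_z - 1e-9, , drop = FALSE]
  if (!nrow(v)) stop("no vertices above the base plane; is the surface in the canonical frame?")
  ofd <- diff(range(v[, 1]))
  bpd <- diff(range(v[, 2]))
  if (ofd <= 0) stop("degenerate anteroposterior extent")
  structure(list(OFD_mm = ofd, BPD_mm = bpd, CI_pct = 100 * bpd / ofd),
            class = "cranial_index_report")
}

#' @export
print.cranial_index_report <- function(x, ...) {
  cat(sprintf("<cranial_index> OFD %.1f mm, BPD %.1f mm, CI %.1f%%\n",
              x$OFD_mm, x$BPD_mm, x$CI_pct))
  invisible(x)
}
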