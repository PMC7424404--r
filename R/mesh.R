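#' Labeled linear-tetrahedral mesh
#'
#' Container for the volume meshes used throughout the package: node
#' coordinates (mm), linear tetrahedra, a per-element tissue label
#' (\code{"bone"} or \code{"suture"}) and named node sets (e.g. the fully
#' constrained \code{"base"}, or the spring groove sets created by
#' [apply_surgery()]).
#'
#' @param nodes numeric matrix, n x 3, node coordinates in mm. Convention:
#'   x = anteroposterior (occipitofrontal axis), y = lateral (biparietal
#'   axis), z = vertical, origin at the centroid of the base cut plane.
#' @param elems integer matrix, m x 4, 1-based node indices. Tetrahedra must
#'   have positive signed volume; use [orient_tets()] to fix orientation.
#' @param labels character or factor of length m with values
#'   \code{"bone"}/\code{"suture"}.
#' @param node_sets named list of integer vectors (node indices).
#' @param meta optional list of provenance data (generator parameters,
#'   landmark coordinates) carried along by mesh operations.
#' @return an object of class \code{tet_mesh}.
#' @export
tet_mesh <- function(nodes, elems, labels = NULL, node_sets = list(), meta = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (ncol(elems) != 4L) stop("elems must be an m x 4 matrix")
  if (is.null(labels)) labels <- rep("bone", nrow(elems))
  labels <- as.character(labels)
  if (length(labels) != nrow(elems)) stop("labels must have one entry per element")
  if (!all(labels %in% c("bone", "suture"))) {
    stop("labels must be 'bone' or 'suture'")
  }
  if (min(elems) < 1L || max(elems) > nrow(nodes)) stop("element indices out of range")
  stopifnot(is.list(node_sets))
  m <- structure(
    list(nodes = nodes, elems = elems, labels = labels,
         node_sets = node_sets, meta = meta),
    class = "tet_mesh")
  v <- tet_volumes(m)
  if (any(v <= 0)) {
    stop(sprintf("mesh contains %d non-positively oriented tetrahedra (first: element %d)",
                 sum(v <= 0), which(v <= 0)[1]))
  }
  m
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tetrahedra (%d bone, %d suture)\n",
              nrow(x$nodes), nrow(x$elems),
              sum(x$labels == "bone"), sum(x$labels == "suture")))
  if (length(x$node_sets)) {
    cat("  node sets:", paste(sprintf("%s[%d]", names(x$node_sets),
                                      lengths(x$node_sets)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Signed tetrahedron volumes
#'
#' @param mesh a [tet_mesh()].
#' @return numeric vector of signed volumes in mm^3 (positive for correctly
#'   oriented elements).
#' @export
tet_volumes <- function(mesh) {
  p1 <- mesh$nodes[mesh$elems[, 1], , drop = FALSE]
  e1 <- mesh$nodes[mesh$elems[, 2], , drop = FALSE] - p1
  e2 <- mesh$nodes[mesh$elems[, 3], , drop = FALSE] - p1
  e3 <- mesh$nodes[mesh$elems[, 4], , drop = FALSE] - p1
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) +
   e1[, 2] * (e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]) +
   e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

#' Fix tetrahedron orientation
#'
#' Swaps the last two nodes of any negatively oriented tetrahedron so all
#' signed volumes are positive.  Node order within a tetrahedron does not
#' change its face set, so mesh conformity is preserved.
#'
#' @param elems m x 4 element matrix
#' @param nodes n x 3 coordinate matrix
#' @return reordered element matrix
#' @export
orient_tets <- function(elems, nodes) {
  m <- list(nodes = as.matrix(nodes), elems = as.matrix(elems))
  v <- tet_volumes(m)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- elems[neg, 3]
    elems[neg, 3] <- elems[neg, 4]
    elems[neg, 4] <- tmp
  }
  elems
}

# face table: 4 faces per tet, oriented outward for a positively oriented tet
.tet_faces <- function(elems) {
  f <- rbind(elems[, c(2, 3, 4)],
             elems[, c(1, 4, 3)],
             elems[, c(1, 2, 4)],
             elems[, c(1, 3, 2)])
  f
}

#' Extract the boundary surface of a tetrahedral mesh
#'
#' Returns the oriented (outward-normal) triangulated boundary: every facet
#' belonging to exactly one tetrahedron.
#'
#' @param mesh a [tet_mesh()].
#' @return a \code{tri_surface}: list with \code{vertices} (v x 3) and
#'   \code{faces} (f x 3, outward oriented), carrying the mesh \code{meta}.
#' @export
mesh_surface <- function(mesh) {
  f <- .tet_faces(mesh$elems)
  key <- .face_key(f)
  cnt <- table(key)
  bnd <- f[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
  used <- sort(unique(as.vector(bnd)))
  remap <- integer(nrow(mesh$nodes))
  remap[used] <- seq_along(used)
  tri_surface(mesh$nodes[used, , drop = FALSE],
              matrix(remap[bnd], ncol = 3), meta = mesh$meta)
}

.face_key <- function(f) {
  s <- t(apply(f, 1, sort))
  paste(s[, 1], s[, 2], s[, 3], sep = "_")
}

#' Triangulated surface
#'
#' @param vertices v x 3 coordinate matrix (mm)
#' @param faces f x 3 matrix of 1-based vertex indices, consistently oriented
#'   (outward normals for closed surfaces)
#' @param meta optional provenance list
#' @export
tri_surface <- function(vertices, faces, meta = list()) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L) stop("vertices/faces must have 3 columns")
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces, meta = meta),
            class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("<tri_surface> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

.tri_cross <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Surface area of a triangulated surface
#' @param surface a [tri_surface()]
#' @return total area in mm^2
#' @export
surface_area <- function(surface) {
  sum(sqrt(rowSums(.tri_cross(surface)^2))) / 2
}

#' Volume enclosed by a closed oriented surface
#'
#' Divergence-theorem volume of a closed, outward-oriented triangulation.
#'
#' @param surface a [tri_surface()]
#' @return enclosed volume in mm^3
#' @export
surface_enclosed_volume <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
      a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Check mesh watertightness
#'
#' A labeled tet mesh is watertight when every face is shared by exactly one
#' (boundary) or two (interior) tetrahedra.
#'
#' @param mesh a [tet_mesh()]
#' @return logical
#' @export
is_watertight <- function(mesh) {
  key <- .face_key(.tet_faces(mesh$elems))
  all(table(key) <= 2L)
}

#' Keep a subset of elements, dropping unused nodes
#'
#' Node sets and meta landmark entries are remapped; node-set entries whose
#' nodes disappear are dropped from the set.
#'
#' @param mesh a [tet_mesh()]
#' @param keep logical or integer index over elements
#' @return a [tet_mesh()]
#' @export
subset_elements <- function(mesh, keep) {
  elems <- mesh$elems[keep, , drop = FALSE]
  labels <- mesh$labels[keep]
  used <- sort(unique(as.vector(elems)))
  remap <- integer(nrow(mesh$nodes))
  remap[used] <- seq_along(used)
  sets <- lapply(mesh$node_sets, function(s) {
    s <- s[s %in% used]
    unname(remap[s])
  })
  meta <- mesh$meta
  if (!is.null(meta$cells)) meta$cells <- meta$cells[keep]
  tet_mesh(mesh$nodes[used, , drop = FALSE], matrix(remap[elems], ncol = 4),
           labels, sets, meta)
}

#' Isotropically scale a mesh about a point
#' @param mesh a [tet_mesh()]
#' @param factor linear scale factor (> 0)
#' @param center 3-vector; defaults to the centroid of the \code{"base"}
#'   node set if present, else the origin
#' @return scaled mesh (topology, labels and node sets unchanged)
#' @export
scale_mesh <- function(mesh, factor, center = NULL) {
  if (!is.finite(factor) || factor <= 0) stop("scale factor must be positive")
  if (factor == 1) return(mesh)
  if (is.null(center)) {
    center <- if (!is.null(mesh$node_sets$base)) {
      colMeans(mesh$nodes[mesh$node_sets$base, , drop = FALSE])
    } else c(0, 0, 0)
  }
  out <- mesh
  out$nodes <- sweep(sweep(mesh$nodes, 2, center), 2, rep(factor, 3), `*`)
  out$nodes <- sweep(out$nodes, 2, center, `+`)
  # keep length-valued metadata consistent with the new scale
  for (f in c("x_coronal", "x_lambdoid", "spring_x")) {
    if (!is.null(out$meta[[f]])) out$meta[[f]] <- out$meta[[f]] * factor
  }
  if (!is.null(out$meta$params)) {
    for (f in c("OFD_mm", "BPD_mm", "height_mm", "thickness_mm", "suture_width_mm")) {
      out$meta$params[[f]] <- out$meta$params[[f]] * factor
    }
  }
  out
}

#' Area-weighted random sampling of points on a surface
#'
#' @param surface a [tri_surface()]
#' @param n number of sample points
#' @param seed integer seed (local RNG; the caller's RNG state is untouched)
#' @return n x 3 matrix of points
#' @export
sample_surface_points <- function(surface, n, seed = 1L) {
  if (nrow(surface$faces) == 0L) stop("empty surface")
  with_local_seed(seed, {
    areas <- sqrt(rowSums(.tri_cross(surface)^2)) / 2
    idx <- sample.int(nrow(surface$faces), n, replace = TRUE, prob = areas)
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
    w1 <- 1 - r1
    w2 <- r1 * (1 - r2)
    w3 <- r1 * r2
    f <- surface$faces[idx, , drop = FALSE]
    v <- surface$vertices
    w1 * v[f[, 1], , drop = FALSE] +
      w2 * v[f[, 2], , drop = FALSE] +
      w3 * v[f[, 3], , drop = FALSE]
  })
}

# run expr with a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
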