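#' Parameters of the synthetic scaphocephalic calvarium
#'
#' The calvarium is idealized as a half-ellipsoid shell: outer semi-axes
#' OFD/2 (anteroposterior, x), BPD/2 (lateral, y) and height (vertical, z),
#' cut by the base plane z = 0 (the supraorbital/nasion cutting plane).  The
#' shell carries patent coronal and lambdoid suture strips (suture material)
#' and a fused midline sagittal strip (bone, the pathology).  A scaphocephalic
#' shape requires OFD > BPD (cephalic index below 100%).
#'
#' @param OFD_mm anteroposterior outer diameter (mm)
#' @param BPD_mm lateral outer diameter (mm); must be < OFD_mm unless
#'   \code{strict = FALSE} in [generate_calvarium()]
#' @param height_mm vertical outer semi-axis (mm)
#' @param thickness_mm shell thickness (mm), applied as a reduction of all
#'   three semi-axes for the inner surface
#' @param suture_width_mm width of the patent suture strips (mm)
#' @param angular_resolution azimuthal grid divisions (full circle); the
#'   meridional division count is derived from it
#' @param layers_through_thickness radial element layers (>= 3, so that at
#'   least three elements span the skull thickness)
#' @param coronal_frac,lambdoid_frac suture positions as fractions of the
#'   anteroposterior outer semi-axis (+ anterior, - posterior)
#' @param polar_cap_deg meridional extent is limited to 90 - polar_cap_deg
#'   degrees to avoid the degenerate pole of the parametrization; the missing
#'   polar cap is a negligible fraction of the shell volume
#' @return list of class \code{calvarium_params}
#' @export
calvarium_params <- function(OFD_mm = 140, BPD_mm = 98, height_mm = 78,
                             thickness_mm = 1.0, suture_width_mm = 8,
                             angular_resolution = 28L,
                             layers_through_thickness = 3L,
                             coronal_frac = 0.45, lambdoid_frac = -0.60,
                             polar_cap_deg = 4) {
  p <- list(OFD_mm = OFD_mm, BPD_mm = BPD_mm, height_mm = height_mm,
            thickness_mm = thickness_mm, suture_width_mm = suture_width_mm,
            angular_resolution = as.integer(angular_resolution),
            layers_through_thickness = as.integer(layers_through_thickness),
            coronal_frac = coronal_frac, lambdoid_frac = lambdoid_frac,
            polar_cap_deg = polar_cap_deg)
  class(p) <- "calvarium_params"
  p
}

.check_calvarium_params <- function(p, strict = TRUE) {
  dims <- c(p$OFD_mm, p$BPD_mm, p$height_mm, p$thickness_mm, p$suture_width_mm)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("calvarium dimensions must all be positive")
  }
  if (p$layers_through_thickness < 3L) {
    stop("layers_through_thickness must be >= 3 (at least three elements through the skull thickness)")
  }
  if (p$angular_resolution < 8L) stop("angular_resolution must be >= 8")
  if (p$angular_resolution %% 2L != 0L) stop("angular_resolution must be even (left/right symmetry)")
  if (strict && p$OFD_mm <= p$BPD_mm) {
    stop("non-scaphocephalic shape: OFD_mm must exceed BPD_mm (set strict = FALSE to allow)")
  }
  if (p$thickness_mm >= min(p$OFD_mm, p$BPD_mm, 2 * p$height_mm) / 2) {
    stop("thickness_mm too large for the given semi-axes")
  }
  invisible(TRUE)
}

#' Generate a scaphocephalic calvarium tetrahedral mesh
#'
#' Builds a structured parametric grid on the half-ellipsoid (azimuth x
#' elevation x thickness), splits every hexahedral cell into six conforming
#' tetrahedra, labels coronal/lambdoid strips as patent suture and keeps the
#' midline sagittal strip fused (bone), and records the \code{"base"} node
#' set (all nodes on the z = 0 cutting plane).
#'
#' @param params a [calvarium_params()]
#' @param strict reject non-scaphocephalic shapes (OFD <= BPD) when TRUE
#' @return a [tet_mesh()] whose \code{meta} records the generator parameters,
#'   suture x-positions and structured-cell ids (used by [apply_surgery()]
#'   to remove whole cells symmetrically)
#' @export
generate_calvarium <- function(params = calvarium_params(), strict = TRUE) {
  .check_calvarium_params(params, strict = strict)
  a <- params$OFD_mm / 2; b <- params$BPD_mm / 2; cz <- params$height_mm
  t <- params$thickness_mm
  nu <- params$angular_resolution
  nv <- max(4L, as.integer(ceiling(nu / 3)))
  nl <- params$layers_through_thickness
  v_max <- (90 - params$polar_cap_deg) * pi / 180

  us <- 2 * pi * (seq_len(nu) - 1L) / nu
  vs <- v_max * (0:nv) / nv
  ls <- (0:nl) / nl

  # node(k, j, i): azimuth k, elevation j, layer i (0 = inner, nl = outer)
  nid <- function(k, j, i) {
    k <- ((k - 1L) %% nu) + 1L
    k + nu * (j + (nv + 1L) * i)
  }
  grid <- expand.grid(u = us, v = vs, l = ls)
  ax <- a - t * (1 - grid$l); bx <- b - t * (1 - grid$l); cx <- cz - t * (1 - grid$l)
  nodes <- cbind(ax * cos(grid$v) * cos(grid$u),
                 bx * cos(grid$v) * sin(grid$u),
                 cx * sin(grid$v))

  # hex cells -> 6 tets around the main diagonal (conforming across cells)
  cell <- expand.grid(k = seq_len(nu), j = seq_len(nv) - 1L, i = seq_len(nl) - 1L)
  n0 <- nid(cell$k,      cell$j,      cell$i)
  n1 <- nid(cell$k + 1L, cell$j,      cell$i)
  n2 <- nid(cell$k + 1L, cell$j + 1L, cell$i)
  n3 <- nid(cell$k,      cell$j + 1L, cell$i)
  n4 <- nid(cell$k,      cell$j,      cell$i + 1L)
  n5 <- nid(cell$k + 1L, cell$j,      cell$i + 1L)
  n6 <- nid(cell$k + 1L, cell$j + 1L, cell$i + 1L)
  n7 <- nid(cell$k,      cell$j + 1L, cell$i + 1L)
  tets <- rbind(cbind(n0, n1, n2, n6),
                cbind(n0, n2, n3, n6),
                cbind(n0, n3, n7, n6),
                cbind(n0, n7, n4, n6),
                cbind(n0, n4, n5, n6),
                cbind(n0, n5, n1, n6))
  cell_id <- rep(seq_len(nrow(cell)), times = 6L)
  tets <- orient_tets(tets, nodes)

  # labels per structured cell (suture strips by cell-centroid x position)
  ccx <- (nodes[n0, 1] + nodes[n1, 1] + nodes[n2, 1] + nodes[n3, 1] +
          nodes[n4, 1] + nodes[n5, 1] + nodes[n6, 1] + nodes[n7, 1]) / 8
  x_cor <- params$coronal_frac * a
  x_lam <- params$lambdoid_frac * a
  w2 <- params$suture_width_mm / 2
  cell_label <- ifelse(abs(ccx - x_cor) <= w2 | abs(ccx - x_lam) <= w2,
                       "suture", "bone")
  labels <- cell_label[cell_id]

  base <- which(abs(nodes[, 3]) < 1e-9 * cz)
  meta <- list(params = params, x_coronal = x_cor, x_lambdoid = x_lam,
               cells = cell_id, n_cells = nrow(cell),
               grid_dims = c(nu = nu, nv = nv, nl = nl))
  tet_mesh(nodes, tets, labels, node_sets = list(base = base), meta = meta)
}

#' Analytic volume of the idealized calvarium shell
#'
#' Half-ellipsoid shell volume (outer minus inner half-ellipsoid), the
#' reference value for checking the meshed volume.
#'
#' @param params a [calvarium_params()]
#' @return volume in mm^3
#' @export
calvarium_shell_volume <- function(params) {
  a <- params$OFD_mm / 2; b <- params$BPD_mm / 2; cz <- params$height_mm
  t <- params$thickness_mm
  2 * pi / 3 * (a * b * cz - (a - t) * (b - t) * (cz - t))
}

#' Surgical plan for spring-assisted cranioplasty
#'
#' Distances are measured posteriorly from the coronal suture along the
#' anteroposterior axis: the craniectomy strip (width
#' \code{craniectomy_width_mm}) spans the osteotomy length \code{LAT_mm};
#' springs sit at \code{A_mm} (anterior) and \code{P_mm} (posterior).
#'
#' @param A_mm distance coronal suture -> anterior spring (mm)
#' @param P_mm distance coronal suture -> posterior spring (mm); must exceed
#'   \code{A_mm}
#' @param LAT_mm parasagittal osteotomy length (mm)
#' @param craniectomy_width_mm width of the discarded midline bone strip (mm)
#' @param osteotomy_offset_mm lateral distance from the midline to each
#'   parasagittal osteotomy cut line (mm); the cuts mobilize the
#'   spring-bearing parietal bone strips for lateral expansion
#' @param osteotomy_kerf_mm width of material removed along each cut line
#'   (mm); must be resolvable by the mesh
#' @param osteotomy_end_margin_mm the cuts stop this far short of the
#'   craniectomy ends, keeping the spring-bearing bone strips anchored
#' @param groove_halfwidth_mm anteroposterior half-extent of each spring
#'   groove node set (mm)
#' @return list of class \code{surgical_plan}
#' @export
surgical_plan <- function(A_mm = 25, P_mm = 60, LAT_mm = 85,
                          craniectomy_width_mm = 15,
                          osteotomy_offset_mm = 20, osteotomy_kerf_mm = 5,
                          osteotomy_end_margin_mm = 8,
                          groove_halfwidth_mm = 6) {
  if (!(A_mm > 0 && P_mm > A_mm)) stop("plan requires 0 < A_mm < P_mm")
  if (LAT_mm <= 0) stop("LAT_mm must be positive")
  if (craniectomy_width_mm <= 0 || groove_halfwidth_mm <= 0) {
    stop("craniectomy width and groove halfwidth must be positive")
  }
  if (osteotomy_offset_mm <= craniectomy_width_mm / 2 + osteotomy_kerf_mm / 2) {
    stop("parasagittal osteotomies must lie clear of the craniectomy strip")
  }
  if (P_mm > LAT_mm) stop("spring positions must lie within the osteotomy span (P_mm <= LAT_mm)")
  structure(list(A_mm = A_mm, P_mm = P_mm, LAT_mm = LAT_mm,
                 craniectomy_width_mm = craniectomy_width_mm,
                 osteotomy_offset_mm = osteotomy_offset_mm,
                 osteotomy_kerf_mm = osteotomy_kerf_mm,
                 osteotomy_end_margin_mm = osteotomy_end_margin_mm,
                 groove_halfwidth_mm = groove_halfwidth_mm),
            class = "surgical_plan")
}

#' Apply osteotomies and craniectomy to a calvarium mesh
#'
#' Removes the midline craniectomy strip (all structured cells whose centroid
#' lies within the strip, so a symmetric plan on a symmetric mesh removes a
#' mirror-symmetric region) over the osteotomy span starting just posterior
#' to the coronal suture, and creates the four spring-groove node sets
#' \code{ant_groove_L/R} and \code{post_groove_L/R} on opposite rims of the
#' gap at distances \code{A_mm} and \code{P_mm} from the coronal suture.
#'
#' @param mesh a calvarium [tet_mesh()] from [generate_calvarium()]
#' @param plan a [surgical_plan()]
#' @return the operated [tet_mesh()]; \code{meta$plan} records the plan and
#'   \code{meta$spring_x} the groove x-positions
#' @export
apply_surgery <- function(mesh, plan) {
  stopifnot(inherits(plan, "surgical_plan"))
  if (is.null(mesh$meta$x_coronal)) {
    stop("mesh does not carry calvarium metadata (x_coronal); generate it with generate_calvarium()")
  }
  x_cor <- mesh$meta$x_coronal
  p <- mesh$meta$params
  x_hi <- x_cor - p$suture_width_mm / 2            # strip starts behind the coronal suture
  x_lo <- x_hi - plan$LAT_mm
  if (x_lo < -p$OFD_mm / 2) stop("osteotomy length LAT_mm exceeds the calvarium extent")
  wc2 <- plan$craniectomy_width_mm / 2

  band_lo <- plan$osteotomy_offset_mm - plan$osteotomy_kerf_mm / 2
  # removal is decided per structured cell on the cell centroid (mean of the
  # eight unique cell corners): selection by tetrahedron centroids would not
  # be left/right symmetric, because the 6-tet diagonalization is not
  cid <- mesh$meta$cells
  if (is.null(cid)) stop("mesh does not carry structured-cell metadata; generate it with generate_calvarium()")
  pair_cell <- rep(cid, 4L)
  pair_node <- as.vector(mesh$elems)
  keep_pair <- !duplicated(pair_cell * (nrow(mesh$nodes) + 1) + pair_node)
  corner_sum <- rowsum(mesh$nodes[pair_node[keep_pair], , drop = FALSE],
                       pair_cell[keep_pair])
  corner_n <- rowsum(rep(1, sum(keep_pair)), pair_cell[keep_pair])
  cell_cen <- corner_sum / as.vector(corner_n)
  cell_ids <- as.integer(rownames(corner_sum))

  ay <- abs(mesh$nodes[pair_node[keep_pair], 2])
  ay_min <- vapply(split(ay, pair_cell[keep_pair]), min, numeric(1))
  ay_max <- vapply(split(ay, pair_cell[keep_pair]), max, numeric(1))

  in_span_c <- cell_cen[, 1] >= x_lo & cell_cen[, 1] <= x_hi
  # a cell is cut when its half-shrunk lateral footprint (the middle half of
  # its corner |y| interval, a left/right-symmetric measure of where the
  # cell's material sits) meets the marked region
  ay_mid <- (ay_min + ay_max) / 2
  ay_h <- (ay_max - ay_min) / 4
  eff_min <- ay_mid - ay_h
  eff_max <- ay_mid + ay_h
  strip_cells <- cell_ids[in_span_c & eff_min < wc2]
  # The parasagittal osteotomies stop short of the craniectomy ends by an
  # end margin, so the spring-bearing bone strips always stay face-connected
  # to the surrounding vault at their anterior and posterior ends.
  margin <- plan$osteotomy_end_margin_mm
  band_hi <- plan$osteotomy_offset_mm + plan$osteotomy_kerf_mm / 2
  kerf_cells <- cell_ids[
    cell_cen[, 1] >= x_lo + margin & cell_cen[, 1] <= x_hi - margin &
      eff_min <= band_hi & eff_max >= band_lo & eff_min >= wc2]
  strip <- cid %in% strip_cells
  kerf <- (cid %in% kerf_cells) & !strip
  remove <- strip | kerf
  if (!any(strip)) stop("craniectomy strip removed no elements; plan inconsistent with mesh extents")
  if (!any(kerf)) stop("parasagittal osteotomies removed no elements; check osteotomy_offset_mm/kerf against the mesh resolution")

  # small bone fragments left face-disconnected from the anchored vault by
  # the cuts are discarded with the craniectomy bone; a large detached
  # segment means the plan is inconsistent with the anatomy
  frag <- rep(FALSE, nrow(mesh$elems))
  for (pass in 1:4) {
    new_frag <- .unanchored_elements(mesh, !(remove | frag)) & !frag
    if (!any(new_frag)) break
    if (any(new_frag) && !is.null(mesh$meta$cells) && !is.null(mesh$meta$grid_dims)) {
      # discard the mirror-image cells too: the tetrahedral diagonalization
      # is not left/right symmetric, so a fragment can detach on one side
      # only, and an asymmetric discard would break the groove-set mirror
      # symmetry; mirrored removal can expose further fragments, hence the
      # fixed-point loop
      nu <- mesh$meta$grid_dims[["nu"]]
      cid <- mesh$meta$cells
      frag_cells <- unique(cid[new_frag])
      k <- ((frag_cells - 1L) %% nu) + 1L
      rest <- frag_cells - k
      k_mirror <- ifelse(k == 1L, 1L, nu - k + 2L)
      new_frag <- new_frag | (cid %in% c(frag_cells, rest + k_mirror))
    }
    frag <- frag | new_frag
    if (sum(frag) > 0.05 * nrow(mesh$elems)) {
      stop("surgery detached a major bone segment from the constrained base; adjust the plan")
    }
  }
  remove <- remove | frag
  strip <- strip | frag

  # groove rim: kept nodes bordering the midline craniectomy gap
  removed_nodes <- unique(as.vector(mesh$elems[strip, ]))
  kept_nodes <- unique(as.vector(mesh$elems[!remove, ]))
  rim <- intersect(removed_nodes, kept_nodes)      # gap rim: shared by cut and kept elements

  out <- subset_elements(mesh, !remove)
  # rim indices in the new node numbering: match by coordinates is fragile;
  # recompute through the kept-node remap used by subset_elements
  used <- sort(kept_nodes)
  remap <- integer(nrow(mesh$nodes)); remap[used] <- seq_along(used)
  rim_new <- remap[rim]

  xyz <- out$nodes[rim_new, , drop = FALSE]
  spring_x <- c(ant = x_cor - plan$A_mm, post = x_cor - plan$P_mm)
  ghw <- plan$groove_halfwidth_mm
  lateral <- abs(xyz[, 2]) > wc2 / 2               # exclude end-cap rim nodes near the midline
  groove <- function(x0, side) {
    sel <- lateral & abs(xyz[, 1] - x0) <= ghw &
      (if (side == "L") xyz[, 2] > 0 else xyz[, 2] < 0)
    rim_new[sel]
  }
  sets <- list(ant_groove_L  = groove(spring_x["ant"], "L"),
               ant_groove_R  = groove(spring_x["ant"], "R"),
               post_groove_L = groove(spring_x["post"], "L"),
               post_groove_R = groove(spring_x["post"], "R"))
  if (any(lengths(sets) == 0L)) {
    stop("empty spring groove node set; spring positions incompatible with mesh resolution")
  }
  groove_y <- abs(out$nodes[unlist(sets), 2])
  if (any(groove_y >= band_lo)) {
    stop("spring grooves reach the parasagittal osteotomy; widen osteotomy_offset_mm or refine the mesh")
  }
  out$node_sets <- c(out$node_sets, sets)
  out$meta$plan <- plan
  out$meta$spring_x <- spring_x
  out$meta$discarded_fragments <- sum(frag)
  out
}

# elements (among `keep`) lying in face-connected components that do not
# reach the constrained base: those would be rigid-body mechanisms
.unanchored_elements <- function(mesh, keep) {
  idx <- which(keep)
  el <- mesh$elems[idx, , drop = FALSE]
  ne <- nrow(el)
  key <- .face_key(.tet_faces(el))
  fe <- rep(seq_len(ne), 4L)
  parent <- seq_len(ne)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (g in split(fe, key)) {
    if (length(g) == 2L) {
      r1 <- find(g[1]); r2 <- find(g[2])
      if (r1 != r2) parent[r2] <- r1
    }
  }
  comp <- vapply(seq_len(ne), find, integer(1))
  base_elem <- rowSums(matrix(el %in% mesh$node_sets$base, ne)) > 0
  anchored <- unique(comp[base_elem])
  out <- rep(FALSE, nrow(mesh$elems))
  out[idx[!(comp %in% anchored)]] <- TRUE
  out
}

#' Generate a prismatic bar mesh (solver verification fixture)
#'
#' A straight bar along +x with a single triangular cross-section of area
#' \code{area_mm2}, split into tetrahedra layer by layer.  With Poisson ratio
#' zero and all lateral degrees of freedom fixed, its axial stiffness is
#' exactly E * area / length, which makes it the one-dimensional surrogate
#' used to verify the spring/structure equilibrium and the viscoelastic time
#' integration against closed-form solutions.
#'
#' @param length_mm bar length (mm)
#' @param area_mm2 cross-section area (mm^2)
#' @param n_layers number of element layers along the bar
#' @return a [tet_mesh()] with node sets \code{"base"} (x = 0 face) and
#'   \code{"end"} (x = length face)
#' @export
generate_bar <- function(length_mm = 50, area_mm2 = 100, n_layers = 4L) {
  if (length_mm <= 0 || area_mm2 <= 0) stop("bar dimensions must be positive")
  h <- sqrt(2 * area_mm2)                          # right triangle legs
  xs <- length_mm * (0:n_layers) / n_layers
  tri <- rbind(c(0, 0), c(h, 0), c(0, h))
  nodes <- do.call(rbind, lapply(xs, function(x) cbind(x, tri)))
  id <- function(layer, corner) (layer) * 3L + corner   # layer 0-based
  tets <- do.call(rbind, lapply(seq_len(n_layers) - 1L, function(l) {
    a <- id(l, 1L); b <- id(l, 2L); cc <- id(l, 3L)
    d <- id(l + 1L, 1L); e <- id(l + 1L, 2L); f <- id(l + 1L, 3L)
    rbind(c(a, b, cc, d), c(b, cc, d, e), c(cc, d, e, f))
  }))
  tets <- orient_tets(tets, nodes)
  tet_mesh(nodes, tets,
           node_sets = list(base = 1:3, end = (n_layers * 3L + 1L):(n_layers * 3L + 3L)),
           meta = list(length_mm = length_mm, area_mm2 = area_mm2))
}
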