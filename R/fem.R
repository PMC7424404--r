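#' @importFrom Matrix sparseMatrix forceSymmetric Cholesky solve crossprod t
NULL

.lame <- function(E, nu) {
  c(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
    mu = E / (2 * (1 + nu)))
}

.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# shape-function gradients and volumes of all tets
.tet_gradients <- function(nodes, elems) {
  p1 <- nodes[elems[, 1], , drop = FALSE]
  e1 <- nodes[elems[, 2], , drop = FALSE] - p1
  e2 <- nodes[elems[, 3], , drop = FALSE] - p1
  e3 <- nodes[elems[, 4], , drop = FALSE] - p1
  c23 <- .cross3(e2, e3)
  det <- rowSums(e1 * c23)              # = 6 V
  if (any(det <= 0)) {
    stop(sprintf("inverted element during assembly (element %d)", which(det <= 0)[1]))
  }
  g2 <- c23 / det
  g3 <- .cross3(e3, e1) / det
  g4 <- .cross3(e1, e2) / det
  list(G = list(-(g2 + g3 + g4), g2, g3, g4), V = det / 6)
}

# constant-strain-tet stiffness for an isotropic material, E = 1, given nu,
# restricted to element subset `which_e`
.assemble_unit <- function(nodes, elems, which_e, nu) {
  elems <- elems[which_e, , drop = FALSE]
  if (nrow(elems) == 0L) {
    nd <- 3L * nrow(nodes)
    return(sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                        dims = c(nd, nd)))
  }
  gd <- .tet_gradients(nodes, elems)
  G <- gd$G; V <- gd$V
  lm <- .lame(1, nu); lambda <- lm[1]; mu <- lm[2]
  ne <- nrow(elems)
  nd <- 3L * nrow(nodes)
  ii <- jj <- integer(144L * ne)
  xx <- numeric(144L * ne)
  pos <- 0L
  for (a in 1:4) for (b in 1:4) {
    dot_ab <- rowSums(G[[a]] * G[[b]])
    ia <- 3L * (elems[, a] - 1L)
    jb <- 3L * (elems[, b] - 1L)
    for (p in 1:3) for (q in 1:3) {
      val <- V * (lambda * G[[a]][, p] * G[[b]][, q] +
                  mu * G[[a]][, q] * G[[b]][, p] +
                  (if (p == q) mu * dot_ab else 0))
      idx <- pos + seq_len(ne)
      ii[idx] <- ia + p
      jj[idx] <- jb + q
      xx[idx] <- val
      pos <- pos + ne
    }
  }
  sparseMatrix(i = ii, j = jj, x = xx, dims = c(nd, nd))
}

#' Precompute the finite-element operator of a mesh
#'
#' Assembles the per-tissue unit-modulus stiffness matrices once; the actual
#' stiffness for any material model is then the cheap combination
#' \code{E_B * K_bone + E_s * K_suture}.  Use this when the same mesh is
#' simulated under many material parameter combinations (design of
#' experiments, calibration).
#'
#' @param mesh a [tet_mesh()]
#' @param nu_B,nu_s Poisson ratios baked into the operator (held fixed during
#'   calibration)
#' @return object of class \code{fem_model}
#' @export
fem_model <- function(mesh, nu_B = 0.22, nu_s = 0.45) {
  structure(list(
    mesh = mesh, nu_B = nu_B, nu_s = nu_s,
    K_bone = .assemble_unit(mesh$nodes, mesh$elems, mesh$labels == "bone", nu_B),
    K_suture = .assemble_unit(mesh$nodes, mesh$elems, mesh$labels == "suture", nu_s),
    ndof = 3L * nrow(mesh$nodes)), class = "fem_model")
}

#' Assemble the global stiffness matrix
#'
#' Standard constant-strain linear-tetrahedron assembly.  Per-element Young's
#' modulus is selected by the tissue label (E_B for bone, E_s for suture) and
#' multiplied by the supplied per-label scale (e.g. a time-dependent
#' relaxation factor).  The unconstrained matrix is symmetric positive
#' semidefinite with exactly six rigid-body zero-energy modes.
#'
#' @param mesh a [tet_mesh()] (or a prebuilt [fem_model()])
#' @param materials a [material_model()]
#' @param modulus_scale named numeric, scale per label
#'   (default \code{c(bone = 1, suture = 1)})
#' @return sparse symmetric 3n x 3n matrix (dgCMatrix)
#' @export
assemble_stiffness <- function(mesh, materials,
                               modulus_scale = c(bone = 1, suture = 1)) {
  model <- if (inherits(mesh, "fem_model")) mesh else {
    fem_model(mesh, nu_B = materials$nu_B, nu_s = materials$nu_s)
  }
  materials$E_B * modulus_scale[["bone"]] * model$K_bone +
    materials$E_s * modulus_scale[["suture"]] * model$K_suture
}

.set_dofs <- function(node_idx) {
  as.vector(t(outer(3L * (node_idx - 1L), 1:3, `+`)))
}

#' Static linear solve with prescribed displacements
#'
#' Solves K u = f with Dirichlet constraints imposed by row/column
#' elimination (exact, no penalty), which is what makes the affine patch test
#' reproduce constant strain fields to machine precision.
#'
#' @param K stiffness matrix (3n x 3n sparse)
#' @param forces numeric load vector of length 3n (or NULL for zero)
#' @param fixed_dofs integer dof indices (dof = 3 * (node - 1) + component)
#' @param fixed_values prescribed displacements at \code{fixed_dofs}
#'   (default zero)
#' @return displacement vector of length 3n
#' @export
solve_static <- function(K, forces = NULL, fixed_dofs, fixed_values = NULL) {
  nd <- nrow(K)
  if (is.null(forces)) forces <- numeric(nd)
  if (is.null(fixed_values)) fixed_values <- numeric(length(fixed_dofs))
  stopifnot(length(fixed_values) == length(fixed_dofs))
  free <- setdiff(seq_len(nd), fixed_dofs)
  if (!length(fixed_dofs)) stop("unconstrained system: no fixed dofs")
  u <- numeric(nd)
  u[fixed_dofs] <- fixed_values
  rhs <- forces[free] - as.numeric(K[free, fixed_dofs, drop = FALSE] %*% fixed_values)
  Kff <- forceSymmetric(K[free, free, drop = FALSE])
  ch <- tryCatch(Cholesky(Kff, LDL = FALSE, perm = TRUE),
                 error = function(e) stop("singular constrained system: ", conditionMessage(e)))
  u[free] <- as.numeric(solve(ch, rhs))
  u
}

# Woodbury solve of (g * K + A diag(k) A^T) x = rhs using a cached Cholesky
# factor of K.  A is ndof x ns dense (ns = number of active springs).
.solve_spring_system <- function(chol_K, g, A, kvec, rhs) {
  if (is.null(A) || ncol(A) == 0L) {
    return(as.numeric(solve(chol_K, rhs)) / g)
  }
  Y <- as.matrix(solve(chol_K, cbind(rhs, A))) / g
  y0 <- Y[, 1]
  Z <- Y[, -1, drop = FALSE]
  Msmall <- diag(1 / kvec, ncol(A)) + crossprod(A, Z)
  as.numeric(y0 - Z %*% base::solve(Msmall, crossprod(A, y0)))
}

.default_time_grid <- function(times, n_substeps = 60L, t_min = 0.002) {
  t_max <- max(times)
  if (t_max <= 0) return(sort(unique(times)))
  internal <- 10^seq(log10(t_min), log10(t_max), length.out = n_substeps)
  sort(unique(c(times, internal[internal < t_max])))
}

#' Quasi-static viscoelastic simulation of spring distraction
#'
#' Solves the instantaneous elastic problem at t = 0 (spring insertion) and
#' advances the hereditary viscoelastic response with the recursive
#' internal-variable exponential update, one variable per Prony term,
#' re-equilibrating the spring forces against the relaxing structure at every
#' step.  Relaxation acts as a scalar multiplier on the full isotropic
#' stiffness (constant Poisson ratio).  Each spring exerts a compressive
#' force k * (free_length - d) along the line joining the current deformed
#' centroids of its two groove node sets, distributed evenly over the groove
#' nodes; springs push only (the force is dropped if the opening reaches the
#' free length).
#'
#' @param model a [fem_model()] or [tet_mesh()]
#' @param materials a [material_model()]
#' @param springs list of springs, each a list with elements \code{spec}
#'   (a [spring_spec()]) and \code{sets} (character pair naming the two
#'   groove node sets of the mesh)
#' @param times output times in days, sorted, starting at 0 (insertion)
#' @param fixed_sets node sets fully constrained (default \code{"base"})
#' @param fixed_dofs extra dof indices to constrain (e.g. all lateral dofs of
#'   the bar surrogate)
#' @param n_substeps number of log-spaced internal integration steps
#' @param max_iter cap on spring/structure equilibrium iterations per step
#' @param tol relative convergence tolerance on the spring openings
#' @return object of class \code{sac_sim}: list with \code{times},
#'   \code{openings} (springs x times matrix, mm), \code{U} (list of n x 3
#'   displacement fields at the output times), \code{spring_names},
#'   \code{residuals} (per-step equilibrium residuals)
#' @export
solve_quasistatic <- function(model, materials, springs, times = c(0, 1, 28),
                              fixed_sets = "base", fixed_dofs = integer(0),
                              n_substeps = 60L, max_iter = 50L, tol = 1e-10) {
  if (inherits(model, "tet_mesh")) {
    model <- fem_model(model, nu_B = materials$nu_B, nu_s = materials$nu_s)
  }
  mesh <- model$mesh
  .check_materials(materials)
  if (is.unsorted(times) || times[1] != 0) stop("times must be sorted with times[1] = 0")
  fixed <- unique(c(unlist(lapply(fixed_sets, function(s) {
    idx <- mesh$node_sets[[s]]
    if (is.null(idx) || !length(idx)) stop("fixed node set '", s, "' is missing or empty")
    .set_dofs(idx)
  })), as.integer(fixed_dofs)))
  nd <- model$ndof
  free <- setdiff(seq_len(nd), fixed)
  free_pos <- integer(nd); free_pos[free] <- seq_along(free)

  K <- materials$E_B * model$K_bone + materials$E_s * model$K_suture
  Kff <- forceSymmetric(K[free, free, drop = FALSE])
  ch <- tryCatch(Cholesky(Kff, LDL = FALSE, perm = TRUE),
                 error = function(e) stop("singular constrained system: ", conditionMessage(e)))

  sp <- lapply(springs, function(s) {
    stopifnot(inherits(s$spec, "spring_spec"), length(s$sets) == 2L)
    iA <- mesh$node_sets[[s$sets[1]]]
    iB <- mesh$node_sets[[s$sets[2]]]
    if (is.null(iA) || is.null(iB) || !length(iA) || !length(iB)) {
      stop("spring groove node set missing or empty: ", paste(s$sets, collapse = "/"))
    }
    list(spec = s$spec, iA = iA, iB = iB,
         dA = .set_dofs(iA), dB = .set_dofs(iB))
  })
  ns <- length(sp)
  nodes <- mesh$nodes

  gap <- function(u_full) {
    vapply(sp, function(s) {
      cA <- colMeans(nodes[s$iA, , drop = FALSE] +
                       matrix(u_full[s$dA], ncol = 3, byrow = TRUE))
      cB <- colMeans(nodes[s$iB, , drop = FALSE] +
                       matrix(u_full[s$dB], ncol = 3, byrow = TRUE))
      c(cB - cA, sqrt(sum((cB - cA)^2)))
    }, numeric(4))
  }
  spring_vec <- function(s, n_hat) {
    a <- numeric(length(free))
    wB <- rep(n_hat / length(s$iB), times = length(s$iB))
    wA <- rep(n_hat / length(s$iA), times = length(s$iA))
    pb <- free_pos[s$dB]; pa <- free_pos[s$dA]
    ok_b <- pb > 0L; ok_a <- pa > 0L
    a[pb[ok_b]] <- a[pb[ok_b]] + wB[ok_b]
    a[pa[ok_a]] <- a[pa[ok_a]] - wA[ok_a]
    a
  }

  ai <- materials$alpha_G * materials$prony$alpha
  ti <- materials$alpha_tau * materials$prony$tau
  a_inf <- 1 - sum(ai)
  np <- length(ai)

  grid <- .default_time_grid(times, n_substeps = n_substeps)
  u <- numeric(length(free))
  u_full <- numeric(nd)
  q <- replicate(np, numeric(length(free)), simplify = FALSE)

  L0 <- vapply(sp, function(s) s$spec$free_length, numeric(1))
  kv <- vapply(sp, function(s) s$spec$stiffness, numeric(1))

  equilibrate <- function(g_eff, rhs_hist, u_start) {
    uu <- u_start
    uu_full <- numeric(nd); uu_full[free] <- uu
    d_prev <- rep(Inf, ns)
    resid <- NA_real_
    for (it in seq_len(max_iter)) {
      gp <- gap(uu_full)
      d_cur <- gp[4, ]
      active <- kv > 0 & (L0 - d_cur) > -1e-9 * L0
      if (!any(active)) {
        uu <- .solve_spring_system(ch, g_eff, NULL, numeric(0), rhs_hist)
      } else {
        A <- vapply(which(active), function(j) {
          spring_vec(sp[[j]], gp[1:3, j] / max(gp[4, j], 1e-12))
        }, numeric(length(free)))
        A <- matrix(A, ncol = sum(active))
        kk <- kv[active]
        const <- kk * (L0[active] - d_cur[active] + as.numeric(base::crossprod(A, uu)))
        rhs <- rhs_hist + as.numeric(A %*% const)
        uu <- .solve_spring_system(ch, g_eff, A, kk, rhs)
      }
      uu_full[free] <- uu
      d_new <- gap(uu_full)[4, ]
      if (max(abs(d_new - d_prev)) < tol * max(L0, 1)) {
        resid <- max(abs(d_new - d_prev))
        return(list(u = uu, u_full = uu_full, d = d_new, resid = resid))
      }
      d_prev <- d_new
    }
    stop(sprintf("spring/structure equilibrium did not converge in %d iterations (residual %.3g mm)",
                 max_iter, max(abs(d_new - d_prev))))
  }

  out_idx <- match(times, grid)
  openings <- matrix(NA_real_, ns, length(times))
  U <- vector("list", length(times))
  residuals <- numeric(0)

  # instantaneous solve at t = 0 (g(0) = 1 by construction); the internal
  # variables pick up the full instantaneous strain, q_i(0+) = alpha_i' u0
  st <- equilibrate(1, numeric(length(free)), u)
  u <- st$u; u_full <- st$u_full
  for (i in seq_len(np)) q[[i]] <- ai[i] * u
  residuals <- c(residuals, st$resid)
  if (1L %in% out_idx) {
    j <- which(out_idx == 1L)
    openings[, j] <- st$d
    U[[j]] <- matrix(u_full, ncol = 3, byrow = TRUE)
  }

  if (length(grid) > 1L) {
    for (step in 2:length(grid)) {
      dt <- grid[step] - grid[step - 1]
      x <- dt / ti
      h <- ifelse(x > 1e-8, -expm1(-x) / x, 1 - x / 2)
      e <- exp(-x)
      g_eff <- a_inf + sum(ai * h)
      hist_vec <- numeric(length(free))
      for (i in seq_len(np)) hist_vec <- hist_vec + (e[i] * q[[i]] - ai[i] * h[i] * u)
      rhs_hist <- if (np) -as.numeric(Kff %*% hist_vec) else numeric(length(free))
      u_old <- u
      st <- equilibrate(g_eff, rhs_hist, u)
      u <- st$u; u_full <- st$u_full
      residuals <- c(residuals, st$resid)
      du <- u - u_old
      for (i in seq_len(np)) q[[i]] <- e[i] * q[[i]] + ai[i] * h[i] * du
      if (step %in% out_idx) {
        j <- which(out_idx == step)
        openings[, j] <- st$d
        U[[j]] <- matrix(u_full, ncol = 3, byrow = TRUE)
      }
    }
  }

  structure(list(times = times, openings = openings, U = U,
                 spring_names = vapply(sp, function(s) s$spec$name, character(1)),
                 residuals = residuals),
            class = "sac_sim")
}

#' @export
print.sac_sim <- function(x, ...) {
  cat("<sac_sim> openings (mm):\n")
  m <- x$openings
  dimnames(m) <- list(x$spring_names, paste0("t=", x$times, "d"))
  print(round(m, 3))
  invisible(x)
}

#' Deformed mesh at an output time of a simulation
#' @param mesh the simulated [tet_mesh()]
#' @param sim a \code{sac_sim} from [solve_quasistatic()]
#' @param time one of \code{sim$times}
#' @return the mesh with displaced nodes
#' @export
deformed_mesh <- function(mesh, sim, time) {
  j <- match(time, sim$times)
  if (is.na(j)) stop("time not among the simulation output times")
  out <- mesh
  out$nodes <- mesh$nodes + sim$U[[j]]
  out
}
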