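# Independent oracles and fixture builders shared across the suite.

# --- analytic elastic energy of a single linear tetrahedron ----------------
# Displacement is affine inside the element; the energy is
# V * (lambda/2 tr(eps)^2 + mu sum(eps^2)) with eps from the fitted gradient.
tet_energy <- function(coords, U, E, nu) {
  X <- cbind(1, coords)
  coefs <- solve(X, U)                      # rows 2:4 = d u_i / d x_j (j rows)
  H <- t(coefs[2:4, ])                      # H[i, j] = d u_i / d x_j
  eps <- (H + t(H)) / 2
  V <- abs(det(coords[2:4, ] - matrix(coords[1, ], 3, 3, byrow = TRUE))) / 6
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  V * (lambda / 2 * sum(diag(eps))^2 + mu * sum(eps^2))
}

# exact Hessian of the (quadratic) energy by central differences
tet_stiffness_oracle <- function(coords, E, nu, h = 1e-3) {
  K <- matrix(0, 12, 12)
  for (i in 1:12) for (j in 1:12) {
    pert <- function(si, sj) {
      U <- matrix(0, 4, 3)
      U[ceiling(i / 3), ((i - 1) %% 3) + 1] <- U[ceiling(i / 3), ((i - 1) %% 3) + 1] + si * h
      U[ceiling(j / 3), ((j - 1) %% 3) + 1] <- U[ceiling(j / 3), ((j - 1) %% 3) + 1] + sj * h
      tet_energy(coords, U, E, nu)
    }
    K[i, j] <- (pert(1, 1) - pert(1, -1) - pert(-1, 1) + pert(-1, -1)) / (4 * h^2)
  }
  K
}

# --- closed-form standard-linear-solid response under spring load ----------
# Bar of instantaneous axial stiffness k_bar relaxing with a single Prony
# term (alpha' = alpha_G * alpha1, tau' = alpha_tau * tau1), loaded by a
# compressed spring (stiffness k, effective free length L0_eff beyond the
# initial gap).  Displacement of the loaded end:
#   u(t) = u_inf + (u_0 - u_inf) exp(-t / tau_eff)
sls_opening_oracle <- function(t, k, k_bar, L0_eff, alpha1, tau1,
                               alpha_G = 1, alpha_tau = 1) {
  ap <- alpha_G * alpha1
  g0 <- 1
  g_inf <- 1 - ap
  tau_p <- alpha_tau * tau1
  u0 <- k * L0_eff / (k + g0 * k_bar)
  u_inf <- k * L0_eff / (k + g_inf * k_bar)
  tau_eff <- tau_p * (k + g0 * k_bar) / (k + g_inf * k_bar)
  u_inf + (u0 - u_inf) * exp(-t / tau_eff)
}

# bar surrogate runner: nu = 0 and all lateral dofs fixed makes the axial
# stiffness exactly E * area / length
run_bar_surrogate <- function(E = 100, L = 20, area = 0.2, k = 0.5, L0 = 60,
                              alpha1 = 0.5, tau1 = 1, alpha_G = 1, alpha_tau = 1,
                              times = c(0, 1, 28), n_substeps = 60) {
  bar <- generate_bar(length_mm = L, area_mm2 = area, n_layers = 4)
  mats <- material_model(E_B = E, E_s = E, nu_B = 0, nu_s = 0,
                         prony = data.frame(alpha = alpha1, tau = tau1),
                         alpha_G = alpha_G, alpha_tau = alpha_tau)
  lateral <- as.vector(vapply(seq_len(nrow(bar$nodes)),
                              function(i) 3L * (i - 1L) + 2:3, integer(2)))
  sim <- solve_quasistatic(bar, mats,
                           list(list(spec = spring_spec("T", k, L0),
                                     sets = c("base", "end"))),
                           times = times, fixed_dofs = lateral,
                           n_substeps = n_substeps)
  list(sim = sim, k_bar = E * area / L, d0 = L)
}

# --- structured block mesh (patch test fixture) ----------------------------
make_block <- function(nx = 2, ny = 2, nz = 2, lx = 1, ly = 1, lz = 1) {
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  zs <- seq(0, lz, length.out = nz + 1)
  nid <- function(i, j, k) i + (nx + 1) * ((j - 1) + (ny + 1) * (k - 1))
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  hexes <- expand.grid(i = 1:nx, j = 1:ny, k = 1:nz)
  tets <- do.call(rbind, lapply(seq_len(nrow(hexes)), function(r) {
    i <- hexes$i[r]; j <- hexes$j[r]; k <- hexes$k[r]
    n0 <- nid(i, j, k);     n1 <- nid(i + 1, j, k)
    n2 <- nid(i + 1, j + 1, k); n3 <- nid(i, j + 1, k)
    n4 <- nid(i, j, k + 1); n5 <- nid(i + 1, j, k + 1)
    n6 <- nid(i + 1, j + 1, k + 1); n7 <- nid(i, j + 1, k + 1)
    rbind(c(n0, n1, n2, n6), c(n0, n2, n3, n6), c(n0, n3, n7, n6),
          c(n0, n7, n4, n6), c(n0, n4, n5, n6), c(n0, n5, n1, n6))
  }))
  tets <- orient_tets(tets, nodes)
  boundary <- which(nodes[, 1] %in% range(xs) | nodes[, 2] %in% range(ys) |
                      nodes[, 3] %in% range(zs))
  tet_mesh(nodes, tets, node_sets = list(boundary = boundary))
}

# --- UV-sphere / ellipsoid surfaces ----------------------------------------
make_uv_sphere <- function(r = 1, n_u = 48, n_v = 24, axes = c(1, 1, 1)) {
  vs <- seq(-pi / 2, pi / 2, length.out = n_v + 1)
  us <- 2 * pi * (seq_len(n_u) - 1) / n_u
  nid <- function(k, j) {
    if (j == 1) return(1L)                         # south pole
    if (j == n_v + 1) return(n_u * (n_v - 1) + 2L) # north pole
    ((k - 1L) %% n_u) + 1L + n_u * (j - 2L) + 1L
  }
  verts <- rbind(c(0, 0, -r),
                 do.call(rbind, lapply(2:n_v, function(j) {
                   cbind(r * cos(vs[j]) * cos(us), r * cos(vs[j]) * sin(us),
                         r * sin(vs[j]))
                 })),
                 c(0, 0, r))
  faces <- list()
  for (k in seq_len(n_u)) {
    faces[[length(faces) + 1]] <- c(nid(k, 1), nid(k + 1, 2), nid(k, 2))
    faces[[length(faces) + 1]] <- c(nid(k, n_v + 1), nid(k, n_v), nid(k + 1, n_v))
  }
  for (j in 2:(n_v - 1)) for (k in seq_len(n_u)) {
    a <- nid(k, j); b <- nid(k + 1, j); cc <- nid(k + 1, j + 1); d <- nid(k, j + 1)
    faces[[length(faces) + 1]] <- c(a, b, cc)
    faces[[length(faces) + 1]] <- c(a, cc, d)
  }
  verts <- sweep(verts, 2, axes, `*`)
  tri_surface(verts, do.call(rbind, faces))
}

# small operated patient fixture (coarse, fast)
make_test_patient <- function(seed = 7, CI = 70, scale = 1) {
  p <- calvarium_params(OFD_mm = 140 * scale, BPD_mm = 140 * CI / 100 * scale,
                        height_mm = 78 * scale, thickness_mm = 1.0 * scale,
                        suture_width_mm = 8 * scale)
  mesh <- apply_surgery(generate_calvarium(p), surgical_plan())
  springs <- list(list(spec = spring_catalog()$S12,
                       sets = c("ant_groove_L", "ant_groove_R")),
                  list(spec = spring_catalog()$S12,
                       sets = c("post_groove_L", "post_groove_R")))
  list(mesh = mesh, springs = springs)
}
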