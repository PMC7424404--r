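test_that("relaxation factor matches the scaled Prony arithmetic", {
  m1 <- material_model()                              # alpha = 0.5, tau = 1 d
  expect_identical(relaxation_factor(m1, 0), 1)
  m2 <- material_model(prony = data.frame(alpha = 0.5, tau = 10))
  expect_equal(relaxation_factor(m2, Inf), 0.5, tolerance = 1e-15)
  expect_equal(relaxation_factor(m2, 10), 0.5 + 0.5 * exp(-1), tolerance = 1e-12)
  # population scales: alpha_i' = alpha_G alpha_i, tau_i' = alpha_tau tau_i
  m3 <- material_model(prony = data.frame(alpha = 0.5, tau = 10),
                       alpha_G = 1.1, alpha_tau = 2)
  expect_equal(relaxation_factor(m3, c(0, 5, 40)),
               (1 - 0.55) + 0.55 * exp(-c(0, 5, 40) / 20), tolerance = 1e-12)
  expect_identical(relaxation_factor(m3, 0), 1)       # g(0) = 1 for any alpha_G
  expect_error(material_model(prony = data.frame(alpha = 0.9, tau = 1),
                              alpha_G = 1.2), "below 1")
  expect_error(relaxation_factor(m1, -1), "non-negative")
})

test_that("single-tet stiffness equals the energy-Hessian oracle", {
  for (nu in c(0, 0.22, 0.45)) {
    coords <- rbind(c(0, 0, 0), c(2, 0.3, 0), c(0.2, 1.5, 0.1), c(0.4, 0.2, 1.8))
    mesh <- tet_mesh(coords, matrix(1:4, 1))
    mats <- material_model(E_B = 600, E_s = 600, nu_B = nu, nu_s = nu)
    K <- as.matrix(assemble_stiffness(mesh, mats))
    K_oracle <- tet_stiffness_oracle(coords, E = 600, nu = nu)
    expect_equal(K, K_oracle, tolerance = 1e-10)
  }
})

test_that("unconstrained stiffness has exactly six rigid-body zero modes", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh <- tet_mesh(coords, matrix(1:4, 1))
  K <- as.matrix(assemble_stiffness(mesh, material_model()))
  expect_equal(K, t(K), tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(ev)
  expect_equal(sum(abs(ev) < 1e-10 * scale), 6)
  expect_true(all(ev > -1e-10 * scale))               # positive semidefinite
  # explicit rigid modes: translations and linearized rotations
  block <- make_block(2, 2, 2)
  Kb <- assemble_stiffness(block, material_model())
  nrmK <- max(abs(Kb))
  for (tr in 1:3) {
    u <- rep(0, 3 * nrow(block$nodes)); u[seq(tr, length(u), by = 3)] <- 1
    expect_lt(max(abs(Kb %*% u)), 1e-10 * nrmK * sqrt(sum(u^2)))
  }
  for (ax in 1:3) {
    omega <- c(0, 0, 0); omega[ax] <- 1
    rot <- t(apply(block$nodes, 1, function(p) c(omega[2] * p[3] - omega[3] * p[2],
                                                 omega[3] * p[1] - omega[1] * p[3],
                                                 omega[1] * p[2] - omega[2] * p[1])))
    u <- as.vector(t(rot))
    expect_lt(max(abs(Kb %*% u)), 1e-9 * nrmK * sqrt(sum(u^2)))
  }
})

test_that("affine patch test is exact", {
  block <- make_block(3, 3, 3, lx = 2, ly = 1.5, lz = 1)
  mats <- material_model(E_B = 421, nu_B = 0.22)
  K <- assemble_stiffness(block, mats)
  FF <- rbind(c(1e-3, 4e-4, -2e-4), c(2e-4, -5e-4, 1e-4), c(-1e-4, 3e-4, 6e-4))
  u_affine <- block$nodes %*% t(FF)
  bd <- block$node_sets$boundary
  fixed <- as.vector(vapply(bd, function(i) 3L * (i - 1L) + 1:3, integer(3)))
  u <- solve_static(K, NULL, fixed, as.vector(t(u_affine[bd, ])))
  expect_equal(matrix(u, ncol = 3, byrow = TRUE), u_affine, tolerance = 1e-10)
})

test_that("inverted elements are reported by name at assembly", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh <- tet_mesh(coords, matrix(1:4, 1))
  mesh$nodes[4, 3] <- -1                  # invert after construction
  expect_error(assemble_stiffness(mesh, material_model()), "element 1")
})

test_that("bar surrogate: instantaneous spring equilibrium is exact", {
  br <- run_bar_surrogate(E = 100, L = 20, area = 0.2, k = 0.5, L0 = 60,
                          times = c(0, 1))
  d <- br$sim$openings[1, 1]
  u_exp <- 0.5 * (60 - br$d0) / (0.5 + br$k_bar)
  expect_equal(d - br$d0, u_exp, tolerance = 1e-8 * u_exp)
  # zero spring stiffness: no load, opening equals the initial gap
  b0 <- run_bar_surrogate(k = 0, times = c(0, 1))
  expect_equal(b0$sim$openings[1, ], c(20, 20), tolerance = 1e-12)
  expect_lt(max(abs(b0$sim$U[[1]])), 1e-14)
})

test_that("bar surrogate matches the standard-linear-solid solution in time", {
  times <- c(0, 0.25, 0.5, 1, 2, 4, 8, 16, 28)
  br <- run_bar_surrogate(E = 100, L = 20, area = 0.2, k = 0.5, L0 = 60,
                          alpha1 = 0.5, tau1 = 1, alpha_G = 1.1, alpha_tau = 2,
                          times = times, n_substeps = 80)
  d <- br$sim$openings[1, ]
  u_oracle <- sls_opening_oracle(times, k = 0.5, k_bar = br$k_bar,
                                 L0_eff = 60 - br$d0, alpha1 = 0.5, tau1 = 1,
                                 alpha_G = 1.1, alpha_tau = 2)
  expect_lt(max(abs((d - br$d0) - u_oracle) / u_oracle), 0.005)
  # long-time limit: k L0 / (k + g_inf k_bar)
  g_inf <- 1 - 1.1 * 0.5
  u_inf <- 0.5 * (60 - br$d0) / (0.5 + g_inf * br$k_bar)
  expect_equal(d[length(d)] - br$d0, u_inf, tolerance = 0.005 * u_inf)
  # openings are monotone non-decreasing under relaxation, below free length
  expect_true(all(diff(d) >= -1e-10))
  expect_true(all(d <= 60 + 1e-9))
})

test_that("halving the time step changes openings by less than 0.1%", {
  br1 <- run_bar_surrogate(alpha_G = 1.1, alpha_tau = 2, n_substeps = 60)
  br2 <- run_bar_surrogate(alpha_G = 1.1, alpha_tau = 2, n_substeps = 120)
  expect_lt(max(abs(br1$sim$openings - br2$sim$openings) /
                  (br1$sim$openings - br1$d0)), 0.001)
})

test_that("spring force balances the base reaction (quasi-static consistency)", {
  br <- run_bar_surrogate(E = 100, L = 20, area = 0.2, k = 0.5, L0 = 60,
                          times = c(0, 1))
  bar <- generate_bar(20, 0.2, 4)
  mats <- material_model(E_B = 100, E_s = 100, nu_B = 0, nu_s = 0)
  K <- assemble_stiffness(bar, mats)
  u <- as.vector(t(br$sim$U[[1]]))
  reaction <- (K %*% u)[3 * (bar$node_sets$base - 1) + 1]
  spring_force <- 0.5 * (60 - br$sim$openings[1, 1])
  expect_equal(-sum(reaction), spring_force, tolerance = 1e-8 * spring_force)
})

test_that("quasistatic solver validates its inputs", {
  bar <- generate_bar(20, 0.2, 2)
  mats <- material_model()
  sp <- list(list(spec = spring_spec(), sets = c("base", "end")))
  expect_error(solve_quasistatic(bar, mats, sp, times = c(1, 0)), "sorted")
  expect_error(solve_quasistatic(bar, mats,
                                 list(list(spec = spring_spec(), sets = c("base", "nope"))),
                                 times = c(0, 1)), "missing or empty")
  expect_error(solve_quasistatic(bar, mats, sp, times = c(0, 1),
                                 fixed_sets = "nothere"), "missing or empty")
})
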