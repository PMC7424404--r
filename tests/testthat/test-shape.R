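test_that("scalp offset displaces along normals by the requested amount", {
  sph <- make_uv_sphere(r = 50, n_u = 48, n_v = 24)
  expect_equal(offset_scalp(sph, 0)$vertices, sph$vertices)
  off <- offset_scalp(sph, 3)
  radii <- sqrt(rowSums(off$vertices^2))
  expect_equal(mean(radii), 53, tolerance = 0.01)
  expect_true(all(abs(radii - 53) < 0.2))
  expect_gt(surface_enclosed_volume(off), surface_enclosed_volume(sph))
  expect_error(offset_scalp(sph, -1), "non-negative")
})

test_that("ICP: identity, known rigid transform recovery, monotone RMSE", {
  surf <- make_uv_sphere(r = 50, n_u = 40, n_v = 20, axes = c(1.3, 0.9, 1))
  pts <- surf$vertices
  self <- icp_register(pts, surf$vertices)
  expect_lt(self$rmse, 1e-10)
  expect_equal(self$R, diag(3), tolerance = 1e-8)
  # rotate 20 degrees about z and translate, then recover
  th <- 20 * pi / 180
  R_true <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(pts %*% t(R_true), 2, c(4, -2, 3), `+`)
  coarse <- icp_register(moved, surf, max_iter = 100, tol = 1e-8)
  reg <- icp_register(coarse$transformed, surf$vertices, max_iter = 50, tol = 1e-14)
  expect_lt(reg$rmse, 1e-6)
  R_tot <- reg$R %*% coarse$R
  expect_equal(R_tot %*% R_true, diag(3), tolerance = 1e-5)
  expect_true(all(diff(coarse$rmse_history) < 1e-9))
  # degenerate input
  line <- cbind(1:10, 0, 0)
  expect_error(icp_register(line, pts), "collinear")
})

test_that("surface distance matches the analytic concentric-sphere field", {
  a <- make_uv_sphere(r = 100, n_u = 64, n_v = 32)
  b1 <- make_uv_sphere(r = 101, n_u = 64, n_v = 32)
  b3 <- make_uv_sphere(r = 103, n_u = 64, n_v = 32)
  same <- surface_distance(a, a, n_samples = 2000, seed = 1)
  expect_lt(same$rmse_mm, 1e-10)
  expect_equal(same$pct_below, 100)
  d1 <- surface_distance(a, b1, n_samples = 4000, seed = 1)
  expect_equal(d1$rmse_mm, 1, tolerance = 0.05)
  expect_equal(d1$pct_below, 100)
  d3 <- surface_distance(a, b3, n_samples = 4000, seed = 1)
  expect_equal(d3$rmse_mm, 3, tolerance = 0.05)
  expect_equal(d3$pct_below, 0)
  # near-symmetry on near-identical shapes
  d_ab <- surface_distance(a, b1, n_samples = 4000, seed = 2)$rmse_mm
  d_ba <- surface_distance(b1, a, n_samples = 4000, seed = 2)$rmse_mm
  expect_equal(d_ab, d_ba, tolerance = 0.05)
})

test_that("cranial index: sphere, ellipsoid, scale invariance", {
  sph <- make_uv_sphere(r = 60)
  expect_equal(cranial_index(sph)$CI_pct, 100, tolerance = 1e-9)
  ell <- make_uv_sphere(r = 1, axes = c(50, 35, 40))   # OFD 100, BPD 70
  ci <- cranial_index(ell)
  expect_equal(ci$OFD_mm, 100, tolerance = 1e-9)
  expect_equal(ci$BPD_mm, 70, tolerance = 1e-9)
  expect_equal(ci$CI_pct, 70, tolerance = 1e-9)
  scaled <- ell
  scaled$vertices <- 2.7 * ell$vertices
  expect_equal(cranial_index(scaled)$CI_pct, ci$CI_pct, tolerance = 1e-12)
  empty <- ell
  empty$vertices[, 3] <- empty$vertices[, 3] - 1000
  expect_error(cranial_index(empty), "base plane")
})

test_that("simulated spring expansion raises the cranial index over time", {
  pat <- make_test_patient()
  fm <- fem_model(pat$mesh)
  fw <- forward_openings(fm, truth_materials(), pat$springs, n_substeps = 40)
  ci_pre <- head_ci(pat$mesh)
  ci_fu1 <- head_ci(deformed_mesh(pat$mesh, fw$sim, 1))
  ci_fu2 <- head_ci(deformed_mesh(pat$mesh, fw$sim, 28))
  expect_lt(ci_pre, 80)                     # scaphocephalic regime
  expect_gt(ci_fu1, ci_pre)
  expect_gt(ci_fu2, ci_fu1)
})
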