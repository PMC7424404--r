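test_that("face-centered CCD has 2^k + 2k + 1 in-box points", {
  box4 <- parameter_box()
  d4 <- ccd_design(box4)
  expect_equal(nrow(d4), 25)
  expect_equal(nrow(unique(d4)), 25)
  for (nm in box4$names) {
    expect_true(all(d4[[nm]] >= box4$lower[nm] - 1e-12))
    expect_true(all(d4[[nm]] <= box4$upper[nm] + 1e-12))
  }
  box2 <- parameter_box(lower = c(a = 0, b = 1), upper = c(a = 1, b = 2),
                        baseline = c(a = 0.5, b = 1.5),
                        transform = c(a = "linear", b = "linear"))
  expect_equal(nrow(ccd_design(box2)), 9)
  # corners and axials sit on the bounds regardless of the factor coding
  Z <- attr(d4, "scaled")
  expect_true(all(abs(Z) %in% c(0, 1)))
})

test_that("quadratic response surfaces interpolate quadratic truths exactly", {
  box <- parameter_box()
  d <- ccd_design(box)
  Z <- attr(d, "scaled")
  y <- 2 + Z[, 1]^2 - 3 * Z[, 2] * Z[, 3]
  rs <- fit_response_surface(d, y, box)
  expect_lt(rs$residual_norm, 1e-8)
  cf <- rs$coefficients
  expect_equal(unname(cf["intercept"]), 2, tolerance = 1e-8)
  expect_equal(unname(cf["x1^2"]), 1, tolerance = 1e-8)
  expect_equal(unname(cf["x2:x3"]), -3, tolerance = 1e-8)
  expect_false(rs$active[4])                      # factor 4 screened as inert
  expect_equal(unname(cf["x4^2"]), 0)
  # surface evaluation reproduces the design responses
  expect_equal(predict_rs(rs, d), y, tolerance = 1e-8)
})

test_that("constant responses yield a constant surface", {
  box <- parameter_box()
  d <- ccd_design(box)
  rs <- fit_response_surface(d, rep(7, nrow(d)), box)
  expect_equal(unname(rs$coefficients["intercept"]), 7)
  expect_true(all(abs(rs$coefficients[-1]) < 1e-10))
  expect_false(any(rs$active))
})

test_that("local sensitivity: inert factors exactly zero, linear case analytic", {
  box <- parameter_box(lower = c(a = 1, b = 2, cc = 0, d = 0),
                       upper = c(a = 3, b = 6, cc = 1, d = 1),
                       baseline = c(a = 2, b = 4, cc = 0.5, d = 0.5),
                       transform = c(a = "linear", b = "linear",
                                     cc = "linear", d = "linear"))
  d_ <- ccd_design(box)
  y <- 5 * d_$a + 0.5 * d_$b                       # linear, independent of cc/d
  rs <- fit_response_surface(d_, y, box)
  S <- local_sensitivity(rs, box)
  expect_identical(unname(S[c("cc", "d")]), c(0, 0))
  y_ref <- 5 * 2 + 0.5 * 4
  expect_equal(unname(S["a"]), 5 * (3 - 1) / y_ref * 100, tolerance = 1e-6)
  expect_equal(unname(S["b"]), 0.5 * (6 - 2) / y_ref * 100, tolerance = 1e-6)
  # strictly decreasing dependence gives a negative sign
  rs_neg <- fit_response_surface(d_, 100 - 5 * d_$a, box)
  expect_lt(local_sensitivity(rs_neg, box)["a"], 0)
})

test_that("optimizer returns the baseline for baseline-consistent targets", {
  box <- parameter_box()
  d <- ccd_design(box)
  Z <- attr(d, "scaled")
  surfaces <- lapply(list(40 + 5 * Z[, 1] + Z[, 4], 50 + 4 * Z[, 1] - Z[, 3],
                          55 + 3 * Z[, 1] + 2 * Z[, 4]),
                     function(y) fit_response_surface(d, y, box))
  targets <- vapply(surfaces, function(s) predict_rs(s, box$baseline), numeric(1))
  opt <- optimize_materials(surfaces, targets, box, seed = 3)
  expect_equal(unname(opt$par), unname(box$baseline), tolerance = 1e-4)
  expect_lt(opt$objective, 1e-6)
  # optimality sanity: no CCD point beats the returned optimum
  obj_at <- function(x) sum((vapply(surfaces, function(s) predict_rs(s, x),
                                    numeric(1)) - targets)^2)
  ccd_objs <- apply(d, 1, obj_at)
  expect_lte(opt$objective, min(ccd_objs) + 1e-9)
})

test_that("population aggregation averages componentwise within the box", {
  box <- parameter_box()
  o1 <- structure(list(par = c(E_B = 400, E_s = 16, alpha_tau = 2, alpha_G = 1.1),
                       objective = 0), class = "optimized_material")
  o2 <- structure(list(par = c(E_B = 436, E_s = 20, alpha_tau = 4, alpha_G = 1.1),
                       objective = 0), class = "optimized_material")
  pop <- aggregate_population(list(o1, o2), box)
  expect_equal(unname(pop$mean["E_B"]), 418)
  expect_equal(unname(pop$sd["E_B"]), stats::sd(c(400, 436)))
  same <- aggregate_population(list(o1, o1), box)
  expect_equal(same$mean, o1$par)
  expect_equal(unname(same$sd), rep(0, 4))
  expect_error(aggregate_population(list()), "no optima")
})

test_that("parameter box validates bounds, baseline and coding", {
  expect_error(parameter_box(lower = c(E_B = 2000, E_s = 8, alpha_tau = 1, alpha_G = 1)),
               "lower < upper")
  expect_error(parameter_box(baseline = c(E_B = 5000, E_s = 16, alpha_tau = 1, alpha_G = 1)),
               "inside the box")
  # log-coded scaling round-trips
  box <- parameter_box()
  X <- ccd_design(box)
  Z <- springsim:::.box_scale(box, X[box$names])
  back <- springsim:::.box_unscale(box, Z)
  expect_equal(unname(as.matrix(X[box$names])), unname(back), tolerance = 1e-12)
})
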