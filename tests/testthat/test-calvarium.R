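test_that("parameter validation guards degenerate calvaria", {
  expect_error(generate_calvarium(calvarium_params(thickness_mm = 0)), "positive")
  expect_error(generate_calvarium(calvarium_params(OFD_mm = -1)), "positive")
  expect_error(calvarium_params(layers_through_thickness = 2) |> generate_calvarium(),
               "at least three")
  # sphere-like head rejected as non-scaphocephalic unless strict is off
  sphere_p <- calvarium_params(OFD_mm = 100, BPD_mm = 100, height_mm = 60)
  expect_error(generate_calvarium(sphere_p), "non-scaphocephalic")
  expect_s3_class(generate_calvarium(sphere_p, strict = FALSE), "tet_mesh")
})

test_that("generated shell is watertight with positive volumes and a base set", {
  m <- generate_calvarium()
  expect_true(all(tet_volumes(m) > 0))
  expect_true(is_watertight(m))
  expect_true(length(m$node_sets$base) > 0)
  expect_true(all(abs(m$nodes[m$node_sets$base, 3]) < 1e-6))
  # every through-thickness line crosses at least three element layers
  expect_gte(m$meta$params$layers_through_thickness, 3)
  expect_equal(nrow(m$elems),
               m$meta$n_cells * 6L)
})

test_that("meshed shell volume matches the analytic half-ellipsoid shell", {
  p <- calvarium_params()
  m <- generate_calvarium(p)
  expect_equal(sum(tet_volumes(m)), calvarium_shell_volume(p), tolerance = 0.05)
})

test_that("surgical plan invariants are enforced", {
  expect_error(surgical_plan(LAT_mm = 0), "positive")
  expect_error(surgical_plan(A_mm = 30, P_mm = 20), "A_mm < P_mm")
  expect_error(surgical_plan(A_mm = 25, P_mm = 90, LAT_mm = 80), "osteotomy span")
  expect_error(surgical_plan(craniectomy_width_mm = 30, osteotomy_offset_mm = 15),
               "clear of the craniectomy")
})

test_that("surgery removes bone, creates symmetric grooves clear of the base", {
  m <- generate_calvarium()
  op <- apply_surgery(m, surgical_plan())
  expect_lt(nrow(op$elems), nrow(m$elems))
  sets <- op$node_sets
  for (nm in c("ant_groove_L", "ant_groove_R", "post_groove_L", "post_groove_R")) {
    expect_gt(length(sets[[nm]]), 0)
    expect_length(intersect(sets[[nm]], sets$base), 0)
  }
  # left/right groove sets mirror each other across the sagittal plane
  for (pair in list(c("ant_groove_L", "ant_groove_R"),
                    c("post_groove_L", "post_groove_R"))) {
    L <- op$nodes[sets[[pair[1]]], , drop = FALSE]
    R <- op$nodes[sets[[pair[2]]], , drop = FALSE]
    L <- L[order(L[, 1], L[, 2], L[, 3]), ]
    R[, 2] <- -R[, 2]
    R <- R[order(R[, 1], R[, 2], R[, 3]), ]
    expect_equal(L, R, tolerance = 1e-9)
  }
  expect_true(is_watertight(op))
})

test_that("infeasible plans raise geometry errors", {
  m <- generate_calvarium()
  expect_error(apply_surgery(m, surgical_plan(LAT_mm = 200)),
               "exceeds the calvarium extent")
  expect_error(apply_surgery(generate_bar(10, 4, 3), surgical_plan()),
               "calvarium metadata")
})

test_that("bar fixture has exact volume and the expected node sets", {
  bar <- generate_bar(length_mm = 30, area_mm2 = 12, n_layers = 5)
  expect_equal(sum(tet_volumes(bar)), 30 * 12, tolerance = 1e-12)
  expect_equal(range(bar$nodes[bar$node_sets$base, 1]), c(0, 0))
  expect_equal(range(bar$nodes[bar$node_sets$end, 1]), c(30, 30))
})
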