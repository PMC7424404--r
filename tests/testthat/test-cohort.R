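test_that("cohort generation is a pure function of its seed", {
  c1 <- generate_cohort(n = 2, seed = 9)
  c2 <- generate_cohort(n = 2, seed = 9)
  expect_identical(cohort_table(c1), cohort_table(c2))
  c3 <- generate_cohort(n = 2, seed = 10)
  expect_false(identical(cohort_table(c1)$OP_IO, cohort_table(c3)$OP_IO))
})

test_that("zero measurement noise reproduces the forward-model openings", {
  co <- generate_cohort(n = 2, seed = 4, noise = noise_spec(opening_sd_mm = 0))
  for (rec in co) {
    expect_equal(rec$measured_openings$mm, rec$true_openings, tolerance = 1e-12)
  }
})

test_that("cohort records satisfy their invariants", {
  co <- generate_cohort(n = 4, seed = 6)
  for (rec in co) {
    expect_gte(rec$age_SAC_months, rec$age_CT_months)
    expect_gt(rec$V_CT_mm3, 0)
    expect_gte(rec$V_SAC_true_mm3, rec$V_CT_mm3)
    expect_true(all(rec$spring_models %in% names(spring_catalog())))
    mm <- rec$measured_openings$mm
    expect_true(all(mm >= 0 & mm <= 60))
    expect_true(all(diff(rec$true_openings) > 0))    # relaxation opens springs
  }
  tb <- cohort_table(co)
  expect_equal(nrow(tb), 4)
  expect_named(tb, c("patient_id", "age_CT", "age_SAC", "V_CT", "spring_ant",
                     "spring_post", "OP_IO", "OP_FU1", "OP_FU2"))
})

test_that("cohort CSV round-trips through the documented schema", {
  co <- generate_cohort(n = 2, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back$OP_FU2, cohort_table(co)$OP_FU2, tolerance = 1e-6)
})

test_that("patient meshes scale with the control volume", {
  co <- generate_cohort(n = 1, seed = 4)
  rec <- co[[1]]
  m1 <- patient_mesh(rec, 800)
  m2 <- patient_mesh(rec, 1100)
  v1 <- surface_enclosed_volume(mesh_surface(m1))
  v2 <- surface_enclosed_volume(mesh_surface(m2))
  expect_equal(v2 / v1, 1100 / 800, tolerance = 1e-9)
})
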