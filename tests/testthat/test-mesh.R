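test_that("tetrahedron volumes and orientation repair behave", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  good <- matrix(c(1, 2, 3, 4), 1)
  bad <- matrix(c(1, 3, 2, 4), 1)
  expect_equal(tet_volumes(list(nodes = nodes, elems = good)), 1 / 6)
  expect_lt(tet_volumes(list(nodes = nodes, elems = bad)), 0)
  fixed <- orient_tets(bad, nodes)
  expect_equal(tet_volumes(list(nodes = nodes, elems = fixed)), 1 / 6)
  expect_error(tet_mesh(nodes, bad), "non-positively oriented")
})

test_that("boundary extraction is closed and consistent with tet volumes", {
  bar <- generate_bar(length_mm = 10, area_mm2 = 4, n_layers = 3)
  expect_true(is_watertight(bar))
  surf <- mesh_surface(bar)
  # enclosed volume by divergence theorem equals the summed tet volumes
  expect_equal(surface_enclosed_volume(surf), sum(tet_volumes(bar)),
               tolerance = 1e-12)
  expect_equal(sum(tet_volumes(bar)), 10 * 4, tolerance = 1e-12)
})

test_that("subset_elements drops nodes and remaps node sets", {
  bar <- generate_bar(length_mm = 10, area_mm2 = 4, n_layers = 4)
  keep <- tet_volumes(bar) > 0
  keep[1:3] <- FALSE                      # drop the first layer prism
  sub <- subset_elements(bar, keep)
  expect_lt(nrow(sub$elems), nrow(bar$elems))
  expect_true(all(unlist(sub$node_sets) <= nrow(sub$nodes)))
  expect_true(all(tet_volumes(sub) > 0))
})

test_that("scale_mesh scales volumes cubically and keeps metadata consistent", {
  m <- generate_calvarium()
  s <- scale_mesh(m, 2)
  expect_equal(sum(tet_volumes(s)), 8 * sum(tet_volumes(m)), tolerance = 1e-12)
  expect_equal(s$meta$x_coronal, 2 * m$meta$x_coronal)
  expect_equal(s$meta$params$OFD_mm, 2 * m$meta$params$OFD_mm)
})

test_that("surface sampling is reproducible and lands on the surface", {
  sph <- make_uv_sphere(r = 10)
  p1 <- sample_surface_points(sph, 200, seed = 42)
  p2 <- sample_surface_points(sph, 200, seed = 42)
  expect_identical(p1, p2)
  radii <- sqrt(rowSums(p1^2))
  expect_true(all(radii <= 10 + 1e-9))     # samples lie on chordal facets
  expect_true(all(radii >= 10 * cos(pi / 48)^2))
})

test_that("STL round trip preserves the surface", {
  surf <- mesh_surface(generate_bar(5, 2, 2))
  path <- tempfile(fileext = ".stl")
  write_stl(surf, path)
  back <- read_stl(path)
  expect_equal(nrow(back$faces), nrow(surf$faces))
  expect_equal(surface_enclosed_volume(back), surface_enclosed_volume(surf),
               tolerance = 1e-6)
})

test_that("VTU writer emits a well-formed labeled grid", {
  m <- generate_bar(5, 2, 2)
  path <- tempfile(fileext = ".vtu")
  write_vtu(m, path, displacement = matrix(0, nrow(m$nodes), 3))
  txt <- readLines(path)
  expect_true(any(grepl("UnstructuredGrid", txt)))
  expect_true(any(grepl("tissue", txt)))
  doc <- xml2::read_xml(path)
  expect_equal(xml2::xml_name(doc), "VTKFile")
})
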