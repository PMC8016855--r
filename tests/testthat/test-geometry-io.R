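# Mesh container, PLY round trips, reflection, preprocessing, clipping,
# and surface-to-surface distance.

test_that("PLY round trips are lossless and dialects agree", {
  m <- bone_like_mesh(1)
  fb <- withr::local_tempfile(fileext = ".ply")
  fa <- withr::local_tempfile(fileext = ".ply")
  sc <- list(dist = sin(seq_len(nrow(m$vertices))))

  save_mesh(m, fb, dialect = "binary_le", scalars = sc)
  mb <- load_mesh(fb)
  expect_identical(mb$vertices, m$vertices)
  expect_identical(mb$faces, m$faces)
  expect_identical(attr(mb, "scalars")$dist, sc$dist)  # bit-exact

  save_mesh(m, fa, dialect = "ascii", scalars = sc)
  ma <- load_mesh(fa)
  expect_equal(ma$vertices, m$vertices, tolerance = 1e-15)
  expect_identical(ma$faces, m$faces)
  expect_equal(attr(ma, "scalars")$dist, sc$dist, tolerance = 1e-12)

  # tetrahedron identity
  tet <- tetra_mesh()
  save_mesh(tet, fb)
  expect_identical(load_mesh(fb)$vertices, tet$vertices)
  expect_identical(load_mesh(fb)$faces, tet$faces)
})

test_that("PLY loader flags unreferenced vertices and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property double x", "property double y",
               "property double z", "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "0 1 0", "5 5 5", "3 0 1 2"), f)
  expect_warning(m <- load_mesh(f), "not referenced")
  expect_equal(nrow(m$vertices), 4L)  # vertex retained

  bad <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1"), bad)
  expect_error(load_mesh(bad), "header")

  expect_error(save_mesh(
    surface_mesh(matrix(0, 1, 3), matrix(integer(0), 0, 3)),
    withr::local_tempfile(fileext = ".ply")), "empty")
})

test_that("reflection is an involution, an isometry, and flips side", {
  m <- bone_like_mesh(2)
  m$side <- "left"
  r <- reflect_mesh(m)
  expect_identical(r$side, "right")
  r2 <- reflect_mesh(r)
  expect_equal(r2$vertices, m$vertices, tolerance = 1e-12)
  expect_identical(r2$side, "left")

  # pairwise distances preserved
  idx <- c(1, 5, 20, 40)
  expect_equal(as.matrix(dist(m$vertices[idx, ])),
               as.matrix(dist(r$vertices[idx, ])), tolerance = 1e-12)

  # winding fixed: signed volume keeps its (positive) sign
  expect_gt(signed_volume(m), 0)
  expect_gt(signed_volume(r), 0)
})

test_that("preprocessing smooths noise and decimation preserves area", {
  s <- icosphere(10, 4)
  expect_identical(preprocess_mesh(s, smoothing_iterations = 0)$vertices,
                   s$vertices)

  set.seed(31)
  noisy <- icosphere(1, 4)
  noisy$vertices <- noisy$vertices +
    matrix(rnorm(length(noisy$vertices), 0, 0.05), ncol = 3)
  rms_radial <- function(m) sqrt(mean((sqrt(rowSums(m$vertices^2)) - 1)^2))
  expect_lt(rms_radial(taubin_smooth(noisy, 10)), rms_radial(noisy))

  d <- decimate_mesh(s, nrow(s$faces) / 2)
  expect_lte(nrow(d$faces), nrow(s$faces) / 2)
  expect_lt(abs(mesh_area(d) / mesh_area(s) - 1), 0.02)
  expect_silent(validate_mesh(d))

  expect_error(preprocess_mesh(s, target_face_count = 3), "target")
})

test_that("plane clipping is exact, open, and conserves area", {
  sp <- icosphere(30, 3, center = c(0, 0, 50))
  pl <- clip_plane(c(0, 0, 70), c(0, 0, 1))
  cl <- clip_mesh(sp, pl)
  expect_lte(max(cl$vertices[, 3]), 70 + 1e-9)

  # complementary clip: kept + removed = original
  comp <- clip_mesh(sp, clip_plane(c(0, 0, 70), c(0, 0, -1)))
  expect_equal(mesh_area(cl) + mesh_area(comp), mesh_area(sp),
               tolerance = 1e-6)

  # plane entirely below the mesh leaves it unchanged
  un <- clip_mesh(sp, clip_plane(c(0, 0, -100), c(0, 0, -1)))
  expect_equal(mesh_area(un), mesh_area(sp), tolerance = 1e-12)

  # clip exactly through vertices of a tetrahedron: no degenerate faces
  tet <- tetra_mesh()
  thru <- clip_mesh(tet, clip_plane(c(0, 0, 0), c(0, 0, 1)))
  expect_silent(validate_mesh(thru))
  ar <- face_normals(thru)$areas
  expect_true(all(ar > 1e-12))
  key <- apply(thru$faces, 1, function(r) paste(sort(r), collapse = "-"))
  expect_false(anyDuplicated(key) > 0)
})

test_that("surface distance matches analytic and brute-force oracles", {
  m <- bone_like_mesh(1)
  expect_equal(max(surface_to_surface_distance(m, m)), 0)

  # translated planar patch
  j <- make_joint(synthetic_joint_spec("plane_pair", radius_a = 1,
                                       gap = 1, resolution = 0.25))
  d <- surface_to_surface_distance(j$meshA, j$meshB)
  expect_equal(unname(range(d)), c(1, 1), tolerance = 1e-9)

  # concentric spheres r = 10, 12 -> 2.0 within mesh resolution
  d2 <- surface_to_surface_distance(icosphere(10, 2), icosphere(12, 4))
  expect_equal(mean(d2), 2, tolerance = 0.01)
  expect_true(all(abs(d2 - 2) < 0.05))

  # per-vertex equality against the independent oracle on small meshes
  q <- bone_like_mesh(1)
  tgt <- icosphere(8, 1, center = c(3, 1, -2))
  expect_equal(surface_to_surface_distance(q, tgt),
               oracle_surface_dist(q$vertices, tgt), tolerance = 1e-9)

  expect_error(surface_to_surface_distance(
    m, surface_mesh(matrix(0, 1, 3), matrix(integer(0), 0, 3))),
    "faces")
})
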