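# Correspondence-particle model: sampling, propagation, mean shape,
# particle mapping.

test_that("farthest-point sampling is nested with monotone coverage", {
  m <- icosphere(10, 4)
  cov_radius <- function(P) {
    idx <- farthest_point_sample(m$vertices, P, seed = 4)
    d2 <- matrix(Inf, nrow(m$vertices), 1)
    for (i in idx)
      d2 <- pmin(d2, rowSums(sweep(m$vertices, 2L, m$vertices[i, ])^2))
    sqrt(max(d2))
  }
  r <- vapply(c(128, 256, 512, 1024), cov_radius, 0)
  expect_true(all(diff(r) < 0))

  # nesting: the first P of a larger sample equal the smaller sample
  s256 <- farthest_point_sample(m$vertices, 256, seed = 4)
  s512 <- farthest_point_sample(m$vertices, 512, seed = 4)
  expect_identical(s512[1:256], s256)
})

test_that("identical and rigidly moved populations give identical particles", {
  m <- bone_like_mesh(2)
  mod <- build_correspondence_model(list(a = m, b = m, c = m), P = 64,
                                    seed = 2)
  expect_equal(mod$particles[[1]], mod$particles[[2]], tolerance = 1e-12)
  expect_equal(mod$mean_particles, mod$particles[[1]], tolerance = 1e-9)

  # rigid motions, after alignment, leave particle arrays identical
  mv <- apply_transform(rigid_transform(rot_z(8), c(2, 1, 0)), m)
  al <- apply_transform(icp_align(mv, m, max_iterations = 1500,
                                  rms_tolerance = 1e-14,
                                  seed = 2)$transform, mv)
  mod2 <- build_correspondence_model(list(a = m, b = al), P = 64,
                                     seed = 2)
  expect_equal(mod2$particles[[1]], mod2$particles[[2]],
               tolerance = 1e-4)
})

test_that("model is deterministic and respects the surface invariant", {
  set.seed(77)
  meshes <- lapply(1:3, function(i) {
    m <- bone_like_mesh(2)
    m$vertices <- m$vertices +
      matrix(rnorm(length(m$vertices), 0, 0.05), ncol = 3)
    m
  })
  names(meshes) <- c("s1", "s2", "s3")
  m1 <- build_correspondence_model(meshes, P = 48, seed = 9)
  m2 <- build_correspondence_model(meshes, P = 48, seed = 9)
  expect_identical(m1$particles, m2$particles)
  expect_identical(m1$mean_particles, m2$mean_particles)

  for (i in 1:3) {
    d <- closest_on_surface(m1$particles[[i]], meshes[[i]])$distance
    expect_true(all(d <= 0.5))
  }

  expect_error(build_correspondence_model(meshes, P = 1e6, seed = 1),
               "coarsest")
})

test_that("concentric-sphere correspondence is radially matched", {
  mod <- build_correspondence_model(
    list(a = icosphere(10, 3), b = icosphere(11, 4)), P = 200, seed = 3)
  pa <- mod$particles[[1]]
  pb <- mod$particles[[2]]
  ang <- acos(pmin(1, rowSums(
    pa / sqrt(rowSums(pa^2)) * pb / sqrt(rowSums(pb^2))))) * 180 / pi
  expect_gte(mean(ang < 2), 0.95)
})

test_that("mean shape interpolates particles exactly via TPS", {
  m <- bone_like_mesh(2)
  mod <- build_correspondence_model(list(a = m, b = m), P = 64, seed = 5)
  ms <- mean_shape(mod, template_mesh = m)
  # identical subjects: mean surface equals the template
  expect_equal(ms$mean_surface$vertices, m$vertices, tolerance = 1e-9)

  # TPS reproduces control displacements exactly at the control sites
  set.seed(8)
  ctrl <- m$vertices[farthest_point_sample(m$vertices, 30, seed = 1), ]
  tgt <- ctrl + matrix(rnorm(90, 0, 0.5), ncol = 3)
  w <- tps_fit(ctrl, tgt)
  expect_equal(tps_apply(w, ctrl), tgt, tolerance = 1e-8)
})

test_that("two subjects symmetric about the template average to it", {
  m <- bone_like_mesh(2)
  vn <- vertex_normals(m)
  plus <- m; plus$vertices <- m$vertices + 0.3 * vn
  minus <- m; minus$vertices <- m$vertices - 0.3 * vn
  mod <- build_correspondence_model(list(a = m, p = plus, q = minus),
                                    P = 64, seed = 2)
  # mean particles sit near the template surface midway between the two
  d <- closest_on_surface(mod$mean_particles, m)$distance
  expect_lt(max(d), 0.08)
})

test_that("particle mapping matches exhaustive nearest-vertex search", {
  m <- bone_like_mesh(1)   # 42 vertices
  set.seed(14)
  particles <- m$vertices[sample(nrow(m$vertices), 20), ] +
    matrix(rnorm(60, 0, 0.2), ncol = 3)
  mp <- map_particles(particles, m)
  brute <- apply(particles, 1L, function(p)
    which.min(colSums((t(m$vertices) - p)^2)))
  expect_identical(mp$vertex_id, as.integer(brute))

  # rigid displacement + ICP realignment gives the same assignments
  mv <- apply_transform(rigid_transform(rot_z(12), c(4, -1, 2)), m)
  mp2 <- map_particles(particles, mv, mean_surface = m)
  expect_identical(mp2$vertex_id, mp$vertex_id)
})

test_that("model serialization round-trips through CSV", {
  m <- bone_like_mesh(1)
  mod <- build_correspondence_model(list(a = m, b = m), P = 16, seed = 1)
  dir <- withr::local_tempdir()
  save_correspondence_model(mod, dir)
  got <- utils::read.csv(file.path(dir, "a.csv"))
  expect_equal(as.matrix(got[, c("x", "y", "z")]),
               mod$particles[["a"]], tolerance = 1e-12,
               ignore_attr = TRUE)
  mf <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(mf$P, 16)
})
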