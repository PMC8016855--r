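# Synthetic joint and population generators and their oracles.

test_that("joint generators are deterministic and oracle-consistent", {
  spec <- synthetic_joint_spec("sphere_socket", radius_a = 10, gap = 2,
                               resolution = 1, noise_sd = 0.01, seed = 8)
  j1 <- make_joint(spec)
  j2 <- make_joint(spec)
  expect_identical(j1$meshA$vertices, j2$meshA$vertices)
  expect_identical(j1$meshB$faces, j2$meshB$faces)

  # oracle self-consistency: principal curvatures from oracle H, G
  for (fam in c("sphere_socket", "cylinder_pair", "plane_pair")) {
    sp <- synthetic_joint_spec(fam, radius_a = 10, gap = 2,
                               resolution = 1.5)
    jj <- make_joint(sp)
    oc <- jj$oracle$curvature(jj$meshA$vertices, "a")
    pk <- principal_from_HG(oc$H, oc$G)
    expect_false(any(pk$clamped))
    expect_true(all(pk$Kmin <= pk$Kmax + 1e-12))
  }

  # sphere family values by side
  sp <- synthetic_joint_spec("sphere_socket", radius_a = 10, gap = 2)
  expect_equal(analytic_curvature(sp, matrix(c(0, 0, 10), 1), "a"),
               tibble::tibble(H = 0.1, G = 0.01))
  expect_equal(analytic_curvature(sp, matrix(c(0, 0, 12), 1), "b"),
               tibble::tibble(H = -1 / 12, G = 1 / 144))
  cy <- synthetic_joint_spec("cylinder_pair", radius_a = 10, gap = 1)
  expect_equal(analytic_curvature(cy, matrix(c(0, 0, 10), 1), "a")$H,
               1 / 20)
  pl <- synthetic_joint_spec("plane_pair", radius_a = 1, gap = 1)
  expect_equal(analytic_curvature(pl, matrix(0, 1, 3), "a")$H, 0)
})

test_that("joint gap oracles agree with measured joint space", {
  for (fam in c("sphere_socket", "cylinder_pair", "plane_pair",
                "trochlea_pair")) {
    spec <- synthetic_joint_spec(fam, radius_a = 10, gap = 2,
                                 angular_extent = 60, resolution = 0.8)
    j <- make_joint(spec)
    ra <- articular_region(j$meshA, seq_len(nrow(j$meshA$vertices)))
    rb <- articular_region(j$meshB, seq_len(nrow(j$meshB$vertices)))
    cov <- coverage(ra, rb, max_ray_length = 6)
    js <- joint_space(cov$coveredA, j$meshB)
    oracle <- j$oracle$gap(
      j$meshA$vertices[cov$coveredA$vertex_ids, , drop = FALSE])
    expect_lt(max(abs(js$distance - oracle)), 2 * spec$resolution,
              label = fam)
  }
})

test_that("trochlea generator has the stated saddle curvature", {
  spec <- synthetic_joint_spec("trochlea_pair", radius_a = 8,
                               radius_b = 15, gap = 2,
                               angular_extent = 40, resolution = 0.5)
  j <- make_joint(spec)
  # crest line: points at the inner equator (y = 0)
  crest <- abs(j$meshA$vertices[, 2]) < 1e-6
  oc <- j$oracle$curvature(j$meshA$vertices[crest, , drop = FALSE], "a")
  expect_equal(oc$H, rep((1 / 8 - 1 / 15) / 2, sum(crest)),
               tolerance = 1e-9)
  expect_equal(oc$G, rep(-1 / (8 * 15), sum(crest)), tolerance = 1e-9)

  # discrete estimate agrees with the oracle away from the boundary
  cf <- curvature_field(j$meshA)
  i <- !cf$boundary
  oall <- j$oracle$curvature(j$meshA$vertices, "a")
  expect_lt(stats::median(abs(cf$H[i] - oall$H[i])), 0.005)
})

test_that("population generator is deterministic with valid ground truth", {
  tmpl <- icosphere(10, 2)
  ps <- population_spec(tmpl, n_subjects = 8, mode_sds = c(2, 1),
                        vertex_noise_sd = 0.05, left_fraction = 0.25,
                        scale_range = c(0.9, 1.1), seed = 21)
  p1 <- make_population(ps)
  p2 <- make_population(ps)
  expect_identical(p1$meshes[[3]]$vertices, p2$meshes[[3]]$vertices)
  expect_identical(p1$ground_truth$b, p2$ground_truth$b)

  expect_equal(sum(p1$ground_truth$mirrored), 2)
  expect_identical(unname(vapply(p1$meshes, `[[`, "", "side")[
    p1$ground_truth$mirrored]), rep("left", 2))

  # planted fields orthonormal
  gram <- crossprod(p1$ground_truth$mode_fields)
  expect_equal(gram, diag(2), tolerance = 1e-9, ignore_attr = TRUE)

  expect_error(population_spec(tmpl, mode_sds = c(1, 2)), "descending")
})

test_that("pose-only populations collapse to the template under GPA", {
  tmpl <- icosphere(10, 1)
  ps <- population_spec(tmpl, n_subjects = 6, rotation_range = 15,
                        translation_range = 5, seed = 5)
  pop <- make_population(ps)
  g <- generalized_procrustes(lapply(pop$meshes, function(m) m$vertices),
                              remove_scale = FALSE)
  for (i in 2:6)
    expect_equal(g$aligned[[1]], g$aligned[[i]], tolerance = 1e-6)
})

test_that("Procrustes scaling removal makes modes scale-independent", {
  tmpl <- icosphere(10, 2)
  ps <- population_spec(tmpl, n_subjects = 30, mode_sds = 2,
                        vertex_noise_sd = 0.02,
                        scale_range = c(0.8, 1.2), seed = 3)
  pop <- make_population(ps)
  ms <- fit_modes(lapply(pop$meshes, function(m) m$vertices),
                  n_reps = 50)
  sc <- mode_scores(ms)
  fit <- summary(lm(sc[, 1] ~ pop$ground_truth$scales))
  # regression of mode-1 scores on planted scale: slope ~ 0
  expect_gt(fit$coefficients[2, 4], 0.05)   # not significant
  expect_lt(abs(cor(sc[, 1], pop$ground_truth$scales)), 0.3)
})
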