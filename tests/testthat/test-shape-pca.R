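# Shape PCA, parallel analysis, mode warps.

test_that("PCA degenerate cases behave as expected", {
  set.seed(3)
  A <- matrix(rnorm(90), 30)
  # identical subjects: all eigenvalues 0
  ms <- fit_modes(list(A, A, A), remove_scale = FALSE, n_reps = 20,
                  align = FALSE)
  expect_true(all(ms$eigenvalues < 1e-18))
  expect_equal(ms$n_significant, 0L)

  # single direction of variation: one nonzero eigenvalue, fraction 1
  v <- matrix(rnorm(90), 30)
  v <- v / sqrt(sum(v^2))
  sets <- lapply(c(-2, -1, 1, 2), function(a) A + a * v)
  ms1 <- fit_modes(sets, remove_scale = FALSE, n_reps = 20,
                   align = FALSE)
  expect_equal(ms1$variance_fraction[1], 1, tolerance = 1e-9)
  expect_lt(ms1$eigenvalues[2] / ms1$eigenvalues[1], 1e-12)

  expect_error(fit_modes(list(A, A)), "at least 3")
})

test_that("planted orthogonal modes are recovered with correct ratios", {
  tmpl <- icosphere(10, 2)
  ps <- population_spec(tmpl, n_subjects = 40, mode_sds = c(3, 2, 1),
                        vertex_noise_sd = 0.05, rotation_range = 10,
                        translation_range = 5, seed = 12)
  pop <- make_population(ps)
  ms <- fit_modes(lapply(pop$meshes, function(m) m$vertices),
                  n_reps = 100)
  expect_equal(ms$n_significant, 3L)
  vf <- ms$variance_fraction[1:3] / ms$variance_fraction[3]
  expect_true(all(abs(vf - c(9, 4, 1)) / c(9, 4, 1) < 0.15))

  # mode-1 scores track the planted coefficients
  sc <- mode_scores(ms)
  expect_gt(abs(cor(sc[, 1], pop$ground_truth$b[, 1])), 0.98)
})

test_that("parallel analysis retains the right number of modes", {
  # identical rows: nothing to retain
  expect_equal(parallel_analysis(matrix(1, 10, 50)), 0L)

  # single planted mode with SD 10x the noise
  set.seed(6)
  v <- rnorm(300); v <- v / sqrt(sum(v^2))
  X <- outer(rnorm(30, 0, 10), v) + matrix(rnorm(30 * 300), 30)
  expect_equal(parallel_analysis(X, n_reps = 100, seed = 2), 1L)

  # pure isotropic noise retains zero modes in >= 95% of runs
  zero <- 0L
  for (s in 1:50) {
    set.seed(1000 + s)
    N <- matrix(rnorm(30 * 300), 30)
    zero <- zero + (parallel_analysis(N, n_reps = 200, seed = s) == 0L)
  }
  expect_gte(zero / 50, 0.95)
})

test_that("parallel analysis is monotone in the planted mode strength", {
  set.seed(9)
  v <- rnorm(200); v <- v / sqrt(sum(v^2))
  noise <- matrix(rnorm(25 * 200), 25)
  coefs <- rnorm(25)
  ns <- vapply(c(0.5, 2, 5, 10, 20), function(sd) {
    parallel_analysis(outer(coefs * sd, v) + noise,
                      n_reps = 100, seed = 4)
  }, 0L)
  expect_true(all(diff(ns) >= 0))
})

test_that("mode warps are linear and recover the planted field", {
  tmpl <- icosphere(10, 2)
  ps <- population_spec(tmpl, n_subjects = 40, mode_sds = 3,
                        vertex_noise_sd = 0.05, rotation_range = 10,
                        translation_range = 5, seed = 11)
  pop <- make_population(ps)
  sets <- lapply(pop$meshes, function(m) m$vertices)
  ms <- fit_modes(sets, n_reps = 50)

  tp <- sets[[1]]
  w0 <- warp_mode(ms, 1, 0, tmpl, tp)
  expect_equal(w0$mesh$vertices, w0$mean_mesh$vertices, tolerance = 1e-12)

  wp <- warp_mode(ms, 1, 2, tmpl, tp)
  wm <- warp_mode(ms, 1, -2, tmpl, tp)
  expect_equal(wp$particles - ms$mean_particles,
               -(wm$particles - ms$mean_particles), tolerance = 1e-9)

  # recovered mode-1 field vs planted displacement field
  cosang <- abs(sum(ms$eigenvectors[, 1] * pop$ground_truth$mode_fields))
  expect_gt(cosang, 0.99)

  # zero-eigenvalue mode warp returns the mean with a warning
  A <- matrix(rnorm(90), 30)
  flat <- fit_modes(list(A, A, A), remove_scale = FALSE, n_reps = 10)
  expect_warning(warp_mode(flat, 1, 2, tmpl, A), "zero-variance")
})

test_that("projection onto all modes reconstructs every subject", {
  set.seed(15)
  sets <- lapply(1:6, function(i) matrix(rnorm(90), 30))
  ms <- fit_modes(sets, remove_scale = FALSE, n_reps = 10)
  sc <- mode_scores(ms)
  recon <- sweep(sc %*% t(ms$eigenvectors), 2L, ms$mean_vector, `+`)
  expect_equal(recon, ms$data_matrix, tolerance = 1e-6,
               ignore_attr = TRUE)
  # explained-variance fractions sum to one over nonzero modes
  expect_equal(sum(ms$variance_fraction), 1, tolerance = 1e-12)
})

test_that("mode distance maps reflect the displacement field", {
  m <- bone_like_mesh(2)
  expect_equal(max(mode_distance_map(m, m)), 0)
  # a 1 mm normal offset of a planar patch reads 1 mm everywhere
  pl <- make_joint(synthetic_joint_spec("plane_pair", radius_a = 1,
                                        gap = 1, resolution = 0.2))$meshA
  shifted <- pl
  shifted$vertices <- sweep(pl$vertices, 2L, c(0, 0, 1), `+`)
  expect_equal(unname(range(mode_distance_map(shifted, pl))), c(1, 1),
               tolerance = 1e-9)
})

test_that("tidy/glance/autoplot summarize a mode set", {
  tmpl <- icosphere(10, 1)
  ps <- population_spec(tmpl, n_subjects = 12, mode_sds = 2,
                        vertex_noise_sd = 0.05, seed = 2)
  pop <- make_population(ps)
  ms <- fit_modes(lapply(pop$meshes, function(m) m$vertices),
                  n_reps = 50)
  td <- tidy(ms)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$eigenvalue, ms$eigenvalues)
  expect_equal(sum(td$significant), ms$n_significant)
  gl <- glance(ms)
  expect_equal(gl$n_subjects, 12)
  expect_s3_class(autoplot(ms), "ggplot")
})
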