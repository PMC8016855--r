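# Articular regions, coverage, joint space, congruence, particle maps,
# paired statistics.

test_that("candidate regions are seeded by second principal curvature", {
  j <- make_joint(synthetic_joint_spec("sphere_socket", radius_a = 10,
                                       gap = 2, angular_extent = 70,
                                       resolution = 0.8))
  socket <- j$meshB
  # disjoint union of the socket patch and a distant flat flange
  flange <- make_joint(synthetic_joint_spec("plane_pair", radius_a = 5,
                                            gap = 1,
                                            resolution = 0.8))$meshA
  flange$vertices <- sweep(flange$vertices, 2L, c(40, 0, 0), `+`)
  un <- surface_mesh(rbind(socket$vertices, flange$vertices),
                     rbind(socket$faces,
                           flange$faces + nrow(socket$vertices)))
  cf <- curvature_field(un)
  reg <- candidate_region(un, cf, list(value = -0.05,
                                       comparison = "less"))
  # only socket vertices selected (flange starts at index offset)
  expect_true(all(reg$vertex_ids <= nrow(socket$vertices)))
  expect_gt(length(reg$vertex_ids), 0.5 * nrow(socket$vertices))

  # convex-only surface with a concave threshold: empty selection error
  ball <- icosphere(10, 2)
  cb <- curvature_field(ball)
  expect_error(candidate_region(ball, cb,
                                list(value = 0, comparison = "less")),
               "empty selection")

  # threshold admitting everything selects the whole mesh
  all_reg <- candidate_region(ball, cb, list(value = 10,
                                             comparison = "less"),
                              exclude_boundary = FALSE)
  expect_equal(length(all_reg$vertex_ids), nrow(ball$vertices))
  expect_equal(all_reg$area, mesh_area(ball), tolerance = 1e-9)
})

test_that("hemispherical coverage area matches the analytic value", {
  j <- make_joint(synthetic_joint_spec("sphere_socket", radius_a = 10,
                                       gap = 2, angular_extent = 90,
                                       resolution = 0.7))
  ra <- articular_region(j$meshA, seq_len(nrow(j$meshA$vertices)))
  rb <- articular_region(j$meshB, seq_len(nrow(j$meshB$vertices)))
  cov <- coverage(ra, rb, max_ray_length = 5)
  expect_lt(abs(cov$coveredA$area - 2 * pi * 100) / (2 * pi * 100), 0.03)
  # full overlap: every candidate vertex of the ball is covered
  expect_equal(length(cov$coveredA$vertex_ids), nrow(j$meshA$vertices))

  # same-mesh regions are rejected
  expect_error(coverage(ra, ra), "distinct")
})

test_that("offset planar patches cover only the overlap strip", {
  j <- make_joint(synthetic_joint_spec("plane_pair", radius_a = 0.5,
                                       gap = 2, resolution = 0.04,
                                       center_offset = c(0.5, 0, 0)))
  ra <- articular_region(j$meshA, seq_len(nrow(j$meshA$vertices)))
  rb <- articular_region(j$meshB, seq_len(nrow(j$meshB$vertices)))
  cov <- coverage(ra, rb, max_ray_length = 5)
  expect_lt(abs(cov$coveredA$area - 0.5) / 0.5, 0.05)
  expect_lt(abs(cov$coveredB$area - 0.5) / 0.5, 0.05)

  # back-to-back patches (normals pointing apart): zero coverage
  away <- j$meshB
  away$faces <- away$faces[, c(1, 3, 2)]
  rb2 <- articular_region(away, seq_len(nrow(away$vertices)))
  cov2 <- coverage(ra, rb2, max_ray_length = 5)
  expect_equal(cov2$coveredA$area, 0)
  expect_equal(cov2$coveredB$area, 0)
})

test_that("enlarging the ray length never shrinks coverage", {
  j <- make_joint(synthetic_joint_spec("sphere_socket", radius_a = 10,
                                       gap = 2, angular_extent = 80,
                                       resolution = 1))
  ra <- articular_region(j$meshA, seq_len(nrow(j$meshA$vertices)))
  rb <- articular_region(j$meshB, seq_len(nrow(j$meshB$vertices)))
  areas <- vapply(c(1, 2.5, 5, 10, 20), function(L)
    coverage(ra, rb, max_ray_length = L)$coveredA$area, 0)
  expect_true(all(diff(areas) >= 0))
})

test_that("joint space reproduces analytic gap fields", {
  # concentric spheres: constant gap
  j <- make_joint(synthetic_joint_spec("sphere_socket", radius_a = 10,
                                       gap = 2, angular_extent = 80,
                                       resolution = 0.7))
  ra <- articular_region(j$meshA, seq_len(nrow(j$meshA$vertices)))
  rb <- articular_region(j$meshB, seq_len(nrow(j$meshB$vertices)))
  cov <- coverage(ra, rb, max_ray_length = 5)
  js <- joint_space(cov$coveredA, j$meshB)
  expect_true(all(abs(js$distance - 2) < 0.02))

  # parallel planes: gap g everywhere
  jp <- make_joint(synthetic_joint_spec("plane_pair", radius_a = 1,
                                        gap = 3, resolution = 0.2))
  rp <- articular_region(jp$meshA, seq_len(nrow(jp$meshA$vertices)))
  rq <- articular_region(jp$meshB, seq_len(nrow(jp$meshB$vertices)))
  cp <- coverage(rp, rq, max_ray_length = 5)
  expect_true(all(abs(joint_space(cp$coveredA, jp$meshB)$distance - 3) <
                    1e-9))

  # laterally offset ball in socket: gap field matches the closed form
  jo <- make_joint(synthetic_joint_spec("sphere_socket", radius_a = 10,
                                        gap = 2, angular_extent = 90,
                                        resolution = 0.7,
                                        center_offset = c(0.5, 0, 0)))
  ro <- articular_region(jo$meshA, seq_len(nrow(jo$meshA$vertices)))
  rs <- articular_region(jo$meshB, seq_len(nrow(jo$meshB$vertices)))
  co <- coverage(ro, rs, max_ray_length = 6)
  jso <- joint_space(co$coveredA, jo$meshB)
  oracle <- jo$oracle$gap(
    jo$meshA$vertices[co$coveredA$vertex_ids, , drop = FALSE])
  expect_lt(max(abs(jso$distance - oracle)), 0.05)
  expect_lt(abs(min(jso$distance) - 1.5), 0.1)
  expect_lt(abs(max(jso$distance) - 2.5), 0.1)

  expect_error(joint_space(articular_region(jo$meshA, integer(0)),
                           jo$meshB), "empty")
})

test_that("congruence algebra matches hand-evaluated cases", {
  # equal-radius ball in socket: perfect congruence
  r0 <- congruence_index(0.1, 0.01, -0.1, 0.01)
  expect_equal(r0$D1, 0, tolerance = 1e-8)
  expect_equal(r0$delta, 0, tolerance = 1e-8)
  expect_equal(r0$CI, 0, tolerance = 1e-8)

  # ball r=10 in socket r=12
  r1 <- congruence_index(0.1, 0.01, -1 / 12, 1 / 144)
  # Ke_min/Ke_max carry the clamped-discriminant rounding of H^2 - G
  expect_equal(r1$Ke_min, 1 / 60, tolerance = 1e-6)
  expect_equal(r1$Ke_max, 1 / 60, tolerance = 1e-6)
  expect_equal(r1$CI, 1 / 60, tolerance = 1e-12)

  # mated congruent cylinders: the small-angle form gives CI = 1/(2r)*...
  r2 <- congruence_index(0.05, 0, -0.05, 0)
  expect_equal(r2$D1, -0.1)
  expect_equal(r2$D2, -0.1)
  expect_equal(r2$delta, 0.2)
  expect_equal(r2$Ke_min, -0.1)
  expect_equal(r2$Ke_max, 0.1)
  expect_equal(r2$CI, 0.1)
})

test_that("congruence index is swap-symmetric and scale-covariant", {
  set.seed(4)
  H1 <- rnorm(20, 0, 0.1); G1 <- H1^2 - abs(rnorm(20, 0, 0.003))
  H2 <- rnorm(20, 0, 0.1); G2 <- H2^2 - abs(rnorm(20, 0, 0.003))
  a <- congruence_index(H1, G1, H2, G2)
  b <- congruence_index(H2, G2, H1, G1)
  expect_equal(a$CI, b$CI, tolerance = 1e-12)
  expect_equal(a$Ke_min, b$Ke_min, tolerance = 1e-12)

  # scaling all lengths by s scales curvature by 1/s and CI by 1/s
  s <- 2.5
  sc <- congruence_index(H1 / s, G1 / s^2, H2 / s, G2 / s^2)
  expect_equal(sc$CI, a$CI / s, tolerance = 1e-12)
})

test_that("congruence over covered regions approaches the analytic CI", {
  j <- make_joint(synthetic_joint_spec("sphere_socket", radius_a = 10,
                                       gap = 2, angular_extent = 70,
                                       resolution = 0.5))
  ca <- curvature_field(j$meshA)
  cb <- curvature_field(j$meshB)
  ra <- candidate_region(j$meshA, ca, list(value = 0.05,
                                           comparison = "greater"))
  rb <- candidate_region(j$meshB, cb, list(value = -0.05,
                                           comparison = "less"))
  cov <- coverage(ra, rb, max_ray_length = 5)
  cg <- congruence(cov$coveredA, cov$coveredB, ca, cb)
  # discrete curvature on clean spheres: CI near 1/60
  expect_lt(abs(median(cg$CI) - 1 / 60), 0.004)
  expect_true(all(cg$delta >= 0))
  expect_true(all(cg$Ke_min <= cg$Ke_max + 1e-12))
})

test_that("particle maps aggregate exactly as a hand computation", {
  vals <- rbind(c(1, 2, NA, 4),
                c(3, 2, NA, 6))
  pm <- particle_map(vals, joint_label = "synthetic")
  expect_identical(pm$particle_ids, c(1L, 2L, 4L))  # col 3 excluded
  expect_equal(pm$per_particle$mean, c(2, 2, 5))
  expect_equal(pm$per_particle$sd, c(sqrt(2), 0, sqrt(2)))
  pooled <- c(1, 3, 2, 2, 4, 6)
  expect_equal(pm$global$mean_pooled, mean(pooled))
  expect_equal(pm$global$sd_pooled, sd(pooled))
  expect_equal(pm$global$min, 1)
  expect_equal(pm$global$max, 6)
  expect_equal(pm$global$mean_of_particle_means, mean(c(2, 2, 5)))

  # identical subjects: per-particle SD zero, global mean = subject mean
  same <- rbind(c(1, 2, 3), c(1, 2, 3))
  ps <- particle_map(same)
  expect_equal(max(ps$per_particle$sd), 0)
  expect_equal(ps$global$mean_pooled, 2)

  expect_error(particle_map(matrix(NA_real_, 2, 3)), "inclusion")
  expect_s3_class(autoplot(pm), "ggplot")
})

test_that("paired area statistics match hand and oracle values", {
  # differences [1, 2, 3] against zero
  st <- paired_area_stats(c(1, 2, 3), c(0, 0, 0))
  expect_equal(st$mean_difference, 2)
  expect_equal(st$sd_difference, 1)
  expect_equal(st$cohens_d, 2)
  expect_equal(st$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(st$df, 2L)
  expect_equal(st$p_two_tailed, 0.0741799002, tolerance = 1e-8)
  expect_identical(st$effect_label, "large")
  # noncentral-t post-hoc power, frozen from an independent evaluation
  expect_equal(st$posthoc_power, 0.4707494313, tolerance = 1e-6)

  # identical pairs: degenerate but well-defined
  eq <- paired_area_stats(c(5, 5), c(5, 5))
  expect_true(eq$degenerate)
  expect_equal(eq$t, 0)
  expect_equal(eq$cohens_d, 0)
  expect_equal(eq$p_two_tailed, 1)

  # effect-size labels at the conventional thresholds
  lab <- function(d) {
    n <- 40
    set.seed(2)
    base <- rnorm(n)
    diffs <- base - mean(base)
    diffs <- diffs / sd(diffs)          # sd 1, mean 0
    paired_area_stats(diffs + d, rep(0, n))$effect_label
  }
  expect_identical(lab(0.8), "large")
  expect_identical(lab(0.5), "medium")
  expect_identical(lab(0.2), "small")
  expect_identical(lab(0.05), "negligible")
})

test_that("required sample size matches the noncentral-t oracle", {
  # frozen from an independent noncentral-t search
  expect_identical(required_n(2, 0.05, 0.95), 6L)
  expect_identical(required_n(0.8, 0.05, 0.95), 23L)
  n_small <- required_n(0.05, 0.05, 0.80)
  expect_lte(abs(n_small - 3140L), 2L)
  # very large effects approach the t-test minimum
  expect_lte(required_n(50, 0.05, 0.80), 3L)
  expect_error(required_n(-1, 0.05, 0.8), "range")
})
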