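# Synthetic mated joints and shape populations with analytic ground
# truth: exact per-vertex curvature, exact gap fields, and planted shape
# modes. Every pipeline stage can be validated against these oracles
# without imaging data.

#' Icosphere mesh
#'
#' Subdivided icosahedron projected to a sphere: near-uniform triangles,
#' counter-clockwise winding, outward orientation.
#'
#' @param radius Sphere radius (mm).
#' @param subdivisions Number of 4-to-1 subdivisions (0 = icosahedron).
#' @param center Sphere center (default origin).
#' @return A closed `surface_mesh`.
#' @export
icosphere <- function(radius = 1, subdivisions = 3L, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    cache <- new.env(hash = TRUE, parent = emptyenv())
    vlist <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- cache[[key]]
      if (!is.null(idx)) return(idx)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      vlist[[length(vlist) + 1L]] <<- m
      idx <- nv + length(vlist)
      cache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, 0, 3)
    newf <- vector("list", nrow(f) * 4L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c_ <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[[4 * k - 3]] <- c(a, ab, ca)
      newf[[4 * k - 2]] <- c(b, bc, ab)
      newf[[4 * k - 1]] <- c(c_, ca, bc)
      newf[[4 * k]] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, vlist))
    f <- do.call(rbind, newf)
  }
  vv <- sweep(v * radius, 2L, as.numeric(center), `+`)
  surface_mesh(vv, f, bone = "synthetic")
}

# spherical cap: faces of an icosphere whose vertices lie within
# `extent_deg` of +z (measured from the sphere center)
sphere_cap <- function(radius, extent_deg, subdivisions, center,
                       flip = FALSE) {
  m <- icosphere(radius, subdivisions, center = c(0, 0, 0))
  ang <- acos(pmin(1, pmax(-1, m$vertices[, 3] / radius)))
  keep_v <- ang <= extent_deg * pi / 180 + 1e-9
  fkeep <- keep_v[m$faces[, 1]] & keep_v[m$faces[, 2]] &
    keep_v[m$faces[, 3]]
  m$faces <- m$faces[fkeep, , drop = FALSE]
  m <- drop_unreferenced_vertices(m)
  if (flip) m$faces <- m$faces[, c(1, 3, 2), drop = FALSE]
  m$vertices <- sweep(m$vertices, 2L, as.numeric(center), `+`)
  m
}

# rectangular grid patch triangulated consistently; maps (u, v) in
# [0,1]^2 through fn(u, v) -> xyz; normal orientation from the (u, v)
# parameterization order
grid_patch <- function(fn, nu, nv, flip = FALSE) {
  us <- seq(0, 1, length.out = nu)
  vs <- seq(0, 1, length.out = nv)
  uv <- expand.grid(u = us, v = vs)
  V <- t(mapply(fn, uv$u, uv$v))
  idx <- function(i, j) (j - 1L) * nu + i
  fl <- list()
  for (j in seq_len(nv - 1L)) for (i in seq_len(nu - 1L)) {
    a <- idx(i, j); b <- idx(i + 1L, j)
    c_ <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    fl[[length(fl) + 1L]] <- c(a, b, c_)
    fl[[length(fl) + 1L]] <- c(a, c_, d)
  }
  f <- do.call(rbind, fl)
  if (flip) f <- f[, c(1, 3, 2), drop = FALSE]
  surface_mesh(V, f, bone = "synthetic")
}

#' Specification of a synthetic mated joint
#'
#' @param family `"sphere_socket"`, `"cylinder_pair"`, `"trochlea_pair"`
#'   or `"plane_pair"`.
#' @param radius_a Radius of the convex member (mm); for `plane_pair` the
#'   patch half-side; for `trochlea_pair` the tube (sagittal) radius.
#' @param gap Joint-space gap (mm, >= 0).
#' @param radius_b Radius of the concave member; defaults to
#'   `radius_a + gap` (concentric mating). For `trochlea_pair` the groove
#'   (transverse, concave) radius at the crest.
#' @param angular_extent Patch angular extent (degrees; default 90).
#' @param resolution Target edge length (mm, default 1).
#' @param center_offset 3-vector offset of member B's center (mm).
#' @param noise_sd Isotropic vertex noise SD (mm, default 0).
#' @param seed Integer seed (noise).
#' @return A `synthetic_joint_spec`.
#' @export
synthetic_joint_spec <- function(family = "sphere_socket", radius_a = 10,
                                 gap = 2, radius_b = NULL,
                                 angular_extent = 90, resolution = 1,
                                 center_offset = c(0, 0, 0),
                                 noise_sd = 0, seed = 1L) {
  family <- match.arg(family, c("sphere_socket", "cylinder_pair",
                                "trochlea_pair", "plane_pair"))
  if (is.null(radius_b)) radius_b <- radius_a + gap
  stopifnot(radius_a > 0, radius_b > 0, gap >= 0)
  structure(list(family = family, radius_a = radius_a,
                 radius_b = radius_b, gap = gap,
                 angular_extent = angular_extent,
                 resolution = resolution,
                 center_offset = as.numeric(center_offset),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_joint_spec")
}

#' Generate a synthetic mated joint with analytic oracles
#'
#' Builds two mated open patches with bone-outward normals (convex member
#' positive mean curvature, concave member negative) and an oracle giving
#' the exact per-point mean/Gaussian curvature and the exact gap field.
#'
#' @param spec A [synthetic_joint_spec()].
#' @return List with `meshA` (convex member), `meshB` (concave member),
#'   and `oracle` (functions `curvature(points, surface)` returning a
#'   tibble of `H`, `G`, and `gap(points)`; plus `nominal_gap`).
#' @export
make_joint <- function(spec) {
  stopifnot(inherits(spec, "synthetic_joint_spec"))
  ra <- spec$radius_a; rb <- spec$radius_b
  off <- spec$center_offset
  res <- spec$resolution
  ext <- spec$angular_extent

  sub_for <- function(r) {
    max(1L, ceiling(log2(1.0515 * r / res)))
  }

  if (spec$family == "sphere_socket") {
    meshA <- sphere_cap(ra, ext, sub_for(ra), center = c(0, 0, 0))
    # socket: sphere about off, larger radius, normals toward its center
    meshB <- sphere_cap(rb, min(ext + 15, 179), sub_for(rb),
                        center = off, flip = TRUE)
    curv <- function(points, surface = c("a", "b")) {
      surface <- match.arg(surface)
      n <- nrow(matrix(points, ncol = 3))
      if (surface == "a")
        tibble::tibble(H = rep(1 / ra, n), G = rep(1 / ra^2, n))
      else
        tibble::tibble(H = rep(-1 / rb, n), G = rep(1 / rb^2, n))
    }
    gapf <- function(points) {
      p <- matrix(points, ncol = 3)
      abs(rb - sqrt(rowSums(sweep(p, 2L, off)^2)))
    }
  } else if (spec$family == "plane_pair") {
    side <- ra
    nu <- max(4L, ceiling(2 * side / res) + 1L)
    meshA <- grid_patch(function(u, v)
      c((u - 0.5) * 2 * side, (v - 0.5) * 2 * side, 0), nu, nu)
    meshB <- grid_patch(function(u, v)
      c((u - 0.5) * 2 * side + off[1],
        (v - 0.5) * 2 * side + off[2], spec$gap + off[3]),
      nu, nu, flip = TRUE)
    curv <- function(points, surface = c("a", "b")) {
      n <- nrow(matrix(points, ncol = 3))
      tibble::tibble(H = rep(0, n), G = rep(0, n))
    }
    gapf <- function(points) {
      p <- matrix(points, ncol = 3)
      rep(spec$gap + off[3], nrow(p))
    }
  } else if (spec$family == "cylinder_pair") {
    L <- 2 * ra
    half <- ext / 2 * pi / 180
    nu <- max(4L, ceiling(2 * half * ra / res) + 1L)
    nv <- max(4L, ceiling(L / res) + 1L)
    cyl <- function(r, offc, flip) grid_patch(function(u, v) {
      th <- -half + u * 2 * half
      c(r * sin(th) + offc[1], (v - 0.5) * L + offc[2],
        r * cos(th) + offc[3])
    }, nu, nv, flip = flip)
    meshA <- cyl(ra, c(0, 0, 0), flip = FALSE)  # outward = +radial
    meshB <- cyl(rb, off, flip = TRUE)           # outward = -radial
    curv <- function(points, surface = c("a", "b")) {
      surface <- match.arg(surface)
      n <- nrow(matrix(points, ncol = 3))
      if (surface == "a")
        tibble::tibble(H = rep(1 / (2 * ra), n), G = rep(0, n))
      else
        tibble::tibble(H = rep(-1 / (2 * rb), n), G = rep(0, n))
    }
    gapf <- function(points) {
      p <- matrix(points, ncol = 3)
      rr <- sqrt((p[, 1] - off[1])^2 + (p[, 3] - off[3])^2)
      abs(rb - rr)
    }
  } else { # trochlea_pair: inner band of a torus (saddle crest)
    r1 <- ra                      # convex (tube) radius
    r2 <- rb                      # concave (ring) radius at the crest
    Rc <- r1 + r2                 # ring radius of the center circle
    wphi <- ext / 2 * pi / 180
    wu <- ext / 2 * pi / 180
    torus_pt <- function(rt, u, phi) {
      # center circle in the xz plane, tube section angle phi measured
      # from the outward (away-from-axis) direction; the inner crest is
      # phi = pi
      c((Rc + rt * cos(phi)) * sin(u), rt * sin(phi),
        (Rc + rt * cos(phi)) * cos(u))
    }
    nu <- max(4L, ceiling(2 * wu * Rc / res) + 1L)
    nv <- max(4L, ceiling(2 * wphi * r1 / res) + 1L)
    band <- function(rt, flip) grid_patch(function(uu, vv) {
      u <- -wu + uu * 2 * wu
      phi <- pi - wphi + vv * 2 * wphi
      torus_pt(rt, u, phi)
    }, nu, nv, flip = flip)
    meshA <- band(r1, flip = FALSE)
    meshB <- band(r1 + spec$gap, flip = TRUE)
    torus_curv <- function(points, rt, sign_flip) {
      p <- matrix(points, ncol = 3)
      rho <- sqrt(p[, 1]^2 + p[, 3]^2)
      cphi <- (rho - Rc) / rt
      cphi <- pmin(1, pmax(-1, cphi))
      k1 <- 1 / rt
      k2 <- cphi / (Rc + rt * cphi)
      if (sign_flip) { k1 <- -k1; k2 <- -k2 }
      tibble::tibble(H = (k1 + k2) / 2, G = k1 * k2)
    }
    curv <- function(points, surface = c("a", "b")) {
      surface <- match.arg(surface)
      if (surface == "a") torus_curv(points, r1, FALSE)
      else torus_curv(points, r1 + spec$gap, TRUE)
    }
    gapf <- function(points) {
      p <- matrix(points, ncol = 3)
      rho <- sqrt(p[, 1]^2 + p[, 3]^2)
      d_axis <- sqrt((rho - Rc)^2 + p[, 2]^2)   # distance to center circle
      abs((r1 + spec$gap) - d_axis)
    }
  }

  if (spec$noise_sd > 0) {
    old <- .Random.seed_save()
    set.seed(spec$seed)
    meshA$vertices <- meshA$vertices +
      matrix(stats::rnorm(length(meshA$vertices), 0, spec$noise_sd),
             ncol = 3)
    meshB$vertices <- meshB$vertices +
      matrix(stats::rnorm(length(meshB$vertices), 0, spec$noise_sd),
             ncol = 3)
    .Random.seed_restore(old)
  }
  meshA$subject_id <- "synthetic_a"
  meshB$subject_id <- "synthetic_b"
  list(meshA = meshA, meshB = meshB,
       oracle = list(spec = spec, curvature = curv, gap = gapf,
                     nominal_gap = spec$gap))
}

#' Exact curvature of a synthetic joint surface at given points
#'
#' Closed-form mean and Gaussian curvature with the bone-outward sign
#' convention, for points on (or near) the parametric surface.
#'
#' @param spec A [synthetic_joint_spec()].
#' @param points q x 3 matrix of surface points.
#' @param surface `"a"` (convex member) or `"b"` (concave member).
#' @return Tibble with `H` (mm^-1) and `G` (mm^-2).
#' @export
analytic_curvature <- function(spec, points, surface = c("a", "b")) {
  joint <- make_joint_oracle(spec)
  joint$curvature(points, match.arg(surface))
}

# oracle functions without re-meshing cost (noise-free geometry)
make_joint_oracle <- function(spec) {
  spec$noise_sd <- 0
  spec$resolution <- max(spec$resolution, spec$radius_a / 2)
  make_joint(spec)$oracle
}

#' Specification of a synthetic shape population
#'
#' @param template A `surface_mesh` used as the population template.
#' @param n_subjects Number of subjects.
#' @param mode_sds Descending vector of planted mode SDs (mm); its length
#'   is the number of planted modes k.
#' @param mode_fields Optional 3V x k matrix of orthonormal per-vertex
#'   displacement fields (columns); generated deterministically from the
#'   seed when `NULL` (orthogonalized smooth low-frequency fields).
#' @param vertex_noise_sd Isotropic vertex noise SD (mm).
#' @param rotation_range Max random rotation magnitude (degrees).
#' @param translation_range Max random translation per axis (mm).
#' @param scale_range Length-2 range of random uniform scales.
#' @param left_fraction Fraction of subjects mirrored and labeled left.
#' @param seed Integer seed.
#' @return A `population_spec`.
#' @export
population_spec <- function(template, n_subjects = 10L,
                            mode_sds = numeric(0), mode_fields = NULL,
                            vertex_noise_sd = 0, rotation_range = 10,
                            translation_range = 5,
                            scale_range = c(1, 1), left_fraction = 0,
                            seed = 1L) {
  stopifnot(inherits(template, "surface_mesh"), n_subjects >= 1L)
  if (length(mode_sds) > 1L && any(diff(mode_sds) > 1e-12))
    stop("mode_sds must be descending")
  structure(list(template = template, n_subjects = as.integer(n_subjects),
                 k_modes = length(mode_sds), mode_sds = mode_sds,
                 mode_fields = mode_fields,
                 vertex_noise_sd = vertex_noise_sd,
                 rotation_range = rotation_range,
                 translation_range = translation_range,
                 scale_range = scale_range,
                 left_fraction = left_fraction, seed = as.integer(seed)),
            class = "population_spec")
}

# deterministic smooth low-frequency displacement fields, orthonormalized
# in R^(3V) and orthogonal to the similarity-transform tangent space at
# the template (translations, infinitesimal rotations, uniform scaling),
# so planted modes are pure shape variation that Procrustes alignment
# cannot absorb
make_mode_fields <- function(template, k, seed) {
  V <- template$vertices
  nv <- nrow(V)
  ctr <- colMeans(V)
  Vc <- sweep(V, 2L, ctr)
  size <- max(sqrt(rowSums(Vc^2)))

  flat <- function(field) as.vector(t(field))
  zero <- numeric(nv)
  pose_basis <- cbind(
    flat(cbind(zero + 1, zero, zero)),      # translations
    flat(cbind(zero, zero + 1, zero)),
    flat(cbind(zero, zero, zero + 1)),
    flat(cbind(zero, -Vc[, 3], Vc[, 2])),   # infinitesimal rotations
    flat(cbind(Vc[, 3], zero, -Vc[, 1])),
    flat(cbind(-Vc[, 2], Vc[, 1], zero)),
    flat(Vc))                               # uniform scaling
  pose_basis <- qr.Q(qr(pose_basis))

  old <- .Random.seed_save()
  set.seed(seed + 7919L)
  M <- matrix(0, 3L * nv, k)
  for (j in seq_len(k)) {
    w <- stats::rnorm(3) / size * (1 + (j - 1) / 2)
    phase <- stats::runif(1, 0, 2 * pi)
    dirn <- stats::rnorm(3)
    dirn <- dirn / sqrt(sum(dirn^2))
    amp <- sin(Vc %*% w + phase)
    field <- cbind(amp * dirn[1], amp * dirn[2], amp * dirn[3])
    M[, j] <- as.vector(t(field))
  }
  .Random.seed_restore(old)
  # project out pose/scale components, then Gram-Schmidt
  M <- M - pose_basis %*% crossprod(pose_basis, M)
  for (j in seq_len(k)) {
    if (j > 1)
      M[, j] <- M[, j] - M[, 1:(j - 1), drop = FALSE] %*%
        crossprod(M[, 1:(j - 1), drop = FALSE], M[, j])
    M[, j] <- M[, j] / sqrt(sum(M[, j]^2))
  }
  M
}

random_rotation <- function(max_deg) {
  if (max_deg <= 0) return(diag(3))
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, -max_deg, max_deg) * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a synthetic shape population with planted modes
#'
#' Each subject is the template plus planted-mode displacements
#' (coefficients drawn Normal(0, mode_sd^2)) plus isotropic vertex noise,
#' then posed by a random similarity transform; a `left_fraction` of
#' subjects is mirrored and labeled left. The returned ground truth holds
#' the planted coefficients, poses, scales and fields.
#'
#' @param popspec A [population_spec()].
#' @return List with `meshes` (named list of `surface_mesh`) and
#'   `ground_truth` (list: `b` n x k coefficients, `scales`, `rotations`,
#'   `translations`, `mirrored`, `mode_fields`, `mode_sds`).
#' @export
make_population <- function(popspec) {
  stopifnot(inherits(popspec, "population_spec"))
  tmpl <- popspec$template
  nv <- nrow(tmpl$vertices)
  k <- popspec$k_modes
  fields <- popspec$mode_fields
  if (k > 0L && is.null(fields))
    fields <- make_mode_fields(tmpl, k, popspec$seed)
  if (k > 0L) {
    gram <- crossprod(fields)
    if (max(abs(gram - diag(k))) > 1e-6)
      stop("mode_fields are not orthonormal")
  }

  old <- .Random.seed_save()
  set.seed(popspec$seed)
  n <- popspec$n_subjects
  b <- if (k > 0L)
    matrix(stats::rnorm(n * k), n, k) %*% diag(popspec$mode_sds, k)
  else matrix(0, n, 0)
  mirrored <- rep(FALSE, n)
  n_left <- round(popspec$left_fraction * n)
  if (n_left > 0) mirrored[sample.int(n, n_left)] <- TRUE

  meshes <- vector("list", n)
  rots <- vector("list", n)
  trans <- matrix(0, n, 3)
  scales <- numeric(n)
  for (i in seq_len(n)) {
    V <- tmpl$vertices
    if (k > 0L) {
      disp <- fields %*% b[i, ]
      V <- V + matrix(disp, ncol = 3, byrow = TRUE)
    }
    if (popspec$vertex_noise_sd > 0)
      V <- V + matrix(stats::rnorm(3 * nv, 0, popspec$vertex_noise_sd),
                      ncol = 3)
    R <- random_rotation(popspec$rotation_range)
    s <- stats::runif(1, popspec$scale_range[1], popspec$scale_range[2])
    t <- stats::runif(3, -popspec$translation_range,
                      popspec$translation_range)
    V <- s * (V %*% t(R))
    V <- sweep(V, 2L, t, `+`)
    m <- surface_mesh(V, tmpl$faces, bone = tmpl$bone, side = "right",
                      subject_id = sprintf("subject_%02d", i),
                      validate = FALSE)
    if (mirrored[i]) {
      m <- reflect_mesh(m)
      m$side <- "left"
    }
    meshes[[i]] <- m
    rots[[i]] <- R
    trans[i, ] <- t
    scales[i] <- s
  }
  .Random.seed_restore(old)
  names(meshes) <- vapply(meshes, `[[`, "", "subject_id")
  list(meshes = meshes,
       ground_truth = list(b = b, scales = scales, rotations = rots,
                           translations = trans, mirrored = mirrored,
                           mode_fields = fields,
                           mode_sds = popspec$mode_sds))
}
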