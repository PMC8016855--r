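# Shared fixtures and independent oracles, all built in code.

# Asymmetric bone-like closed mesh: scaled icosphere with a Gaussian bump
# (no rotational symmetry, so rigid registration is well-posed).
bone_like_mesh <- function(subdiv = 2, radii = c(12, 9, 7)) {
  m <- icosphere(1, subdiv)
  V <- m$vertices
  V <- cbind(V[, 1] * radii[1], V[, 2] * radii[2], V[, 3] * radii[3])
  bump <- exp(-((V[, 1] - 8)^2 + V[, 2]^2 + (V[, 3] - 4)^2) / 18)
  n <- V / sqrt(rowSums(V^2))
  m$vertices <- V + 3 * bump * n
  m
}

# Outward-oriented unit tetrahedron.
tetra_mesh <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               rbind(c(1L, 3L, 2L), c(1L, 2L, 4L), c(1L, 4L, 3L),
                     c(2L, 3L, 4L)))
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

# Independent point-to-triangle distance: project onto the plane, accept
# if the barycentric coordinates are inside, otherwise the minimum of the
# three exact point-segment distances. Written deliberately differently
# from the compiled kernel.
oracle_point_tri_dist <- function(p, a, b, c) {
  seg_dist <- function(p, u, v) {
    w <- v - u
    t <- sum((p - u) * w) / sum(w * w)
    t <- min(1, max(0, t))
    sqrt(sum((u + t * w - p)^2))
  }
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  n <- cross3(b - a, c - a)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-300) return(min(seg_dist(p, a, b), seg_dist(p, b, c),
                              seg_dist(p, a, c)))
  n <- n / nn
  q <- p - sum((p - a) * n) * n
  # barycentric coordinates of q
  m <- cbind(b - a, c - a)
  bc <- qr.solve(crossprod(m), crossprod(m, q - a))
  if (bc[1] >= -1e-12 && bc[2] >= -1e-12 && sum(bc) <= 1 + 1e-12)
    return(abs(sum((p - a) * n)))
  min(seg_dist(p, a, b), seg_dist(p, b, c), seg_dist(p, a, c))
}

oracle_surface_dist <- function(points, mesh) {
  apply(points, 1L, function(p) {
    min(apply(mesh$faces, 1L, function(f)
      oracle_point_tri_dist(p, mesh$vertices[f[1], ],
                            mesh$vertices[f[2], ],
                            mesh$vertices[f[3], ])))
  })
}

# Brute-force rigid fit: direct minimization over an axis-angle
# parameterization with the translation solved analytically.
oracle_best_fit_rigid <- function(X, Y) {
  rot_from <- function(w) {
    th <- sqrt(sum(w^2))
    if (th < 1e-12) return(diag(3))
    ax <- w / th
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj <- function(w) {
    R <- rot_from(w)
    Xr <- X %*% t(R)
    t <- colMeans(Y) - colMeans(Xr)
    sum((sweep(Xr, 2L, -t) - Y)^2)
  }
  best <- NULL
  for (start in list(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, 0, -2),
                     c(2, 2, 0))) {
    o <- stats::optim(start, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
    if (is.null(best) || o$value < best$value) best <- o
  }
  R <- rot_from(best$par)
  list(rotation = R,
       translation = colMeans(Y) - colMeans(X %*% t(R)),
       sse = best$value)
}
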