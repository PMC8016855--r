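# Mesh conditioning: Taubin smoothing, quadric edge-collapse decimation,
# and exact plane clipping. These mirror the standard surface clean-up
# applied to segmented bone models before shape analysis.

mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Taubin (volume-preserving) mesh smoothing
#'
#' Alternates a shrinking Laplacian step (factor `lambda`) with an
#' inflating step (factor `mu`, negative) using the uniform umbrella
#' operator, which smooths noise with little overall shrinkage.
#'
#' @param mesh A [surface_mesh()].
#' @param iterations Number of lambda/mu passes.
#' @param lambda Positive smoothing factor (default 0.5).
#' @param mu Negative inflation factor (default -0.53).
#' @return Smoothed `surface_mesh`.
#' @export
taubin_smooth <- function(mesh, iterations = 10L, lambda = 0.5,
                          mu = -0.53) {
  if (iterations <= 0L) return(mesh)
  v <- mesh$vertices
  e <- mesh_edges(mesh$faces)
  i <- c(e[, 1], e[, 2])
  j <- c(e[, 2], e[, 1])
  deg <- tabulate(i, nbins = nrow(v))
  deg[deg == 0L] <- 1L
  lap_step <- function(v, w) {
    nb <- rowsum(v[j, , drop = FALSE], i)
    nbm <- matrix(0, nrow(v), 3)
    nbm[as.integer(rownames(nb)), ] <- nb
    v + w * (nbm / deg - v)
  }
  for (it in seq_len(iterations)) {
    v <- lap_step(v, lambda)
    v <- lap_step(v, mu)
  }
  mesh$vertices <- v
  mesh
}

#' Quadric edge-collapse decimation
#'
#' Iteratively collapses the edge with the smallest quadric error (sum of
#' squared distances to the incident face planes of both endpoints,
#' evaluated at the edge midpoint) until the face count is at or below
#' `target_face_count`. Degenerate and duplicate faces are removed.
#'
#' @param mesh A [surface_mesh()].
#' @param target_face_count Desired maximum number of faces (>= 4).
#' @return Decimated `surface_mesh`.
#' @export
decimate_mesh <- function(mesh, target_face_count) {
  if (target_face_count < 4L) stop("target_face_count must be >= 4")
  if (nrow(mesh$faces) <= target_face_count) return(mesh)
  v <- mesh$vertices
  f <- mesh$faces

  # per-vertex quadric: 10 unique coefficients of sum over incident faces
  # of (n x + d)^2, i.e. [nn^T, dn; dn^T, d^2]
  fn <- face_normals(mesh)
  n <- fn$normals
  d <- -rowSums(n * v[f[, 1], , drop = FALSE])
  # quadric coefficient rows: a11 a12 a13 a22 a23 a33 b1 b2 b3 c
  fq <- cbind(n[, 1]^2, n[, 1] * n[, 2], n[, 1] * n[, 3],
              n[, 2]^2, n[, 2] * n[, 3], n[, 3]^2,
              d * n[, 1], d * n[, 2], d * n[, 3], d^2)
  # weight by face area for scale stability
  fq <- fq * fn$areas
  Q <- matrix(0, nrow(v), 10)
  for (k in 1:3) {
    acc <- rowsum(fq, f[, k])
    idx <- as.integer(rownames(acc))
    Q[idx, ] <- Q[idx, ] + acc
  }

  quad_cost <- function(Qrow, p) {
    # p' A p + 2 b' p + c for stacked coefficient rows
    Qrow[, 1] * p[, 1]^2 + Qrow[, 4] * p[, 2]^2 + Qrow[, 6] * p[, 3]^2 +
      2 * (Qrow[, 2] * p[, 1] * p[, 2] + Qrow[, 3] * p[, 1] * p[, 3] +
           Qrow[, 5] * p[, 2] * p[, 3] +
           Qrow[, 7] * p[, 1] + Qrow[, 8] * p[, 2] + Qrow[, 9] * p[, 3]) +
      Qrow[, 10]
  }

  edges <- mesh_edges(f)
  mid <- (v[edges[, 1], , drop = FALSE] + v[edges[, 2], , drop = FALSE]) / 2
  cost <- quad_cost(Q[edges[, 1], , drop = FALSE] +
                    Q[edges[, 2], , drop = FALSE], mid)

  alive_f <- rep(TRUE, nrow(f))
  n_faces <- nrow(f)
  # vertex -> faces incidence kept implicitly; update by scanning is fine
  # at fixture scale
  while (n_faces > target_face_count) {
    k <- which.min(cost)
    if (!is.finite(cost[k])) break
    a <- edges[k, 1]; b <- edges[k, 2]
    if (a == b) { cost[k] <- Inf; next }
    # merge b into a at midpoint
    v[a, ] <- (v[a, ] + v[b, ]) / 2
    Q[a, ] <- Q[a, ] + Q[b, ]
    hit_b <- f[, 1] == b | f[, 2] == b | f[, 3] == b
    f[f == b] <- a
    dead <- alive_f & (f[, 1] == f[, 2] | f[, 2] == f[, 3] |
                         f[, 1] == f[, 3])
    n_faces <- n_faces - sum(dead & alive_f)
    alive_f <- alive_f & !dead
    # retarget edges and refresh costs around a
    edges[edges == b] <- a
    self <- edges[, 1] == edges[, 2]
    cost[self] <- Inf
    touch <- which(!self & (edges[, 1] == a | edges[, 2] == a))
    if (length(touch)) {
      midt <- (v[edges[touch, 1], , drop = FALSE] +
               v[edges[touch, 2], , drop = FALSE]) / 2
      cost[touch] <- quad_cost(Q[edges[touch, 1], , drop = FALSE] +
                               Q[edges[touch, 2], , drop = FALSE], midt)
    }
  }

  f <- f[alive_f, , drop = FALSE]
  # drop duplicate faces (same vertex set) that collapses can create
  key <- apply(f, 1L, function(r) paste(sort(r), collapse = "-"))
  f <- f[!duplicated(key), , drop = FALSE]
  out <- surface_mesh(v, f, bone = mesh$bone, side = mesh$side,
                      subject_id = mesh$subject_id, validate = FALSE)
  out <- drop_degenerate_faces(out)
  out <- drop_unreferenced_vertices(out)
  validate_mesh(out)
  out
}

#' Smooth and decimate a segmented bone surface
#'
#' The standard conditioning applied to segmented bone models: Taubin
#' smoothing to reduce segmentation artifact, then quadric decimation to a
#' target face budget.
#'
#' @param mesh A [surface_mesh()].
#' @param smoothing_iterations Taubin passes (default 10).
#' @param smoothing_factor Taubin lambda (default 0.5; mu is fixed at
#'   -0.53).
#' @param target_face_count Maximum face count after decimation; defaults
#'   to the current face count (no decimation).
#' @return Conditioned `surface_mesh`.
#' @export
preprocess_mesh <- function(mesh, smoothing_iterations = 10L,
                            smoothing_factor = 0.5,
                            target_face_count = nrow(mesh$faces)) {
  if (target_face_count < 4L) stop("target_face_count must be >= 4")
  out <- taubin_smooth(mesh, iterations = smoothing_iterations,
                       lambda = smoothing_factor)
  if (target_face_count < nrow(out$faces))
    out <- decimate_mesh(out, target_face_count)
  out <- drop_degenerate_faces(out)
  validate_mesh(out)
  out
}

#' Clip a mesh at a plane
#'
#' Exact clip: faces crossing the plane are cut, with new boundary vertices
#' inserted at the edge/plane intersections; the part on the plane's normal
#' side is removed and the boundary is left open (not capped).
#'
#' @param mesh A [surface_mesh()].
#' @param plane A [clip_plane()]; geometry on the normal side is discarded.
#' @param tol On-plane tolerance (mm).
#' @return Clipped `surface_mesh` (possibly empty of faces when the whole
#'   mesh lies on the discard side).
#' @export
clip_mesh <- function(mesh, plane, tol = 1e-9) {
  v <- mesh$vertices
  f <- mesh$faces
  s <- as.vector((v - matrix(plane$point, nrow(v), 3, byrow = TRUE)) %*%
                   plane$normal)
  cls <- ifelse(s > tol, 1L, ifelse(s < -tol, -1L, 0L))
  fc <- matrix(cls[f], ncol = 3)
  npos <- rowSums(fc > 0)
  keep_whole <- npos == 0L
  drop_whole <- rowSums(fc < 0) == 0L & npos > 0L
  crossing <- which(!keep_whole & !drop_whole)

  new_v <- list()
  edge_cache <- new.env(hash = TRUE, parent = emptyenv())
  nv0 <- nrow(v)
  get_cut <- function(i, j) {
    key <- paste(min(i, j), max(i, j), sep = "_")
    idx <- edge_cache[[key]]
    if (!is.null(idx)) return(idx)
    t <- s[i] / (s[i] - s[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    new_v[[length(new_v) + 1L]] <<- p
    idx <- nv0 + length(new_v)
    edge_cache[[key]] <- idx
    idx
  }

  new_f <- list()
  for (fi in crossing) {
    ids <- f[fi, ]
    cl <- cls[ids]
    # walk the triangle boundary, collecting the kept polygon in order
    poly <- integer(0)
    for (k in 1:3) {
      i <- ids[k]; j <- ids[if (k == 3L) 1L else k + 1L]
      if (cl[k] <= 0L) poly <- c(poly, i)
      if (cl[k] * cls[j] < 0L) poly <- c(poly, get_cut(i, j))
    }
    if (length(poly) >= 3L)
      for (k in 2:(length(poly) - 1L))
        new_f[[length(new_f) + 1L]] <- poly[c(1L, k, k + 1L)]
  }

  v_out <- if (length(new_v)) rbind(v, do.call(rbind, new_v)) else v
  f_out <- rbind(f[keep_whole, , drop = FALSE],
                 if (length(new_f)) do.call(rbind, new_f))
  if (is.null(f_out) || nrow(f_out) == 0L) {
    out <- surface_mesh(v_out[1, , drop = FALSE],
                        matrix(integer(0), 0, 3), bone = mesh$bone,
                        side = mesh$side, subject_id = mesh$subject_id,
                        validate = FALSE)
    return(out)
  }
  storage.mode(f_out) <- "integer"
  out <- surface_mesh(v_out, f_out, bone = mesh$bone, side = mesh$side,
                      subject_id = mesh$subject_id, validate = FALSE)
  out <- drop_degenerate_faces(out)
  out <- drop_unreferenced_vertices(out)
  validate_mesh(out)
  out
}
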