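#' Triangulated bone surface mesh
#'
#' Constructs a `surface_mesh`, the package's container for a triangulated
#' bone surface in millimetres. Faces are vertex-index triples wound
#' counter-clockwise when seen from outside the bone, so that for a closed
#' mesh the signed volume is positive.
#'
#' @param vertices Numeric matrix, one row per vertex, 3 columns (x, y, z)
#'   in mm.
#' @param faces Integer matrix, one row per triangle, 3 columns of 1-based
#'   vertex indices.
#' @param bone Bone label: one of `"tibia"`, `"fibula"`, `"talus"`,
#'   `"synthetic"`.
#' @param side `"left"`, `"right"` or `"n/a"`.
#' @param subject_id Opaque subject identifier string.
#' @param validate Run invariant checks (default `TRUE`).
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, bone = "synthetic", side = "n/a",
                         subject_id = NA_character_, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  m <- structure(
    list(vertices = vertices, faces = faces, bone = bone, side = side,
         subject_id = subject_id),
    class = "surface_mesh"
  )
  if (validate) validate_mesh(m)
  m
}

#' Validate surface-mesh invariants
#'
#' Checks finite coordinates, in-range face indices, no repeated vertex
#' within a face, and recognized metadata labels. Stops on violation.
#'
#' @param mesh A `surface_mesh`.
#' @return The mesh, invisibly.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!is.matrix(v) || ncol(v) != 3L)
    stop("vertices must be an n x 3 matrix")
  if (nrow(v) == 0L) stop("mesh has no vertices")
  if (!all(is.finite(v))) stop("non-finite vertex coordinates")
  if (!is.matrix(f) || ncol(f) != 3L)
    stop("faces must be an m x 3 matrix of vertex indices")
  if (nrow(f) > 0L) {
    if (min(f) < 1L || max(f) > nrow(v))
      stop("face index out of range")
    if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]))
      stop("face repeats a vertex")
  }
  if (!mesh$bone %in% c("tibia", "fibula", "talus", "synthetic"))
    stop("unknown bone label: ", mesh$bone)
  if (!mesh$side %in% c("left", "right", "n/a"))
    stop("unknown side: ", mesh$side)
  invisible(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %s (%s) subject=%s: %d vertices, %d faces\n",
              x$bone, x$side, x$subject_id, nrow(x$vertices),
              nrow(x$faces)))
  invisible(x)
}

#' Per-face unit normals and areas
#'
#' @param mesh A `surface_mesh`.
#' @return List with `normals` (m x 3, unit length; zero rows for
#'   degenerate faces) and `areas` (length m, mm^2).
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(cr^2))
  areas <- nrm / 2
  normals <- cr / ifelse(nrm > 0, nrm, 1)
  list(normals = normals, areas = areas)
}

#' Outward vertex normals (area-weighted)
#'
#' Averages incident face normals weighted by face area, then normalizes.
#' With counter-clockwise winding these point outward from the bone.
#'
#' @param mesh A `surface_mesh`.
#' @return n x 3 matrix of unit normals (zero rows for isolated vertices).
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  f <- mesh$faces
  w <- fn$normals * fn$areas
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    n[, 1] <- n[, 1] + unname(tapply2(w[, 1], f[, k], nrow(n)))
    n[, 2] <- n[, 2] + unname(tapply2(w[, 2], f[, k], nrow(n)))
    n[, 3] <- n[, 3] + unname(tapply2(w[, 3], f[, k], nrow(n)))
  }
  len <- sqrt(rowSums(n^2))
  n / ifelse(len > 0, len, 1)
}

# sum `vals` into bins given by `idx` over 1..n (fast accumulation)
tapply2 <- function(vals, idx, n) {
  out <- numeric(n)
  acc <- rowsum(vals, idx)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}

#' Total surface area of a mesh
#' @param mesh A `surface_mesh`.
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_normals(mesh)$areas)

#' Signed volume enclosed by a mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for a
#' closed, outward-oriented mesh. Meaningful only for closed meshes.
#'
#' @param mesh A `surface_mesh`.
#' @return Signed volume in mm^3.
#' @export
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Mirror a mesh across a coordinate plane
#'
#' Reflects the mesh (by default across the YZ plane, x -> -x) and reverses
#' the face winding so outward orientation is preserved. Left/right side
#' metadata is flipped. Applying twice returns the original mesh.
#'
#' @param mesh A `surface_mesh`.
#' @param axis Coordinate axis to negate: 1 (x, default), 2 or 3.
#' @return The mirrored `surface_mesh`.
#' @export
reflect_mesh <- function(mesh, axis = 1L) {
  stopifnot(axis %in% 1:3)
  v <- mesh$vertices
  v[, axis] <- -v[, axis]
  f <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  side <- switch(mesh$side, left = "right", right = "left", "n/a")
  surface_mesh(v, f, bone = mesh$bone, side = side,
               subject_id = mesh$subject_id, validate = FALSE)
}

#' Closest-point distance from each vertex of one mesh to another surface
#'
#' For every vertex of `meshA`, the unsigned distance to the closest point
#' on any triangle of `meshB` (true point-to-triangle distance, not
#' vertex-to-vertex).
#'
#' @param meshA Query `surface_mesh` (distances are reported on its
#'   vertices).
#' @param meshB Target `surface_mesh`.
#' @return Numeric vector of distances (mm), one per vertex of `meshA`.
#' @export
surface_to_surface_distance <- function(meshA, meshB) {
  if (nrow(meshB$faces) == 0L) stop("target mesh has no faces")
  cpp_closest_on_surface(meshA$vertices, meshB$vertices,
                         meshB$faces)$distance
}

#' Closest points on a surface
#'
#' Lower-level variant of [surface_to_surface_distance()] for arbitrary
#' query points: returns the closest surface point, its distance, and the
#' face it lies on.
#'
#' @param points q x 3 matrix of query points.
#' @param mesh Target `surface_mesh`.
#' @return List with `distance`, `closest` (q x 3) and `face` (1-based).
#' @export
closest_on_surface <- function(points, mesh) {
  points <- matrix(as.double(points), ncol = 3)
  cpp_closest_on_surface(points, mesh$vertices, mesh$faces)
}

# drop zero-area faces (used after clipping / decimation)
drop_degenerate_faces <- function(mesh, tol = 1e-12) {
  ar <- face_normals(mesh)$areas
  keep <- ar > tol
  mesh$faces <- mesh$faces[keep, , drop = FALSE]
  mesh
}

# remove vertices not referenced by any face, remapping face indices
drop_unreferenced_vertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  mesh$vertices <- mesh$vertices[used, , drop = FALSE]
  mesh$faces <- matrix(map[mesh$faces], ncol = 3)
  storage.mode(mesh$faces) <- "integer"
  mesh
}
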