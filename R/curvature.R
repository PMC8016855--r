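# Discrete per-vertex curvature with the bone-outward sign convention:
# mean curvature H from the cotangent mean-curvature normal over mixed
# Voronoi areas, Gaussian curvature G from the angle defect, principal
# curvatures from H and G. Convex bone regions have H > 0.

#' Per-vertex discrete curvature of a triangle mesh
#'
#' Mean curvature `H` (mm^-1) from the cotangent-weighted mean-curvature
#' normal with mixed Voronoi vertex areas, signed by the outward vertex
#' normal; Gaussian curvature `G` (mm^-2) from the angle defect; principal
#' curvatures `Kmin <= Kmax` via [principal_from_HG()]. Boundary vertices
#' (incident to an open edge) are flagged: their estimates lack a full
#' one-ring and are excluded from region seeding downstream.
#'
#' @param mesh A consistently wound [surface_mesh()].
#' @return A `curvature_field` tibble with columns `vertex_id`, `H`, `G`,
#'   `Kmin`, `Kmax`, `clamped` (discriminant clamped to 0), `boundary`,
#'   and `area` (mixed Voronoi area, mm^2; angle defect = `G * area`).
#' @export
curvature_field <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  nv <- nrow(v)

  # winding consistency: no directed edge may appear twice
  de <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- de[, 1] + (nv + 1) * de[, 2]
  if (anyDuplicated(key))
    stop("inconsistent face winding (directed edge repeated)")
  # boundary edges appear in only one direction
  rkey <- de[, 2] + (nv + 1) * de[, 1]
  open_edge <- !(key %in% rkey)
  boundary <- rep(FALSE, nv)
  boundary[unique(as.vector(de[open_edge, ]))] <- TRUE

  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  e12 <- v[i2, , drop = FALSE] - v[i1, , drop = FALSE]
  e13 <- v[i3, , drop = FALSE] - v[i1, , drop = FALSE]
  e23 <- v[i3, , drop = FALSE] - v[i2, , drop = FALSE]
  l12 <- rowSums(e12^2); l13 <- rowSums(e13^2); l23 <- rowSums(e23^2)
  cr <- cbind(e12[, 2] * e13[, 3] - e12[, 3] * e13[, 2],
              e12[, 3] * e13[, 1] - e12[, 1] * e13[, 3],
              e12[, 1] * e13[, 2] - e12[, 2] * e13[, 1])
  dbl_area <- sqrt(rowSums(cr^2))
  if (any(dbl_area < 1e-14)) stop("degenerate face in curvature input")

  # corner angles and cotangents
  ang1 <- acos(pmin(1, pmax(-1, rowSums(e12 * e13) /
                              sqrt(l12 * l13))))
  ang2 <- acos(pmin(1, pmax(-1, rowSums(-e12 * e23) /
                              sqrt(l12 * l23))))
  ang3 <- pi - ang1 - ang2
  cot1 <- cos(ang1) / sin(ang1)
  cot2 <- cos(ang2) / sin(ang2)
  cot3 <- cos(ang3) / sin(ang3)

  # mixed Voronoi areas (Meyer et al.): circumcentric for non-obtuse
  # triangles, area/2 at the obtuse corner and area/4 elsewhere otherwise
  area_f <- dbl_area / 2
  amix <- numeric(nv)
  obtuse1 <- ang1 > pi / 2; obtuse2 <- ang2 > pi / 2
  obtuse3 <- ang3 > pi / 2
  any_obt <- obtuse1 | obtuse2 | obtuse3
  vor1 <- (l12 * cot3 + l13 * cot2) / 8
  vor2 <- (l12 * cot3 + l23 * cot1) / 8
  vor3 <- (l13 * cot2 + l23 * cot1) / 8
  a1 <- ifelse(any_obt, ifelse(obtuse1, area_f / 2, area_f / 4), vor1)
  a2 <- ifelse(any_obt, ifelse(obtuse2, area_f / 2, area_f / 4), vor2)
  a3 <- ifelse(any_obt, ifelse(obtuse3, area_f / 2, area_f / 4), vor3)
  amix <- tapply2(a1, i1, nv) + tapply2(a2, i2, nv) + tapply2(a3, i3, nv)

  # cotangent mean-curvature normal: K_i = sum over opposite corners of
  # cot(angle) * (x_i - x_j), assembled per face corner
  K <- matrix(0, nv, 3)
  addK <- function(i, j, w) {
    d <- (v[i, , drop = FALSE] - v[j, , drop = FALSE]) * w
    K[, 1] <<- K[, 1] + tapply2(d[, 1], i, nv)
    K[, 2] <<- K[, 2] + tapply2(d[, 2], i, nv)
    K[, 3] <<- K[, 3] + tapply2(d[, 3], i, nv)
  }
  # edge (1,2) opposite corner 3, etc.; each direction accumulated
  addK(i1, i2, cot3); addK(i2, i1, cot3)
  addK(i2, i3, cot1); addK(i3, i2, cot1)
  addK(i1, i3, cot2); addK(i3, i1, cot2)
  K <- K / (2 * pmax(amix, 1e-300))

  vn <- vertex_normals(mesh)
  Hmag <- sqrt(rowSums(K^2)) / 2
  H <- Hmag * sign(rowSums(K * vn))

  defect <- rep(2 * pi, nv)
  defect[boundary] <- pi
  defect <- defect - (tapply2(ang1, i1, nv) + tapply2(ang2, i2, nv) +
                        tapply2(ang3, i3, nv))
  G <- defect / pmax(amix, 1e-300)

  pk <- principal_from_HG(H, G)
  out <- tibble::tibble(vertex_id = seq_len(nv), H = H, G = G,
                        Kmin = pk$Kmin, Kmax = pk$Kmax,
                        clamped = pk$clamped, boundary = boundary,
                        area = amix)
  class(out) <- c("curvature_field", class(out))
  out
}

#' Principal curvatures from mean and Gaussian curvature
#'
#' `Kmin = H - sqrt(max(H^2 - G, 0))`, `Kmax = H + sqrt(max(H^2 - G, 0))`.
#' Discrete H and G need not satisfy `H^2 >= G`; negative discriminants
#' are clamped to zero and flagged.
#'
#' @param H,G Numeric vectors of mean (mm^-1) and Gaussian (mm^-2)
#'   curvature.
#' @param tol Discriminant flag tolerance (default 1e-9).
#' @return List with `Kmin`, `Kmax`, `clamped`.
#' @export
principal_from_HG <- function(H, G, tol = 1e-9) {
  disc <- H^2 - G
  clamped <- disc < -tol
  s <- sqrt(pmax(disc, 0))
  list(Kmin = H - s, Kmax = H + s, clamped = clamped)
}

#' Second principal curvature
#'
#' The algebraically smaller principal curvature `Kmin` at each vertex,
#' the quantity used to seed articular regions (strongly negative on
#' concave sockets, near zero on flats, positive on convex caps).
#'
#' @param field A `curvature_field` from [curvature_field()].
#' @return Numeric vector of `Kmin` (mm^-1).
#' @export
second_principal_curvature <- function(field) field$Kmin

#' Export a curvature field as CSV
#' @param field A `curvature_field`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_curvature_csv <- function(field, path) {
  utils::write.csv(as.data.frame(field[c("vertex_id", "H", "G", "Kmin",
                                         "Kmax", "clamped")]),
                   path, row.names = FALSE)
  invisible(path)
}
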