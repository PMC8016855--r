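#' Clipping plane
#'
#' A plane given by a point and a unit normal. By convention, geometry on
#' the normal side of the plane is discarded by [clip_mesh()] (the normal
#' points proximal for the shaft cutting plane).
#'
#' @param point 3-vector, a point on the plane (mm).
#' @param normal 3-vector; normalized internally, must be non-zero.
#' @return An object of class `clip_plane`.
#' @export
clip_plane <- function(point, normal) {
  point <- as.numeric(point)
  normal <- as.numeric(normal)
  stopifnot(length(point) == 3L, length(normal) == 3L)
  len <- sqrt(sum(normal^2))
  if (len < 1e-12) stop("plane normal must be non-zero")
  structure(list(point = point, normal = normal / len),
            class = "clip_plane")
}

#' @export
print.clip_plane <- function(x, ...) {
  cat(sprintf("<clip_plane> point (%.3f, %.3f, %.3f), normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Rigid (or similarity) transform
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation 3-vector (mm).
#' @param scale Positive scalar; 1 for a pure rigid transform.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L, scale > 0)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0) stop("rotation must be proper (det +1)")
  structure(list(rotation = rotation, translation = translation,
                 scale = scale),
            class = "rigid_transform")
}

#' Apply a transform to points or a mesh
#'
#' Maps `x` to `scale * R x + t`. For a `surface_mesh` the faces and
#' metadata are carried over unchanged.
#'
#' @param transform A [rigid_transform()].
#' @param x n x 3 matrix of points, or a `surface_mesh`.
#' @return Transformed points or mesh.
#' @export
apply_transform <- function(transform, x) {
  if (inherits(x, "surface_mesh")) {
    x$vertices <- apply_transform(transform, x$vertices)
    return(x)
  }
  p <- matrix(as.numeric(x), ncol = 3)
  p <- transform$scale * (p %*% t(transform$rotation))
  sweep(p, 2L, transform$translation, `+`)
}

#' Invert a rigid/similarity transform
#' @param transform A [rigid_transform()].
#' @return The inverse transform.
#' @export
invert_transform <- function(transform) {
  Rinv <- t(transform$rotation)
  s <- transform$scale
  rigid_transform(Rinv, -(Rinv %*% transform$translation) / s, 1 / s)
}

#' Serialize / deserialize a transform as JSON
#'
#' Rotation is stored row-major.
#'
#' @param transform A [rigid_transform()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (or `path` invisibly when written to file).
#' @export
transform_to_json <- function(transform, path = NULL) {
  obj <- list(rotation = as.vector(t(transform$rotation)),
              translation = transform$translation,
              scale = transform$scale)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname transform_to_json
#' @param json JSON string or file path produced by [transform_to_json()].
#' @export
transform_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  rigid_transform(matrix(obj$rotation, 3, 3, byrow = TRUE),
                  obj$translation, obj$scale)
}
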