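# Thin-plate-spline interpolation in 3D with the biharmonic kernel
# U(r) = r and zero regularization: control displacements are exact
# interpolation constraints. Used to warp the template surface by
# particle displacement fields.

#' Fit a 3D thin-plate-spline deformation
#'
#' @param control n x 3 matrix of control points.
#' @param target n x 3 matrix of their displaced positions.
#' @return A `tps_warp` object usable with [tps_apply()].
#' @export
tps_fit <- function(control, target) {
  C <- matrix(as.numeric(control), ncol = 3)
  Y <- matrix(as.numeric(target), ncol = 3)
  n <- nrow(C)
  stopifnot(nrow(Y) == n, n >= 4L)
  K <- as.matrix(stats::dist(C))
  Pm <- cbind(1, C)
  L <- rbind(cbind(K, Pm), cbind(t(Pm), matrix(0, 4, 4)))
  rhs <- rbind(Y, matrix(0, 4, 3))
  coef <- solve(L, rhs)
  structure(list(control = C, w = coef[seq_len(n), , drop = FALSE],
                 affine = coef[n + 1:4, , drop = FALSE]),
            class = "tps_warp")
}

#' Evaluate a thin-plate-spline deformation at points
#'
#' @param warp A `tps_warp` from [tps_fit()].
#' @param points q x 3 matrix.
#' @return q x 3 matrix of warped points.
#' @export
tps_apply <- function(warp, points) {
  P <- matrix(as.numeric(points), ncol = 3)
  # kernel matrix between query and control points, chunked for memory
  out <- matrix(0, nrow(P), 3)
  chunk <- 4096L
  for (st in seq(1L, nrow(P), by = chunk)) {
    en <- min(st + chunk - 1L, nrow(P))
    Q <- P[st:en, , drop = FALSE]
    d2 <- outer(rowSums(Q^2), rowSums(warp$control^2), `+`) -
      2 * Q %*% t(warp$control)
    U <- sqrt(pmax(d2, 0))
    out[st:en, ] <- U %*% warp$w + cbind(1, Q) %*% warp$affine
  }
  out
}

#' Warp a mesh with a thin-plate spline
#'
#' @param mesh A [surface_mesh()].
#' @param control,target Control points and their displaced positions.
#' @return Warped `surface_mesh`.
#' @export
tps_warp_mesh <- function(mesh, control, target) {
  w <- tps_fit(control, target)
  mesh$vertices <- tps_apply(w, mesh$vertices)
  mesh
}
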