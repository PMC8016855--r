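# Rigid and similarity registration: Kabsch/Umeyama least-squares fit,
# point-to-surface ICP (the cohort is aligned to the talus), and
# generalized Procrustes analysis with optional scaling removal.

#' Least-squares rigid (or similarity) fit between paired point sets
#'
#' Finds the proper rotation R, translation t (and optionally scale s)
#' minimizing sum ||s R x_i + t - y_i||^2 over paired points. Reflections
#' are never returned.
#'
#' @param source_points,target_points n x 3 matrices, paired by row,
#'   n >= 3, non-collinear.
#' @param allow_scale If `TRUE`, fit a similarity transform (Umeyama
#'   scale); otherwise scale is fixed at 1.
#' @return A [rigid_transform()].
#' @export
best_fit_rigid <- function(source_points, target_points,
                           allow_scale = FALSE) {
  X <- matrix(as.numeric(source_points), ncol = 3)
  Y <- matrix(as.numeric(target_points), ncol = 3)
  if (nrow(X) != nrow(Y)) stop("point counts differ")
  if (nrow(X) < 3L) stop("need at least 3 point pairs")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2L, mx); Yc <- sweep(Y, 2L, my)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) point configuration")
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  s <- 1
  if (allow_scale) {
    varx <- sum(Xc^2)
    s <- sum(sv$d * diag(S)) / varx
    if (s <= 0) stop("non-positive scale in similarity fit")
  }
  t <- my - s * as.vector(R %*% mx)
  rigid_transform(R, t, s)
}

#' Iterative closest point alignment of one mesh onto another
#'
#' Point-to-surface ICP: a fixed, seeded uniform sample of source vertices
#' is repeatedly matched to its closest points on the target surface and
#' re-fit rigidly. The RMS objective is non-increasing across iterations.
#'
#' @param source_mesh,target_mesh `surface_mesh` objects.
#' @param max_iterations Iteration cap (default 50).
#' @param rms_tolerance Stop when the RMS improves by less than this
#'   (default 1e-7 mm).
#' @param init Initial [rigid_transform()] (default identity).
#' @param n_samples Number of source vertices used (default 500, or all).
#' @param seed Integer seed for the vertex sample.
#' @return List with `transform` (a [rigid_transform()]), `rms` (final
#'   point-to-surface RMS, mm), `iterations`, `converged`, and
#'   `rms_history`.
#' @export
icp_align <- function(source_mesh, target_mesh, max_iterations = 50L,
                      rms_tolerance = 1e-7,
                      init = rigid_transform(), n_samples = 500L,
                      seed = 1L) {
  V <- source_mesh$vertices
  n <- nrow(V)
  if (n_samples < n) {
    old <- .Random.seed_save()
    set.seed(seed)
    samp <- sort(sample.int(n, n_samples))
    .Random.seed_restore(old)
  } else samp <- seq_len(n)
  P0 <- V[samp, , drop = FALSE]

  Tcur <- init
  rms_hist <- numeric(0)
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    P <- apply_transform(Tcur, P0)
    cp <- cpp_closest_on_surface(P, target_mesh$vertices,
                                 target_mesh$faces)
    rms <- sqrt(mean(cp$distance^2))
    if (length(rms_hist) && rms > rms_hist[length(rms_hist)] + 1e-12)
      stop("ICP objective increased; this should not happen")
    rms_hist <- c(rms_hist, rms)
    if (prev - rms < rms_tolerance) { converged <- TRUE; break }
    prev <- rms
    Tstep <- best_fit_rigid(P, cp$closest)
    Tcur <- compose_transforms(Tstep, Tcur)
  }
  list(transform = Tcur, rms = rms_hist[length(rms_hist)],
       iterations = length(rms_hist), converged = converged,
       rms_history = rms_hist)
}

# T2 applied first, then T1
compose_transforms <- function(T1, T2) {
  R <- T1$rotation %*% T2$rotation
  s <- T1$scale * T2$scale
  t <- T1$scale * as.vector(T1$rotation %*% T2$translation) +
    T1$translation
  rigid_transform(R, t, s)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}

#' Generalized Procrustes analysis of correspondence particle sets
#'
#' Iteratively aligns every particle set to the evolving mean with
#' similarity (or rigid) transforms until the mean stops moving. With
#' `remove_scale = TRUE` every configuration is normalized to unit
#' centroid size, removing size from the shape analysis.
#'
#' @param particle_sets List of P x 3 matrices with index correspondence.
#' @param remove_scale Normalize each set to centroid size 1 (default
#'   `TRUE`).
#' @param tol Convergence tolerance on mean movement (default 1e-10).
#' @param max_rounds Iteration cap (default 100).
#' @return List with `aligned` (list of P x 3 matrices), `mean` (P x 3),
#'   and `scale` (per-subject centroid size removed; 1s when
#'   `remove_scale = FALSE`).
#' @export
generalized_procrustes <- function(particle_sets, remove_scale = TRUE,
                                   tol = 1e-10, max_rounds = 100L) {
  if (length(particle_sets) < 2L) stop("need at least 2 particle sets")
  P <- nrow(particle_sets[[1]])
  if (!all(vapply(particle_sets, nrow, 0L) == P))
    stop("particle count mismatch across sets")

  centroid_size <- function(X) sqrt(sum(scale(X, scale = FALSE)^2))
  sizes <- vapply(particle_sets, centroid_size, 0)
  sets <- lapply(particle_sets, function(X) {
    Xc <- sweep(X, 2L, colMeans(X))
    if (remove_scale) Xc / centroid_size(X) else Xc
  })

  mean_set <- sets[[1]]
  for (round in seq_len(max_rounds)) {
    sets <- lapply(sets, function(X) {
      Tr <- best_fit_rigid(X, mean_set, allow_scale = FALSE)
      apply_transform(Tr, X)
    })
    new_mean <- Reduce(`+`, sets) / length(sets)
    if (remove_scale) new_mean <- new_mean / centroid_size(new_mean)
    delta <- sqrt(mean((new_mean - mean_set)^2))
    mean_set <- new_mean
    if (delta < tol) break
  }
  list(aligned = sets, mean = mean_set,
       scale = if (remove_scale) sizes else rep(1, length(sets)))
}

#' Common proximal cutting plane across an aligned cohort
#'
#' Returns the plane perpendicular to the shaft axis at the most proximal
#' level present in all aligned specimens: the minimum over subjects of
#' each subject's maximal extent along the axis. The plane normal points
#' proximal (along `axis`), so clipping discards the shaft above it.
#'
#' @param aligned_meshes List of `surface_mesh` objects in a common frame.
#' @param axis Shaft direction 3-vector (default +z of the aligned frame).
#' @return A [clip_plane()].
#' @export
common_cutting_plane <- function(aligned_meshes, axis = c(0, 0, 1)) {
  if (length(aligned_meshes) == 0L) stop("no meshes supplied")
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  maxima <- vapply(aligned_meshes,
                   function(m) max(m$vertices %*% axis), 0)
  level <- min(maxima)
  clip_plane(point = level * axis, normal = axis)
}
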