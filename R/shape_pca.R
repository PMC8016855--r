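# PCA of correspondence particles ("modes of variation"), Horn's parallel
# analysis for mode retention, and +/- k SD surface warps.

#' Principal-component shape modes of a correspondence model
#'
#' Runs generalized Procrustes alignment of the per-subject particle
#' arrays (removing size when `remove_scale = TRUE`) and PCA of the
#' resulting n x 3P matrix (rows mean-centred; covariance with the n-1
#' denominator, computed by singular value decomposition). Mode SD is
#' sqrt(eigenvalue); walking +/- 2 SD along a mode spans the mode's
#' visualized range.
#'
#' @param model A `correspondence_model`, or a list of P x 3 particle
#'   matrices.
#' @param remove_scale Remove size by Procrustes scaling (default `TRUE`).
#' @param restore_size After unit-size alignment, rescale shapes by the
#'   mean original centroid size so eigenvalues stay in mm^2 (default
#'   `TRUE`; ignored when `remove_scale = FALSE`).
#' @param align Run generalized Procrustes alignment first (default
#'   `TRUE`); set `FALSE` for particle arrays that are already
#'   superimposed.
#' @param n_reps,percentile,pa_seed Parallel-analysis settings (see
#'   [parallel_analysis()]).
#' @return A `shape_mode_set`: mean vector and mean particles, descending
#'   eigenvalues (mm^2), orthonormal eigenvectors (columns, length 3P),
#'   `variance_fraction`, `n_significant`, `n_subjects`, plus the aligned
#'   data matrix used.
#' @export
fit_modes <- function(model, remove_scale = TRUE, restore_size = TRUE,
                      n_reps = 200L, percentile = 95, pa_seed = 1L,
                      align = TRUE) {
  sets <- if (inherits(model, "correspondence_model")) model$particles
          else model
  n <- length(sets)
  if (n < 3L) stop("need at least 3 subjects for PCA")
  if (align) {
    g <- generalized_procrustes(sets, remove_scale = remove_scale)
    aligned <- g$aligned
    if (remove_scale && restore_size) {
      s <- mean(g$scale)
      aligned <- lapply(aligned, function(X) X * s)
    }
  } else {
    aligned <- sets
  }
  X <- t(vapply(aligned, function(m) as.vector(t(m)),
                numeric(3L * nrow(aligned[[1]]))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0)
  ev <- pmax(sv$d^2 / (n - 1), 0)
  keep <- seq_len(min(n - 1L, ncol(X)))
  ev <- ev[keep]
  vecs <- sv$v[, keep, drop = FALSE]
  vf <- if (sum(ev) > 0) ev / sum(ev) else rep(0, length(ev))
  nsig <- parallel_analysis(X, n_reps = n_reps, percentile = percentile,
                            seed = pa_seed)
  structure(
    list(mean_vector = mu,
         mean_particles = matrix(mu, ncol = 3, byrow = TRUE),
         eigenvalues = ev, eigenvectors = vecs,
         variance_fraction = vf, n_significant = nsig,
         n_subjects = n, data_matrix = X,
         settings = list(remove_scale = remove_scale,
                         restore_size = restore_size, n_reps = n_reps,
                         percentile = percentile, pa_seed = pa_seed)),
    class = "shape_mode_set")
}

#' @export
print.shape_mode_set <- function(x, ...) {
  cat(sprintf("<shape_mode_set> %d subjects, %d modes (%d significant)\n",
              x$n_subjects, length(x$eigenvalues), x$n_significant))
  invisible(x)
}

#' Horn's parallel analysis for PCA mode retention
#'
#' Compares the eigenvalues of the (column-standardized) observed data
#' with the same-rank eigenvalues of `n_reps` random matrices of matching
#' shape with independent standard-normal entries. Mode i is retained iff
#' its observed eigenvalue exceeds the chosen percentile of the null
#' eigenvalue distribution for rank i; retention stops at the first
#' failure.
#'
#' @param data_matrix n x p matrix, rows = subjects.
#' @param n_reps Number of null replicates (default 200).
#' @param percentile Null percentile used as threshold (default 95).
#' @param seed Integer seed for the null draws.
#' @return Integer: number of retained (significant) modes.
#' @export
parallel_analysis <- function(data_matrix, n_reps = 200L,
                              percentile = 95, seed = 1L) {
  X <- as.matrix(data_matrix)
  n <- nrow(X); p <- ncol(X)
  sds <- apply(X, 2L, stats::sd)
  if (all(sds < 1e-14)) return(0L)
  active <- sds > 1e-14
  Z <- scale(X[, active, drop = FALSE])
  m <- min(n - 1L, sum(active))
  obs <- (svd(Z, nu = 0, nv = 0)$d^2 / (n - 1))[seq_len(m)]

  old <- .Random.seed_save()
  set.seed(seed)
  null_ev <- matrix(0, n_reps, m)
  for (r in seq_len(n_reps)) {
    Zr <- scale(matrix(stats::rnorm(n * sum(active)), n))
    null_ev[r, ] <- (svd(Zr, nu = 0, nv = 0)$d^2 / (n - 1))[seq_len(m)]
  }
  .Random.seed_restore(old)
  thr <- apply(null_ev, 2L, stats::quantile, probs = percentile / 100)
  nsig <- 0L
  for (i in seq_len(m)) {
    if (is.na(obs[i]) || obs[i] <= thr[i]) break
    nsig <- nsig + 1L
  }
  nsig
}

#' Warp the mean surface along a shape mode
#'
#' Displaces the mean particles by `k_sd * sqrt(eigenvalue) * eigenvector`
#' for the chosen mode and warps the mean surface by thin-plate-spline
#' interpolation of the particle displacements.
#'
#' @param modeset A `shape_mode_set`.
#' @param mode_index Mode number (1-based).
#' @param k_sd Displacement in mode standard deviations (e.g. 2 or -2).
#' @param template_mesh Template subject's `surface_mesh`.
#' @param template_particles Template particle array (P x 3) matching the
#'   model the modes were fitted to.
#' @return List with `mesh` (warped `surface_mesh`), `particles` (the
#'   displaced particle array) and `mean_mesh` (the mean surface).
#' @export
warp_mode <- function(modeset, mode_index, k_sd, template_mesh,
                      template_particles) {
  if (!is.finite(k_sd)) stop("k_sd must be finite")
  if (mode_index < 1L || mode_index > length(modeset$eigenvalues))
    stop("mode_index out of range")
  mean_p <- modeset$mean_particles
  mean_mesh <- tps_warp_mesh(template_mesh, template_particles, mean_p)
  ev <- modeset$eigenvalues[mode_index]
  if (ev <= 0 && k_sd != 0) {
    warning("zero-variance mode; returning the mean surface")
    return(list(mesh = mean_mesh, particles = mean_p,
                mean_mesh = mean_mesh))
  }
  disp <- k_sd * sqrt(ev) *
    matrix(modeset$eigenvectors[, mode_index], ncol = 3, byrow = TRUE)
  new_p <- mean_p + disp
  warped <- if (k_sd == 0) mean_mesh
            else tps_warp_mesh(mean_mesh, mean_p, new_p)
  list(mesh = warped, particles = new_p, mean_mesh = mean_mesh)
}

#' Surface-distance map between mean and warped surfaces
#'
#' Per-vertex unsigned distance from the mean surface to the warped
#' surface, the quantity shown as mode color maps (mm).
#'
#' @param mean_surface,warped_surface `surface_mesh` objects.
#' @return Numeric vector, one distance per vertex of `mean_surface`.
#' @export
mode_distance_map <- function(mean_surface, warped_surface) {
  surface_to_surface_distance(mean_surface, warped_surface)
}

#' Project subjects onto shape modes
#'
#' Mode scores (principal-component coordinates) of each training subject.
#'
#' @param modeset A `shape_mode_set`.
#' @return n x n_modes matrix of scores.
#' @export
mode_scores <- function(modeset) {
  Xc <- sweep(modeset$data_matrix, 2L, modeset$mean_vector)
  Xc %*% modeset$eigenvectors
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a shape-mode set
#'
#' One row per mode: eigenvalue (mm^2), mode SD (mm), variance fraction of
#' the total, variance fraction of the significant-mode variance, and
#' whether parallel analysis retained the mode.
#'
#' @param x A `shape_mode_set`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy shape_mode_set
#' @export
tidy.shape_mode_set <- function(x, ...) {
  sig <- seq_along(x$eigenvalues) <= x$n_significant
  vsig <- sum(x$eigenvalues[sig])
  tibble::tibble(
    mode = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    sd = sqrt(x$eigenvalues),
    variance_fraction = x$variance_fraction,
    variance_fraction_significant =
      ifelse(sig & vsig > 0, x$eigenvalues / vsig, NA_real_),
    significant = sig
  )
}

#' Glance at a shape-mode set
#' @param x A `shape_mode_set`.
#' @param ... Unused.
#' @return One-row tibble with subject/mode counts and variance summaries.
#' @method glance shape_mode_set
#' @export
glance.shape_mode_set <- function(x, ...) {
  sig <- seq_along(x$eigenvalues) <= x$n_significant
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_modes = length(x$eigenvalues),
    n_significant = x$n_significant,
    total_variance = sum(x$eigenvalues),
    variance_explained_significant = sum(x$variance_fraction[sig])
  )
}

#' Scree plot of a shape-mode set
#'
#' Bars of per-mode explained variance, colored by parallel-analysis
#' retention.
#'
#' @param object A `shape_mode_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot shape_mode_set
#' @export
autoplot.shape_mode_set <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode,
                                   y = .data$variance_fraction,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mode", y = "Fraction of total variance",
                  fill = "Retained") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
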