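# Cross-subject correspondence-particle model. Particles are placed on a
# template by farthest-point sampling and propagated to every subject by
# rigid registration plus closest-point projection, a deliberately simple
# template-propagation scheme (entropy-based particle optimization as done
# by dedicated correspondence tools is out of scope; see the vignette).

#' Farthest-point sampling of mesh vertices
#'
#' Greedy max-min sampling: starting from a seeded vertex, repeatedly adds
#' the vertex farthest (Euclidean) from the current sample. Sample
#' sequences are nested, so coverage improves monotonically with P.
#'
#' @param vertices n x 3 matrix.
#' @param P Number of samples (<= n).
#' @param seed Integer seed choosing the starting vertex.
#' @param subset Optional integer vector restricting eligible vertices.
#' @return Integer vector of P vertex indices (into `vertices`).
#' @export
farthest_point_sample <- function(vertices, P, seed = 1L, subset = NULL) {
  cand <- if (is.null(subset)) seq_len(nrow(vertices)) else sort(subset)
  if (P > length(cand)) stop("P exceeds number of eligible vertices")
  V <- vertices[cand, , drop = FALSE]
  start <- (abs(seed) %% length(cand)) + 1L
  picked <- integer(P)
  picked[1L] <- start
  d <- sqrt(rowSums(sweep(V, 2L, V[start, ])^2))
  if (P > 1L) for (k in 2L:P) {
    nxt <- which.max(d)
    picked[k] <- nxt
    dn <- sqrt(rowSums(sweep(V, 2L, V[nxt, ])^2))
    d <- pmin(d, dn)
  }
  cand[picked]
}

#' Build a cross-subject correspondence-particle model
#'
#' Places `P` particles on a template subject by farthest-point sampling,
#' then propagates them to every subject by rigid ICP of the template onto
#' the subject followed by closest-point projection onto the subject
#' surface. The template is the medoid subject (minimal summed
#' closest-point RMS to all others in the aligned frame). A supplied
#' cutting plane restricts particles to the distal side.
#'
#' @param aligned_meshes Named list of mutually aligned `surface_mesh`
#'   objects (one per subject).
#' @param P Particles per bone (default 1024).
#' @param cutting_plane Optional [clip_plane()]; particle seeds and
#'   projections are restricted distal to it (the non-normal side).
#' @param seed Integer seed (farthest-point start, ICP sampling).
#' @param rounds Extra mean-repropagation rounds (default 0: single
#'   template propagation).
#' @param surface_tol Maximum allowed particle-to-surface distance (mm,
#'   default 0.5); violations are an error.
#' @return A `correspondence_model`: list with `subject_ids`, `particles`
#'   (per subject P x 3, index-matched), `mean_particles` (arithmetic mean
#'   of the pose-aligned arrays), `P`, `template_subject_id`, `gpa`
#'   (pose-only Procrustes result), and `provenance`.
#' @export
build_correspondence_model <- function(aligned_meshes, P = 1024L,
                                       cutting_plane = NULL, seed = 1L,
                                       rounds = 0L, surface_tol = 0.5) {
  n <- length(aligned_meshes)
  if (n < 2L) stop("need at least 2 subjects")
  ids <- names(aligned_meshes)
  if (is.null(ids))
    ids <- vapply(seq_len(n), function(i) {
      sid <- aligned_meshes[[i]]$subject_id
      if (is.na(sid)) sprintf("subject_%02d", i) else sid
    }, "")
  names(aligned_meshes) <- ids
  nv <- vapply(aligned_meshes, function(m) nrow(m$vertices), 0L)
  if (P > min(nv))
    stop("P exceeds the vertex count of the coarsest mesh (",
         min(nv), ")")

  distal_subset <- function(mesh) {
    if (is.null(cutting_plane)) return(seq_len(nrow(mesh$vertices)))
    s <- as.vector((mesh$vertices -
                      matrix(cutting_plane$point, nrow(mesh$vertices), 3,
                             byrow = TRUE)) %*% cutting_plane$normal)
    which(s <= 1e-9)
  }

  # template: medoid by summed sampled closest-point RMS (frames are
  # already aligned, so no re-registration is needed for the medoid)
  rms_pair <- function(a, b) {
    Va <- a$vertices
    take <- seq(1L, nrow(Va), length.out = min(200L, nrow(Va)))
    d <- cpp_closest_on_surface(Va[take, , drop = FALSE], b$vertices,
                                b$faces)$distance
    sqrt(mean(d^2))
  }
  score <- vapply(seq_len(n), function(i)
    sum(vapply(seq_len(n)[-i], function(j)
      rms_pair(aligned_meshes[[i]], aligned_meshes[[j]]), 0)), 0)
  ti <- which.min(score)
  template <- aligned_meshes[[ti]]

  tsub <- distal_subset(template)
  if (length(tsub) < P)
    stop("template subject ", ids[ti],
         " has too few vertices distal to the cutting plane")
  seeds <- farthest_point_sample(template$vertices, P, seed = seed,
                                 subset = tsub)
  tpart <- template$vertices[seeds, , drop = FALSE]

  propagate <- function(ref_particles, ref_mesh) {
    lapply(seq_len(n), function(i) {
      m <- aligned_meshes[[i]]
      if (length(distal_subset(m)) == 0L)
        stop("subject ", ids[i], " has no surface distal to the ",
             "cutting plane")
      fit <- icp_align(ref_mesh, m, seed = seed)
      pts <- apply_transform(fit$transform, ref_particles)
      cp <- cpp_closest_on_surface(pts, m$vertices, m$faces)
      cp$closest
    })
  }

  particles <- propagate(tpart, template)
  for (r in seq_len(rounds)) {
    g <- generalized_procrustes(particles, remove_scale = FALSE)
    ctr <- colMeans(do.call(rbind, lapply(particles, colMeans)))
    mn <- sweep(g$mean, 2L, ctr, `+`)
    # re-propagate from the evolving mean via the template geometry
    mwarped <- tps_warp_mesh(template, tpart, mn)
    particles <- propagate(mn, mwarped)
    tpart <- mn
  }

  # surface-proximity invariant
  for (i in seq_len(n)) {
    m <- aligned_meshes[[i]]
    d <- cpp_closest_on_surface(particles[[i]], m$vertices,
                                m$faces)$distance
    if (any(d > surface_tol))
      stop("particle farther than ", surface_tol, " mm from surface of ",
           ids[i])
  }

  g <- generalized_procrustes(particles, remove_scale = FALSE)
  # Procrustes centers configurations at the origin; restore the cohort's
  # average centroid so the mean stays in the ICP-aligned (mm) frame
  ctr <- colMeans(do.call(rbind, lapply(particles, colMeans)))
  g$aligned <- lapply(g$aligned, function(X) sweep(X, 2L, ctr, `+`))
  g$mean <- sweep(g$mean, 2L, ctr, `+`)
  names(particles) <- ids
  structure(
    list(subject_ids = ids, particles = particles, P = as.integer(P),
         mean_particles = g$mean, gpa = g,
         template_subject_id = ids[ti], template_index = ti,
         template_particles = tpart, template_seed_vertices = seeds,
         provenance = list(P = P, seed = seed, rounds = rounds,
                           surface_tol = surface_tol,
                           cutting_plane = cutting_plane)),
    class = "correspondence_model")
}

#' @export
print.correspondence_model <- function(x, ...) {
  cat(sprintf("<correspondence_model> %d subjects x %d particles (template %s)\n",
              length(x$subject_ids), x$P, x$template_subject_id))
  invisible(x)
}

#' Mean shape of a correspondence model
#'
#' Returns the mean particle array and, when the template mesh is given,
#' the mean surface: the template mesh warped by thin-plate-spline
#' interpolation of the template-particle to mean-particle displacements
#' (exact at the particles).
#'
#' @param model A `correspondence_model`.
#' @param template_mesh The template subject's `surface_mesh` (as used to
#'   build the model); when `NULL` only the mean particles are returned.
#' @return List with `mean_particles` (P x 3) and `mean_surface` (a
#'   `surface_mesh`, or `NULL`).
#' @export
mean_shape <- function(model, template_mesh = NULL) {
  surf <- NULL
  if (!is.null(template_mesh)) {
    surf <- tps_warp_mesh(template_mesh, model$template_particles,
                          model$mean_particles)
    surf$subject_id <- "mean"
  }
  list(mean_particles = model$mean_particles, mean_surface = surf)
}

#' Map mean particles onto a subject mesh
#'
#' Rigidly aligns the subject to the mean shape (ICP onto the mean
#' surface when supplied; subjects already in the model frame can skip
#' alignment) and assigns each particle its nearest subject vertex, ties
#' broken by lowest index.
#'
#' @param mean_particles P x 3 matrix (model frame).
#' @param subject_mesh The subject's `surface_mesh`.
#' @param mean_surface Optional mean `surface_mesh` used as the ICP target;
#'   when `NULL` the subject is assumed to be in the model frame already.
#' @param seed Seed for ICP sampling.
#' @return A tibble with `particle_id`, `vertex_id` (nearest subject
#'   vertex, in the subject's own indexing) and `residual` (mm).
#' @export
map_particles <- function(mean_particles, subject_mesh,
                          mean_surface = NULL, seed = 1L) {
  mesh <- subject_mesh
  if (!is.null(mean_surface)) {
    fit <- icp_align(subject_mesh, mean_surface, seed = seed)
    mesh <- apply_transform(fit$transform, subject_mesh)
  }
  V <- mesh$vertices
  P <- matrix(as.numeric(mean_particles), ncol = 3)
  idx <- integer(nrow(P))
  res <- numeric(nrow(P))
  for (i in seq_len(nrow(P))) {
    d2 <- (V[, 1] - P[i, 1])^2 + (V[, 2] - P[i, 2])^2 +
      (V[, 3] - P[i, 3])^2
    idx[i] <- which.min(d2)   # first minimum = lowest index on ties
    res[i] <- sqrt(d2[idx[i]])
  }
  tibble::tibble(particle_id = seq_len(nrow(P)), vertex_id = idx,
                 residual = res)
}

#' Serialize a correspondence model to a directory
#'
#' One CSV per subject (`particle_id, x, y, z`), the mean particles, and a
#' JSON manifest with provenance.
#'
#' @param model A `correspondence_model`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_correspondence_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(mat, path) {
    utils::write.csv(data.frame(particle_id = seq_len(nrow(mat)),
                                x = mat[, 1], y = mat[, 2], z = mat[, 3]),
                     path, row.names = FALSE)
  }
  for (id in model$subject_ids)
    wr(model$particles[[id]], file.path(dir, paste0(id, ".csv")))
  wr(model$mean_particles, file.path(dir, "mean_particles.csv"))
  manifest <- list(subject_ids = model$subject_ids, P = model$P,
                   template_subject_id = model$template_subject_id,
                   provenance = model$provenance[c("P", "seed", "rounds",
                                                   "surface_tol")])
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(dir, "manifest.json"))
  invisible(dir)
}
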