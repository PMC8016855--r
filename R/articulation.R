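# Joint-level analyses: articular region seeding by second principal
# curvature, coverage by surface-normal ray intersection between mated
# surfaces, joint-space distance mapping, the Ateshian congruence index,
# per-particle population aggregation, and paired-area statistics.

#' Articular region of a bone surface
#'
#' @param mesh The host `surface_mesh`.
#' @param vertex_ids Member vertex indices.
#' @param stage `"candidate"` (curvature-seeded) or `"covered"`.
#' @param joint_label One of `"tibiotalar"`, `"tibiofibular"`,
#'   `"talofibular"`, `"synthetic"`.
#' @return An `articular_region`: vertex ids, face ids (faces with all
#'   three vertices in the region), and summed face area (mm^2).
#' @export
articular_region <- function(mesh, vertex_ids, stage = "candidate",
                             joint_label = "synthetic") {
  vertex_ids <- sort(unique(as.integer(vertex_ids)))
  if (any(vertex_ids < 1L | vertex_ids > nrow(mesh$vertices)))
    stop("vertex id out of range")
  inreg <- logical(nrow(mesh$vertices))
  inreg[vertex_ids] <- TRUE
  f <- mesh$faces
  face_ids <- which(inreg[f[, 1]] & inreg[f[, 2]] & inreg[f[, 3]])
  areas <- face_normals(mesh)$areas
  structure(list(mesh = mesh, vertex_ids = vertex_ids,
                 face_ids = face_ids, area = sum(areas[face_ids]),
                 stage = stage, joint_label = joint_label),
            class = "articular_region")
}

#' @export
print.articular_region <- function(x, ...) {
  cat(sprintf("<articular_region> %s (%s): %d vertices, %d faces, %.2f mm^2\n",
              x$joint_label, x$stage, length(x$vertex_ids),
              length(x$face_ids), x$area))
  invisible(x)
}

#' Seed a candidate articular region by second principal curvature
#'
#' Selects vertices by a threshold on the second (smaller) principal
#' curvature, restricts the selection to its largest connected component
#' on the mesh graph, and optionally dilates by whole rings. Boundary
#' vertices are excluded from seeding by default (their curvature is
#' unreliable), but dilation may re-admit them.
#'
#' @param mesh A `surface_mesh` with curvature computed.
#' @param field Its [curvature_field()].
#' @param threshold_spec List: either `list(value = v, comparison =
#'   "less")` selecting `Kmin < v` (concave targets) / `"greater"` for
#'   `Kmin > v`, or `list(percentile = q, comparison = ...)` thresholding
#'   at the q-th percentile of `Kmin` over non-boundary vertices.
#' @param dilate_rings Number of one-ring dilations (default 0).
#' @param exclude_boundary Drop boundary vertices from the initial
#'   selection (default `TRUE`).
#' @param joint_label Joint label recorded on the region.
#' @return An `articular_region` at stage `"candidate"`.
#' @export
candidate_region <- function(mesh, field, threshold_spec,
                             dilate_rings = 0L, exclude_boundary = TRUE,
                             joint_label = "synthetic") {
  k2 <- second_principal_curvature(field)
  cmp <- threshold_spec$comparison
  if (is.null(cmp)) cmp <- "less"
  eligible <- if (exclude_boundary) !field$boundary
              else rep(TRUE, length(k2))
  thr <- threshold_spec$value
  if (is.null(thr)) {
    if (is.null(threshold_spec$percentile))
      stop("threshold_spec needs $value or $percentile")
    thr <- stats::quantile(k2[eligible],
                           probs = threshold_spec$percentile / 100,
                           names = FALSE)
  }
  sel <- eligible & (if (cmp == "less") k2 < thr else k2 > thr)
  if (!any(sel))
    stop(sprintf("empty selection for threshold Kmin %s %.4g",
                 ifelse(cmp == "less", "<", ">"), thr))

  # largest connected component on the vertex graph
  e <- mesh_edges(mesh$faces)
  keep_e <- sel[e[, 1]] & sel[e[, 2]]
  verts <- which(sel)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(e[keep_e, , drop = FALSE]), ncol = 2),
    directed = FALSE)
  g <- igraph::add_vertices(
    g, sum(!as.character(verts) %in% igraph::V(g)$name),
    name = setdiff(as.character(verts), igraph::V(g)$name))
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  ids <- as.integer(igraph::V(g)$name[comp$membership == big])

  if (dilate_rings > 0L) {
    inreg <- logical(nrow(mesh$vertices))
    inreg[ids] <- TRUE
    for (r in seq_len(dilate_rings)) {
      grow <- inreg[e[, 1]] | inreg[e[, 2]]
      inreg[e[grow, 1]] <- TRUE
      inreg[e[grow, 2]] <- TRUE
    }
    ids <- which(inreg)
  }
  articular_region(mesh, ids, stage = "candidate",
                   joint_label = joint_label)
}

#' Articular coverage by surface-normal ray intersection
#'
#' A vertex of region A is covered iff the ray from it along its outward
#' vertex normal intersects a candidate face of region B within
#' `max_ray_length`, and symmetrically for B. Covered faces are faces
#' whose three vertices are all covered; their summed area is the coverage
#' area. Both meshes must be posed in a shared (weightbearing) frame.
#'
#' @param regionA,regionB `articular_region`s on two distinct meshes.
#' @param max_ray_length Maximum ray length (mm, default 10).
#' @param joint_label Label recorded on the covered regions (defaults to
#'   `regionA$joint_label`).
#' @return List with `coveredA` and `coveredB` (`articular_region`s at
#'   stage `"covered"`).
#' @export
coverage <- function(regionA, regionB, max_ray_length = 10,
                     joint_label = regionA$joint_label) {
  if (identical(regionA$mesh$vertices, regionB$mesh$vertices) &&
      identical(regionA$mesh$faces, regionB$mesh$faces))
    stop("regions must lie on distinct meshes")
  cov_one <- function(ra, rb) {
    mesh <- ra$mesh
    vn <- vertex_normals(mesh)
    ids <- ra$vertex_ids
    fb <- rb$mesh$faces[rb$face_ids, , drop = FALSE]
    if (nrow(fb) == 0L) return(integer(0))
    hit <- cpp_ray_hits(mesh$vertices[ids, , drop = FALSE],
                        vn[ids, , drop = FALSE],
                        rb$mesh$vertices, fb, max_ray_length)$hit
    ids[hit]
  }
  ca <- cov_one(regionA, regionB)
  cb <- cov_one(regionB, regionA)
  list(coveredA = articular_region(regionA$mesh, ca, stage = "covered",
                                   joint_label = joint_label),
       coveredB = articular_region(regionB$mesh, cb, stage = "covered",
                                   joint_label = joint_label))
}

#' Joint-space distance at covered nodes
#'
#' Unsigned closest-point (point-to-triangle) distance from every covered
#' vertex of one articular surface to the opposing bone surface: the
#' subchondral bone-to-bone joint space.
#'
#' @param covered A covered `articular_region`.
#' @param opposing_mesh The opposing bone's `surface_mesh`.
#' @return Tibble with `vertex_id` and `distance` (mm).
#' @export
joint_space <- function(covered, opposing_mesh) {
  if (length(covered$vertex_ids) == 0L)
    stop("empty covered region")
  pts <- covered$mesh$vertices[covered$vertex_ids, , drop = FALSE]
  d <- cpp_closest_on_surface(pts, opposing_mesh$vertices,
                              opposing_mesh$faces)$distance
  tibble::tibble(vertex_id = covered$vertex_ids, distance = d)
}

#' Congruence index at paired articular points
#'
#' For each evaluation point, principal curvatures on both surfaces are
#' derived from mean and Gaussian curvature (`Kmin = H - sqrt(H^2 - G)`,
#' `Kmax = H + sqrt(H^2 - G)`), the curvature differences are
#' `D = Kmin - Kmax` per surface, and with the small-angle approximation
#' (`cos 2a = 1`, the points being paired perpendicularly) the relative
#' curvature spread is `delta = |D1 + D2|`. The relative principal
#' curvatures are `Ke_min = H1 + H2 - delta/2` and
#' `Ke_max = H1 + H2 + delta/2`, and the congruence index is their RMS,
#' `CI = sqrt((Ke_min^2 + Ke_max^2)/2)` (mm^-1); 0 indicates perfect
#' congruence at a locally spherical contact.
#'
#' @param H1,G1 Mean/Gaussian curvature on surface 1 at the evaluation
#'   points (numeric vectors).
#' @param H2,G2 Curvatures on surface 2 at the paired points.
#' @return Tibble with `D1`, `D2`, `delta`, `alpha` (identically 0),
#'   `Ke_min`, `Ke_max`, `CI`.
#' @export
congruence_index <- function(H1, G1, H2, G2) {
  p1 <- principal_from_HG(H1, G1)
  p2 <- principal_from_HG(H2, G2)
  D1 <- p1$Kmin - p1$Kmax
  D2 <- p2$Kmin - p2$Kmax
  delta2 <- D1^2 + D2^2 + 2 * D1 * D2   # cos 2a = 1
  delta <- sqrt(pmax(delta2, 0))
  Ke_min <- H1 + H2 - delta / 2
  Ke_max <- H1 + H2 + delta / 2
  CI <- sqrt((Ke_min^2 + Ke_max^2) / 2)
  tibble::tibble(D1 = D1, D2 = D2, delta = delta, alpha = 0,
                 Ke_min = Ke_min, Ke_max = Ke_max, CI = CI)
}

#' Congruence records over a covered region pair
#'
#' Evaluation points are the covered vertices of the first surface; the
#' paired point on the opposing surface is its nearest covered vertex
#' there. Curvatures are looked up per vertex from the two fields.
#'
#' @param coveredA,coveredB Covered `articular_region`s.
#' @param curvA,curvB Their meshes' [curvature_field()]s.
#' @return Tibble: `vertex_a`, `vertex_b`, plus the [congruence_index()]
#'   columns.
#' @export
congruence <- function(coveredA, coveredB, curvA, curvB) {
  if (length(coveredA$vertex_ids) == 0L ||
      length(coveredB$vertex_ids) == 0L)
    stop("empty covered region")
  pa <- coveredA$mesh$vertices[coveredA$vertex_ids, , drop = FALSE]
  pb <- coveredB$mesh$vertices[coveredB$vertex_ids, , drop = FALSE]
  # nearest opposing covered vertex for each evaluation point
  nb <- integer(nrow(pa))
  for (i in seq_len(nrow(pa))) {
    d2 <- (pb[, 1] - pa[i, 1])^2 + (pb[, 2] - pa[i, 2])^2 +
      (pb[, 3] - pa[i, 3])^2
    nb[i] <- which.min(d2)
  }
  va <- coveredA$vertex_ids
  vb <- coveredB$vertex_ids[nb]
  rec <- congruence_index(curvA$H[va], curvA$G[va],
                          curvB$H[vb], curvB$G[vb])
  tibble::tibble(vertex_a = va, vertex_b = vb, rec)
}

#' Population particle map of a joint scalar field
#'
#' Aggregates a subject-by-particle table of joint values (distance in mm
#' or congruence index in mm^-1, `NA` where a subject's mapped node is not
#' in the covered region). A particle is included when it has a value for
#' at least `min_fraction` of subjects. Reports per-particle mean/SD
#' across subjects and global summaries under both pooling conventions:
#' pooled over all (subject, particle) values, and across per-particle
#' means.
#'
#' @param values Numeric matrix, subjects x particles (with particle
#'   columns 1..P); `NA` marks unavailable values.
#' @param joint_label Joint label.
#' @param min_fraction Inclusion rule threshold (default 0.5).
#' @return A `joint_particle_map`: included `particle_ids`, the raw value
#'   table restricted to them, a `per_particle` tibble, and `global`
#'   (one-row tibble with pooled and per-particle-mean summaries, min,
#'   max).
#' @export
particle_map <- function(values, joint_label = "synthetic",
                         min_fraction = 0.5) {
  values <- as.matrix(values)
  n_sub <- nrow(values)
  frac <- colMeans(!is.na(values))
  keep <- which(frac >= min_fraction)
  if (length(keep) == 0L) stop("no particle meets the inclusion rule")
  sub <- values[, keep, drop = FALSE]
  per <- tibble::tibble(
    particle_id = keep,
    n_subjects = colSums(!is.na(sub)),
    mean = colMeans(sub, na.rm = TRUE),
    sd = apply(sub, 2L, stats::sd, na.rm = TRUE)
  )
  pooled <- as.vector(sub)
  pooled <- pooled[!is.na(pooled)]
  global <- tibble::tibble(
    joint = joint_label,
    n_particles = length(keep), n_subjects = n_sub,
    mean_pooled = mean(pooled), sd_pooled = stats::sd(pooled),
    mean_of_particle_means = mean(per$mean),
    sd_of_particle_means = stats::sd(per$mean),
    min = min(pooled), max = max(pooled)
  )
  structure(list(joint_label = joint_label, particle_ids = keep,
                 values = sub, per_particle = per, global = global,
                 min_fraction = min_fraction),
            class = "joint_particle_map")
}

#' @export
print.joint_particle_map <- function(x, ...) {
  g <- x$global
  cat(sprintf(
    "<joint_particle_map> %s: %d particles, %d subjects; %.3f +/- %.3f [%.3f, %.3f]\n",
    x$joint_label, g$n_particles, g$n_subjects, g$mean_pooled,
    g$sd_pooled, g$min, g$max))
  invisible(x)
}

#' @rdname particle_map
#' @param x A `joint_particle_map`.
#' @param ... Unused.
#' @method tidy joint_particle_map
#' @export
tidy.joint_particle_map <- function(x, ...) {
  tibble::tibble(joint = x$joint_label, x$per_particle)
}

#' @rdname particle_map
#' @method glance joint_particle_map
#' @export
glance.joint_particle_map <- function(x, ...) x$global

#' Per-particle mean vs variability plot for a joint particle map
#' @param object A `joint_particle_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot joint_particle_map
#' @export
autoplot.joint_particle_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$sd)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(title = object$joint_label,
                  x = "Per-particle mean", y = "Per-particle SD") +
    ggplot2::theme_minimal()
}

#' Paired comparison of mated articular surface areas
#'
#' Paired t-test of the per-subject area difference `A - B`, with Cohen's
#' d for paired data (`mean(d)/sd(d)`), the conventional effect-size
#' label (small/medium/large at 0.2/0.5/0.8), and post-hoc power from the
#' noncentral t distribution at alpha two-tailed.
#'
#' @param areasA,areasB Equal-length paired area samples (mm^2), n >= 2.
#' @param alpha Significance level for the power computation (default
#'   0.05, two-tailed).
#' @return A `paired_area_stats` object; see [tidy.paired_area_stats()].
#' @export
paired_area_stats <- function(areasA, areasB, alpha = 0.05) {
  stopifnot(length(areasA) == length(areasB), length(areasA) >= 2L)
  d <- areasA - areasB
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  degenerate <- s < 1e-12
  if (degenerate) {
    if (abs(m) < 1e-12) {
      tval <- 0; cohend <- 0; p <- 1
    } else {
      tval <- NA_real_; cohend <- NA_real_; p <- NA_real_
    }
  } else {
    tval <- m / (s / sqrt(n))
    cohend <- m / s
    p <- 2 * stats::pt(-abs(tval), df = n - 1)
  }
  power <- if (is.na(cohend) || degenerate) NA_real_ else {
    tcrit <- stats::qt(1 - alpha / 2, df = n - 1)
    ncp <- abs(cohend) * sqrt(n)
    1 - stats::pt(tcrit, df = n - 1, ncp = ncp) +
      stats::pt(-tcrit, df = n - 1, ncp = ncp)
  }
  lab <- if (is.na(cohend)) NA_character_
         else if (abs(cohend) >= 0.8) "large"
         else if (abs(cohend) >= 0.5) "medium"
         else if (abs(cohend) >= 0.2) "small"
         else "negligible"
  structure(list(n = n, mean_difference = m, sd_difference = s,
                 t = tval, df = n - 1L, p_two_tailed = p,
                 cohens_d = cohend, effect_label = lab,
                 posthoc_power = power, alpha = alpha,
                 degenerate = degenerate),
            class = "paired_area_stats")
}

#' @export
print.paired_area_stats <- function(x, ...) {
  cat(sprintf(
    "<paired_area_stats> n=%d, mean diff %.2f mm^2, t(%d)=%.3f, p=%.4g, d=%.2f (%s), power=%.3f\n",
    x$n, x$mean_difference, x$df, x$t, x$p_two_tailed, x$cohens_d,
    x$effect_label, x$posthoc_power))
  invisible(x)
}

#' Tidy paired-area statistics
#' @param x A `paired_area_stats`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method tidy paired_area_stats
#' @export
tidy.paired_area_stats <- function(x, ...) {
  tibble::tibble(n = x$n, mean_difference = x$mean_difference,
                 sd_difference = x$sd_difference, t = x$t, df = x$df,
                 p_two_tailed = x$p_two_tailed, cohens_d = x$cohens_d,
                 effect_label = x$effect_label,
                 posthoc_power = x$posthoc_power,
                 degenerate = x$degenerate)
}

#' Required sample size for a paired t-test
#'
#' Smallest n such that a two-tailed paired t-test with effect size `d`
#' (noncentrality `d * sqrt(n)`) attains the target power at level
#' `alpha`, by noncentral-t search starting from the normal-approximation
#' closed form `((z_{1-alpha/2} + z_{power}) / d)^2`.
#'
#' @param d Effect size (Cohen's d for the paired differences), > 0.
#' @param alpha Two-tailed significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @return Integer sample size (>= 2).
#' @export
required_n <- function(d, alpha = 0.05, power = 0.80) {
  if (d <= 0 || alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("parameters out of range")
  pw <- function(n) {
    tcrit <- stats::qt(1 - alpha / 2, df = n - 1)
    ncp <- d * sqrt(n)
    1 - stats::pt(tcrit, df = n - 1, ncp = ncp) +
      stats::pt(-tcrit, df = n - 1, ncp = ncp)
  }
  n0 <- max(2, floor(((stats::qnorm(1 - alpha / 2) +
                         stats::qnorm(power)) / d)^2) - 5)
  n <- n0
  while (n > 2 && pw(n - 1) >= power) n <- n - 1
  while (pw(n) < power) n <- n + 1
  as.integer(n)
}
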