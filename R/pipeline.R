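# Config-driven end-to-end orchestration: reflect -> preprocess -> align
# (reference bone) -> cutting plane -> correspondence -> shape modes ->
# (original pose) curvature -> articular regions -> coverage -> distance
# -> congruence -> particle maps -> statistics -> report tables.

#' Build a pipeline configuration
#'
#' @param bones Named list, one entry per bone label; each entry a named
#'   list/vector mapping `subject_id` to a PLY path or an in-memory
#'   `surface_mesh`.
#' @param sides Optional named vector mapping `subject_id` to
#'   `"left"`/`"right"` (left bones are mirrored). Defaults to the side
#'   recorded on the meshes.
#' @param joints Named list of joint definitions: each a list with
#'   `bone_a`, `bone_b`, `threshold_a`, `threshold_b` (threshold specs for
#'   [candidate_region()]), optional `max_ray_length` (mm, default 10) and
#'   `map_bone` (bone whose particle model carries the joint map; default
#'   `bone_a`).
#' @param reference_bone Bone used as the ICP reference (default
#'   `"talus"` when present, else the first bone).
#' @param cut_bones Bones clipped at the common proximal plane (default
#'   `c("tibia", "fibula")` intersected with the bones present).
#' @param P Correspondence particles per bone (default 1024).
#' @param smoothing_iterations,target_face_count Preprocessing settings
#'   (`NULL` face count = no decimation).
#' @param n_reps,percentile Parallel-analysis settings.
#' @param min_fraction Particle inclusion rule (default 0.5).
#' @param warp_sd SD multiple for mode warps (default 2).
#' @param do_warps Compute mode warps and distance maps (default `TRUE`).
#' @param remove_scale Remove size in the shape PCA (default `TRUE`).
#' @param output_dir Optional directory for CSV/JSON/PLY outputs.
#' @param seed Integer seed used for every stochastic stage.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(bones, joints = list(), sides = NULL,
                            reference_bone = NULL, cut_bones = NULL,
                            P = 1024L, smoothing_iterations = 10L,
                            target_face_count = NULL, n_reps = 200L,
                            percentile = 95, min_fraction = 0.5,
                            warp_sd = 2, do_warps = TRUE,
                            remove_scale = TRUE, output_dir = NULL,
                            seed = 1L) {
  if (length(bones) == 0L) stop("no bones configured")
  subj <- names(bones[[1]])
  if (is.null(subj)) stop("bone entries must be named by subject_id")
  for (bn in names(bones)) {
    if (!identical(sort(names(bones[[bn]])), sort(subj)))
      stop("subject sets differ across bones")
    for (sid in subj) {
      x <- bones[[bn]][[sid]]
      if (is.character(x) && !file.exists(x))
        stop("mesh path not found for ", bn, "/", sid, ": ", x)
      if (!is.character(x) && !inherits(x, "surface_mesh"))
        stop("bone entry must be a path or surface_mesh")
    }
  }
  # one limb per subject: a subject must not appear with both sides
  if (!is.null(sides)) {
    if (!all(subj %in% names(sides)))
      stop("sides must cover every subject")
    if (anyDuplicated(names(sides)))
      stop("subject listed with more than one limb")
  }
  for (jn in names(joints)) {
    j <- joints[[jn]]
    if (!all(c(j$bone_a, j$bone_b) %in% names(bones)))
      stop("joint ", jn, " references unknown bone")
  }
  if (is.null(reference_bone))
    reference_bone <- if ("talus" %in% names(bones)) "talus"
                      else names(bones)[1]
  if (is.null(cut_bones))
    cut_bones <- intersect(c("tibia", "fibula"), names(bones))
  structure(list(bones = bones, sides = sides, joints = joints,
                 reference_bone = reference_bone, cut_bones = cut_bones,
                 P = as.integer(P),
                 smoothing_iterations = smoothing_iterations,
                 target_face_count = target_face_count,
                 n_reps = n_reps, percentile = percentile,
                 min_fraction = min_fraction, warp_sd = warp_sd,
                 do_warps = do_warps, remove_scale = remove_scale,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML mirroring the [pipeline_config()] arguments, with bone mesh
#' paths under `bones:` and joint definitions under `joints:`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

#' Run the full joint shape-modeling pipeline
#'
#' Executes every stage on the configured cohort and returns a result
#' bundle; see [pipeline_config()] for the stage parameters. Coverage,
#' joint-space and congruence are computed with the bones in their
#' original (weightbearing) pose; shape modes are computed in the aligned,
#' Procrustes-standardized frame. Deterministic under a fixed seed.
#'
#' @param config A `pipeline_config`.
#' @return A `pipeline_result` list: `meshes` (original pose),
#'   `aligned`, `transforms`, `cutting_plane`, `models` (per bone),
#'   `modes` (per bone `shape_mode_set`), `warps`, `joints` (per joint:
#'   covered areas, distance and congruence particle maps, paired area
#'   stats), and `tables` (report tibbles).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  log <- list(config = config[setdiff(names(config),
                                      c("bones", "sides"))])

  stage <- function(name, sid, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed for %s: %s", name, sid,
                   conditionMessage(e)), call. = FALSE))
  }

  bones <- names(config$bones)
  subjects <- names(config$bones[[1]])

  # load + reflect + preprocess (original pose)
  meshes <- list()
  for (bn in bones) {
    meshes[[bn]] <- list()
    for (sid in subjects) {
      m <- stage("load", paste(bn, sid), {
        x <- config$bones[[bn]][[sid]]
        if (is.character(x))
          load_mesh(x, bone = if (bn %in% c("tibia", "fibula", "talus"))
                                bn else "synthetic",
                    subject_id = sid)
        else x
      })
      side <- if (!is.null(config$sides)) config$sides[[sid]] else m$side
      if (identical(side, "left")) m <- reflect_mesh(m)
      tf <- config$target_face_count
      m <- stage("preprocess", paste(bn, sid),
                 preprocess_mesh(m,
                   smoothing_iterations = config$smoothing_iterations,
                   target_face_count = if (is.null(tf)) nrow(m$faces)
                                       else tf))
      meshes[[bn]][[sid]] <- m
    }
  }

  # per-subject rigid alignment via the reference bone
  ref_bone <- config$reference_bone
  ref_sid <- subjects[1]
  transforms <- list()
  for (sid in subjects) {
    transforms[[sid]] <- if (sid == ref_sid) rigid_transform() else
      stage("align", sid,
            icp_align(meshes[[ref_bone]][[sid]],
                      meshes[[ref_bone]][[ref_sid]],
                      seed = seed)$transform)
  }
  aligned <- lapply(meshes, function(bm)
    lapply(subjects, function(sid)
      apply_transform(transforms[[sid]], bm[[sid]])))
  for (bn in bones) names(aligned[[bn]]) <- subjects

  # common proximal cutting plane over the cut bones, applied in the
  # original pose (so vertex indexing matches between frames)
  plane <- NULL
  if (length(config$cut_bones)) {
    cut_set <- unlist(lapply(config$cut_bones,
                             function(bn) aligned[[bn]]),
                      recursive = FALSE)
    plane <- common_cutting_plane(cut_set)
    for (bn in config$cut_bones) for (sid in subjects) {
      Tinv <- invert_transform(transforms[[sid]])
      pl_local <- clip_plane(
        as.vector(apply_transform(Tinv, matrix(plane$point, 1))),
        as.vector(Tinv$rotation %*% plane$normal))
      meshes[[bn]][[sid]] <- stage("clip", paste(bn, sid),
                                   clip_mesh(meshes[[bn]][[sid]],
                                             pl_local))
      aligned[[bn]][[sid]] <- apply_transform(transforms[[sid]],
                                              meshes[[bn]][[sid]])
    }
  }

  # correspondence + shape modes per bone
  models <- list()
  modes <- list()
  warps <- list()
  for (bn in bones) {
    models[[bn]] <- stage("correspondence", bn,
      build_correspondence_model(aligned[[bn]], P = config$P,
        cutting_plane = if (bn %in% config$cut_bones) plane else NULL,
        seed = seed))
    modes[[bn]] <- stage("pca", bn,
      fit_modes(models[[bn]], remove_scale = config$remove_scale,
                n_reps = config$n_reps, percentile = config$percentile,
                pa_seed = seed))
    if (config$do_warps && modes[[bn]]$n_significant > 0) {
      tmpl <- aligned[[bn]][[models[[bn]]$template_subject_id]]
      warps[[bn]] <- lapply(seq_len(modes[[bn]]$n_significant),
        function(k) {
          wp <- warp_mode(modes[[bn]], k, config$warp_sd, tmpl,
                          models[[bn]]$template_particles)
          wm <- warp_mode(modes[[bn]], k, -config$warp_sd, tmpl,
                          models[[bn]]$template_particles)
          list(mode = k,
               plus = wp$mesh, minus = wm$mesh,
               dist_plus = mode_distance_map(wp$mean_mesh, wp$mesh),
               dist_minus = mode_distance_map(wm$mean_mesh, wm$mesh))
        })
    }
  }

  # joint analyses in the original pose
  joint_results <- list()
  for (jn in names(config$joints)) {
    jdef <- config$joints[[jn]]
    maxray <- if (is.null(jdef$max_ray_length)) 10 else
      jdef$max_ray_length
    map_bone <- if (is.null(jdef$map_bone)) jdef$bone_a else
      jdef$map_bone
    areasA <- areasB <- numeric(length(subjects))
    dist_vals <- ci_vals <- matrix(NA_real_, length(subjects), config$P)
    for (si in seq_along(subjects)) {
      sid <- subjects[si]
      ma <- meshes[[jdef$bone_a]][[sid]]
      mb <- meshes[[jdef$bone_b]][[sid]]
      ca <- stage("curvature", paste(jn, sid), curvature_field(ma))
      cb <- stage("curvature", paste(jn, sid), curvature_field(mb))
      ra <- stage("candidate_region", paste(jn, sid),
                  candidate_region(ma, ca, jdef$threshold_a,
                                   joint_label = jn))
      rb <- stage("candidate_region", paste(jn, sid),
                  candidate_region(mb, cb, jdef$threshold_b,
                                   joint_label = jn))
      cov <- stage("coverage", paste(jn, sid),
                   coverage(ra, rb, max_ray_length = maxray))
      areasA[si] <- cov$coveredA$area
      areasB[si] <- cov$coveredB$area
      covA <- cov$coveredA; covB <- cov$coveredB
      js <- stage("joint_space", paste(jn, sid), joint_space(covA, mb))
      cg <- stage("congruence", paste(jn, sid),
                  congruence(covA, covB, ca, cb))

      # per-particle values through the map bone's correspondence model
      mmap <- map_particles(models[[map_bone]]$mean_particles,
                            aligned[[map_bone]][[sid]])
      # values live on bone_a vertices; when the map bone is bone_a the
      # mapped vertex indexes the same mesh in both frames
      if (map_bone == jdef$bone_a) {
        dv <- rep(NA_real_, nrow(ma$vertices))
        dv[js$vertex_id] <- js$distance
        cv <- rep(NA_real_, nrow(ma$vertices))
        cv[cg$vertex_a] <- cg$CI
        dist_vals[si, ] <- dv[mmap$vertex_id]
        ci_vals[si, ] <- cv[mmap$vertex_id]
      } else {
        # carry values from bone_a to the mapped bone_b vertices via the
        # nearest covered node
        jsB <- stage("joint_space", paste(jn, sid),
                     joint_space(covB, ma))
        cgB <- stage("congruence", paste(jn, sid),
                     congruence(covB, covA, cb, ca))
        dv <- rep(NA_real_, nrow(mb$vertices))
        dv[jsB$vertex_id] <- jsB$distance
        cv <- rep(NA_real_, nrow(mb$vertices))
        cv[cgB$vertex_a] <- cgB$CI
        dist_vals[si, ] <- dv[mmap$vertex_id]
        ci_vals[si, ] <- cv[mmap$vertex_id]
      }
    }
    stats <- if (length(subjects) >= 2L)
      paired_area_stats(areasA, areasB) else NULL
    dmap <- tryCatch(particle_map(dist_vals, joint_label = jn,
                                  min_fraction = config$min_fraction),
                     error = function(e) NULL)
    cmap <- tryCatch(particle_map(ci_vals, joint_label = jn,
                                  min_fraction = config$min_fraction),
                     error = function(e) NULL)
    joint_results[[jn]] <- list(
      areas = tibble::tibble(subject_id = subjects,
                             area_a = areasA, area_b = areasB),
      bone_a = jdef$bone_a, bone_b = jdef$bone_b,
      area_stats = stats, distance_map = dmap, congruence_map = cmap)
  }

  res <- structure(
    list(meshes = meshes, aligned = aligned, transforms = transforms,
         cutting_plane = plane, models = models, modes = modes,
         warps = warps, joints = joint_results, subjects = subjects,
         config = config, log = log),
    class = "pipeline_result")
  res$tables <- report_tables(res,
                              output_dir = config$output_dir)
  if (!is.null(config$output_dir))
    write_pipeline_outputs(res, config$output_dir)
  res
}

#' Report tables for a pipeline result
#'
#' `table1`: per joint, mean +/- SD covered area for each bone of the
#' pair with the paired t-test, Cohen's d and post-hoc power. `table2`:
#' per joint, joint-space distance and congruence index as mean +/- SD
#' with population minima and maxima, under both pooling conventions.
#' `modes`: per bone, the tidied shape-mode summary.
#'
#' @param result A `pipeline_result`.
#' @param output_dir Optional directory for the CSVs.
#' @return List of tibbles `table1`, `table2`, `modes`.
#' @export
report_tables <- function(result, output_dir = NULL) {
  t1 <- lapply(names(result$joints), function(jn) {
    jr <- result$joints[[jn]]
    st <- jr$area_stats
    tibble::tibble(
      joint = jn, bone_a = jr$bone_a, bone_b = jr$bone_b,
      n = nrow(jr$areas),
      area_a_mean = mean(jr$areas$area_a),
      area_a_sd = if (nrow(jr$areas) > 1) stats::sd(jr$areas$area_a)
                  else NA_real_,
      area_b_mean = mean(jr$areas$area_b),
      area_b_sd = if (nrow(jr$areas) > 1) stats::sd(jr$areas$area_b)
                  else NA_real_,
      mean_difference = if (!is.null(st)) st$mean_difference else
        NA_real_,
      t = if (!is.null(st)) st$t else NA_real_,
      p = if (!is.null(st)) st$p_two_tailed else NA_real_,
      cohens_d = if (!is.null(st)) st$cohens_d else NA_real_,
      effect_label = if (!is.null(st)) st$effect_label else
        NA_character_,
      posthoc_power = if (!is.null(st)) st$posthoc_power else NA_real_)
  })
  t1 <- do.call(rbind, t1)

  row2 <- function(jn, what, pm) {
    if (is.null(pm)) return(NULL)
    g <- pm$global
    tibble::tibble(joint = jn, measure = what,
                   n_particles = g$n_particles,
                   mean = g$mean_pooled, sd = g$sd_pooled,
                   min = g$min, max = g$max,
                   mean_of_particle_means = g$mean_of_particle_means,
                   sd_of_particle_means = g$sd_of_particle_means)
  }
  t2 <- do.call(rbind, unlist(lapply(names(result$joints), function(jn) {
    jr <- result$joints[[jn]]
    list(row2(jn, "distance_mm", jr$distance_map),
         row2(jn, "congruence_mm^-1", jr$congruence_map))
  }), recursive = FALSE))

  md <- do.call(rbind, lapply(names(result$modes), function(bn)
    tibble::tibble(bone = bn, tidy(result$modes[[bn]]))))

  out <- list(table1 = t1, table2 = t2, modes = md)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(t1),
                     file.path(output_dir, "table1_coverage.csv"),
                     row.names = FALSE)
    if (!is.null(t2))
      utils::write.csv(as.data.frame(t2),
                       file.path(output_dir, "table2_distance_congruence.csv"),
                       row.names = FALSE)
    utils::write.csv(as.data.frame(md),
                     file.path(output_dir, "mode_summary.csv"),
                     row.names = FALSE)
  }
  out
}

# CSV/JSON side outputs for provenance and audit
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (jn in names(result$joints)) {
    jr <- result$joints[[jn]]
    utils::write.csv(as.data.frame(jr$areas),
                     file.path(dir, paste0("areas_", jn, ".csv")),
                     row.names = FALSE)
    for (w in c("distance_map", "congruence_map")) {
      if (is.null(jr[[w]])) next
      utils::write.csv(as.data.frame(tidy(jr[[w]])),
                       file.path(dir, paste0(w, "_", jn, ".csv")),
                       row.names = FALSE)
    }
  }
  cfg <- result$log$config
  cfg$joints <- NULL
  writeLines(jsonlite::toJSON(cfg[!vapply(cfg, is.null, TRUE)],
                              auto_unbox = TRUE, force = TRUE,
                              digits = NA),
             file.path(dir, "provenance.json"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects, bones: %s; joints: %s\n",
              length(x$subjects),
              paste(names(x$models), collapse = ", "),
              paste(names(x$joints), collapse = ", ")))
  invisible(x)
}

#' Simulate a synthetic joint cohort
#'
#' A convenience generator for end-to-end runs: each subject is a mated
#' ball-and-socket joint whose members get consistent small random shape
#' perturbations, posed together (preserving the joint gap) by a random
#' rigid transform. Returns configs directly consumable by
#' [run_pipeline()].
#'
#' @param n_subjects Number of subjects.
#' @param spec Base [synthetic_joint_spec()] for the joint.
#' @param mode_sds Planted mode SDs (mm) applied to the convex member.
#' @param vertex_noise_sd Vertex noise SD (mm).
#' @param rotation_range,translation_range Pose ranges (deg, mm).
#' @param seed Integer seed.
#' @return List with `bones` (list `ball`, `socket` of per-subject
#'   meshes), `oracle` of the base joint, and `ground_truth`.
#' @export
simulate_joint_cohort <- function(n_subjects = 10L,
                                  spec = synthetic_joint_spec(),
                                  mode_sds = numeric(0),
                                  vertex_noise_sd = 0,
                                  rotation_range = 5,
                                  translation_range = 2, seed = 1L) {
  base <- make_joint(spec)
  k <- length(mode_sds)
  fields <- if (k > 0)
    make_mode_fields(base$meshA, k, seed) else NULL
  old <- .Random.seed_save()
  set.seed(seed)
  b <- if (k > 0)
    matrix(stats::rnorm(n_subjects * k), n_subjects, k) %*%
      diag(mode_sds, k) else matrix(0, n_subjects, 0)
  ball <- list(); socket <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("subject_%02d", i)
    ma <- base$meshA; mb <- base$meshB
    if (k > 0) {
      disp <- fields %*% b[i, ]
      ma$vertices <- ma$vertices + matrix(disp, ncol = 3, byrow = TRUE)
    }
    if (vertex_noise_sd > 0) {
      ma$vertices <- ma$vertices +
        matrix(stats::rnorm(length(ma$vertices), 0, vertex_noise_sd),
               ncol = 3)
      mb$vertices <- mb$vertices +
        matrix(stats::rnorm(length(mb$vertices), 0, vertex_noise_sd),
               ncol = 3)
    }
    R <- random_rotation(rotation_range)
    t <- stats::runif(3, -translation_range, translation_range)
    Tr <- rigid_transform(R, t)
    ma <- apply_transform(Tr, ma); mb <- apply_transform(Tr, mb)
    ma$subject_id <- sid; mb$subject_id <- sid
    ma$side <- "right"; mb$side <- "right"
    ball[[sid]] <- ma; socket[[sid]] <- mb
  }
  .Random.seed_restore(old)
  list(bones = list(ball = ball, socket = socket), oracle = base$oracle,
       ground_truth = list(b = b, mode_fields = fields))
}
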