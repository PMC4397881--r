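#' Contact zone at a blocked pose
#'
#' All face pairs within the contact tolerance, the femoral zone's
#' area-weighted centroid and summed area, and (when a femur frame is
#' supplied) the centroid's clock-face hour on the head-neck clock.
#'
#' @param femur_posed femur mesh already at the queried pose.
#' @param pelvis pelvis mesh.
#' @param tolerance contact tolerance (mm).
#' @param femur_frame optional [femur_frame()] for the clock conversion.
#' @param side `"right"` or `"left"`.
#' @return A list of class `contact_zone`: `femur_faces`, `pelvis_faces`,
#'   `centroid`, `area` (mm^2), `clock_hour` (NA without a frame), `pairs`.
#'   An empty zone (no pair within tolerance) is valid.
#' @export
contact_zone <- function(femur_posed, pelvis, tolerance = 0.1,
                         femur_frame = NULL, side = "right") {
  q <- query_contact(femur_posed, pelvis, tolerance = tolerance)
  pairs <- q$witness_pairs
  ff <- sort(unique(pairs$face_a))
  pf <- sort(unique(pairs$face_b))
  if (length(ff) == 0) {
    z <- list(femur_faces = integer(), pelvis_faces = integer(),
              centroid = rep(NA_real_, 3), area = 0,
              clock_hour = NA_real_, pairs = pairs)
    return(structure(z, class = "contact_zone"))
  }
  V <- femur_posed$vertices; F <- femur_posed$faces[ff, , drop = FALSE]
  areas <- face_areas_(V, F)
  cent <- (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
             V[F[, 3], , drop = FALSE]) / 3
  ctr <- colSums(cent * areas) / sum(areas)
  hour <- if (!is.null(femur_frame))
    clock_position(ctr, femur_frame, side) else NA_real_
  structure(list(femur_faces = ff, pelvis_faces = pf, centroid = ctr,
                 area = sum(areas), clock_hour = hour, pairs = pairs),
            class = "contact_zone")
}

#' @export
print.contact_zone <- function(x, ...) {
  cat(sprintf("<contact_zone: %d femur faces, area %.1f mm^2, clock %s>\n",
              length(x$femur_faces), x$area,
              if (is.na(x$clock_hour)) "NA" else sprintf("%.1f", x$clock_hour)))
  invisible(x)
}

#' Clock-face position on the head-neck junction
#'
#' Radiological clock convention on the head-neck clock face, viewed along
#' the femoral neck axis: 12 superior, 3 anterior on a right hip (mirrored
#' on a left hip, where anterior is 9).  The hour is the point's angular
#' position about the neck axis through the hip center.
#'
#' @param point length-3 position (mm).
#' @param femur_frame a [femur_frame()].
#' @param side `"right"` or `"left"`.
#' @param neck_axis unit direction of the neck axis (hip center toward the
#'   neck/shaft junction) in the same coordinates.  Defaults to a typical
#'   neck inclination: 40 degrees below the medio-lateral (Z) axis of the
#'   femur frame.
#' @return Hour in (0, 12]; `NA` (with a warning) for a point on the clock
#'   axis, where the hour is undefined.
#' @export
clock_position <- function(point, femur_frame, side = "right",
                           neck_axis = NULL) {
  lat <- if (side == "right") 1 else -1
  if (is.null(neck_axis))
    neck_axis <- -sin(40 * pi / 180) * femur_frame$Y +
      lat * cos(40 * pi / 180) * femur_frame$Z
  n <- neck_axis / sqrt(sum(neck_axis^2))
  e3 <- femur_frame$X - n * sum(femur_frame$X * n)   # anterior, in-face
  e3 <- e3 / sqrt(sum(e3^2))
  e12 <- if (side == "right") vcross_(n, e3) else vcross_(e3, n)
  v <- as.numeric(point) - femur_frame$origin
  c12 <- sum(v * e12)
  c3 <- sum(v * e3)
  if (sqrt(c12^2 + c3^2) < 1e-9 * max(1, sqrt(sum(v^2)))) {
    warning("point lies on the clock axis; hour undefined", call. = FALSE)
    return(NA_real_)
  }
  w <- atan2(c3, c12) * 180 / pi          # 0 = 12 o'clock, +90 = 3 o'clock
  if (side == "left") w <- -w
  h <- (w / 30) %% 12
  if (h < 1e-9 || h > 12 - 1e-9) 12 else h
}

#' Aggregate impingement map over a motion set
#'
#' Runs each motion to its endpoint and unions the contact zones at the
#' first impinged poses; per-vertex depth is the maximum penetration (of the
#' femoral surface into the pelvis) over those poses.
#'
#' @param model a [hip_model()].
#' @param motions list of [motion_definition()]s.
#' @param config a [sim_config()].
#' @return A list of class `impingement_map`: `face_flags` (logical, per
#'   femur face), `vertex_depth` (mm, >= 0, per femur vertex), `endpoints`
#'   (tibble: motion, angle, status, clock_hour, area).
#' @export
aggregate_map <- function(model, motions, config = sim_config()) {
  nf <- nrow(model$femur$faces)
  nv <- nrow(model$femur$vertices)
  flags <- logical(nf)
  depth <- numeric(nv)
  rows <- list()
  for (m in motions) {
    ep <- find_endpoint(model, m, config)
    if (ep$status == "bound_reached") {
      rows[[length(rows) + 1]] <- tibble::tibble(
        motion = m$label, angle = ep$angle, status = ep$status,
        clock_hour = NA_real_, area = 0)
      next
    }
    ang_imp <- ep$angle + if (ep$status == "start_impinged") 0 else
      config$angle_resolution
    pose <- pose_at_(m, ang_imp)
    Tm <- pose_to_transform(pose, model$pelvis_frame, model$femur_frame,
                            model$hip_center, model$side)
    posed <- transform_mesh(model$femur, Tm)
    z <- contact_zone(posed, model$pelvis, config$contact_tolerance,
                      femur_frame = model$femur_frame, side = model$side)
    flags[z$femur_faces] <- TRUE
    sd <- .points_mesh_dist_cpp(posed$vertices, model$pelvis$vertices,
                                model$pelvis$faces - 1L, TRUE)
    depth <- pmax(depth, pmax(0, -sd))
    rows[[length(rows) + 1]] <- tibble::tibble(
      motion = m$label, angle = ep$angle, status = ep$status,
      clock_hour = z$clock_hour, area = z$area)
  }
  structure(list(face_flags = flags, vertex_depth = depth,
                 endpoints = dplyr::bind_rows(rows)),
            class = "impingement_map")
}

# one-ring vertex adjacency dilation
dilate_vertices_ <- function(faces, in_set) {
  sel <- in_set
  hit <- in_set[faces[, 1]] | in_set[faces[, 2]] | in_set[faces[, 3]]
  sel[faces[hit, ]] <- TRUE
  sel
}

vertex_normals_ <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])   # area-weighted
  vn <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    acc <- rowsum(fn, F[, k])
    idx <- as.integer(rownames(acc))
    vn[idx, ] <- vn[idx, ] + acc
  }
  n <- sqrt(rowSums(vn^2))
  vn / pmax(n, 1e-30)
}

#' Estimate the resection that dissolves impingement
#'
#' Iteratively poses the femur at each target angle (corrective translation
#' allowed), finds the femoral vertices within the contact tolerance of the
#' pelvis, carves them inward along their normals, and re-checks, for at
#' most `max_iter` rounds.  In `"spherical"` mode (default) contacting
#' vertices near the femoral head are cut back to the best-fit spherical
#' head contour — the osteochondroplasty goal of restoring head sphericity —
#' which removes the whole local prominence rather than a thin sliver; in
#' `"minimal"` mode only the clearance deficit plus tolerance is carved.
#' The carved region is dilated by one vertex ring per round.
#'
#' @param model a [hip_model()] (femur with the deformity).
#' @param targets tibble with columns `motion` (label among the standard
#'   six) and `angle` (target degrees), e.g. a native [simulate_standard_set()]
#'   table.
#' @param config a [sim_config()].
#' @param mode `"spherical"` or `"minimal"`.
#' @param max_iter iteration cap.
#' @return Object of class `resection_estimate`: `depth` (per-vertex mm),
#'   `resected_volume` (mm^3, closed-mesh volume difference), `swept_volume`
#'   (depth x vertex-area estimate), `achieved`, `iterations`,
#'   `femur_resected`.
#' @export
resection_estimate <- function(model, targets, config = sim_config(),
                               mode = c("spherical", "minimal"),
                               max_iter = 20) {
  mode <- match.arg(mode)
  motions <- standard_motions(config)
  labs <- vapply(motions, function(m) m$label, "")
  stopifnot(all(targets$motion %in% labs))
  femur0 <- model$femur
  cur <- femur0
  tol <- config$contact_tolerance
  ctr <- model$hip_center
  r0 <- sqrt(rowSums(sweep(femur0$vertices, 2, ctr)^2))
  # baseline head radius from the dominant spherical surface
  rfit <- if (mode == "spherical") {
    head_pts <- femur0$vertices[r0 <= stats::quantile(r0, 0.3), , drop = FALSE]
    fit_hip_center(head_pts)$head_radius
  } else NA_real_
  achieved <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    mdl <- model; mdl$femur <- cur
    carved_any <- FALSE
    all_clear <- TRUE
    for (i in seq_len(nrow(targets))) {
      m <- motions[[match(targets$motion[i], labs)]]
      pose <- pose_at_(m, targets$angle[i])
      chk <- check_pose(mdl, pose, config)
      if (chk$status == "free" ||
          (chk$status == "resolved" && chk$clearance >= tol)) next
      all_clear <- FALSE
      Tm <- pose_to_transform(
        joint_pose(pose$flexion, pose$abduction, pose$internal_rotation,
                   correction = chk$correction),
        mdl$pelvis_frame, mdl$femur_frame, mdl$hip_center, mdl$side)
      posed <- transform_mesh(cur, Tm)
      sd <- .points_mesh_dist_cpp(posed$vertices, mdl$pelvis$vertices,
                                  mdl$pelvis$faces - 1L, TRUE)
      contact <- sd < tol
      if (!any(contact)) next
      sel <- dilate_vertices_(cur$faces, contact)
      vn <- vertex_normals_(cur)
      rel <- sweep(cur$vertices, 2, ctr)
      r <- sqrt(rowSums(rel^2))
      need <- numeric(length(sd))
      need[contact] <- pmax(tol - sd[contact], 0)
      if (mode == "spherical") {
        # the sphericity carve acts radially toward the fitted head sphere,
        # and only where the surface is radial (head/bump); neck and shaft
        # vertices, whose normals run across the radial direction, get the
        # minimal clearance carve along their normals
        u <- rel / r
        radial <- rowSums(vn * u)
        prom <- pmax(r - rfit, 0)
        sph <- sel & radial > 0.6 & prom < 0.4 * rfit
        drop_r <- pmax(prom, need) * sph
        lin <- sel & !sph & need > 0
        if (all(drop_r <= 0) && !any(lin)) next
        cur$vertices <- cur$vertices - u * drop_r - vn * (need * lin)
      } else {
        if (all(need <= 0)) next
        cur$vertices <- cur$vertices - vn * need
      }
      carved_any <- TRUE
    }
    if (all_clear) { achieved <- TRUE; break }
    if (!carved_any) break
  }
  depth <- sqrt(rowSums((femur0$vertices - cur$vertices)^2))
  # vertex area (one third of incident face area), averaged between the
  # original and carved surfaces: a prism-rule swept-volume estimate
  vert_area <- function(m) {
    fa <- face_areas_(m$vertices, m$faces)
    va <- numeric(nrow(m$vertices))
    for (k in 1:3) {
      acc <- rowsum(fa, m$faces[, k])
      idx <- as.integer(rownames(acc))
      va[idx] <- va[idx] + acc / 3
    }
    va
  }
  va <- (vert_area(femur0) + vert_area(cur)) / 2
  # project the carve displacement onto the surface normal: only the normal
  # component sweeps volume on tilted (bump-flank) surface elements
  nmean <- (vertex_normals_(femur0) + vertex_normals_(cur)) / 2
  dirs <- femur0$vertices - cur$vertices
  proj <- abs(rowSums(dirs * nmean))
  proj[depth > 0] <- proj[depth > 0] / depth[depth > 0]
  proj[depth == 0] <- 0
  structure(list(depth = depth,
                 resected_volume = mesh_volume(femur0) - mesh_volume(cur),
                 swept_volume = sum(depth * proj * va),
                 achieved = achieved, iterations = iters,
                 femur_resected = cur),
            class = "resection_estimate")
}

#' @export
print.resection_estimate <- function(x, ...) {
  cat(sprintf(
    "<resection_estimate: %.1f mm^3 removed (swept %.1f), max depth %.2f mm, achieved=%s in %d iterations>\n",
    x$resected_volume, x$swept_volume, max(x$depth), x$achieved, x$iterations))
  invisible(x)
}

#' @export
glance.resection_estimate <- function(x, ...) {
  tibble::tibble(resected_volume = x$resected_volume,
                 swept_volume = x$swept_volume,
                 max_depth = max(x$depth),
                 achieved = x$achieved, iterations = x$iterations)
}

#' Write a resection report
#'
#' Depth map as a per-vertex scalar PLY, a JSON summary, and the zone
#' report CSV from an [aggregate_map()].
#'
#' @param resection a [resection_estimate()].
#' @param map an [impingement_map()] (for the zone CSV), or `NULL`.
#' @param prefix output path prefix.
#' @export
write_resection_report <- function(resection, map = NULL, prefix) {
  write_mesh(resection$femur_resected, paste0(prefix, "_depth.ply"),
             scalars = resection$depth)
  jsonlite::write_json(
    list(resected_volume_mm3 = resection$resected_volume,
         swept_volume_mm3 = resection$swept_volume,
         achieved = resection$achieved,
         iterations = resection$iterations),
    paste0(prefix, "_summary.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(map))
    utils::write.csv(map$endpoints, paste0(prefix, "_zones.csv"),
                     row.names = FALSE)
  invisible(prefix)
}
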