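#' Simulation configuration
#'
#' @param max_translation corrective femoral-head translation cap, mm
#'   (default 3; a pose needing more is impinged).
#' @param contact_tolerance contact-reporting band and the minimum clearance
#'   a resolved pose must reach, mm (default 0.1).
#' @param angle_resolution endpoint resolution, degrees (default 0.1).
#' @param coarse_step coarse sweep step, degrees (default 2).
#' @param rotation_order fixed rotation composition order (informational;
#'   the pose model composes flexion about the pelvis Z, abduction about the
#'   pelvis X, then internal rotation about the femoral long axis,
#'   intrinsic).
#' @param bounds named sweep upper bounds in degrees.
#' @export
sim_config <- function(max_translation = 3, contact_tolerance = 0.1,
                       angle_resolution = 0.1, coarse_step = 2,
                       rotation_order = c("flexion", "abduction",
                                          "internal_rotation"),
                       bounds = c(flexion = 150, abduction = 90,
                                  internal_rotation = 90)) {
  stopifnot(max_translation >= 0, contact_tolerance > 0,
            angle_resolution > 0, coarse_step > 0,
            angle_resolution <= coarse_step,
            identical(sort(names(bounds)),
                      sort(c("flexion", "abduction", "internal_rotation"))))
  structure(list(max_translation = max_translation,
                 contact_tolerance = contact_tolerance,
                 angle_resolution = angle_resolution,
                 coarse_step = coarse_step,
                 rotation_order = rotation_order,
                 bounds = bounds),
            class = "sim_config")
}

#' Motion definition
#'
#' A clinically defined motion: one swept component, the others held fixed.
#'
#' @param sweep `"flexion"`, `"abduction"` or `"internal_rotation"`.
#' @param fixed named list/vector of fixed component angles (degrees).
#' @param start sweep start angle (degrees).
#' @param bound sweep upper bound (degrees).
#' @param label motion label used in tables.
#' @export
motion_definition <- function(sweep, fixed = c(flexion = 0, abduction = 0,
                                               internal_rotation = 0),
                              start = 0, bound = 90, label = NULL) {
  sweep <- match.arg(sweep, c("flexion", "abduction", "internal_rotation"))
  fixed <- as.list(fixed)
  for (nm in c("flexion", "abduction", "internal_rotation"))
    if (is.null(fixed[[nm]])) fixed[[nm]] <- 0
  stopifnot(bound > start,
            all(unlist(fixed) >= -30), all(unlist(fixed) <= 120))
  if (is.null(label)) label <- sweep
  structure(list(sweep = sweep, fixed = fixed, start = start, bound = bound,
                 label = label),
            class = "motion_definition")
}

#' The six standard motions
#'
#' Maximum flexion, maximum abduction, and maximum internal rotation at 0,
#' 30, 60 and 90 degrees of flexion.
#'
#' @param config a [sim_config()] supplying sweep bounds.
#' @return A list of six [motion_definition()] objects.
#' @export
standard_motions <- function(config = sim_config()) {
  b <- config$bounds
  ir <- function(flex) motion_definition(
    "internal_rotation", fixed = c(flexion = flex),
    bound = b[["internal_rotation"]], label = sprintf("max_ir_%d", flex))
  list(motion_definition("flexion", bound = b[["flexion"]], label = "max_flexion"),
       motion_definition("abduction", bound = b[["abduction"]], label = "max_abduction"),
       ir(0), ir(30), ir(60), ir(90))
}

#' Joint pose
#'
#' @param flexion,abduction,internal_rotation angles in degrees.
#' @param correction corrective head translation (mm, |correction| <= cap).
#' @export
joint_pose <- function(flexion = 0, abduction = 0, internal_rotation = 0,
                       correction = c(0, 0, 0)) {
  structure(list(flexion = flexion, abduction = abduction,
                 internal_rotation = internal_rotation,
                 correction = as.numeric(correction)),
            class = "joint_pose")
}

#' Hip model: meshes plus anatomical frames
#'
#' Bundles the femur and pelvis meshes with the ISB frames and the hip
#' rotation center, the unit the ROM engine operates on.
#'
#' @param femur,pelvis [trimesh()] objects in a common coordinate system.
#' @param landmarks a [landmark_set()].
#' @param hip_center a [fit_hip_center()] result or a length-3 center (mm);
#'   typically fitted to the femoral head surface.
#' @export
hip_model <- function(femur, pelvis, landmarks, hip_center) {
  pf <- pelvis_frame(landmarks)
  ctr <- if (inherits(hip_center, "hip_center_fit")) hip_center$center
         else as.numeric(hip_center)
  ff <- femur_frame(landmarks, ctr)
  structure(list(femur = femur, pelvis = pelvis,
                 pelvis_frame = pf, femur_frame = ff,
                 hip_center = ctr, side = landmarks$side),
            class = "hip_model")
}

#' Build the hip models of a phantom
#'
#' @param phantom a [generate_phantom()] result.
#' @param condition `"cam"` (cam bump included, when the phantom has one)
#'   or `"native"`.
#' @export
phantom_model <- function(phantom, condition = c("cam", "native")) {
  condition <- match.arg(condition)
  femur <- if (condition == "cam") phantom$femur else phantom$femur_native
  hip_model(femur, phantom$pelvis, phantom$landmarks, phantom$hip_center)
}

#' Pose to rigid transform
#'
#' Composes flexion (about the pelvis Z axis), abduction (about the pelvis
#' X axis) and internal rotation (about the femoral long axis, intrinsic),
#' pivoting at the hip center, then adds the corrective translation.
#' Rotation signs follow the side: on a right hip positive flexion carries
#' the thigh anteriorly, positive abduction laterally (rightward), positive
#' internal rotation turns the anterior femur medially; a left hip mirrors
#' abduction and internal rotation.
#'
#' @param pose a [joint_pose()].
#' @param pelvis_frame,femur_frame [pelvis_frame()] / [femur_frame()] results.
#' @param hip_center length-3 center (mm) or [fit_hip_center()] result.
#' @param side `"right"` or `"left"`.
#' @return A [rigid_transform()] to apply to the femur mesh.
#' @export
pose_to_transform <- function(pose, pelvis_frame, femur_frame, hip_center,
                              side = "right") {
  ctr <- if (inherits(hip_center, "hip_center_fit")) hip_center$center
         else as.numeric(hip_center)
  right <- side == "right"
  Rf <- rotation_about(pelvis_frame$Z, pose$flexion)
  Ra <- rotation_about(if (right) -pelvis_frame$X else pelvis_frame$X,
                       pose$abduction)
  Ri <- rotation_about(if (right) femur_frame$Y else -femur_frame$Y,
                       pose$internal_rotation)
  R <- Rf %*% Ra %*% Ri
  rigid_transform(R, ctr - as.numeric(R %*% ctr) + pose$correction)
}

#' Check a pose for impingement
#'
#' `free` when the reoriented femur is collision-free with zero correction;
#' otherwise `resolved` when a corrective head translation within
#' `max_translation` restores a clearance of at least `contact_tolerance`
#' (the equidistant selection of [resolve_translation()]); otherwise
#' `impinged`.
#'
#' @param model a [hip_model()].
#' @param pose a [joint_pose()] (its `correction` is ignored; the check
#'   derives its own).
#' @param config a [sim_config()].
#' @return A list: `status`, `correction`, `min_distance` (at zero
#'   correction), `clearance` (after correction, `NA` if impinged).
#' @export
check_pose <- function(model, pose, config = sim_config()) {
  Tm <- pose_to_transform(pose, model$pelvis_frame, model$femur_frame,
                          model$hip_center, model$side)
  posed <- transform_mesh(model$femur, Tm)
  d0 <- contact_distance_(model$pelvis, posed)
  if (d0 > 0)
    return(list(status = "free", correction = c(0, 0, 0),
                min_distance = d0, clearance = d0))
  if (config$max_translation > 0) {
    t <- resolve_translation(model$pelvis, posed,
                             max_norm = config$max_translation,
                             tolerance = config$contact_tolerance)
    if (!is.null(t)) {
      cl <- contact_distance_(model$pelvis, translate_mesh(posed, t))
      return(list(status = "resolved", correction = t,
                  min_distance = d0, clearance = cl))
    }
  }
  list(status = "impinged", correction = c(0, 0, 0),
       min_distance = d0, clearance = NA_real_)
}

pose_at_ <- function(motion, angle) {
  ang <- motion$fixed
  ang[[motion$sweep]] <- angle
  joint_pose(ang$flexion, ang$abduction, ang$internal_rotation)
}

#' Find the ROM endpoint of a motion
#'
#' Sweeps the motion from its start angle in coarse steps, then bisects to
#' the angle resolution.  The returned angle is the largest checked angle
#' whose pose is free or resolved; the pose one resolution step beyond is
#' impinged (unless the sweep bound was reached).  The corrective
#' translation is re-derived independently at every candidate pose, so the
#' result is path-independent.
#'
#' @param model a [hip_model()].
#' @param motion a [motion_definition()].
#' @param config a [sim_config()].
#' @return A list of class `rom_endpoint`: `motion`, `angle`, `status`
#'   (`"impinged"`, `"bound_reached"`, or `"start_impinged"`), `contact`
#'   (a [query_contact()] result at the first impinged pose, `NULL` when the
#'   bound was reached), `correction_at_endpoint`.
#' @export
find_endpoint <- function(model, motion, config = sim_config()) {
  res <- config$angle_resolution
  # integer grid in resolution units keeps the bracket guarantee exact
  n_bound <- floor((motion$bound - motion$start) / res + 1e-9)
  step_u <- max(1L, round(config$coarse_step / res))
  chk <- function(u) check_pose(model, pose_at_(motion, motion$start + u * res),
                                config)
  c0 <- chk(0L)
  if (c0$status == "impinged") {
    ct <- endpoint_contact_(model, motion, 0L, res, config)
    return(structure(list(motion = motion, angle = motion$start,
                          status = "start_impinged", contact = ct,
                          correction_at_endpoint = c(0, 0, 0)),
                     class = "rom_endpoint"))
  }
  lo <- 0L; lo_chk <- c0; hi <- NA_integer_
  u <- 0L
  while (u < n_bound) {
    u <- min(u + step_u, n_bound)
    ci <- chk(u)
    if (ci$status == "impinged") { hi <- u; break }
    lo <- u; lo_chk <- ci
  }
  if (is.na(hi))
    return(structure(list(motion = motion, angle = motion$start + lo * res,
                          status = "bound_reached", contact = NULL,
                          correction_at_endpoint = lo_chk$correction),
                     class = "rom_endpoint"))
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    ci <- chk(mid)
    if (ci$status == "impinged") hi <- mid else { lo <- mid; lo_chk <- ci }
  }
  ct <- endpoint_contact_(model, motion, hi, res, config)
  structure(list(motion = motion, angle = motion$start + lo * res,
                 status = "impinged", contact = ct,
                 correction_at_endpoint = lo_chk$correction),
            class = "rom_endpoint")
}

endpoint_contact_ <- function(model, motion, u_imp, res, config) {
  pose <- pose_at_(motion, motion$start + u_imp * res)
  Tm <- pose_to_transform(pose, model$pelvis_frame, model$femur_frame,
                          model$hip_center, model$side)
  query_contact(transform_mesh(model$femur, Tm), model$pelvis,
                tolerance = config$contact_tolerance)
}

#' @export
print.rom_endpoint <- function(x, ...) {
  cat(sprintf("<rom_endpoint %s: %.1f deg (%s), |correction| %.2f mm>\n",
              x$motion$label, x$angle, x$status,
              sqrt(sum(x$correction_at_endpoint^2))))
  invisible(x)
}

#' Simulate the six standard motions
#'
#' Runs [find_endpoint()] for maximum flexion, maximum abduction, and
#' maximum internal rotation at 0, 30, 60 and 90 degrees of flexion.
#'
#' @param model a [hip_model()].
#' @param config a [sim_config()].
#' @return A tibble of class `rom_table`: `motion`, `angle` (degrees),
#'   `status`, `correction_mm`; endpoint objects in `attr(, "endpoints")`.
#' @export
simulate_standard_set <- function(model, config = sim_config()) {
  eps <- lapply(standard_motions(config), function(m)
    find_endpoint(model, m, config))
  out <- purrr::map_dfr(eps, function(e)
    tibble::tibble(motion = e$motion$label, angle = e$angle,
                   status = e$status,
                   correction_mm = sqrt(sum(e$correction_at_endpoint^2))))
  attr(out, "endpoints") <- eps
  class(out) <- c("rom_table", class(out))
  out
}
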