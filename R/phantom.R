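#' Parametric hip phantom specification
#'
#' Describes a synthetic ball-in-cup hip: a spherical femoral head of radius
#' `head_radius` articulating inside a spherical cup shell of inner radius
#' `head_radius + clearance`, a cylindrical neck/shaft along an oblique axis,
#' and an optional cam bump (spherical-cap profile) at the head-neck
#' junction.  The geometry is concentric at the neutral pose, which makes
#' closed-form range-of-motion endpoints available ([analytic_rom()]).
#'
#' Directions (right hip, ISB-style world axes: X anterior, Y superior,
#' Z right): the cup pole points superior-medially, tilted `cup_pole_tilt`
#' degrees from superior toward medial; the neck axis (head toward shaft)
#' points inferior-laterally, `neck_tilt` degrees below horizontal.  The
#' neutral neck-to-pole offset `alpha0 = 90 + cup_pole_tilt + neck_tilt`
#' degrees is reported in the returned object.  A left hip mirrors the
#' medio-lateral axis.
#'
#' The default cam matches an artificial deformity made from a nylon screw
#' head 1 cm in diameter and 3.5 mm proud, placed on the anterosuperior
#' head-neck junction (clock hours 11-2).
#'
#' @param side `"right"` or `"left"`.
#' @param head_radius femoral head radius, mm.
#' @param clearance joint-space width between head and cup, mm.
#' @param cup_coverage rim polar angle from the cup pole, degrees (< 90).
#' @param cup_pole_tilt cup pole tilt from superior toward medial, degrees.
#' @param cup_thickness cup shell thickness, mm.
#' @param neck_radius,neck_length neck/shaft cylinder dimensions, mm.
#' @param neck_tilt neck axis angle below the horizontal, degrees.
#' @param cam `NULL` for a native hip, otherwise a list with `clock_hour`
#'   (11-2 band), `cap_radius` (mm), `height` (mm) and `polar_deg` (cam
#'   center's polar angle from the neck axis, degrees).
#' @param n_az azimuthal mesh divisions (mesh resolution; polar/axial
#'   spacing follows suit).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(side = "right",
                         head_radius = 25, clearance = 2,
                         cup_coverage = 70, cup_pole_tilt = 40,
                         cup_thickness = 4,
                         neck_radius = 12, neck_length = 80,
                         neck_tilt = 40,
                         cam = list(clock_hour = 2, cap_radius = 5,
                                    height = 3.5, polar_deg = 40),
                         n_az = 96) {
  side <- match.arg(side, c("right", "left"))
  stopifnot(head_radius > neck_radius, neck_radius > 0, clearance > 0,
            cup_coverage > 0, cup_coverage < 90, cup_thickness > 0,
            neck_length > head_radius, n_az >= 24)
  R_cup <- head_radius + clearance
  eta <- asin(neck_radius / R_cup) * 180 / pi
  alpha0 <- 90 + cup_pole_tilt + neck_tilt
  if (cup_coverage + eta >= alpha0)
    stop("phantom spec violates neutral-pose clearance: ",
         "cup_coverage + asin(neck_radius/R_cup) must be < alpha0", call. = FALSE)
  if (!is.null(cam)) {
    stopifnot(cam$height >= 0, cam$cap_radius > 0)
    if (cam$height == 0) cam <- NULL
  }
  s <- list(side = side, head_radius = head_radius, clearance = clearance,
            cup_radius = R_cup, cup_coverage = cup_coverage,
            cup_pole_tilt = cup_pole_tilt, cup_thickness = cup_thickness,
            neck_radius = neck_radius, neck_length = neck_length,
            neck_tilt = neck_tilt, cam = cam, n_az = n_az,
            alpha0 = alpha0, neck_half_angle = eta)
  class(s) <- "phantom_spec"
  ax <- phantom_axes_(s)
  if (!is.null(cam)) {
    g <- cam_super_clearance_(s)
    if (!is.na(g)) {
      A0 <- acos(sum(ax$cam_dir * ax$pole)) * 180 / pi
      if (A0 <= s$cup_coverage + g)
        warning("cam overlaps the cup at the neutral pose", call. = FALSE)
    }
  }
  s
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec (%s): head r=%.1f, clearance=%.1f, coverage=%.0f deg, alpha0=%.0f deg, cam=%s>\n",
    x$side, x$head_radius, x$clearance, x$cup_coverage, x$alpha0,
    if (is.null(x$cam)) "none" else
      sprintf("h=%.1f a=%.1f @%.1fh", x$cam$height, x$cam$cap_radius, x$cam$clock_hour)))
  invisible(x)
}

# unit directions of the phantom in world (= pelvis-frame) coordinates
phantom_axes_ <- function(spec) {
  lat <- if (spec$side == "right") 1 else -1     # lateral sign on Z
  mu <- spec$cup_pole_tilt * pi / 180
  nu <- spec$neck_tilt * pi / 180
  pole <- c(0, cos(mu), -lat * sin(mu))          # superior-medial
  neck <- c(0, -sin(nu), lat * cos(nu))          # inferior-lateral (head->shaft)
  e3 <- c(1, 0, 0)                               # 3 o'clock: anterior
  e12 <- if (spec$side == "right") vcross_(neck, e3) else vcross_(e3, neck)
  cam_dir <- NULL
  if (!is.null(spec$cam)) {
    w <- spec$cam$clock_hour * 30 * pi / 180
    ssgn <- if (spec$side == "right") 1 else -1
    azim <- cos(w) * e12 + ssgn * sin(w) * e3
    th <- spec$cam$polar_deg * pi / 180
    cam_dir <- cos(th) * neck + sin(th) * azim
  }
  list(pole = pole, neck = neck, e12 = e12, e3 = e3, cam_dir = cam_dir,
       lateral = lat)
}

vcross_ <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# spherical-cap bump profile: radial displacement at angular distance th
# (radians) from the cam center, on a head of radius rh
cam_profile_ <- function(th, rh, a, h) {
  Rb <- (a^2 + h^2) / (2 * h)
  s <- rh * sin(th)
  out <- numeric(length(th))
  ok <- s <= a & th < pi / 2
  out[ok] <- sqrt(Rb^2 - s[ok]^2) - (Rb - h)
  pmax(out, 0)
}

# angular half-width (degrees) of the cam region whose height exceeds the
# joint clearance; NA when the cam passes under the rim (h <= clearance)
cam_super_clearance_ <- function(spec) {
  h <- spec$cam$height; a <- spec$cam$cap_radius; cl <- spec$clearance
  if (h <= cl) return(NA_real_)
  Rb <- (a^2 + h^2) / (2 * h)
  sc <- sqrt(Rb^2 - (Rb - h + cl)^2)
  asin(sc / spec$head_radius) * 180 / pi
}

# ------------------------------------------------------------ mesh builders

# surface of revolution: rings (t, r) about unit axis with basis (b1, b2),
# closed by apex points at axial positions t0 and t1; phi is the shared
# azimuth grid (radians, sorted, in [0, 2 pi))
revolve_mesh_ <- function(axis, b1, b2, t0, rings, t1, phi, name) {
  n_r <- nrow(rings)
  n_az <- length(phi)
  ring_pts <- function(t, r) {
    outer(rep(t, n_az), axis) +
      r * (outer(cos(phi), b1) + outer(sin(phi), b2))
  }
  V <- rbind(axis * t0,
             do.call(rbind, lapply(seq_len(n_r),
                                   function(i) ring_pts(rings$t[i], rings$r[i]))),
             axis * t1)
  idx <- function(ring, k) 1L + (ring - 1L) * n_az + ((k - 1L) %% n_az) + 1L
  F <- vector("list", n_r + 1)
  F[[1]] <- cbind(1L, idx(1, 2:(n_az + 1)), idx(1, 1:n_az))
  for (q in seq_len(n_r - 1)) {
    a <- idx(q, 1:n_az); b <- idx(q, 2:(n_az + 1))
    cc <- idx(q + 1, 1:n_az); d <- idx(q + 1, 2:(n_az + 1))
    F[[q + 1]] <- rbind(cbind(a, b, d), cbind(a, d, cc))
  }
  apex1 <- nrow(V)
  F[[n_r + 1]] <- cbind(apex1, idx(n_r, 1:n_az), idx(n_r, 2:(n_az + 1)))
  m <- trimesh(V, do.call(rbind, F), name = name)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# merge a fine grid segment into a base grid, dropping base points that
# would create slivers against the fine points
merge_grid_ <- function(base, fine, min_gap) {
  if (length(fine) == 0) return(sort(base))
  keep <- vapply(base, function(x) min(abs(x - fine)) > min_gap, TRUE)
  sort(unique(c(base[keep], fine)))
}

phantom_femur_ <- function(spec) {
  ax <- phantom_axes_(spec)
  d <- ax$neck; b1 <- ax$e12; b2 <- ax$e3
  rh <- spec$head_radius; rn <- spec$neck_radius; L <- spec$neck_length
  step <- 2 * pi / spec$n_az
  thj <- asin(rn / rh)
  n_sph <- max(8L, ceiling((pi - thj) / step))
  th_s <- pi - (pi - thj) * seq_len(n_sph) / n_sph      # down to junction
  phi <- 2 * pi * (seq_len(spec$n_az) - 1) / spec$n_az
  if (!is.null(spec$cam)) {
    # refine the lathe grid locally around the cam cap so the bump profile
    # is resolved well below the joint clearance
    cd <- ax$cam_dir
    th_cam <- acos(pmin(1, pmax(-1, sum(cd * d))))
    az_cam <- atan2(sum(cd * b2), sum(cd * b1)) %% (2 * pi)
    cap_ang <- asin(min(1, spec$cam$cap_radius / rh))
    fine_arc <- 0.45                                    # target chord, mm
    dth <- fine_arc / rh
    th_band <- seq(max(thj, th_cam - cap_ang - 3 * dth),
                   min(pi - dth, th_cam + cap_ang + 3 * dth), by = dth)
    th_s <- merge_grid_(th_s, th_band, dth * 0.4)
    dph <- fine_arc / (rh * max(sin(th_cam), 0.2))
    ph_band <- (seq(az_cam - cap_ang / max(sin(th_cam), 0.2) - 3 * dph,
                    az_cam + cap_ang / max(sin(th_cam), 0.2) + 3 * dph,
                    by = dph)) %% (2 * pi)
    phi <- merge_grid_(phi, ph_band, dph * 0.4)
  }
  th_s <- sort(th_s, decreasing = TRUE)
  if (abs(th_s[length(th_s)] - thj) > 1e-12) th_s <- c(th_s, thj)
  t_j <- rh * cos(thj)
  n_cyl <- max(2L, ceiling((L - t_j) / (rh * step)))
  t_c <- t_j + (L - t_j) * seq_len(n_cyl)[-n_cyl] / n_cyl
  n_cap <- max(4L, ceiling((pi / 2) / step * rn / rh))
  th_cap <- (pi / 2) * (1 - seq_len(n_cap - 1) / n_cap)
  rings <- rbind(
    data.frame(t = rh * cos(th_s), r = rh * sin(th_s)),
    data.frame(t = c(t_c, L), r = rn),
    data.frame(t = L + rn * cos(th_cap), r = rn * sin(th_cap)))
  revolve_mesh_(d, b1, b2, -rh, rings, L + rn, phi, "femur")
}

phantom_pelvis_ <- function(spec) {
  ax <- phantom_axes_(spec)
  p <- ax$pole
  b1 <- vcross_(p, c(1, 0, 0)); b1 <- b1 / sqrt(sum(b1^2))
  b2 <- vcross_(p, b1)
  Ri <- spec$cup_radius; Ro <- Ri + spec$cup_thickness
  thc <- spec$cup_coverage * pi / 180
  step <- 2 * pi / spec$n_az
  n_in <- max(6L, ceiling(thc / step))
  th <- thc * seq_len(n_in) / n_in
  Rm <- (Ri + Ro) / 2
  rings <- rbind(
    data.frame(t = Ri * cos(th), r = Ri * sin(th)),
    data.frame(t = Rm * cos(thc), r = Rm * sin(thc)),
    data.frame(t = Ro * cos(rev(th)), r = Ro * sin(rev(th))))
  phi <- 2 * pi * (seq_len(spec$n_az) - 1) / spec$n_az
  revolve_mesh_(p, b1, b2, Ri, rings, Ro, phi, "pelvis")
}

#' Add a cam bump to a femoral head mesh
#'
#' Displaces head-surface vertices outward along the radial direction with a
#' spherical-cap profile: maximum height `cam$height` at the cam center,
#' falling to zero at planar radius `cam$cap_radius`.  The mesh stays
#' watertight (pure vertex displacement).  Multiple calls superimpose
#' (displacements add where caps overlap).
#'
#' @param femur a [trimesh()] femoral mesh whose head is a sphere of radius
#'   `head_radius` about `hip_center`.
#' @param cam cam description (see [phantom_spec()]).
#' @param hip_center length-3 head center (mm).
#' @param cam_dir unit direction from the head center to the cam center.
#' @param head_radius head sphere radius (mm).
#' @return The displaced mesh.
#' @export
add_cam <- function(femur, cam, hip_center, cam_dir, head_radius) {
  if (is.null(cam) || cam$height == 0) return(femur)
  V <- femur$vertices
  rel <- sweep(V, 2, hip_center)
  r <- sqrt(rowSums(rel^2))
  on_head <- abs(r - head_radius) < 1e-6 * head_radius
  u <- rel / r
  cth <- pmin(1, pmax(-1, u %*% cam_dir))
  th <- acos(cth)
  delta <- cam_profile_(th, head_radius, cam$cap_radius, cam$height)
  delta[!on_head] <- 0
  out <- femur
  out$vertices <- V + u * delta
  out
}

#' Generate a parametric hip phantom
#'
#' Builds watertight femur and pelvis meshes, the landmark set needed by the
#' anatomical-frame constructors (with paired pelvic K-wire fiducials 30 mm
#' apart), and carries the analytic parameters used by [analytic_rom()].
#' The hip center sits at the world origin; world axes coincide with the
#' ISB pelvis frame the landmarks produce.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `hip_phantom`: `femur` (cam included when the
#'   spec has one), `femur_native`, `pelvis`, `landmarks`, `hip_center`,
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ax <- phantom_axes_(spec)
  femur0 <- phantom_femur_(spec)
  pelvis <- phantom_pelvis_(spec)
  femur <- if (!is.null(spec$cam))
    add_cam(femur0, spec$cam, c(0, 0, 0), ax$cam_dir, spec$head_radius)
  else femur0
  lat <- ax$lateral
  lms <- landmark_set(
    spec$side,
    list(ASIS_left = c(60, 60, -120),
         ASIS_right = c(60, 60, 120),
         PSIS_mid = c(-40, 60, 0),
         greater_trochanter = c(0, -20, lat * 60),
         epicondyle_medial = c(0, -400, -lat * 40),
         epicondyle_lateral = c(0, -400, lat * 40)),
    fiducials = rbind(c(60, 60, lat * 105), c(60, 60, lat * 135),
                      c(0, -20, lat * 60), c(0, -400, -lat * 40),
                      c(0, -400, lat * 40)))
  structure(list(femur = femur, femur_native = femur0, pelvis = pelvis,
                 landmarks = lms, hip_center = c(0, 0, 0), spec = spec),
            class = "hip_phantom")
}

#' @export
print.hip_phantom <- function(x, ...) {
  cat("<hip_phantom>\n")
  print(x$spec)
  print(x$femur); print(x$pelvis)
  invisible(x)
}

# ------------------------------------------------------- analytic ROM oracle

# axis and sign of each standard motion component, given side
motion_axis_ <- function(component, side, femur_y = c(0, 1, 0)) {
  right <- side == "right"
  switch(component,
    flexion = c(0, 0, 1),
    abduction = if (right) c(-1, 0, 0) else c(1, 0, 0),
    internal_rotation = if (right) femur_y else -femur_y,
    stop("unknown motion component: ", component, call. = FALSE))
}

# first positive rotation (degrees) about unit `axis` at which the angle
# between rotated probe `q` and fixed `p` falls to Astar (degrees); Inf when
# it never does, 0 when already at or past contact
solve_axis_contact_ <- function(axis, q, p, Astar) {
  Astar <- Astar * pi / 180
  A0 <- acos(pmin(1, pmax(-1, sum(q * p))))
  if (A0 <= Astar + 1e-12) return(0)
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- vcross_(axis, ref); b1 <- b1 / sqrt(sum(b1^2))
  b2 <- vcross_(axis, b1)
  zq <- sum(q * axis); zp <- sum(p * axis)
  rq <- sqrt(max(0, 1 - zq^2)); rp <- sqrt(max(0, 1 - zp^2))
  if (rq * rp < 1e-12) return(Inf)             # probe or pole on the axis
  K <- (cos(Astar) - zq * zp) / (rq * rp)
  if (K > 1 || K < -1) return(Inf)
  u <- atan2(sum(q * b2), sum(q * b1))
  v <- atan2(sum(p * b2), sum(p * b1))
  psi <- acos(K)
  # cos A(phi) = rq rp cos(u + phi - v) + zq zp; approach crossing at
  # u + phi - v = -psi (mod 2 pi), where A is decreasing
  phi <- (v - u - psi) %% (2 * pi)
  phi * 180 / pi
}

#' Closed-form ROM endpoint for a concentric phantom
#'
#' For a single-axis sweep of the concentric ball-in-cup phantom with the
#' femoral head held at the cup center (no corrective translation), the
#' impingement angle has a closed form.  The neck cylinder meets the rim
#' when the angle between the neck axis and the cup pole falls to
#' `cup_coverage + asin(neck_radius / cup_radius)`; for the neutral in-plane
#' sweep this is `alpha0 - cup_coverage - asin(neck_radius / cup_radius)`.
#' A cam taller than the joint clearance adds a second contact: the cam
#' region whose bump height exceeds the clearance (angular half-width
#' `gamma_c`) reaches the rim circle when the cam-center-to-pole angle falls
#' to `cup_coverage + gamma_c`.  The endpoint is the earlier of the two
#' contacts, clipped at the sweep bound.
#'
#' Validity: concentric head and cup, zero corrective translation, the cam
#' contained in the head-sphere region.  Compare against engine runs with
#' `max_translation = 0`.
#'
#' @param spec a [phantom_spec()].
#' @param motion a [motion_definition()] (fixed components are applied as
#'   rotations before the sweep).
#' @return A list: `angle` (degrees), `status` (`"impinged"` or
#'   `"bound_reached"`), `limiter` (`"neck"`, `"cam"` or `"none"`).
#' @export
analytic_rom <- function(spec, motion) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(motion, "motion_definition"))
  ax <- phantom_axes_(spec)
  side <- spec$side
  # apply fixed components in engine order: flexion, abduction, then IR
  Rfix <- diag(3)
  femur_y <- c(0, 1, 0)
  for (comp in c("flexion", "abduction", "internal_rotation")) {
    ang <- motion$fixed[[comp]]
    if (is.null(ang) || ang == 0) next
    a_axis <- motion_axis_(comp, side, femur_y = as.numeric(Rfix %*% femur_y))
    Rfix <- rotation_about(a_axis, ang) %*% Rfix
  }
  d <- as.numeric(Rfix %*% ax$neck)
  cam_d <- if (!is.null(ax$cam_dir)) as.numeric(Rfix %*% ax$cam_dir) else NULL
  axis <- motion_axis_(motion$sweep, side, femur_y = as.numeric(Rfix %*% femur_y))
  p <- ax$pole
  ang_neck <- solve_axis_contact_(axis, d, p,
                                  spec$cup_coverage + spec$neck_half_angle)
  ang_cam <- Inf
  if (!is.null(cam_d)) {
    g <- cam_super_clearance_(spec)
    if (!is.na(g))
      ang_cam <- solve_axis_contact_(axis, cam_d, p, spec$cup_coverage + g)
  }
  ang <- min(ang_neck, ang_cam)
  if (ang > motion$bound)
    list(angle = motion$bound, status = "bound_reached", limiter = "none")
  else
    list(angle = ang, status = "impinged",
         limiter = if (ang_cam < ang_neck) "cam" else "neck")
}

#' Analytic endpoints for the six standard motions
#'
#' @param spec a [phantom_spec()].
#' @param config a [sim_config()] (for sweep bounds).
#' @return A tibble with `motion`, `angle`, `status`, `limiter`.
#' @export
analytic_standard_set <- function(spec, config = sim_config()) {
  motions <- standard_motions(config)
  purrr::map_dfr(motions, function(m) {
    res <- analytic_rom(spec, m)
    tibble::tibble(motion = m$label, angle = res$angle,
                   status = res$status, limiter = res$limiter)
  })
}

# brute-force contact angle by dense sampling of the rim edge circle.
# First contact of either the neck cylinder or the cam bump with the cup
# shell {R_cup <= r <= R_out, polar <= coverage} occurs on the rim edge
# circle (the bump and neck approach from outside the covered cone at radii
# straddling R_cup), so it suffices to track, per pose, the pointwise
# penetration margins of the rim samples against the femur's analytic
# surfaces.  Independent of the spherical-trigonometry solve in
# analytic_rom(); used as its validation oracle in tests.
brute_rom_ <- function(spec, motion, coarse = 0.25, refine_to = 0.002,
                       rim_step_deg = 0.05) {
  ax <- phantom_axes_(spec)
  rh <- spec$head_radius; rn <- spec$neck_radius
  Ri <- spec$cup_radius
  thc <- spec$cup_coverage * pi / 180
  p <- ax$pole
  f1 <- vcross_(p, c(1, 0, 0)); f1 <- f1 / sqrt(sum(f1^2))
  f2 <- vcross_(p, f1)
  psi <- seq(0, 2 * pi, by = rim_step_deg * pi / 180)
  rim <- Ri * (outer(rep(cos(thc), length(psi)), p) +
                 sin(thc) * (outer(cos(psi), f1) + outer(sin(psi), f2)))
  # fixed components applied to the femur
  Rfix <- diag(3)
  femur_y <- c(0, 1, 0)
  for (comp in c("flexion", "abduction", "internal_rotation")) {
    angf <- motion$fixed[[comp]]
    if (is.null(angf) || angf == 0) next
    a_axis <- motion_axis_(comp, spec$side, femur_y = as.numeric(Rfix %*% femur_y))
    Rfix <- rotation_about(a_axis, angf) %*% Rfix
  }
  axis <- motion_axis_(motion$sweep, spec$side,
                       femur_y = as.numeric(Rfix %*% femur_y))
  d <- ax$neck
  tj <- sqrt(rh^2 - rn^2)
  L <- spec$neck_length
  cam <- spec$cam
  cd <- ax$cam_dir
  hits <- function(ang) {
    Rtot <- rotation_about(axis, ang) %*% Rfix
    q <- rim %*% Rtot                        # rim points in femur coordinates
    t_ax <- as.numeric(q %*% d)
    perp2 <- pmax(Ri^2 - t_ax^2, 0)
    neck_hit <- any(t_ax >= tj & t_ax <= L & perp2 <= rn^2)
    cam_hit <- FALSE
    if (!is.null(cam)) {
      th <- acos(pmin(1, pmax(-1, (q %*% cd) / Ri)))
      cam_hit <- any(rh + cam_profile_(th, rh, cam$cap_radius, cam$height) >= Ri)
    }
    neck_hit || cam_hit
  }
  if (hits(0)) return(0)
  lo <- 0; hi <- NA
  for (ang in seq(coarse, motion$bound, by = coarse)) {
    if (hits(ang)) { hi <- ang; break } else lo <- ang
  }
  if (is.na(hi)) return(motion$bound)
  while (hi - lo > refine_to) {
    mid <- (lo + hi) / 2
    if (hits(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Icosphere mesh
#'
#' Unit-sphere triangulation by icosahedron subdivision, scaled to `radius`
#' and centered at `center`.  Used for closed-form geometry tests.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 face subdivisions (default 3).
#' @param center sphere center.
#' @export
icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env()
    nv <- nrow(V)
    newV <- list()
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_mid[[key]]
      if (!is.null(id)) return(id)
      m <- V[i, ] + V[j, ]
      m <- m / sqrt(sum(m^2))
      newV[[length(newV) + 1]] <<- m
      id <- nv + length(newV)
      edge_mid[[key]] <- id
      id
    }
    newF <- matrix(0L, nrow = 4 * nrow(F), ncol = 3)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; cc <- F[f, 3]
      ab <- mid(a, b); bc <- mid(b, cc); ca <- mid(cc, a)
      newF[(4 * f - 3):(4 * f), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    V <- rbind(V, do.call(rbind, newV))
    F <- newF
  }
  trimesh(sweep(V * radius, 2, center, "+"), F, name = "icosphere")
}
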