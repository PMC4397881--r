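#' Landmark set for anatomical frame construction
#'
#' Named anatomical landmarks (mm) plus ordered registration fiducials
#' (K-wire points).  The pelvis frame needs `ASIS_left`, `ASIS_right` and
#' `PSIS_mid`; the femur frame needs `epicondyle_medial` and
#' `epicondyle_lateral`.
#'
#' @param side `"left"` or `"right"` hip; controls axis signs and the
#'   clock-face mirror.
#' @param landmarks named list of length-3 numeric vectors.
#' @param fiducials optional matrix (n x 3) of fiducial points, ordered.
#' @export
landmark_set <- function(side, landmarks, fiducials = NULL) {
  side <- match.arg(side, c("left", "right"))
  landmarks <- lapply(landmarks, as.numeric)
  stopifnot(all(vapply(landmarks, length, 1L) == 3))
  pts <- do.call(rbind, landmarks)
  if (nrow(pts) > 1 && any(stats::dist(pts) < 1e-9))
    stop("two landmarks coincide", call. = FALSE)
  if (!is.null(fiducials)) {
    fiducials <- as.matrix(fiducials)
    stopifnot(ncol(fiducials) == 3)
  }
  structure(list(side = side, landmarks = landmarks, fiducials = fiducials),
            class = "landmark_set")
}

#' Read/write the landmark JSON schema
#'
#' Schema: `{"side": "left"|"right", "landmarks": {name: [x,y,z]},
#' "fiducials": [[x,y,z], ...]}`, units mm.
#'
#' @param path file path.
#' @export
read_landmarks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fid <- if (!is.null(j$fiducials)) {
    f <- j$fiducials
    if (is.list(f)) do.call(rbind, f) else rbind(f)
  } else NULL
  landmark_set(j$side, lapply(j$landmarks, as.numeric), fid)
}

#' @rdname read_landmarks
#' @param lms a [landmark_set()].
#' @export
write_landmarks <- function(lms, path) {
  jsonlite::write_json(
    list(side = lms$side,
         landmarks = lapply(lms$landmarks, as.numeric),
         fiducials = if (is.null(lms$fiducials)) list() else
           unname(apply(lms$fiducials, 1, as.numeric, simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

frame_ <- function(origin, X, Y, Z) {
  unit <- function(v) v / sqrt(sum(v^2))
  X <- unit(X); Y <- unit(Y); Z <- unit(Z)
  R <- cbind(X, Y, Z)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    stop("degenerate frame: axes not right-handed orthonormal", call. = FALSE)
  structure(list(origin = as.numeric(origin), X = X, Y = Y, Z = Z,
                 rotation = R),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("<anatomical_frame>\n origin:", paste(round(x$origin, 3), collapse = ", "), "\n")
  for (ax in c("X", "Y", "Z"))
    cat(sprintf(" %s: %s\n", ax, paste(round(x[[ax]], 4), collapse = ", ")))
  invisible(x)
}

#' ISB pelvis anatomical frame
#'
#' Z runs from the left to the right anterior superior iliac spine; X is
#' orthogonal to Z in the plane of the two ASISs and the posterior midpoint,
#' pointing anteriorly; Y = Z x X points superiorly.  Origin at the ASIS
#' midpoint.
#'
#' @param lms a [landmark_set()] with `ASIS_left`, `ASIS_right`, `PSIS_mid`.
#' @return An `anatomical_frame`.
#' @export
pelvis_frame <- function(lms) {
  need <- c("ASIS_left", "ASIS_right", "PSIS_mid")
  if (!all(need %in% names(lms$landmarks)))
    stop("pelvis frame needs landmarks: ", paste(need, collapse = ", "), call. = FALSE)
  L <- lms$landmarks
  Z <- L$ASIS_right - L$ASIS_left
  origin <- (L$ASIS_right + L$ASIS_left) / 2
  w <- origin - L$PSIS_mid                 # posterior midpoint -> anterior
  X <- w - Z * sum(w * Z) / sum(Z^2)
  if (sqrt(sum(X^2)) < 1e-9 * sqrt(sum(Z^2)))
    stop("degenerate frame: PSIS_mid collinear with the ASIS axis", call. = FALSE)
  Zu <- Z / sqrt(sum(Z^2)); Xu <- X / sqrt(sum(X^2))
  Y <- c(Zu[2] * Xu[3] - Zu[3] * Xu[2],
         Zu[3] * Xu[1] - Zu[1] * Xu[3],
         Zu[1] * Xu[2] - Zu[2] * Xu[1])
  frame_(origin, Xu, Y, Zu)
}

#' ISB femur anatomical frame
#'
#' Origin at the hip rotation center; Y from the epicondyle midpoint toward
#' the hip center (the long axis used for axial rotation); Z orthogonal to Y
#' in the plane of the epicondyles and hip center, pointing to the right
#' (toward the lateral epicondyle on a right hip, mirrored on a left hip);
#' X = Y x Z points anteriorly.
#'
#' @param lms a [landmark_set()] with both epicondyles.
#' @param hip_center a [fit_hip_center()] result, or a length-3 center (mm).
#' @export
femur_frame <- function(lms, hip_center) {
  need <- c("epicondyle_medial", "epicondyle_lateral")
  if (!all(need %in% names(lms$landmarks)))
    stop("femur frame needs landmarks: ", paste(need, collapse = ", "), call. = FALSE)
  ctr <- if (inherits(hip_center, "hip_center_fit")) hip_center$center
         else as.numeric(hip_center)
  L <- lms$landmarks
  if (sqrt(sum((L$epicondyle_medial - L$epicondyle_lateral)^2)) < 1e-9)
    stop("degenerate frame: epicondyles coincide", call. = FALSE)
  mid <- (L$epicondyle_medial + L$epicondyle_lateral) / 2
  Y <- ctr - mid
  if (sqrt(sum(Y^2)) < 1e-9)
    stop("degenerate frame: hip center at epicondyle midpoint", call. = FALSE)
  lat <- if (lms$side == "right") L$epicondyle_lateral - L$epicondyle_medial
         else L$epicondyle_medial - L$epicondyle_lateral
  Z <- lat - Y * sum(lat * Y) / sum(Y^2)
  if (sqrt(sum(Z^2)) < 1e-9 * sqrt(sum(lat^2)))
    stop("degenerate frame: epicondyle axis parallel to long axis", call. = FALSE)
  Yu <- Y / sqrt(sum(Y^2)); Zu <- Z / sqrt(sum(Z^2))
  X <- c(Yu[2] * Zu[3] - Yu[3] * Zu[2],
         Yu[3] * Zu[1] - Yu[1] * Zu[3],
         Yu[1] * Zu[2] - Yu[2] * Zu[1])
  frame_(ctr, X, Yu, Zu)
}

#' Fit the hip rotation center
#'
#' Least-squares sphere fit to femoral-head surface points (algebraic fit,
#' exact on noiseless spheres).  When the acetabular cup surface is supplied
#' the center is refined by the equidistant criterion: minimize the variance
#' of the head-to-cup clearance over the cup-facing directions, starting
#' from the sphere-fit center.
#'
#' @param head_surface a [trimesh()] or an n x 3 point matrix sampling the
#'   femoral head (n >= 10, non-coplanar).
#' @param cup_surface optional [trimesh()] or point matrix of the acetabular
#'   articular surface.
#' @return Object of class `hip_center_fit`: `center` (mm), `head_radius`
#'   (mm), `fit_rms` (mm).
#' @export
fit_hip_center <- function(head_surface, cup_surface = NULL) {
  P <- if (inherits(head_surface, "trimesh")) head_surface$vertices
       else as.matrix(head_surface)
  if (nrow(P) < 10) stop("need >= 10 head-surface points", call. = FALSE)
  ctr0 <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr0))$d
  if (sv[3] < 1e-9 * sv[1]) stop("head points are coplanar", call. = FALSE)
  # algebraic fit: |p|^2 = 2 c.p + (r^2 - |c|^2)
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  sol <- qr.solve(A, b)
  center <- sol[1:3]
  radius <- sqrt(sol[4] + sum(center^2))
  if (!is.null(cup_surface)) {
    Q <- if (inherits(cup_surface, "trimesh")) cup_surface$vertices
         else as.matrix(cup_surface)
    obj <- function(cc) stats::var(sqrt(rowSums(sweep(Q, 2, cc)^2)))
    center <- stats::optim(center, obj, method = "Nelder-Mead",
                           control = list(maxit = 200, reltol = 1e-10))$par
    radius <- mean(sqrt(rowSums(sweep(P, 2, center)^2)))
  }
  r_i <- sqrt(rowSums(sweep(P, 2, center)^2))
  structure(list(center = as.numeric(center), head_radius = radius,
                 fit_rms = sqrt(mean((r_i - radius)^2)), n_points = nrow(P)),
            class = "hip_center_fit")
}

#' @export
print.hip_center_fit <- function(x, ...) {
  cat(sprintf("<hip_center_fit: center (%.3f, %.3f, %.3f) mm, radius %.3f mm, RMS %.4f mm>\n",
              x$center[1], x$center[2], x$center[3], x$head_radius, x$fit_rms))
  invisible(x)
}

#' @export
tidy.hip_center_fit <- function(x, ...) {
  tibble::tibble(term = c("center_x", "center_y", "center_z", "head_radius"),
                 estimate = c(x$center, x$head_radius))
}

#' @export
glance.hip_center_fit <- function(x, ...) {
  tibble::tibble(head_radius = x$head_radius, fit_rms = x$fit_rms,
                 n_points = x$n_points)
}

#' Rigid point-set registration (no scaling)
#'
#' Least-squares rigid transform mapping ordered `source` fiducials onto
#' `target` (SVD/Kabsch solution).  FRE is the root-mean-square residual
#' after alignment.
#'
#' @param source,target n x 3 matrices of corresponding points (n >= 3,
#'   non-collinear).
#' @return Object of class `fiducial_registration`: `transform`
#'   (a [rigid_transform()]), `fre` (mm), `n`.
#' @export
register_point_sets <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (nrow(source) != nrow(target))
    stop("point count mismatch between source and target", call. = FALSE)
  if (nrow(source) < 3) stop("need >= 3 correspondences", call. = FALSE)
  cs <- colMeans(source); ct <- colMeans(target)
  S0 <- sweep(source, 2, cs); T0 <- sweep(target, 2, ct)
  sv <- svd(S0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stop("degenerate registration: points are collinear", call. = FALSE)
  H <- crossprod(S0, T0)
  dec <- svd(H)
  D <- diag(c(1, 1, sign(det(dec$v %*% t(dec$u)))))
  R <- dec$v %*% D %*% t(dec$u)
  t <- ct - as.numeric(R %*% cs)
  res <- sweep(source %*% t(R), 2, t, "+") - target
  structure(list(transform = rigid_transform(R, t),
                 fre = sqrt(mean(rowSums(res^2))), n = nrow(source)),
            class = "fiducial_registration")
}

#' @export
print.fiducial_registration <- function(x, ...) {
  cat(sprintf("<fiducial_registration: n=%d, FRE=%.4f mm>\n", x$n, x$fre))
  invisible(x)
}

#' @export
glance.fiducial_registration <- function(x, ...) {
  tibble::tibble(n = x$n, fre = x$fre)
}
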