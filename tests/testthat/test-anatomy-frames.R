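example_landmarks <- function(side = "right") {
  landmark_set(side, list(
    ASIS_left = c(-120, 0, 0), ASIS_right = c(120, 0, 0),
    PSIS_mid = c(0, -10, -60),
    epicondyle_medial = c(0, -400, -40), epicondyle_lateral = c(0, -400, 40),
    greater_trochanter = c(0, -20, 60)))
}

transform_landmarks <- function(lms, Tm) {
  landmark_set(lms$side,
               lapply(lms$landmarks, function(p) drop(apply_transform(Tm, p))),
               if (is.null(lms$fiducials)) NULL
               else apply_transform(Tm, lms$fiducials))
}

test_that("pelvis frame follows the ISB construction and is equivariant", {
  lms <- example_landmarks()
  fr <- pelvis_frame(lms)
  expect_equal(fr$Z, c(1, 0, 0))
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(fr$X[1], 0, tolerance = 1e-12)        # X in the y-z plane
  expect_equal(crossprod(fr$rotation), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(det(fr$rotation), 1, tolerance = 1e-9)

  set.seed(3)
  for (i in 1:25) {
    Tm <- random_rigid()
    fr2 <- pelvis_frame(transform_landmarks(lms, Tm))
    expect_equal(fr2$rotation, Tm$rotation %*% fr$rotation, tolerance = 1e-9)
    expect_equal(fr2$origin, drop(apply_transform(Tm, fr$origin)),
                 tolerance = 1e-9)
  }
  bad <- lms; bad$landmarks$PSIS_mid <- c(30, 0, 0)  # on the ASIS line
  expect_error(pelvis_frame(bad), "degenerate")
  expect_error(pelvis_frame(landmark_set("right", list(ASIS_left = c(0, 0, 0)))),
               "needs landmarks")
})

test_that("femur frame uses the long axis through the hip center and respects side", {
  lms <- example_landmarks()
  ctr <- c(0, 20, 0)
  fr <- femur_frame(lms, ctr)
  expect_equal(fr$origin, ctr)
  expect_equal(fr$Y, c(0, 1, 0))
  expect_equal(fr$Z, c(0, 0, 1))                     # toward lateral, right hip
  expect_equal(fr$X, c(1, 0, 0))
  lms_l <- example_landmarks("left")
  lms_l$landmarks$epicondyle_medial <- c(0, -400, 40)
  lms_l$landmarks$epicondyle_lateral <- c(0, -400, -40)
  fr_l <- femur_frame(lms_l, ctr)
  expect_equal(fr_l$Z, c(0, 0, 1))                   # still to the subject right

  set.seed(4)
  for (i in 1:25) {
    Tm <- random_rigid()
    fr2 <- femur_frame(transform_landmarks(lms, Tm),
                       drop(apply_transform(Tm, ctr)))
    expect_equal(fr2$rotation, Tm$rotation %*% fr$rotation, tolerance = 1e-9)
    xyz <- c(fr2$Y[2] * fr2$Z[3] - fr2$Y[3] * fr2$Z[2],
             fr2$Y[3] * fr2$Z[1] - fr2$Y[1] * fr2$Z[3],
             fr2$Y[1] * fr2$Z[2] - fr2$Y[2] * fr2$Z[1])
    expect_equal(fr2$X, xyz, tolerance = 1e-9)       # right-handed
  }
  bad <- lms; bad$landmarks$epicondyle_medial <- bad$landmarks$epicondyle_lateral
  expect_error(femur_frame(bad, ctr), "coincide")
})

test_that("hip-center sphere fit is exact on noiseless data and robust to noise", {
  set.seed(5)
  P <- sphere_points(500, 25, c(10, 0, 5))
  fit <- fit_hip_center(P)
  expect_equal(fit$center, c(10, 0, 5), tolerance = 1e-6)
  expect_equal(fit$head_radius, 25, tolerance = 1e-6)
  expect_lt(fit$fit_rms, 1e-8)

  Pn <- sphere_points(2000, 25, c(10, 0, 5)) + matrix(stats::rnorm(6000, sd = 0.2),
                                                      ncol = 3)
  fitn <- fit_hip_center(Pn)
  expect_lt(sqrt(sum((fitn$center - c(10, 0, 5))^2)), 0.1)

  # hemisphere-only coverage
  H <- sphere_points(4000, 25, c(0, 0, 0))
  H <- H[H[, 2] > 0, ][1:1500, ] + matrix(stats::rnorm(4500, sd = 0.2), ncol = 3)
  fith <- fit_hip_center(H)
  expect_lt(sqrt(sum(fith$center^2)), 0.5)

  expect_error(fit_hip_center(P[1:5, ]), ">= 10")
  flat <- cbind(matrix(stats::runif(40), ncol = 2), 0)
  expect_error(fit_hip_center(flat), "coplanar")

  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "head_radius"], 25, tolerance = 1e-6)
  expect_named(glance(fit), c("head_radius", "fit_rms", "n_points"))
})

test_that("equidistant refinement against a cup keeps the concentric center", {
  set.seed(6)
  ph <- default_phantom()
  head_pts <- ph$femur_native$vertices
  r <- sqrt(rowSums(head_pts^2))
  head_pts <- head_pts[abs(r - 25) < 1e-6, ]
  cup_pts <- ph$pelvis$vertices[abs(sqrt(rowSums(ph$pelvis$vertices^2)) - 27) < 1e-6, ]
  fit <- fit_hip_center(head_pts, cup_pts)
  expect_lt(sqrt(sum(fit$center^2)), 0.05)
  expect_equal(fit$head_radius, 25, tolerance = 1e-3)
})

test_that("point-set registration recovers exact transforms and scales FRE with noise", {
  set.seed(8)
  src <- matrix(stats::rnorm(15, sd = 40), ncol = 3)
  reg0 <- register_point_sets(src, src)
  expect_equal(reg0$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(reg0$fre, 0, tolerance = 1e-12)

  for (i in 1:20) {
    Tm <- random_rigid()
    tgt <- apply_transform(Tm, src)
    reg <- register_point_sets(src, tgt)
    expect_equal(reg$transform$rotation, Tm$rotation, tolerance = 1e-9)
    expect_equal(reg$transform$translation, Tm$translation, tolerance = 1e-9)
    expect_lt(reg$fre, 1e-9)
  }

  # 0.25 mm isotropic noise on 5 fiducials: FRE on the noise scale
  fres <- replicate(200, {
    Tm <- random_rigid()
    tgt <- apply_transform(Tm, src) + matrix(stats::rnorm(15, sd = 0.25), ncol = 3)
    register_point_sets(src, tgt)$fre
  })
  expect_gt(mean(fres), 0.1)
  expect_lt(mean(fres), 0.5)

  expect_error(register_point_sets(src[1:2, ], src[1:2, ]), ">= 3")
  expect_error(register_point_sets(src, src[1:3, ]), "mismatch")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(register_point_sets(line, line), "collinear")
})
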