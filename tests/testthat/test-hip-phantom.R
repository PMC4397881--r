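test_that("generated phantoms are watertight and clear at the neutral pose", {
  ph <- default_phantom()
  vf <- validate_mesh(ph$femur)
  vp <- validate_mesh(ph$pelvis)
  expect_true(vf$watertight)
  expect_true(vp$watertight)
  expect_gt(vf$volume, 0)
  expect_gt(vp$volume, 0)
  q <- query_contact(ph$femur, ph$pelvis, want_pairs = FALSE)
  expect_false(q$colliding)
  expect_equal(q$min_distance, ph$spec$clearance, tolerance = 0.1)
  # landmarks feed the frame constructors; pelvic K-wires sit 30 mm apart
  expect_s3_class(pelvis_frame(ph$landmarks), "anatomical_frame")
  expect_equal(sqrt(sum((ph$landmarks$fiducials[1, ] -
                           ph$landmarks$fiducials[2, ])^2)), 30)
  expect_error(phantom_spec(cup_coverage = 89, cup_pole_tilt = 10,
                            neck_tilt = 10), "clearance")
})

# exact added volume of the radial bump field on a sphere, by quadrature:
# the independent oracle for the mesh volume difference
bump_volume_quad <- function(rh, a, h) {
  psi_max <- asin(a / rh)
  f <- function(psi) {
    delta <- hipsim:::cam_profile_(psi, rh, a, h)
    ((rh + delta)^3 - rh^3) / 3 * 2 * pi * sin(psi)
  }
  stats::integrate(f, 0, psi_max, rel.tol = 1e-10)$value
}

test_that("cam bump adds the closed-form spherical-cap volume", {
  spec <- phantom_spec(n_az = 48)
  ph <- generate_phantom(spec)
  flat_cap <- pi * 3.5 * (3 * 5^2 + 3.5^2) / 6      # flat-base cap formula
  v_quad <- bump_volume_quad(25, 5, 3.5)
  # on the convex head the exact bump volume runs slightly over the
  # flat-base formula; the mesh must match the quadrature oracle closely
  expect_lt(abs(v_quad - flat_cap) / flat_cap, 0.15)
  added <- mesh_volume(ph$femur) - mesh_volume(ph$femur_native)
  expect_lt(abs(added - v_quad) / v_quad, 0.02)

  # zero height is the identity
  same <- add_cam(ph$femur_native,
                  list(clock_hour = 1, cap_radius = 5, height = 0,
                       polar_deg = 40),
                  c(0, 0, 0), c(0, 1, 0), 25)
  expect_identical(same$vertices, ph$femur_native$vertices)
  spec0 <- phantom_spec(n_az = 48, cam = list(clock_hour = 1, cap_radius = 5,
                                              height = 0, polar_deg = 40))
  expect_null(spec0$cam)
  ph0 <- generate_phantom(spec0)
  expect_equal(ph0$femur$vertices, ph0$femur_native$vertices)

  # two adjacent caps (the paired-screw layout) add nearly two cap volumes
  ax <- hipsim:::phantom_axes_(spec)
  cam2 <- spec$cam; cam2$clock_hour <- 12
  w <- cam2$clock_hour * 30 * pi / 180
  azim <- cos(w) * ax$e12 + sin(w) * ax$e3
  th <- cam2$polar_deg * pi / 180
  dir2 <- cos(th) * ax$neck + sin(th) * azim
  fem2 <- add_cam(ph$femur, cam2, c(0, 0, 0), dir2, 25)
  added2 <- mesh_volume(fem2) - mesh_volume(ph$femur_native)
  expect_gt(added2, 1.8 * v_quad)    # disjoint caps: volumes add
  expect_lt(added2, 2.1 * v_quad)
})

test_that("analytic endpoints obey their limiting cases", {
  cfg <- cfg0()
  ab <- function(spec) analytic_rom(spec, standard_motions(cfg)[[2]])
  # neck term: endpoint = alpha0 - coverage - asin(r_n / R_cup), and the
  # point-neck limit alpha0 - coverage as r_n -> 0
  s <- phantom_spec(n_az = 24, cam = NULL, neck_radius = 8)
  expect_equal(ab(s)$angle,
               s$alpha0 - s$cup_coverage - asin(8 / s$cup_radius) * 180 / pi,
               tolerance = 1e-9)
  s_thin <- phantom_spec(n_az = 24, cam = NULL, neck_radius = 0.05,
                         head_radius = 25)
  expect_equal(ab(s_thin)$angle, s_thin$alpha0 - s_thin$cup_coverage,
               tolerance = 0.2)
  # a cam lower than the joint clearance passes under the rim
  s_low <- phantom_spec(n_az = 24, clearance = 2,
                        cam = list(clock_hour = 12, cap_radius = 5,
                                   height = 1.5, polar_deg = 40))
  s_no <- phantom_spec(n_az = 24, clearance = 2, cam = NULL)
  for (m in standard_motions(cfg))
    expect_equal(analytic_rom(s_low, m)$angle, analytic_rom(s_no, m)$angle)
})

test_that("closed-form endpoints match the rim-sampling brute force", {
  set.seed(21)
  cfg <- cfg0()
  motions <- standard_motions(cfg)
  for (i in 1:5) {
    spec <- random_phantom_spec(with_cam = i > 2)
    for (m in motions[c(1, 2, 6)]) {
      a <- analytic_rom(spec, m)$angle
      b <- hipsim:::brute_rom_(spec, m)
      expect_lt(abs(a - b), 0.02)
    }
  }
})

test_that("voxelization reproduces volumes and material intensities", {
  sph <- icosphere(25, 3)
  ct <- ct_spec(in_plane = 0.53, slice = 1, margin = 3)   # scaled-down grid
  vol <- voxelize_ct(bone = list(sph), soft_envelope = FALSE, ct = ct)
  v_est <- sum(vol$data > 1) * prod(vol$spacing)
  expect_lt(abs(v_est - 4 / 3 * pi * 25^3) / (4 / 3 * pi * 25^3), 0.02)

  empty <- voxelize_ct(soft_envelope = FALSE, ct = ct)
  expect_true(all(empty$data == 0))

  ph <- default_phantom()
  vol2 <- voxelize_ct(bone = list(ph$femur_native), nylon = list(ph$femur),
                      nylon_minus = list(ph$femur_native),
                      ct = ct_spec(in_plane = 0.53, slice = 1))
  ints <- sort(unique(round(as.numeric(vol2$data), 2)))
  expect_true(all(c(1, 1.15, 1.9) %in% ints))        # soft, nylon cam, bone
  nylon_vol <- sum(abs(vol2$data - 1.15) < 0.01) * prod(vol2$spacing)
  cap_vol <- pi * 3.5 * (3 * 25 + 3.5^2) / 6
  expect_lt(abs(nylon_vol - cap_vol) / cap_vol, 0.25)

  open_tri <- trimesh(matrix(stats::rnorm(9), 3, 3), rbind(c(1, 2, 3)))
  expect_error(voxelize_ct(bone = list(open_tri)), "closed")
})

test_that("NIfTI round-trip preserves data, spacing and origin", {
  sph <- icosphere(10, 2)
  vol <- voxelize_ct(bone = list(sph), ct = ct_spec(in_plane = 1, slice = 1))
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  write_ct_nifti(vol, tmp)
  back <- read_ct_nifti(tmp)
  expect_equal(back$data, vol$data, ignore_attr = TRUE)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-5)
})

test_that("segmentation separates components and honors the nylon band", {
  sph <- icosphere(20, 3)
  vol <- voxelize_ct(bone = list(sph), ct = ct_spec(in_plane = 0.53, slice = 1))
  seg <- segment_volume(vol, iso = 1.45, max_components = 1)
  expect_equal(length(seg), 1)
  expect_true(validate_mesh(seg[[1]])$watertight)
  expect_lt(abs(mesh_volume(seg[[1]]) - mesh_volume(sph)) / mesh_volume(sph),
            0.05)
  expect_error(segment_volume(vol, iso = 2.5), "empty segmentation")

  dec <- decimate_mesh(seg[[1]], 2)
  expect_lt(nrow(dec$faces), nrow(seg[[1]]$faces))
  expect_lt(abs(mesh_volume(dec) - mesh_volume(sph)) / mesh_volume(sph), 0.05)
})
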