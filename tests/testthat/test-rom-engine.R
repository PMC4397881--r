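test_that("pose_to_transform composes the clinical rotations correctly", {
  ph <- default_phantom()
  mdl <- default_models()$native
  pf <- mdl$pelvis_frame; ff <- mdl$femur_frame; ctr <- mdl$hip_center

  T0 <- pose_to_transform(joint_pose(), pf, ff, ctr, "right")
  expect_equal(T0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(T0$translation, c(0, 0, 0), tolerance = 1e-12)

  # 90 deg flexion carries the femoral long axis from inferior to anterior
  T90 <- pose_to_transform(joint_pose(flexion = 90), pf, ff, ctr, "right")
  shaft <- drop(T90$rotation %*% c(0, -1, 0))        # inferior direction
  expect_equal(shaft, c(1, 0, 0), tolerance = 1e-9)  # anterior

  # abduction carries a right leg laterally (toward +Z)
  Tab <- pose_to_transform(joint_pose(abduction = 90), pf, ff, ctr, "right")
  expect_equal(drop(Tab$rotation %*% c(0, -1, 0)), c(0, 0, 1), tolerance = 1e-9)
  Tab_l <- pose_to_transform(joint_pose(abduction = 90), pf, ff, ctr, "left")
  expect_equal(drop(Tab_l$rotation %*% c(0, -1, 0)), c(0, 0, -1),
               tolerance = 1e-9)

  # internal rotation turns the anterior femur medially (right hip: -Z)
  Tir <- pose_to_transform(joint_pose(internal_rotation = 90), pf, ff, ctr,
                           "right")
  expect_equal(drop(Tir$rotation %*% c(1, 0, 0)), c(0, 0, -1), tolerance = 1e-9)

  # internal rotation by a then -a composes to the identity
  Ta <- pose_to_transform(joint_pose(internal_rotation = 37), pf, ff, ctr, "right")
  Tb <- pose_to_transform(joint_pose(internal_rotation = -37), pf, ff, ctr, "right")
  expect_equal(compose_transform(Ta, Tb)$rotation, diag(3), tolerance = 1e-9)

  # rotations pivot at the hip center and the correction adds afterward
  Tc <- pose_to_transform(joint_pose(flexion = 45, correction = c(1, 2, 3)),
                          pf, ff, ctr, "right")
  expect_equal(drop(apply_transform(Tc, ctr)), ctr + c(1, 2, 3),
               tolerance = 1e-9)
})

test_that("check_pose distinguishes free, resolved and impinged states", {
  mdl <- default_models()$cam
  cfg <- sim_config()                            # 3 mm cap
  free <- check_pose(mdl, joint_pose(), cfg)
  expect_equal(free$status, "free")
  expect_gt(free$min_distance, 1.5)              # near the 2 mm design clearance

  # just past the zero-translation cam endpoint: a capped translation resolves
  res <- check_pose(mdl, joint_pose(flexion = 90, internal_rotation = 22), cfg)
  expect_equal(res$status, "resolved")
  expect_gt(sqrt(sum(res$correction^2)), 0.2)
  expect_lte(sqrt(sum(res$correction^2)), 3)
  expect_gte(res$clearance, cfg$contact_tolerance)

  # far past it: more than 3 mm would be needed
  imp <- check_pose(mdl, joint_pose(flexion = 90, internal_rotation = 55), cfg)
  expect_equal(imp$status, "impinged")

  # with the cap at zero the resolved pose above is impinged
  imp0 <- check_pose(mdl, joint_pose(flexion = 90, internal_rotation = 22), cfg0())
  expect_equal(imp0$status, "impinged")
})

test_that("find_endpoint brackets the impingement angle at the resolution", {
  mdl <- default_models()$cam
  cfg <- cfg0()
  m <- standard_motions(cfg)[[6]]                # internal rotation at 90 flexion
  ep <- find_endpoint(mdl, m, cfg)
  expect_equal(ep$status, "impinged")
  at <- check_pose(mdl, hipsim:::pose_at_(m, ep$angle), cfg)
  beyond <- check_pose(mdl, hipsim:::pose_at_(m, ep$angle + cfg$angle_resolution),
                       cfg)
  expect_true(at$status %in% c("free", "resolved"))
  expect_equal(beyond$status, "impinged")
  expect_false(is.null(ep$contact))
  expect_gt(nrow(ep$contact$witness_pairs), 0)

  # determinism: re-running reproduces the angle bit for bit
  ep2 <- find_endpoint(mdl, m, cfg)
  expect_identical(ep$angle, ep2$angle)

  # no cup to hit: a sweep away from the cup reaches its bound
  m_free <- motion_definition("internal_rotation", bound = 45)
  ep_free <- find_endpoint(default_models()$native, m_free, cfg)
  expect_equal(ep_free$status, "bound_reached")
  expect_equal(ep_free$angle, 45)
})

test_that("the standard set reports six motions with the cam pattern", {
  cfg <- cfg0()
  sim_cam <- simulate_standard_set(default_models()$cam, cfg)
  sim_nat <- simulate_standard_set(default_models()$native, cfg)
  expect_equal(sim_cam$motion,
               c("max_flexion", "max_abduction", "max_ir_0", "max_ir_30",
                 "max_ir_60", "max_ir_90"))
  expect_true(tibble::is_tibble(sim_cam))
  # anterosuperior cam: internal rotation at 90 flexion loses more than abduction
  loss <- sim_nat$angle - sim_cam$angle
  names(loss) <- sim_nat$motion
  expect_gt(loss[["max_ir_90"]], loss[["max_abduction"]])
  expect_true(all(loss >= -1e-9))
  p <- autoplot(sim_cam)
  expect_s3_class(p, "ggplot")
})
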