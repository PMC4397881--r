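test_that("mesh I/O round-trips STL, PLY and OBJ and applies unit scaling", {
  cube <- unit_cube()
  expect_true(validate_mesh(cube)$watertight)
  expect_equal(mesh_volume(cube), 1)

  tmp <- withr::local_tempdir()
  for (ext in c("stl", "ply", "obj")) {
    path <- file.path(tmp, paste0("cube.", ext))
    write_mesh(cube, path)
    m <- load_mesh(path, quiet = TRUE)
    expect_equal(nrow(m$vertices), 8, info = ext)
    expect_equal(nrow(m$faces), 12, info = ext)
    expect_equal(mesh_volume(m), 1, tolerance = 1e-9, info = ext)
  }
  m10 <- load_mesh(file.path(tmp, "cube.stl"), units = 10, quiet = TRUE)
  expect_equal(mesh_volume(m10), 1000, tolerance = 1e-9)

  sph <- icosphere(25, 3)
  path <- file.path(tmp, "head.ply")
  write_mesh(sph, path)
  m <- load_mesh(path, quiet = TRUE)
  expect_lt(abs(mesh_volume(m) - 4 / 3 * pi * 25^3) / (4 / 3 * pi * 25^3), 0.02)

  expect_error(load_mesh(file.path(tmp, "missing.stl")), "not found")
  writeLines("not a mesh", file.path(tmp, "cube.xyz"))
  expect_error(load_mesh(file.path(tmp, "cube.xyz")), "unsupported")
})

test_that("binary STL is read and degenerate faces are dropped with a log", {
  cube <- unit_cube()
  V <- cube$vertices; F <- cube$faces
  tmp <- withr::local_tempfile(fileext = ".stl")
  con <- file(tmp, "wb")
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(F) + 1L), con, size = 4, endian = "little")
  tri_rec <- function(a, b, c) {
    writeBin(as.numeric(c(0, 0, 0, a, b, c)), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  for (i in seq_len(nrow(F)))
    tri_rec(V[F[i, 1], ], V[F[i, 2], ], V[F[i, 3], ])
  tri_rec(V[1, ], V[1, ], V[2, ])          # zero-area face
  close(con)
  expect_message(m <- load_mesh(tmp), "degenerate")
  expect_equal(nrow(m$faces), 12)
  expect_equal(m$n_dropped, 1L)
  expect_equal(abs(mesh_volume(m)), 1, tolerance = 1e-6)
})

test_that("rigid transforms obey group axioms and preserve mesh volume", {
  set.seed(42)
  for (i in 1:20) {
    A <- random_rigid(); B <- random_rigid()
    p <- matrix(stats::rnorm(30), ncol = 3)
    expect_equal(apply_transform(compose_transform(A, B), p),
                 apply_transform(A, apply_transform(B, p)), tolerance = 1e-9)
    expect_equal(apply_transform(compose_transform(invert_transform(A), A), p),
                 p, tolerance = 1e-9)
  }
  sph <- icosphere(10, 2, c(3, -2, 7))
  v0 <- mesh_volume(sph)
  for (i in 1:10) {
    Tm <- random_rigid()
    m2 <- transform_mesh(sph, Tm)
    expect_equal(mesh_volume(m2) / v0, 1, tolerance = 1e-6)
    back <- transform_mesh(m2, invert_transform(Tm))
    expect_lt(max(abs(back$vertices - sph$vertices)), 1e-9)
  }
  cube <- unit_cube()
  rot <- transform_mesh(cube, rigid_transform(rotation_about(c(0, 0, 1), 90)))
  expect_equal(apply(rot$vertices, 2, max) - apply(rot$vertices, 2, min),
               c(1, 1, 1), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(rigid_transform(diag(3) * 2), "orthonormal")
})

test_that("contact queries match closed-form sphere gaps and overlaps", {
  s0 <- icosphere(1, 3)
  q_gap <- query_contact(s0, icosphere(1, 3, c(3, 0, 0)))
  expect_false(q_gap$colliding)
  expect_equal(q_gap$min_distance, 1, tolerance = 0.02)

  q_overlap <- query_contact(s0, icosphere(1, 3, c(1.5, 0, 0)))
  expect_true(q_overlap$colliding)
  expect_equal(-q_overlap$min_distance, 0.5, tolerance = 0.03)
  expect_equal(q_overlap$min_distance, -q_overlap$penetration)

  q_self <- query_contact(s0, translate_mesh(s0, c(0, 0, 0)))
  expect_true(q_self$colliding)

  # containment without surface intersection still collides
  q_in <- query_contact(icosphere(3, 2), icosphere(1, 2))
  expect_true(q_in$colliding)

  # witness pairs appear whenever min_distance is within tolerance
  q_near <- query_contact(s0, icosphere(1, 3, c(2.05, 0, 0)), tolerance = 0.1)
  expect_gt(nrow(q_near$witness_pairs), 0)
  expect_true(all(q_near$witness_pairs$distance <= 0.1 + 1e-12))

  expect_error(query_contact(s0, s0, closed = FALSE), "closed")
  expect_error(query_contact(s0, s0, tolerance = -1), "tolerance")
})

test_that("collision boolean is symmetric and tree distance matches brute force", {
  set.seed(7)
  for (i in 1:40) {
    a <- icosphere(stats::runif(1, 0.5, 2), 1, stats::rnorm(3, sd = 2))
    b <- icosphere(stats::runif(1, 0.5, 2), 1, stats::rnorm(3, sd = 2))
    qa <- query_contact(a, b, want_pairs = FALSE)
    qb <- query_contact(b, a, want_pairs = FALSE)
    expect_equal(qa$colliding, qb$colliding)
    if (!qa$colliding) {
      brute <- hipsim:::.brute_min_dist_cpp(a$vertices, a$faces - 1L,
                                            b$vertices, b$faces - 1L)
      expect_equal(qa$min_distance, brute, tolerance = 1e-9)
    }
  }
})

test_that("triangle distances are consistent with dense surface sampling", {
  set.seed(11)
  bary <- function(n) {
    r <- matrix(stats::runif(2 * n), ncol = 2)
    flip <- rowSums(r) > 1
    r[flip, ] <- 1 - r[flip, ]
    cbind(1 - rowSums(r), r)
  }
  for (i in 1:20) {
    t1 <- matrix(stats::rnorm(9), 3, 3)
    t2 <- matrix(stats::rnorm(9), 3, 3) + 5    # separated
    d <- hipsim:::.contact_query_cpp(t1, rbind(c(0L, 1L, 2L)),
                                     t2, rbind(c(0L, 1L, 2L)),
                                     0, FALSE, FALSE)$min_distance
    p1 <- bary(2000) %*% t1
    p2 <- bary(2000) %*% t2
    sampled <- min(sqrt(pmax(outer(rowSums(p1^2), rowSums(p2^2), "+") -
                               2 * p1 %*% t(p2), 0)))
    expect_lte(d, sampled + 1e-9)   # surface sampling upper-bounds the distance
    expect_lt(sampled - d, 0.15)
  }
})

test_that("resolve_translation separates overlaps within the cap and reports unresolvable beyond it", {
  # spheres of radius 1 overlapping by 0.4 mm
  A <- icosphere(1, 3)
  B <- icosphere(1, 3, c(1.6, 0, 0))
  t <- resolve_translation(A, B, max_norm = 3)
  expect_false(is.null(t))
  expect_gte(sqrt(sum(t^2)), 0.4 + 0.1)
  expect_lte(sqrt(sum(t^2)), 3 + 1e-9)
  u <- t / sqrt(sum(t^2))
  expect_gt(u[1], 0.95)                     # along the center line
  q <- query_contact(A, translate_mesh(B, t), want_pairs = FALSE)
  expect_false(q$colliding)
  expect_gte(q$min_distance, 0.1)

  expect_null(resolve_translation(A, B, max_norm = 0.1))
  expect_equal(resolve_translation(A, icosphere(1, 3, c(5, 0, 0)), 3),
               c(0, 0, 0))

  # monotonicity: resolvable at a cap stays resolvable at larger caps
  B5 <- icosphere(10, 3, c(15, 0, 0))       # 5 mm structural overlap
  A10 <- icosphere(10, 3)
  expect_null(resolve_translation(A10, B5, 3))
  t6 <- resolve_translation(A10, B5, 6)
  expect_false(is.null(t6))
  expect_gte(sqrt(sum(t6^2)), 5)
})
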