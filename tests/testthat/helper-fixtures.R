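# Shared fixtures, built in code and cached for the session.

phantom_cache <- new.env(parent = emptyenv())

default_phantom <- function() {
  if (is.null(phantom_cache$ph))
    phantom_cache$ph <- generate_phantom(phantom_spec(n_az = 48))
  phantom_cache$ph
}

default_models <- function() {
  if (is.null(phantom_cache$models)) {
    ph <- default_phantom()
    phantom_cache$models <- list(cam = phantom_model(ph, "cam"),
                                 native = phantom_model(ph, "native"))
  }
  phantom_cache$models
}

# zero-translation config: the regime the analytic oracle models
cfg0 <- function(...) sim_config(max_translation = 0, ...)

unit_cube <- function() {
  V <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  F <- rbind(
    c(1, 3, 2), c(2, 3, 4),     # z = 0
    c(5, 6, 7), c(6, 8, 7),     # z = 1
    c(1, 2, 5), c(2, 6, 5),     # y = 0
    c(3, 7, 4), c(4, 7, 8),     # y = 1
    c(1, 5, 3), c(3, 5, 7),     # x = 0
    c(2, 4, 6), c(4, 8, 6))     # x = 1
  trimesh(V, F, name = "cube")
}

random_rotation <- function() {
  axis <- stats::rnorm(3)
  rotation_about(axis / sqrt(sum(axis^2)), stats::runif(1, -180, 180))
}

random_rigid <- function(scale = 50) {
  rigid_transform(random_rotation(), stats::rnorm(3, sd = scale))
}

# uniform-ish sample on a sphere
sphere_points <- function(n, radius = 1, center = c(0, 0, 0)) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  sweep(u * radius, 2, center, "+")
}

random_phantom_spec <- function(with_cam = TRUE, n_az = 48,
                                height_range = c(2.6, 4.5)) {
  side <- sample(c("right", "left"), 1)
  rh <- stats::runif(1, 22, 28)
  cl <- stats::runif(1, 1.5, 2.5)
  rn <- stats::runif(1, 10, 13)
  cam <- if (with_cam) {
    h <- stats::runif(1, height_range[1], height_range[2])
    a <- stats::runif(1, 4, 6)
    # keep the cam's super-clearance band on the head sphere, above the
    # head-neck junction ring (the analytic oracle's validity domain)
    thj <- asin(rn / rh) * 180 / pi
    gam <- if (h > cl) {
      Rb <- (a^2 + h^2) / (2 * h)
      asin(sqrt(Rb^2 - (Rb - h + cl)^2) / rh) * 180 / pi
    } else 0
    list(clock_hour = stats::runif(1, 11, 14) %% 12,
         cap_radius = a, height = h,
         polar_deg = max(stats::runif(1, 37, 43), thj + gam + 1.5))
  } else NULL
  phantom_spec(side = side, n_az = n_az,
               head_radius = rh, clearance = cl,
               cup_coverage = stats::runif(1, 60, 75),
               cup_pole_tilt = stats::runif(1, 34, 46),
               neck_tilt = stats::runif(1, 34, 46),
               neck_radius = rn, cam = cam)
}
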