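#' Contact query between two meshes
#'
#' Reports whether two meshes collide (surface intersection or containment),
#' the minimal surface-to-surface distance when separated, and a penetration
#' depth estimate when colliding (as a negative `min_distance`).  Witness
#' face pairs within `tolerance` are returned for contact-zone work.
#'
#' The penetration estimate is the maximum unsigned distance from penetrating
#' vertices of one mesh to the other mesh's surface — an estimate suited to
#' the shallow overlaps bony impingement produces, not an exact minimal
#' translation depth.
#'
#' @param mesh_a,mesh_b [trimesh()] objects.
#' @param tolerance contact tolerance in mm (default 0.1): the reporting band
#'   for witness pairs.
#' @param want_pairs collect witness face pairs (default `TRUE`).
#' @param closed declare the meshes closed (default `TRUE`).  Inside tests
#'   (containment, penetration depth) require closed meshes; passing
#'   `closed = FALSE` raises a validation error.
#' @return A list of class `contact_query`: `colliding` (true iff
#'   `min_distance <= 0`), `min_distance` (mm), `penetration` (mm, >= 0), and
#'   `witness_pairs`, a tibble with `face_a`, `face_b`, `distance` (1-based
#'   face indices).
#' @export
query_contact <- function(mesh_a, mesh_b, tolerance = 0.1,
                          want_pairs = TRUE, closed = TRUE) {
  stopifnot(inherits(mesh_a, "trimesh"), inherits(mesh_b, "trimesh"))
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  if (!isTRUE(closed))
    stop("inside tests require closed meshes; got closed = FALSE", call. = FALSE)
  res <- .contact_query_cpp(mesh_a$vertices, mesh_a$faces - 1L,
                            mesh_b$vertices, mesh_b$faces - 1L,
                            tolerance, want_pairs, TRUE)
  pairs <- if (want_pairs)
    tibble::tibble(face_a = res$pair_a + 1L, face_b = res$pair_b + 1L,
                   distance = res$pair_dist)
  else tibble::tibble(face_a = integer(), face_b = integer(), distance = numeric())
  structure(list(colliding = res$colliding,
                 min_distance = res$min_distance,
                 penetration = res$penetration,
                 witness_pairs = pairs),
            class = "contact_query")
}

#' @export
print.contact_query <- function(x, ...) {
  cat(sprintf("<contact_query: colliding=%s, min_distance=%.4f mm, %d witness pairs>\n",
              x$colliding, x$min_distance, nrow(x$witness_pairs)))
  invisible(x)
}

# fast path used by the ROM sweep: distance/collision only, no pairs
contact_distance_ <- function(mesh_a, mesh_b) {
  res <- .contact_query_cpp(mesh_a$vertices, mesh_a$faces - 1L,
                            mesh_b$vertices, mesh_b$faces - 1L,
                            0, FALSE, TRUE)
  res$min_distance
}

#' Penetration-resolving translation under a norm cap
#'
#' Searches for a translation `t` of the moving mesh, with `|t| <= max_norm`,
#' after which the meshes are collision-free with clearance at least
#' `tolerance`.  Among feasible translations the one maximizing the minimal
#' surface clearance is selected (the equidistant criterion: keep the
#' articular surfaces as uniformly separated as the cap allows).  The search
#' is a deterministic multi-start local optimization: a penetration-direction
#' heuristic plus the six axis directions seed a Nelder-Mead polish of the
#' minimal clearance over the capped ball.
#'
#' @param fixed,moving [trimesh()] objects; `moving` is translated.
#' @param max_norm translation cap in mm (default 3).
#' @param tolerance minimum clearance a resolved state must reach (mm,
#'   default 0.1).
#' @return The selected translation (length-3 numeric, possibly zero when
#'   the input is already clear), or `NULL` when no capped translation
#'   resolves the contact ("unresolvable").
#' @export
resolve_translation <- function(fixed, moving, max_norm = 3, tolerance = 0.1) {
  stopifnot(max_norm > 0)
  f <- function(t) contact_distance_(fixed, translate_mesh(moving, t))
  d0 <- f(c(0, 0, 0))
  if (d0 >= tolerance) return(c(0, 0, 0))

  dirs <- rbind(diag(3), -diag(3))
  pen_dir <- penetration_direction_(fixed, moving)
  if (!is.null(pen_dir)) dirs <- rbind(pen_dir, dirs)

  best_t <- NULL
  best_f <- -Inf
  for (i in seq_len(nrow(dirs))) {
    u <- dirs[i, ]
    for (s in c(0.25, 0.5, 0.75, 1) * max_norm) {
      v <- f(s * u)
      if (v > best_f) { best_f <- v; best_t <- s * u }
    }
  }
  obj <- function(t) {
    n <- sqrt(sum(t^2))
    pen <- if (n > max_norm) 1e3 * (n - max_norm)^2 else 0
    -f(t) + pen
  }
  opt <- stats::optim(best_t, obj, method = "Nelder-Mead",
                      control = list(maxit = 80, reltol = 1e-4))
  t_opt <- opt$par
  n <- sqrt(sum(t_opt^2))
  if (n > max_norm) t_opt <- t_opt * (max_norm / n)
  cand <- list(t_opt, best_t)
  vals <- vapply(cand, f, numeric(1))
  k <- which.max(vals)
  if (vals[k] >= tolerance) cand[[k]] else NULL
}

# outward direction at the deepest penetrating vertex, by numeric gradient of
# the signed distance to the fixed surface
penetration_direction_ <- function(fixed, moving, eps = 1e-3) {
  Vf <- fixed$vertices
  Ff <- fixed$faces - 1L
  d <- .points_mesh_dist_cpp(moving$vertices, Vf, Ff, TRUE)
  i <- which.min(d)
  if (d[i] > 0) return(NULL)
  p <- moving$vertices[i, ]
  probe <- rbind(p + c(eps, 0, 0), p - c(eps, 0, 0),
                 p + c(0, eps, 0), p - c(0, eps, 0),
                 p + c(0, 0, eps), p - c(0, 0, eps))
  dp <- .points_mesh_dist_cpp(probe, Vf, Ff, TRUE)
  g <- c(dp[1] - dp[2], dp[3] - dp[4], dp[5] - dp[6]) / (2 * eps)
  n <- sqrt(sum(g^2))
  if (n < 1e-12) return(NULL)
  g / n  # gradient of signed distance points out of the fixed solid
}
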