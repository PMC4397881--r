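#' Triangle mesh in millimetres
#'
#' Construct a triangle mesh from a vertex matrix and a face index matrix.
#' All geometry in the package operates on this representation; coordinates
#' are in millimetres throughout.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param name label carried through reports (e.g. `"femur"`, `"pelvis"`).
#' @param drop_degenerate drop zero-area faces (default `TRUE`).
#' @return An object of class `trimesh` with elements `vertices`, `faces`,
#'   `name`, and `n_dropped` (degenerate faces removed at construction).
#' @export
trimesh <- function(vertices, faces, name = "mesh", drop_degenerate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must have 3 columns", call. = FALSE)
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates", call. = FALSE)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face index out of range", call. = FALSE)
  n_dropped <- 0L
  if (drop_degenerate && nrow(faces) > 0) {
    a2 <- face_areas_(vertices, faces)
    keep <- a2 > 1e-12
    n_dropped <- sum(!keep)
    faces <- faces[keep, , drop = FALSE]
  }
  if (nrow(faces) == 0L) stop("mesh has no (non-degenerate) faces", call. = FALSE)
  structure(
    list(vertices = vertices, faces = faces, name = name, n_dropped = n_dropped),
    class = "trimesh")
}

face_areas_ <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("<trimesh '%s': %d vertices, %d faces>\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Mesh surface areas and enclosed volume
#'
#' `mesh_volume()` returns the signed volume (mm^3) by summing signed
#' tetrahedron volumes against the origin; positive for a closed mesh with
#' outward winding.  `mesh_area()` returns the total surface area (mm^2).
#'
#' @param mesh a [trimesh()].
#' @return A scalar.
#' @export
mesh_volume <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  cx <- b[, 2] * c[, 3] - b[, 3] * c[, 2]
  cy <- b[, 3] * c[, 1] - b[, 1] * c[, 3]
  cz <- b[, 1] * c[, 2] - b[, 2] * c[, 1]
  sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6
}

#' @rdname mesh_volume
#' @export
mesh_area <- function(mesh) sum(face_areas_(mesh$vertices, mesh$faces))

#' Validate mesh topology
#'
#' Checks finiteness, index validity and watertightness (every edge shared by
#' exactly two faces with opposite orientation) and reports the enclosed
#' volume for closed meshes.
#'
#' @param mesh a [trimesh()].
#' @return A list with `watertight`, `volume` (NA when open), `n_vertices`,
#'   `n_faces`, `n_boundary_edges`.
#' @export
validate_mesh <- function(mesh) {
  F <- mesh$faces
  he <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key_fwd <- paste(he[, 1], he[, 2])
  key_rev <- paste(he[, 2], he[, 1])
  tab <- table(key_fwd)
  # watertight & consistently wound: every directed edge unique and its
  # reverse present exactly once
  watertight <- all(tab == 1L) && all(key_rev %in% key_fwd)
  n_boundary <- sum(!(key_rev %in% key_fwd))
  vol <- if (watertight) mesh_volume(mesh) else NA_real_
  list(watertight = watertight, volume = vol,
       n_vertices = nrow(mesh$vertices), n_faces = nrow(F),
       n_boundary_edges = n_boundary)
}

# ---------------------------------------------------------------- transforms

#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  print(round(x$rotation, 6))
  cat("t =", paste(round(x$translation, 6), collapse = ", "), "mm\n")
  invisible(x)
}

#' Compose, invert and apply rigid transforms
#'
#' `compose_transform(A, B)` returns the transform applying `B` first, then
#' `A`.  `invert_transform(A)` is the group inverse.  `apply_transform`
#' maps an n x 3 point matrix.
#'
#' @param A,B [rigid_transform()] objects.
#' @param points n x 3 numeric matrix.
#' @export
compose_transform <- function(A, B) {
  rigid_transform(A$rotation %*% B$rotation,
                  as.numeric(A$rotation %*% B$translation) + A$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(A) {
  Rt <- t(A$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% A$translation))
}

#' @rdname compose_transform
#' @export
apply_transform <- function(A, points) {
  points <- rbind(points)  # tolerate a bare length-3 vector
  sweep(points %*% t(A$rotation), 2, A$translation, "+")
}

#' Rotation about an axis
#'
#' @param axis length-3 axis vector (normalized internally).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Apply a rigid transform to a mesh
#'
#' Topology unchanged; volume preserved (rigid motion).
#'
#' @param mesh a [trimesh()].
#' @param transform a [rigid_transform()].
#' @export
transform_mesh <- function(mesh, transform) {
  out <- mesh
  out$vertices <- apply_transform(transform, mesh$vertices)
  out
}

#' Translate a mesh
#' @param mesh a [trimesh()].
#' @param t length-3 translation (mm).
#' @export
translate_mesh <- function(mesh, t) {
  out <- mesh
  out$vertices <- sweep(mesh$vertices, 2, as.numeric(t), "+")
  out
}

# ---------------------------------------------------------------- file I/O

#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Format is inferred from the file extension.  STL may be binary or ASCII;
#' PLY must be ASCII; OBJ supports triangular `f` records.  Degenerate
#' (zero-area) faces are dropped and counted in the returned object's
#' `n_dropped` field; a structured message reports the load.
#'
#' @param path file path.
#' @param units scale factor applied to coordinates to obtain millimetres
#'   (e.g. `1000` for a mesh stored in metres).
#' @param name mesh label; defaults to the file name without extension.
#' @param quiet suppress the load log message.
#' @return A [trimesh()] in millimetres.
#' @export
load_mesh <- function(path, units = 1, name = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    stl = read_stl_(path),
    ply = read_ply_(path),
    obj = read_obj_(path),
    stop("unsupported mesh format: .", ext, call. = FALSE))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  m <- trimesh(raw$vertices * units, raw$faces, name = name)
  if (!quiet) {
    v <- validate_mesh(m)
    message(sprintf(
      "loaded '%s': %d vertices, %d faces, %d degenerate dropped, watertight=%s",
      name, v$n_vertices, v$n_faces, m$n_dropped, v$watertight))
  }
  m
}

read_stl_ <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  fsize <- file.size(path)
  if (length(ntri) == 1 && !is.na(ntri) && fsize == 84 + 50 * as.numeric(ntri)) {
    v <- matrix(0, nrow = 3 * ntri, ncol = 3)
    for (i in seq_len(ntri)) {
      rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
      readBin(con, "raw", 2)
      v[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    close(con); on.exit()
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
    v <- do.call(rbind, nums)
    if (is.null(v) || nrow(v) %% 3 != 0) stop("malformed ASCII STL", call. = FALSE)
  }
  weld_vertices_(v)
}

weld_vertices_ <- function(v) {
  key <- apply(round(v, 9), 1, paste, collapse = ",")
  idx <- match(key, unique(key))
  verts <- v[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

read_ply_ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^ply", lines[1])) stop("not a PLY file", call. = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) stop("PLY header not terminated", call. = FALSE)
  hdr <- lines[seq_len(endh)]
  if (any(grepl("format\\s+binary", hdr))) stop("binary PLY not supported", call. = FALSE)
  nv <- as.integer(sub(".*element vertex\\s+(\\d+).*", "\\1",
                       grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+(\\d+).*", "\\1",
                       grep("element face", hdr, value = TRUE)[1]))
  body <- lines[(endh + 1):length(lines)]
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  verts <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  faces <- t(vapply(fparts, function(p) {
    if (as.integer(p[1]) != 3L) stop("non-triangular PLY face", call. = FALSE)
    as.integer(p[2:4]) + 1L
  }, integer(3)))
  list(vertices = verts, faces = faces)
}

read_obj_ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  verts <- t(vapply(strsplit(trimws(vl), "\\s+"),
                    function(p) as.numeric(p[2:4]), numeric(3)))
  faces <- t(vapply(strsplit(trimws(fl), "\\s+"), function(p) {
    idx <- as.integer(sub("/.*", "", p[2:4]))
    idx
  }, integer(3)))
  list(vertices = verts, faces = faces)
}

#' Write a triangle mesh to STL (ASCII), PLY (ASCII) or OBJ
#'
#' @param mesh a [trimesh()].
#' @param path output path; format inferred from extension.
#' @param scalars optional per-vertex numeric attribute written as a
#'   `quality` property (PLY only), used for resection depth maps.
#' @export
write_mesh <- function(mesh, path, scalars = NULL) {
  ext <- tolower(tools::file_ext(path))
  V <- mesh$vertices; F <- mesh$faces
  if (ext == "stl") {
    e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    n <- n / pmax(sqrt(rowSums(n^2)), 1e-30)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$name), con)
    for (i in seq_len(nrow(F))) {
      writeLines(c(
        sprintf("facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
        "  outer loop",
        sprintf("    vertex %.9g %.9g %.9g",
                V[F[i, 1:3], 1], V[F[i, 1:3], 2], V[F[i, 1:3], 3]),
        "  endloop", "endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", mesh$name), con)
  } else if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(V)),
             "property float x", "property float y", "property float z")
    if (!is.null(scalars)) hdr <- c(hdr, "property float quality")
    hdr <- c(hdr, sprintf("element face %d", nrow(F)),
             "property list uchar int vertex_indices", "end_header")
    vb <- if (is.null(scalars))
      sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3])
    else
      sprintf("%.9g %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3], scalars)
    fb <- sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)
    writeLines(c(hdr, vb, fb), path)
  } else if (ext == "obj") {
    writeLines(c(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]),
                 sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3])), path)
  } else stop("unsupported mesh format: .", ext, call. = FALSE)
  invisible(path)
}
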