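#' Synthetic CT volume specification
#'
#' Voxel spacing defaults to the acquisition protocol the phantom emulates:
#' 0.265 mm in-plane pixels and 1.0 mm slices (slices stacked along the
#' superior axis Y).  Intensities are relative material densities, not
#' calibrated Hounsfield units: air 0, soft tissue 1.0, nylon 1.15 and bone
#' 1.9 (nylon sits between soft tissue and bone, so a cam made of nylon can
#' be included or excluded by choice of threshold).
#'
#' @param in_plane in-plane pixel size, mm.
#' @param slice slice thickness, mm.
#' @param intensities named vector with `air`, `soft`, `nylon`, `bone`.
#' @param margin air/soft margin around the mesh bounding box, mm.
#' @param supersample integer anti-aliasing factor; `2` voxelizes on a
#'   refined grid and block-averages, yielding partial-volume fractions at
#'   material boundaries.
#' @export
ct_spec <- function(in_plane = 0.265, slice = 1.0,
                    intensities = c(air = 0, soft = 1.0, nylon = 1.15,
                                    bone = 1.9),
                    margin = 4, supersample = 1) {
  stopifnot(in_plane > 0, slice > 0, supersample %in% c(1L, 2L),
            all(c("air", "soft", "nylon", "bone") %in% names(intensities)),
            intensities["bone"] > intensities["nylon"],
            intensities["nylon"] > intensities["soft"])
  structure(list(in_plane = in_plane, slice = slice,
                 intensities = intensities, margin = margin,
                 supersample = as.integer(supersample)),
            class = "ct_spec")
}

#' Voxelize labeled meshes into a synthetic CT volume
#'
#' Rasterizes closed meshes on the CT grid (slice axis Y): each voxel takes
#' the material intensity of the innermost enclosing mesh, with priority
#' bone > nylon > soft tissue > air.  The soft-tissue envelope, when
#' requested, fills the whole volume interior so bone is embedded in tissue
#' as in an acquisition.
#'
#' @param bone list of [trimesh()] (e.g. femur and pelvis).
#' @param nylon list of meshes enclosing nylon material (a cam femur can be
#'   paired with its native femur via `nylon_minus` so only the bump
#'   voxelizes as nylon).
#' @param nylon_minus optional list of meshes subtracted from the nylon
#'   region (voxelwise).
#' @param soft_envelope fill non-bone voxels with soft tissue (default TRUE).
#' @param ct a [ct_spec()].
#' @param extent optional 2x3 matrix (min/max corners, mm) overriding the
#'   automatic bounding box.
#' @return Object of class `ct_volume`: `data` (3D array, x/y/z), `spacing`,
#'   `origin` (center of voxel \[1,1,1\]).
#' @export
voxelize_ct <- function(bone = list(), nylon = list(), nylon_minus = list(),
                        soft_envelope = TRUE, ct = ct_spec(), extent = NULL) {
  for (m in c(bone, nylon, nylon_minus)) {
    v <- validate_mesh(m)
    if (!v$watertight)
      stop("voxelization requires closed meshes; '", m$name, "' is open",
           call. = FALSE)
  }
  spacing <- c(ct$in_plane, ct$slice, ct$in_plane)
  if (is.null(extent)) {
    all_m <- c(bone, nylon, nylon_minus)
    if (length(all_m) == 0) {
      extent <- rbind(c(0, 0, 0), c(10, 10, 10))
    } else {
      vv <- do.call(rbind, lapply(all_m, function(m) m$vertices))
      extent <- rbind(apply(vv, 2, min) - ct$margin,
                      apply(vv, 2, max) + ct$margin)
    }
  }
  dims <- pmax(2L, as.integer(ceiling((extent[2, ] - extent[1, ]) / spacing)))
  origin <- extent[1, ] + spacing / 2
  k <- ct$supersample
  sdim <- dims * k
  ssp <- spacing / k
  sorg <- extent[1, ] + ssp / 2
  rast <- function(meshes) {
    acc <- NULL
    for (m in meshes) {
      msk <- .voxelize_mask_cpp(m$vertices, m$faces - 1L, sorg, ssp, sdim)
      acc <- if (is.null(acc)) msk else (acc | msk)
    }
    if (is.null(acc)) rep(FALSE, prod(sdim)) else acc
  }
  frac <- function(mask) {
    a <- array(as.numeric(mask), dim = sdim)
    if (k == 1) return(a)
    # 2x2x2 block mean
    (a[seq(1, sdim[1], 2), seq(1, sdim[2], 2), seq(1, sdim[3], 2)] +
     a[seq(2, sdim[1], 2), seq(1, sdim[2], 2), seq(1, sdim[3], 2)] +
     a[seq(1, sdim[1], 2), seq(2, sdim[2], 2), seq(1, sdim[3], 2)] +
     a[seq(2, sdim[1], 2), seq(2, sdim[2], 2), seq(1, sdim[3], 2)] +
     a[seq(1, sdim[1], 2), seq(1, sdim[2], 2), seq(2, sdim[3], 2)] +
     a[seq(2, sdim[1], 2), seq(1, sdim[2], 2), seq(2, sdim[3], 2)] +
     a[seq(1, sdim[1], 2), seq(2, sdim[2], 2), seq(2, sdim[3], 2)] +
     a[seq(2, sdim[1], 2), seq(2, sdim[2], 2), seq(2, sdim[3], 2)]) / 8
  }
  ints <- ct$intensities
  vol <- array(if (soft_envelope) ints[["soft"]] else ints[["air"]], dim = dims)
  if (length(nylon) > 0) {
    fn <- frac(rast(nylon))
    if (length(nylon_minus) > 0) fn <- pmax(fn - frac(rast(nylon_minus)), 0)
    vol <- vol + fn * (ints[["nylon"]] - vol)
  }
  if (length(bone) > 0) {
    fb <- frac(rast(bone))
    vol <- vol + fb * (ints[["bone"]] - vol)
  }
  structure(list(data = vol, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume: %s voxels, spacing %.3f x %.3f x %.3f mm>\n",
              paste(dim(x$data), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Read/write a CT volume as NIfTI
#'
#' Spacing and origin are carried in the NIfTI header (pixdim and a
#' translation-only sform).
#'
#' @param vol a `ct_volume`.
#' @param path output `.nii` or `.nii.gz` path.
#' @export
write_ct_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  mat <- diag(c(vol$spacing, 1))
  mat[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(mat, code = 2L))
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_ct_nifti
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  xf <- RNifti::xform(img)
  structure(list(data = array(as.numeric(img), dim = dim(img)),
                 spacing = as.numeric(sp),
                 origin = as.numeric(xf[1:3, 4])),
            class = "ct_volume")
}

block_mean_ <- function(a, f) {
  d <- dim(a)
  dn <- floor(d / f)
  a <- a[seq_len(dn[1] * f[1]), seq_len(dn[2] * f[2]), seq_len(dn[3] * f[3]),
         drop = FALSE]
  out <- array(0, dn)
  for (i in seq_len(f[1])) for (j in seq_len(f[2])) for (k in seq_len(f[3]))
    out <- out + a[seq(i, by = f[1], length.out = dn[1]),
                   seq(j, by = f[2], length.out = dn[2]),
                   seq(k, by = f[3], length.out = dn[3])]
  out / prod(f)
}

#' Segment a CT volume into bone surface meshes
#'
#' Threshold the volume at `iso`, keep the largest connected components,
#' and extract their iso-surfaces by marching tetrahedra (edge-interpolated,
#' watertight by construction).  A threshold between the nylon and bone
#' intensities excludes an artificial nylon cam; a threshold between soft
#' tissue and nylon includes it, reproducing paired with/without-deformity
#' models from one acquisition.
#'
#' @param vol a `ct_volume`.
#' @param iso iso-level (between the intensities to separate).
#' @param max_components number of components to keep (largest first).
#' @param target_spacing optional reconstruction spacing, mm (scalar or
#'   per-axis length 3); the thresholded mask is block-averaged toward it
#'   and surfaced at 0.5 occupancy, trading boundary resolution for
#'   tractable mesh sizes.
#' @param min_voxels discard components smaller than this.
#' @param decimate_to optional vertex-clustering cell size, mm, applied to
#'   each surface after extraction (see [decimate_mesh()]).
#' @return List of [trimesh()] objects, largest volume first.
#' @export
segment_volume <- function(vol, iso = 1.5, max_components = 2,
                           target_spacing = NULL, min_voxels = 50,
                           decimate_to = NULL) {
  data <- vol$data
  spacing <- vol$spacing
  origin <- vol$origin
  if (!is.null(target_spacing)) {
    f <- pmax(1L, as.integer(round(rep(target_spacing, length.out = 3) / spacing)))
    if (any(f > 1)) {
      # threshold at native resolution, then downsample the binary mask to
      # an occupancy fraction surfaced at 0.5: reconstruction at a coarser
      # grid without biasing the boundary toward either material
      data <- block_mean_(array(as.numeric(vol$data > iso), dim(vol$data)), f)
      iso <- 0.5
      origin <- origin + (f - 1) * spacing / 2
      spacing <- spacing * f
    }
  }
  # pad one air voxel so border components close
  d <- dim(data)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- data
  origin <- origin - spacing
  d <- dim(padded)
  mask <- padded > iso
  if (!any(mask)) stop("empty segmentation at iso = ", iso, call. = FALSE)
  lab <- .label_components_cpp(as.logical(mask), d)
  sizes <- tabulate(lab)
  keep <- order(sizes, decreasing = TRUE)
  keep <- keep[sizes[keep] >= min_voxels]
  keep <- keep[seq_len(min(length(keep), max_components))]
  if (length(keep) == 0) stop("no component above min_voxels", call. = FALSE)
  lab_arr <- array(lab, d)
  out <- lapply(seq_along(keep), function(i) {
    vals <- padded
    vals[lab_arr != keep[i] & mask] <- 0   # suppress other components
    mc <- .marching_tet_cpp(as.numeric(vals), d, iso, origin, spacing)
    w <- weld_mesh_(mc$vertices, mc$faces + 1L)
    m <- trimesh(w$vertices, w$faces, name = sprintf("component_%d", i))
    if (!is.null(decimate_to)) m <- decimate_mesh(m, decimate_to)
    if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
    m
  })
  vols <- vapply(out, mesh_volume, numeric(1))
  out[order(vols, decreasing = TRUE)]
}

# merge coincident vertices (marching tetrahedra emits them where the iso
# surface passes exactly through grid corners) and drop collapsed faces
weld_mesh_ <- function(V, F, digits = 6) {
  key <- paste(round(V[, 1], digits), round(V[, 2], digits),
               round(V[, 3], digits))
  first <- match(key, key)
  remap <- match(first, sort(unique(first)))
  Vw <- V[sort(unique(first)), , drop = FALSE]
  Fw <- matrix(remap[F], ncol = 3)
  ok <- Fw[, 1] != Fw[, 2] & Fw[, 2] != Fw[, 3] & Fw[, 1] != Fw[, 3]
  list(vertices = Vw, faces = Fw[ok, , drop = FALSE])
}

#' Decimate a mesh by vertex clustering
#'
#' Collapses all vertices within each cell of a uniform grid of size `cell`
#' to their centroid and drops collapsed faces.  Crude but topology-safe
#' for closed surfaces (edges stay paired), and well suited to reducing
#' dense iso-surface meshes before collision sweeps.
#'
#' @param mesh a [trimesh()].
#' @param cell clustering cell size, mm.
#' @export
decimate_mesh <- function(mesh, cell) {
  V <- mesh$vertices
  key <- paste(floor(V[, 1] / cell), floor(V[, 2] / cell),
               floor(V[, 3] / cell))
  cl <- match(key, unique(key))
  Vc <- rowsum(V, cl) / as.numeric(table(cl)[as.character(sort(unique(cl)))])
  Fc <- matrix(cl[mesh$faces], ncol = 3)
  ok <- Fc[, 1] != Fc[, 2] & Fc[, 2] != Fc[, 3] & Fc[, 1] != Fc[, 3]
  trimesh(Vc, Fc[ok, , drop = FALSE], name = mesh$name)
}
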