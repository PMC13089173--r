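#' Voxel volumes and structure masks
#'
#' A `voxel_volume` is a 3D scalar grid (Hounsfield units or relative stopping
#' power) with isotropic or anisotropic voxel spacing and a physical origin.
#' The patient frame is fixed throughout the package: x = patient-left,
#' y = patient-posterior, z = patient-superior, with the centre of voxel
#' `(1,1,1)` at `origin` and voxel centres at `origin + (index - 1) * spacing`
#' (all physical quantities in mm).
#'
#' @param data numeric 3D array.
#' @param spacing_mm positive numeric length-3 voxel size in mm.
#' @param origin_mm numeric length-3 physical position (mm) of the first
#'   voxel's centre.
#' @param units scalar string, e.g. `"HU"` or `"RSP"`.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0),
                         units = "HU") {
  data <- as_array3d(data)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  stopifnot(length(spacing_mm) == 3, length(origin_mm) == 3)
  if (!all(is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing must be strictly positive and finite", call. = FALSE)
  if (!all(is.finite(origin_mm)))
    stop("origin must be finite", call. = FALSE)
  if (anyNA(data) || !all(is.finite(data)))
    stop("volume data must be finite", call. = FALSE)
  structure(
    list(data = data, spacing = spacing_mm, origin = origin_mm, units = units),
    class = "voxel_volume"
  )
}

as_array3d <- function(data) {
  if (is.null(dim(data)) || length(dim(data)) != 3)
    stop("data must be a 3D array", call. = FALSE)
  storage.mode(data) <- "double"
  data
}

#' @param mask logical/0-1 3D array on the volume grid.
#' @param role structure role: one of `"GTV"`, `"CTV"`, `"ITV"`, `"lungs"`,
#'   `"heart"`, `"spinal_cord"`, `"body"`.
#' @rdname voxel_volume
#' @export
structure_mask <- function(mask, spacing_mm = c(1, 1, 1),
                           origin_mm = c(0, 0, 0), role = "GTV") {
  if (is.null(dim(mask)) || length(dim(mask)) != 3)
    stop("mask must be a 3D array", call. = FALSE)
  m <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(m)) stop("mask must be 0/1 with no NA", call. = FALSE)
  role <- match.arg(role, c("GTV", "CTV", "ITV", "lungs", "heart",
                            "spinal_cord", "body"))
  if (role %in% c("GTV", "CTV", "ITV") && !any(m))
    stop("target mask (", role, ") is empty", call. = FALSE)
  out <- voxel_volume(array(as.double(m), dim = dim(m)), spacing_mm,
                      origin_mm, units = "mask")
  out$data <- m
  out$role <- role
  class(out) <- c("structure_mask", "voxel_volume")
  out
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<%s> %s  dim %s  spacing %s mm  origin (%s) mm\n",
              class(x)[1],
              if (!is.null(x$role)) x$role else x$units,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = "x"),
              paste(format(x$origin, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

check_same_grid <- function(vols, what = "volumes") {
  ref <- vols[[1]]
  for (v in vols[-1]) {
    if (!same_grid(ref, v))
      stop(what, " do not share shape, spacing and origin", call. = FALSE)
  }
  invisible(TRUE)
}

#' Physical coordinates of voxel centres
#'
#' @param vol a `voxel_volume` or `structure_mask`.
#' @param which logical array selecting voxels (default: all for volumes, the
#'   set voxels for masks).
#' @return numeric matrix, one row per voxel, columns x/y/z in mm.
#' @export
voxel_centers <- function(vol, which = NULL) {
  dm <- dim(vol$data)
  if (is.null(which)) {
    which <- if (inherits(vol, "structure_mask")) vol$data else
      array(TRUE, dm)
  }
  ijk <- which(which, arr.ind = TRUE)  # 1-based
  sweep(sweep(ijk - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Read and write volumes as NIfTI
#'
#' Volumes are stored with the grid axes mapped directly onto the package's
#' patient frame (x = left, y = posterior, z = superior); the NIfTI affine is
#' the positive-diagonal spacing matrix plus the origin translation. Oblique
#' or axis-flipped files are rejected rather than resampled, so no silent
#' interpolation can occur.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume()` returns a `voxel_volume`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3)
    stop("expected a 3D volume: ", path, call. = FALSE)
  aff <- RNifti::xform(img)
  lin <- aff[1:3, 1:3]
  if (any(abs(lin[!diag(3)]) > 1e-4 * max(abs(lin))))
    stop("non-axis-aligned (oblique) orientation is unsupported: ", path,
         call. = FALSE)
  if (any(diag(lin) <= 0))
    stop("axis-flipped orientation is unsupported: ", path, call. = FALSE)
  arr <- array(as.numeric(img), dim = dim(img))
  voxel_volume(arr, spacing_mm = diag(lin), origin_mm = aff[1:3, 4])
}

#' @param vol a `voxel_volume` (or `structure_mask`, written as 0/1).
#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  dat <- if (is.logical(vol$data))
    array(as.double(vol$data), dim(vol$data)) else vol$data
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- vol$spacing
  aff[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @param path file path of a NIfTI 0/1 labelmap.
#' @param role structure role, see [structure_mask()].
#' @rdname read_volume
#' @export
read_mask <- function(path, role = "GTV") {
  v <- read_volume(path)
  structure_mask(v$data != 0, v$spacing, v$origin, role = role)
}

#' Average intensity projection
#'
#' Voxelwise arithmetic mean over the breathing-phase volumes; the AIP-CT is
#' the static reference against which per-phase WEPL is compared.
#'
#' @param phases list of `voxel_volume`s on identical grids.
#' @return a `voxel_volume` with the same grid.
#' @export
average_intensity_projection <- function(phases) {
  stopifnot(length(phases) >= 1)
  check_same_grid(phases, "phase volumes")
  acc <- phases[[1]]$data
  if (length(phases) > 1)
    for (p in phases[-1]) acc <- acc + p$data
  voxel_volume(acc / length(phases), phases[[1]]$spacing, phases[[1]]$origin,
               units = phases[[1]]$units)
}
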