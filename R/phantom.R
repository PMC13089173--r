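#' Synthetic 4D thorax phantom specification
#'
#' Defines a digital thorax — elliptical body, two low-density lungs, heart,
#' spinal cord and a spherical tumour — sampled over one breathing cycle as
#' `n_phases` co-registered HU volumes. The tumour translates rigidly along
#' `motion_axis` with sinusoidal displacement of peak-to-peak amplitude
#' `motion_amplitude_mm`; all other structures are static. This isolates the
#' radiological-path effect that the delta-WEPL metric measures.
#'
#' Geometry arguments are lists: ellipsoids take `center` (mm), `semi_axes`
#' (mm) and `hu`; the cord is a z-axis cylinder with `center` (x, y in mm),
#' `radius` and `hu`; the tumour a sphere with `center`, `radius` and `hu`.
#' Default HU values are representative thorax tissues spanning the
#' calibration curve: air -1000, lungs -750, body/cord +40, heart/tumour +30.
#'
#' @param grid_shape integer length-3 voxel counts (default 96^3).
#' @param spacing_mm voxel size in mm (default 2 mm isotropic).
#' @param body,heart,tumour,cord geometry lists (see Details); `lungs` is a
#'   list of two ellipsoid lists plus `hu`.
#' @param lungs list with `left`, `right` ellipsoids and `hu`.
#' @param motion_amplitude_mm peak-to-peak tumour displacement (default 10).
#' @param motion_axis unit direction of motion (default superior-inferior).
#' @param n_phases number of breathing phases (default 10).
#' @param noise_sd_hu additive Gaussian HU noise SD (default 0:
#'   deterministic).
#' @param seed integer RNG seed for the noise.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         spacing_mm = c(2, 2, 2),
                         body = list(center = c(95, 95, 95),
                                     semi_axes = c(80, 70, 95), hu = 40),
                         lungs = list(
                           left = list(center = c(137, 92, 95),
                                       semi_axes = c(30, 48, 72)),
                           right = list(center = c(53, 92, 95),
                                        semi_axes = c(30, 48, 72)),
                           hu = -750),
                         heart = list(center = c(105, 62, 80),
                                      semi_axes = c(30, 26, 30), hu = 30),
                         cord = list(center = c(95, 150), radius = 8, hu = 40),
                         tumour = list(center = c(130, 110, 95), radius = 12,
                                       hu = 30),
                         motion_amplitude_mm = 10,
                         motion_axis = c(0, 0, 1),
                         n_phases = 10,
                         noise_sd_hu = 0,
                         seed = 1L,
                         air_hu = -1000) {
  spec <- list(grid_shape = as.integer(grid_shape),
               spacing_mm = as.numeric(spacing_mm),
               body = body, lungs = lungs, heart = heart, cord = cord,
               tumour = tumour,
               motion_amplitude_mm = as.numeric(motion_amplitude_mm),
               motion_axis = as.numeric(motion_axis),
               n_phases = as.integer(n_phases),
               noise_sd_hu = as.numeric(noise_sd_hu),
               seed = as.integer(seed), air_hu = air_hu)
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$grid_shape) == 3, all(spec$grid_shape >= 8),
            length(spec$spacing_mm) == 3)
  if (any(spec$spacing_mm <= 0)) stop("spacing must be positive", call. = FALSE)
  if (spec$n_phases < 1) stop("n_phases must be >= 1", call. = FALSE)
  if (spec$motion_amplitude_mm < 0)
    stop("motion amplitude must be >= 0", call. = FALSE)
  if (spec$noise_sd_hu < 0) stop("noise SD must be >= 0", call. = FALSE)
  hus <- c(spec$air_hu, spec$body$hu, spec$lungs$hu, spec$heart$hu,
           spec$cord$hu, spec$tumour$hu)
  if (any(hus < -1024 | hus > 3071))
    stop("HU values must lie in [-1024, 3071]", call. = FALSE)
  n <- sqrt(sum(spec$motion_axis^2))
  if (spec$motion_amplitude_mm > 0 && n == 0)
    stop("motion_axis must be nonzero when amplitude > 0", call. = FALSE)
  if (n > 0) spec$motion_axis <- spec$motion_axis / n
  class(spec) <- "phantom_spec"
  spec
}

#' @param path JSON file with fields matching the [phantom_spec()] arguments.
#' @rdname phantom_spec
#' @export
read_phantom_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw), names(formals(phantom_spec)))]
  do.call(phantom_spec, args)
}

# sinusoidal displacement: 0 at phase 0, full amplitude at mid-cycle
phase_displacement <- function(spec, k) {
  spec$motion_axis * (spec$motion_amplitude_mm / 2) *
    (1 - cos(2 * pi * k / spec$n_phases))
}

phantom_coords <- function(spec) {
  ax <- lapply(1:3, function(a) (seq_len(spec$grid_shape[a]) - 1) *
                 spec$spacing_mm[a])
  dm <- spec$grid_shape
  list(x = array(rep(ax[[1]], times = dm[2] * dm[3]), dm),
       y = array(rep(rep(ax[[2]], each = dm[1]), times = dm[3]), dm),
       z = array(rep(ax[[3]], each = dm[1] * dm[2]), dm))
}

ellipsoid_mask <- function(co, center, semi_axes) {
  ((co$x - center[1]) / semi_axes[1])^2 +
    ((co$y - center[2]) / semi_axes[2])^2 +
    ((co$z - center[3]) / semi_axes[3])^2 <= 1
}

sphere_mask <- function(co, center, radius) {
  (co$x - center[1])^2 + (co$y - center[2])^2 + (co$z - center[3])^2 <=
    radius^2
}

#' Generate a synthetic 4DCT phantom
#'
#' Paints the phantom structures in priority order (body, then lungs, then
#' heart and cord, then tumour; later structures overwrite earlier ones) into
#' each phase's HU volume, marks the tumour sphere as the per-phase GTV, and
#' returns static OAR masks. With zero amplitude and zero noise all phases
#' are voxel-identical; with the same seed the output is bit-identical.
#'
#' @param spec a [phantom_spec()].
#' @return list with `phases` (list of HU `voxel_volume`s), `gtv` (list of
#'   per-phase `structure_mask`s), `oars` (named list: lungs, heart,
#'   spinal_cord) and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  co <- phantom_coords(spec)
  sp <- spec$spacing_mm
  org <- c(0, 0, 0)
  extent_lo <- org - sp / 2
  extent_hi <- org + (spec$grid_shape - 0.5) * sp

  base <- array(spec$air_hu, spec$grid_shape)
  base[ellipsoid_mask(co, spec$body$center, spec$body$semi_axes)] <-
    spec$body$hu
  lung_l <- ellipsoid_mask(co, spec$lungs$left$center,
                           spec$lungs$left$semi_axes)
  lung_r <- ellipsoid_mask(co, spec$lungs$right$center,
                           spec$lungs$right$semi_axes)
  base[lung_l | lung_r] <- spec$lungs$hu
  heart <- ellipsoid_mask(co, spec$heart$center,
                          spec$heart$semi_axes)
  base[heart] <- spec$heart$hu
  cord <- (co$x - spec$cord$center[1])^2 + (co$y - spec$cord$center[2])^2 <=
    spec$cord$radius^2
  base[cord] <- spec$cord$hu

  if (spec$noise_sd_hu > 0) set.seed(spec$seed)
  phases <- vector("list", spec$n_phases)
  gtvs <- vector("list", spec$n_phases)
  for (k in seq_len(spec$n_phases) - 1L) {
    ctr <- spec$tumour$center + phase_displacement(spec, k)
    if (any(ctr - spec$tumour$radius < extent_lo) ||
        any(ctr + spec$tumour$radius > extent_hi))
      stop("tumour sphere leaves the grid at phase ", k, call. = FALSE)
    tum <- sphere_mask(co, ctr, spec$tumour$radius)
    vol <- base
    vol[tum] <- spec$tumour$hu
    if (spec$noise_sd_hu > 0) {
      vol <- vol + stats::rnorm(length(vol), sd = spec$noise_sd_hu)
      vol <- pmin(pmax(vol, -1024), 3071)
    }
    phases[[k + 1]] <- voxel_volume(vol, sp, org, units = "HU")
    gtvs[[k + 1]] <- structure_mask(tum, sp, org, role = "GTV")
  }
  # the lung contour excludes mediastinal structures painted over it
  oars <- list(
    lungs = structure_mask((lung_l | lung_r) & !heart & !cord, sp, org,
                           role = "lungs"),
    heart = structure_mask(heart, sp, org, role = "heart"),
    spinal_cord = structure_mask(cord, sp, org, role = "spinal_cord")
  )
  list(phases = phases, gtv = gtvs, oars = oars, spec = spec)
}

#' Write a generated phantom to disk
#'
#' Writes `phase_00.nii.gz` ... plus `gtv_phase_XX.nii.gz` and the static
#' OAR masks `lungs.nii.gz`, `heart.nii.gz`, `cord.nii.gz`.
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(phantom$phases)) {
    write_volume(phantom$phases[[k]],
                 file.path(dir, sprintf("phase_%02d.nii.gz", k - 1)))
    write_volume(phantom$gtv[[k]],
                 file.path(dir, sprintf("gtv_phase_%02d.nii.gz", k - 1)))
  }
  write_volume(phantom$oars$lungs, file.path(dir, "lungs.nii.gz"))
  write_volume(phantom$oars$heart, file.path(dir, "heart.nii.gz"))
  write_volume(phantom$oars$spinal_cord, file.path(dir, "cord.nii.gz"))
  invisible(dir)
}
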