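#' Exact voxel traversal of a single ray
#'
#' Siddon-style traversal: the ray is clipped to the volume, every voxel
#' boundary crossing becomes a breakpoint, and each interval is attributed to
#' the voxel containing its midpoint, which makes boundary grazing
#' deterministic (half-open voxel intervals per axis). Chord lengths are
#' exact for axis-aligned voxel boundaries and their sum telescopes to the
#' in-grid geometric path length.
#'
#' @param p0 numeric length-3 ray start point (mm); may lie outside the
#'   volume.
#' @param direction unit length-3 travel direction.
#' @param vol a `voxel_volume`.
#' @param tmax distance (mm) from `p0` at which integration stops
#'   (default `Inf`: the volume exit).
#' @return tibble with columns `i, j, k` (1-based voxel indices) and
#'   `length_mm`; attributes `t_entry` / `t_exit` give the clipped parametric
#'   range. Zero rows if the ray misses the volume.
#' @export
trace_ray <- function(p0, direction, vol, tmax = Inf) {
  stopifnot(inherits(vol, "voxel_volume"))
  direction <- direction / sqrt(sum(direction^2))
  res <- cpp_trace_ray(as.numeric(p0), as.numeric(direction),
                       if (is.finite(tmax)) tmax else 1e12,
                       dim(vol$data), vol$spacing, vol$origin)
  dm <- dim(vol$data)
  lin <- res$idx - 1L
  out <- tibble::tibble(
    i = lin %% dm[1] + 1L,
    j = (lin %/% dm[1]) %% dm[2] + 1L,
    k = lin %/% (dm[1] * dm[2]) + 1L,
    length_mm = res$length
  )
  attr(out, "t_entry") <- res$t_entry
  attr(out, "t_exit") <- res$t_exit
  out
}

#' Water-equivalent path length of a ray
#'
#' WEPL is the line integral of relative stopping power along the ray: the
#' sum over traversed voxels of chord length times voxel RSP, i.e. the depth
#' of water producing the same proton energy loss. Integration starts at the
#' volume boundary (air RSP is ~0.001, so the skin-to-boundary difference is
#' negligible) and ends at `tmax`.
#'
#' @inheritParams trace_ray
#' @param rsp a `voxel_volume` of relative stopping power.
#' @return WEPL in mm (water-equivalent).
#' @export
ray_wepl <- function(p0, direction, rsp, tmax = Inf) {
  seg <- trace_ray(p0, direction, rsp, tmax)
  if (nrow(seg) == 0) return(0)
  dm <- dim(rsp$data)
  lin <- (seg$i - 1L) + dm[1] * ((seg$j - 1L) + dm[2] * (seg$k - 1L)) + 1L
  sum(seg$length_mm * rsp$data[lin])
}

# deterministic orthonormal basis perpendicular to d
beam_basis <- function(d) {
  ref <- diag(3)[, which.min(abs(d))]
  u <- c(d[2] * ref[3] - d[3] * ref[2],
         d[3] * ref[1] - d[1] * ref[3],
         d[1] * ref[2] - d[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v)
}

#' Build a parallel ray bundle covering a target
#'
#' Rays are parallel (source at infinity) and seeded on a uniform 2D grid of
#' pitch `pitch_mm` in the plane perpendicular to the beam, covering the
#' target's beam's-eye-view projection plus one pitch of margin. Seeds whose
#' axis passes within `pitch_mm / sqrt(2)` (the seed-grid half-diagonal) of
#' at least one target voxel centre are kept; this radius guarantees that
#' every target voxel centre lies within `pitch_mm / sqrt(2)` of some kept
#' ray. Each ray's distal stop point is the last exit of its axis from the
#' target mask, so integration ends at the target's distal edge.
#'
#' @param gantry_deg,couch_deg beam orientation in degrees.
#' @param target a nonempty `structure_mask` (typically the ITV).
#' @param pitch_mm lateral ray spacing in mm (default 2, spot-grid scale).
#' @return a `ray_bundle`: list with the orientation, unit `direction`,
#'   ray start points `p0` (n x 3, behind the volume), per-ray stop distance
#'   `t_stop` (mm from `p0`) and `pitch_mm`.
#' @export
build_ray_bundle <- function(gantry_deg, couch_deg, target, pitch_mm = 2) {
  stopifnot(inherits(target, "structure_mask"))
  if (!any(target$data)) stop("target mask is empty", call. = FALSE)
  d <- as.numeric(beam_direction(gantry_deg, couch_deg))
  basis <- beam_basis(d)
  ctr <- voxel_centers(target)
  a <- as.numeric(ctr %*% basis$u)
  b <- as.numeric(ctr %*% basis$v)
  tp <- as.numeric(ctr %*% d)

  sa <- seq(min(a) - pitch_mm, max(a) + pitch_mm, by = pitch_mm)
  sb <- seq(min(b) - pitch_mm, max(b) + pitch_mm, by = pitch_mm)
  seeds <- as.matrix(expand.grid(a = sa, b = sb))

  # nearest target-centre distance in the beam's-eye view, chunked
  keep_r2 <- pitch_mm^2 / 2
  min_d2 <- rep(Inf, nrow(seeds))
  t_near <- rep(-Inf, nrow(seeds))
  idx <- seq_along(a)
  for (ch in split(idx, ceiling(idx / 4000))) {
    d2 <- outer(seeds[, 1], a[ch], "-")^2 + outer(seeds[, 2], b[ch], "-")^2
    min_d2 <- pmin(min_d2, apply(d2, 1, min))
    tm <- matrix(tp[ch], nrow = nrow(seeds), ncol = length(ch), byrow = TRUE)
    tm[d2 > keep_r2 + 1e-9] <- -Inf
    t_near <- pmax(t_near, apply(tm, 1, max))
  }
  keep <- min_d2 <= keep_r2 + 1e-9
  if (!any(keep))
    stop("no ray intersects the target (degenerate geometry)", call. = FALSE)
  seeds <- seeds[keep, , drop = FALSE]
  t_near <- t_near[keep]

  # start rays behind everything along the beam axis
  corners <- as.matrix(expand.grid(
    x = target$origin[1] + c(-0.5, dim(target$data)[1] - 0.5) *
      target$spacing[1],
    y = target$origin[2] + c(-0.5, dim(target$data)[2] - 0.5) *
      target$spacing[2],
    z = target$origin[3] + c(-0.5, dim(target$data)[3] - 0.5) *
      target$spacing[3]))
  t_base <- min(corners %*% d) - 1
  p0 <- seeds[, 1, drop = FALSE] %*% t(basis$u) +
    seeds[, 2, drop = FALSE] %*% t(basis$v)
  p0 <- sweep(p0, 2, d * t_base, "+")

  t_stop <- cpp_mask_stop(p0, d, dim(target$data), target$spacing,
                          target$origin, as.logical(target$data))
  # rays grazing near a centre without traversing a mask voxel: stop at the
  # most distal nearby centre plus half a voxel diagonal
  miss <- is.na(t_stop)
  if (any(miss))
    t_stop[miss] <- (t_near[miss] - t_base) +
      0.5 * sqrt(sum(target$spacing^2))

  structure(list(gantry_deg = gantry_deg, couch_deg = couch_deg,
                 direction = d, u = basis$u, v = basis$v, p0 = p0,
                 t_stop = as.numeric(t_stop), pitch_mm = pitch_mm),
            class = "ray_bundle")
}

#' @export
print.ray_bundle <- function(x, ...) {
  cat(sprintf("<ray_bundle> gantry %g, couch %g: %d rays at %g mm pitch\n",
              x$gantry_deg, x$couch_deg, nrow(x$p0), x$pitch_mm))
  invisible(x)
}

#' WEPL of every bundle ray through one or more volumes
#'
#' Each ray is traversed once and its chords are reused for every volume, so
#' the AIP and all breathing phases are integrated along identical geometric
#' paths.
#'
#' @param bundle a [build_ray_bundle()] result.
#' @param rsp_vols a `voxel_volume` or list of them, sharing one grid.
#' @return numeric matrix, rays x volumes, of WEPL in mm.
#' @export
bundle_wepl <- function(bundle, rsp_vols) {
  if (inherits(rsp_vols, "voxel_volume")) rsp_vols <- list(rsp_vols)
  check_same_grid(rsp_vols, "RSP volumes")
  ref <- rsp_vols[[1]]
  cpp_bundle_wepl(bundle$p0, bundle$direction, bundle$t_stop,
                  dim(ref$data), ref$spacing, ref$origin,
                  lapply(rsp_vols, function(v) v$data))
}

#' Voxels traversed by a bundle
#'
#' Marks every voxel crossed with positive chord length by at least one ray,
#' each ray truncated at its distal stop point. This is the ray-traced beam
#' path used for organ-exposure scoring.
#'
#' @inheritParams bundle_wepl
#' @param vol a `voxel_volume` or `structure_mask` defining the grid.
#' @return logical 3D array on the grid.
#' @export
bundle_footprint <- function(bundle, vol) {
  m <- cpp_bundle_mark(bundle$p0, bundle$direction, bundle$t_stop,
                       dim(vol$data), vol$spacing, vol$origin)
  array(m, dim(vol$data))
}
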