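#' Isotropic margin expansion of a structure mask
#'
#' Expands a binary structure by a physical margin: the output contains
#' exactly the voxels whose centre lies within `margin_mm` (Euclidean, in mm)
#' of some input voxel centre. This is the CTV construction — a 5 mm
#' isotropic expansion of the GTV — and it handles anisotropic spacing by
#' thresholding true physical distance rather than applying a
#' structuring-element approximation.
#'
#' @param mask a `structure_mask`.
#' @param margin_mm non-negative margin in mm.
#' @param role role of the returned mask (default `"CTV"` when expanding a
#'   GTV, otherwise the input role).
#' @return a `structure_mask` on the same grid.
#' @export
expand_margin <- function(mask, margin_mm, role = NULL) {
  stopifnot(inherits(mask, "structure_mask"), margin_mm >= 0)
  if (is.null(role)) role <- if (mask$role == "GTV") "CTV" else mask$role
  dm <- dim(mask$data)
  if (margin_mm == 0)
    return(structure_mask(mask$data, mask$spacing, mask$origin, role = role))

  # all integer offsets whose physical length is within the margin
  rng <- floor(margin_mm / mask$spacing)
  off <- expand.grid(dx = -rng[1]:rng[1], dy = -rng[2]:rng[2],
                     dz = -rng[3]:rng[3])
  d2 <- (off$dx * mask$spacing[1])^2 + (off$dy * mask$spacing[2])^2 +
    (off$dz * mask$spacing[3])^2
  off <- as.matrix(off[d2 <= margin_mm^2 + 1e-9, , drop = FALSE])

  ijk <- which(mask$data, arr.ind = TRUE)
  out <- array(FALSE, dm)
  clipped <- FALSE
  for (r in seq_len(nrow(off))) {
    s <- ijk
    s[, 1] <- s[, 1] + off[r, 1]
    s[, 2] <- s[, 2] + off[r, 2]
    s[, 3] <- s[, 3] + off[r, 3]
    ok <- s[, 1] >= 1 & s[, 1] <= dm[1] &
      s[, 2] >= 1 & s[, 2] <= dm[2] &
      s[, 3] >= 1 & s[, 3] <= dm[3]
    if (!all(ok)) clipped <- TRUE
    out[s[ok, , drop = FALSE]] <- TRUE
  }
  if (clipped)
    warning("margin expansion clipped at the grid boundary", call. = FALSE)
  structure_mask(out, mask$spacing, mask$origin, role = role)
}

#' Union of structure masks
#'
#' Voxelwise logical OR on a shared grid. Used for the ITV (union of all
#' per-phase CTVs across the breathing cycle) and for composite OAR contours
#' encompassing all respiratory phases.
#'
#' @param masks list of `structure_mask`s on identical grids.
#' @param role role of the returned mask (default `"ITV"` when the inputs are
#'   CTVs, otherwise the first input's role).
#' @return a `structure_mask`.
#' @export
union_masks <- function(masks, role = NULL) {
  stopifnot(length(masks) >= 1)
  check_same_grid(masks, "masks")
  if (is.null(role)) {
    roles <- unique(vapply(masks, function(m) m$role, character(1)))
    role <- if (identical(roles, "CTV")) "ITV" else roles[1]
  }
  acc <- masks[[1]]$data
  if (length(masks) > 1)
    for (m in masks[-1]) acc <- acc | m$data
  structure_mask(acc, masks[[1]]$spacing, masks[[1]]$origin, role = role)
}
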