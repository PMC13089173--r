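#' Assemble a 4DCT case for metric computation
#'
#' Builds everything the angular metrics need from the raw per-phase inputs:
#' per-phase CTVs (GTV + isotropic margin), the ITV (union of CTVs over the
#' breathing cycle), composite OAR masks (union over phases when per-phase
#' masks are given), the AIP-CT (voxelwise mean of the phases) and RSP
#' volumes for the AIP and every phase via the calibration table.
#'
#' @param phases list of per-phase HU `voxel_volume`s on one grid.
#' @param gtvs list of per-phase GTV `structure_mask`s.
#' @param oars named list of OAR masks (each a `structure_mask`, or a list of
#'   per-phase masks to be unioned). Names become the map VOI labels.
#' @param ctv_margin_mm isotropic GTV-to-CTV margin (default 5 mm).
#' @param table HU-to-RSP calibration, see [rsp_table()].
#' @return a `beam_case`: list with `aip_rsp`, `phase_rsps`, `itv`, `oars`,
#'   `ctvs`, `aip`.
#' @export
build_case <- function(phases, gtvs, oars, ctv_margin_mm = 5,
                       table = default_rsp_table()) {
  stopifnot(length(phases) >= 1, length(gtvs) == length(phases))
  oar_flat <- list()
  for (o in oars)
    oar_flat <- c(oar_flat, if (inherits(o, "structure_mask")) list(o) else o)
  check_same_grid(c(phases, gtvs, oar_flat), "case inputs")
  ctvs <- lapply(gtvs, expand_margin, margin_mm = ctv_margin_mm)
  itv <- union_masks(ctvs)
  oars <- lapply(oars, function(o) {
    if (inherits(o, "structure_mask")) o else union_masks(o)
  })
  aip <- average_intensity_projection(phases)
  structure(list(
    aip = aip,
    aip_rsp = hu_to_rsp(aip, table),
    phase_rsps = lapply(phases, hu_to_rsp, table = table),
    ctvs = ctvs, itv = itv, oars = oars
  ), class = "beam_case")
}

#' @export
print.beam_case <- function(x, ...) {
  cat(sprintf("<beam_case> %d phases, ITV %d voxels, OARs: %s\n",
              length(x$phase_rsps), sum(x$itv$data),
              paste(names(x$oars), collapse = ", ")))
  invisible(x)
}

#' Motion sensitivity of one beam orientation (delta-WEPL)
#'
#' The mean absolute difference in WEPL between the AIP-CT and each 4DCT
#' phase, averaged across all rays and breathing phases:
#' `mean over phases and rays of |WEPL_AIP - WEPL_phase|`. Rays and their
#' distal stop points are fixed on the AIP-frame target, so every phase is
#' integrated along identical geometric paths and a motionless case gives
#' exactly zero.
#'
#' @param bundle a [build_ray_bundle()] result.
#' @param aip_rsp AIP RSP `voxel_volume`.
#' @param phase_rsps list of per-phase RSP volumes.
#' @return delta-WEPL in mm (>= 0).
#' @export
delta_wepl <- function(bundle, aip_rsp, phase_rsps) {
  stopifnot(length(phase_rsps) >= 1)
  w <- bundle_wepl(bundle, c(list(aip_rsp), phase_rsps))
  mean(abs(w[, -1, drop = FALSE] - w[, 1]))
}

#' Geometric organ exposure of one beam orientation (PIV)
#'
#' The percentage irradiated volume: the fraction of an OAR's voxels
#' intersected by the ray-traced beam path, each ray truncated at its distal
#' stop point at the target edge. A purely geometric surrogate for organ
#' exposure in [0, 1].
#'
#' @inheritParams delta_wepl
#' @param oar a nonempty OAR `structure_mask`.
#' @return fraction in [0, 1].
#' @export
piv <- function(bundle, oar) {
  stopifnot(inherits(oar, "structure_mask"))
  n <- sum(oar$data)
  if (n == 0) stop("OAR mask is empty", call. = FALSE)
  fp <- bundle_footprint(bundle, oar)
  sum(fp & oar$data) / n
}

#' Metric maps over the gantry-couch grid
#'
#' For every deliverable orientation, builds the AIP-frame ray bundle on the
#' ITV and computes the target delta-WEPL plus one PIV value per OAR. The
#' result is a long tibble over the angular grid, one row per
#' (orientation, VOI).
#'
#' @param case a [build_case()] result.
#' @param grid angular grid tibble from [beam_grid()].
#' @param pitch_mm lateral ray pitch (default 2 mm).
#' @param oars character vector of OAR names to score (default: all in the
#'   case).
#' @param verbose log per-orientation progress to stderr.
#' @return a `metric_map` tibble with columns `gantry_deg`, `couch_deg`,
#'   `voi` (`"target"` or OAR name), `metric` (`"delta_wepl_mm"` or
#'   `"piv_fraction"`) and `value`.
#' @export
compute_metric_maps <- function(case, grid = beam_grid(), pitch_mm = 2,
                                oars = names(case$oars), verbose = FALSE) {
  stopifnot(inherits(case, "beam_case"))
  missing_oars <- setdiff(oars, names(case$oars))
  if (length(missing_oars))
    stop("case has no OAR named: ", paste(missing_oars, collapse = ", "),
         call. = FALSE)
  rows <- purrr::pmap(grid[, c("gantry_deg", "couch_deg")],
                      function(gantry_deg, couch_deg) {
    bundle <- build_ray_bundle(gantry_deg, couch_deg, case$itv, pitch_mm)
    vals <- c(delta_wepl(bundle, case$aip_rsp, case$phase_rsps),
              vapply(oars, function(o) piv(bundle, case$oars[[o]]),
                     numeric(1)))
    if (verbose)
      message(sprintf("gantry %4g couch %4g: dWEPL %.3f mm", gantry_deg,
                      couch_deg, vals[1]))
    tibble::tibble(
      gantry_deg = gantry_deg, couch_deg = couch_deg,
      voi = c("target", oars),
      metric = c("delta_wepl_mm", rep("piv_fraction", length(oars))),
      value = unname(vals)
    )
  })
  out <- dplyr::bind_rows(rows)
  stopifnot(all(is.finite(out$value)),
            all(out$value[out$metric == "piv_fraction"] >= 0 &
                  out$value[out$metric == "piv_fraction"] <= 1),
            all(out$value[out$metric == "delta_wepl_mm"] >= 0))
  new_metric_map(out)
}

new_metric_map <- function(x) {
  class(x) <- c("metric_map", class(tibble::tibble()))
  x
}

#' Write metric or risk maps
#'
#' CSV export holds one row per orientation and VOI
#' (`gantry_deg,couch_deg,voi,metric,value`); JSON export adds grid metadata.
#'
#' @param maps a `metric_map` or `risk_map` tibble.
#' @param path output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_map <- function(maps, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(
      gantry_deg = sort(unique(maps$gantry_deg)),
      couch_deg = sort(unique(maps$couch_deg)),
      values = as.data.frame(maps)
    ), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(maps), path, row.names = FALSE)
  }
  invisible(path)
}
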