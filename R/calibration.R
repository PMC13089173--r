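#' Hounsfield-unit to relative stopping power calibration
#'
#' Proton WEPL is a line integral of relative stopping power (RSP), the
#' voxel's proton stopping power relative to water. CT Hounsfield units are
#' converted to RSP with a piecewise-linear lookup table in the style of a
#' stoichiometric calibration curve. `default_rsp_table()` ships a surrogate
#' curve anchored at water (0 HU = RSP 1); site-specific calibrations are
#' supplied as a CSV with `hu,rsp` columns via [read_rsp_table()].
#'
#' @param nodes data frame / tibble with numeric columns `hu` (strictly
#'   increasing) and `rsp` (non-negative, non-decreasing).
#' @return an `rsp_table`.
#' @export
rsp_table <- function(nodes) {
  nodes <- as.data.frame(nodes)[, c("hu", "rsp")]
  if (nrow(nodes) < 2) stop("calibration table needs >= 2 nodes", call. = FALSE)
  if (any(diff(nodes$hu) <= 0))
    stop("calibration HU values must be strictly increasing", call. = FALSE)
  if (any(nodes$rsp < 0) || any(diff(nodes$rsp) < 0))
    stop("calibration RSP values must be non-negative and non-decreasing",
         call. = FALSE)
  structure(list(hu = nodes$hu, rsp = nodes$rsp), class = "rsp_table")
}

#' @rdname rsp_table
#' @export
default_rsp_table <- function() {
  rsp_table(data.frame(
    hu  = c(-1000, -750, -120,    0,   50,  300, 1000, 3000),
    rsp = c(0.001, 0.25, 0.93, 1.00, 1.05, 1.15, 1.55, 2.40)
  ))
}

#' @param path CSV file with header `hu,rsp`, one node per line.
#' @rdname rsp_table
#' @export
read_rsp_table <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("hu", "rsp") %in% names(tab)))
    stop("calibration CSV must have columns hu,rsp", call. = FALSE)
  rsp_table(tab)
}

#' @export
print.rsp_table <- function(x, ...) {
  cat("<rsp_table>", length(x$hu), "nodes,",
      sprintf("HU [%g, %g] -> RSP [%g, %g]\n",
              min(x$hu), max(x$hu), min(x$rsp), max(x$rsp)))
  invisible(x)
}

#' Convert an HU volume to relative stopping power
#'
#' Voxelwise piecewise-linear interpolation between the table nodes; HU
#' outside the node range is clamped to the end nodes, so the map is monotone
#' and continuous everywhere.
#'
#' @param vol a `voxel_volume` in HU.
#' @param table an `rsp_table` (default [default_rsp_table()]).
#' @return a `voxel_volume` in RSP units.
#' @export
hu_to_rsp <- function(vol, table = default_rsp_table()) {
  stopifnot(inherits(vol, "voxel_volume"), inherits(table, "rsp_table"))
  vals <- stats::approx(table$hu, table$rsp, xout = as.vector(vol$data),
                        method = "linear", rule = 2)$y
  voxel_volume(array(vals, dim(vol$data)), vol$spacing, vol$origin,
               units = "RSP")
}

#' @param hu numeric vector of HU values.
#' @rdname hu_to_rsp
#' @export
lookup_rsp <- function(hu, table = default_rsp_table()) {
  stats::approx(table$hu, table$rsp, xout = hu, method = "linear", rule = 2)$y
}
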