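#' Beam direction from gantry and couch angles
#'
#' Maps IEC-style gantry and couch angles to the unit beam travel direction
#' (source toward isocenter) in the patient frame (x = left, y = posterior,
#' z = superior; supine patient). Gantry 0 is an anterior beam travelling
#' posteriorly, gantry increasing toward patient-left; the couch rotates the
#' beam about the vertical (anterior-posterior) axis, so a vertical beam is
#' invariant under couch rotation. The closed form is
#' `(-sin(g) cos(c), cos(g), sin(g) sin(c))`.
#'
#' @param gantry_deg,couch_deg numeric vectors of angles in degrees.
#' @return numeric matrix with one unit row vector per angle pair.
#' @export
beam_direction <- function(gantry_deg, couch_deg) {
  g <- gantry_deg * pi / 180
  c_ <- couch_deg * pi / 180
  cbind(x = -sin(g) * cos(c_), y = cos(g), z = sin(g) * sin(c_))
}

#' Enumerate the deliverable gantry-couch angular grid
#'
#' Builds the full grid of gantry angles `0 .. 360 - step` and couch angles
#' `-90 .. 90`, applies an optional machine deliverability mask, and by
#' default removes duplicate beam directions: at gantry 0 and 180 the beam is
#' vertical, so every nonzero couch value repeats the couch-0 direction.
#' The default 10 degree gantry / 15 degree couch grid has 36 x 13 = 468 raw
#' cells and 444 unique directions.
#'
#' @param gantry_step gantry spacing in degrees (default 10; must divide 360).
#' @param couch_step couch spacing in degrees (default 15; must divide 180).
#' @param deliverability optional data frame with columns
#'   `gantry_deg, couch_deg, deliverable`; cells marked not deliverable (or
#'   absent from the table) are dropped.
#' @param remove_duplicates drop repeated vertical-beam directions
#'   (default TRUE).
#' @return a tibble with columns `gantry_deg`, `couch_deg` in row-major
#'   (couch, gantry) order.
#' @export
beam_grid <- function(gantry_step = 10, couch_step = 15,
                      deliverability = NULL, remove_duplicates = TRUE) {
  stopifnot(gantry_step > 0, couch_step > 0)
  if (abs(360 / gantry_step - round(360 / gantry_step)) > 1e-9)
    stop("gantry_step must divide 360 evenly", call. = FALSE)
  if (abs(180 / couch_step - round(180 / couch_step)) > 1e-9)
    stop("couch_step must divide 180 evenly", call. = FALSE)
  grid <- tidyr::expand_grid(
    couch_deg = seq(-90, 90, by = couch_step),
    gantry_deg = seq(0, 360 - gantry_step, by = gantry_step)
  )[, c("gantry_deg", "couch_deg")]
  if (remove_duplicates) {
    vertical <- abs(sin(grid$gantry_deg * pi / 180)) < 1e-12
    grid <- grid[!(vertical & grid$couch_deg != 0), ]
  }
  if (!is.null(deliverability)) {
    d <- as.data.frame(deliverability)
    keep <- d[as.logical(d$deliverable), c("gantry_deg", "couch_deg")]
    grid <- dplyr::inner_join(grid, keep,
                              by = c("gantry_deg", "couch_deg"))
  }
  if (nrow(grid) == 0) stop("angular grid is empty", call. = FALSE)
  tibble::as_tibble(grid)
}

#' @param path CSV with columns `gantry_deg,couch_deg,deliverable`.
#' @rdname beam_grid
#' @export
read_deliverability <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("gantry_deg", "couch_deg", "deliverable") %in% names(d)))
    stop("deliverability CSV needs gantry_deg,couch_deg,deliverable",
         call. = FALSE)
  d
}

#' Central angle between two beams
#'
#' The angle between two beam direction unit vectors (arccos of their dot
#' product), in degrees in [0, 180]. Used as the pairwise beam-separation
#' criterion during selection. For coplanar beams (couch 0) it reduces to the
#' wrapped absolute gantry difference.
#'
#' @param gantry1,couch1,gantry2,couch2 angles in degrees (vectorised).
#' @return numeric vector of central angles in degrees.
#' @export
central_angle <- function(gantry1, couch1, gantry2, couch2) {
  n <- max(length(gantry1), length(couch1), length(gantry2), length(couch2))
  a <- beam_direction(rep_len(gantry1, n), rep_len(couch1, n))
  b <- beam_direction(rep_len(gantry2, n), rep_len(couch2, n))
  dot <- rowSums(a * b)
  acos(pmin(1, pmax(-1, dot))) * 180 / pi
}
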