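#' Z-score normalisation of metric maps
#'
#' Puts delta-WEPL (mm) and PIV (fraction) maps on a common relative-risk
#' scale: per VOI, `(value - mean) / sd` over the deliverable cells, with the
#' population standard deviation. After normalisation each map has mean 0 and
#' SD 1 and expresses the relative sensitivity of beam geometries rather than
#' absolute clinical constraints. A constant map carries no angular
#' preference and becomes all zeros with a warning.
#'
#' Statistics are always computed over all deliverable cells, before any
#' constraint exclusion, so adding a hard constraint changes admissibility
#' but not the normalisation.
#'
#' @param maps a `metric_map` tibble from [compute_metric_maps()].
#' @return the same tibble with `value` replaced by its per-VOI Z-score.
#' @export
zscore_maps <- function(maps) {
  stopifnot(all(c("gantry_deg", "couch_deg", "voi", "value") %in% names(maps)))
  zscore1 <- function(v, voi) {
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))  # population SD
    if (s == 0) {
      warning("metric map for '", voi[1],
              "' is constant; Z-scores set to 0", call. = FALSE)
      return(rep(0, length(v)))
    }
    (v - m) / s
  }
  out <- dplyr::mutate(dplyr::group_by(maps, .data$voi),
                       value = zscore1(.data$value, .data$voi))
  out <- dplyr::ungroup(out)
  attr(out, "zscored") <- TRUE
  new_metric_map(out)
}

#' Hard beam-exclusion constraints
#'
#' A constraint removes orientations from consideration: with mode
#' `"exclude_intersecting"` any beam whose path intersects the OAR at all
#' (PIV > 0) is excluded; with mode `"piv_threshold"` beams with PIV strictly
#' above `threshold` are excluded.
#'
#' @param ... named constraints, one per OAR, each either a mode string
#'   (`"exclude_intersecting"`) or `list(mode = "piv_threshold",
#'   threshold = x)` with `x` in `[0, 1]`.
#' @return a `constraint_config`.
#' @examples
#' constraint_config(spinal_cord = "exclude_intersecting")
#' constraint_config(heart = list(mode = "piv_threshold", threshold = 0.3))
#' @export
constraint_config <- function(...) {
  cfg <- list(...)
  cfg <- lapply(cfg, function(x) {
    if (is.character(x)) x <- list(mode = x)
    x$mode <- match.arg(x$mode, c("none", "exclude_intersecting",
                                  "piv_threshold"))
    if (x$mode == "piv_threshold") {
      if (is.null(x$threshold) || x$threshold < 0 || x$threshold > 1)
        stop("piv_threshold constraint needs threshold in [0, 1]",
             call. = FALSE)
    }
    x
  })
  structure(cfg, class = "constraint_config")
}

#' Apply hard constraints to metric maps
#'
#' Evaluates each constraint against the (raw, unnormalised) PIV map of the
#' named OAR and returns the per-cell exclusion status with reason codes.
#'
#' @param maps a `metric_map` tibble containing PIV maps for every
#'   constrained OAR (raw values, not Z-scores).
#' @param constraints a [constraint_config()].
#' @return tibble with `gantry_deg`, `couch_deg`, `excluded` (logical) and
#'   `reason` (comma-separated OAR names, `NA` when admissible).
#' @export
apply_constraints <- function(maps, constraints = constraint_config()) {
  cells <- dplyr::distinct(maps[, c("gantry_deg", "couch_deg")])
  cells$excluded <- FALSE
  cells$reason <- NA_character_
  for (oar in names(constraints)) {
    cfg <- constraints[[oar]]
    if (cfg$mode == "none") next
    pm <- maps[maps$voi == oar & maps$metric == "piv_fraction", ]
    if (nrow(pm) == 0)
      stop("constraint on '", oar, "' but no PIV map for it", call. = FALSE)
    thr <- if (cfg$mode == "exclude_intersecting") 0 else cfg$threshold
    bad <- pm[pm$value > thr, c("gantry_deg", "couch_deg")]
    hit <- paste(cells$gantry_deg, cells$couch_deg) %in%
      paste(bad$gantry_deg, bad$couch_deg)
    cells$reason[hit] <- ifelse(is.na(cells$reason[hit]), oar,
                                paste(cells$reason[hit], oar, sep = ","))
    cells$excluded <- cells$excluded | hit
  }
  cells
}

#' Unified risk map
#'
#' Sums the Z-scored, weighted per-VOI maps into a single relative-risk
#' score per orientation: `score = sum over VOIs of weight * z`. Lower score
#' means lower combined risk. Excluded cells keep their exclusion reason and
#' never receive a rank downstream.
#'
#' @param zmaps Z-scored maps from [zscore_maps()].
#' @param weights named non-negative weights, one per VOI present in the
#'   maps; at least one must be positive. Defaults mirror a
#'   target-prioritising plan: target 2, heart and lungs 1.5, spinal cord
#'   0.5.
#' @param exclusions optional output of [apply_constraints()].
#' @return a `risk_map` tibble: `gantry_deg`, `couch_deg`, `score`,
#'   `admissible`, `reason`.
#' @export
unify_risk <- function(zmaps,
                       weights = c(target = 2, heart = 1.5, lungs = 1.5,
                                   spinal_cord = 0.5),
                       exclusions = NULL) {
  if (!isTRUE(attr(zmaps, "zscored")))
    stop("unify_risk() expects Z-scored maps; call zscore_maps() first",
         call. = FALSE)
  vois <- unique(zmaps$voi)
  miss <- setdiff(vois, names(weights))
  if (length(miss))
    stop("no weight supplied for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(weights < 0) || all(weights[vois] <= 0))
    stop("weights must be >= 0 with at least one > 0", call. = FALSE)
  scored <- dplyr::mutate(zmaps,
                          w = unname(weights[.data$voi]) * .data$value)
  out <- dplyr::summarise(dplyr::group_by(scored, .data$gantry_deg,
                                          .data$couch_deg),
                          score = sum(.data$w), .groups = "drop")
  if (is.null(exclusions)) {
    out$admissible <- TRUE
    out$reason <- NA_character_
  } else {
    out <- dplyr::left_join(out, exclusions,
                            by = c("gantry_deg", "couch_deg"))
    out$admissible <- !out$excluded
    out$excluded <- NULL
  }
  out <- out[order(out$couch_deg, out$gantry_deg), ]
  structure(out, class = c("risk_map", class(tibble::tibble())),
            weights = weights)
}

#' One-call risk map from raw metric maps
#'
#' Convenience wrapper running the normalise / constrain / combine sequence:
#' Z-score each map, evaluate hard constraints on the raw PIV values, then
#' sum the weighted Z-scores.
#'
#' @inheritParams unify_risk
#' @inheritParams apply_constraints
#' @param maps raw `metric_map` tibble.
#' @return a `risk_map` tibble, see [unify_risk()].
#' @export
build_risk_map <- function(maps,
                           weights = c(target = 2, heart = 1.5, lungs = 1.5,
                                       spinal_cord = 0.5),
                           constraints = constraint_config()) {
  weights <- weights[intersect(names(weights), unique(maps$voi))]
  unify_risk(zscore_maps(maps), weights,
             apply_constraints(maps, constraints))
}
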