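#' Tidy and summarise angular maps and selections
#'
#' `tidy()` returns the underlying per-cell tibble; `glance()` returns a
#' one-row summary (cell counts, value ranges, exclusions).
#'
#' @param x a `metric_map`, `risk_map` or `beam_selection`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.metric_map <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' @rdname tidy.metric_map
#' @export
tidy.risk_map <- function(x, ...) tibble::as_tibble(unclass_tbl(x))

#' @rdname tidy.metric_map
#' @export
tidy.beam_selection <- function(x, ...) tibble::as_tibble(unclass_tbl(x))

unclass_tbl <- function(x) {
  class(x) <- class(tibble::tibble())
  x
}

#' @rdname tidy.metric_map
#' @export
glance.metric_map <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tidy.metric_map(x), .data$voi, .data$metric),
    n_cells = dplyr::n(),
    min = min(.data$value), mean = mean(.data$value),
    max = max(.data$value), .groups = "drop")
}

#' @rdname tidy.metric_map
#' @export
glance.risk_map <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    n_admissible = sum(x$admissible),
    n_excluded = sum(!x$admissible),
    score_min = min(x$score[x$admissible]),
    score_max = max(x$score[x$admissible])
  )
}

#' @rdname tidy.metric_map
#' @export
glance.beam_selection <- function(x, ...) {
  seps <- NA_real_
  if (nrow(x) > 1) {
    pairs <- utils::combn(nrow(x), 2)
    seps <- central_angle(x$gantry_deg[pairs[1, ]], x$couch_deg[pairs[1, ]],
                          x$gantry_deg[pairs[2, ]], x$couch_deg[pairs[2, ]])
  }
  tibble::tibble(
    n_beams = nrow(x),
    mode = attr(x, "mode"),
    min_separation_deg = min(seps),
    total_score = sum(x$score)
  )
}
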