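#' Select a beam set from a unified risk map
#'
#' Greedy scan of the admissible cells in score order (ascending for
#' `mode = "best"`, descending for `"worst"`): a candidate is accepted iff
#' its central angle to every already-selected beam is at least
#' `min_sep_deg`. Ties in score are broken by (couch, gantry) lexicographic
#' order, so the output is deterministic. Worst-case selection exists to
#' benchmark deliberately poor geometry: it is equivalent to best-mode
#' selection on the negated map.
#'
#' @param risk a `risk_map` tibble from [unify_risk()] / [build_risk_map()].
#' @param n_beams number of beams to select.
#' @param min_sep_deg minimum pairwise central angle in degrees (default 20).
#' @param mode `"best"` (lowest risk) or `"worst"` (highest risk).
#' @return a `beam_selection` tibble: `rank`, `gantry_deg`, `couch_deg`,
#'   `score`.
#' @export
select_beams <- function(risk, n_beams, min_sep_deg = 20,
                         mode = c("best", "worst")) {
  mode <- match.arg(mode)
  stopifnot(n_beams >= 1, min_sep_deg >= 0)
  adm <- risk[risk$admissible, ]
  if (nrow(adm) == 0)
    stop("no admissible beams: every cell is excluded by constraints",
         call. = FALSE)
  if (nrow(adm) < n_beams)
    stop("only ", nrow(adm), " admissible beams for n_beams = ", n_beams,
         call. = FALSE)
  key <- if (mode == "best") adm$score else -adm$score
  adm <- adm[order(key, adm$couch_deg, adm$gantry_deg), ]

  sel <- integer(0)
  for (i in seq_len(nrow(adm))) {
    if (length(sel) == 0) {
      sel <- i
    } else {
      seps <- central_angle(adm$gantry_deg[i], adm$couch_deg[i],
                            adm$gantry_deg[sel], adm$couch_deg[sel])
      if (all(seps >= min_sep_deg)) sel <- c(sel, i)
    }
    if (length(sel) == n_beams) break
  }
  if (length(sel) < n_beams)
    stop("only ", length(sel), " mutually separated admissible beams found ",
         "(needed ", n_beams, " at >= ", min_sep_deg, " degrees)",
         call. = FALSE)
  out <- tibble::tibble(rank = seq_len(n_beams),
                        gantry_deg = adm$gantry_deg[sel],
                        couch_deg = adm$couch_deg[sel],
                        score = adm$score[sel])
  structure(out, class = c("beam_selection", class(tibble::tibble())),
            mode = mode, min_sep_deg = min_sep_deg)
}
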