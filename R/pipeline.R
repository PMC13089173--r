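#' Run a full beam-angle selection case from a config
#'
#' End-to-end driver: load or generate the case inputs, build CTV/ITV and
#' composite OARs, convert to RSP, compute the angular metric maps, build one
#' unified risk map per scenario and select its beam set, writing every
#' artifact plus a run manifest to the output directory. Any stage error
#' aborts with the stage name and cause.
#'
#' The config is a JSON file or an equivalent nested list:
#' \preformatted{
#' {
#'   "phantom": { ... phantom_spec fields ... },      // or "volumes": {...}
#'   "volumes": { "phases": [...], "gtvs": [...],
#'                "oars": {"lungs": "lungs.nii.gz", ...} },
#'   "calibration": "hu_rsp.csv",                     // optional
#'   "ctv_margin_mm": 5,
#'   "grid": { "gantry_step": 10, "couch_step": 15,
#'             "deliverability": "deliverable.csv" }, // optional mask
#'   "pitch_mm": 2,
#'   "write_rsp": false,
#'   "scenarios": {
#'     "scenario1": { "weights": {"target": 2, "heart": 1.5, "lungs": 1.5,
#'                                "spinal_cord": 0.5},
#'                    "n_beams": 3, "min_sep_deg": 20, "mode": "best" },
#'     "scenario2": { "constraints": {"spinal_cord":
#'                                    {"mode": "exclude_intersecting"}} }
#'   }
#' }
#' }
#'
#' @param config path to a JSON config, or a list with the same fields.
#' @param out_dir output directory (created if needed).
#' @param verbose log progress to stderr.
#' @return invisibly, a list with the computed `case`, `maps`, and per
#'   scenario `risk` and `selection`.
#' @export
run_case <- function(config, out_dir = NULL, verbose = TRUE) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- fill_config(config)
  if (!is.null(out_dir)) cfg$out <- out_dir
  if (is.null(cfg$out)) stop("config needs an output directory", call. = FALSE)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  inputs <- stage("inputs", load_case_inputs(cfg))
  say("inputs: ", length(inputs$phases), " phases, OARs: ",
      paste(names(inputs$oars), collapse = ", "))

  table <- stage("calibration", {
    if (is.null(cfg$calibration)) default_rsp_table()
    else read_rsp_table(cfg$calibration)
  })

  case <- stage("case", build_case(inputs$phases, inputs$gtvs, inputs$oars,
                                   ctv_margin_mm = cfg$ctv_margin_mm,
                                   table = table))
  stage("case-artifacts", {
    write_volume(case$aip, file.path(cfg$out, "aip.nii.gz"))
    write_volume(case$itv, file.path(cfg$out, "itv.nii.gz"))
    if (isTRUE(cfg$write_rsp))
      write_volume(case$aip_rsp, file.path(cfg$out, "aip_rsp.nii.gz"))
  })

  grid <- stage("grid", beam_grid(
    gantry_step = cfg$grid$gantry_step, couch_step = cfg$grid$couch_step,
    deliverability = if (!is.null(cfg$grid$deliverability))
      read_deliverability(cfg$grid$deliverability)))
  say("grid: ", nrow(grid), " deliverable orientations")

  maps <- stage("metric-maps",
                compute_metric_maps(case, grid, pitch_mm = cfg$pitch_mm,
                                    verbose = verbose))
  write_map(maps, file.path(cfg$out, "metric_maps.csv"))

  results <- list(case = case, maps = maps, scenarios = list())
  for (sc in names(cfg$scenarios)) {
    s <- cfg$scenarios[[sc]]
    risk <- stage(paste0("riskmap:", sc), {
      cons <- do.call(constraint_config, as.list(s$constraints))
      build_risk_map(maps, weights = unlist(s$weights), constraints = cons)
    })
    selection <- stage(paste0("select:", sc),
                       select_beams(risk, n_beams = s$n_beams,
                                    min_sep_deg = s$min_sep_deg,
                                    mode = s$mode))
    write_map(risk, file.path(cfg$out, paste0("risk_", sc, ".csv")))
    jsonlite::write_json(tidy.beam_selection(selection),
                         file.path(cfg$out, paste0("beams_", sc, ".json")),
                         auto_unbox = TRUE, digits = NA)
    say(sc, ": beams at ",
        paste(sprintf("(%g, %g)", selection$gantry_deg,
                      selection$couch_deg), collapse = " "))
    results$scenarios[[sc]] <- list(risk = risk, selection = selection)
  }

  stage("manifest", jsonlite::write_json(list(
    config = cfg,
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("beamrisk")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")
  ), file.path(cfg$out, "manifest.json"), auto_unbox = TRUE, digits = NA))
  invisible(results)
}

fill_config <- function(cfg) {
  defaults <- list(ctv_margin_mm = 5, pitch_mm = 2, write_rsp = FALSE,
                   grid = list(gantry_step = 10, couch_step = 15),
                   scenarios = list(
                     scenario1 = list()
                   ))
  cfg <- utils::modifyList(defaults, cfg)
  for (g in c("gantry_step", "couch_step"))
    if (is.null(cfg$grid[[g]])) cfg$grid[[g]] <- defaults$grid[[g]]
  sc_defaults <- list(weights = list(target = 2, heart = 1.5, lungs = 1.5,
                                     spinal_cord = 0.5),
                      constraints = list(), n_beams = 3, min_sep_deg = 20,
                      mode = "best")
  cfg$scenarios <- lapply(cfg$scenarios, function(s)
    utils::modifyList(sc_defaults, as.list(s)))
  cfg
}

load_case_inputs <- function(cfg) {
  if (!is.null(cfg$phantom)) {
    args <- cfg$phantom[intersect(names(cfg$phantom),
                                  names(formals(phantom_spec)))]
    ph <- generate_phantom(do.call(phantom_spec, args))
    return(list(phases = ph$phases, gtvs = ph$gtv, oars = ph$oars))
  }
  if (is.null(cfg$volumes))
    stop("config needs either 'phantom' or 'volumes'", call. = FALSE)
  v <- cfg$volumes
  phases <- lapply(v$phases, read_volume)
  gtvs <- lapply(v$gtvs, read_mask, role = "GTV")
  oar_roles <- c(lungs = "lungs", heart = "heart",
                 spinal_cord = "spinal_cord")
  oars <- lapply(names(v$oars), function(nm)
    read_mask(v$oars[[nm]],
              role = if (nm %in% names(oar_roles)) oar_roles[[nm]] else
                "body"))
  names(oars) <- names(v$oars)
  list(phases = phases, gtvs = gtvs, oars = oars)
}
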