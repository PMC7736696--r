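# Whole-workflow configuration and the end-to-end driver used by the
# command-line interface.

# recursive modifyList for nested config sections
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Workflow configuration
#'
#' All tunable tolerances and thresholds of the pipeline in one structured
#' list, with the workflow's standard values as defaults: block mass
#' tolerance 0.02 Da, feature intensity threshold 1e6, anchor tolerance
#' 10 ppm, RT alignment 30 s / 0.1 m/z, extraction window 0.025 m/z, QC
#' gates ppm < 10 / IPQ < 0.2 / S/N > 9, RT cluster width 15 s. A YAML file
#' with any subset of the sections `identify`, `convert`, `quant`, `sim`
#' overrides the defaults.
#'
#' @param path optional YAML config file.
#' @param ... named overrides, e.g. `identify = list(mass_tol = 0.01)`.
#' @return nested list of parameters.
#' @export
gf_config <- function(path = NULL, ...) {
  cfg <- list(
    identify = list(mass_tol = 0.02, intensity_threshold = 1e6,
                    anchor_ppm = 10, anchor_rt_tol = 30,
                    rt_merge_window = 60, strict = FALSE),
    convert = list(default_rt_width = 15, charges = c(2L, 3L)),
    quant = quant_config(),
    sim = sim_config())
  if (!is.null(path)) cfg <- merge_config(cfg, yaml::read_yaml(path))
  merge_config(cfg, list(...))
}

#' Run the full synthetic-data workflow end to end
#'
#' Simulates the default six-cluster IgG/IgA ground truth, identifies
#' glycopeptides on the feature graph with one MS/MS anchor per cluster,
#' converts the cluster table to an analyte list, simulates MS1 scans and
#' quantifies the analytes with QC. Primarily the engine behind the
#' `run-all` command-line verb and the reproducibility checks.
#'
#' @param seed integer seed driving every random choice.
#' @param config workflow configuration ([gf_config()]).
#' @param truth optional list of site profiles (defaults to
#'   [make_default_truth()] under `seed`).
#' @return list: `truth`, `sim`, `identification`, `scores`, `analytes`,
#'   `scan_sim`, `quant`.
#' @export
run_workflow <- function(seed = 1L, config = gf_config(), truth = NULL) {
  config$sim$seed <- seed
  if (is.null(truth)) truth <- make_default_truth(seed)
  sim <- simulate_features(truth, config$sim)
  anchors <- anchors_from_truth(sim)
  idres <- identify_glycopeptides(
    sim$features, anchors,
    mass_tol = config$identify$mass_tol,
    intensity_threshold = config$identify$intensity_threshold,
    anchor_ppm = config$identify$anchor_ppm,
    anchor_rt_tol = config$identify$anchor_rt_tol,
    rt_merge_window = config$identify$rt_merge_window,
    strict = config$identify$strict)
  scores <- score_identification(idres$table, sim)
  analytes <- graphms_to_analytes(idres$table,
                                  default_rt_width = config$convert$default_rt_width,
                                  charges = config$convert$charges)
  scan_sim <- simulate_scans(truth, config$sim)
  quant <- quantify_analytes(scan_sim$scans, analytes, config$quant)
  list(truth = truth, sim = sim, identification = idres, scores = scores,
       analytes = analytes, scan_sim = scan_sim, quant = quant)
}
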