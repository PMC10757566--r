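# Tabular and JSON interfaces: waveform CSV, RCR JSON, cohort CSV,
# convergence CSV, pipeline configuration.

#' Read and write waveform CSV files
#'
#' Two-column CSV with header `time_s,flow_cm3_s`; one cardiac cycle,
#' time starting at 0 and ending at the period.
#'
#' @param wf a [waveform()].
#' @param path file path.
#' @return `write_waveform_csv()` returns `path` invisibly;
#'   `read_waveform_csv()` returns a [waveform()].
#' @export
write_waveform_csv <- function(wf, path) {
  stopifnot(inherits(wf, "waveform"))
  utils::write.csv(data.frame(time_s = sprintf("%.17g", wf$time),
                              flow_cm3_s = sprintf("%.17g", wf$flow)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("time_s", "flow_cm3_s") %in% names(tab))) {
    stop("waveform CSV must have columns time_s, flow_cm3_s",
         call. = FALSE)
  }
  waveform(as.numeric(tab$time_s), as.numeric(tab$flow_cm3_s))
}

#' Read and write RCR parameter sets as JSON
#'
#' JSON serialization with explicit units: resistances in
#' dyne s/cm^5, capacitances in cm^5/dyne, reference pressure in
#' dyne/cm^2.
#'
#' @param rcr an [rcr_set()].
#' @param path file path.
#' @return `write_rcr_json()` returns `path` invisibly;
#'   `read_rcr_json()` returns an [rcr_set()].
#' @export
write_rcr_json <- function(rcr, path) {
  stopifnot(inherits(rcr, "rcr_set"))
  obj <- list(units = list(resistance = "dyne.s/cm^5",
                           capacitance = "cm^5/dyne",
                           pressure = "dyne/cm^2"),
              R_p = rcr$R_p, C = rcr$C, R_d = rcr$R_d,
              P_ref = rcr$P_ref,
              proximal_fraction = rcr$proximal_fraction)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_rcr_json
#' @export
read_rcr_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rcr_set(obj$R_p, obj$C, obj$R_d, P_ref = obj$P_ref)
}

#' Read and write matched-pair cohort tables as CSV
#'
#' Columns: `pair_id`, `group` (stable/growing), `location`, then one
#' column per metric named as in [shear_metric_names()].
#'
#' @param cohort a `paired_cohort` data.frame.
#' @param path file path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a `paired_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "group")
  if (!all(need %in% names(tab))) {
    stop("cohort CSV must have columns pair_id and group", call. = FALSE)
  }
  if (!all(tab$group %in% c("stable", "growing"))) {
    stop("cohort group labels must be 'stable' or 'growing'",
         call. = FALSE)
  }
  class(tab) <- c("paired_cohort", "data.frame")
  tab
}

#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end pipeline with
#' physiological defaults: blood density/viscosity, inflow waveform
#' parameters, pressure targets and 1:9 proximal:distal split for the
#' outlet tuning, low-shear thresholds {50, 70, 90}%, the 5%
#' convergence tolerances, the 0.1 significance level, and the
#' synthetic model/cohort parameters.
#'
#' @param fluid list: `density`, `viscosity` (see
#'   [fluid_properties()]).
#' @param waveform list: `mean_flow`, `pulsatility_index`,
#'   `heart_rate`, `n_harmonics`.
#' @param outlet_areas_cm2 per-outlet areas in cm^2.
#' @param tuning list: `systolic_mmHg`, `diastolic_mmHg`, `tol`,
#'   `proximal_fraction`, `P_ref`, `max_iter`.
#' @param metrics list: `thresholds` (MTLSA percents, ascending),
#'   `lsa_sd_mult`.
#' @param convergence list: `tol`, `factor`, `n_refinements`.
#' @param stats list: `alpha`, `zero_method`.
#' @param patient named list of [patient_spec()] arguments.
#' @param cohort list: `n_pairs`, `effect`, `effect_metric`,
#'   `noise_sd`.
#' @param seed integer master seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(fluid = list(),
                            waveform = list(),
                            outlet_areas_cm2 = c(0.05, 0.03),
                            tuning = list(),
                            metrics = list(),
                            convergence = list(),
                            stats = list(),
                            patient = list(),
                            cohort = list(),
                            seed = 1L) {
  merge_defaults <- function(given, defaults) {
    utils::modifyList(defaults, as.list(given))
  }
  cfg <- list(
    fluid = merge_defaults(fluid, list(density = 1.06, viscosity = 0.04)),
    waveform = merge_defaults(waveform, list(
      mean_flow = 4.0, pulsatility_index = 1.0, heart_rate = 60,
      n_harmonics = 4L)),
    outlet_areas_cm2 = as.numeric(outlet_areas_cm2),
    tuning = merge_defaults(tuning, list(
      systolic_mmHg = 120, diastolic_mmHg = 80, tol = 0.05,
      proximal_fraction = 0.1, P_ref = 0, max_iter = 100L)),
    metrics = merge_defaults(metrics, list(
      thresholds = c(50, 70, 90), lsa_sd_mult = 1)),
    convergence = merge_defaults(convergence, list(
      tol = 0.05, factor = 0.9, n_refinements = 4L)),
    stats = merge_defaults(stats, list(alpha = 0.1,
                                       zero_method = "wilcox")),
    patient = as.list(patient),
    cohort = merge_defaults(cohort, list(
      n_pairs = 11L, effect = 0, effect_metric = "MTLSA_70",
      noise_sd = NULL)),
    seed = as.integer(seed))
  for (tl in c(cfg$tuning$tol, cfg$convergence$tol)) {
    if (!is.numeric(tl) || tl <= 0 || tl >= 1) {
      stop("tolerances must lie strictly between 0 and 1", call. = FALSE)
    }
  }
  if (cfg$convergence$factor <= 0 || cfg$convergence$factor >= 1) {
    stop("refinement factor must lie strictly between 0 and 1",
         call. = FALSE)
  }
  if (is.unsorted(cfg$metrics$thresholds, strictly = TRUE)) {
    stop("metric thresholds must be sorted ascending", call. = FALSE)
  }
  if (cfg$stats$alpha <= 0 || cfg$stats$alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to the defaults of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  keep <- intersect(names(raw), names(formals(pipeline_config)))
  do.call(pipeline_config, raw[keep])
}
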