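# File interfaces for the ITC stage: YAML experiment descriptions,
# two-column heats CSV, raw trace CSV, and the JSON fit report.

#' Read a titration experiment description
#'
#' YAML keys: `v_cell_ml`, `c_analyte_uM`, `c_lipid_syringe_mM`,
#' `temperature_C`, `injections` (list of uL volumes), `discard_first`,
#' `interval_s`, `heat_unit`.
#'
#' @param path YAML file
#' @param heats per-injection heats for the retained injections; usually
#'   from [read_heats_csv()] or [integrate_peaks()]
#' @return a [titration_experiment()]
#' @export
read_titration_config <- function(path, heats) {
  cfg <- yaml::read_yaml(path)
  need <- c("v_cell_ml", "c_analyte_uM", "c_lipid_syringe_mM", "injections")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) abort_schema(paste("config missing keys:", paste(miss, collapse = ", ")))
  sched <- injection_schedule(
    unlist(cfg$injections),
    discard_first = if (is.null(cfg$discard_first)) TRUE else cfg$discard_first,
    interval_s = if (is.null(cfg$interval_s)) 600 else cfg$interval_s)
  titration_experiment(
    V_cell_mL = cfg$v_cell_ml, C_A0_uM = cfg$c_analyte_uM,
    C_syringe_lipid_mM = cfg$c_lipid_syringe_mM, schedule = sched,
    heats = heats,
    heat_unit = if (is.null(cfg$heat_unit)) "ucal" else cfg$heat_unit,
    temperature_C = if (is.null(cfg$temperature_C)) 26 else cfg$temperature_C)
}

#' Read per-injection heats (CSV: injection_index, heat)
#' @param path CSV file
#' @return numeric heats ordered by injection index
#' @export
read_heats_csv <- function(path) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) abort_schema("heats CSV needs columns (injection_index, heat)")
  d[order(d[[1]]), 2]
}

#' Read a raw power trace (CSV: time_s, power)
#' @param path CSV file
#' @return data frame `(time_s, power)`
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "power") %in% names(d))) {
    abort_schema("trace CSV needs columns (time_s, power)")
  }
  d
}

#' Write a JSON fit report and residuals CSV
#'
#' @param fit a `partition_fit`
#' @param thermo a `thermo_params` for the same fit
#' @param path output JSON path; residuals go to the same stem with
#'   `_residuals.csv`
#' @return `path`, invisibly
#' @export
write_fit_report <- function(fit, thermo, path) {
  report <- list(
    K_mM = fit$K, K_se = fit$K_se, dH_kJ_mol = fit$dH, dH_se = fit$dH_se,
    dG_kJ_mol = thermo$dG, TdS_kJ_mol = thermo$TdS, T_K = thermo$T_K,
    standard_state_factor_M = thermo$standard_state_factor,
    mode = fit$mode, heat_unit = fit$heat_unit, offset = fit$offset,
    converged = fit$converged, residual_norm = fit$residual_norm)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res_path <- sub("\\.json$", "_residuals.csv", path)
  utils::write.csv(
    data.frame(point = seq_along(fit$residuals), fitted = fit$fitted,
               residual = fit$residuals),
    res_path, row.names = FALSE)
  invisible(path)
}
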