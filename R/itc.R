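#' Injection schedule of a titration
#'
#' @param volumes_uL ordered injection volumes in microlitres
#' @param discard_first should the first injection's heat be excluded from
#'   fitting? Its volume still counts toward the concentration bookkeeping.
#'   (Standard practice: a small first injection purges the syringe tip.)
#' @param interval_s spacing between injections in seconds
#' @return an `injection_schedule` list
#' @export
injection_schedule <- function(volumes_uL, discard_first = TRUE, interval_s = 600) {
  check_finite(volumes_uL, "volumes_uL")
  if (any(volumes_uL <= 0)) abort_input("all injection volumes must be > 0")
  check_scalar(interval_s, "interval_s")
  structure(list(volumes_uL = as.numeric(volumes_uL),
                 discard_first = isTRUE(discard_first),
                 interval_s = interval_s),
            class = "injection_schedule")
}

#' The default VP-ITC schedule: one 2 uL purge injection (discarded from
#' fitting) followed by 28 additions of 10 uL at 600 s intervals.
#' @return an [injection_schedule()]
#' @export
default_schedule <- function() injection_schedule(c(2, rep(10, 28)))

retained_injections <- function(schedule) {
  n <- length(schedule$volumes_uL)
  if (schedule$discard_first) seq_len(n)[-1] else seq_len(n)
}

#' Describe one ITC lipid-into-solute titration
#'
#' @param V_cell_mL sample cell volume in mL
#' @param C_A0_uM initial solute (analyte) concentration in the cell, uM
#' @param C_syringe_lipid_mM lipid concentration in the syringe, mM
#' @param schedule an [injection_schedule()]
#' @param heats per-injection heats for the non-discarded injections, in
#'   `heat_unit`
#' @param heat_unit `"ucal"` (VP-ITC convention), `"uJ"` or `"J"`
#' @param temperature_C experiment temperature, deg C
#' @return a `titration_experiment` list
#' @export
titration_experiment <- function(V_cell_mL = 1.4565, C_A0_uM, C_syringe_lipid_mM,
                                 schedule = default_schedule(), heats,
                                 heat_unit = c("ucal", "uJ", "J"),
                                 temperature_C = 26) {
  heat_unit <- match.arg(heat_unit)
  check_scalar(V_cell_mL, "V_cell_mL"); check_scalar(C_A0_uM, "C_A0_uM")
  check_scalar(C_syringe_lipid_mM, "C_syringe_lipid_mM")
  if (V_cell_mL <= 0 || C_A0_uM <= 0 || C_syringe_lipid_mM <= 0) {
    abort_input("cell volume and concentrations must be > 0")
  }
  if (!inherits(schedule, "injection_schedule")) abort_input("schedule must be an injection_schedule")
  check_finite(heats, "heats")
  if (length(heats) != length(retained_injections(schedule))) {
    abort_input(sprintf("got %d heats but schedule retains %d injections",
                        length(heats), length(retained_injections(schedule))))
  }
  structure(list(V_cell_mL = V_cell_mL, C_A0_uM = C_A0_uM,
                 C_syringe_lipid_mM = C_syringe_lipid_mM, schedule = schedule,
                 heats = as.numeric(heats), heat_unit = heat_unit,
                 temperature_C = temperature_C),
            class = "titration_experiment")
}

#' Per-injection cell concentrations
#'
#' Total lipid and solute concentrations in the cell after each injection,
#' under one of three bookkeeping modes:
#' \describe{
#'   \item{naive}{injected volume is ignored for the denominator:
#'     `C_L0(i) = C_syr * sumV_i / V_cell`, solute concentration constant.}
#'   \item{dilution}{(default) the cell is volume-additive: both species are
#'     scaled by `V_cell / (V_cell + sumV_i)` relative to naive. Appropriate
#'     when cumulative injected volume is a substantial fraction of the cell
#'     (default schedule: 282 uL into 1.4565 mL, ~19 percent).}
#'   \item{overfill}{perfusion-cell displacement: each injection expels
#'     premixed cell content; prior concentrations are scaled by
#'     `(1 - v/2V)/(1 + v/2V)` per injection and freshly injected lipid by
#'     `(v/V)/(1 + v/2V)`.}
#' }
#'
#' @param exp a [titration_experiment()] (its `heats` are not consulted)
#' @param mode `"dilution"`, `"naive"`, or `"overfill"`
#' @return data frame `(injection, volume_uL, cum_volume_uL, C_L0_mM, C_A0_uM)`,
#'   one row per injection including any discarded ones
#' @export
concentration_series <- function(exp, mode = c("dilution", "naive", "overfill")) {
  mode <- match.arg(mode)
  vols <- exp$schedule$volumes_uL
  if (length(vols) == 0) abort_input("empty injection schedule")
  V_uL <- exp$V_cell_mL * 1000
  cumv <- cumsum(vols)
  if (max(cumv) > 0.25 * V_uL) {
    warning(sprintf(
      "cumulative injected volume (%.0f uL) exceeds 25%% of the cell (%.0f uL); partition model validity is doubtful",
      max(cumv), V_uL))
  }
  if (mode == "naive") {
    C_L <- exp$C_syringe_lipid_mM * cumv / V_uL
    C_A <- rep(exp$C_A0_uM, length(vols))
  } else if (mode == "dilution") {
    C_L <- exp$C_syringe_lipid_mM * cumv / (V_uL + cumv)
    C_A <- exp$C_A0_uM * V_uL / (V_uL + cumv)
  } else {
    C_L <- C_A <- numeric(length(vols))
    cl <- 0; ca <- exp$C_A0_uM
    for (i in seq_along(vols)) {
      f <- (1 - vols[i] / (2 * V_uL)) / (1 + vols[i] / (2 * V_uL))
      cl <- cl * f + exp$C_syringe_lipid_mM * (vols[i] / V_uL) / (1 + vols[i] / (2 * V_uL))
      ca <- ca * f
      C_L[i] <- cl; C_A[i] <- ca
    }
  }
  data.frame(injection = seq_along(vols), volume_uL = vols,
             cum_volume_uL = cumv, C_L0_mM = C_L, C_A0_uM = C_A)
}

#' Cumulative-heat partition isotherm
#'
#' The one-site partition model for lipid-into-solute titrations: after `i`
#' injections the cumulative heat released is
#' `sum(dh_k) = dH * V_cell * C_A0(i) * K*C_L0(i) / (1 + K*C_L0(i))`
#' where `K` is the partition constant and `dH` the molar transfer enthalpy
#' of the solute from water to the bilayer. Saturation plateau
#' `dH * V_cell * C_A0`; half-saturation at `C_L0 = 1/K`.
#'
#' @param K_mM partition constant, mM^-1 (> 0)
#' @param dH_kJ_mol molar transfer enthalpy, kJ/mol
#' @param V_cell_mL cell volume, mL
#' @param C_A0_uM solute concentration(s) in the cell, uM (vectorized)
#' @param C_L0_mM lipid concentration(s) in the cell, mM (vectorized)
#' @param heat_unit unit of the returned heats
#' @return cumulative heat(s) in `heat_unit`
#' @export
cumulative_heat_model <- function(K_mM, dH_kJ_mol, V_cell_mL, C_A0_uM, C_L0_mM,
                                  heat_unit = c("ucal", "uJ", "J")) {
  heat_unit <- match.arg(heat_unit)
  check_scalar(K_mM, "K_mM")
  if (K_mM <= 0) abort_input("K must be > 0")
  check_scalar(dH_kJ_mol, "dH_kJ_mol"); check_scalar(V_cell_mL, "V_cell_mL")
  x <- K_mM * C_L0_mM
  heat_J <- (dH_kJ_mol * 1000) * (V_cell_mL * 1e-3) * (C_A0_uM * 1e-6) * x / (1 + x)
  heat_J / .heat_unit_to_J[[heat_unit]]
}

#' Integrate per-injection heats from a raw power trace
#'
#' Each inter-injection window `[t_i, t_i + interval)` is baseline-corrected
#' and integrated (trapezoid rule). Baseline per window: `"median"` uses the
#' window's median power (robust when the peak occupies a minority of the
#' window); `"linear"` fits a line through the first and last 10 percent of
#' the window's samples.
#'
#' @param trace data frame `(time_s, power)`; power in heat-unit per second
#' @param schedule an [injection_schedule()] giving injection count and
#'   spacing
#' @param baseline_mode `"linear"` or `"median"`
#' @param t0 time of the first injection, s
#' @return per-injection heats (same unit basis as `power * time`), for all
#'   injections including any discarded ones
#' @export
integrate_peaks <- function(trace, schedule, baseline_mode = c("linear", "median"),
                            t0 = 0) {
  baseline_mode <- match.arg(baseline_mode)
  if (!all(c("time_s", "power") %in% names(trace))) {
    abort_schema("trace needs columns time_s, power")
  }
  check_finite(trace$time_s, "time_s"); check_finite(trace$power, "power")
  n <- length(schedule$volumes_uL)
  dt <- schedule$interval_s
  starts <- t0 + (seq_len(n) - 1) * dt
  vapply(seq_len(n), function(i) {
    sel <- trace$time_s >= starts[i] & trace$time_s < starts[i] + dt
    if (sum(sel) < 2) {
      abort_missing_data(sprintf(
        "injection %d window [%g, %g) has %d trace points; trace does not cover the schedule",
        i, starts[i], starts[i] + dt, sum(sel)))
    }
    tt <- trace$time_s[sel]; pp <- trace$power[sel]
    base <- if (baseline_mode == "median") {
      rep(stats::median(pp), length(pp))
    } else {
      k <- max(2, ceiling(0.1 * length(pp)))
      edge <- c(seq_len(k), length(pp) - seq_len(k) + 1)
      cf <- stats::coef(stats::lm(pp[edge] ~ tt[edge]))
      cf[1] + cf[2] * tt
    }
    y <- pp - base
    sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }, numeric(1))
}

#' Fit the partition isotherm to observed heats
#'
#' Least-squares fit of the observed cumulative heats against
#' [cumulative_heat_model()] over `(K, dH)`. The first (discarded)
#' injection's heat is excluded but its volume counts in the concentration
#' bookkeeping, so the model is referenced to the cumulative heat already
#' evolved at the end of the discarded injections. `K` is constrained
#' positive through a log parameterization; an optional constant offset
#' absorbs a heat-of-dilution background. Initialization: `dH0` from the
#' final-plateau estimate, `K0` as the reciprocal of the lipid concentration
#' nearest half-plateau.
#'
#' @param exp a [titration_experiment()]
#' @param mode concentration bookkeeping mode, see [concentration_series()]
#' @param weights optional per-point weights (inverse-variance); default
#'   unit weights
#' @param offset fit a constant heat offset? default `FALSE`
#' @return a `partition_fit` list: `K` (mM^-1), `dH` (kJ/mol), `K_se`,
#'   `dH_se`, `residual_norm`, `converged`, `mode`, `heat_unit`, `offset`,
#'   `fitted`, `residuals`, `series`
#' @export
fit_partition <- function(exp, mode = c("dilution", "naive", "overfill"),
                          weights = NULL, offset = FALSE) {
  mode <- match.arg(mode)
  keep <- retained_injections(exp$schedule)
  if (length(keep) < 5) abort_input("need at least 5 non-discarded injections")
  series <- concentration_series(exp, mode)
  obs_cum <- cumsum(exp$heats)
  unit <- exp$heat_unit
  V <- exp$V_cell_mL
  n_discard <- min(keep) - 1

  model_cum <- function(K, dH) {
    m <- cumulative_heat_model(K, dH, V, series$C_A0_uM, series$C_L0_mM, unit)
    ref <- if (n_discard > 0) m[n_discard] else 0
    m[keep] - ref
  }

  # initialization from the data
  plateau <- obs_cum[length(obs_cum)]
  half_i <- which.min(abs(obs_cum - plateau / 2))
  K0 <- 1 / series$C_L0_mM[keep[half_i]]
  xl <- K0 * series$C_L0_mM[keep[length(keep)]]
  dH0 <- plateau * .heat_unit_to_J[[unit]] * (1 + xl) / xl /
    ((V * 1e-3) * (series$C_A0_uM[keep[length(keep)]] * 1e-6)) / 1000
  failed_fit <- function(msg) {
    warning(paste("partition fit did not converge:", msg))
    structure(list(K = K0, dH = if (is.finite(dH0)) dH0 else 0,
                   K_se = NA_real_, dH_se = NA_real_,
                   residual_norm = sqrt(sum(obs_cum^2)), converged = FALSE,
                   mode = mode, heat_unit = unit, offset = offset,
                   fitted = rep(NA_real_, length(keep)),
                   residuals = rep(NA_real_, length(keep)), series = series),
              class = "partition_fit")
  }
  if (!is.finite(dH0) || dH0 == 0) return(failed_fit("degenerate plateau estimate"))

  d <- data.frame(y = obs_cum)
  w <- if (is.null(weights)) rep(1, nrow(d)) else weights
  form <- if (offset) y ~ model_cum(exp(lk), dH) + c0 else y ~ model_cum(exp(lk), dH)
  start <- list(lk = log(K0), dH = dH0)
  if (offset) start$c0 <- 0
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = d, start = start, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(failed_fit("optimizer error"))

  cf <- stats::coef(fit)
  K <- exp(cf[["lk"]]); dH <- cf[["dH"]]
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  res <- stats::residuals(fit)
  sd_est <- stats::sd(res)
  # flag decreases the fitted model itself does not predict (a high-K
  # titration under dilution bookkeeping legitimately tails downward);
  # judged on the increment scale so injection-level noise sets the bar
  excess <- diff(obs_cum) - diff(stats::fitted(fit))
  sd_inc <- stats::sd(excess)
  if (is.finite(sd_inc) && sd_inc > 0 && any(excess < -4 * sd_inc)) {
    warning("an injection heat falls more than 4 sd below the fitted curve; check data")
  }
  structure(list(K = K, dH = dH,
                 K_se = unname(K * se[["lk"]]), dH_se = unname(se[["dH"]]),
                 residual_norm = sqrt(sum(res^2)),
                 converged = isTRUE(fit$convInfo$isConv),
                 mode = mode, heat_unit = unit, offset = offset,
                 fitted = stats::fitted(fit), residuals = res, series = series),
            class = "partition_fit")
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("Partition fit (%s mode, %s): %s\n", x$mode, x$heat_unit,
              if (x$converged) "converged" else "NOT CONVERGED"))
  cat(sprintf("  K  = %.4g +/- %.2g mM^-1\n", x$K, x$K_se))
  cat(sprintf("  dH = %.4g +/- %.2g kJ/mol\n", x$dH, x$dH_se))
  cat(sprintf("  residual norm = %.3g %s over %d points\n",
              x$residual_norm, x$heat_unit, length(x$fitted)))
  invisible(x)
}

#' Thermodynamic decomposition of a partition constant
#'
#' Converts a fitted partition constant and enthalpy into the transfer free
#' energy and entropic term:
#' `dG = -R*T*ln(f * K[M^-1])`, `TdS = dH - dG`,
#' where `f` is the mole-fraction standard-state factor (55.5 M, the
#' molarity of water, by default) making the argument of the logarithm
#' dimensionless.
#'
#' @param K_mM partition constant in mM^-1, or a `partition_fit`
#' @param dH_kJ_mol molar transfer enthalpy, kJ/mol (ignored when `K_mM` is
#'   a fit)
#' @param T_K absolute temperature, K
#' @param standard_state_factor mole-fraction correction, M; default 55.5
#' @return a `thermo_params` list: `dG`, `TdS`, `dH` (kJ/mol), `T_K`,
#'   `standard_state_factor`, `K_mM`
#' @export
derive_thermodynamics <- function(K_mM, dH_kJ_mol = NULL, T_K = 299.15,
                                  standard_state_factor = WATER_MOLARITY) {
  if (inherits(K_mM, "partition_fit")) {
    fit <- K_mM
    K_mM <- fit$K
    if (is.null(dH_kJ_mol)) dH_kJ_mol <- fit$dH
  }
  check_scalar(K_mM, "K_mM"); check_scalar(dH_kJ_mol, "dH_kJ_mol")
  check_scalar(T_K, "T_K")
  if (K_mM <= 0) abort_input("K must be > 0")
  if (T_K <= 0) abort_input("T must be > 0 K")
  K_M <- K_mM * 1000
  dG <- -GAS_CONSTANT_KJ * T_K * log(standard_state_factor * K_M)
  structure(list(dG = dG, TdS = dH_kJ_mol - dG, dH = dH_kJ_mol, T_K = T_K,
                 standard_state_factor = standard_state_factor, K_mM = K_mM),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("Transfer thermodynamics at %.2f K (standard state %.1f M):\n",
              x$T_K, x$standard_state_factor))
  cat(sprintf("  K   = %.4g mM^-1\n  dH  = %+.3f kJ/mol\n  dG  = %+.3f kJ/mol\n  TdS = %+.3f kJ/mol\n",
              x$K_mM, x$dH, x$dG, x$TdS))
  invisible(x)
}
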