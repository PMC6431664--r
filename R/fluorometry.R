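#' Subtract a blank intensity from a sample intensity
#'
#' Fluorescence intensities are always blank-corrected before any ratio is
#' formed. The result may be negative (an over-subtracted blank); negative
#' corrected intensities are passed through here and rejected, with a named
#' error, by the downstream ratio functions whose preconditions they break,
#' so instrument problems surface instead of being clipped.
#'
#' @param sample_intensity sample emission intensity (arbitrary units)
#' @param blank_intensity matched blank emission intensity (same units)
#' @return blank-subtracted intensity; vectorized
#' @export
blank_subtract <- function(sample_intensity, blank_intensity) {
  check_finite(sample_intensity, "sample_intensity")
  check_finite(blank_intensity, "blank_intensity")
  sample_intensity - blank_intensity
}

#' Laurdan generalized polarization
#'
#' `GP = (I440 - I490) / (I440 + I490)` from blank-subtracted emission
#' intensities at 440 nm (gel-phase band) and 490 nm (fluid-phase band).
#' GP is high (toward +1) for ordered, dehydrated headgroup interfaces and
#' low for fluid ones.
#'
#' @param I440,I490 blank-subtracted emission intensities; vectorized
#' @return GP, dimensionless; in `[-1, 1]` whenever both intensities are
#'   non-negative
#' @export
generalized_polarization <- function(I440, I490) {
  check_finite(I440, "I440")
  check_finite(I490, "I490")
  denom <- I440 + I490
  if (any(denom <= 0)) {
    abort_degenerate("I440 + I490 must be > 0 for GP to be defined")
  }
  (I440 - I490) / denom
}

#' Instrumental G-factor from horizontally excited intensities
#'
#' `G = I_HV / I_HH` corrects the emission channel's polarization bias.
#' Measured per sample quadruplet (no global instrument constant is
#' assumed).
#'
#' @param I_HV,I_HH blank-subtracted intensities, excitation polarizer
#'   horizontal, emission polarizer vertical/horizontal; vectorized
#' @return G, dimensionless, positive for physical signals
#' @export
g_factor <- function(I_HV, I_HH) {
  check_finite(I_HV, "I_HV")
  check_finite(I_HH, "I_HH")
  if (any(I_HH <= 0)) abort_degenerate("I_HH must be > 0 for the G-factor")
  I_HV / I_HH
}

#' DPH fluorescence anisotropy from a polarized intensity quadruplet
#'
#' `r = (I_VV - G * I_VH) / (I_VV + 2 * G * I_VH)` with the G-factor taken
#' from the same quadruplet's horizontally excited pair. High `r` means a
#' rigid (viscous) probe environment in the bilayer hydrophobic core.
#'
#' @param I_VV,I_VH,I_HV,I_HH blank-subtracted intensities; subscripts give
#'   excitation then emission polarizer orientation; vectorized
#' @return data frame with columns `r` and `G`
#' @export
anisotropy <- function(I_VV, I_VH, I_HV, I_HH) {
  check_finite(I_VV, "I_VV")
  check_finite(I_VH, "I_VH")
  G <- g_factor(I_HV, I_HH)
  denom <- I_VV + 2 * G * I_VH
  if (any(denom <= 0)) {
    abort_degenerate("I_VV + 2*G*I_VH must be > 0 for anisotropy")
  }
  data.frame(r = (I_VV - G * I_VH) / denom, G = G)
}

#' Build a GP-versus-temperature curve from replicated intensities
#'
#' Replicate shots at each temperature are averaged at the intensity level
#' before the GP ratio is formed (ratio of means, matching how blanks are
#' subtracted at the intensity level); the per-shot alternative (mean of
#' ratios) is available via `average = "per_shot"`. The reported `sd` is
#' the standard deviation of the per-shot GP values, describing shot
#' dispersion at that temperature.
#'
#' @param measurements data frame with columns `temperature_C`, `I440`,
#'   `I490` (blank-subtracted), one row per shot
#' @param composition_label optional label for the liposome composition
#' @param average `"intensity"` (default, ratio of means) or `"per_shot"`
#' @return a `gp_curve`: data frame `(temperature_C, GP, sd, n)` sorted by
#'   temperature, with attribute `composition_label`
#' @export
build_gp_curve <- function(measurements, composition_label = NA_character_,
                           average = c("intensity", "per_shot")) {
  average <- match.arg(average)
  need <- c("temperature_C", "I440", "I490")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements))) {
    abort_schema("measurements needs columns temperature_C, I440, I490")
  }
  if (nrow(measurements) < 1) abort_input("at least one measurement required")
  check_finite(measurements$I440, "I440")
  check_finite(measurements$I490, "I490")

  pieces <- lapply(split(measurements, measurements$temperature_C), function(d) {
    shot_ok <- all(d$I440 + d$I490 > 0)
    gp_shot <- if (shot_ok) (d$I440 - d$I490) / (d$I440 + d$I490) else NA_real_
    gp <- if (average == "intensity") {
      generalized_polarization(mean(d$I440), mean(d$I490))
    } else {
      if (!shot_ok) abort_degenerate("per-shot GP undefined: I440 + I490 <= 0")
      mean(gp_shot)
    }
    sdev <- if (shot_ok && nrow(d) > 1) stats::sd(gp_shot) else if (nrow(d) == 1) 0 else NA_real_
    data.frame(temperature_C = d$temperature_C[1], GP = gp, sd = sdev, n = nrow(d))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$temperature_C), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("gp_curve", "data.frame"),
            composition_label = composition_label)
}

#' Estimate the phase-transition temperature from a GP melting curve
#'
#' Fits the descending four-parameter logistic
#' `GP(T) = GP_fluid + (GP_gel - GP_fluid) / (1 + exp((T - Tm)/width))`
#' whose midpoint is the gel-to-fluid transition temperature Tm. A
#' model-free fallback (`method = "derivative"`) reports the temperature of
#' steepest finite-difference descent instead of fitting.
#'
#' A curve whose GP range does not exceed `range_threshold` carries no
#' detectable transition and is rejected with a no-transition error rather
#' than extrapolated.
#'
#' @param curve a [build_gp_curve()] result, or any data frame with columns
#'   `temperature_C` and `GP`
#' @param range_threshold minimum GP range (max - min) required to attempt
#'   an estimate; default 0.2
#' @param method `"logistic"` (default) or `"derivative"`
#' @return a `tm_estimate` list: `Tm`, `width` (both deg C), `GP_gel`,
#'   `GP_fluid`, `fit_residual` (RMS of fit residuals; `NA` for the
#'   derivative method), `method`
#' @export
estimate_tm <- function(curve, range_threshold = 0.2,
                        method = c("logistic", "derivative")) {
  method <- match.arg(method)
  d <- as.data.frame(curve)[, c("temperature_C", "GP")]
  d <- d[order(d$temperature_C), ]
  if (nrow(d) < 4) abort_input("need at least 4 temperatures to locate a transition")
  if (anyDuplicated(d$temperature_C)) abort_schema("duplicate temperatures in curve")
  rng <- diff(range(d$GP))
  if (!is.finite(rng) || rng <= range_threshold) {
    abort_no_transition(sprintf(
      "GP range %.3g does not exceed threshold %.3g: no melting transition in range",
      rng, range_threshold))
  }

  # model-free initial estimate: steepest descending finite difference
  slope <- diff(d$GP) / diff(d$temperature_C)
  i <- which.min(slope)
  if (slope[i] >= 0) abort_no_transition("no descending segment: curve does not melt")
  tm0 <- mean(d$temperature_C[i + 0:1])
  gel0 <- max(d$GP)
  fluid0 <- min(d$GP)
  width0 <- min(max((gel0 - fluid0) / (4 * abs(slope[i])), 1e-3),
                diff(range(d$temperature_C)))

  if (method == "derivative") {
    return(structure(list(Tm = tm0, width = width0, GP_gel = gel0,
                          GP_fluid = fluid0, fit_residual = NA_real_,
                          method = method),
                     class = "tm_estimate"))
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      GP ~ fluid + (gel - fluid) / (1 + exp((temperature_C - Tm) / w)),
      data = d,
      start = list(fluid = fluid0, gel = gel0, Tm = tm0, w = width0),
      lower = c(fluid = -1, gel = -1, Tm = min(d$temperature_C), w = 1e-4),
      upper = c(fluid = 1, gel = 1, Tm = max(d$temperature_C),
                w = diff(range(d$temperature_C))),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("logistic fit failed; returning derivative-based estimate")
    return(estimate_tm(d, range_threshold, method = "derivative"))
  }
  cf <- stats::coef(fit)
  if (cf[["gel"]] <= cf[["fluid"]]) {
    abort_no_transition("fitted plateaus are not gel > fluid: no melting transition")
  }
  structure(list(Tm = unname(cf[["Tm"]]), width = unname(cf[["w"]]),
                 GP_gel = unname(cf[["gel"]]), GP_fluid = unname(cf[["fluid"]]),
                 fit_residual = sqrt(mean(stats::residuals(fit)^2)),
                 method = method),
            class = "tm_estimate")
}

#' @export
print.tm_estimate <- function(x, ...) {
  cat(sprintf("Phase transition estimate (%s):\n  Tm = %.3f degC, width = %.3f degC\n",
              x$method, x$Tm, x$width))
  cat(sprintf("  GP plateaus: gel %.3f -> fluid %.3f", x$GP_gel, x$GP_fluid))
  if (is.finite(x$fit_residual)) cat(sprintf("  (rms residual %.2g)", x$fit_residual))
  cat("\n")
  invisible(x)
}

#' @export
print.gp_curve <- function(x, ...) {
  lbl <- attr(x, "composition_label")
  cat("GP melting curve", if (!is.na(lbl)) paste0("[", lbl, "]"), "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}
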