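test_that("naive concentration bookkeeping matches hand arithmetic", {
  exp1 <- titration_experiment(
    V_cell_mL = 1.4565, C_A0_uM = 500, C_syringe_lipid_mM = 5,
    schedule = injection_schedule(10, discard_first = FALSE), heats = 0)
  s1 <- concentration_series(exp1, mode = "naive")
  expect_equal(s1$C_L0_mM, 5 * 10 / 1456.5)
  expect_equal(s1$C_A0_uM, 500)

  exp29 <- titration_experiment(
    V_cell_mL = 1.4565, C_A0_uM = 500, C_syringe_lipid_mM = 5,
    schedule = default_schedule(), heats = rep(1, 28))
  s29 <- concentration_series(exp29, mode = "naive")
  # independent arithmetic over the printed schedule: 2 + 28 x 10 uL
  expect_equal(s29$cum_volume_uL[29], 2 + 28 * 10)
  expect_equal(s29$C_L0_mM[29], 5 * 282 / 1456.5)
  expect_true(all(diff(s29$C_L0_mM) > 0))
})

test_that("dilution mode scales both species by the volume ratio", {
  exp29 <- titration_experiment(
    V_cell_mL = 1.4565, C_A0_uM = 500, C_syringe_lipid_mM = 5,
    schedule = default_schedule(), heats = rep(1, 28))
  nai <- concentration_series(exp29, mode = "naive")
  dil <- concentration_series(exp29, mode = "dilution")
  f <- 1456.5 / (1456.5 + nai$cum_volume_uL)
  expect_equal(dil$C_L0_mM, nai$C_L0_mM * f)
  expect_equal(dil$C_A0_uM, nai$C_A0_uM * f)
  expect_true(all(diff(dil$C_A0_uM) < 0))

  ovf <- concentration_series(exp29, mode = "overfill")
  expect_true(all(diff(ovf$C_L0_mM) > 0))
  expect_true(all(diff(ovf$C_A0_uM) < 0))
})

test_that("empty or oversized schedules are rejected or flagged", {
  expect_memprobe_error(injection_schedule(numeric(0)), "memprobe_input_error")
  expect_memprobe_error(injection_schedule(c(10, 0)), "memprobe_input_error")
  big <- titration_experiment(
    V_cell_mL = 1, C_A0_uM = 100, C_syringe_lipid_mM = 5,
    schedule = injection_schedule(rep(50, 6), discard_first = FALSE),
    heats = rep(1, 6))
  expect_warning(concentration_series(big), "25%")
})

test_that("the cumulative-heat model obeys its closed form and limits", {
  # hand oracle: K=2 mM^-1, dH=1 kJ/mol, V=1 mL, C_A0=100 uM, C_L0=0.5 mM
  # -> 1000 J/mol * 1e-3 L * 1e-4 M * (1/2) = 5e-5 J = 50 uJ
  expect_equal(cumulative_heat_model(2, 1, 1, 100, 0.5, heat_unit = "uJ"), 50)
  expect_equal(cumulative_heat_model(2, 1, 1, 100, 0.5, heat_unit = "J"), 5e-5)
  # unit conversion: 1 cal = 4.184 J
  expect_equal(cumulative_heat_model(2, 1, 1, 100, 0.5, heat_unit = "ucal"),
               50 / 4.184)

  # saturation plateau and half-saturation (machine precision)
  plateau <- 1 * 1e-3 * 100e-6 * 1000  # dH * V * C_A0 in J
  sat <- cumulative_heat_model(2, 1, 1, 100, 1e9, heat_unit = "J")
  expect_equal(sat, plateau, tolerance = 1e-8)
  half <- cumulative_heat_model(2, 1, 1, 100, 1 / 2, heat_unit = "J")
  expect_equal(half, plateau / 2, tolerance = 1e-14)
  expect_memprobe_error(cumulative_heat_model(-1, 1, 1, 100, 0.5),
                        "memprobe_input_error")
})

test_that("the model is strictly increasing in lipid concentration", {
  cl <- seq(0.01, 2, length.out = 50)
  h <- cumulative_heat_model(1.69, 1.47, 1.4565, 75, cl)
  expect_true(all(diff(h) > 0))
})

test_that("peak integration recovers rectangular pulse areas", {
  sched <- injection_schedule(c(10, 10), discard_first = FALSE, interval_s = 600)
  tt <- seq(0, 1199, by = 1)
  pulse <- function(t0) as.numeric(tt >= t0 & tt < t0 + 30) * 2
  trace <- data.frame(time_s = tt, power = pulse(100) + pulse(700))
  h <- integrate_peaks(trace, sched, baseline_mode = "median")
  expect_equal(h, c(60, 60), tolerance = 0.05)
  # constant baseline of 1 is removed by both baseline modes
  trace$power <- trace$power + 1
  expect_equal(integrate_peaks(trace, sched, baseline_mode = "median"),
               c(60, 60), tolerance = 0.05)
  expect_equal(integrate_peaks(trace, sched, baseline_mode = "linear"),
               c(60, 60), tolerance = 0.05)
  # trace shorter than the schedule
  expect_memprobe_error(
    integrate_peaks(trace[tt < 500, ], sched, baseline_mode = "median"),
    "memprobe_missing_data_error")
})

test_that("noiseless round trips recover the generating parameters", {
  ref <- reference_compounds()
  for (i in seq_len(nrow(ref))) {
    sim <- gen_itc_thermogram(ref$K_mM[i], ref$dH[i],
                              C_A0_uM = ref$C_A0_uM[i],
                              C_syringe_lipid_mM = ref$C_syr_mM[i])
    fit <- fit_partition(sim$experiment)
    expect_true(fit$converged)
    expect_lt(abs(fit$K / ref$K_mM[i] - 1), 1e-3)
    expect_lt(abs(fit$dH / ref$dH[i] - 1), 1e-3)
    expect_true(is.finite(fit$K_se) && is.finite(fit$dH_se))
  }
})

test_that("fit mode must match the generating bookkeeping to be exact", {
  sim <- gen_itc_thermogram(1.69, 1.47, C_A0_uM = 75, C_syringe_lipid_mM = 5,
                            mode = "naive")
  fit <- fit_partition(sim$experiment, mode = "naive")
  expect_lt(abs(fit$K / 1.69 - 1), 1e-6)
})

test_that("constant-zero heats yield a flagged non-convergent fit", {
  exp0 <- titration_experiment(
    V_cell_mL = 1.4565, C_A0_uM = 75, C_syringe_lipid_mM = 5,
    schedule = default_schedule(), heats = rep(0, 28))
  expect_warning(fit <- fit_partition(exp0), "converge")
  expect_false(fit$converged)
  expect_equal(fit$dH, 0, tolerance = 1e-9)
})

test_that("doubling cell and injection volumes preserves K and doubles heats", {
  sched1 <- injection_schedule(c(2, rep(10, 20)))
  sched2 <- injection_schedule(c(4, rep(20, 20)))
  s1 <- gen_itc_thermogram(1.69, 1.47, V_cell_mL = 1.4565, C_A0_uM = 75,
                           C_syringe_lipid_mM = 5, schedule = sched1)
  s2 <- gen_itc_thermogram(1.69, 1.47, V_cell_mL = 2.913, C_A0_uM = 75,
                           C_syringe_lipid_mM = 5, schedule = sched2)
  expect_equal(s2$experiment$heats, 2 * s1$experiment$heats, tolerance = 1e-12)
  f1 <- fit_partition(s1$experiment)
  f2 <- fit_partition(s2$experiment)
  expect_equal(f2$K, f1$K, tolerance = 1e-6)
  expect_equal(f2$dH, f1$dH, tolerance = 1e-6)
})

test_that("thermodynamic decomposition matches the published table rows", {
  ref <- reference_compounds()
  for (i in seq_len(nrow(ref))) {
    th <- derive_thermodynamics(ref$K_mM[i], ref$dH[i], T_K = 299.15)
    expect_lt(abs(th$dG - ref$dG[i]), ref$dG_unc[i])
    # internal identity holds to machine precision
    expect_equal(th$dH - th$TdS, th$dG, tolerance = 1e-12)
    # published rows are self-consistent to printed rounding
    expect_lt(abs((ref$dH[i] - ref$TdS[i]) - ref$dG[i]), 0.02 + 1e-9)
  }
})

test_that("the standard-state boundary gives zero free energy", {
  th <- derive_thermodynamics(1 / 55.5 / 1000, 2, T_K = 299.15)
  expect_equal(th$dG, 0, tolerance = 1e-12)
  expect_equal(th$TdS, 2, tolerance = 1e-12)
  expect_memprobe_error(derive_thermodynamics(-1, 2), "memprobe_input_error")
})

test_that("experiment configs and heats round-trip through files", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "exp.yaml")
  yaml::write_yaml(list(
    v_cell_ml = 1.4565, c_analyte_uM = 75, c_lipid_syringe_mM = 1,
    temperature_C = 26, injections = c(2, rep(10, 28)),
    discard_first = TRUE, interval_s = 600, heat_unit = "ucal"), cfg)
  sim <- gen_itc_thermogram(28.5, 1.79, C_A0_uM = 75, C_syringe_lipid_mM = 1)
  hp <- file.path(dir, "heats.csv")
  utils::write.csv(data.frame(injection_index = seq_along(sim$experiment$heats),
                              heat = sim$experiment$heats), hp, row.names = FALSE)
  exp <- read_titration_config(cfg, read_heats_csv(hp))
  expect_s3_class(exp, "titration_experiment")
  expect_equal(exp$heats, sim$experiment$heats)

  fit <- fit_partition(exp)
  th <- derive_thermodynamics(fit)
  out <- file.path(dir, "fit.json")
  write_fit_report(fit, th, out)
  parsed <- jsonlite::read_json(out)
  expect_equal(parsed$K_mM, fit$K, tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "fit_residuals.csv")))
})
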