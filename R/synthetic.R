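# Seeded generators emulating each experiment's raw data, in exactly the
# dialects the analysis stages read. Each generator is the exact inverse of
# its analysis stage in the noiseless limit.

#' Generate a laurdan GP melting-curve plate
#'
#' Emits replicated em440/em490 intensities (plus matched blanks) whose
#' underlying GP follows a descending logistic in temperature:
#' `GP(T) = GP_fluid + (GP_gel - GP_fluid)/(1 + exp((T - Tm)/width))`.
#' Per-shot Gaussian noise is applied on the GP scale (and clamped to the
#' physical `[-1, 1]` range) before conversion back to a 440/490 intensity
#' pair of fixed total intensity, so the noiseless output round-trips
#' exactly through [gp_table()].
#'
#' @param Tm,width logistic midpoint and width, deg C
#' @param GP_gel,GP_fluid plateau GP values (gel > fluid for a melting
#'   transition)
#' @param temperatures temperature grid, deg C; should span `Tm`
#' @param replicates shots per temperature (instrument protocol: at least 12)
#' @param total_intensity I440 + I490 of each shot, arbitrary units
#' @param gp_noise_sd per-shot Gaussian noise on the GP scale
#' @param blank_em440,blank_em490 blank intensities added to the sample
#'   signal and emitted as matched blank rows
#' @param sample_id sample label
#' @param seed optional RNG seed (same seed, byte-identical output)
#' @return a plate-schema data frame (see [read_plate()])
#' @export
gen_gp_curve <- function(Tm = 41.5, width = 0.7, GP_gel = 0.6, GP_fluid = -0.2,
                         temperatures = c(31, 35, 38, 40, 41, 42, 43, 44, 46, 49, 53),
                         replicates = 12, total_intensity = 1000,
                         gp_noise_sd = 0, blank_em440 = 30, blank_em490 = 20,
                         sample_id = "DPPC", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (min(temperatures) > Tm || max(temperatures) < Tm) {
    warning("temperature grid does not span Tm; the transition will be truncated")
  }
  grid <- expand.grid(replicate = seq_len(replicates),
                      temperature_C = temperatures)
  gp_true <- GP_fluid + (GP_gel - GP_fluid) /
    (1 + exp((grid$temperature_C - Tm) / width))
  gp <- gp_true + stats::rnorm(nrow(grid), 0, gp_noise_sd)
  gp <- pmin(pmax(gp, -1), 1)
  I440 <- total_intensity * (1 + gp) / 2
  I490 <- total_intensity * (1 - gp) / 2
  rows <- function(channel, sample_int, blank_int) {
    rbind(
      data.frame(sample_id = sample_id, temperature_C = grid$temperature_C,
                 channel = channel, intensity = sample_int + blank_int,
                 is_blank = 0, replicate = grid$replicate),
      data.frame(sample_id = sample_id, temperature_C = grid$temperature_C,
                 channel = channel, intensity = blank_int,
                 is_blank = 1, replicate = grid$replicate))
  }
  out <- rbind(rows("em440", I440, blank_em440), rows("em490", I490, blank_em490))
  rownames(out) <- NULL
  out
}

#' Generate a polarized intensity quadruplet plate
#'
#' Constructs `I_VV, I_VH, I_HV, I_HH` such that [anisotropy()] applied to
#' the noiseless output returns exactly `(r_true, G_true)`:
#' `I_VH = I_VV (1 - r) / (G (1 + 2r))` and `I_HV = G I_HH`.
#'
#' @param r_true target anisotropy, in `(-0.5, 1]`
#' @param G_true target instrumental G-factor, > 0
#' @param temperature_C measurement temperature
#' @param replicates shots per polarizer combination
#' @param I_VV,I_HH base intensities of the vertically/horizontally excited
#'   channels
#' @param noise_sd additive Gaussian noise per shot, intensity units
#' @param blank blank intensity added to every channel
#' @param sample_id sample label
#' @param seed optional RNG seed
#' @return a plate-schema data frame
#' @export
gen_polarized_quad <- function(r_true, G_true = 1, temperature_C = 50,
                               replicates = 12, I_VV = 500, I_HH = 400,
                               noise_sd = 0, blank = 10, sample_id = "DPPC",
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_scalar(r_true, "r_true"); check_scalar(G_true, "G_true")
  if (r_true <= -0.5 || r_true > 1) {
    abort_input("r_true must lie in (-0.5, 1] for positive intensities")
  }
  if (G_true <= 0) abort_input("G_true must be > 0")
  truth <- c(VV = I_VV,
             VH = I_VV * (1 - r_true) / (G_true * (1 + 2 * r_true)),
             HV = G_true * I_HH,
             HH = I_HH)
  out <- do.call(rbind, lapply(names(truth), function(ch) {
    sig <- truth[[ch]] + stats::rnorm(replicates, 0, noise_sd)
    rbind(
      data.frame(sample_id = sample_id, temperature_C = temperature_C,
                 channel = ch, intensity = sig + blank, is_blank = 0,
                 replicate = seq_len(replicates)),
      data.frame(sample_id = sample_id, temperature_C = temperature_C,
                 channel = ch, intensity = blank, is_blank = 1,
                 replicate = seq_len(replicates)))
  }))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic ITC titration
#'
#' Per-injection heats are the first differences of the cumulative
#' partition isotherm ([cumulative_heat_model()]) under the chosen
#' concentration bookkeeping; optional multiplicative Gaussian noise
#' emulates instrument scatter. The result can also be rendered as a raw
#' power-versus-time trace of Gaussian peaks on a flat baseline for testing
#' peak integration.
#'
#' @param K_mM,dH_kJ_mol generating partition constant (mM^-1) and molar
#'   transfer enthalpy (kJ/mol), both > 0 for an endothermic titration
#' @param V_cell_mL,C_A0_uM,C_syringe_lipid_mM cell geometry and
#'   concentrations (defaults: 1.4565 mL cell)
#' @param schedule an [injection_schedule()]
#' @param mode concentration bookkeeping, see [concentration_series()]
#' @param noise_cv multiplicative noise coefficient of variation on each
#'   per-injection heat
#' @param heat_unit unit of emitted heats
#' @param temperature_C experiment temperature
#' @param trace also render a raw power trace?
#' @param peak_sd_s,peak_lag_s,baseline_power,dt_s trace rendering: Gaussian
#'   peak width and centre lag after each injection, flat baseline level
#'   (power units), sampling step
#' @param seed optional RNG seed
#' @return an `itc_sim` list: `experiment` (a [titration_experiment()] with
#'   the retained noisy heats), `trace` (data frame or `NULL`), `truth`
#'   (generating `K_mM`, `dH_kJ_mol`, and all per-injection heats)
#' @export
gen_itc_thermogram <- function(K_mM, dH_kJ_mol, V_cell_mL = 1.4565,
                               C_A0_uM = 75, C_syringe_lipid_mM = 5,
                               schedule = default_schedule(),
                               mode = c("dilution", "naive", "overfill"),
                               noise_cv = 0, heat_unit = c("ucal", "uJ", "J"),
                               temperature_C = 26, trace = FALSE,
                               peak_sd_s = 15, peak_lag_s = 60,
                               baseline_power = 0, dt_s = 2, seed = NULL) {
  mode <- match.arg(mode)
  heat_unit <- match.arg(heat_unit)
  if (!is.null(seed)) set.seed(seed)
  if (K_mM <= 0 || dH_kJ_mol <= 0) abort_input("K and dH must be > 0")
  geom <- list(V_cell_mL = V_cell_mL, C_A0_uM = C_A0_uM,
               C_syringe_lipid_mM = C_syringe_lipid_mM, schedule = schedule)
  series <- concentration_series(geom, mode)
  cum <- cumulative_heat_model(K_mM, dH_kJ_mol, V_cell_mL,
                               series$C_A0_uM, series$C_L0_mM, heat_unit)
  dh <- diff(c(0, cum))
  dh <- dh * (1 + stats::rnorm(length(dh), 0, noise_cv))
  keep <- retained_injections(schedule)
  experiment <- titration_experiment(
    V_cell_mL = V_cell_mL, C_A0_uM = C_A0_uM,
    C_syringe_lipid_mM = C_syringe_lipid_mM, schedule = schedule,
    heats = dh[keep], heat_unit = heat_unit, temperature_C = temperature_C)

  trace_df <- NULL
  if (trace) {
    n <- length(schedule$volumes_uL)
    tt <- seq(0, n * schedule$interval_s, by = dt_s)
    centers <- (seq_len(n) - 1) * schedule$interval_s + peak_lag_s
    power <- rep(baseline_power, length(tt))
    for (i in seq_len(n)) {
      power <- power + dh[i] * stats::dnorm(tt, centers[i], peak_sd_s)
    }
    trace_df <- data.frame(time_s = tt, power = power)
  }
  structure(list(experiment = experiment, trace = trace_df,
                 truth = list(K_mM = K_mM, dH_kJ_mol = dH_kJ_mol,
                              heats_all = dh, mode = mode)),
            class = "itc_sim")
}

# ---- bilayer frame generator --------------------------------------------

# ideal zig-zag chain: anchor = first atom, axis = unit propagation
# direction, psi rotates the zig-zag plane about the axis
build_zigzag <- function(anchor, axis, psi, n, u, w) {
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  ep <- cos(psi) * e1 + sin(psi) * e2
  k <- seq_len(n) - 1
  cbind(anchor[1] + axis[1] * k * u + ep[1] * w * (k %% 2),
        anchor[2] + axis[2] * k * u + ep[2] * w * (k %% 2),
        anchor[3] + axis[3] * k * u + ep[3] * w * (k %% 2))
}

MAGIC_ANGLE_RAD <- acos(1 / sqrt(3))

bead_masses_chain <- function(prefix, n) {
  stats::setNames(c(rep(14.03, n - 1), 15.03), paste0(prefix, seq_len(n)))
}

#' Default bead topology for generated bilayers
#'
#' @param chain_length lipid acyl-chain carbon count
#' @param herbicide_chain_length alkyl-chain carbon count of the solute, or
#'   `NULL` for lipid-only systems
#' @return a [topology_map()] matching [gen_bilayer_frames()] output
#' @export
bead_topology <- function(chain_length = 16, herbicide_chain_length = NULL) {
  species <- list(
    PLPC = list(
      role = "lipid",
      chains = list(palmitoyl = paste0("C", seq_len(chain_length))),
      phosphorus = "P", glycerol = "GL",
      masses = c(P = 94.97, GL = 43.04,
                 bead_masses_chain("C", chain_length))))
  if (!is.null(herbicide_chain_length)) {
    m <- herbicide_chain_length
    species$HRB <- list(
      role = "herbicide",
      chains = list(alkyl = paste0("A", seq_len(m))),
      polar = "PH", terminal = paste0("A", m),
      masses = c(PH = 45.02, bead_masses_chain("A", m)))
  }
  topology_map(species)
}

#' Generate synthetic two-leaflet bilayer frames
#'
#' Places bead-chain "lipids" (P headgroup bead, glycerol bead, acyl chain
#' of `chain_length` zig-zag carbons) on two mirrored leaflets, plus
#' optional herbicide chains at a fixed molar ratio with their polar bead
#' at a prescribed depth. Chain orientations are drawn so the ensemble
#' order parameter approaches a target level:
#'
#' * `orientation = "sampled"` (default): each chain is all-trans along z
#'   with probability `order_level`, otherwise its axis tilt is drawn
#'   uniformly in `cos(tilt)` over the leaflet hemisphere (expected
#'   `-S_CD = order_level / 2`, strictly monotone in `order_level`).
#' * `"all_trans"`: every chain exactly along z (`-S_CD = 0.5` at each
#'   internal carbon).
#' * `"magic_angle"`: rigid chains tilted 54.7356 deg from z with random
#'   azimuths (`-S_CD = 0` in the azimuthal average).
#' * `"isotropic"`: axes uniform over the full sphere (`-S_CD = 0`).
#' * `"fixed"`: rigid tilt of `tilt_deg`, random azimuths.
#'
#' The headgroup plane height follows each chain's own z-extent, so more
#' ordered ensembles are genuinely thicker. This is a geometric stand-in
#' for a simulated bilayer, not a physical model: it targets exactly the
#' observables the analysis stage measures.
#'
#' @param n_lipids even total lipid count (both leaflets)
#' @param chain_length acyl-chain carbons (>= 3)
#' @param order_level target order level in `[0, 1]` for `"sampled"`
#' @param orientation see above
#' @param tilt_deg tilt for `orientation = "fixed"`, degrees from z
#' @param n_frames number of frames (independent orientation draws)
#' @param lipid_herbicide_ratio lipid:herbicide molar ratio, or `NULL` for
#'   none (e.g. 5 gives 28 herbicide molecules per 140 lipids)
#' @param herbicide_chain_length herbicide alkyl carbons
#' @param herbicide_polar_depth_nm |z| of the herbicide polar bead relative
#'   to the bilayer midplane
#' @param herbicide_depth_sd_nm per-molecule Gaussian jitter on that depth
#' @param spacing_nm lateral grid spacing between molecules
#' @param bond_nm C-C bond length of the zig-zag chains
#' @param frame_dt_ps time step between frames
#' @param equilibration_fraction stored on the returned trajectory
#' @param seed optional RNG seed
#' @return list with `trajectory` (a [trajectory()]), `topology`
#'   (a [topology_map()]), and `composition` (a [compose_system()] result
#'   when herbicides are present)
#' @export
gen_bilayer_frames <- function(n_lipids = 140, chain_length = 16,
                               order_level = 1,
                               orientation = c("sampled", "all_trans",
                                               "magic_angle", "isotropic", "fixed"),
                               tilt_deg = NULL, n_frames = 1,
                               lipid_herbicide_ratio = NULL,
                               herbicide_chain_length = 9,
                               herbicide_polar_depth_nm = 1.2,
                               herbicide_depth_sd_nm = 0,
                               spacing_nm = 0.8, bond_nm = 0.153,
                               frame_dt_ps = 1000,
                               equilibration_fraction = 0, seed = NULL) {
  orientation <- match.arg(orientation)
  if (!is.null(seed)) set.seed(seed)
  if (n_lipids < 2 || n_lipids %% 2 != 0) abort_input("n_lipids must be even and >= 2")
  if (chain_length < 3) abort_input("chain_length must be >= 3")
  if (order_level < 0 || order_level > 1) abort_input("order_level must be in [0, 1]")
  if (orientation == "fixed" && is.null(tilt_deg)) abort_input("orientation='fixed' needs tilt_deg")

  alpha <- 2 * asin(sqrt(2 / 3))          # tetrahedral backbone angle
  u <- bond_nm * sin(alpha / 2)           # axis advance per carbon
  w <- bond_nm * cos(alpha / 2)           # lateral zig-zag amplitude
  gl_off <- 0.25; p_off <- 0.45           # glycerol / P bead heights above C1

  n_herb <- 0
  composition <- NULL
  if (!is.null(lipid_herbicide_ratio)) {
    composition <- compose_system(n_lipids, lipid_herbicide_ratio, "HRB")
    n_herb <- composition$n_herbicide
  }
  topo <- bead_topology(chain_length,
                        if (n_herb > 0) herbicide_chain_length else NULL)

  per_leaf_lip <- n_lipids / 2
  herb_upper <- ceiling(n_herb / 2)
  per_leaf <- per_leaf_lip + herb_upper
  n_side <- ceiling(sqrt(per_leaf))
  if (n_side * spacing_nm < 2 * (chain_length * bond_nm)) {
    # box must exceed twice any intramolecular distance for minimum-image safety
    n_side <- ceiling(2 * chain_length * bond_nm / spacing_nm)
  }
  Lxy <- n_side * spacing_nm
  zmax <- (chain_length - 1) * u + p_off
  Lz <- 2 * zmax + 3.0
  zc <- Lz / 2
  box <- c(Lxy, Lxy, Lz)

  draw_axis_tilt <- function() {
    switch(orientation,
      all_trans = 0,
      magic_angle = MAGIC_ANGLE_RAD,
      fixed = tilt_deg * pi / 180,
      isotropic = acos(stats::runif(1, -1, 1)),
      sampled = if (stats::runif(1) < order_level) 0 else acos(stats::runif(1, 0, 1)))
  }

  n_atoms <- n_lipids * (chain_length + 2) +
    n_herb * (herbicide_chain_length + 1)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- matrix(NA_real_, n_atoms, 3)
    species <- character(n_atoms); name <- character(n_atoms)
    molid <- integer(n_atoms)
    row <- 0L; mol <- 0L; site <- 0L
    add_mol <- function(sp, nms, coords) {
      k <- nrow(coords)
      idx <- row + seq_len(k)
      xyz[idx, ] <<- coords
      species[idx] <<- sp; name[idx] <<- nms; molid[idx] <<- mol
      row <<- row + k
    }
    next_site <- function() {
      site <<- site + 1L
      c(((site - 1L) %% n_side) + 0.5, ((site - 1L) %/% n_side) + 0.5) * spacing_nm
    }

    for (leaf in c(1, -1)) {
      site <- 0L
      for (j in seq_len(per_leaf_lip)) {
        mol <- mol + 1L
        xy <- next_site()
        tau <- draw_axis_tilt()
        phi <- stats::runif(1, 0, 2 * pi)
        psi <- stats::runif(1, 0, 2 * pi)
        axis <- c(sin(tau) * cos(phi), sin(tau) * sin(phi), -leaf * cos(tau))
        z1 <- leaf * (chain_length - 1) * u * cos(tau)
        anchor <- c(xy, zc + z1)
        chain <- build_zigzag(anchor, axis, psi, chain_length, u, w)
        add_mol("PLPC",
                c("P", "GL", paste0("C", seq_len(chain_length))),
                rbind(c(xy, zc + z1 + leaf * p_off),
                      c(xy, zc + z1 + leaf * gl_off),
                      chain))
      }
      nh_leaf <- if (leaf == 1) herb_upper else n_herb - herb_upper
      for (j in seq_len(nh_leaf)) {
        mol <- mol + 1L
        xy <- next_site()
        depth <- herbicide_polar_depth_nm +
          stats::rnorm(1, 0, herbicide_depth_sd_nm)
        psi <- stats::runif(1, 0, 2 * pi)
        axis <- c(0, 0, -leaf)
        anchor <- c(xy, zc + leaf * (depth - 0.15))
        chain <- build_zigzag(anchor, axis, psi, herbicide_chain_length, u, w)
        add_mol("HRB",
                c("PH", paste0("A", seq_len(herbicide_chain_length))),
                rbind(c(xy, zc + leaf * depth), chain))
      }
    }
    atoms <- data.frame(species = species, molid = molid, name = name,
                        x = xyz[, 1] %% Lxy, y = xyz[, 2] %% Lxy,
                        z = xyz[, 3] %% Lz)
    frames[[f]] <- bilayer_frame(atoms, box, time = f * frame_dt_ps)
  }
  list(trajectory = trajectory(frames, equilibration_fraction),
       topology = topo, composition = composition)
}
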