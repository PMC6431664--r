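#' Topology map: atom roles per molecular species
#'
#' Names the structurally meaningful atoms of each species in a coordinate
#' frame: the ordered acyl-chain carbons (carbonyl end first, terminal
#' methyl last), the phosphorus atom and glycerol group of lipids, and the
#' polar-part and terminal-methyl atoms of a membrane-active solute
#' ("herbicide" role). Masses are per-atom and are used for all
#' centre-of-mass work.
#'
#' @param species named list; each element a list with fields
#'   `role` ("lipid", "herbicide" or "other"),
#'   `chains` (named list of ordered atom-name vectors),
#'   `phosphorus` (atom name, lipids), `glycerol` (atom names, lipids),
#'   `polar` (atom names), `terminal` (atom name),
#'   `masses` (named numeric covering every atom of the species)
#' @return a `topology_map`
#' @export
topology_map <- function(species) {
  if (!is.list(species) || is.null(names(species)) || any(names(species) == "")) {
    abort_input("species must be a named list")
  }
  for (nm in names(species)) {
    s <- species[[nm]]
    if (is.null(s$role)) abort_input(sprintf("species %s lacks a role", nm))
    if (is.null(s$masses) || is.null(names(s$masses))) {
      abort_input(sprintf("species %s lacks named masses", nm))
    }
    referenced <- unique(c(unlist(s$chains), s$phosphorus, s$glycerol,
                           s$polar, s$terminal))
    miss <- setdiff(referenced, names(s$masses))
    if (length(miss)) {
      abort_input(sprintf("species %s: atoms without masses: %s", nm,
                          paste(miss, collapse = ", ")))
    }
  }
  structure(list(species = species), class = "topology_map")
}

species_of_role <- function(topo, role) {
  names(which(vapply(topo$species, function(s) identical(s$role, role), logical(1))))
}

#' A single bilayer coordinate frame
#'
#' @param atoms data frame with columns `species`, `molid`, `name`,
#'   `x`, `y`, `z` (coordinates in nm)
#' @param box periodic box lengths `c(Lx, Ly, Lz)` in nm, or `NULL` for a
#'   non-periodic frame
#' @param time frame time in ps
#' @return a `bilayer_frame`
#' @export
bilayer_frame <- function(atoms, box = NULL, time = 0) {
  need <- c("species", "molid", "name", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms))) {
    abort_schema("atoms needs columns species, molid, name, x, y, z")
  }
  if (!is.null(box)) {
    check_finite(box, "box")
    if (length(box) != 3 || any(box <= 0)) abort_input("box must be 3 positive lengths")
  }
  structure(list(atoms = atoms, box = box, time = time), class = "bilayer_frame")
}

#' An ordered set of frames
#'
#' @param frames list of [bilayer_frame()]s with non-decreasing times
#' @param equilibration_fraction leading fraction of the time span treated
#'   as equilibration and excluded by the analysis operations; default 0.6
#'   (e.g. the first 150 ns of a 250 ns run)
#' @return a `trajectory`
#' @export
trajectory <- function(frames, equilibration_fraction = 0.6) {
  if (!length(frames)) abort_input("trajectory needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "bilayer_frame"))) {
    abort_input("frames must be bilayer_frame objects")
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (is.unsorted(times)) abort_input("frame times must be non-decreasing")
  if (equilibration_fraction < 0 || equilibration_fraction >= 1) {
    abort_input("equilibration_fraction must be in [0, 1)")
  }
  structure(list(frames = frames, equilibration_fraction = equilibration_fraction),
            class = "trajectory")
}

#' Drop the equilibration portion of a trajectory
#'
#' Retains the trailing `1 - discard_fraction` of the time span: frames at
#' or after `t0 + discard_fraction * (t_end - t0)` are kept.
#'
#' @param traj a [trajectory()]
#' @param discard_fraction fraction of the time span to discard from the
#'   front; defaults to the trajectory's own `equilibration_fraction`
#' @return a [trajectory()] with `equilibration_fraction = 0`
#' @export
equilibration_split <- function(traj, discard_fraction = traj$equilibration_fraction) {
  check_scalar(discard_fraction, "discard_fraction")
  if (discard_fraction < 0 || discard_fraction >= 1) {
    abort_input("discard_fraction must be in [0, 1)")
  }
  times <- vapply(traj$frames, `[[`, numeric(1), "time")
  cutoff <- times[1] + discard_fraction * (times[length(times)] - times[1])
  keep <- times >= cutoff
  if (!any(keep)) abort_input("no frames remain after equilibration discard")
  trajectory(traj$frames[keep], equilibration_fraction = 0)
}

production_frames <- function(traj) {
  if (traj$equilibration_fraction > 0) {
    traj <- equilibration_split(traj)
  }
  traj$frames
}

# ---- mass and periodic-boundary helpers ---------------------------------

frame_masses <- function(frame, topo) {
  m <- rep(NA_real_, nrow(frame$atoms))
  for (sp in unique(frame$atoms$species)) {
    entry <- topo$species[[sp]]
    if (is.null(entry)) abort_input(sprintf("species %s not in topology map", sp))
    sel <- frame$atoms$species == sp
    m[sel] <- entry$masses[frame$atoms$name[sel]]
  }
  if (anyNA(m)) abort_input("frame contains atoms without masses in the topology map")
  m
}

wrap_delta <- function(d, L) {
  if (is.null(L) || !is.finite(L)) d else d - L * round(d / L)
}

# Mass-weighted mean z under periodic boundaries: the occupied arc is
# unwrapped by placing the midpoint of the largest empty gap at the
# boundary (so no atom sits numerically on the cut), then a linear
# weighted mean is taken. Exact for any selection that does not fill the box.
com_z_pbc <- function(z, m, Lz) {
  if (is.null(Lz)) return(sum(z * m) / sum(m))
  zw <- z %% Lz
  zs <- sort(zw)
  gaps <- diff(c(zs, zs[1] + Lz))
  j <- which.max(gaps)
  if (gaps[j] <= 0) return(sum(zw * m) / sum(m))
  origin <- zs[j] + gaps[j] / 2
  zu <- (zw - origin) %% Lz
  (sum(zu * m) / sum(m) + origin) %% Lz
}

#' Bilayer centre of mass along z
#'
#' Mass-weighted mean z of a selection (all lipid-role atoms by default),
#' with molecules unwrapped across the periodic z boundary before
#' averaging.
#'
#' @param frame a [bilayer_frame()]
#' @param topo a [topology_map()] (provides masses and the default lipid
#'   selection)
#' @param selection optional logical or integer atom index into
#'   `frame$atoms`; default all atoms of lipid-role species
#' @return z of the centre of mass, nm (wrapped into `[0, Lz)` when the
#'   frame is periodic)
#' @export
bilayer_center_of_mass <- function(frame, topo, selection = NULL) {
  if (is.null(selection)) {
    lip <- species_of_role(topo, "lipid")
    selection <- frame$atoms$species %in% lip
  }
  atoms <- frame$atoms[selection, , drop = FALSE]
  if (nrow(atoms) == 0) abort_input("empty selection for centre of mass")
  m <- frame_masses(bilayer_frame(atoms, frame$box, frame$time), topo)
  com_z_pbc(atoms$z, m, frame$box[3])
}

# Per-molecule leaflet assignment: +1 above the bilayer COM, -1 below.
# Lipids are referenced by their phosphorus atom, other species by their
# molecular centre of mass. Molecules exactly at the midplane are excluded
# from that frame with a logged count.
molecule_leaflets <- function(frame, topo, zcom) {
  atoms <- frame$atoms
  Lz <- frame$box[3]
  key <- paste(atoms$species, atoms$molid)
  ref <- numeric(0); refkey <- character(0)
  for (sp in unique(atoms$species)) {
    entry <- topo$species[[sp]]
    sel <- atoms$species == sp
    if (identical(entry$role, "lipid") && !is.null(entry$phosphorus)) {
      psel <- sel & atoms$name == entry$phosphorus
      refkey <- c(refkey, key[psel])
      ref <- c(ref, wrap_delta(atoms$z[psel] - zcom, Lz))
    } else {
      sub <- atoms[sel, , drop = FALSE]
      m <- entry$masses[sub$name]
      for (id in unique(sub$molid)) {
        msel <- sub$molid == id
        refkey <- c(refkey, paste(sp, id))
        ref <- c(ref, wrap_delta(
          com_z_pbc(sub$z[msel], m[msel], Lz) - zcom, Lz))
      }
    }
  }
  excl <- sum(ref == 0)
  if (excl > 0) {
    message(sprintf("%d molecule(s) exactly at the midplane excluded from leaflet assignment", excl))
  }
  stats::setNames(sign(ref), refkey)
}

# ---- observables ---------------------------------------------------------

resolve_group <- function(topo, label) {
  lip <- species_of_role(topo, "lipid")
  herb <- species_of_role(topo, "herbicide")
  pick <- function(spp, field, all_atoms = FALSE) {
    sel <- list()
    for (sp in spp) {
      s <- topo$species[[sp]]
      atoms <- if (all_atoms) names(s$masses) else s[[field]]
      if (!is.null(atoms) && length(atoms)) sel[[sp]] <- atoms
    }
    sel
  }
  sel <- switch(label,
    P = pick(lip, "phosphorus"),
    glycerol = pick(lip, "glycerol"),
    polar = pick(herb, "polar"),
    terminal = pick(herb, "terminal"),
    herbicide = pick(herb, NULL, all_atoms = TRUE),
    list())
  if (!length(sel)) {
    abort_input(sprintf("group '%s' cannot be resolved from the topology map", label))
  }
  sel
}

#' Distance of atomic groups from the bilayer centre of mass
#'
#' For each requested group and frame, the group's mass-weighted centre of
#' mass is computed per leaflet; the reported value is the time- and
#' leaflet-averaged `|z_group - z_bilayerCOM|`, the standard way of locating
#' where a chemical group resides across the membrane depth. Equilibration
#' frames are excluded per the trajectory's `equilibration_fraction`.
#'
#' Recognized group labels: `"P"` (lipid phosphorus atoms), `"glycerol"`
#' (lipid glycerol groups), `"polar"` (herbicide polar part), `"terminal"`
#' (herbicide terminal methyl), `"herbicide"` (whole herbicide molecules).
#'
#' @param traj a [trajectory()]
#' @param topo a [topology_map()]
#' @param groups character vector of group labels
#' @return a `z_profile` data frame `(group, mean_abs_z_nm, se, n_frames)`
#' @export
z_profile <- function(traj, topo,
                      groups = c("P", "glycerol", "polar", "terminal", "herbicide")) {
  frames <- production_frames(traj)
  sels <- lapply(groups, resolve_group, topo = topo)
  names(sels) <- groups

  per_frame <- vapply(frames, function(frame) {
    zcom <- bilayer_center_of_mass(frame, topo)
    leaf <- molecule_leaflets(frame, topo, zcom)
    atoms <- frame$atoms
    Lz <- frame$box[3]
    key <- paste(atoms$species, atoms$molid)
    vapply(groups, function(g) {
      sel <- rep(FALSE, nrow(atoms))
      for (sp in names(sels[[g]])) {
        sel <- sel | (atoms$species == sp & atoms$name %in% sels[[g]][[sp]])
      }
      sub <- atoms[sel, , drop = FALSE]
      if (nrow(sub) == 0) abort_input(sprintf("group '%s' has no atoms in frame", g))
      m <- frame_masses(bilayer_frame(sub, frame$box, frame$time), topo)
      lf <- leaf[paste(sub$species, sub$molid)]
      vals <- c()
      for (side in c(-1, 1)) {
        s2 <- !is.na(lf) & lf == side
        if (!any(s2)) next
        dz <- wrap_delta(sub$z[s2] - zcom, Lz)
        vals <- c(vals, abs(sum(dz * m[s2]) / sum(m[s2])))
      }
      mean(vals)
    }, numeric(1))
  }, numeric(length(groups)))
  per_frame <- matrix(per_frame, nrow = length(groups))

  nf <- ncol(per_frame)
  out <- data.frame(
    group = groups,
    mean_abs_z_nm = rowMeans(per_frame),
    se = apply(per_frame, 1, stats::sd) / sqrt(nf),
    n_frames = nf)
  rownames(out) <- NULL
  structure(out, class = c("z_profile", "data.frame"))
}

# Per-molecule, per-carbon S_CD for one frame from chain coordinate
# matrices [n_mol x n_carbon]. United-atom C-H vectors at internal carbon i
# are reconstructed in the local frame of C_{i-1}, C_i, C_{i+1} assuming
# tetrahedral geometry: both hydrogens lie in the plane perpendicular to
# the C_{i-1}..C_{i+1} plane, symmetric about the inverted bisector.
scd_frame <- function(X, Y, Z, box) {
  nc <- ncol(X)
  Lx <- box[1]; Ly <- box[2]; Lz <- box[3]
  cosb <- sqrt(1 / 3)   # half the tetrahedral H-C-H angle
  sinb <- sqrt(2 / 3)
  out <- matrix(NA_real_, nrow(X), nc)
  for (i in 2:(nc - 1)) {
    ax <- wrap_delta(X[, i - 1] - X[, i], Lx)
    ay <- wrap_delta(Y[, i - 1] - Y[, i], Ly)
    az <- wrap_delta(Z[, i - 1] - Z[, i], Lz)
    bx <- wrap_delta(X[, i + 1] - X[, i], Lx)
    by <- wrap_delta(Y[, i + 1] - Y[, i], Ly)
    bz <- wrap_delta(Z[, i + 1] - Z[, i], Lz)
    na_ <- sqrt(ax^2 + ay^2 + az^2)
    nb_ <- sqrt(bx^2 + by^2 + bz^2)
    ux <- ax / na_; uy <- ay / na_; uz <- az / na_
    vx <- bx / nb_; vy <- by / nb_; vz <- bz / nb_
    sx <- ux + vx; sy <- uy + vy; sz <- uz + vz
    ns <- sqrt(sx^2 + sy^2 + sz^2)
    px <- uy * vz - uz * vy
    py <- uz * vx - ux * vz
    pz <- ux * vy - uy * vx
    np <- sqrt(px^2 + py^2 + pz^2)
    ok <- ns > 1e-9 & np > 1e-9   # collinear backbone -> geometry undefined
    szn <- sz / ns; pzn <- pz / np
    h1 <- -szn * cosb + pzn * sinb
    h2 <- -szn * cosb - pzn * sinb
    s <- ((3 * h1^2 - 1) + (3 * h2^2 - 1)) / 4
    s[!ok] <- NA_real_
    out[, i] <- s
  }
  out
}

#' Per-carbon deuterium order parameters of an acyl chain
#'
#' For every internal carbon of the chain, C-H unit vectors are
#' reconstructed from the united-atom backbone (tetrahedral local frame of
#' the two neighbouring carbons) and
#' `S_CD(i) = <(3 cos^2 theta - 1)/2>` is averaged over both hydrogens,
#' molecules, leaflets and production frames, with `theta` the C-H angle to
#' the z axis (the bilayer normal). By the `"minus"` convention (default)
#' the profile is reported as `-S_CD`, positive for ordered chains with a
#' maximum of 0.5; terminal carbons lack a reconstruction frame and are
#' reported as `NA`.
#'
#' @param traj a [trajectory()]
#' @param topo a [topology_map()]
#' @param chain chain label to analyse (must appear in one species' `chains`)
#' @param convention `"minus"` (report `-S_CD`), `"magnitude"` (`|S_CD|`) or
#'   `"signed"` (raw `S_CD`)
#' @return an `order_profile` data frame
#'   `(carbon_index, order_parameter, se, n_frames)` with attribute `chain`
#' @export
order_parameters <- function(traj, topo, chain = "palmitoyl",
                             convention = c("minus", "magnitude", "signed")) {
  convention <- match.arg(convention)
  sp <- NULL
  for (nm in names(topo$species)) {
    if (chain %in% names(topo$species[[nm]]$chains)) { sp <- nm; break }
  }
  if (is.null(sp)) abort_input(sprintf("no species carries a chain named '%s'", chain))
  carbons <- topo$species[[sp]]$chains[[chain]]
  if (length(carbons) < 3) {
    abort_input("chain must have >= 3 carbons for C-H reconstruction")
  }
  frames <- production_frames(traj)

  prof <- vapply(frames, function(frame) {
    atoms <- frame$atoms
    sel <- atoms$species == sp & atoms$name %in% carbons
    sub <- atoms[sel, , drop = FALSE]
    if (nrow(sub) == 0) abort_input(sprintf("no chain atoms for species %s in frame", sp))
    mids <- unique(sub$molid)
    ri <- match(sub$molid, mids); ci <- match(sub$name, carbons)
    X <- Y <- Z <- matrix(NA_real_, length(mids), length(carbons))
    idx <- cbind(ri, ci)
    X[idx] <- sub$x; Y[idx] <- sub$y; Z[idx] <- sub$z
    if (anyNA(X)) abort_input("chain atoms missing for some molecules")
    box <- if (is.null(frame$box)) rep(NA_real_, 3) else frame$box
    colMeans(scd_frame(X, Y, Z, box), na.rm = TRUE)
  }, numeric(length(carbons)))
  prof <- matrix(prof, nrow = length(carbons))

  mean_s <- rowMeans(prof)
  se <- apply(prof, 1, stats::sd) / sqrt(ncol(prof))
  value <- switch(convention, minus = -mean_s, magnitude = abs(mean_s),
                  signed = mean_s)
  value[is.nan(value)] <- NA_real_   # terminal carbons: no reconstruction frame
  out <- data.frame(carbon_index = seq_along(carbons),
                    order_parameter = value, se = se, n_frames = ncol(prof))
  structure(out, class = c("order_profile", "data.frame"),
            chain = chain, convention = convention)
}

#' Bilayer thickness from the phosphate planes
#'
#' Twice the time-averaged distance of lipid phosphorus atoms from the
#' bilayer centre of mass, i.e. the mean inter-leaflet P-P separation.
#'
#' @param traj a [trajectory()]
#' @param topo a [topology_map()]
#' @return a `bilayer_thickness` list: `thickness_nm`, `se`, `n_frames`
#' @export
bilayer_thickness <- function(traj, topo) {
  frames <- production_frames(traj)
  lip <- species_of_role(topo, "lipid")
  if (!length(lip)) abort_input("topology map has no lipid species")
  per_frame <- vapply(frames, function(frame) {
    atoms <- frame$atoms
    sel <- rep(FALSE, nrow(atoms))
    for (sp in lip) {
      p <- topo$species[[sp]]$phosphorus
      if (!is.null(p)) sel <- sel | (atoms$species == sp & atoms$name == p)
    }
    if (!any(sel)) abort_input("no phosphorus atoms in frame")
    zcom <- bilayer_center_of_mass(frame, topo)
    dz <- wrap_delta(atoms$z[sel] - zcom, frame$box[3])
    if (all(dz >= 0) || all(dz <= 0)) {
      abort_input("phosphorus atoms on a single side of the midplane: not a two-leaflet bilayer")
    }
    2 * mean(abs(dz))
  }, numeric(1))
  structure(list(thickness_nm = mean(per_frame),
                 se = stats::sd(per_frame) / sqrt(length(per_frame)),
                 n_frames = length(per_frame)),
            class = "bilayer_thickness")
}

#' @export
print.bilayer_thickness <- function(x, ...) {
  cat(sprintf("Bilayer thickness (P-P): %.3f +/- %.3g nm over %d frames\n",
              x$thickness_nm, x$se, x$n_frames))
  invisible(x)
}

#' Compose a simulated bilayer system
#'
#' Bookkeeping for a two-leaflet bilayer with a membrane-active solute at a
#' fixed lipid:solute molar ratio, plus the counterions needed for overall
#' neutrality (e.g. 140 lipids at ratio 5 with a deprotonated monoanionic
#' solute: 28 solute molecules and 28 monovalent counterions).
#'
#' @param n_lipids total lipid count; must split into two equal leaflets
#' @param lipid_to_herbicide_ratio lipid:solute molar ratio (> 0)
#' @param herbicide_species name of the solute
#' @param herbicide_net_charge formal charge per solute molecule
#' @param waters_per_lipid hydration level used for the water count
#' @return a `system_composition` list: `n_lipids`, `n_herbicide`,
#'   `herbicide_species`, `n_counterions`, `n_waters`
#' @export
compose_system <- function(n_lipids, lipid_to_herbicide_ratio, herbicide_species,
                           herbicide_net_charge = 0, waters_per_lipid = 40) {
  check_scalar(n_lipids, "n_lipids")
  check_scalar(lipid_to_herbicide_ratio, "lipid_to_herbicide_ratio")
  if (lipid_to_herbicide_ratio <= 0) abort_input("ratio must be > 0")
  if (n_lipids %% 2 != 0) {
    abort_composition("n_lipids must be even (two equal leaflets)")
  }
  nh <- n_lipids / lipid_to_herbicide_ratio
  if (abs(nh - round(nh)) > 1e-9) {
    abort_composition(sprintf(
      "lipid count %d is not divisible by ratio %g: non-integral herbicide count %.4g",
      n_lipids, lipid_to_herbicide_ratio, nh))
  }
  nh <- round(nh)
  structure(list(n_lipids = as.integer(n_lipids), n_herbicide = as.integer(nh),
                 herbicide_species = herbicide_species,
                 n_counterions = as.integer(abs(nh * round(herbicide_net_charge))),
                 n_waters = as.integer(round(waters_per_lipid * n_lipids))),
            class = "system_composition")
}

#' @export
print.system_composition <- function(x, ...) {
  cat(sprintf("Bilayer system: %d lipids + %d %s (+%d counterions, %d waters)\n",
              x$n_lipids, x$n_herbicide, x$herbicide_species,
              x$n_counterions, x$n_waters))
  invisible(x)
}
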