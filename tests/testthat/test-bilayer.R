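test_that("system composition reproduces the 5:1 lipid:herbicide stoichiometry", {
  a <- compose_system(140, 5, "nonanoic_acid", herbicide_net_charge = -1)
  expect_equal(a$n_herbicide, 28L)
  expect_equal(a$n_counterions, 28L)
  b <- compose_system(140, 5, "sorgoleone", herbicide_net_charge = 0)
  expect_equal(b$n_herbicide, 28L)
  expect_equal(b$n_counterions, 0L)
  expect_memprobe_error(compose_system(141, 5, "x"), "memprobe_composition_error")
  expect_memprobe_error(compose_system(100, 7, "x"), "memprobe_composition_error")
})

test_that("centre of mass is a mass-weighted mean with periodic unwrapping", {
  topo <- topology_map(list(
    X = list(role = "lipid", phosphorus = "P", masses = c(P = 1)),
    Y = list(role = "other", masses = c(A = 3))))
  fr <- bilayer_frame(data.frame(
    species = c("X", "X"), molid = 1:2, name = "P",
    x = 0, y = 0, z = c(1, 3)))
  expect_equal(bilayer_center_of_mass(fr, topo), 2)

  fr2 <- bilayer_frame(data.frame(
    species = c("X", "Y"), molid = 1:2, name = c("P", "A"),
    x = 0, y = 0, z = c(0, 4)))
  expect_equal(bilayer_center_of_mass(fr2, topo,
                                      selection = rep(TRUE, 2)), 3)

  # a cluster split across the periodic z boundary is made whole first
  fr3 <- bilayer_frame(data.frame(
    species = "X", molid = 1:2, name = "P",
    x = 0, y = 0, z = c(9.5, 0.5)), box = c(5, 5, 10))
  expect_equal(bilayer_center_of_mass(fr3, topo), 0)

  expect_memprobe_error(
    bilayer_center_of_mass(fr, topo, selection = logical(2)),
    "memprobe_input_error")
})

test_that("a symmetric synthetic bilayer has its COM at the box centre", {
  g <- gen_bilayer_frames(n_lipids = 40, chain_length = 8, seed = 31)
  fr <- g$trajectory$frames[[1]]
  expect_equal(bilayer_center_of_mass(fr, g$topology), fr$box[3] / 2,
               tolerance = 1e-9)
})

test_that("equilibration split keeps the trailing fraction by time", {
  frames <- lapply(1:250, function(i) flat_bilayer_frame(time = i))
  traj <- trajectory(frames, equilibration_fraction = 0)
  kept <- equilibration_split(traj, 0.6)
  times <- vapply(kept$frames, `[[`, numeric(1), "time")
  expect_equal(times, 151:250)
  expect_equal(length(equilibration_split(traj, 0)$frames), 250)
  expect_memprobe_error(equilibration_split(traj, 1), "memprobe_input_error")
})

test_that("z profiles read exact constructed geometry", {
  fr <- flat_bilayer_frame(d = 2.0)
  traj <- trajectory(list(fr), equilibration_fraction = 0)
  zp <- z_profile(traj, flat_topo(), groups = "P")
  expect_equal(zp$mean_abs_z_nm, 2.0, tolerance = 1e-9)
  expect_memprobe_error(z_profile(traj, flat_topo(), groups = "polar"),
                        "memprobe_input_error")
})

test_that("a group at the bilayer COM has zero mean distance", {
  g <- gen_bilayer_frames(n_lipids = 40, chain_length = 8,
                          lipid_herbicide_ratio = 5,
                          herbicide_chain_length = 3,
                          herbicide_polar_depth_nm = 0.4, seed = 33)
  traj <- g$trajectory
  # terminal methyls of 3-carbon herbicides end essentially at the midplane
  zp <- z_profile(traj, g$topology, groups = "terminal")
  expect_lt(zp$mean_abs_z_nm, 0.05)
})

test_that("seeded herbicide depth is recovered to 0.01 nm over 100 frames", {
  g <- gen_bilayer_frames(n_lipids = 140, chain_length = 16, order_level = 1,
                          lipid_herbicide_ratio = 5,
                          herbicide_polar_depth_nm = 1.2,
                          herbicide_depth_sd_nm = 0.05,
                          n_frames = 100, seed = 5)
  zp <- z_profile(g$trajectory, g$topology, groups = "polar")
  expect_equal(zp$n_frames, 100)
  expect_lt(abs(zp$mean_abs_z_nm - 1.2), 0.01)
})

test_that("all-trans chains along z give -S_CD = 0.5 at every internal carbon", {
  g <- gen_bilayer_frames(n_lipids = 20, chain_length = 16,
                          orientation = "all_trans", seed = 35)
  ord <- order_parameters(g$trajectory, g$topology, "palmitoyl")
  internal <- 2:15
  expect_equal(ord$order_parameter[internal], rep(0.5, 14), tolerance = 1e-9)
  expect_true(all(is.na(ord$order_parameter[c(1, 16)])))
})

test_that("order profiles are invariant under translation and z-rotation", {
  g <- gen_bilayer_frames(n_lipids = 40, chain_length = 10, order_level = 0.5,
                          seed = 36)
  fr <- g$trajectory$frames[[1]]
  # make molecules whole, then drop the box so rigid motions are exact
  a <- fr$atoms
  for (cc in c("x", "y", "z")) {
    L <- fr$box[match(cc, c("x", "y", "z"))]
    a[[cc]] <- ave(a[[cc]], a$molid,
                   FUN = function(v) v[1] + (v - v[1]) - L * round((v - v[1]) / L))
  }
  traj <- trajectory(list(bilayer_frame(a, NULL, fr$time)), 0)
  ord0 <- order_parameters(traj, g$topology, "palmitoyl")

  th <- 0.7
  rot <- a
  rot$x <- cos(th) * a$x - sin(th) * a$y
  rot$y <- sin(th) * a$x + cos(th) * a$y
  rot$z <- a$z + 2.5
  traj_r <- trajectory(list(bilayer_frame(rot, NULL, fr$time)), 0)
  ord_r <- order_parameters(traj_r, g$topology, "palmitoyl")
  expect_equal(ord_r$order_parameter, ord0$order_parameter, tolerance = 1e-9)
})

test_that("observables are invariant under periodic re-wrapping", {
  g <- gen_bilayer_frames(n_lipids = 40, chain_length = 10, order_level = 0.8,
                          lipid_herbicide_ratio = 5, herbicide_chain_length = 5,
                          seed = 37)
  fr <- g$trajectory$frames[[1]]
  shifted <- fr$atoms
  shifted$z <- (shifted$z + 0.4 * fr$box[3]) %% fr$box[3]
  traj_s <- trajectory(list(bilayer_frame(shifted, fr$box, fr$time)), 0)
  traj_0 <- trajectory(list(fr), 0)

  t0 <- bilayer_thickness(traj_0, g$topology)
  ts <- bilayer_thickness(traj_s, g$topology)
  expect_equal(ts$thickness_nm, t0$thickness_nm, tolerance = 1e-9)

  z0 <- z_profile(traj_0, g$topology, c("P", "polar"))
  zs <- z_profile(traj_s, g$topology, c("P", "polar"))
  expect_equal(zs$mean_abs_z_nm, z0$mean_abs_z_nm, tolerance = 1e-9)

  o0 <- order_parameters(traj_0, g$topology, "palmitoyl")
  os <- order_parameters(traj_s, g$topology, "palmitoyl")
  expect_equal(os$order_parameter, o0$order_parameter, tolerance = 1e-9)
})

test_that("mirror symmetry through the midplane preserves observables", {
  g <- gen_bilayer_frames(n_lipids = 40, chain_length = 10, order_level = 0.6,
                          seed = 38)
  fr <- g$trajectory$frames[[1]]
  mir <- fr$atoms
  mir$z <- fr$box[3] - mir$z
  traj_m <- trajectory(list(bilayer_frame(mir, fr$box, fr$time)), 0)
  traj_0 <- trajectory(list(fr), 0)
  expect_equal(bilayer_thickness(traj_m, g$topology)$thickness_nm,
               bilayer_thickness(traj_0, g$topology)$thickness_nm,
               tolerance = 1e-9)
  expect_equal(order_parameters(traj_m, g$topology, "palmitoyl")$order_parameter,
               order_parameters(traj_0, g$topology, "palmitoyl")$order_parameter,
               tolerance = 1e-9)
})

test_that("|S_CD| never exceeds 0.5 for randomized geometry", {
  set.seed(39)
  for (rep in 1:5) {
    n <- 30
    atoms <- do.call(rbind, lapply(seq_len(n), function(m) {
      data.frame(species = "PLPC", molid = m,
                 name = c("P", "GL", paste0("C", 1:6)),
                 x = runif(8, 0, 5), y = runif(8, 0, 5),
                 z = c(runif(1, 3, 5), runif(7, 0, 5)))
    }))
    # force both leaflets
    atoms$z[atoms$name == "P" & atoms$molid <= n / 2] <- runif(n / 2, 4, 5)
    atoms$z[atoms$name == "P" & atoms$molid > n / 2] <- runif(n / 2, 0, 1)
    traj <- trajectory(list(bilayer_frame(atoms, NULL, 0)), 0)
    ord <- order_parameters(traj, bead_topology(6), "palmitoyl")
    vals <- ord$order_parameter[!is.na(ord$order_parameter)]
    expect_true(all(abs(vals) <= 0.5 + 1e-12))
  }
})

test_that("phosphate-plane thickness matches construction and orderings", {
  fr <- flat_bilayer_frame(d = 1.9)
  traj <- trajectory(list(fr), 0)
  th <- bilayer_thickness(traj, flat_topo())
  expect_equal(th$thickness_nm, 3.8, tolerance = 1e-9)

  go <- gen_bilayer_frames(order_level = 0.9, n_frames = 3, seed = 41)
  gd <- gen_bilayer_frames(order_level = 0.1, n_frames = 3, seed = 42)
  expect_gt(bilayer_thickness(go$trajectory, go$topology)$thickness_nm,
            bilayer_thickness(gd$trajectory, gd$topology)$thickness_nm)

  # single-leaflet input is rejected
  a <- fr$atoms
  up <- a[a$z >= fr$box[3] / 2, ]
  traj1 <- trajectory(list(bilayer_frame(up, fr$box, 0)), 0)
  expect_memprobe_error(bilayer_thickness(traj1, flat_topo()),
                        "memprobe_input_error")
})

test_that("chains shorter than 3 carbons cannot be analysed", {
  topo <- topology_map(list(
    PLPC = list(role = "lipid", chains = list(palmitoyl = c("C1", "C2")),
                phosphorus = "P",
                masses = c(P = 95, C1 = 14, C2 = 15))))
  traj <- trajectory(list(flat_bilayer_frame()), 0)
  expect_memprobe_error(order_parameters(traj, topo, "palmitoyl"),
                        "memprobe_input_error")
  expect_memprobe_error(order_parameters(traj, topo, "oleoyl"),
                        "memprobe_input_error")
})
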