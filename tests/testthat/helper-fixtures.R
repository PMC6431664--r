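# Shared fixture builders. Everything is generated in code; no data files.

# Published-style reference rows (partition constant mM^-1, enthalpy kJ/mol,
# entropic term and free energy kJ/mol at 299.15 K) used as generator truths
# and as the cross-check for the thermodynamic decomposition.
reference_compounds <- function() {
  data.frame(
    compound = c("nonanoic_acid", "sarmentine", "sorgoleone"),
    K_mM = c(0.36, 1.69, 28.5),
    dH = c(3.32, 1.47, 1.79),
    TdS = c(27.85, 29.77, 37.13),
    dG = c(-24.53, -28.3, -35.34),
    dG_unc = c(0.48, 0.82, 0.8),
    C_A0_uM = c(500, 75, 75),
    C_syr_mM = c(5, 5, 1))
}

# A minimal hand-built frame: two flat P planes at +/- d from the box
# centre, each lipid a vertical 3-carbon chain (enough for one internal
# carbon), n lipids per leaflet.
flat_bilayer_frame <- function(d = 1.9, n_per_leaflet = 4, Lxy = 4, Lz = 10,
                               time = 0) {
  zc <- Lz / 2
  rows <- list()
  mol <- 0
  for (leaf in c(1, -1)) {
    for (j in seq_len(n_per_leaflet)) {
      mol <- mol + 1
      x <- (j - 0.5) * Lxy / n_per_leaflet
      z1 <- zc + leaf * (d - 0.45)
      rows[[mol]] <- data.frame(
        species = "PLPC", molid = mol,
        name = c("P", "GL", "C1", "C2", "C3"),
        x = x, y = 1,
        z = c(zc + leaf * d, zc + leaf * (d - 0.2),
              z1, z1 - leaf * 0.125, z1 - leaf * 0.25))
      # give the chain a zig-zag so the C-H frame is defined
      rows[[mol]]$x <- rows[[mol]]$x + c(0, 0, 0, 0.09, 0)
    }
  }
  bilayer_frame(do.call(rbind, rows), box = c(Lxy, Lxy, Lz), time = time)
}

flat_topo <- function() bead_topology(3)

expect_memprobe_error <- function(expr, class) {
  expect_error(expr, class = class)
}
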