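# Coordinate-file dialects.
#
# GRO-style fixed width (positions in nm):
#   title line containing "t= <ps>"
#   atom count
#   %5d%-5s%5s%5d%8.3f%8.3f%8.3f   (resid resname atomname atomid x y z)
#   box line: Lx Ly Lz
# Multi-frame files repeat the block.
#
# XYZ dialect (one frame block):
#   atom count
#   comment: "t= <ps> box <Lx> <Ly> <Lz>"
#   <species>:<molid>:<name> x y z
# The topology map travels in a JSON sidecar (see read_topology_json).

#' Write frames in GRO format
#'
#' @param x a `trajectory` or a single `bilayer_frame`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gro <- function(x, path) {
  frames <- if (inherits(x, "trajectory")) x$frames else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    a <- fr$atoms
    writeLines(sprintf("memprobe frame t= %.3f", fr$time), con)
    writeLines(as.character(nrow(a)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$molid %% 100000L, substr(a$species, 1, 5),
                       substr(a$name, 1, 5), seq_len(nrow(a)) %% 100000L,
                       a$x, a$y, a$z), con)
    box <- if (is.null(fr$box)) c(0, 0, 0) else fr$box
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
  invisible(path)
}

#' Read GRO-format frames
#'
#' @param path GRO file (single- or multi-frame)
#' @param equilibration_fraction stored on the returned trajectory
#' @return a [trajectory()]
#' @export
read_gro <- function(path, equilibration_fraction = 0) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else length(frames)
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) abort_schema(sprintf("bad atom count at line %d", i + 1L))
    al <- lines[i + 1L + seq_len(nat)]
    atoms <- data.frame(
      molid = as.integer(substr(al, 1, 5)),
      species = trimws(substr(al, 6, 10)),
      name = trimws(substr(al, 11, 15)),
      x = as.numeric(substr(al, 21, 28)),
      y = as.numeric(substr(al, 29, 36)),
      z = as.numeric(substr(al, 37, 44)))
    if (anyNA(atoms$x)) abort_schema("unparseable coordinates in GRO frame")
    bx <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]])[1:3]
    box <- if (all(is.finite(bx)) && all(bx > 0)) bx else NULL
    frames[[length(frames) + 1L]] <- bilayer_frame(
      atoms[, c("species", "molid", "name", "x", "y", "z")], box, time)
    i <- i + 3L + nat
  }
  if (!length(frames)) abort_schema("no frames found in GRO file")
  trajectory(frames, equilibration_fraction)
}

#' Write frames in the XYZ+sidecar dialect
#' @inheritParams write_gro
#' @return `path`, invisibly
#' @export
write_xyz <- function(x, path) {
  frames <- if (inherits(x, "trajectory")) x$frames else list(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    a <- fr$atoms
    writeLines(as.character(nrow(a)), con)
    box <- if (is.null(fr$box)) c(0, 0, 0) else fr$box
    writeLines(sprintf("t= %.3f box %.5f %.5f %.5f", fr$time, box[1], box[2], box[3]), con)
    writeLines(sprintf("%s:%d:%s %.5f %.5f %.5f",
                       a$species, a$molid, a$name, a$x, a$y, a$z), con)
  }
  invisible(path)
}

#' Read XYZ+sidecar frames
#' @inheritParams read_gro
#' @return a [trajectory()]
#' @export
read_xyz <- function(path, equilibration_fraction = 0) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) abort_schema(sprintf("bad atom count at line %d", i))
    hdr <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    time <- as.numeric(hdr[2])
    box <- as.numeric(hdr[4:6])
    if (!all(is.finite(box)) || !all(box > 0)) box <- NULL
    al <- lines[i + 1L + seq_len(nat)]
    parts <- strsplit(al, "\\s+")
    lab <- strsplit(vapply(parts, `[[`, character(1), 1), ":", fixed = TRUE)
    atoms <- data.frame(
      species = vapply(lab, `[[`, character(1), 1),
      molid = as.integer(vapply(lab, `[[`, character(1), 2)),
      name = vapply(lab, `[[`, character(1), 3),
      x = as.numeric(vapply(parts, `[[`, character(1), 2)),
      y = as.numeric(vapply(parts, `[[`, character(1), 3)),
      z = as.numeric(vapply(parts, `[[`, character(1), 4)))
    frames[[length(frames) + 1L]] <- bilayer_frame(atoms, box, time)
    i <- i + 2L + nat
  }
  if (!length(frames)) abort_schema("no frames found in XYZ file")
  trajectory(frames, equilibration_fraction)
}

#' Write a topology map as JSON
#' @param topo a [topology_map()]
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_topology_json <- function(topo, path) {
  ser <- lapply(topo$species, function(s) {
    s$masses <- as.list(s$masses)
    s
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a topology map from JSON
#' @param path JSON file written by [write_topology_json()]
#' @return a [topology_map()]
#' @export
read_topology_json <- function(path) {
  raw <- jsonlite::read_json(path)
  species <- lapply(raw, function(s) {
    s$masses <- unlist(s$masses)
    s$chains <- lapply(s$chains, function(ch) unlist(ch))
    for (f in c("glycerol", "polar")) if (!is.null(s[[f]])) s[[f]] <- unlist(s[[f]])
    s
  })
  topology_map(species)
}

#' Write an order profile or z profile as CSV
#' @param x an `order_profile` or `z_profile`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_profile_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
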