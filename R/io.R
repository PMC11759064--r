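# Plain-text interchange: extended XYZ configurations/trajectories, a JSON
# topology sidecar, and the stress-log CSV.

#' Write an extended XYZ file
#'
#' One frame per call appends `species x y z` records with the box (and
#' tilt) in the comment line, the common extended-XYZ `Lattice=` form.
#'
#' @param system a [particle_system()] (or a list of them for a trajectory)
#' @param path output file
#' @param append append a frame instead of overwriting
#' @export
write_xyz <- function(system, path, append = FALSE) {
  if (inherits(system, "particle_system")) system <- list(system)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  for (sys in system) {
    L <- sys$box$L; tilt <- sys$box$tilt
    lattice <- sprintf('Lattice="%.8g 0 0 %.8g %.8g 0 0 0 %.8g"',
                       L[1], tilt, L[2], L[3])
    writeLines(as.character(nrow(sys$pos)), con)
    writeLines(paste(lattice, "Properties=species:S:1:pos:R:3"), con)
    writeLines(sprintf("T%d %.8g %.8g %.8g", sys$type,
                       sys$pos[, 1], sys$pos[, 2], sys$pos[, 3]), con)
  }
  invisible(path)
}

#' Read an extended XYZ file
#'
#' @param path file written by [write_xyz()] (or compatible)
#' @return list of frames, each a list with `pos`, `type`, `L`, `tilt`
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comment <- lines[i + 1]
    lat <- regmatches(comment, regexec('Lattice="([^"]+)"', comment))[[1]][2]
    cell <- as.numeric(strsplit(lat, "\\s+")[[1]])
    body <- lines[(i + 2):(i + 1 + n)]
    parts <- do.call(rbind, strsplit(trimws(body), "\\s+"))
    frames[[length(frames) + 1]] <- list(
      pos = matrix(as.numeric(parts[, 2:4]), n, 3),
      type = as.integer(sub("^T", "", parts[, 1])),
      L = cell[c(1, 5, 9)], tilt = cell[4])
    i <- i + 2 + n
  }
  frames
}

#' Write the topology sidecar as JSON
#'
#' @param topology a [cg_topology()]
#' @param box a [simulation_box()] (stored alongside for completeness)
#' @param path output file
#' @export
write_topology_json <- function(topology, box, path) {
  obj <- list(n_atoms = topology$n_atoms,
              bonds = topology$bonds,
              bond_type = topology$bond_type,
              bond_k = topology$bond_k, bond_r0 = topology$bond_r0,
              angles = topology$angles,
              angle_k = topology$angle_k,
              angle_theta0 = topology$angle_theta0,
              types = topology$types,
              box = list(L = box$L, tilt = box$tilt,
                         periodic = box$periodic, xwalls = box$xwalls))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a JSON topology sidecar
#'
#' @param path file written by [write_topology_json()]
#' @return list with `topology` ([cg_topology()]) and `box`
#'   ([simulation_box()])
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(m, k) {
    if (is.null(m) || length(m) == 0) matrix(integer(), 0, k)
    else matrix(as.integer(m), ncol = k)
  }
  topo <- cg_topology(n_atoms = obj$n_atoms,
                      bonds = as_mat(obj$bonds, 2),
                      bond_type = obj$bond_type,
                      bond_k = obj$bond_k, bond_r0 = obj$bond_r0,
                      angles = as_mat(obj$angles, 3),
                      angle_k = obj$angle_k,
                      angle_theta0 = obj$angle_theta0,
                      types = obj$types)
  xw <- obj$box$xwalls
  if (length(xw) != 2) xw <- NULL
  box <- simulation_box(obj$box$L, tilt = obj$box$tilt,
                        periodic = obj$box$periodic, xwalls = xw)
  list(topology = topo, box = box)
}

#' Write a stress log as CSV
#'
#' Columns `t, strain, sxy, sxz, syz, sxx, syy, szz, Tkin` plus the volume
#' and temperature in a `# key: value` header.
#'
#' @param stress a [stress_series()]
#' @param path output file
#' @export
write_stress_csv <- function(stress, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# volume: %.10g", attr(stress, "volume")), con)
  writeLines(sprintf("# temperature: %.10g", attr(stress, "temperature")), con)
  write.csv(as.data.frame(stress), con, row.names = FALSE)
  invisible(path)
}

#' Read a stress log CSV
#'
#' @param path file written by [write_stress_csv()]
#' @return a [stress_series()]
#' @export
read_stress_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  vol <- as.numeric(sub("# volume: ", "", hdr[1]))
  temp <- as.numeric(sub("# temperature: ", "", hdr[2]))
  d <- read.csv(path, comment.char = "#")
  stress_series(d, volume = vol, temperature = temp)
}
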