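# State containers: the periodic (optionally tilted, optionally walled)
# simulation box, the particle system, and the bonded topology.

#' Simulation box
#'
#' @param L edge lengths `c(Lx, Ly, Lz)` in sigma; a scalar is recycled
#' @param tilt xy tilt (x-offset of the y box vector); shear strain is
#'   `tilt / Ly`
#' @param periodic logical per-axis flags
#' @param xwalls optional `c(xlo, xhi)` reflective walls on x; requires the
#'   x axis to be non-periodic
#' @return object of class `simulation_box`
#' @export
simulation_box <- function(L, tilt = 0, periodic = c(TRUE, TRUE, TRUE),
                           xwalls = NULL) {
  if (length(L) == 1) L <- rep(L, 3)
  stopifnot(length(L) == 3, all(L > 0), length(periodic) == 3)
  if (abs(tilt) > L[1] / 2 + 1e-9)
    stop("box tilt exceeds Lx/2; remap the strain before constructing")
  if (!is.null(xwalls)) {
    stopifnot(length(xwalls) == 2, xwalls[1] < xwalls[2])
    if (periodic[1]) stop("x walls require a non-periodic x axis")
  }
  structure(list(L = as.numeric(L), tilt = as.numeric(tilt),
                 periodic = as.logical(periodic), xwalls = xwalls),
            class = "simulation_box")
}

box_volume <- function(box) {
  if (!is.null(box$xwalls)) (box$xwalls[2] - box$xwalls[1]) * box$L[2] * box$L[3]
  else prod(box$L)
}

#' Particle system
#'
#' Positions, velocities, bead types and chain ids in a [simulation_box()].
#' Positions are stored wrapped; `image` holds the periodic image counts so
#' observables can unwrap trajectories. Bead mass is 1 in reduced units.
#'
#' @param pos N x 3 matrix of positions (sigma)
#' @param type integer bead types (1 = polymer/spacer, 2 = solvent,
#'   3 = sticker by the builders' convention)
#' @param chain integer chain id per bead (0 for free beads)
#' @param box a [simulation_box()]
#' @param vel optional N x 3 velocity matrix (defaults to zero)
#' @param image optional N x 3 integer image-flag matrix
#' @return object of class `particle_system`
#' @export
particle_system <- function(pos, type, chain, box, vel = NULL, image = NULL) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  stopifnot(ncol(pos) == 3, all(is.finite(pos)),
            length(type) == n, length(chain) == n,
            inherits(box, "simulation_box"))
  if (is.null(vel)) vel <- matrix(0, n, 3)
  if (is.null(image)) image <- matrix(0L, n, 3)
  stopifnot(all(is.finite(vel)), nrow(vel) == n, nrow(image) == n)
  structure(list(pos = pos, vel = vel, image = matrix(as.integer(image), n, 3),
                 type = as.integer(type), chain = as.integer(chain),
                 box = box),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  tt <- table(x$type)
  cat(sprintf("<particle_system> %d beads (%s), %d chain(s)\n",
              nrow(x$pos),
              paste(sprintf("type %s: %d", names(tt), tt), collapse = ", "),
              length(unique(x$chain[x$chain > 0]))))
  cat(sprintf("  box: %.3f x %.3f x %.3f, tilt %.3f, periodic %s%s\n",
              x$box$L[1], x$box$L[2], x$box$L[3], x$box$tilt,
              paste(ifelse(x$box$periodic, "T", "F"), collapse = ""),
              if (!is.null(x$box$xwalls))
                sprintf(", x walls [%.2f, %.2f]", x$box$xwalls[1], x$box$xwalls[2])
              else ""))
  invisible(x)
}

box_to_list <- function(box) {
  list(L = box$L, tilt = box$tilt, periodic = box$periodic,
       xwalls = box$xwalls)
}

#' Bonded topology
#'
#' Bonds (FENE or harmonic), angle terms with per-angle parameters, and the
#' per-bead types. Angle equilibrium values are stored in radians.
#'
#' @param n_atoms number of beads
#' @param bonds m x 2 integer matrix (1-based bead indices)
#' @param bond_type integer per bond: 1 = FENE, 2 = harmonic
#' @param bond_k,bond_r0 per-bond parameters (for FENE, `bond_r0` is R0)
#' @param angles k x 3 integer matrix, vertex in column 2
#' @param angle_k,angle_theta0 per-angle stiffness and equilibrium (radians)
#' @param types per-bead types mirrored from the system
#' @return object of class `cg_topology`
#' @export
cg_topology <- function(n_atoms, bonds = NULL, bond_type = NULL,
                        bond_k = NULL, bond_r0 = NULL, angles = NULL,
                        angle_k = NULL, angle_theta0 = NULL, types = NULL) {
  if (is.null(bonds)) bonds <- matrix(integer(), 0, 2)
  if (is.null(angles)) angles <- matrix(integer(), 0, 3)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  angles <- matrix(as.integer(angles), ncol = 3)
  nb <- nrow(bonds); na <- nrow(angles)
  if (is.null(bond_type)) bond_type <- rep(1L, nb)
  if (is.null(bond_k)) bond_k <- rep(30, nb)
  if (is.null(bond_r0)) bond_r0 <- rep(1.5, nb)
  if (is.null(angle_k)) angle_k <- rep(0, na)
  if (is.null(angle_theta0)) angle_theta0 <- rep(pi, na)
  if (is.null(types)) types <- rep(1L, n_atoms)
  topo <- structure(list(
    n_atoms = as.integer(n_atoms),
    bonds = bonds, bond_type = as.integer(bond_type),
    bond_k = as.numeric(bond_k), bond_r0 = as.numeric(bond_r0),
    angles = angles, angle_k = as.numeric(angle_k),
    angle_theta0 = as.numeric(angle_theta0),
    types = as.integer(types)
  ), class = "cg_topology")
  validate_topology(topo)
  topo
}

validate_topology <- function(topo) {
  n <- topo$n_atoms
  if (nrow(topo$bonds) > 0) {
    stopifnot(all(topo$bonds >= 1), all(topo$bonds <= n),
              length(topo$bond_type) == nrow(topo$bonds),
              length(topo$bond_k) == nrow(topo$bonds),
              length(topo$bond_r0) == nrow(topo$bonds))
    key <- paste(pmin(topo$bonds[, 1], topo$bonds[, 2]),
                 pmax(topo$bonds[, 1], topo$bonds[, 2]))
    if (anyDuplicated(key)) stop("duplicate bonds in topology")
  }
  if (nrow(topo$angles) > 0)
    stopifnot(all(topo$angles >= 1), all(topo$angles <= n),
              length(topo$angle_k) == nrow(topo$angles))
  stopifnot(length(topo$types) == n)
  invisible(topo)
}

#' @export
print.cg_topology <- function(x, ...) {
  cat(sprintf("<cg_topology> %d beads, %d bond(s) (%d FENE / %d harmonic), %d angle(s)\n",
              x$n_atoms, nrow(x$bonds), sum(x$bond_type == 1L),
              sum(x$bond_type == 2L), nrow(x$angles)))
  invisible(x)
}

topo_to_list <- function(topo) {
  list(bonds = topo$bonds, bond_type = topo$bond_type, bond_k = topo$bond_k,
       bond_r0 = topo$bond_r0, angles = topo$angles, angle_k = topo$angle_k,
       angle_theta0 = topo$angle_theta0)
}

#' Copy the topology's bead types onto the particle system
#'
#' The topology is the authority on bead types (sticker placement retypes
#' beads there); call this after [place_stickers()] to keep the system's
#' type vector in step.
#'
#' @param system a [particle_system()]
#' @param topology a [cg_topology()]
#' @return the system with `type` replaced
#' @export
apply_topology_types <- function(system, topology) {
  stopifnot(nrow(system$pos) == topology$n_atoms)
  system$type <- topology$types
  system
}

#' Total force, energy and virial of a configuration
#'
#' Thin wrapper over the compiled force kernel; mainly for tests and for the
#' instantaneous stress estimator.
#'
#' @param system a [particle_system()]
#' @param topology a [cg_topology()]
#' @param ff a [forcefield()]
#' @return list with `forces` (N x 3), `energy`, `virial` (named length-6)
#' @export
compute_forces <- function(system, topology, ff) {
  cpp_forces(system$pos, system$type, box_to_list(system$box),
             ff_to_pairlist(ff), topo_to_list(topology))
}

#' Instantaneous virial stress tensor
#'
#' Kinetic plus configurational (virial) estimator,
#' (sum_i m v_a v_b + sum_pairs r_a F_b) / V, in units of eps sigma^-3.
#' Diagonals follow the pressure-tensor sign (ideal gas averages to
#' +rho kB T); off-diagonals are reported as the material shear stress
#' (negative of the pressure-tensor component), so an elastic solid
#' sheared by +gamma reports +G gamma.
#'
#' @inheritParams compute_forces
#' @return named vector `c(sxx, syy, szz, sxy, sxz, syz, pressure)`
#' @export
compute_virial_stress <- function(system, topology, ff) {
  f <- compute_forces(system, topology, ff)
  v <- system$vel
  V <- box_volume(system$box)
  kin <- c(sum(v[, 1]^2), sum(v[, 2]^2), sum(v[, 3]^2),
           sum(v[, 1] * v[, 2]), sum(v[, 1] * v[, 3]), sum(v[, 2] * v[, 3]))
  s <- (kin + f$virial[c("xx", "yy", "zz", "xy", "xz", "yz")]) / V
  s[4:6] <- -s[4:6]
  names(s) <- c("sxx", "syy", "szz", "sxy", "sxz", "syz")
  c(s, pressure = mean(s[1:3]))
}

#' Minimum pair distance in a configuration
#'
#' @param system a [particle_system()]
#' @return smallest minimum-image pair distance (sigma)
#' @export
minimum_distance <- function(system) {
  cpp_min_distance(system$pos, box_to_list(system$box))
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Zero-momentum Gaussian velocities at temperature `temp` (kB = m = 1).
#'
#' @param system a [particle_system()]
#' @param temp target temperature (eps/kB)
#' @param seed optional integer seed
#' @return the system with fresh velocities
#' @export
init_velocities <- function(system, temp = 1, seed = NULL) {
  n <- nrow(system$pos)
  with_seed(seed, {
    v <- matrix(rnorm(3 * n, sd = sqrt(temp)), n, 3)
    v <- sweep(v, 2, colMeans(v))
    system$vel <- v
  })
  system
}
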