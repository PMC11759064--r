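# Initial-configuration builders: melts, solvated mixtures, sticker-spacer
# chains and cross-linked gels. All builders are pure functions of
# (composition, blueprint): the composition's seed fully determines the
# output.

TYPE_POLYMER <- 1L
TYPE_SOLVENT <- 2L
TYPE_STICKER <- 3L

#' System composition
#'
#' What to build: chain count and length, polymer/solvent/gel volume
#' fractions, sticker placement and strength, cross-linking mode, target
#' number density and the seed.
#'
#' The standard study compositions use polymer:solvent fractions 1:2, 1:1,
#' 2:1 and 1:0 with chain lengths Np = 200 or 20, at rho = 0.85 sigma^-3.
#'
#' @param n_chains number of chains (>= 1)
#' @param np beads per chain (>= 1)
#' @param phi_p,phi_s,phi_g polymer, solvent and gel volume fractions; must
#'   sum to 1
#' @param sticker_interval place a sticker every this many beads (0 = none)
#' @param sticker_strength chi_ps, the sticker-sticker attraction in eps
#' @param crosslink_mode `"none"`, `"transient"` (attractive sticker channel
#'   only) or `"irreversible"` (permanent harmonic links via
#'   [crosslink_gel()])
#' @param target_density total bead number density rho (sigma^-3), <= 1.2
#' @param seed integer seed; fully determines the built configuration
#' @return object of class `composition`
#' @export
composition <- function(n_chains, np, phi_p = 1, phi_s = 0, phi_g = 0,
                        sticker_interval = 0, sticker_strength = 1,
                        crosslink_mode = c("none", "transient", "irreversible"),
                        target_density = 0.85, seed = 1) {
  crosslink_mode <- match.arg(crosslink_mode)
  stopifnot(n_chains >= 1, np >= 1, phi_p >= 0, phi_s >= 0, phi_g >= 0)
  if (abs(phi_p + phi_s + phi_g - 1) > 1e-8)
    stop("phi_p + phi_s + phi_g must sum to 1")
  if (phi_p + phi_g <= 0) stop("composition has no polymer component")
  stopifnot(target_density > 0, target_density <= 1.2,
            sticker_interval >= 0, sticker_strength >= 0)
  structure(list(n_chains = as.integer(n_chains), np = as.integer(np),
                 phi_p = phi_p, phi_s = phi_s, phi_g = phi_g,
                 sticker_interval = as.integer(sticker_interval),
                 sticker_strength = sticker_strength,
                 crosslink_mode = crosslink_mode,
                 target_density = target_density, seed = as.integer(seed)),
            class = "composition")
}

#' Chain blueprint
#'
#' Per-chain mechanics: bead diameter, FENE bond parameters, the optional
#' backbone angle potential that sets chain rigidity, and the equilibrium
#' angle for sticker-sticker-sticker triplets (near 180 degrees, making
#' stiff stickers).
#'
#' @param sigma bead diameter (the length unit)
#' @param bond named vector `c(k =, R0 =)` of FENE parameters
#' @param angle `NULL` for fully flexible chains, else a list
#'   `list(k =, theta0 =)` with `theta0` the equilibrium backbone angle in
#'   degrees (e.g. 111.6 for the flexible limit, 120-170 for semiflexible)
#' @param sticker_angle equilibrium angle (degrees) for sticker triplets
#' @return object of class `chain_blueprint`
#' @export
chain_blueprint <- function(sigma = 1, bond = c(k = 30, R0 = 1.5),
                            angle = NULL, sticker_angle = 180) {
  if (!is.null(angle))
    stopifnot(is.list(angle), !is.null(angle$k), !is.null(angle$theta0),
              angle$theta0 > 0, angle$theta0 <= 180)
  stopifnot(sigma > 0, bond["k"] > 0, bond["R0"] > 0,
            sticker_angle > 0, sticker_angle <= 180)
  structure(list(sigma = sigma, bond = bond, angle = angle,
                 sticker_angle = sticker_angle),
            class = "chain_blueprint")
}

# grow one chain as a random walk with bond length b; with an angle model
# the interior angles are drawn from their Boltzmann distribution
# P(theta) ~ exp(-K (theta - theta0)^2 / T) sin(theta), so semiflexible
# chains start with near-equilibrium conformational statistics instead of
# flexible-coil ones. Returns np x 3 unwrapped coordinates.
grow_chain <- function(np, b, start, angle = NULL, temp = 1) {
  xyz <- matrix(0, np, 3)
  xyz[1, ] <- start
  if (np == 1) return(xyz)
  dir_prev <- NULL
  for (i in 2:np) {
    if (is.null(dir_prev) || is.null(angle)) {
      for (try in 1:50) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        # self-avoiding-ish: reject steps folding straight back
        if (is.null(dir_prev) || sum(u * dir_prev) > -0.6) break
      }
    } else {
      # rejection-sample the interior angle, rotate by the deflection about
      # a uniform azimuth
      t0 <- angle$theta0 * pi / 180
      repeat {
        th <- runif(1, 0, pi)
        if (runif(1) < exp(-angle$k * (th - t0)^2 / temp) * sin(th)) break
      }
      defl <- pi - th
      perp <- rnorm(3)
      perp <- perp - sum(perp * dir_prev) * dir_prev
      perp <- perp / sqrt(sum(perp^2))
      phi <- runif(1, 0, 2 * pi)
      ax <- cos(phi) * perp + sin(phi) * vec_cross(dir_prev, perp)
      u <- cos(defl) * dir_prev + sin(defl) * ax
      u <- u / sqrt(sum(u^2))
    }
    xyz[i, ] <- xyz[i - 1, ] + b * u
    dir_prev <- u
  }
  xyz
}

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

wrap_positions <- function(pos, box) {
  for (ax in 1:3)
    if (box$periodic[ax]) pos[, ax] <- pos[, ax] %% box$L[ax]
  pos
}

# soft-core push-off then a short WCA settle, removing overlaps from the
# random-walk start. Bounded retries; errors out as a packing failure.
relax_pushoff <- function(system, topology, ff_target, min_dist = 0.8,
                          max_rounds = 6) {
  n_types <- ff_target$n_types
  for (round in seq_len(max_rounds)) {
    amp <- 10 * 4^(round - 1)
    ff_soft <- forcefield(n_types, eps = amp, sigma = ff_target$sigma,
                          rc = 2^(1/6) * ff_target$sigma, style = "soft",
                          fene = ff_target$fene)
    run <- langevin_run(system, topology, ff_soft, n_steps = 400, dt = 0.005,
                        temp = 1, damping = 2)
    system <- run$system
    # short settle under the real repulsive core, capped timestep
    ff_wca <- forcefield(n_types, eps = 1, sigma = ff_target$sigma,
                         rc = 2^(1/6) * ff_target$sigma, fene = ff_target$fene)
    ok <- tryCatch({
      run <- langevin_run(system, topology, ff_wca, n_steps = 200, dt = 0.002,
                          temp = 1, damping = 2)
      system <- run$system
      TRUE
    }, error = function(e) FALSE)
    if (ok && minimum_distance(system) >= min_dist) return(system)
  }
  stop("packing error: could not reach minimum pair distance ",
       min_dist, " after ", max_rounds, " push-off rounds")
}

build_chain_topology <- function(n_chains, np, blueprint) {
  bonds <- NULL
  angles <- NULL
  for (c in seq_len(n_chains)) {
    off <- (c - 1) * np
    if (np >= 2)
      bonds <- rbind(bonds, cbind(off + 1:(np - 1), off + 2:np))
    if (!is.null(blueprint$angle) && np >= 3)
      angles <- rbind(angles, cbind(off + 1:(np - 2), off + 2:(np - 1),
                                    off + 3:np))
  }
  nb <- if (is.null(bonds)) 0 else nrow(bonds)
  na <- if (is.null(angles)) 0 else nrow(angles)
  cg_topology(
    n_atoms = n_chains * np, bonds = bonds,
    bond_type = rep(1L, nb),
    bond_k = rep(unname(blueprint$bond["k"]), nb),
    bond_r0 = rep(unname(blueprint$bond["R0"]), nb),
    angles = angles,
    angle_k = rep(if (is.null(blueprint$angle)) 0 else blueprint$angle$k, na),
    angle_theta0 = rep(if (is.null(blueprint$angle)) pi
                       else blueprint$angle$theta0 * pi / 180, na),
    types = rep(TYPE_POLYMER, n_chains * np)
  )
}

#' Build a polymer melt
#'
#' Grows `n_chains` random-walk chains with bond length 0.97 sigma in a
#' cubic periodic box sized for the target density, then removes overlaps
#' with a soft-core push-off so that no pair sits below 0.8 sigma. Chain ids
#' are contiguous; the topology lists Np-1 FENE bonds per chain and, when
#' the blueprint carries an angle model, Np-2 angle terms per chain.
#'
#' @param comp a [composition()]
#' @param blueprint a [chain_blueprint()]
#' @param relax run the push-off relaxation (default TRUE; skipping it is
#'   only useful for inspecting raw random-walk starts)
#' @return list with `system` ([particle_system()]) and `topology`
#'   ([cg_topology()])
#' @export
build_melt <- function(comp, blueprint = chain_blueprint(), relax = TRUE) {
  stopifnot(inherits(comp, "composition"), inherits(blueprint, "chain_blueprint"))
  if (comp$n_chains < 1) stop("zero chains requested")
  n <- comp$n_chains * comp$np
  L <- (n / comp$target_density)^(1 / 3)
  rc_max <- 2^(1/6) * blueprint$sigma
  if (L < 2 * rc_max)
    stop("box edge ", round(L, 3), " below 2*rc; too few beads for density")
  box <- simulation_box(L)
  topo <- build_chain_topology(comp$n_chains, comp$np, blueprint)
  with_seed(comp$seed, {
    pos <- NULL
    for (c in seq_len(comp$n_chains)) {
      start <- runif(3, 0, L)
      pos <- rbind(pos, grow_chain(comp$np, 0.97 * blueprint$sigma, start,
                                   angle = blueprint$angle))
    }
    # positions are left unwrapped (chains continuous); the integrator wraps
    # them on the fly while tracking image flags
    sys <- particle_system(pos, type = topo$types,
                           chain = rep(seq_len(comp$n_chains), each = comp$np),
                           box = box)
    sys <- init_velocities(sys, temp = 1)
    if (relax && comp$np * comp$n_chains > 1) {
      ff <- forcefield(1, sigma = blueprint$sigma, fene = blueprint$bond)
      sys <- relax_pushoff(sys, topo, ff)
    }
  })
  list(system = sys, topology = topo)
}

#' Build a solvated polymer mixture
#'
#' Polymer chains as in [build_melt()] plus free solvent monomers (distinct
#' type id) inserted to meet the requested phi_p:phi_s ratio at the target
#' total density. The solvent count is `round(phi_s/phi_p x polymer beads)`
#' (deterministic integer rounding). With phi_s = 0 this reduces to
#' [build_melt()].
#'
#' @inheritParams build_melt
#' @return list with `system` and `topology`
#' @export
build_solvated <- function(comp, blueprint = chain_blueprint(), relax = TRUE) {
  stopifnot(inherits(comp, "composition"))
  if (comp$phi_s <= 0) return(build_melt(comp, blueprint, relax))
  n_poly <- comp$n_chains * comp$np
  n_solv <- round(comp$phi_s / comp$phi_p * n_poly)
  n <- n_poly + n_solv
  L <- (n / comp$target_density)^(1 / 3)
  box <- simulation_box(L)
  topo <- build_chain_topology(comp$n_chains, comp$np, blueprint)
  topo$n_atoms <- as.integer(n)
  topo$types <- c(topo$types, rep(TYPE_SOLVENT, n_solv))
  with_seed(comp$seed, {
    pos <- NULL
    for (c in seq_len(comp$n_chains)) {
      start <- runif(3, 0, L)
      pos <- rbind(pos, grow_chain(comp$np, 0.97 * blueprint$sigma, start,
                                   angle = blueprint$angle))
    }
    pos <- rbind(pos, matrix(runif(3 * n_solv, 0, L), n_solv, 3))
    sys <- particle_system(pos, type = topo$types,
                           chain = c(rep(seq_len(comp$n_chains), each = comp$np),
                                     rep(0L, n_solv)),
                           box = box)
    sys <- init_velocities(sys, temp = 1)
    if (relax) {
      ff <- forcefield(2, sigma = blueprint$sigma, fene = blueprint$bond)
      sys <- relax_pushoff(sys, topo, ff)
    }
  })
  list(system = sys, topology = topo)
}

#' Place sticker beads along the chains
#'
#' Retypes every `interval`-th bead of each chain as a sticker and adds a
#' stiff angle term (equilibrium `sticker_angle`, default near 180 degrees)
#' to every triplet of consecutive stickers on the same backbone. The
#' sticker-sticker nonbonded channel is activated separately on the
#' forcefield via [sticker_forcefield()] with strength chi_ps.
#'
#' @param topology a [cg_topology()] whose chains are contiguous bead runs
#' @param chain integer chain id per bead (as in the built system)
#' @param interval sticker spacing in beads (>= 2); an interval larger than
#'   the chain length places no stickers and warns
#' @param sticker_angle equilibrium sticker-triplet angle in degrees
#' @param angle_k sticker-triplet angle stiffness (energy/rad^2)
#' @return the modified topology
#' @export
place_stickers <- function(topology, chain, interval, sticker_angle = 180,
                           angle_k = 10) {
  stopifnot(inherits(topology, "cg_topology"), interval >= 2)
  chains <- split(seq_len(topology$n_atoms), chain)
  chains <- chains[names(chains) != "0"]
  np <- max(lengths(chains))
  if (interval > np) {
    warning("sticker interval exceeds chain length; no stickers placed")
    return(topology)
  }
  new_angles <- NULL
  for (idx in chains) {
    within <- seq_along(idx)
    st <- idx[within %% interval == 0]
    topology$types[st] <- TYPE_STICKER
    if (length(st) >= 3)
      new_angles <- rbind(new_angles,
                          cbind(st[1:(length(st) - 2)], st[2:(length(st) - 1)],
                                st[3:length(st)]))
  }
  if (!is.null(new_angles)) {
    topology$angles <- rbind(topology$angles, new_angles)
    topology$angle_k <- c(topology$angle_k, rep(angle_k, nrow(new_angles)))
    topology$angle_theta0 <- c(topology$angle_theta0,
                               rep(sticker_angle * pi / 180, nrow(new_angles)))
  }
  validate_topology(topology)
  topology
}

#' Activate the sticker-sticker attraction channel
#'
#' Gives sticker pairs (type 3) an attractive LJ well of depth `chi_ps`
#' with cutoff `rc` (default 4 sigma, where the attraction has decayed to
#' zero). This is the transient-sticker route: stickers bind and unbind
#' thermally with a lifetime set by chi_ps.
#'
#' @param ff a [forcefield()] with at least 3 types
#' @param chi_ps sticker-sticker well depth in eps
#' @param rc attraction cutoff
#' @return the modified forcefield
#' @export
sticker_forcefield <- function(ff, chi_ps, rc = 4) {
  stopifnot(ff$n_types >= TYPE_STICKER)
  set_pair(ff, TYPE_STICKER, TYPE_STICKER, eps = chi_ps, rc = rc)
}

#' Irreversibly cross-link stickers into a gel
#'
#' Adds permanent harmonic bonds between eligible sticker pairs within
#' `cutoff`, each sticker used at most once per pass, pairs taken in order
#' of increasing distance (ties by lowest bead index). `linker_fraction`
#' scales how many of the possible links are made. The connectivity of the
#' resulting network (fraction of polymer beads in the largest connected
#' component) is attached as attribute `"connectivity"`.
#'
#' @param system a relaxed [particle_system()]
#' @param topology a [cg_topology()] with stickers placed
#' @param linker_fraction fraction of matchable sticker pairs to link,
#'   in (0, 1]; 0 returns the topology unchanged
#' @param cutoff maximum link length (sigma)
#' @param seed integer seed (the pairing itself is deterministic; the seed
#'   is consumed only if subsampling ever randomises, kept for API
#'   stability)
#' @param link_k harmonic stiffness of the new bonds
#' @return the topology with extra harmonic bonds; attributes
#'   `"n_links"` and `"connectivity"` report the outcome
#' @export
crosslink_gel <- function(system, topology, linker_fraction = 1,
                          cutoff = 1.3, seed = 1, link_k = 30) {
  stopifnot(linker_fraction >= 0, linker_fraction <= 1)
  stickers <- which(topology$types == TYPE_STICKER)
  if (linker_fraction == 0 || length(stickers) < 2) {
    attr(topology, "n_links") <- 0L
    attr(topology, "connectivity") <- largest_component_fraction(topology)
    return(topology)
  }
  pos <- system$pos
  box <- box_to_list(system$box)
  # candidate sticker pairs within cutoff (min image); links join different
  # chains - intra-chain loops add no network connectivity
  cand <- NULL
  for (a in seq_along(stickers)) {
    i <- stickers[a]
    js <- stickers[-seq_len(a)]
    js <- js[system$chain[js] != system$chain[i] | system$chain[i] == 0]
    if (!length(js)) next
    d <- min_image_dist(pos[i, , drop = FALSE], pos[js, , drop = FALSE],
                        system$box)
    keep <- which(d <= cutoff)
    if (length(keep))
      cand <- rbind(cand, cbind(i, js[keep], d[keep]))
  }
  if (is.null(cand)) {
    attr(topology, "n_links") <- 0L
    attr(topology, "connectivity") <- largest_component_fraction(topology)
    return(topology)
  }
  ord <- order(cand[, 3], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  target <- max(1L, floor(linker_fraction * length(stickers) / 2))
  used <- logical(topology$n_atoms)
  links <- NULL
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used[i] || used[j]) next
    links <- rbind(links, cand[r, ])
    used[i] <- used[j] <- TRUE
    if (nrow(links) >= target) break
  }
  if (!is.null(links)) {
    topology$bonds <- rbind(topology$bonds, links[, 1:2, drop = FALSE])
    topology$bond_type <- c(topology$bond_type, rep(2L, nrow(links)))
    topology$bond_k <- c(topology$bond_k, rep(link_k, nrow(links)))
    topology$bond_r0 <- c(topology$bond_r0, pmin(pmax(links[, 3], 0.8), cutoff))
    validate_topology(topology)
  }
  attr(topology, "n_links") <- if (is.null(links)) 0L else nrow(links)
  attr(topology, "connectivity") <- largest_component_fraction(topology)
  topology
}

# fraction of polymer-type beads in the largest bonded component
largest_component_fraction <- function(topology) {
  poly <- topology$types != TYPE_SOLVENT
  if (nrow(topology$bonds) == 0) return(1 / max(1, sum(poly)))
  g <- igraph::graph_from_edgelist(topology$bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, topology$n_atoms - igraph::vcount(g)))
  comp <- igraph::components(g)
  members <- which(comp$membership == which.max(tabulate(
    comp$membership[poly], nbins = comp$no)))
  sum(poly[members]) / sum(poly)
}

# min-image distances from one point to a set of points
min_image_dist <- function(p, q, box) {
  d <- sweep(q, 2, as.numeric(p))
  for (ax in 3:1) {
    if (box$periodic[ax]) {
      n <- round(d[, ax] / box$L[ax])
      d[, ax] <- d[, ax] - n * box$L[ax]
      if (ax == 2 && box$tilt != 0) d[, 1] <- d[, 1] - n * box$tilt
    }
  }
  sqrt(rowSums(d^2))
}
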