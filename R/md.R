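# Langevin dynamics drivers. The hot loop lives in compiled code
# (src/engine.cpp); these wrappers manage seeds, strides and the stress /
# trajectory records.

#' Stress time series
#'
#' Off-diagonal stresses, normal-stress differences, kinetic temperature and
#' (for sheared runs) the applied strain, on a uniform time grid, together
#' with the box volume and the thermostat temperature needed by the
#' Green-Kubo estimator.
#'
#' @param data data.frame with columns `t`, `strain`, `sxy`, `sxz`, `syz`,
#'   `sxx`, `syy`, `szz`, `Tkin` (and optionally `pe`)
#' @param volume box volume (sigma^3)
#' @param temperature thermostat temperature (eps/kB)
#' @return object of class `stress_series` (a data.frame with attributes)
#' @export
stress_series <- function(data, volume, temperature) {
  need <- c("t", "sxy", "sxz", "syz")
  stopifnot(all(need %in% names(data)), volume > 0, temperature > 0)
  if (nrow(data) > 2) {
    dt <- diff(data$t)
    if (max(abs(dt - dt[1])) > 1e-8 * max(abs(dt)))
      stop("stress series must have a uniform time stride")
  }
  structure(as.data.frame(data), volume = volume, temperature = temperature,
            class = c("stress_series", "data.frame"))
}

# normal-stress differences Nij = Sii - Sjj; NULL if diagonals absent
normal_diffs <- function(stress) {
  if (!all(c("sxx", "syy", "szz") %in% names(stress))) return(NULL)
  data.frame(nxy = stress$sxx - stress$syy,
             nxz = stress$sxx - stress$szz,
             nyz = stress$syy - stress$szz)
}

#' Run Langevin dynamics
#'
#' BAOAB-discretised Langevin dynamics at temperature `temp` with friction
#' `damping`; `damping = 0` gives plain velocity-Verlet (NVE). Stress and
#' trajectory frames are recorded at fixed strides. Noise is drawn from R's
#' RNG, so `seed` (or the caller's RNG state) fully determines the
#' trajectory.
#'
#' @param system a [particle_system()]
#' @param topology a [cg_topology()]
#' @param ff a [forcefield()]
#' @param n_steps number of timesteps
#' @param dt timestep (tau); 0.005-0.01 is the standard range
#' @param temp thermostat temperature (eps/kB)
#' @param damping Langevin friction gamma (1/tau); default 1
#' @param stress_stride record stress every this many steps (0 = never)
#' @param traj_stride record an unwrapped trajectory frame every this many
#'   steps (0 = never)
#' @param seed optional integer seed
#' @return list with the final `system`, `stress` (a [stress_series()] or
#'   NULL), `traj` (list of unwrapped N x 3 frames), `traj_times`, and the
#'   final potential `energy`
#' @export
langevin_run <- function(system, topology, ff, n_steps, dt = 0.005, temp = 1,
                         damping = 1, stress_stride = 0, traj_stride = 0,
                         seed = NULL) {
  stopifnot(dt > 0, n_steps >= 1, damping >= 0)
  res <- with_seed(seed,
    cpp_run(system$pos, system$vel, system$image, system$type,
            box_to_list(system$box), ff_to_pairlist(ff),
            topo_to_list(topology),
            as.integer(n_steps), dt, temp, damping,
            0, 0, 0,
            as.integer(stress_stride), as.integer(traj_stride), 0.3))
  finish_run(system, res, temp)
}

finish_run <- function(system, res, temp) {
  system$pos <- res$pos
  system$vel <- res$vel
  system$image <- res$image
  system$box$tilt <- res$tilt
  stress <- NULL
  if (nrow(res$stress) > 0)
    stress <- stress_series(as.data.frame(res$stress),
                            volume = box_volume(system$box),
                            temperature = temp)
  list(system = system, stress = stress, traj = res$traj,
       traj_times = if (length(res$traj))
         seq_along(res$traj) * (res$t_end / max(1, length(res$traj)))
       else numeric(),
       energy = res$energy, t_end = res$t_end)
}

#' Oscillatory shear protocol
#'
#' Parameters of a sinusoidal box deformation gamma_xy(t) = gamma0 sin(w t).
#'
#' @param gamma0 strain amplitude (dimensionless); ~0.1 stays in the linear
#'   regime for the standard melts
#' @param omega angular frequency (rad/tau)
#' @param dt timestep (tau)
#' @param n_cycles number of full strain cycles to run
#' @param temp thermostat temperature
#' @param damping Langevin friction (applied to peculiar velocities)
#' @param stress_stride steps between stress records
#' @return object of class `shear_protocol`
#' @export
shear_protocol <- function(gamma0, omega, dt = 0.005, n_cycles = 8, temp = 1,
                           damping = 1, stress_stride = 5) {
  stopifnot(gamma0 > 0, omega > 0, dt > 0, n_cycles >= 1)
  if (dt < 0.0005 || dt > 0.05)
    warning("timestep outside the usual 0.005-0.01 tau range")
  if (omega * dt > 0.1)
    stop("resolution error: omega * dt = ", signif(omega * dt, 3),
         " rad/step exceeds 0.1; reduce dt or omega")
  structure(list(gamma0 = gamma0, omega = omega, dt = dt,
                 n_cycles = as.integer(n_cycles), temp = temp,
                 damping = damping, stress_stride = as.integer(stress_stride)),
            class = "shear_protocol")
}

#' Run oscillatory shear
#'
#' Deforms the (periodic) box with sinusoidal xy strain using a tilted box
#' with Lees-Edwards wrapping; the thermostat acts on peculiar velocities
#' (the affine streaming profile is removed). Records the shear stress
#' Sigma_xy(t) together with the applied strain for [os_moduli()].
#'
#' @inheritParams langevin_run
#' @param protocol a [shear_protocol()]
#' @return as [langevin_run()]; the stress series carries the applied
#'   strain in its `strain` column
#' @export
oscillatory_shear_run <- function(system, topology, ff, protocol,
                                  traj_stride = 0, seed = NULL) {
  stopifnot(inherits(protocol, "shear_protocol"))
  if (!all(system$box$periodic))
    stop("oscillatory shear requires a fully periodic box")
  period <- 2 * pi / protocol$omega
  n_steps <- ceiling(protocol$n_cycles * period / protocol$dt)
  res <- with_seed(seed,
    cpp_run(system$pos, system$vel, system$image, system$type,
            box_to_list(system$box), ff_to_pairlist(ff),
            topo_to_list(topology),
            as.integer(n_steps), protocol$dt, protocol$temp, protocol$damping,
            protocol$gamma0, protocol$omega, 0,
            protocol$stress_stride, as.integer(traj_stride), 0.3))
  out <- finish_run(system, res, protocol$temp)
  out$protocol <- protocol
  out
}

#' Kinetic temperature of a stress record
#'
#' @param stress a [stress_series()]
#' @return mean kinetic temperature and its blocked standard error
#' @export
kinetic_temperature <- function(stress) {
  x <- stress$Tkin
  nb <- max(2, min(20, floor(length(x) / 10)))
  blocks <- split(x, cut(seq_along(x), nb, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  c(mean = mean(x), se = sd(bm) / sqrt(length(bm)))
}
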