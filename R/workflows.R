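# Config-driven orchestration: validated configuration, reduced-scale
# end-to-end workflows mirroring the study's experiments, and run manifests
# with file checksums for reproducibility.

default_config <- function() {
  list(
    build = list(n_chains = 16L, np = 10L, density = 0.85,
                 sticker_interval = 5L, chi_ps = 1.5),
    engine = list(dt = 0.005, temp = 1, damping = 1, seed = 1L,
                  stress_stride = 4L, equil_tau = 20, prod_tau = 150),
    rheology = list(p = 16L, gamma0 = 0.1, n_modes = NULL),
    aging = list(evap_rate = 10, evap_slab = 0.5, duration = 30,
                 chi_ps = 1.5)
  )
}

#' Validate and normalize a configuration
#'
#' Accepts a YAML file path, a list, or nothing (full defaults). Unknown
#' keys and out-of-range values are reported as an itemized error list;
#' missing keys are filled with defaults. Normalization is idempotent.
#'
#' @param config path to a YAML config file, a nested list, or `NULL`
#' @return normalized config list of class `cg_config`
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  def <- default_config()
  errors <- character()
  bad_sections <- setdiff(names(config), names(def))
  if (length(bad_sections))
    errors <- c(errors, paste("unknown section(s):",
                              paste(bad_sections, collapse = ", ")))
  out <- def
  for (sec in intersect(names(config), names(def))) {
    bad_keys <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(bad_keys))
      errors <- c(errors, sprintf("unknown key(s) in [%s]: %s", sec,
                                  paste(bad_keys, collapse = ", ")))
    for (k in intersect(names(config[[sec]]), names(def[[sec]])))
      out[[sec]][k] <- config[[sec]][k] # single-bracket keeps NULL values
  }
  if (out$engine$dt <= 0 || out$engine$dt > 0.05)
    errors <- c(errors,
                sprintf("engine.dt = %g outside (0, 0.05] tau", out$engine$dt))
  if (out$rheology$gamma0 <= 0)
    errors <- c(errors, "rheology.gamma0 must be positive")
  if (out$build$np < 1 || out$build$n_chains < 1)
    errors <- c(errors, "build.np and build.n_chains must be >= 1")
  if (out$aging$evap_rate < 0)
    errors <- c(errors, "aging.evap_rate must be >= 0")
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  class(out) <- "cg_config"
  out
}

workflow_names <- c("solvent_sweep", "rigidity_sweep", "length_compare",
                    "gel_vs_melt", "sticker_sweep", "aging", "phase_diagram")

# equilibrate then record an equilibrium stress series; shared by workflows
equil_and_sample <- function(system, topology, ff, cfg, prod_tau = NULL) {
  eng <- cfg$engine
  nequil <- round(eng$equil_tau / eng$dt)
  nprod <- round((if (is.null(prod_tau)) eng$prod_tau else prod_tau) / eng$dt)
  run <- langevin_run(system, topology, ff, n_steps = nequil, dt = eng$dt,
                      temp = eng$temp, damping = eng$damping)
  langevin_run(run$system, topology, ff, n_steps = nprod, dt = eng$dt,
               temp = eng$temp, damping = eng$damping,
               stress_stride = eng$stress_stride)
}

#' Green-Kubo modulus spectrum
#'
#' Convenience pipeline: stress series -> G*(t) via [gk_complex_modulus()]
#' -> generalized Maxwell fit -> analytic G'(w), G''(w) evaluated over the
#' frequency window resolved by the data (1/t_max to 1/t_min by default).
#'
#' @param stress an equilibrium [stress_series()]
#' @param n_modes Maxwell mode count (NULL = automatic)
#' @param omega frequencies to evaluate; default spans the resolved window
#' @param p multi-tau lags per level
#' @param include_fast_dissipation add `omega * eta_fast` to the loss
#'   modulus, where `eta_fast` is the trapezoidal integral of G*(t) over
#'   the short-time window the Maxwell fit excludes (the bond-vibration /
#'   glassy part). This is what an oscillatory-shear measurement sees at
#'   finite frequency, so turn it on when comparing against OS moduli.
#' @return list with `Gt` (complex modulus series), `fit` (`maxwell_fit`),
#'   `spectrum` ([modulus_spectrum()]), `eta_fast`
#' @export
gk_modulus_spectrum <- function(stress, n_modes = NULL, omega = NULL, p = 16,
                                include_fast_dissipation = FALSE) {
  Gt <- gk_complex_modulus(stress, p = p)
  fit <- fit_maxwell(Gt, n_modes = n_modes)
  if (is.null(omega)) {
    tpos <- Gt$t[Gt$t > 0]
    omega <- 10^seq(log10(1 / max(tpos)), log10(1 / min(tpos)),
                    length.out = 40)
  }
  # dissipation carried by the window below the fit (finely sampled at the
  # native stride, so the trapezoid is accurate there)
  eta_fast <- 0
  if (!is.null(fit$fit_window)) {
    fastwin <- Gt$t <= fit$fit_window[1]
    if (sum(fastwin) >= 2) {
      tf <- Gt$t[fastwin]; gf <- Gt$G[fastwin]
      eta_fast <- sum(diff(tf) * (head(gf, -1) + tail(gf, -1)) / 2)
    }
  }
  spectrum <- predict(fit, omega = omega)
  if (include_fast_dissipation)
    spectrum$Gpp <- spectrum$Gpp + spectrum$omega * eta_fast
  list(Gt = Gt, fit = fit, spectrum = spectrum, eta_fast = eta_fast)
}

write_spectrum_csv <- function(spectrum, path) {
  write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  path
}

#' Run a named end-to-end workflow
#'
#' Builds the systems, runs the engine, applies the analysis and writes all
#' artifacts plus a JSON manifest (config snapshot, seeds, package version,
#' output registry with checksums). All presets are reduced-scale desk
#' runs.
#'
#' Workflows: `solvent_sweep` (phi_p:phi_s = 1:2, 1:1, 2:1, 1:0 spectra +
#' crossover summary), `rigidity_sweep` (flexible vs semiflexible),
#' `length_compare` (short vs longer chains), `gel_vs_melt` (Kelvin-Voigt
#' gel vs Maxwell melt classification), `sticker_sweep` (transient sticker
#' strengths), `aging` (evaporation run + corona metrics), `phase_diagram`
#' (slab coexistence over a small temperature grid + critical fit).
#'
#' @param name one of the workflow names above
#' @param config a [validate_config()] result, or anything it accepts
#' @param output_dir directory for artifacts (created if needed)
#' @return the manifest (invisibly readable from `manifest.json`); each
#'   workflow also returns its key results in `$results`
#' @export
run_workflow <- function(name, config = NULL, output_dir = tempfile("wf_")) {
  name <- match.arg(name, workflow_names)
  cfg <- if (inherits(config, "cg_config")) config else validate_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  seed <- cfg$engine$seed
  set.seed(seed) # every stochastic stage below draws from this stream
  results <- switch(
    name,
    solvent_sweep = wf_solvent_sweep(cfg, output_dir),
    rigidity_sweep = wf_rigidity_sweep(cfg, output_dir),
    length_compare = wf_length_compare(cfg, output_dir),
    gel_vs_melt = wf_gel_vs_melt(cfg, output_dir),
    sticker_sweep = wf_sticker_sweep(cfg, output_dir),
    aging = wf_aging(cfg, output_dir),
    phase_diagram = wf_phase_diagram(cfg, output_dir))
  files <- setdiff(list.files(output_dir, full.names = TRUE,
                              recursive = TRUE),
                   file.path(output_dir, "manifest.json"))
  manifest <- list(
    workflow = name,
    package_version = as.character(packageVersion("cgrheo")),
    config = unclass(cfg),
    seed = seed,
    wall_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, results = results,
                 output_dir = output_dir))
}

wf_solvent_sweep <- function(cfg, out) {
  ratios <- list(c(1, 2), c(1, 1), c(2, 1), c(1, 0))
  cross <- NULL
  specs <- list()
  for (r in ratios) {
    phi_p <- r[1] / sum(r); phi_s <- r[2] / sum(r)
    comp <- composition(cfg$build$n_chains, cfg$build$np, phi_p = phi_p,
                        phi_s = phi_s, target_density = cfg$build$density,
                        seed = cfg$engine$seed)
    built <- build_solvated(comp, chain_blueprint(angle = list(k = 10, theta0 = 150)))
    ff <- forcefield(2)
    run <- equil_and_sample(built$system, built$topology, ff, cfg)
    sp <- gk_modulus_spectrum(run$stress, p = cfg$rheology$p)
    tag <- sprintf("phi_%g_%g", r[1], r[2])
    write_spectrum_csv(sp$spectrum, file.path(out, paste0("spectrum_", tag, ".csv")))
    cw <- crossover_frequencies(sp$spectrum)
    if (nrow(cw)) cw$ratio <- tag
    cross <- rbind(cross, cw)
    specs[[tag]] <- sp
  }
  if (is.null(cross)) cross <- data.frame()
  write.csv(cross, file.path(out, "crossover_summary.csv"), row.names = FALSE)
  list(spectra = specs, crossovers = cross)
}

wf_rigidity_sweep <- function(cfg, out) {
  cases <- list(flexible = NULL, semiflexible = list(k = 10, theta0 = 150))
  res <- list()
  for (nm in names(cases)) {
    comp <- composition(cfg$build$n_chains, cfg$build$np,
                        target_density = cfg$build$density,
                        seed = cfg$engine$seed)
    built <- build_melt(comp, chain_blueprint(angle = cases[[nm]]))
    run <- equil_and_sample(built$system, built$topology, forcefield(1), cfg)
    sp <- gk_modulus_spectrum(run$stress, p = cfg$rheology$p)
    write_spectrum_csv(sp$spectrum, file.path(out, paste0("spectrum_", nm, ".csv")))
    res[[nm]] <- sp
  }
  res
}

wf_length_compare <- function(cfg, out) {
  res <- list()
  for (np in c(cfg$build$np, max(2L, cfg$build$np %/% 4L))) {
    n_chains <- max(2L, round(cfg$build$n_chains * cfg$build$np / np))
    comp <- composition(n_chains, np, target_density = cfg$build$density,
                        seed = cfg$engine$seed)
    built <- build_melt(comp, chain_blueprint())
    run <- equil_and_sample(built$system, built$topology, forcefield(1), cfg)
    sp <- gk_modulus_spectrum(run$stress, p = cfg$rheology$p)
    tag <- paste0("np", np)
    write_spectrum_csv(sp$spectrum, file.path(out, paste0("spectrum_", tag, ".csv")))
    res[[tag]] <- sp
  }
  res
}

wf_gel_vs_melt <- function(cfg, out) {
  # melt: flexible homopolymer chains -> Maxwell fluid
  comp <- composition(cfg$build$n_chains, cfg$build$np,
                      target_density = cfg$build$density,
                      seed = cfg$engine$seed)
  melt <- build_melt(comp, chain_blueprint())
  run_m <- equil_and_sample(melt$system, melt$topology, forcefield(1), cfg)
  sp_m <- gk_modulus_spectrum(run_m$stress, p = cfg$rheology$p)

  # gel: stickers irreversibly cross-linked into a percolating network.
  # Reduced preset uses a dense two-bead sticker interval: a tiny gel needs
  # that linker density to percolate across the box.
  gel_interval <- 2L
  gelc <- composition(cfg$build$n_chains, cfg$build$np,
                      sticker_interval = gel_interval,
                      crosslink_mode = "irreversible",
                      target_density = cfg$build$density,
                      seed = cfg$engine$seed + 1)
  gel <- build_melt(gelc, chain_blueprint())
  gel$topology <- place_stickers(gel$topology, gel$system$chain,
                                 interval = gel_interval)
  gel$system <- apply_topology_types(gel$system, gel$topology)
  ff_gel <- forcefield(3)
  short <- langevin_run(gel$system, gel$topology, ff_gel,
                        n_steps = round(5 / cfg$engine$dt),
                        dt = cfg$engine$dt, temp = cfg$engine$temp)
  gel$system <- short$system
  gel$topology <- crosslink_gel(gel$system, gel$topology,
                                linker_fraction = 1, cutoff = 2.5,
                                seed = cfg$engine$seed)
  run_g <- equil_and_sample(gel$system, gel$topology, ff_gel, cfg)
  sp_g <- gk_modulus_spectrum(run_g$stress, p = cfg$rheology$p)

  cls <- list(melt = classify_response(sp_m$spectrum),
              gel = classify_response(sp_g$spectrum))
  write_spectrum_csv(sp_m$spectrum, file.path(out, "spectrum_melt.csv"))
  write_spectrum_csv(sp_g$spectrum, file.path(out, "spectrum_gel.csv"))
  jsonlite::write_json(
    list(melt = cls$melt$classification, gel = cls$gel$classification,
         gel_connectivity = attr(gel$topology, "connectivity")),
    file.path(out, "classification.json"), auto_unbox = TRUE)
  list(classification = cls, spectra = list(melt = sp_m, gel = sp_g),
       connectivity = attr(gel$topology, "connectivity"))
}

wf_sticker_sweep <- function(cfg, out) {
  res <- list()
  for (chi in c(0.5 * cfg$build$chi_ps, cfg$build$chi_ps)) {
    comp <- composition(cfg$build$n_chains, cfg$build$np,
                        sticker_interval = cfg$build$sticker_interval,
                        sticker_strength = chi, crosslink_mode = "transient",
                        target_density = cfg$build$density,
                        seed = cfg$engine$seed)
    built <- build_melt(comp, chain_blueprint())
    built$topology <- place_stickers(built$topology, built$system$chain,
                                     interval = cfg$build$sticker_interval)
    built$system <- apply_topology_types(built$system, built$topology)
    ff <- sticker_forcefield(forcefield(3), chi_ps = chi)
    run <- equil_and_sample(built$system, built$topology, ff, cfg)
    sp <- gk_modulus_spectrum(run$stress, p = cfg$rheology$p)
    tag <- sprintf("chi%g", chi)
    write_spectrum_csv(sp$spectrum, file.path(out, paste0("spectrum_", tag, ".csv")))
    res[[tag]] <- sp
  }
  res
}

wf_aging <- function(cfg, out) {
  built <- build_aging_system(n_chains = cfg$build$n_chains,
                              np = cfg$build$np,
                              phi_s = 0.5,
                              chi_ps = cfg$aging$chi_ps,
                              seed = cfg$engine$seed)
  acfg <- aging_config(evap_rate = cfg$aging$evap_rate,
                       evap_slab = cfg$aging$evap_slab,
                       chi_ps = cfg$aging$chi_ps,
                       duration = cfg$aging$duration,
                       dt = cfg$engine$dt, temp = cfg$engine$temp,
                       seed = cfg$engine$seed)
  trace <- run_aging(built$system, built$topology, built$ff, acfg)
  write.csv(data.frame(t = trace$times, L = trace$L,
                       n_evaporated = trace$n_evaporated),
            file.path(out, "aging_scalars.csv"), row.names = FALSE)
  write.csv(as.data.frame(trace$rho_poly), file.path(out, "rho_poly.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(trace$rho_sol), file.path(out, "rho_sol.csv"),
            row.names = FALSE)
  metrics <- corona_metrics(trace, shell_threshold = 0.5)
  jsonlite::write_json(metrics, file.path(out, "corona_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  list(trace = trace, metrics = metrics)
}

wf_phase_diagram <- function(cfg, out) {
  # subcritical grid for the reduced monomer fluid (force-shifted LJ,
  # rc = 2.5 sigma, whose own critical point sits near T ~ 0.95)
  temps <- c(0.65, 0.72, 0.80)
  pts <- lapply(temps, function(Ti)
    slab_coexistence_run(temperature = Ti, seed = cfg$engine$seed,
                         dt = cfg$engine$dt))
  df <- do.call(rbind, lapply(pts, function(p)
    data.frame(T = p$temperature, rho_l = p$rho_l, rho_v = p$rho_v)))
  write.csv(df, file.path(out, "coexistence.csv"), row.names = FALSE)
  fit <- tryCatch(fit_critical_point(df), error = function(e) NULL)
  if (!is.null(fit))
    jsonlite::write_json(as.list(coef(fit)), file.path(out, "critical_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  list(points = df, fit = fit)
}

#' Build an elongated walled system for aging runs
#'
#' Sticker-spacer chains plus solvent packed into the lower part of a box
#' elongated along x, with reflective x walls and periodic y/z - the
#' starting state of the evaporation protocol.
#'
#' @param n_chains,np chain count and length
#' @param phi_s solvent fraction
#' @param chi_ps sticker strength (eps)
#' @param sticker_interval sticker spacing (beads)
#' @param aspect box elongation factor along x
#' @param density total bead density of the filled region
#' @param angle backbone angle model (default semiflexible, k = 10,
#'   theta0 = 150 degrees)
#' @param seed integer seed
#' @return list with `system`, `topology`, `ff`
#' @export
build_aging_system <- function(n_chains, np, phi_s = 0.5, chi_ps = 1.5,
                               sticker_interval = 5, aspect = 3,
                               density = 0.85,
                               angle = list(k = 10, theta0 = 150),
                               seed = 1) {
  blueprint <- chain_blueprint(angle = angle)
  n_poly <- n_chains * np
  n_solv <- if (phi_s > 0) round(phi_s / (1 - phi_s) * n_poly) else 0L
  n <- n_poly + n_solv
  # material fills the whole elongated box: the evaporation wall starts in
  # contact with the condensate, as the shrink controller assumes
  Lyz <- (n / density / aspect)^(1 / 3)
  Lx <- aspect * Lyz
  box <- simulation_box(c(Lx, Lyz, Lyz), periodic = c(FALSE, TRUE, TRUE),
                        xwalls = c(0, Lx))
  # continuity-preserving fold of x into the walled interval (reflection
  # never lengthens a bond)
  foldx <- function(x, lo, hi) {
    W <- hi - lo
    y <- (x - lo) %% (2 * W)
    lo + ifelse(y < W, y, 2 * W - y)
  }
  topo <- build_chain_topology(n_chains, np, blueprint)
  topo$n_atoms <- as.integer(n)
  topo$types <- c(topo$types, rep(TYPE_SOLVENT, n_solv))
  sys <- with_seed(seed, {
    pos <- NULL
    for (c in seq_len(n_chains)) {
      start <- c(runif(1, 0.3, Lx - 0.3), runif(2, 0, Lyz))
      pos <- rbind(pos, grow_chain(np, 0.97, start, angle = blueprint$angle))
    }
    if (n_solv > 0)
      pos <- rbind(pos, cbind(runif(n_solv, 0.2, Lx - 0.2),
                              matrix(runif(2 * n_solv, 0, Lyz), n_solv, 2)))
    pos[, 1] <- foldx(pos[, 1], 0.2, Lx - 0.2)
    s <- particle_system(pos, type = topo$types,
                         chain = c(rep(seq_len(n_chains), each = np),
                                   rep(0L, n_solv)),
                         box = box)
    s <- init_velocities(s, temp = 1)
    relax_pushoff(s, topo, forcefield(3))
  })
  if (sticker_interval > 0 && sticker_interval <= np) {
    topo <- place_stickers(topo, sys$chain, interval = sticker_interval)
    sys <- apply_topology_types(sys, topo)
  }
  # minimal sticker-spacer interactions: repulsive spacers and solvent,
  # cohesion carried entirely by the sticker-sticker channel chi_ps
  ff <- sticker_forcefield(forcefield(3), chi_ps = chi_ps)
  list(system = sys, topology = topo, ff = ff)
}

#' Slab coexistence run at one temperature
#'
#' Builds a small attractive monomer fluid in an x-elongated periodic box,
#' equilibrates into a slab, samples frames and extracts the coexistence
#' point. Reduced-scale building block of the `phase_diagram` workflow.
#'
#' @param temperature run temperature (eps/kB)
#' @param n particle count
#' @param rho_init overall density (slab forms below the critical point)
#' @param aspect box elongation along x
#' @param equil_tau,prod_tau equilibration and sampling times
#' @param dt timestep
#' @param seed integer seed
#' @return a `coexistence_point`
#' @export
slab_coexistence_run <- function(temperature, n = 400, rho_init = 0.3,
                                 aspect = 4, equil_tau = 60, prod_tau = 60,
                                 dt = 0.005, seed = 1) {
  Lyz <- (n / rho_init / aspect)^(1 / 3)
  Lx <- aspect * Lyz
  box <- simulation_box(c(Lx, Lyz, Lyz))
  with_seed(seed, {
    # start as a moderate-density slab in the middle (rho ~ 0.75, liquid-
    # like but relaxable) to speed equilibration toward coexistence
    slab_w <- n / (0.75 * Lyz^2)
    pos <- cbind(runif(n, (Lx - slab_w) / 2, (Lx + slab_w) / 2),
                 runif(n, 0, Lyz), runif(n, 0, Lyz))
    sys <- particle_system(pos, type = rep(1L, n), chain = rep(0L, n),
                           box = box)
    sys <- init_velocities(sys, temp = temperature)
    topo <- cg_topology(n_atoms = n, types = rep(1L, n))
    sys <- relax_pushoff(sys, topo, forcefield(1))
    ff <- forcefield(1, eps = 1, rc = 2.5, shift_force = TRUE)
    sys <- langevin_run(sys, topo, ff, n_steps = round(equil_tau / dt),
                        dt = dt, temp = temperature)$system
    run <- langevin_run(sys, topo, ff, n_steps = round(prod_tau / dt),
                        dt = dt, temp = temperature,
                        traj_stride = round(1 / dt))
  })
  frames <- lapply(run$traj, function(fr) fr)
  coexistence_from_slab(frames, run$system$box, axis = 1,
                        temperature = temperature)
}
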