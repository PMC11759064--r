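# Shared fixture builders. Everything is generated in code; sizes are kept
# small so each file runs in seconds.

# small WCA melt (chains of np beads), relaxed and equilibrated briefly
tiny_melt <- function(n_chains = 10, np = 5, density = 0.6, seed = 42,
                      angle = NULL, equil_steps = 1000) {
  b <- build_melt(composition(n_chains, np, target_density = density,
                              seed = seed),
                  chain_blueprint(angle = angle))
  ff <- forcefield(1)
  if (equil_steps > 0) {
    run <- langevin_run(b$system, b$topology, ff, n_steps = equil_steps,
                        dt = 0.005, temp = 1, damping = 1, seed = seed + 1)
    b$system <- run$system
  }
  c(b, list(ff = ff))
}

# a random small bonded configuration exercising FENE + harmonic bonds,
# angles and both LJ cutoffs; used by the force-gradient checks
random_bonded_config <- function(seed = 7, n = 12) {
  set.seed(seed)
  pos <- matrix(runif(3 * n, 0, 4), n, 3)
  sys <- particle_system(pos, type = rep(c(1L, 2L), n / 2),
                         chain = rep(1L, n), box = simulation_box(4))
  topo <- cg_topology(n,
                      bonds = cbind(1:(n - 1), 2:n),
                      bond_type = rep(c(1L, 2L), length.out = n - 1),
                      bond_k = rep(30, n - 1),
                      bond_r0 = rep(c(3.0, 1.0), length.out = n - 1),
                      angles = cbind(1:(n - 2), 2:(n - 1), 3:n),
                      angle_k = rep(10, n - 2),
                      angle_theta0 = rep(2.0, n - 2),
                      types = rep(c(1L, 2L), n / 2))
  ff <- forcefield(2, eps = matrix(c(1, 0.5, 0.5, 0.8), 2),
                   rc = matrix(c(2^(1/6), 2.5, 2.5, 4), 2),
                   shift_force = TRUE)
  list(system = sys, topology = topo, ff = ff)
}

# Ornstein-Uhlenbeck sample path (exact discretisation)
ou_series <- function(n, tau = 5, var = 2, dt = 0.1, seed = 1) {
  set.seed(seed)
  a <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sqrt(var))
  innov <- rnorm(n - 1, sd = sqrt(var * (1 - a^2)))
  for (i in 2:n) x[i] <- a * x[i - 1] + innov[i - 1]
  x
}

# brute-force (O(N^2)) unnormalized autocorrelation at given integer lags
direct_acf <- function(x, lags) {
  vapply(lags, function(k) {
    n <- length(x)
    mean(x[1:(n - k)] * x[(1 + k):n])
  }, numeric(1))
}

# stress series with the same signal injected into chosen channels
synthetic_stress <- function(sig, dt = 0.1, volume = 100, temperature = 1,
                             diag_sig = NULL) {
  n <- length(sig)
  zero <- rep(0, n)
  if (is.null(diag_sig)) diag_sig <- list(zero, zero, zero)
  stress_series(data.frame(t = (seq_len(n) - 1) * dt, strain = zero,
                           sxy = sig, sxz = sig, syz = sig,
                           sxx = diag_sig[[1]], syy = diag_sig[[2]],
                           szz = diag_sig[[3]], Tkin = rep(temperature, n)),
                volume = volume, temperature = temperature)
}

# closed-form single-mode Maxwell spectrum
maxwell_spectrum_exact <- function(G1, tau1, omega) {
  modulus_spectrum(omega,
                   G1 * (omega * tau1)^2 / (1 + (omega * tau1)^2),
                   G1 * omega * tau1 / (1 + (omega * tau1)^2))
}

# worm-like-chain ensemble with fixed deflection angle theta_m and uniform
# azimuth; the generator's exact persistence length is -1/log(cos theta_m)
# bond lengths
wlc_chains <- function(n_chains, np, theta_m, b = 1, seed = 1) {
  set.seed(seed)
  frames <- matrix(0, n_chains * np, 3)
  chain <- rep(seq_len(n_chains), each = np)
  for (c in seq_len(n_chains)) {
    xyz <- matrix(0, np, 3)
    t_prev <- c(0, 0, 1)
    for (i in 2:np) {
      # rotate t_prev by theta_m about a random perpendicular axis
      perp <- rnorm(3)
      perp <- perp - sum(perp * t_prev) * t_prev
      perp <- perp / sqrt(sum(perp^2))
      phi <- runif(1, 0, 2 * pi)
      ax <- cos(phi) * perp + sin(phi) * pracma_cross(t_prev, perp)
      t_new <- cos(theta_m) * t_prev + sin(theta_m) * ax
      t_prev <- t_new / sqrt(sum(t_new^2))
      xyz[i, ] <- xyz[i - 1, ] + b * t_prev
    }
    frames[chain == c, ] <- xyz
  }
  list(pos = frames, chain = chain)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# fractional Gaussian displacement trajectory with MSD ~ t^(2H): build
# per-axis fBm via Cholesky of the fGn covariance
fbm_frames <- function(n_particles, n_frames, H, seed = 1) {
  set.seed(seed)
  k <- 0:(n_frames - 2)
  gamma_k <- 0.5 * ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
  C <- stats::toeplitz(gamma_k)
  Lc <- t(chol(C))
  frames <- vector("list", n_frames)
  coords <- matrix(0, n_particles, 3)
  frames[[1]] <- coords
  incr <- array(0, c(n_frames - 1, n_particles, 3))
  for (p in seq_len(n_particles)) for (d in 1:3)
    incr[, p, d] <- Lc %*% rnorm(n_frames - 1)
  for (f in 2:n_frames) {
    coords <- coords + incr[f - 1, , ]
    frames[[f]] <- coords
  }
  frames
}
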