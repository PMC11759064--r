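# Evaporation bookkeeping, wall shrinkage, aging traces, corona metrics.

walled_system <- function(n_solv_slab = 25, n_solv_bulk = 30, n_poly = 20,
                          Lx = 20, Lyz = 5, slab = 0.4, seed = 13) {
  set.seed(seed)
  pos <- rbind(
    cbind(runif(n_poly, 1, 6), runif(n_poly, 0, Lyz), runif(n_poly, 0, Lyz)),
    cbind(runif(n_solv_bulk, 6, Lx - 2), runif(n_solv_bulk, 0, Lyz),
          runif(n_solv_bulk, 0, Lyz)),
    cbind(runif(n_solv_slab, Lx - slab, Lx), runif(n_solv_slab, 0, Lyz),
          runif(n_solv_slab, 0, Lyz)))
  type <- c(rep(1L, n_poly), rep(2L, n_solv_bulk + n_solv_slab))
  box <- simulation_box(c(Lx, Lyz, Lyz), periodic = c(FALSE, TRUE, TRUE),
                        xwalls = c(0, Lx))
  init_velocities(particle_system(pos, type, rep(0L, length(type)), box),
                  temp = 1, seed = seed)
}

test_that("evaporation honours slab, quota and determinism", {
  sys <- walled_system()
  cfg <- aging_config(evap_rate = 10, evap_slab = 0.5, duration = 1)

  # 25 solvent beads in the slab, rate 10/tau, one tau: exactly 10 removed
  ev <- evaporate_step(sys, cfg, elapsed = 1)
  expect_equal(ev$n_removed, 10L)
  expect_equal(sum(ev$system$type == 2L), 55 - 10)
  # polymer untouched
  expect_equal(sum(ev$system$type == 1L), 20)

  # removal order: closest to the wall first
  d_removed <- 20 - sys$pos[ev$removed, 1]
  others <- setdiff(which(sys$type == 2L & sys$pos[, 1] >= 19.5), ev$removed)
  expect_lte(max(d_removed), min(20 - sys$pos[others, 1]) + 1e-12)

  # same state: identical removal set
  ev2 <- evaporate_step(sys, cfg, elapsed = 1)
  expect_identical(ev$removed, ev2$removed)

  # no solvent in the slab: zero removed
  sys_dry <- sys
  sys_dry$pos[sys_dry$type == 2L, 1] <- 5
  ev3 <- evaporate_step(sys_dry, cfg, elapsed = 1)
  expect_equal(ev3$n_removed, 0L)

  # removals never exceed the configured rate quota
  ev4 <- evaporate_step(sys, cfg, elapsed = 0.25)
  expect_lte(ev4$n_removed, floor(10 * 0.25))
})

test_that("wall shrinkage: modes, monotonicity, polymer guard", {
  sys <- walled_system()
  cfg_const <- aging_config(shrink_mode = "constant", shrink_rate = 0.3,
                            duration = 1)
  s1 <- shrink_box(sys, cfg_const, elapsed = 1)
  expect_equal(s1$box$xwalls[2], 20 - 0.3)
  # reflected particles stay inside
  expect_true(all(s1$pos[, 1] <= s1$box$xwalls[2] + 1e-12))

  # wall_follow with balanced pressure: wall barely moves
  cfg_wf <- aging_config(shrink_mode = "wall_follow", shrink_gain = 0.1,
                         duration = 1)
  p0 <- cgrheo:::boundary_slab_pressure(sys, temp = 1)
  s2 <- shrink_box(sys, cfg_wf, reference_pressure = p0, elapsed = 1)
  expect_equal(s2$box$xwalls[2], 20, tolerance = 1e-8)
  # emptied boundary: wall moves inward, never outward
  s3 <- shrink_box(sys, cfg_wf, reference_pressure = p0 * 10, elapsed = 1)
  expect_lt(s3$box$xwalls[2], 20)

  # guard: wall stops at the polymer extent
  sys_tall <- walled_system()
  sys_tall$pos[1, 1] <- 19.3 # a polymer bead near the wall
  s4 <- shrink_box(sys_tall, cfg_const, elapsed = 10)
  expect_equal(s4$box$xwalls[2], 19.8)
  expect_true(isTRUE(attr(s4, "shrink_halted")))
})

test_that("aging run: duration 0, conservation, quota and monotone records", {
  built <- build_aging_system(n_chains = 6, np = 10, phi_s = 0.5,
                              chi_ps = 1.5, aspect = 2, seed = 3)
  cfg0 <- aging_config(duration = 0, n_bins = 10)
  tr0 <- run_aging(built$system, built$topology, built$ff, cfg0)
  expect_equal(length(tr0$times), 1)

  cfg <- aging_config(evap_rate = 5, duration = 6, chunk_tau = 1,
                      n_bins = 16, seed = 5)
  n_solv0 <- sum(built$system$type == 2L)
  n_poly0 <- sum(built$system$type != 2L)
  tr <- run_aging(built$system, built$topology, built$ff, cfg)
  # polymer count constant; solvent decreases exactly by the removals
  expect_equal(sum(tr$system$type != 2L), n_poly0)
  expect_equal(n_solv0 - sum(tr$system$type == 2L),
               tail(tr$n_evaporated, 1))
  # quota: per-interval removals never exceed rate * chunk
  expect_true(all(diff(tr$n_evaporated) <= 5))
  # monotone bookkeeping
  expect_true(all(diff(tr$n_evaporated) >= 0))
  expect_true(all(diff(tr$L) <= 1e-9))
})

test_that("corona metrics: constructed step-function shell, bounds", {
  # hand-built trace: boundary bin densifies at t = 3
  nb <- 10
  rp <- matrix(0.2, 5, nb)
  rp[3:5, nb - 1] <- 0.9
  rp[3:5, nb] <- 0.9
  rs <- matrix(0.3, 5, nb)
  trace <- structure(list(times = 0:4, L = rep(10, 5),
                          n_evaporated = c(0, 5, 10, 15, 20),
                          rho_poly = rp, rho_sol = rs,
                          bin_centers = seq(0.5, 9.5), bin_volume = 25,
                          n_solvent0 = 1000),
                     class = "aging_trace")
  m <- corona_metrics(trace, shell_threshold = 0.5)
  expect_equal(m$shell_onset_time, 2) # times[3]
  expect_equal(m$shell_density, 0.9)
  expect_gte(m$trapped_solvent_fraction, 0)
  expect_lte(m$trapped_solvent_fraction, 1)

  # threshold above every density: no shell
  m2 <- corona_metrics(trace, shell_threshold = 2)
  expect_true(m2$no_shell)

  # trace with no polymer near the boundary
  rp3 <- matrix(0.2, 3, nb); rp3[, 1:2] <- 0.9
  trace3 <- trace
  trace3$rho_poly <- rp3; trace3$times <- 0:2
  trace3$rho_sol <- rs[1:3, ]
  m3 <- corona_metrics(trace3, shell_threshold = 0.5)
  # the dense region hugs the far (non-evaporating) wall: the outermost
  # contiguous run above threshold starts at bin 2, so no boundary shell
  expect_true(m3$no_shell || m3$shell_width_bins <= 2)
})
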