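# Persistence length (two estimators), Rg, MSD exponent, density profiles.

test_that("angle-based persistence length: flexible limit, closed form, guards", {
  # interior angle 111.6 deg -> deflection 68.4 deg -> lp ~ one bond length
  expect_equal(persistence_length_angle(111.6), 1.0, tolerance = 0.01)
  # interior 120 deg: lp = -1/ln(cos 60) = 1/ln 2
  expect_equal(persistence_length_angle(120), 1 / log(2), tolerance = 1e-10)
  # straight limit: large finite value with flag
  straight <- persistence_length_angle(180)
  expect_gt(straight, 1e9)
  expect_true(attr(straight, "straight_limit"))
  expect_error(persistence_length_angle(85), "domain")
})

test_that("tangent estimator matches the worm-like-chain generator", {
  for (theta_m_deg in c(30, 50)) {
    theta_m <- theta_m_deg * pi / 180
    w <- wlc_chains(500, 60, theta_m, seed = theta_m_deg)
    lp <- persistence_length_tangent(w$pos, w$chain)
    expect_equal(as.numeric(lp), -1 / log(cos(theta_m)), tolerance = 0.05)
    # the two estimators agree on the same ensemble
    lp_angle <- persistence_length_angle(180 - theta_m_deg)
    expect_lt(abs(lp - lp_angle) / lp_angle, 0.15)
  }
})

test_that("tangent estimator flags rods and handles freely jointed chains", {
  # straight rigid rods: lower-bound flag
  rod <- matrix(0, 60, 3)
  rod[, 1] <- rep(0:19, 3) * 0.97
  chain <- rep(1:3, each = 20)
  lp <- persistence_length_tangent(rod, chain)
  expect_true(attr(lp, "lower_bound"))

  # freely jointed chains: lp of the order of the bond length
  set.seed(4)
  fj <- lapply(1:200, function(c) {
    steps <- matrix(rnorm(3 * 29), 29, 3)
    steps <- steps / sqrt(rowSums(steps^2))
    rbind(0, apply(steps, 2, cumsum))
  })
  pos <- do.call(rbind, fj)
  lp2 <- persistence_length_tangent(pos, rep(1:200, each = 30))
  expect_lt(as.numeric(lp2), 2)
})

test_that("radius of gyration: closed forms and rigid-motion invariance", {
  # two beads at distance d -> Rg = d/2
  two <- matrix(c(0, 0, 0, 3, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two, c(1, 1))$mean, 1.5)

  # rod of N equally spaced beads: Rg^2 = b^2 (N^2 - 1)/12
  N <- 11; b <- 0.7
  rod <- cbind((0:(N - 1)) * b, 0, 0)
  expect_equal(radius_of_gyration(rod, rep(1, N))$mean,
               sqrt(b^2 * (N^2 - 1) / 12), tolerance = 1e-12)

  # invariance under rotation + translation
  set.seed(5)
  pts <- matrix(rnorm(30), 10, 3)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- pts %*% R + matrix(rep(c(5, -2, 1), each = 10), 10, 3)
  expect_equal(radius_of_gyration(pts, rep(1, 10))$mean,
               radius_of_gyration(moved, rep(1, 10))$mean, tolerance = 1e-12)
})

test_that("MSD exponent: ballistic, Brownian, fractional-Brownian recovery", {
  nf <- 120
  times <- seq_len(nf)

  # ballistic free particles: alpha = 2
  set.seed(6)
  v <- matrix(rnorm(60), 20, 3)
  ball <- lapply(times, function(t) v * t)
  expect_equal(msd_exponent(ball, times)$alpha, 2, tolerance = 1e-8)

  # Brownian particles: alpha = 1
  brow <- fbm_frames(40, nf, H = 0.5, seed = 7)
  a1 <- msd_exponent(brow, times, window = c(2, 60))$alpha
  expect_equal(a1, 1, tolerance = 0.05)

  # subdiffusive fractional-Brownian fixture: MSD ~ t^(2H)
  for (H in c(0.25, 0.4)) {
    fr <- fbm_frames(40, nf, H = H, seed = 8)
    a <- msd_exponent(fr, times, window = c(2, 60))$alpha
    expect_equal(a, 2 * H, tolerance = 0.05)
  }

  # MSD is non-decreasing in lag
  m <- msd_exponent(brow, times)
  expect_true(all(diff(m$msd$msd) > -1e-9))

  expect_error(msd_exponent(brow, times, window = c(500, 600)), "window")
})

test_that("density profiles: conservation, flatness, slab structure", {
  set.seed(9)
  box <- simulation_box(c(10, 5, 5))
  n <- 4000
  pos <- cbind(runif(n, 0, 10), runif(n, 0, 5), runif(n, 0, 5))
  prof <- density_profile(pos, box, axis = 1, n_bins = 20)
  # integral of profile x bin volume = particle count exactly
  expect_equal(sum(prof$rho) * (10 / 20) * 25, n)
  # uniform gas: flat within Poisson error (~5 sigma)
  expect_lt(max(abs(prof$rho - n / 250)), 5 * sqrt(n / 20) / 12.5)

  # slab: two-plateau profile
  pos2 <- pos
  half <- pos2[, 1] < 5
  pos2[half, 1] <- pos2[half, 1] / 2 + 1.25 # compress half into [1.25, 3.75]
  prof2 <- density_profile(pos2, box, axis = 1, n_bins = 20)
  dense <- mean(prof2$rho[prof2$x > 1.5 & prof2$x < 3.5])
  dilute <- mean(prof2$rho[prof2$x > 6 & prof2$x < 9])
  expect_gt(dense, 1.8 * dilute)

  # per-species selection and empty flag
  types <- rep(c(1L, 2L), n / 2)
  ps <- density_profile(pos, box, n_bins = 10, type = types, species = 2L)
  expect_equal(sum(ps$rho) * 1 * 25, n / 2)
  pe <- density_profile(pos, box, n_bins = 10, type = types, species = 9L)
  expect_true(all(pe$rho == 0))
  expect_match(attr(pe, "flagged"), "empty")
})
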