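# Builders: counts, determinism, packing, sticker placement, cross-linking.

test_that("composition validates fractions and density", {
  expect_error(composition(1, 5, phi_p = 0.5, phi_s = 0.2), "sum to 1")
  expect_error(composition(1, 5, target_density = 1.5), "target_density")
  expect_s3_class(composition(2, 10, phi_p = 0.5, phi_s = 0.5), "composition")
})

test_that("minimal chain: one bond, zero angles", {
  b <- build_melt(composition(1, 2, target_density = 0.01, seed = 1),
                  relax = FALSE)
  expect_equal(nrow(b$topology$bonds), 1)
  expect_equal(nrow(b$topology$angles), 0)
})

test_that("angle-term count follows n_chains * (np - 2)", {
  b <- build_melt(composition(10, 200, target_density = 0.3, seed = 2),
                  chain_blueprint(angle = list(k = 10, theta0 = 150)),
                  relax = FALSE)
  expect_equal(nrow(b$topology$angles), 10 * 198)
  expect_equal(nrow(b$topology$bonds), 10 * 199)
})

test_that("builders are deterministic in the seed", {
  b1 <- build_melt(composition(20, 20, seed = 7))
  b2 <- build_melt(composition(20, 20, seed = 7))
  expect_identical(b1$system$pos, b2$system$pos)
  b3 <- build_melt(composition(20, 20, seed = 8))
  expect_false(identical(b1$system$pos, b3$system$pos))
})

test_that("relaxed packing reaches the minimum pair distance", {
  b <- tiny_melt(n_chains = 20, np = 10, density = 0.85, seed = 3,
                 equil_steps = 0)
  expect_gte(minimum_distance(b$system), 0.8)
  # generated topology is valid
  expect_true(all(b$topology$bonds <= nrow(b$system$pos)))
  # bond lengths near 0.97 sigma, far from FENE overstretch (unwrap first)
  up <- b$system$pos + b$system$image %*% diag(b$system$box$L)
  d <- sqrt(rowSums((up[b$topology$bonds[, 1], ] -
                     up[b$topology$bonds[, 2], ])^2))
  expect_lt(max(d), 1.4)
})

test_that("solvated builds honour the composition ratios", {
  # phi 1:0 degenerates to the melt
  m <- build_solvated(composition(5, 8, phi_p = 1, phi_s = 0, seed = 4),
                      relax = FALSE)
  expect_equal(sum(m$system$type == 2L), 0)

  # 1:1 gives equal polymer and solvent counts
  s1 <- build_solvated(composition(5, 8, phi_p = 0.5, phi_s = 0.5, seed = 4),
                       relax = FALSE)
  expect_equal(sum(s1$system$type == 2L), 40)

  # 1:2 gives twice as many solvent beads as polymer beads
  s2 <- build_solvated(composition(5, 8, phi_p = 1/3, phi_s = 2/3, seed = 4),
                       relax = FALSE)
  expect_equal(sum(s2$system$type == 2L), 80)
  expect_equal(sum(s2$system$type == 1L), 40)
})

test_that("sticker placement: counts, angles, interval guard", {
  b <- build_melt(composition(3, 200, target_density = 0.3, seed = 5),
                  relax = FALSE)
  topo <- place_stickers(b$topology, b$system$chain, interval = 10,
                         sticker_angle = 180)
  # every 10th bead per 200-bead chain -> 20 stickers per chain
  expect_equal(sum(topo$types == 3L), 3 * 20)
  # sticker triplets get near-straight equilibrium angles
  new_angles <- tail(topo$angle_theta0, 3 * 18)
  expect_true(all(abs(new_angles - pi) < 1e-12))

  # interval larger than the chain: unchanged with a warning
  expect_warning(un <- place_stickers(b$topology, b$system$chain,
                                      interval = 300), "no stickers")
  expect_identical(un, b$topology)
})

test_that("cross-linking: no-op at zero fraction, deterministic, percolating", {
  b <- tiny_melt(n_chains = 12, np = 10, density = 0.85, seed = 6,
                 equil_steps = 500)
  topo <- place_stickers(b$topology, b$system$chain, interval = 2)
  b$system <- apply_topology_types(b$system, topo)

  t0 <- crosslink_gel(b$system, topo, linker_fraction = 0)
  expect_equal(attr(t0, "n_links"), 0L)
  expect_equal(nrow(t0$bonds), nrow(topo$bonds))

  t1 <- crosslink_gel(b$system, topo, linker_fraction = 1, cutoff = 1.3)
  t2 <- crosslink_gel(b$system, topo, linker_fraction = 1, cutoff = 1.3)
  expect_identical(t1$bonds, t2$bonds)
  expect_gt(attr(t1, "n_links"), 0)

  # dense sticker melt with generous cutoff percolates
  t3 <- crosslink_gel(b$system, topo, linker_fraction = 1, cutoff = 2.0)
  expect_gt(attr(t3, "connectivity"), 0.9)

  # no duplicate bonds, all indices valid
  expect_silent(cgrheo:::validate_topology(t3))
})
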