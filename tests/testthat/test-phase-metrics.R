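test_that("density profile counts windows exactly", {
  # all beads in window 5 (z in [40, 50) for Lz = 300)
  p <- density_profile(rep(45, 120), lz = 300)
  expect_equal(unname(p[5]), 1)
  expect_equal(sum(p), 1)
  expect_equal(sum(p > 0), 1)

  # exactly uniform: one bead per window centre
  z <- (0:29) * 10 + 5
  expect_equal(unname(density_profile(z, 300)), rep(1 / 30, 30))

  # hand-placed 12-bead toy: 3 in window 1, 4 in window 2, 5 in window 30
  z <- c(1, 5, 9.999, 10, 12, 15, 19, 295, 296, 297, 298, 299)
  p <- density_profile(z, 300)
  expect_equal(unname(p[c(1, 2, 30)]), c(3, 4, 5) / 12)

  # wrapping: coordinates outside the box land in the right window
  expect_equal(density_profile(c(305, -5), 300),
               density_profile(c(5, 295), 300))
})

test_that("P_H / P_L extrema follow the time-averaged profile convention", {
  expect_equal(unname(ph_pl(density_profile(rep(45, 10), 300))["diff"]), 1)
  expect_equal(unname(ph_pl(rep(1 / 30, 30))["diff"]), 0)
  m <- cbind(density_profile(c(5, 15, 15, 25), 300),
             density_profile(c(5, 5, 15, 295), 300))
  avg <- rowMeans(m)
  expect_equal(unname(ph_pl(m)["p_h"]), max(avg))
  expect_equal(unname(ph_pl(m)["p_l"]), min(avg))
  pf <- ph_pl(m, per_frame = TRUE)
  expect_equal(unname(pf["p_h"]), mean(apply(m, 2, max)))
})

test_that("condensed-phase centering handles wrap-around and translation", {
  # dense slab straddling the box edge: half near z = 0, half near z = Lz
  lz <- 300
  set.seed(4)
  z <- c(runif(60, 0, 10), runif(60, 290, 300))
  traj <- make_scripted_trajectory(matrix(z, ncol = 1), times = 0,
                                  box = c(10, 10, lz))
  s <- center_condensed_phase(traj)
  expect_true(all(s$absz < 12))  # recentred: everything near the slab centre

  # translating every frame by a constant z leaves |z| unchanged
  z2 <- matrix(rep(seq(10, 200, length.out = 40), 3), ncol = 3)
  tr1 <- make_scripted_trajectory(z2, box = c(10, 10, lz))
  z3 <- z2 + 37.5
  tr2 <- make_scripted_trajectory(z3, box = c(10, 10, lz))
  expect_equal(center_condensed_phase(tr1)$absz,
               center_condensed_phase(tr2)$absz, tolerance = 1e-8)
})

test_that("z motion rate matches hand-computed values", {
  # one chain moving +1 A every 0.5 tau -> 2 A/tau
  z <- matrix(seq(0, 0.5, by = 0.1), nrow = 1)  # nm, 0.1 nm = 1 A per frame
  tr <- make_scripted_trajectory(z)
  expect_equal(z_motion_rate(tr), 2)

  # static system
  expect_equal(z_motion_rate(make_scripted_trajectory(matrix(1, 3, 5))), 0)

  # 3-chain, 4-interval scripted fixture, hand-summed:
  # |dz| sums (nm): chain1: .1+.2+.1+.3=.7; chain2: 0+.4+.2+.1=.7; chain3: 1.3
  z <- rbind(c(0, .1, .3, .2, .5),
             c(1, 1, 1.4, 1.2, 1.1),
             c(5, 4.9, 4.6, 5.1, 4.7))
  tr <- make_scripted_trajectory(z)
  expect_equal(z_motion_rate(tr), 10 * (0.7 + 0.7 + 1.3) / (3 * 4 * 0.5),
               tolerance = 1e-12)

  # window selection by t0 / t_end
  expect_equal(z_motion_rate(z, times = c(0, .5, 1, 1.5, 2), t0 = 1),
               10 * (0.4 + 0.3 + 0.9) / (3 * 2 * 0.5), tolerance = 1e-12)
})

test_that("z motion rate is shift-invariant and scales with time rescaling", {
  set.seed(9)
  z <- matrix(cumsum(rnorm(40, 0, 0.3)), nrow = 4)
  r1 <- z_motion_rate(z, times = 0.5 * (0:9))
  expect_equal(z_motion_rate(z + 123.4, times = 0.5 * (0:9)), r1,
               tolerance = 1e-12)
  expect_equal(z_motion_rate(z, times = 1.0 * (0:9)), r1 / 2,
               tolerance = 1e-12)
  expect_error(z_motion_rate(z, times = c(0, 1, 2, 3, 5, 6, 7, 8, 9, 10)),
               "regular")
})

test_that("flux counts boundary crossings per interval", {
  lz <- 300
  # chain oscillating across the +25 nm plane once per interval
  z <- matrix(rep(c(20, 30), 5), nrow = 1)
  tr <- make_scripted_trajectory(cbind(z, 20), box = c(10, 10, lz))
  s <- center_condensed_phase(tr)
  # hold the centre at 0 by adding a static bulk of chains around z = 0
  bulk <- matrix(0.01, 99, 11)
  tr2 <- make_scripted_trajectory(rbind(cbind(z, 20), bulk), box = c(10, 10, lz))
  s2 <- center_condensed_phase(tr2)
  fl <- flux(s2, boundary = 25)
  expect_equal(fl$n_t, rep(2, 10))  # 1 crossing / 0.5 tau
  expect_equal(fl$mean, 2)

  # nothing near the boundary
  quiet <- make_scripted_trajectory(matrix(rep(c(0, 3), 8), 2, 8),
                                    box = c(10, 10, lz))
  expect_equal(flux(center_condensed_phase(quiet), boundary = 25)$mean, 0)

  # scripted 5-chain fixture with 7 crossings over 2 tau -> 3.5 chains/tau
  z5 <- rbind(c(0, 26, 0, 26, 0),    # 4 crossings of +25
              c(-20, -26, -26, -20, -26),  # 3 crossings of -25
              c(0, 1, 2, 1, 0),
              c(10, 12, 14, 12, 10),
              c(-10, -12, -10, -12, -10))
  trf <- make_scripted_trajectory(rbind(z5, matrix(0, 95, 5)),
                                  box = c(10, 10, lz))
  sf <- center_condensed_phase(trf)
  expect_equal(flux(sf, boundary = 25)$mean, 7 / 4 / 0.5)
})

test_that("chain probability profile is a normalized |z| histogram", {
  lz <- 300
  pin <- make_scripted_trajectory(matrix(0.01, 50, 4), box = c(10, 10, lz))
  p <- chain_probability_profile(center_condensed_phase(pin))
  expect_equal(unname(p[1]), 1)
  expect_equal(sum(p), 1)

  # histogram oracle on a scripted series
  set.seed(11)
  z <- matrix(runif(600, 0, lz), 30, 20)
  tr <- make_scripted_trajectory(z, box = c(10, 10, lz))
  s <- center_condensed_phase(tr)
  p <- chain_probability_profile(s)
  oracle <- table(cut(as.vector(s$absz), breaks = seq(0, 150, by = 5),
                      right = FALSE)) / length(s$absz)
  expect_equal(unname(p), as.numeric(oracle), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("the printed-form flux indicator is available for comparison", {
  # unwrapped z in nm; planes at 250 and 275 nm +/- 25 in the printed form
  z <- matrix(c(249, 251, 249, 251), 1)  # crosses 2500 A every interval
  tr <- make_scripted_trajectory(z, box = c(10, 10, 300))
  s <- center_condensed_phase(tr)
  fp <- flux(s, convention = "printed")
  expect_equal(length(fp$n_t), 3)
})
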