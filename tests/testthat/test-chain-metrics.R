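straight_chain_coords <- function(n, spacing = 0.38, origin = c(1, 1, 1),
                                  axis = 1) {
  x <- matrix(rep(origin, each = n), n, 3)
  x[, axis] <- origin[axis] + (seq_len(n) - 1) * spacing
  x
}

test_that("head-to-tail distance follows the geometry", {
  sys <- replicate_system(chain_spec(strrep("G", 50)), 1, c(100, 100, 100),
                          seed = 1)
  x <- straight_chain_coords(50)
  expect_equal(end_to_end(x, sys$topology), 49 * 3.8, tolerance = 1e-10)

  # closed loop: first and last bead coincide
  xl <- x
  xl[50, ] <- xl[1, ]
  expect_equal(end_to_end(xl, sys$topology), 0)

  # minimum image across the periodic boundary
  sys2 <- replicate_system(chain_spec("GG"), 1, c(10, 10, 10), seed = 1)
  xx <- rbind(c(5, 5, 0.1), c(5, 5, 9.9))
  expect_equal(end_to_end(xx, sys2$topology), 2, tolerance = 1e-10)
})

test_that("inserted glycines are excluded from the head-to-tail distance", {
  sys <- replicate_system(chain_spec(strrep("G", 50), 1.0, "tail10"), 1,
                          c(100, 100, 100), seed = 1)
  x60 <- straight_chain_coords(60)
  expect_equal(end_to_end(x60, sys$topology, exclude_inserts = TRUE),
               49 * 3.8, tolerance = 1e-10)
  expect_equal(end_to_end(x60, sys$topology, exclude_inserts = FALSE),
               59 * 3.8, tolerance = 1e-10)

  # head5tail5: termini are beads 6 and 55
  sys2 <- replicate_system(chain_spec(strrep("G", 50), 1.0, "head5tail5"), 1,
                           c(100, 100, 100), seed = 1)
  expect_equal(end_to_end(x60, sys2$topology), 49 * 3.8, tolerance = 1e-10)
})

test_that("electrostatic contacts follow the cutoff rules", {
  # one chain with +1 and -1 at 10 A -> one intra contact
  spec <- chain_spec("KGD")
  sys <- replicate_system(spec, 1, c(50, 50, 50), seed = 1)
  x <- rbind(c(10, 10, 10), c(10.5, 10, 10), c(11, 10, 10))  # K..D at 10 A
  ec <- electrostatic_contacts(x, sys$topology)
  expect_equal(ec$e_intra, 1L)
  expect_equal(ec$e_inter, 0L)

  # +1 and +1 at 5 A are not a contact
  sys2 <- replicate_system(chain_spec("KGK"), 1, c(50, 50, 50), seed = 1)
  x2 <- rbind(c(10, 10, 10), c(10.25, 10, 10), c(10.5, 10, 10))
  ec2 <- electrostatic_contacts(x2, sys2$topology)
  expect_equal(ec2$e_intra, 0L)

  # just over the 12 A intra cutoff
  x3 <- rbind(c(10, 10, 10), c(10.6, 10, 10), c(11.21, 10, 10))
  expect_equal(electrostatic_contacts(x3, sys$topology)$e_intra, 0L)

  # inter-chain: 13 A apart counts (cutoff 15 A) and credits both chains
  sysKD <- replicate_system(chain_spec("KD"), 2, c(50, 50, 50), seed = 1)
  x4 <- rbind(c(10, 10, 10), c(30, 30, 30),       # chain 1: K, D (far apart)
              c(11.3, 10, 10), c(35, 35, 35))     # chain 2: K, D
  # chain1 K at 10 vs chain2 D at 35: far; chain2 K at 11.3 vs chain1 D at 30:
  # far; chain1 K (10,10,10) vs chain2 D? no. Build an explicit close pair:
  x4[4, ] <- c(11.3, 10, 10)  # chain 2 D, 13 A from chain 1 K
  x4[3, ] <- c(40, 40, 40)
  ec4 <- electrostatic_contacts(x4, sysKD$topology)
  expect_equal(ec4$e_inter, c(1L, 1L))
  expect_equal(sum(ec4$e_intra), 0L)
})

test_that("contact counts match a brute-force oracle on a random system", {
  sys <- make_test_system(n_chains = 5, L = 8, box = c(5, 5, 5), seed = 13,
                          n_neg = 3, n_pos = 2)
  got <- electrostatic_contacts(sys$coords, sys$topology)
  # oracle: enumerate all opposite-charge pairs
  beads <- sys$topology$beads
  e_intra <- integer(5)
  e_inter <- integer(5)
  n <- nrow(beads)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (beads$charge[i] * beads$charge[j] != -1) next
      d <- sqrt(sum(mi(sys$coords[i, ] - sys$coords[j, ], sys$topology$box)^2))
      if (beads$chain_id[i] == beads$chain_id[j]) {
        if (d < 1.2) e_intra[beads$chain_id[i]] <- e_intra[beads$chain_id[i]] + 1L
      } else if (d < 1.5) {
        e_inter[beads$chain_id[i]] <- e_inter[beads$chain_id[i]] + 1L
        e_inter[beads$chain_id[j]] <- e_inter[beads$chain_id[j]] + 1L
      }
    }
  }
  expect_equal(got$e_intra, e_intra)
  expect_equal(got$e_inter, e_inter)
})

test_that("uncharged systems return zero contacts with a notice", {
  sys <- make_test_system(n_chains = 3, L = 4, box = c(6, 6, 6), seed = 2,
                          n_neg = 0, n_pos = 0)
  expect_message(ec <- electrostatic_contacts(sys$coords, sys$topology),
                 "no opposite-charge")
  expect_equal(ec$e_intra, integer(3))
  expect_equal(ec$e_inter, integer(3))
})

test_that("per-window statistics along |z| match direct computation", {
  lz <- 300
  # constant observable -> SE 0, exact mean
  z <- matrix(c(2, 7, 12, 40), 2, 2)
  tr <- make_scripted_trajectory(z, box = c(10, 10, lz))
  s <- center_condensed_phase(tr)
  vals <- matrix(5, 2, 2)
  pw <- profile_vs_absz(vals, s)
  expect_true(all(pw$mean[pw$n > 0] == 5))
  expect_true(all(pw$se[pw$n > 1] == 0, na.rm = TRUE))

  # two populations in one window -> mean 15
  z2 <- matrix(0.01, 2, 5)
  tr2 <- make_scripted_trajectory(rbind(z2, matrix(140, 1, 5)),
                                  box = c(10, 10, lz))
  s2 <- center_condensed_phase(tr2)
  # two populations (D = 10 and D = 20 A) in the same window -> mean 15
  s3 <- s2
  s3$absz <- matrix(2, 2, 5)  # both chains in the first 5 nm window
  pw3 <- profile_vs_absz(rbind(matrix(10, 1, 5), matrix(20, 1, 5)), s3)
  expect_equal(pw3$mean[1], 15)

  # observations beyond the exclusion boundary are dropped
  s4 <- s2
  s4$absz <- matrix(c(10, 145, 10, 145), 2, 2)
  pw4 <- profile_vs_absz(matrix(1, 2, 2), s4, exclude_above = 140)
  expect_equal(sum(pw4$n), 2)
})

test_that("temperature summary aggregates mean and standard error", {
  d_list <- list(`1` = matrix(c(10, 20), 2, 50), `2` = matrix(15, 2, 50))
  tab <- d_vs_temperature(d_list, c(1, 2))
  expect_equal(tab$mean, c(15, 15))
  expect_equal(tab$se[2], 0)
  expect_equal(tab$se[1], sd(rep(c(10, 20), 50)) / sqrt(100), tolerance = 1e-6)
})

test_that("inter-chain contacts track local chain density along |z|", {
  # short charged slab run: windows holding more chains should show more
  # inter-chain opposite-charge contacts per chain (positive rank correlation)
  spec <- chain_spec(make_sequence(10, 2, 3, seed = 51))
  box <- c(8, 8, 40)
  sys <- replicate_system(spec, 20, box, seed = 52, z_range = c(14, 26))
  v <- initialize_velocities(sys$topology, 1.0, seed = 53)
  ff <- force_field(kappa = kappa_from_salt(0.01), r_cut_lj = 1.5)
  tr <- langevin_run(sys$topology, sys$coords, v, ff, temperature = 1.0,
                     n_steps = 50000, save_every = 5000, seed = 54)
  s <- center_condensed_phase(tr)
  nf <- dim(tr$coords)[3]
  einter <- vapply(seq_len(nf), function(f)
    electrostatic_contacts(tr$coords[, , f], sys$topology)$e_inter,
    numeric(20))
  prob <- chain_probability_profile(s, n_windows = 10)
  contact_profile <- profile_vs_absz(einter, s, n_windows = 10,
                                     exclude_above = 20)
  keep <- contact_profile$n > 0 & prob > 0
  expect_gt(sum(keep), 2)
  expect_gt(cor(prob[keep], contact_profile$mean[keep], method = "spearman"), 0)
})
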