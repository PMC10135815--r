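# Independent oracles, written in plain R against the model definitions
# (never calling the package's compiled paths).

# minimum-image displacement
mi <- function(d, L) d - L * round(d / L)

# O(N^2) double-loop energy/force oracle with the same conventions as the
# engine: LJ and DH truncated-and-shifted at their cutoffs, 1-2 bonded pairs
# excluded from nonbonded terms, insert pairs on eps_insert.
brute_energy_forces <- function(topology, coords, params) {
  n <- nrow(coords)
  box <- topology$box
  ch <- topology$beads$charge
  ins <- topology$beads$is_insert
  bonded_pair <- matrix(FALSE, n, n)
  if (nrow(topology$bonds) > 0) {
    for (b in seq_len(nrow(topology$bonds))) {
      i <- topology$bonds[b, 1]; j <- topology$bonds[b, 2]
      bonded_pair[i, j] <- bonded_pair[j, i] <- TRUE
    }
  }
  pref4 <- params$lj_prefactor_mode == "standard_4eps"
  sc6 <- (params$sigma / params$r_cut_lj)^6
  lj_shift_unit <- sc6^2 - sc6
  dh_unit <- params$kcoulomb * params$b_kappa / params$dielectric
  dh_shift_unit <- exp(-params$kappa * params$r_cut_dh) / params$r_cut_dh
  e_bond <- e_lj <- e_dh <- 0
  f <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- mi(coords[i, ] - coords[j, ], box)
      r <- sqrt(sum(d^2))
      if (bonded_pair[i, j]) {
        e_bond <- e_bond + params$kb * (r - params$r0)^2
        fr <- -2 * params$kb * (r - params$r0) / r
        f[i, ] <- f[i, ] + fr * d
        f[j, ] <- f[j, ] - fr * d
        next
      }
      if (r < params$r_cut_lj) {
        pe <- if (ins[i] || ins[j]) params$eps_insert else params$eps
        pref <- if (pref4) 4 * pe else pe
        s6 <- (params$sigma / r)^6
        e_lj <- e_lj + pref * (s6^2 - s6) - pref * lj_shift_unit
        fr <- pref * (12 * s6^2 - 6 * s6) / r^2
        f[i, ] <- f[i, ] + fr * d
        f[j, ] <- f[j, ] - fr * d
      }
      qq <- ch[i] * ch[j]
      if (params$charge_mode != "no_charge" && qq != 0 && r < params$r_cut_dh) {
        e_dh <- e_dh + dh_unit * qq * (exp(-params$kappa * r) / r - dh_shift_unit)
        fr <- dh_unit * qq * exp(-params$kappa * r) * (params$kappa * r + 1) / r^3
        f[i, ] <- f[i, ] + fr * d
        f[j, ] <- f[j, ] - fr * d
      }
    }
  }
  list(energy = e_bond + e_lj + e_dh,
       components = c(bond = e_bond, lj = e_lj, dh = e_dh), forces = f)
}

# standard error of a correlated scalar series by block averaging
block_se <- function(x, n_blocks = 20) {
  m <- floor(length(x) / n_blocks)
  bm <- vapply(seq_len(n_blocks), function(b) mean(x[((b - 1) * m + 1):(b * m)]),
               numeric(1))
  sd(bm) / sqrt(n_blocks)
}

# a small interacting test system: n_chains random-walk chains with charges
make_test_system <- function(n_chains = 6, L = 5, box = c(6, 6, 6), seed = 1,
                             n_neg = 1, n_pos = 1, mass_scale = 1.0,
                             insertion_mode = "none") {
  spec <- chain_spec(make_sequence(L, n_neg, n_pos, seed),
                     mass_scale = mass_scale, insertion_mode = insertion_mode)
  replicate_system(spec, n_chains, box, seed = seed + 100)
}
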