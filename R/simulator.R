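# Langevin slab simulations: velocity initialization, the BAOAB stochastic
# integrator (compiled), and the equilibrate -> slab -> production protocol.
#
# Reduced units for the user surface: temperature in T0 (= 100 K), time in
# tau (= 1 ns).  Internally everything runs in nm/ps/kJ/mol/amu, in which the
# published constants enter verbatim and the default time step 2 fs is
# dt = 0.002 ps = 2e-6 tau.

#' Simulation configuration
#'
#' @param temperature thermostat temperature in T0 units (T0 = 100 K).
#' @param dt time step in ps (default 0.002 ps = 2 fs).
#' @param friction Langevin friction in ps^-1 (default 1.0).
#' @param duration production length in tau (1 tau = 1 ns).
#' @param equil equilibration (NVT relaxation) length in tau before the box is
#'   analysed; run at `temperature`.
#' @param frame_interval frame cadence in tau (default 0.5, the grid on which
#'   the motion-rate and flux statistics are defined).
#' @param seed integer seed; all stochastic elements of the run derive from it.
#' @param slab_fraction fraction of the box z-length into which chains are
#'   packed initially (compact-slab start); 1 places chains anywhere.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(temperature = 2.0, dt = 0.002, friction = 1.0,
                       duration = 5000, equil = 10, frame_interval = 0.5,
                       seed = 1, slab_fraction = 0.2) {
  stopifnot(temperature > 0, dt > 0, friction >= 0, duration > 0,
            frame_interval > 0, slab_fraction > 0, slab_fraction <= 1)
  steps_per_frame <- round(frame_interval * TAU_PS / dt)
  if (abs(steps_per_frame * dt - frame_interval * TAU_PS) > 1e-9 * TAU_PS)
    stop("frame_interval must be an integer multiple of dt")
  structure(list(temperature = temperature, dt = dt, friction = friction,
                 duration = duration, equil = equil,
                 frame_interval = frame_interval, seed = as.integer(seed),
                 slab_fraction = slab_fraction),
            class = "sim_config")
}

#' Maxwell-Boltzmann velocity initialization
#'
#' Draws each velocity component from N(0, kT/m) for each bead's mass and
#' removes the net momentum.
#'
#' @param topology a `cg_topology`.
#' @param temperature temperature in T0 units.
#' @param seed integer seed.
#' @return N x 3 velocity matrix, nm/ps.
#' @export
initialize_velocities <- function(topology, temperature, seed) {
  m <- topology$beads$mass
  n <- length(m)
  set.seed(as.integer(seed))
  kT <- kT_reduced(temperature)
  v <- matrix(rnorm(3 * n, sd = rep(sqrt(kT / m), 3)), ncol = 3)
  # remove net momentum
  ptot <- colSums(v * m)
  sweep(v, 2, ptot / sum(m))
}

#' Advance a system by Langevin dynamics
#'
#' Runs `n_steps` of the BAOAB splitting of Langevin dynamics at fixed
#' temperature and volume.  The same bead mass enters both the inertia and the
#' thermostat, so heavier beads genuinely move more slowly at equal
#' temperature.  Deterministic for a fixed seed.
#'
#' @param topology a `cg_topology`.
#' @param coords N x 3 starting coordinates (nm).
#' @param velocities N x 3 starting velocities (nm/ps), e.g. from
#'   [initialize_velocities()].
#' @param params a [force_field()].
#' @param temperature temperature in T0 units.
#' @param dt time step, ps.
#' @param friction friction, ps^-1 (0 gives plain velocity-Verlet dynamics).
#' @param n_steps number of steps.
#' @param save_every save a frame every this many steps.
#' @param seed integer seed for the thermostat noise.
#' @param skin Verlet-list skin, nm.
#' @return a `cg_trajectory`: unwrapped coordinates array `coords`
#'   (beads x 3 x frames), `times` (tau), per-frame kinetic/potential energy,
#'   the kinetic temperature averaged over the saved frames (T0 units), the
#'   final state, box and topology.
#' @export
langevin_run <- function(topology, coords, velocities, params = force_field(),
                         temperature = 2.0, dt = 0.002, friction = 1.0,
                         n_steps = 1000L, save_every = 100L, seed = 1,
                         skin = 0.3) {
  stopifnot(inherits(topology, "cg_topology"))
  n <- nrow(topology$beads)
  stopifnot(nrow(coords) == n, nrow(velocities) == n)
  set.seed(as.integer(seed))
  cpp_seed <- sample.int(.Machine$integer.max, 1L)
  res <- cpp_langevin_run(coords, velocities, topology$box,
                          topology$beads$mass,
                          as.integer(topology$beads$charge),
                          topology$beads$is_insert, topology$bonds,
                          ff_vector(params), dt, friction,
                          kT_reduced(temperature),
                          as.integer(n_steps), as.integer(save_every),
                          cpp_seed, skin)
  ndof <- 3 * n
  new_trajectory(coords = res$frames,
                 times = res$steps * dt / TAU_PS,
                 box = topology$box, topology = topology,
                 ke = res$ke, pe = res$pe,
                 t_kin = 2 * res$ke / (ndof * kB) / T0_KELVIN,
                 t_kin_mean = 2 * res$ke_mean / (ndof * kB) / T0_KELVIN,
                 final = list(coords = res$x, velocities = res$v))
}

new_trajectory <- function(coords, times, box, topology = NULL, ke = NULL,
                           pe = NULL, t_kin = NULL, t_kin_mean = NULL,
                           final = NULL) {
  structure(list(coords = coords, times = times, box = as.numeric(box),
                 topology = topology, ke = ke, pe = pe, t_kin = t_kin,
                 t_kin_mean = t_kin_mean, final = final),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("cg_trajectory: ", d[1], " beads, ", d[3], " frames, t = ",
      signif(min(x$times), 4), " .. ", signif(max(x$times), 4), " tau, box ",
      paste(signif(x$box, 4), collapse = " x "), " nm\n", sep = "")
  if (!is.null(x$t_kin_mean))
    cat("  mean kinetic temperature ", signif(x$t_kin_mean, 4), " T0\n", sep = "")
  invisible(x)
}

#' Per-frame chain centres of mass
#'
#' @param traj a `cg_trajectory` with a topology.
#' @param dims which coordinate columns to return (default z only).
#' @return for `dims` of length 1, an n_chains x n_frames matrix (unwrapped,
#'   nm); otherwise an n_chains x length(dims) x n_frames array.
#' @export
chain_cm <- function(traj, dims = 3L) {
  topo <- traj$topology
  stopifnot(!is.null(topo))
  m <- topo$beads$mass
  cid <- topo$beads$chain_id
  mtot <- tapply(m, cid, sum)
  nf <- dim(traj$coords)[3]
  out <- array(NA_real_, c(topo$n_chains, length(dims), nf))
  for (f in seq_len(nf)) {
    for (k in seq_along(dims)) {
      out[, k, f] <- tapply(m * traj$coords[, dims[k], f], cid, sum) / mtot
    }
  }
  if (length(dims) == 1L)
    array(out[, 1L, , drop = FALSE], c(topo$n_chains, nf))
  else out
}

#' Run the slab protocol
#'
#' Builds a compact slab start (chains packed into the central
#' `slab_fraction` of the box z-length), relaxes it by NVT Langevin dynamics
#' for `equil` tau at the target temperature, then runs production for
#' `duration` tau, saving frames every `frame_interval` tau.  For the
#' published geometries use `box = c(31, 31, 300)` (10,000-bead systems) or
#' `c(34, 34, 300)` (12,000-bead systems).
#'
#' @param spec a [chain_spec()] or prebuilt chain data.frame.
#' @param n_chains number of chains.
#' @param box length-3 box in nm (slab geometry: Lz elongated).
#' @param config a [sim_config()].
#' @param params a [force_field()].
#' @return a `cg_trajectory` of the production run (frame at t = 0 is the
#'   first production frame).
#' @export
run_protocol <- function(spec, n_chains, box, config = sim_config(),
                         params = force_field()) {
  stopifnot(inherits(config, "sim_config"))
  zc <- box[3] / 2
  half <- config$slab_fraction * box[3] / 2
  sys <- replicate_system(spec, n_chains, box, seed = config$seed,
                          z_range = c(zc - half, zc + half))
  v <- initialize_velocities(sys$topology, config$temperature,
                             seed = config$seed + 1L)
  steps_per_frame <- round(config$frame_interval * TAU_PS / config$dt)
  x <- sys$coords
  if (config$equil > 0) {
    eq_steps <- max(1L, round(config$equil * TAU_PS / config$dt))
    eq <- langevin_run(sys$topology, x, v, params,
                       temperature = config$temperature, dt = config$dt,
                       friction = config$friction, n_steps = eq_steps,
                       save_every = eq_steps, seed = config$seed + 2L)
    x <- eq$final$coords
    v <- eq$final$velocities
  }
  n_steps <- round(config$duration * TAU_PS / config$dt)
  traj <- langevin_run(sys$topology, x, v, params,
                       temperature = config$temperature, dt = config$dt,
                       friction = config$friction, n_steps = n_steps,
                       save_every = steps_per_frame,
                       seed = config$seed + 3L)
  traj
}

#' Desk, medium and paper problem-size presets
#'
#' `desk` (30 chains x 20 beads, 15 x 15 x 75 nm, 1.5 tau production) is sized
#' for test suites; `medium` (50 x 50, 500 tau) for workstation studies;
#' `paper` (200 x 50, 31 x 31 x 300 nm, 5000 tau) is the published scale.
#'
#' @param name `"desk"`, `"medium"` or `"paper"`.
#' @return list with `n_chains`, `chain_length`, `box`, `duration`, `equil`,
#'   `slab_fraction`, `flux_boundary` (nm) and `analysis_fraction` (tail
#'   fraction of production analysed).
#' @export
preset <- function(name = c("desk", "medium", "paper")) {
  name <- match.arg(name)
  switch(name,
    desk = list(n_chains = 30L, chain_length = 20L, box = c(15, 15, 75),
                duration = 1.0, equil = 0.05, slab_fraction = 0.2,
                flux_boundary = 75 / 12, analysis_fraction = 1.0,
                r_cut_lj = 1.5, frame_interval = 0.1),
    medium = list(n_chains = 50L, chain_length = 50L, box = c(20, 20, 150),
                  duration = 500, equil = 10, slab_fraction = 0.2,
                  flux_boundary = 150 / 12, analysis_fraction = 0.2,
                  r_cut_lj = 3.0, frame_interval = 0.5),
    paper = list(n_chains = 200L, chain_length = 50L, box = c(31, 31, 300),
                 duration = 5000, equil = 10, slab_fraction = 0.2,
                 flux_boundary = 25, analysis_fraction = 0.2,
                 r_cut_lj = 3.0, frame_interval = 0.5))
}
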