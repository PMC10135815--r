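# Experiment orchestration over (system x mass x insertion x salt x
# temperature x seed) grids, and the per-trajectory summary statistics.

#' Summarise one trajectory
#'
#' Computes the standard observables over the analysis window: the
#' time-averaged density profile extrema (P_H, P_L and their difference), the
#' chain z motion rate, the boundary flux, and the mean head-to-tail distance;
#' optionally the electrostatic contact counts.  The analysis window is the
#' last `tail_fraction` of the production frames (the published convention is
#' the last 1000 tau of 5000 tau, i.e. 0.2); the initial frame at t = 0 is
#' never included.
#'
#' @param traj a `cg_trajectory` with topology.
#' @param tail_fraction fraction of the production analysed, in (0, 1].
#' @param flux_boundary boundary distance for [flux()], nm.
#' @param n_windows density-profile window count.
#' @param contacts also compute mean per-chain E_intra / E_inter (meaningful
#'   only for charged systems).
#' @param motion_interval time grid for the motion metrics, tau (default 0.5,
#'   the grid on which the z motion rate and flux are defined).  Frames may be
#'   saved more often; state averages use every frame, motion metrics only the
#'   frames on this grid.
#' @return one-row data.frame with `p_h`, `p_l`, `ph_pl`, `z_rate` (A/tau),
#'   `flux` (chains/tau), `d_mean` (A), and `e_intra` / `e_inter` when
#'   requested.
#' @details The frame at t = 0 is the constructed initial condition; it enters
#'   the motion metrics (as the start of the first interval) but never the
#'   state averages (density profile, D, contacts).
#' @export
analyze_trajectory <- function(traj, tail_fraction = 0.2, flux_boundary = 25,
                               n_windows = 30L, contacts = FALSE,
                               motion_interval = 0.5) {
  stopifnot(tail_fraction > 0, tail_fraction <= 1)
  t_end <- max(traj$times)
  frames <- which(traj$times >= (1 - tail_fraction) * t_end - 1e-9)
  if (length(frames) < 2L)
    stop("analysis window holds fewer than two frames")
  state_frames <- frames[traj$times[frames] > 0]
  prof <- density_profile_series(traj, state_frames, n_windows)
  pp <- ph_pl(prof)
  motion_frames <- frames[abs(traj$times[frames] / motion_interval -
                                round(traj$times[frames] / motion_interval)) < 1e-6]
  if (length(motion_frames) < 2L) motion_frames <- frames
  series <- center_condensed_phase(traj, motion_frames)
  cm <- chain_cm(traj)[, motion_frames, drop = FALSE]
  zr <- z_motion_rate(cm, traj$times[motion_frames])
  fl <- flux(series, boundary = flux_boundary)
  frames <- state_frames
  dmat <- vapply(frames, function(f)
    end_to_end(traj$coords[, , f], traj$topology), numeric(traj$topology$n_chains))
  out <- data.frame(p_h = pp["p_h"], p_l = pp["p_l"], ph_pl = pp["diff"],
                    z_rate = zr, flux = fl$mean, d_mean = mean(dmat),
                    row.names = NULL)
  if (contacts) {
    ec <- lapply(frames, function(f)
      electrostatic_contacts(traj$coords[, , f], traj$topology))
    out$e_intra <- mean(vapply(ec, function(e) mean(e$e_intra), numeric(1)))
    out$e_inter <- mean(vapply(ec, function(e) mean(e$e_inter), numeric(1)))
  }
  out
}

#' Enumerate an experiment grid
#'
#' Deterministic Cartesian product of systems, mass scales, insertion modes,
#' charge conditions, temperatures and seeds.  Each cell gets a stable key
#' built from its settings.
#'
#' @param systems character: `"PLD"`, `"RGG"` or names of entries in
#'   `sequences`.
#' @param mass_scales bead-mass scales (published set: 1.0, 1.1, 1.2, 1.3,
#'   1.5).
#' @param insertion_modes subset of `"none"`, `"tail10"`, `"head5tail5"`.
#' @param charge_modes subset of `"no_charge"`, `"salt_10mM"`.
#' @param temperatures T0 units (published grid: 1.0, 1.5, 2.0, 3.0, 4.0).
#' @param seeds integer seeds.
#' @param preset_name problem-size preset (see [preset()]).
#' @param sequences optional named list of custom sequences.
#' @return data.frame of cells, class `experiment_grid`.
#' @export
experiment_grid <- function(systems = c("PLD", "RGG"),
                            mass_scales = c(1.0, 1.2),
                            insertion_modes = "none",
                            charge_modes = c("no_charge", "salt_10mM"),
                            temperatures = c(1.0, 1.5, 2.0, 3.0, 4.0),
                            seeds = 1L,
                            preset_name = "desk",
                            sequences = NULL) {
  stopifnot(all(insertion_modes %in% c("none", "tail10", "head5tail5")),
            all(charge_modes %in% c("no_charge", "salt_10mM")))
  g <- expand.grid(system = systems, mass_scale = mass_scales,
                   insertion_mode = insertion_modes,
                   charge_mode = charge_modes,
                   temperature = temperatures, seed = as.integer(seeds),
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g$cell <- sprintf("%s_m%s_%s_%s_T%s_s%d", g$system, g$mass_scale,
                    g$insertion_mode, g$charge_mode, g$temperature, g$seed)
  attr(g, "preset_name") <- preset_name
  attr(g, "sequences") <- sequences
  class(g) <- c("experiment_grid", "data.frame")
  g
}

cell_sequence <- function(system, sequences) {
  if (!is.null(sequences) && system %in% names(sequences))
    return(sequences[[system]])
  fus_segment(system)
}

#' Run an experiment grid
#'
#' For each cell: build the chain variant, run the slab protocol at the
#' grid's preset size, and summarise with [analyze_trajectory()].  Cell
#' failures are isolated (the row carries the error message) and the grid
#' continues.  `dry_run = TRUE` only enumerates the cells.
#'
#' @param grid an [experiment_grid()].
#' @param dry_run enumerate without simulating.
#' @param contacts compute contact statistics for charged cells.
#' @param verbose print one line per cell.
#' @param preset_overrides named list overriding individual [preset()] fields
#'   (problem sizes, durations, cadences) for all cells.
#' @return the grid with summary columns appended.
#' @export
run_grid <- function(grid, dry_run = FALSE, contacts = FALSE, verbose = FALSE,
                     preset_overrides = NULL) {
  stopifnot(inherits(grid, "experiment_grid"))
  if (dry_run) return(grid)
  ps <- preset(attr(grid, "preset_name"))
  if (!is.null(preset_overrides)) ps <- modifyList(ps, preset_overrides)
  seqs <- attr(grid, "sequences")
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    res[[i]] <- tryCatch({
      spec <- chain_spec(cell_sequence(row$system, seqs),
                         mass_scale = row$mass_scale,
                         insertion_mode = row$insertion_mode)
      ff <- if (row$charge_mode == "salt_10mM")
        force_field(kappa = kappa_from_salt(0.01), r_cut_lj = ps$r_cut_lj)
      else force_field(charge_mode = "no_charge", r_cut_lj = ps$r_cut_lj)
      cfg <- sim_config(temperature = row$temperature,
                        duration = ps$duration, equil = ps$equil,
                        frame_interval = ps$frame_interval,
                        seed = row$seed, slab_fraction = ps$slab_fraction)
      traj <- run_protocol(spec, ps$n_chains, ps$box, cfg, ff)
      s <- analyze_trajectory(traj, tail_fraction = ps$analysis_fraction,
                              flux_boundary = ps$flux_boundary,
                              contacts = contacts && row$charge_mode == "salt_10mM")
      s$error <- NA_character_
      if (verbose) message(row$cell, ": ph_pl=", signif(s$ph_pl, 3),
                           " z_rate=", signif(s$z_rate, 4))
      s
    }, error = function(e) {
      data.frame(p_h = NA_real_, p_l = NA_real_, ph_pl = NA_real_,
                 z_rate = NA_real_, flux = NA_real_, d_mean = NA_real_,
                 error = conditionMessage(e))
    })
  }
  cols <- unique(unlist(lapply(res, names)))
  res <- lapply(res, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA_real_
    r[cols]
  })
  cbind(as.data.frame(grid), do.call(rbind, res))
}
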