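# Phase-separation observables: windowed z density profiles and their
# high-low difference, condensed-phase centering, chain |z| probability
# profiles, the z motion rate, and the boundary flux.

#' Windowed bead density profile along z
#'
#' Fraction of beads per window (P_gamma = m_gamma / N) for `n_windows`
#' equal half-open windows spanning the box z-length (30 windows of 10 nm for
#' the published 300 nm slab).  Coordinates are wrapped into the box first.
#'
#' @param z bead z coordinates, nm (any image).
#' @param lz box z-length, nm.
#' @param n_windows number of windows (default 30).
#' @return numeric vector of occupancy fractions summing to 1, with the
#'   window lower edges as names.
#' @export
density_profile <- function(z, lz, n_windows = 30L) {
  stopifnot(lz > 0, n_windows >= 1L)
  zw <- z %% lz
  idx <- pmin(floor(zw / (lz / n_windows)), n_windows - 1L) + 1L
  p <- tabulate(idx, nbins = n_windows) / length(z)
  names(p) <- signif((seq_len(n_windows) - 1L) * lz / n_windows, 6)
  p
}

#' Density profiles for a series of trajectory frames
#'
#' @param traj a `cg_trajectory`.
#' @param frames frame indices (default all).
#' @param n_windows number of windows.
#' @return an `n_windows` x `length(frames)` matrix of occupancy fractions.
#' @export
density_profile_series <- function(traj, frames = NULL, n_windows = 30L) {
  nf <- dim(traj$coords)[3]
  if (is.null(frames)) frames <- seq_len(nf)
  vapply(frames,
         function(f) density_profile(traj$coords[, 3, f], traj$box[3], n_windows),
         numeric(n_windows))
}

#' Highest and lowest window densities
#'
#' For a profile time-series (windows x frames matrix) the per-frame profiles
#' are averaged over the analysis window before taking the extrema (the
#' published convention); `per_frame = TRUE` instead takes per-frame extrema
#' and averages those.
#'
#' @param profile a profile vector from [density_profile()] or a windows x
#'   frames matrix.
#' @param per_frame average per-frame extrema instead of the extrema of the
#'   time-averaged profile.
#' @return named vector `c(p_h, p_l, diff)`.
#' @export
#' @examples
#' ph_pl(density_profile(rep(5, 100), lz = 300))  # delta profile: diff = 1
ph_pl <- function(profile, per_frame = FALSE) {
  if (is.matrix(profile)) {
    if (per_frame) {
      ph <- mean(apply(profile, 2, max))
      pl <- mean(apply(profile, 2, min))
      return(c(p_h = ph, p_l = pl, diff = ph - pl))
    }
    profile <- rowMeans(profile)
  }
  c(p_h = max(profile), p_l = min(profile), diff = max(profile) - min(profile))
}

# circular (periodic) centre of a set of coordinates along a box dimension
circular_center <- function(z, lz) {
  theta <- 2 * pi * (z %% lz) / lz
  ((atan2(mean(sin(theta)), mean(cos(theta))) / (2 * pi)) %% 1) * lz
}

#' Centre the condensed phase and compute chain |z| displacements
#'
#' Per frame, the condensed-phase centre z_c is the circular (periodic) mean
#' of all bead z coordinates; each chain's displacement is the minimum-image
#' distance of its centre of mass to z_c.  This removes the arbitrary slab
#' position (including wrap-around across the box edge).
#'
#' @param traj a `cg_trajectory` with topology.
#' @param frames frame indices to use (default all).
#' @return object of class `cg_chain_series`: `absz` and signed `z_rel`
#'   (n_chains x n_frames, nm), `z_center` per frame, `times`, `lz`.
#' @export
center_condensed_phase <- function(traj, frames = NULL) {
  nf <- dim(traj$coords)[3]
  if (is.null(frames)) frames <- seq_len(nf)
  lz <- traj$box[3]
  cm <- chain_cm(traj)  # n_chains x n_frames, unwrapped
  cm <- cm[, frames, drop = FALSE]
  zc <- vapply(frames, function(f) circular_center(traj$coords[, 3, f], lz),
               numeric(1))
  zrel <- sweep(cm, 2, zc)
  zrel <- (zrel + lz / 2) %% lz - lz / 2   # minimum image, in [-lz/2, lz/2)
  structure(list(absz = abs(zrel), z_rel = zrel, z_center = zc,
                 times = traj$times[frames], lz = lz,
                 n_chains = nrow(cm)),
            class = "cg_chain_series")
}

#' @export
print.cg_chain_series <- function(x, ...) {
  cat("cg_chain_series: ", x$n_chains, " chains x ", ncol(x$absz),
      " frames, |z| up to ", signif(max(x$absz), 4), " nm\n", sep = "")
  invisible(x)
}

#' Mean z motion rate of the chains
#'
#' Mean absolute z displacement of the chain centres of mass per unit reduced
#' time: v = sum_t sum_n |z_n(t+1) - z_n(t)| / (n_chains n_intervals dt),
#' evaluated on unwrapped coordinates at the frame cadence (0.5 tau).  The
#' published convention uses the last 1000 tau of a 5000 tau run (200 chains,
#' 2000 intervals).
#'
#' @param cm_z n_chains x n_frames matrix of unwrapped chain CM z, nm (e.g.
#'   [chain_cm()]), or a `cg_trajectory`.
#' @param times frame times in tau (taken from the trajectory if one is
#'   given).
#' @param t0,t_end analysis window in tau (default: all frames).
#' @return rate in Angstrom per tau.
#' @export
z_motion_rate <- function(cm_z, times = NULL, t0 = NULL, t_end = NULL) {
  if (inherits(cm_z, "cg_trajectory")) {
    times <- cm_z$times
    cm_z <- chain_cm(cm_z)
  }
  stopifnot(is.matrix(cm_z), length(times) == ncol(cm_z))
  keep <- rep(TRUE, length(times))
  if (!is.null(t0)) keep <- keep & times >= t0 - 1e-9
  if (!is.null(t_end)) keep <- keep & times <= t_end + 1e-9
  cm_z <- cm_z[, keep, drop = FALSE]
  times <- times[keep]
  if (ncol(cm_z) < 2L) stop("need at least two frames in the analysis window")
  dts <- diff(times)
  if (max(abs(dts - dts[1])) > 1e-6)
    stop("frames are not on a regular time grid")
  dz <- abs(cm_z[, -1L, drop = FALSE] - cm_z[, -ncol(cm_z), drop = FALSE])
  n_intervals <- ncol(dz)
  10 * sum(dz) / (nrow(cm_z) * n_intervals * dts[1])  # nm -> Angstrom
}

#' Chain flux across the condensed-phase boundary
#'
#' Counts, per frame interval, the chains whose centre of mass crosses the
#' condensed-phase boundary, divided by the interval (0.5 tau), giving
#' chains/tau.  Default convention `"planes"`: the boundary is the pair of
#' planes at z - z_c = +/- `boundary` of the recentered coordinates; a chain
#' crossing either plane between consecutive frames is counted once.
#' `"printed"` applies the raw published indicator on unwrapped coordinates in
#' Angstrom (sign changes about 2500 A, 3000 A and 0).
#'
#' @param series a `cg_chain_series` from [center_condensed_phase()] (or, for
#'   `"printed"`, an n_chains x n_frames matrix of unwrapped z in nm).
#' @param boundary boundary distance from the slab centre, nm (default 25,
#'   the published 250 A line).
#' @param convention `"planes"` or `"printed"`.
#' @return list with `times` (interval end times, tau), `n_t` (chains/tau per
#'   interval) and `mean` over the intervals.
#' @export
flux <- function(series, boundary = 25, convention = c("planes", "printed")) {
  convention <- match.arg(convention)
  if (convention == "planes") {
    stopifnot(inherits(series, "cg_chain_series"))
    z <- series$z_rel
    lz <- series$lz
    times <- series$times
    nfr <- ncol(z)
    if (nfr < 2L) stop("need at least two frames")
    dt <- diff(times)
    z1 <- z[, -nfr, drop = FALSE]
    step <- z[, -1L, drop = FALSE] - z1
    step <- (step + lz / 2) %% lz - lz / 2     # minimum-image displacement
    if (any(abs(step) >= lz / 2 - 1e-9))
      warning("chain displacement of half a box per interval: cadence too coarse")
    z2 <- z1 + step
    crossed <- ((z1 - boundary) * (z2 - boundary) < 0) |
               ((z1 + boundary) * (z2 + boundary) < 0)
  } else {
    z <- if (inherits(series, "cg_chain_series")) series$z_rel else series
    times <- attr(series, "times")
    if (inherits(series, "cg_chain_series")) times <- series$times
    stopifnot(!is.null(times))
    za <- z * 10  # nm -> Angstrom, unwrapped
    nfr <- ncol(za)
    dt <- diff(times)
    z1 <- za[, -nfr, drop = FALSE]
    z2 <- za[, -1L, drop = FALSE]
    b <- 250
    crossed <- ((z1 - (2750 - b)) * (z2 - (2750 - b)) < 0) |
               ((z1 - (2750 + b)) * (z2 - (2750 + b)) < 0) |
               (z1 * z2 < 0)
  }
  n_t <- colSums(crossed) / dt
  list(times = times[-1L], n_t = n_t, mean = mean(n_t))
}

#' Chain probability profile along |z|
#'
#' Fraction of chain-frame observations per |z| window.  Windows span 0 to
#' Lz/2 in `n_windows` equal bins (5 nm each for the published 300 nm slab);
#' values at exactly Lz/2 fall in the last window.
#'
#' @param series a `cg_chain_series`.
#' @param n_windows number of |z| windows (default 30).
#' @return named numeric vector of fractions summing to 1.
#' @export
chain_probability_profile <- function(series, n_windows = 30L) {
  stopifnot(inherits(series, "cg_chain_series"))
  half <- series$lz / 2
  w <- half / n_windows
  idx <- pmin(floor(series$absz / w), n_windows - 1L) + 1L
  p <- tabulate(idx, nbins = n_windows) / length(idx)
  names(p) <- signif((seq_len(n_windows) - 1L) * w, 6)
  p
}
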