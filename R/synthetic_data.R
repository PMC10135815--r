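# Synthetic-data generators: charge-composition-matched sequences, scripted
# toy trajectories with hand-countable observables, slab-like static
# configurations, and power-law binodal series.  Every generator is
# deterministic under its seed and carries its construction record, so
# downstream metrics can be tested against ground truth.

#' Random sequence with a prescribed charge composition
#'
#' Places `n_neg` acidic residues (D/E) and `n_pos` basic residues (K/R) at
#' random positions of a glycine background.
#'
#' @param length sequence length.
#' @param n_neg,n_pos number of negative / positive residues.
#' @param seed integer seed.
#' @return one-letter sequence string.
#' @export
#' @examples
#' s <- make_sequence(50, 6, 9, seed = 1)   # RGG-like composition
#' sum(assign_charges(s) == -1)             # 6
make_sequence <- function(length, n_neg, n_pos, seed) {
  stopifnot(n_neg >= 0, n_pos >= 0, n_neg + n_pos <= length)
  set.seed(as.integer(seed))
  res <- rep("G", length)
  idx <- sample.int(length, n_neg + n_pos)
  if (n_neg > 0) res[idx[seq_len(n_neg)]] <- sample(c("D", "E"), n_neg, TRUE)
  if (n_pos > 0) res[idx[n_neg + seq_len(n_pos)]] <- sample(c("K", "R"), n_pos, TRUE)
  paste(res, collapse = "")
}

#' Scripted toy trajectory with known chain paths
#'
#' Builds a `cg_trajectory` of single-bead chains whose z coordinates follow a
#' prescribed (chains x frames) script, so motion-rate, flux and profile
#' calculations can be checked against hand counts.  The script is stored
#' unwrapped; x/y default to fixed chain-specific positions.
#'
#' @param z n_chains x n_frames matrix of unwrapped chain z coordinates, nm.
#' @param times frame times in tau (default `0.5 * (0:(n_frames-1))`).
#' @param box length-3 box, nm (default `c(10, 10, 300)`).
#' @param ground_truth optional list of constructed-by-hand expected values,
#'   attached as the `"ground_truth"` attribute.
#' @return a `cg_trajectory` with one bead per chain.
#' @export
make_scripted_trajectory <- function(z, times = NULL, box = c(10, 10, 300),
                                     ground_truth = NULL) {
  z <- as.matrix(z)
  n_chains <- nrow(z)
  n_frames <- ncol(z)
  if (is.null(times)) times <- 0.5 * (seq_len(n_frames) - 1L)
  stopifnot(length(times) == n_frames, length(box) == 3L)
  beads <- data.frame(residue = rep("G", n_chains), mass = 1.0,
                      charge = 0L, is_insert = FALSE,
                      chain_id = seq_len(n_chains),
                      index_in_chain = 1L, stringsAsFactors = FALSE)
  topo <- structure(list(beads = beads,
                         bonds = matrix(integer(0), ncol = 2),
                         n_chains = n_chains, chain_length = 1L,
                         box = as.numeric(box)),
                    class = "cg_topology")
  coords <- array(0, c(n_chains, 3L, n_frames))
  # fixed, distinct x/y per chain keeps the frames valid 3D configurations
  coords[, 1, ] <- (seq_len(n_chains) - 0.5) %% box[1]
  coords[, 2, ] <- box[2] / 2
  coords[, 3, ] <- z
  traj <- new_trajectory(coords = coords, times = times, box = box,
                         topology = topo)
  attr(traj, "ground_truth") <- ground_truth
  traj
}

#' Static slab configuration with known occupancy
#'
#' Packs chains into the central `slab_fraction` of the box z-length and
#' records which density windows the slab spans, providing a density-profile
#' oracle and a compact-slab initial condition.
#'
#' @param n_chains,chain_length chains and beads per chain.
#' @param slab_fraction central z-fraction occupied, in (0, 1].
#' @param box length-3 box, nm.
#' @param seed integer seed.
#' @param n_windows window count of the recorded profile oracle.
#' @return list with `topology`, `coords` and `record` (`z_range` and the
#'   logical vector `window_occupied` over `n_windows` windows).
#' @export
make_slab_configuration <- function(n_chains, chain_length, slab_fraction,
                                    box, seed, n_windows = 30L) {
  stopifnot(slab_fraction > 0, slab_fraction <= 1)
  spec <- chain_spec(strrep("G", chain_length))
  zc <- box[3] / 2
  half <- slab_fraction * box[3] / 2
  z_range <- c(zc - half, zc + half)
  sys <- replicate_system(spec, n_chains, box, seed, z_range = z_range)
  edges <- seq(0, box[3], length.out = n_windows + 1L)
  occupied <- edges[-length(edges)] < z_range[2] & edges[-1L] > z_range[1]
  sys$record <- list(z_range = z_range, window_occupied = occupied,
                     slab_fraction = slab_fraction)
  sys
}

#' Synthetic power-law binodal series
#'
#' Order-parameter values from P_H - P_L = A (t_cr - T)^beta for T < t_cr
#' (0 above), plus optional Gaussian noise, clipped at 0.  The generating
#' parameters are stored in the `"ground_truth"` attribute.
#'
#' @param A,t_cr,beta generating parameters.
#' @param temperature temperature grid, T0 units (strictly increasing).
#' @param noise_sd Gaussian noise standard deviation (0 = exact).
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @return data.frame with `temperature` and `value`.
#' @export
#' @examples
#' make_binodal(0.5, 3.0, 0.325, c(1, 1.5, 2, 2.5, 2.75, 2.9))
make_binodal <- function(A, t_cr, beta, temperature, noise_sd = 0, seed = 1) {
  stopifnot(A > 0, beta > 0, all(diff(temperature) > 0), noise_sd >= 0)
  value <- A * pmax(t_cr - temperature, 0)^beta
  truth <- value
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    value <- pmax(value + rnorm(length(value), 0, noise_sd), 0)
  }
  out <- data.frame(temperature = temperature, value = value)
  attr(out, "ground_truth") <- list(A = A, t_cr = t_cr, beta = beta,
                                    noiseless = truth)
  out
}
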