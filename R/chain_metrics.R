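# Per-chain conformation and electrostatic-contact observables: head-to-tail
# distance D (excluding inserted glycines) and intra-/inter-chain
# opposite-charge contact counts, with profiles along |z|.

#' Head-to-tail distance of each chain
#'
#' Minimum-image distance between the first and last bead of each chain.  With
#' `exclude_inserts` (the default) the termini are the first and last
#' non-inserted beads, so a glycine-tailed chain reports the distance of the
#' underlying segment.
#'
#' @param coords N x 3 coordinates (nm) of one frame, or a `cg_trajectory`.
#' @param topology a `cg_topology` (taken from the trajectory if omitted).
#' @param exclude_inserts skip inserted glycines when picking the termini.
#' @return for one frame a vector of per-chain D in Angstrom; for a
#'   trajectory an n_chains x n_frames matrix.
#' @export
#' @examples
#' # straight 50-mer at 0.38 nm spacing: D = 49 * 3.8 = 186.2 A
end_to_end <- function(coords, topology = NULL, exclude_inserts = TRUE) {
  if (inherits(coords, "cg_trajectory")) {
    traj <- coords
    if (is.null(topology)) topology <- traj$topology
    nf <- dim(traj$coords)[3]
    return(vapply(seq_len(nf), function(f)
      end_to_end(traj$coords[, , f], topology, exclude_inserts),
      numeric(topology$n_chains)))
  }
  stopifnot(inherits(topology, "cg_topology"))
  beads <- topology$beads
  box <- topology$box
  keep <- if (exclude_inserts) !beads$is_insert else rep(TRUE, nrow(beads))
  idx <- split(which(keep), beads$chain_id[keep])
  vapply(idx, function(ii) {
    a <- coords[ii[1L], ]
    b <- coords[ii[length(ii)], ]
    d <- a - b
    d <- d - box * round(d / box)
    10 * sqrt(sum(d * d))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Opposite-charge contact counts per chain
#'
#' E_intra counts pairs of opposite-charge beads of the *same* chain closer
#' than `intra_cutoff`; E_inter counts opposite-charge pairs of *different*
#' chains closer than `inter_cutoff`, attributed to both chains.  Distances
#' are bead-bead minimum-image distances.  Systems with no charged beads
#' return all zeros with a message (only the RGG systems at 10 mM salt carry
#' these observables).
#'
#' @param coords N x 3 coordinates (nm) of one frame.
#' @param topology a `cg_topology`.
#' @param intra_cutoff intra-chain cutoff, nm (default 1.2 = 12 A).
#' @param inter_cutoff inter-chain cutoff, nm (default 1.5 = 15 A).
#' @return list with per-chain integer vectors `e_intra` and `e_inter`.
#' @export
electrostatic_contacts <- function(coords, topology,
                                   intra_cutoff = 1.2, inter_cutoff = 1.5) {
  stopifnot(inherits(topology, "cg_topology"), intra_cutoff > 0,
            inter_cutoff > 0)
  beads <- topology$beads
  nch <- topology$n_chains
  pos <- which(beads$charge > 0L)
  neg <- which(beads$charge < 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    message("no opposite-charge pairs in this system; contact counts are zero")
    return(list(e_intra = integer(nch), e_inter = integer(nch)))
  }
  box <- topology$box
  dd2 <- function(ii, jj) {  # squared min-image distances, |ii| x |jj|
    d2 <- 0
    for (k in 1:3) {
      d <- outer(coords[ii, k], coords[jj, k], "-")
      d <- d - box[k] * round(d / box[k])
      d2 <- d2 + d * d
    }
    d2
  }
  d2 <- dd2(pos, neg)
  same <- outer(beads$chain_id[pos], beads$chain_id[neg], "==")
  e_intra <- integer(nch)
  hit_in <- which(same & d2 < intra_cutoff^2, arr.ind = TRUE)
  if (nrow(hit_in) > 0L) {
    tab <- table(beads$chain_id[pos][hit_in[, 1]])
    e_intra[as.integer(names(tab))] <- as.integer(tab)
  }
  e_inter <- integer(nch)
  hit_out <- which(!same & d2 < inter_cutoff^2, arr.ind = TRUE)
  if (nrow(hit_out) > 0L) {
    cp <- beads$chain_id[pos][hit_out[, 1]]
    cn <- beads$chain_id[neg][hit_out[, 2]]
    tab <- table(c(cp, cn))  # each contact credited to both chains
    e_inter[as.integer(names(tab))] <- as.integer(tab)
  }
  list(e_intra = e_intra, e_inter = e_inter)
}

#' Mean and standard error of a per-chain observable along |z|
#'
#' Bins chain-frame observations of an observable (head-to-tail distance,
#' contact counts, ...) by the chain's |z| window and reports the per-window
#' mean and standard error.  Observations beyond `exclude_above` (nm; default
#' 140, near the slab half-length where boundary effects set in) are omitted.
#'
#' @param values n_chains x n_frames matrix of the observable.
#' @param series the matching `cg_chain_series`.
#' @param n_windows number of |z| windows (default 30).
#' @param exclude_above drop observations with |z| above this, nm.
#' @return data.frame with `absz` (window lower edge, nm), `mean`, `se`, `n`.
#' @export
profile_vs_absz <- function(values, series, n_windows = 30L,
                            exclude_above = 140) {
  stopifnot(inherits(series, "cg_chain_series"),
            all(dim(values) == dim(series$absz)))
  half <- series$lz / 2
  w <- half / n_windows
  idx <- pmin(floor(series$absz / w), n_windows - 1L) + 1L
  keep <- series$absz <= exclude_above
  f <- factor(idx[keep], levels = seq_len(n_windows))
  v <- values[keep]
  n <- as.integer(table(f))
  mu <- tapply(v, f, mean)
  se <- tapply(v, f, function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_)
  data.frame(absz = (seq_len(n_windows) - 1L) * w,
             mean = as.numeric(mu), se = as.numeric(se), n = n)
}

#' Mean head-to-tail distance per temperature
#'
#' @param d_list named list of per-chain D matrices (one per temperature, as
#'   returned by [end_to_end()] on a trajectory).
#' @param temperatures temperatures in T0 units, matching `d_list`.
#' @return data.frame with `temperature`, `mean` (Angstrom), `se`.
#' @export
d_vs_temperature <- function(d_list, temperatures = as.numeric(names(d_list))) {
  stopifnot(length(d_list) == length(temperatures))
  data.frame(
    temperature = temperatures,
    mean = vapply(d_list, function(m) mean(m), numeric(1)),
    se = vapply(d_list, function(m) sd(m) / sqrt(length(m)), numeric(1)))
}
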