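# Chain construction: one bead per residue, mass variants and glycine-insert
# variants of the FUS PLD / RGG segments, and replication into a simulation box.

AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

#' Assign bead charges from a residue sequence
#'
#' Aspartate and glutamate carry charge -1, lysine and arginine +1, all other
#' residues 0 (in elementary charge units).
#'
#' @param sequence one-letter residue string, or a character vector of
#'   single letters.
#' @return integer vector of per-residue charges in \{-1, 0, +1\}.
#' @export
#' @examples
#' assign_charges("GKRG")  # 0  1  1  0
#' assign_charges("DEDE")  # -1 -1 -1 -1
assign_charges <- function(sequence) {
  res <- split_sequence(sequence)
  bad <- which(!(res %in% AA1))
  if (length(bad) > 0L) {
    stop("unknown residue letter(s) '", paste(res[bad], collapse = "', '"),
         "' at position(s) ", paste(bad, collapse = ", "))
  }
  ch <- integer(length(res))
  ch[res %in% c("D", "E")] <- -1L
  ch[res %in% c("K", "R")] <- 1L
  ch
}

split_sequence <- function(sequence) {
  if (length(sequence) == 1L && nchar(sequence) > 1L) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  toupper(as.character(sequence))
}

#' Specify a coarse-grained chain variant
#'
#' A chain is a residue sequence plus a bead-mass scale (the isotope-labelling
#' surrogate) and a glycine-insertion mode.  `tail10` appends 10 glycines;
#' `head5tail5` prepends 5 and appends 5.  Inserted glycines are flagged,
#' interact through the reduced `eps_insert` Lennard-Jones scale, and always
#' carry mass 1.0, so a `tail10` mass-1.0 60-mer has the same total mass as a
#' mass-1.2 50-mer.
#'
#' @param sequence one-letter residue string.
#' @param mass_scale bead mass for the non-inserted residues, in bead mass
#'   units m0 (1.0, 1.1, 1.2, 1.3 and 1.5 are the studied values).
#' @param insertion_mode one of `"none"`, `"tail10"`, `"head5tail5"`.
#' @return an object of class `chain_spec`.
#' @export
#' @examples
#' chain_spec(strrep("G", 50), mass_scale = 1.2)
chain_spec <- function(sequence, mass_scale = 1.0,
                       insertion_mode = c("none", "tail10", "head5tail5")) {
  insertion_mode <- match.arg(insertion_mode)
  res <- split_sequence(sequence)
  assign_charges(res)  # validates letters
  stopifnot(is.numeric(mass_scale), length(mass_scale) == 1L, mass_scale > 0)
  structure(list(sequence = paste(res, collapse = ""),
                 mass_scale = mass_scale,
                 insertion_mode = insertion_mode),
            class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat("chain_spec: ", nchar(x$sequence), "-mer, mass scale ", x$mass_scale,
      ", insertion ", x$insertion_mode, "\n", sep = "")
  invisible(x)
}

#' Build the per-bead records of a chain variant
#'
#' Expands a [chain_spec()] into one record per bead: residue, mass, charge,
#' insert flag and position in the chain.  Charges are assigned on the full
#' post-insertion sequence (inserted glycines are neutral).
#'
#' @param spec a [chain_spec()].
#' @return a data.frame with columns `residue`, `mass`, `charge`, `is_insert`,
#'   `index_in_chain`.
#' @export
#' @examples
#' b <- build_chain(chain_spec(strrep("G", 50), 1.0, "tail10"))
#' nrow(b)       # 60
#' sum(b$mass)   # 60, equal to the mass-1.2 50-mer
build_chain <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  res <- split_sequence(spec$sequence)
  ins <- rep(FALSE, length(res))
  if (spec$insertion_mode == "tail10") {
    res <- c(res, rep("G", 10L))
    ins <- c(ins, rep(TRUE, 10L))
  } else if (spec$insertion_mode == "head5tail5") {
    res <- c(rep("G", 5L), res, rep("G", 5L))
    ins <- c(rep(TRUE, 5L), ins, rep(TRUE, 5L))
  }
  mass <- ifelse(ins, 1.0, spec$mass_scale)
  data.frame(residue = res,
             mass = mass,
             charge = assign_charges(res),
             is_insert = ins,
             index_in_chain = seq_along(res),
             stringsAsFactors = FALSE)
}

#' Replicate a chain into a periodic simulation box
#'
#' Places `n_chains` copies of a chain as random walks with bond length `r0`,
#' rejecting any bead that falls within `min_dist` of a bead of another chain.
#' Placement is deterministic under `set.seed`-style seeding.
#'
#' @param chain a per-bead data.frame from [build_chain()], or a [chain_spec()].
#' @param n_chains number of chains.
#' @param box numeric length-3 box (Lx, Ly, Lz) in nm.
#' @param seed integer seed for the placement RNG.
#' @param r0 bond length in nm (default 0.38).
#' @param min_dist minimum inter-chain bead distance in nm (default 0.5).
#' @param z_range optional length-2 vector restricting chain starting points
#'   (and growth) to a z-interval, used to construct compact slabs.
#' @param max_retries bounded retry count per bead before placement is
#'   declared failed.
#' @return a list with `topology` (class `cg_topology`: beads data.frame with
#'   `chain_id`, `bonds` 1-based index matrix, `n_chains`, `chain_length`,
#'   `box`) and `coords` (N x 3 matrix, nm, wrapped into the box).
#' @export
#' @examples
#' sys <- replicate_system(build_chain(chain_spec(strrep("G", 5))),
#'                         n_chains = 3, box = c(10, 10, 10), seed = 1)
#' nrow(sys$coords)  # 15
replicate_system <- function(chain, n_chains, box, seed,
                             r0 = 0.38, min_dist = 0.5,
                             z_range = NULL, max_retries = 200L) {
  if (inherits(chain, "chain_spec")) chain <- build_chain(chain)
  stopifnot(is.data.frame(chain), n_chains >= 1L,
            length(box) == 3L, all(box > 0))
  if (is.null(z_range)) z_range <- c(0, box[3])
  stopifnot(length(z_range) == 2L, z_range[1] >= 0, z_range[2] <= box[3],
            z_range[2] > z_range[1])
  L <- nrow(chain)
  set.seed(as.integer(seed))
  cpp_seed <- sample.int(.Machine$integer.max, 1L)
  coords <- cpp_place_chains(as.integer(n_chains), as.integer(L),
                             as.numeric(box), r0, min_dist,
                             as.numeric(z_range), as.integer(max_retries),
                             cpp_seed)
  if (is.character(coords)) stop(coords)
  beads <- chain[rep(seq_len(L), n_chains), , drop = FALSE]
  beads$chain_id <- rep(seq_len(n_chains), each = L)
  rownames(beads) <- NULL
  bonds <- chain_bonds(n_chains, L)
  topo <- structure(list(beads = beads, bonds = bonds,
                         n_chains = n_chains, chain_length = L,
                         box = as.numeric(box)),
                    class = "cg_topology")
  list(topology = topo, coords = coords)
}

chain_bonds <- function(n_chains, chain_length) {
  if (chain_length < 2L) return(matrix(integer(0), ncol = 2))
  one <- cbind(seq_len(chain_length - 1L), 2:chain_length)
  off <- rep((seq_len(n_chains) - 1L) * chain_length, each = chain_length - 1L)
  cbind(one[rep(seq_len(nrow(one)), n_chains), 1] + off,
        one[rep(seq_len(nrow(one)), n_chains), 2] + off)
}

#' @export
print.cg_topology <- function(x, ...) {
  cat("cg_topology: ", x$n_chains, " chains x ", x$chain_length, " beads = ",
      nrow(x$beads), " beads, ", nrow(x$bonds), " bonds, box ",
      paste(signif(x$box, 4), collapse = " x "), " nm\n", sep = "")
  cat("  masses: ", paste(unique(x$beads$mass), collapse = ", "),
      "; charges -1/0/+1: ",
      paste(tabulate(factor(x$beads$charge, levels = c(-1, 0, 1))),
            collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Load a packaged FUS segment sequence
#'
#' Returns the one-letter sequence of the packaged FUS fixtures: `"PLD"`
#' (residues 1-50, prion-like domain; 2 negative, 0 positive charges) or
#' `"RGG"` (residues 453-502, RGG3 segment; 6 negative, 9 positive charges).
#'
#' @param segment `"PLD"` or `"RGG"`.
#' @return one-letter sequence string.
#' @export
#' @examples
#' sum(assign_charges(fus_segment("RGG")) == 1)  # 9
fus_segment <- function(segment = c("PLD", "RGG")) {
  segment <- match.arg(segment)
  path <- system.file("extdata", "fus_segments.fasta", package = "cgslab")
  seqs <- read_fasta(path)
  unname(seqs[segment])
}
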