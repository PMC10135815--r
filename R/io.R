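# Readers and writers: FASTA sequences, topology JSON, extended-XYZ and DCD
# trajectories, YAML run configs, and TSV tables.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of one-letter sequences; names are the
#'   first word of each header.
#' @export
read_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  out <- toupper(vapply(seqs, `[[`, character(1), 1L))
  names(out) <- names(seqs)
  out
}

#' Write / read a topology as JSON
#'
#' Serializes beads (residue, mass, charge, insert flag, chain id), bonds,
#' chain counts and the box.  Reading validates the schema and rejects
#' dangling bond indices.
#'
#' @param topology a `cg_topology`.
#' @param path output file.
#' @return `write_topology_json` returns `path` invisibly;
#'   `read_topology_json` returns the `cg_topology`.
#' @export
write_topology_json <- function(topology, path) {
  stopifnot(inherits(topology, "cg_topology"))
  obj <- list(beads = topology$beads,
              bonds = unname(apply(topology$bonds, 1, function(r) as.integer(r),
                                   simplify = FALSE)),
              n_chains = topology$n_chains,
              chain_length = topology$chain_length,
              box = topology$box)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_topology_json
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("beads", "n_chains", "chain_length", "box")
  miss <- setdiff(need, names(obj))
  if (length(miss) > 0L)
    stop("topology file lacks field(s): ", paste(miss, collapse = ", "))
  beads <- as.data.frame(obj$beads)
  bonds <- if (length(obj$bonds) == 0L) matrix(integer(0), ncol = 2)
           else if (is.matrix(obj$bonds)) matrix(as.integer(obj$bonds),
                                                 ncol = 2)
           else do.call(rbind, lapply(obj$bonds, as.integer))
  n <- nrow(beads)
  if (length(bonds) > 0L && (any(bonds < 1L) || any(bonds > n)))
    stop("topology file has dangling bond indices (bead count ", n, ")")
  structure(list(beads = beads, bonds = bonds,
                 n_chains = as.integer(obj$n_chains),
                 chain_length = as.integer(obj$chain_length),
                 box = as.numeric(obj$box)),
            class = "cg_topology")
}

#' Write / read a trajectory in extended-XYZ format
#'
#' One block per frame: atom count, a comment line carrying
#' `Lattice="..." Time=<tau>`, then residue code and x/y/z in nm.
#' `wrap = TRUE` (default) wraps coordinates into the box on output.
#'
#' @param traj a `cg_trajectory`.
#' @param path output file.
#' @param wrap wrap coordinates into the box.
#' @return `write_xyz` returns `path` invisibly; `read_xyz` a
#'   `cg_trajectory` (without topology).
#' @export
write_xyz <- function(traj, path, wrap = TRUE) {
  d <- dim(traj$coords)
  con <- file(path, "w")
  on.exit(close(con))
  species <- if (!is.null(traj$topology)) traj$topology$beads$residue
             else rep("X", d[1])
  box <- traj$box
  lattice <- sprintf('Lattice="%.9g 0 0 0 %.9g 0 0 0 %.9g"',
                     box[1], box[2], box[3])
  for (f in seq_len(d[3])) {
    xyz <- traj$coords[, , f]
    if (wrap) xyz <- sweep(xyz, 2, box, function(a, b) a %% b)
    writeLines(as.character(d[1]), con)
    writeLines(sprintf('%s Properties=species:S:1:pos:R:3 Time=%.9g',
                       lattice, traj$times[f]), con)
    writeLines(sprintf("%s %.9f %.9f %.9f", species, xyz[, 1], xyz[, 2],
                       xyz[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  times <- numeric(0)
  box <- NULL
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n))
      stop("malformed frame header at line ", i, " (frame ",
           length(frames) + 1L, ")")
    if (i + 1L + n > length(lines))
      stop("truncated trajectory: frame ", length(frames) + 1L,
           " is incomplete; last good frame is ", length(frames))
    comment <- lines[i + 1L]
    lat <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
    if (length(lat) == 1L) {
      v <- as.numeric(strsplit(sub('Lattice="', "", sub('"$', "", lat)),
                               "\\s+")[[1]])
      box <- v[c(1, 5, 9)]
    }
    tm <- regmatches(comment, regexpr("Time=[-0-9.eE+]+", comment))
    times <- c(times, if (length(tm) == 1L)
      as.numeric(sub("Time=", "", tm)) else NA_real_)
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    mat <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- mat
    i <- i + 2L + n
  }
  coords <- array(unlist(frames), c(nrow(frames[[1]]), 3L, length(frames)))
  new_trajectory(coords = coords, times = times,
                 box = if (is.null(box)) rep(NA_real_, 3) else box)
}

#' Write / read a trajectory in DCD format
#'
#' `write_dcd` emits a minimal CHARMM-style DCD (little-endian, float32,
#' coordinates in Angstrom, no unit-cell records); `read_dcd` reads through
#' `bio3d::read.dcd` and converts back to nm.  DCD stores single-precision
#' coordinates and no frame times; supply `times` on read if needed.
#'
#' @param traj a `cg_trajectory`.
#' @param path file path.
#' @param times frame times (tau) to attach on read.
#' @param box box to attach on read, nm.
#' @return `write_dcd` returns `path` invisibly; `read_dcd` a
#'   `cg_trajectory`.
#' @export
write_dcd <- function(traj, path) {
  d <- dim(traj$coords)
  n <- d[1]
  nf <- d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: payload wrapped in byte-count markers
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(length(payload), con, size = 4, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf      # frames
  icntrl[2] <- 1L      # first step
  icntrl[3] <- 1L      # save interval
  icntrl[20] <- 24L    # CHARMM version stamp
  rec(function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    writeBin(icntrl, c2, size = 4, endian = "little")
  })
  title <- sprintf("%-80s", "coarse-grained slab trajectory (Angstrom)")
  rec(function(c2) {
    writeBin(1L, c2, size = 4, endian = "little")
    writeChar(title, c2, nchars = 80, eos = NULL)
  })
  rec(function(c2) writeBin(as.integer(n), c2, size = 4, endian = "little"))
  for (f in seq_len(nf)) {
    for (k in 1:3) {
      rec(function(c2) writeBin(as.numeric(10 * traj$coords[, k, f]), c2,
                                size = 4, endian = "little"))
    }
  }
  invisible(path)
}

#' @rdname write_dcd
#' @export
read_dcd <- function(path, times = NULL, box = rep(NA_real_, 3)) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("DCD support requires the bio3d package")
  m <- bio3d::read.dcd(path, verbose = FALSE)
  nf <- nrow(m)
  n <- ncol(m) / 3L
  coords <- array(NA_real_, c(n, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(m[f, ], ncol = 3, byrow = TRUE) / 10  # A -> nm
  if (is.null(times)) times <- seq_len(nf) - 1
  new_trajectory(coords = coords, times = times, box = box)
}

#' Write / read a run configuration as YAML
#'
#' @param config a [sim_config()] (or plain named list).
#' @param path file path.
#' @return `read_config` returns a [sim_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(sim_config, obj)
}

#' Write a table as TSV
#'
#' @param x data.frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
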