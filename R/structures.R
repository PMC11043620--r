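# Containers for static structures and multi-frame trajectories, plus
# multi-model PDB input/output.
#
# A structure holds one coordinate set (Angstrom) and a per-atom topology
# table with columns: chain (character), resid (1-based integer, contiguous
# within a chain), resname, atom (PDB atom name), element, solvent (logical).
# A trajectory holds an ordered list of coordinate matrices sharing one
# topology.

#' Create a structure object
#'
#' @param coords numeric matrix (n_atoms x 3), coordinates in Angstrom.
#' @param topology data.frame with columns `chain`, `resid`, `resname`,
#'   `atom`, `element`, `solvent`.
#' @return An object of class `idp_structure`.
#' @export
idp_structure <- function(coords, topology) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("`coords` must have 3 columns")
  required <- c("chain", "resid", "resname", "atom", "element", "solvent")
  if (!all(required %in% names(topology))) {
    stop("topology must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(topology) != nrow(coords)) {
    stop("coords and topology row counts differ")
  }
  structure(list(coords = coords, topology = topology),
            class = "idp_structure")
}

#' Create a trajectory object
#'
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom), all with
#'   the same atom count.
#' @param topology shared per-atom topology (see [idp_structure()]).
#' @return An object of class `idp_trajectory`.
#' @export
idp_trajectory <- function(frames, topology) {
  if (!length(frames)) stop("trajectory needs at least one frame")
  n <- vapply(frames, nrow, integer(1))
  if (length(unique(n)) != 1L) stop("all frames must share one atom count")
  s <- idp_structure(frames[[1L]], topology)  # validates topology
  structure(list(frames = lapply(frames, function(f) {
    f <- as.matrix(f); storage.mode(f) <- "double"; f
  }), topology = s$topology), class = "idp_trajectory")
}

#' @export
print.idp_structure <- function(x, ...) {
  cat(sprintf("<idp_structure> %d atoms, %d chain(s)\n",
              nrow(x$coords), length(unique(x$topology$chain))))
  invisible(x)
}

#' @export
print.idp_trajectory <- function(x, ...) {
  cat(sprintf("<idp_trajectory> %d frames, %d atoms, chains: %s\n",
              length(x$frames), nrow(x$frames[[1L]]),
              paste(unique(x$topology$chain), collapse = ",")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `idp_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame of a trajectory as a structure
#' @param traj an `idp_trajectory`.
#' @param i frame index (1-based).
#' @return An `idp_structure`.
#' @export
trajectory_frame <- function(traj, i) {
  if (i < 1L || i > length(traj$frames)) stop("frame index out of range")
  idp_structure(traj$frames[[i]], traj$topology)
}

# ---------------------------------------------------------------------------
# Multi-model PDB I/O.  MODEL/ENDMDL records delimit frames; chain IDs are
# single characters (protein chains A/B, water W by convention).

.pdb_atom_line <- function(serial, atom, resname, chain, resid, xyz, element) {
  # PDB columns: left-justify 4-char atom names that start in column 14
  aname <- if (nchar(atom) < 4L) sprintf(" %-3s", atom) else substr(atom, 1, 4)
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, aname, substr(resname, 1, 3), substr(chain, 1, 1),
          resid %% 10000L, xyz[1], xyz[2], xyz[3], 1, 0, element)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Frames become MODEL/ENDMDL blocks; solvent atoms are written like any
#' other atom.
#'
#' @param traj an `idp_trajectory` (or a single `idp_structure`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path) {
  if (inherits(traj, "idp_structure")) {
    traj <- idp_trajectory(list(traj$coords), traj$topology)
  }
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- traj$frames[[m]]
    lines <- character(nrow(top))
    for (k in seq_len(nrow(top))) {
      lines[k] <- .pdb_atom_line(k, top$atom[k], top$resname[k], top$chain[k],
                                 top$resid[k], xyz[k, ], top$element[k])
    }
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB file as a trajectory
#'
#' @param path PDB file path.
#' @param solvent_resnames residue names flagged as solvent
#'   (default `c("HOH", "SOL", "WAT", "TIP")`).
#' @return An `idp_trajectory`.
#' @export
read_pdb_trajectory <- function(path, solvent_resnames = c("HOH", "SOL", "WAT", "TIP")) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  model_idx <- cumsum(startsWith(lines, "MODEL"))
  if (max(model_idx) == 0L) model_idx <- rep(1L, length(lines))
  atoms <- lines[is_atom]
  if (!length(atoms)) stop("no ATOM records in ", path)
  frame_of <- model_idx[is_atom]
  frame_of <- frame_of - min(frame_of) + 1L
  parse_block <- function(block) {
    n <- length(block)
    coords <- matrix(NA_real_, n, 3)
    coords[, 1] <- as.numeric(substr(block, 31, 38))
    coords[, 2] <- as.numeric(substr(block, 39, 46))
    coords[, 3] <- as.numeric(substr(block, 47, 54))
    list(
      coords = coords,
      atom = trimws(substr(block, 13, 16)),
      resname = trimws(substr(block, 18, 20)),
      chain = substr(block, 22, 22),
      resid = as.integer(substr(block, 23, 26)),
      element = trimws(substr(block, 77, 78))
    )
  }
  first <- parse_block(atoms[frame_of == 1L])
  element <- first$element
  blank <- element == ""
  if (any(blank)) element[blank] <- substr(gsub("[0-9']", "", first$atom[blank]), 1, 1)
  topology <- data.frame(
    chain = first$chain, resid = first$resid, resname = first$resname,
    atom = first$atom, element = element,
    solvent = first$resname %in% solvent_resnames,
    stringsAsFactors = FALSE
  )
  frames <- lapply(sort(unique(frame_of)), function(m) {
    parse_block(atoms[frame_of == m])$coords
  })
  idp_trajectory(frames, topology)
}

# Topology for an all-backbone polypeptide chain built by the generators:
# atoms N, (H for residues >= 2), CA, C, O per residue.
.backbone_topology <- function(n_res, chain_id, resname = "ALA") {
  rows <- list()
  for (i in seq_len(n_res)) {
    atoms <- if (i == 1L) c("N", "CA", "C", "O") else c("N", "H", "CA", "C", "O")
    elements <- substr(atoms, 1, 1)
    rows[[i]] <- data.frame(chain = chain_id, resid = i, resname = resname,
                            atom = atoms, element = elements, solvent = FALSE,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
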