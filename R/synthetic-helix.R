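# Synthetic helix and helix-coil trajectory generators.
#
# Chains are built from ideal internal coordinates (trans peptide, standard
# bond lengths and angles) by sequential natural-extension placement, so a
# chain is fully specified by its per-residue (phi, psi) dihedrals.  Helical
# residues use the canonical alpha-helix (phi = -57, psi = -47); coil
# residues draw dihedrals from the broad beta/PPII basin
# (phi in [-180, -60], psi in [60, 180]) which guarantees they never form
# the i -> i+4 hydrogen-bond pattern the helicity detector looks for.

.BOND <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.01)
.ANGLE <- list(c_n_ca = 121.7, n_ca_c = 110.0, ca_c_n = 116.2, ca_c_o = 120.8)

# Build one chain from per-residue dihedrals.  phi[1] and the placement of
# the first residue are conventional (no preceding peptide unit).  Returns a
# (5n - 1) x 3 coordinate matrix matching .backbone_topology() order.
.build_backbone <- function(phi, psi, omega = 180) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2L)
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N; H <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BOND$n_ca, 0, 0)
  ang <- .ANGLE$n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + .BOND$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in 2:n) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         .BOND$c_n, .ANGLE$ca_c_n, psi[i - 1])
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                          .BOND$n_ca, .ANGLE$c_n_ca, omega)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                         .BOND$ca_c, .ANGLE$n_ca_c, phi[i])
    # amide H on the bisector of C(i-1)-N(i)-CA(i), pointing outward
    bis <- .unit(.unit(C[i - 1, ] - N[i, ]) + .unit(CA[i, ] - N[i, ]))
    H[i, ] <- N[i, ] - .BOND$n_h * bis
  }
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         .BOND$c_o, .ANGLE$ca_c_o, psi[i] + 180)
  }
  coords <- matrix(NA_real_, 5L * n - 1L, 3)
  k <- 1L
  for (i in seq_len(n)) {
    if (i == 1L) {
      coords[k:(k + 3L), ] <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ]); k <- k + 4L
    } else {
      coords[k:(k + 4L), ] <- rbind(N[i, ], H[i, ], CA[i, ], C[i, ], O[i, ]); k <- k + 5L
    }
  }
  coords
}

#' Generate an ideal alpha-helix backbone
#'
#' Builds the backbone (N, H, CA, C, O; no amide H on residue 1) of a
#' canonical alpha-helix with phi = -57 deg, psi = -47 deg, standard bond
#' geometry, ~1.5 Angstrom rise and ~100 deg twist per residue.  The output
#' is deterministic.
#'
#' @param n_res number of residues (>= 5).
#' @param chain_id single-character chain label (default "A").
#' @return An [idp_structure()].
#' @export
#' @examples
#' helix <- make_ideal_helix(18)
make_ideal_helix <- function(n_res, chain_id = "A") {
  if (!is.numeric(n_res) || n_res < 5) stop("`n_res` must be >= 5")
  n_res <- as.integer(n_res)
  coords <- .build_backbone(rep(-57, n_res), rep(-47, n_res))
  idp_structure(coords, .backbone_topology(n_res, chain_id))
}

#' Parameters for the helix-coil unraveling trajectory generator
#'
#' Defines the stated world of a progressively unfolding helical protein:
#' at each frame the outermost helical residue at each chain terminus
#' converts to coil with probability `unravel_rate`, never eroding into the
#' protected `core_span`.
#'
#' @param n_res residues per chain.
#' @param n_frames number of frames.
#' @param n_chains 1 (monomer) or 2 (antiparallel dimer).
#' @param unravel_rate per-frame, per-terminus erosion probability in `[0, 1]`.
#' @param core_span integer pair: residue interval guaranteed helical.
#' @param seed mandatory RNG seed; identical inputs give bit-identical output.
#' @param axial_separation inter-axis distance (Angstrom) of the two chains
#'   in the dimer arrangement (default 10).
#' @param n_waters optional count of randomly placed water molecules per
#'   frame (default 0), used to exercise protein-water hydrogen-bond
#'   statistics.
#' @return A validated parameter list of class `helix_coil_params`.
#' @export
helix_coil_params <- function(n_res, n_frames, n_chains = 1, unravel_rate = 0.1,
                              core_span = NULL, seed = 1L,
                              axial_separation = 10, n_waters = 0) {
  if (n_res < 5) stop("`n_res` must be >= 5")
  if (!n_chains %in% c(1, 2)) stop("`n_chains` must be 1 or 2")
  if (unravel_rate < 0 || unravel_rate > 1) stop("`unravel_rate` must be in [0, 1]")
  if (is.null(core_span)) {
    core_span <- c(max(1L, floor(n_res / 2) - 5L), min(n_res, floor(n_res / 2) + 5L))
  }
  core_span <- as.integer(core_span)
  if (length(core_span) != 2L || core_span[1] < 1L || core_span[2] > n_res ||
      core_span[1] > core_span[2]) {
    stop("`core_span` must be an increasing pair within [1, n_res]")
  }
  structure(list(n_res = as.integer(n_res), n_frames = as.integer(n_frames),
                 n_chains = as.integer(n_chains), unravel_rate = unravel_rate,
                 core_span = core_span, seed = as.integer(seed),
                 axial_separation = axial_separation,
                 n_waters = as.integer(n_waters)),
            class = "helix_coil_params")
}

# Rotate/translate a chain so its CA principal axis lies along `direction`
# (+1 => +z, -1 => -z) and its centroid sits at `offset`.
.orient_chain <- function(coords, ca_idx, direction, offset) {
  ctr <- colMeans(coords[ca_idx, , drop = FALSE])
  centered <- sweep(coords, 2, ctr)
  ca <- centered[ca_idx, , drop = FALSE]
  ax <- svd(ca, nu = 0, nv = 1)$v[, 1]
  ends <- ca[nrow(ca), ] - ca[1, ]
  if (sum(ax * ends) < 0) ax <- -ax
  R <- .rotation_between(ax, c(0, 0, direction))
  sweep(centered %*% t(R), 2, offset, `+`)
}

#' Generate a stochastically unraveling helix-coil trajectory
#'
#' Each chain starts as a full helix; at every frame the helical segment
#' shrinks from both termini toward `core_span` with per-frame probability
#' `unravel_rate`.  Coil residues receive dihedrals redrawn every frame from
#' the beta/PPII basin.  For dimers the two chains are arranged antiparallel
#' at `axial_separation` Angstrom.  The per-residue, per-frame helical
#' ground truth is attached as attribute `helix_truth` (list of
#' n_res x n_frames indicator matrices, one per chain).
#'
#' @param params a [helix_coil_params()] object.
#' @return An [idp_trajectory()] with ground-truth attributes.
#' @export
make_helix_coil_trajectory <- function(params) {
  stopifnot(inherits(params, "helix_coil_params"))
  p <- params
  with_seed(p$seed, {
    chains <- LETTERS[seq_len(p$n_chains)]
    # erosion state per chain: residues 1..eL and (n-eR+1)..n are coil
    eL <- integer(p$n_chains)
    eR <- integer(p$n_chains)
    eL_max <- p$core_span[1] - 1L
    eR_max <- p$n_res - p$core_span[2]
    truth <- lapply(seq_len(p$n_chains),
                    function(.) matrix(NA, p$n_res, p$n_frames))
    top <- do.call(rbind, lapply(chains, function(ch) .backbone_topology(p$n_res, ch)))
    if (p$n_waters > 0L) {
      wtop <- do.call(rbind, lapply(seq_len(p$n_waters), function(w) {
        data.frame(chain = "W", resid = w, resname = "HOH",
                   atom = c("OW", "HW1", "HW2"), element = c("O", "H", "H"),
                   solvent = TRUE, stringsAsFactors = FALSE)
      }))
      top <- rbind(top, wtop)
    }
    frames <- vector("list", p$n_frames)
    for (f in seq_len(p$n_frames)) {
      if (f > 1L) {
        for (ch in seq_len(p$n_chains)) {
          if (eL[ch] < eL_max && stats::runif(1) < p$unravel_rate) eL[ch] <- eL[ch] + 1L
          if (eR[ch] < eR_max && stats::runif(1) < p$unravel_rate) eR[ch] <- eR[ch] + 1L
        }
      }
      chain_coords <- vector("list", p$n_chains)
      for (ch in seq_len(p$n_chains)) {
        helical <- rep(TRUE, p$n_res)
        if (eL[ch] > 0L) helical[seq_len(eL[ch])] <- FALSE
        if (eR[ch] > 0L) helical[(p$n_res - eR[ch] + 1L):p$n_res] <- FALSE
        truth[[ch]][, f] <- helical
        phi <- ifelse(helical, -57, stats::runif(p$n_res, -180, -60))
        psi <- ifelse(helical, -47, stats::runif(p$n_res, 60, 180))
        xyz <- .build_backbone(phi, psi)
        ca_idx <- which(.backbone_topology(p$n_res, "A")$atom == "CA")
        if (p$n_chains == 2L) {
          dirn <- if (ch == 1L) 1 else -1
          off <- c((ch - 1L) * p$axial_separation, 0, 0)
          xyz <- .orient_chain(xyz, ca_idx, dirn, off)
        }
        chain_coords[[ch]] <- xyz
      }
      xyz <- do.call(rbind, chain_coords)
      if (p$n_waters > 0L) {
        lo <- apply(xyz, 2, min) - 6
        hi <- apply(xyz, 2, max) + 6
        wat <- matrix(NA_real_, 3L * p$n_waters, 3)
        for (w in seq_len(p$n_waters)) {
          o <- stats::runif(3, lo, hi)
          d1 <- .unit(stats::rnorm(3))
          d2raw <- stats::rnorm(3)
          d2 <- .unit(d2raw - sum(d2raw * d1) * d1)
          # H-O-H angle 104.5 deg, O-H 0.96 A
          h2 <- cos(104.5 * pi / 180) * d1 + sin(104.5 * pi / 180) * d2
          wat[(3 * w - 2):(3 * w), ] <- rbind(o, o + 0.96 * d1, o + 0.96 * h2)
        }
        xyz <- rbind(xyz, wat)
      }
      frames[[f]] <- xyz
    }
    traj <- idp_trajectory(frames, top)
    attr(traj, "helix_truth") <- truth
    attr(traj, "params") <- p
    traj
  })
}
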