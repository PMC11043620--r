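# Structural statistics over trajectories: superposition/RMSD, hydrogen
# bonds, contact maps, helicity timelines, backbone orientational
# correlation and hydrophobic moments.

#' Hydrogen-bond geometric criteria
#'
#' Donor-acceptor heavy-atom distance cutoff and donor-H-acceptor angle
#' threshold.  The angle criterion is strict (`> min_angle`).
#'
#' @param max_donor_acceptor_distance Angstrom (default 3.5).
#' @param min_angle degrees (default 120).
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_donor_acceptor_distance = 3.5, min_angle = 120) {
  if (max_donor_acceptor_distance <= 0) stop("distance cutoff must be > 0")
  if (min_angle <= 0 || min_angle >= 180) stop("angle must be in (0, 180)")
  structure(list(max_donor_acceptor_distance = max_donor_acceptor_distance,
                 min_angle = min_angle), class = "hbond_criteria")
}

# ---------------------------------------------------------------------------
# Superposition

#' Optimal rigid-body superposition (Kabsch) and RMSD
#'
#' Least-squares superposition of `mobile` onto `reference` over the atoms
#' named in `atom_selection`, using the Kabsch singular-value-decomposition
#' algorithm with a reflection guard (the returned rotation always has
#' determinant +1).  The RMSD is the global minimum over rigid transforms.
#'
#' @param mobile,reference `idp_structure` objects with matching selections.
#' @param atom_selection character vector of atom names (default backbone
#'   `c("N", "CA", "C", "O")`).
#' @return list with `rotation` (3x3), `translation` (length 3; the
#'   transform is `x %*% t(rotation) + translation`), `rmsd` (Angstrom) and
#'   `transformed` (the superposed mobile selection coordinates).
#' @export
kabsch_superpose <- function(mobile, reference,
                             atom_selection = c("N", "CA", "C", "O")) {
  sel_m <- mobile$topology$atom %in% atom_selection & !mobile$topology$solvent
  sel_r <- reference$topology$atom %in% atom_selection & !reference$topology$solvent
  X <- mobile$coords[sel_m, , drop = FALSE]
  Y <- reference$coords[sel_r, , drop = FALSE]
  if (nrow(X) != nrow(Y)) stop("selections do not match between structures")
  if (nrow(X) < 3L) stop("need at least 3 atoms to superpose")
  if (qr(sweep(X, 2, colMeans(X)))$rank < 2L) stop("selected atoms are collinear")
  xc <- colMeans(X); yc <- colMeans(Y)
  X0 <- sweep(X, 2, xc); Y0 <- sweep(Y, 2, yc)
  s <- svd(crossprod(X0, Y0))          # X0^T Y0 = U D V^T
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Xr <- X0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((Xr - Y0)^2)))
  list(rotation = R, translation = as.numeric(yc - xc %*% t(R)),
       rmsd = rmsd, transformed = sweep(Xr, 2, yc, `+`))
}

#' Per-frame backbone RMSD relative to a reference structure
#'
#' Every frame is superposed independently onto the reference over the
#' backbone atoms (N, CA, C, O) before the RMSD is evaluated.
#'
#' @param traj an `idp_trajectory`.
#' @param reference an `idp_structure` with matching topology.
#' @param atom_selection atom names used for fitting and RMSD.
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_timeseries <- function(traj, reference,
                            atom_selection = c("N", "CA", "C", "O")) {
  vapply(seq_along(traj$frames), function(f) {
    kabsch_superpose(trajectory_frame(traj, f), reference, atom_selection)$rmsd
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Hydrogen bonds

# Donor table: N/O heavy atoms with an attached hydrogen (same residue,
# within 1.2 A).  Returns data.frame(donor, hydrogen) of atom row indices.
.find_donors <- function(struct) {
  top <- struct$topology
  xyz <- struct$coords
  heavy <- which(top$element %in% c("N", "O"))
  hyd <- which(top$element == "H")
  out <- list()
  if (length(hyd)) {
    key <- paste(top$chain, top$resid)
    for (h in hyd) {
      cand <- heavy[key[heavy] == key[h]]
      if (!length(cand)) next
      d2 <- rowSums((xyz[cand, , drop = FALSE] -
                       matrix(xyz[h, ], length(cand), 3, byrow = TRUE))^2)
      j <- cand[which.min(d2)]
      if (min(d2) <= 1.2^2) out[[length(out) + 1L]] <- c(donor = j, hydrogen = h)
    }
  }
  if (!length(out)) return(data.frame(donor = integer(), hydrogen = integer()))
  as.data.frame(do.call(rbind, out))
}

#' Detect hydrogen bonds in a single frame
#'
#' All and only donor/hydrogen/acceptor triplets satisfying the geometric
#' criteria: donor-acceptor distance at most the cutoff and donor-H-acceptor
#' angle strictly greater than the threshold.  Donors are N/O heavy atoms
#' carrying a hydrogen; acceptors are N/O heavy atoms.  Pairs within the
#' same residue are excluded.
#'
#' @param frame an `idp_structure`.
#' @param criteria an [hbond_criteria()] object.
#' @return data.frame with atom indices `donor`, `hydrogen`, `acceptor`,
#'   the donor-acceptor `distance` (Angstrom), the `angle` (degrees), and
#'   logical `donor_solvent` / `acceptor_solvent` flags.
#' @export
detect_hbonds <- function(frame, criteria = hbond_criteria()) {
  top <- frame$topology
  xyz <- frame$coords
  donors <- .find_donors(frame)
  if (any(top$element %in% c("N", "O")) && !nrow(donors) &&
      !any(top$element == "H")) {
    stop("no hydrogens in topology; place them first with place_amide_hydrogens()")
  }
  acceptors <- which(top$element %in% c("N", "O"))
  key <- paste(top$chain, top$resid)
  res <- list()
  cutoff2 <- criteria$max_donor_acceptor_distance^2
  for (k in seq_len(nrow(donors))) {
    d_i <- donors$donor[k]; h_i <- donors$hydrogen[k]
    acc <- acceptors[key[acceptors] != key[d_i]]
    if (!length(acc)) next
    dv <- xyz[acc, , drop = FALSE] - matrix(xyz[d_i, ], length(acc), 3, byrow = TRUE)
    d2 <- rowSums(dv^2)
    near <- which(d2 <= cutoff2)
    for (a in acc[near]) {
      u <- xyz[d_i, ] - xyz[h_i, ]
      v <- xyz[a, ] - xyz[h_i, ]
      ang <- acos(max(-1, min(1, sum(u * v) / (.norm(u) * .norm(v))))) * 180 / pi
      if (ang > criteria$min_angle) {
        res[[length(res) + 1L]] <- data.frame(
          donor = d_i, hydrogen = h_i, acceptor = a,
          distance = sqrt(sum((xyz[a, ] - xyz[d_i, ])^2)), angle = ang,
          donor_solvent = top$solvent[d_i], acceptor_solvent = top$solvent[a])
      }
    }
  }
  if (!length(res)) {
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric(), donor_solvent = logical(),
                      acceptor_solvent = logical()))
  }
  do.call(rbind, res)
}

#' Geometric amide hydrogen placement
#'
#' Adds missing backbone amide hydrogens at 1.01 Angstrom on the outward
#' bisector of the C(i-1)-N(i)-CA(i) angle (residue 1 of each chain has no
#' preceding carbonyl and receives none).  Useful for PDB input lacking
#' hydrogens.
#'
#' @param struct an `idp_structure`.
#' @return A new `idp_structure` including H atoms.
#' @export
place_amide_hydrogens <- function(struct) {
  top <- struct$topology
  xyz <- struct$coords
  chains <- unique(top$chain[!top$solvent])
  add_rows <- list(); add_xyz <- list()
  for (ch in chains) {
    resids <- sort(unique(top$resid[top$chain == ch & !top$solvent]))
    for (i in resids[-1]) {
      sel <- function(rid, at) which(top$chain == ch & top$resid == rid & top$atom == at)
      if (length(sel(i, "H"))) next
      nN <- sel(i, "N"); nCA <- sel(i, "CA"); nCp <- sel(i - 1L, "C")
      if (!length(nN) || !length(nCA) || !length(nCp)) next
      bis <- .unit(.unit(xyz[nCp, ] - xyz[nN, ]) + .unit(xyz[nCA, ] - xyz[nN, ]))
      add_rows[[length(add_rows) + 1L]] <- data.frame(
        chain = ch, resid = i, resname = top$resname[nN], atom = "H",
        element = "H", solvent = FALSE, stringsAsFactors = FALSE)
      add_xyz[[length(add_xyz) + 1L]] <- xyz[nN, ] - 1.01 * bis
    }
  }
  if (!length(add_rows)) return(struct)
  top2 <- rbind(top, do.call(rbind, add_rows))
  xyz2 <- rbind(xyz, do.call(rbind, add_xyz))
  ord <- order(match(top2$chain, unique(top2$chain)), top2$resid)
  idp_structure(xyz2[ord, , drop = FALSE], top2[ord, , drop = FALSE])
}

#' Per-frame hydrogen-bond counts split by partner class
#'
#' Counts hydrogen bonds per frame and partitions them into protein-protein
#' (neither partner flagged solvent) and protein-water (exactly one partner
#' flagged solvent).  Water-water bonds are reported separately so the two
#' published series plus `water_water` always sum to the total.
#'
#' @param traj an `idp_trajectory` whose topology carries a solvent flag.
#' @param criteria an [hbond_criteria()] object.
#' @return data.frame with columns `frame`, `protein_protein`,
#'   `protein_water`, `water_water`, `total`.
#' @export
hbond_timeseries <- function(traj, criteria = hbond_criteria()) {
  out <- lapply(seq_along(traj$frames), function(f) {
    hb <- detect_hbonds(trajectory_frame(traj, f), criteria)
    n_solv <- hb$donor_solvent + hb$acceptor_solvent
    data.frame(frame = f,
               protein_protein = sum(n_solv == 0L),
               protein_water = sum(n_solv == 1L),
               water_water = sum(n_solv == 2L),
               total = nrow(hb))
  })
  do.call(rbind, out)
}

# ---------------------------------------------------------------------------
# Contact maps

# residue table of a topology: one row per (chain, resid), heavy non-solvent
.residue_index <- function(top) {
  keep <- !top$solvent
  key <- paste(top$chain[keep], top$resid[keep])
  u <- !duplicated(key)
  data.frame(chain = top$chain[keep][u], resid = top$resid[keep][u],
             stringsAsFactors = FALSE)
}

#' Residue-residue contact probability map
#'
#' P(i, j) is the fraction of pooled frames -- all replicate trajectories
#' with equal weight -- in which the minimum heavy-atom distance between
#' residues i and j is at most `cutoff`.  Pairs are labeled `intra` (same
#' chain) or `inter` (different chains).  Solvent and hydrogens are ignored.
#'
#' @param trajs a single `idp_trajectory` or a list of replicates sharing
#'   one topology.
#' @param cutoff Angstrom (default 3.5, the length of a hydrogen bond).
#' @return A list of class `contact_map`: `probability` (symmetric matrix,
#'   diagonal `NA`), `residues` (chain/resid table), `interchain` (logical
#'   matrix), `cutoff`, `n_frames`.
#' @export
contact_probability_map <- function(trajs, cutoff = 3.5) {
  if (inherits(trajs, "idp_trajectory")) trajs <- list(trajs)
  if (!length(trajs)) stop("empty trajectory list")
  top <- trajs[[1L]]$topology
  heavy <- which(!top$solvent & top$element != "H")
  res <- .residue_index(top)
  n_res <- nrow(res)
  res_key <- paste(res$chain, res$resid)
  atom_res <- match(paste(top$chain[heavy], top$resid[heavy]), res_key)
  counts <- matrix(0, n_res, n_res)
  total <- 0L
  for (traj in trajs) {
    if (nrow(traj$topology) != nrow(top)) stop("replicates must share topology")
    for (f in seq_along(traj$frames)) {
      xyz <- traj$frames[[f]][heavy, , drop = FALSE]
      D <- as.matrix(stats::dist(xyz))
      hit <- which(D <= cutoff & upper.tri(D), arr.ind = TRUE)
      if (nrow(hit)) {
        pr <- unique(cbind(atom_res[hit[, 1]], atom_res[hit[, 2]]))
        pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
        if (nrow(pr)) {
          idx <- cbind(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
          idx <- unique(idx)
          counts[idx] <- counts[idx] + 1
        }
      }
      total <- total + 1L
    }
  }
  P <- counts / total
  P <- P + t(P)
  diag(P) <- NA_real_
  inter <- outer(res$chain, res$chain, `!=`)
  structure(list(probability = P, residues = res, interchain = inter,
                 cutoff = cutoff, n_frames = total),
            class = "contact_map")
}

#' Most persistent non-adjacent contacts
#'
#' Returns all residue pairs with contact probability at or above
#' `threshold`, sorted by probability (descending; ties broken by ascending
#' indices).  Sequence-adjacent pairs (|i - j| <= 2 within one chain) are
#' excluded.
#'
#' @param map a [contact_probability_map()] result.
#' @param threshold probability threshold (default 0.75).
#' @return data.frame with chain/resid of both partners, `probability` and
#'   `label` ("intra" or "inter").
#' @export
top_contacts <- function(map, threshold = 0.75) {
  stopifnot(inherits(map, "contact_map"))
  P <- map$probability
  res <- map$residues
  n <- nrow(res)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (is.na(P[i, j]) || P[i, j] < threshold) next
      same <- res$chain[i] == res$chain[j]
      if (same && abs(res$resid[i] - res$resid[j]) <= 2L) next
      out[[length(out) + 1L]] <- data.frame(
        chain_i = res$chain[i], resid_i = res$resid[i],
        chain_j = res$chain[j], resid_j = res$resid[j],
        probability = P[i, j], label = if (same) "intra" else "inter",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chain_i = character(), resid_i = integer(),
                      chain_j = character(), resid_j = integer(),
                      probability = numeric(), label = character()))
  }
  tab <- do.call(rbind, out)
  tab[order(-tab$probability, tab$resid_i, tab$resid_j), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# Helicity

# i -> i+4 backbone H-bond indicator per residue for one chain in one frame
.helix_bonds_chain <- function(xyz, top, chain, criteria) {
  sel <- top$chain == chain & !top$solvent
  resids <- sort(unique(top$resid[sel]))
  n <- length(resids)
  bond <- rep(FALSE, n)
  if (n < 5L) return(bond)
  get1 <- function(rid, at) {
    k <- which(sel & top$resid == rid & top$atom == at)
    if (length(k)) xyz[k[1L], ] else NULL
  }
  for (ii in seq_len(n - 4L)) {
    O <- get1(resids[ii], "O")
    N <- get1(resids[ii + 4L], "N")
    H <- get1(resids[ii + 4L], "H")
    if (is.null(O) || is.null(N) || is.null(H)) next
    if (sum((N - O)^2) > criteria$max_donor_acceptor_distance^2) next
    u <- N - H; v <- O - H
    ang <- acos(max(-1, min(1, sum(u * v) / (.norm(u) * .norm(v))))) * 180 / pi
    bond[ii] <- ang > criteria$min_angle
  }
  bond
}

#' Helix/coil assignment from the i -> i+4 hydrogen-bond pattern
#'
#' A helical turn starts at residue i when the backbone O(i)...H-N(i+4)
#' hydrogen bond satisfies the criteria; following the alpha-helix
#' convention of DSSP, two consecutive turns (at i-1 and i) mark the
#' donor-side residues i..i+3 as helical.  Marking the spanned donor-side
#' residues (rather than the turn-start acceptor residue) keeps the
#' helical set inside a rigid helical core: the carbonyl O of residue i is
#' rigid in the i/i+1 peptide plane, so the turn at core_start-1 exists
#' whenever the core itself is helical.  The result is the helix/coil
#' dichotomy (3-10/pi/turn/bridge classes are not distinguished).
#'
#' @param traj an `idp_trajectory`.
#' @param criteria an [hbond_criteria()] object.
#' @return A list of class `helicity_timeline`: `indicator` (residues x
#'   frames logical matrix over all chains stacked), `residues`, per-frame
#'   `helix_fraction` and `coil_fraction`, and per-residue mean `ratio`.
#' @export
assign_helicity <- function(traj, criteria = hbond_criteria()) {
  top <- traj$topology
  chains <- unique(top$chain[!top$solvent])
  res <- .residue_index(top)
  nf <- length(traj$frames)
  ind <- matrix(FALSE, nrow(res), nf)
  for (ch in chains) {
    rows <- which(res$chain == ch)
    if (length(rows) < 5L) {
      warning(sprintf("chain %s shorter than 5 residues: assigned all-coil", ch))
      next
    }
    for (f in seq_len(nf)) {
      turn <- .helix_bonds_chain(traj$frames[[f]], top, ch, criteria)
      n <- length(turn)
      helical <- rep(FALSE, n)
      for (i in which(turn[-1L] & turn[-n]) + 1L) {
        helical[i:min(n, i + 3L)] <- TRUE
      }
      ind[rows, f] <- helical
    }
  }
  helix_fraction <- colMeans(ind)
  structure(list(indicator = ind, residues = res,
                 helix_fraction = helix_fraction,
                 coil_fraction = 1 - helix_fraction,
                 ratio = rowMeans(ind)),
            class = "helicity_timeline")
}

# ---------------------------------------------------------------------------
# Orientational correlation

#' Backbone orientational correlation matrix
#'
#' Entry (i, j) is |< v_i . v_j >| where v_i is the per-frame normalized
#' vector from CA(i) to CA(i+1) and the average runs over frames.  Vectors
#' never span a chain boundary.  Randomly oriented (or constantly
#' orthogonal) vector pairs average to zero; rigid parallel segments give 1.
#'
#' @param traj an `idp_trajectory` with CA atoms.
#' @return A list of class `orientational_correlation`: `matrix` (absolute
#'   mean dot products, diagonal 1), `vectors` (chain/start-residue table).
#' @export
orientational_correlation <- function(traj) {
  top <- traj$topology
  chains <- unique(top$chain[!top$solvent])
  vec_rows <- list()
  for (ch in chains) {
    ca <- which(top$chain == ch & top$atom == "CA" & !top$solvent)
    if (length(ca) >= 2L) {
      vec_rows[[ch]] <- data.frame(chain = ch, from = ca[-length(ca)],
                                   to = ca[-1L],
                                   resid = top$resid[ca][-length(ca)],
                                   stringsAsFactors = FALSE)
    }
  }
  if (!length(vec_rows)) {
    return(structure(list(matrix = matrix(numeric(0), 0, 0),
                          vectors = data.frame()),
                     class = "orientational_correlation"))
  }
  vecs <- do.call(rbind, vec_rows)
  m <- nrow(vecs)
  acc <- matrix(0, m, m)
  for (f in seq_along(traj$frames)) {
    xyz <- traj$frames[[f]]
    V <- xyz[vecs$to, , drop = FALSE] - xyz[vecs$from, , drop = FALSE]
    V <- V / sqrt(rowSums(V^2))
    acc <- acc + tcrossprod(V)
  }
  M <- abs(acc / length(traj$frames))
  diag(M) <- 1
  structure(list(matrix = M, vectors = vecs[, c("chain", "resid")]),
            class = "orientational_correlation")
}

# ---------------------------------------------------------------------------
# Hydrophobic moment

# Eisenberg consensus hydrophobicity scale
.EISENBERG <- c(A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29,
                Q = -0.85, E = -0.74, G = 0.48, H = -0.40, I = 1.38,
                L = 1.06, K = -1.50, M = 0.64, F = 1.19, P = 0.12,
                S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08)

#' Helical-wheel hydrophobic moment
#'
#' Eisenberg consensus-scale vector sum over a helical-wheel projection
#' with angular step `periodicity` (default 100 degrees, the alpha-helix
#' twist).  The magnitude is normalized per residue.  When `window` is
#' smaller than the sequence, every window position is evaluated and the
#' maximum-magnitude window is reported.
#'
#' @param sequence one-letter residue string (standard 20 amino acids).
#' @param window window length (default: whole sequence).
#' @param periodicity degrees per residue (default 100).
#' @return list with `magnitude` (mean-vector length per residue),
#'   `direction` (degrees), `window_start`, and `per_window` data.frame.
#' @export
hydrophobic_moment <- function(sequence, window = NULL, periodicity = 100) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  unknown <- setdiff(unique(aa), names(.EISENBERG))
  if (length(unknown)) stop("unknown residue code(s): ", paste(unknown, collapse = ", "))
  h <- .EISENBERG[aa]
  n <- length(h)
  if (is.null(window)) window <- n
  if (window < 1L || window > n) stop("`window` must be in [1, sequence length]")
  delta <- periodicity * pi / 180
  starts <- seq_len(n - window + 1L)
  mags <- numeric(length(starts)); dirs <- numeric(length(starts))
  for (s in starts) {
    k <- seq(s, s + window - 1L)
    ang <- (k - 1L) * delta
    sx <- sum(h[k] * cos(ang)); sy <- sum(h[k] * sin(ang))
    mags[s] <- sqrt(sx^2 + sy^2) / window
    dirs[s] <- atan2(sy, sx) * 180 / pi
  }
  best <- which.max(mags)
  list(magnitude = mags[best], direction = dirs[best],
       window_start = starts[best],
       per_window = data.frame(start = starts, magnitude = mags,
                               direction = dirs))
}

# ---------------------------------------------------------------------------
# Formal charge / counterions

#' Formal net charge of a peptide at neutral pH
#'
#' Counts Asp/Glu as -1, Lys/Arg as +1, His as 0; free termini contribute
#' +1 and -1 and therefore cancel (included for completeness via
#' `termini`).
#'
#' @param sequence one-letter residue string.
#' @param termini include free N-/C-terminal charges (default TRUE; they
#'   cancel).
#' @return integer net formal charge.
#' @export
peptide_net_charge <- function(sequence, termini = TRUE) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  chg <- sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E"))
  if (termini) chg <- chg + 1L - 1L
  as.integer(chg)
}

#' Read a single-record FASTA sequence
#'
#' @param path FASTA file with one sequence record.
#' @return the sequence as a single uppercase string.
#' @export
read_fasta_sequence <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, ">") & nzchar(trimws(lines))]
  if (!length(body)) stop("no sequence data in ", path)
  toupper(paste(trimws(body), collapse = ""))
}

#' Neutralizing counterion count for a simulation box
#'
#' Number of monovalent counterions (sodium for a net-negative chain,
#' chloride for net-positive) needed to neutralize `n_copies` of the chain.
#'
#' @param sequence one-letter residue string.
#' @param n_copies number of chains in the box (default 1).
#' @return list with `ion` ("Na+", "Cl-" or "none") and `count`.
#' @export
counterions_needed <- function(sequence, n_copies = 1L) {
  q <- peptide_net_charge(sequence) * n_copies
  list(ion = if (q < 0) "Na+" else if (q > 0) "Cl-" else "none",
       count = abs(q))
}
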