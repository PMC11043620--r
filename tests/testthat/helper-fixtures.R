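# Shared fixture builders and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

# independent brute-force H-bond scan over backbone N-H donors / O acceptors
brute_force_backbone_hbonds <- function(struct, cutoff = 3.5, min_angle = 120) {
  top <- struct$topology
  xyz <- struct$coords
  hits <- 0L
  for (ch in unique(top$chain)) {
    res <- sort(unique(top$resid[top$chain == ch]))
    at <- function(rid, a) {
      k <- which(top$chain == ch & top$resid == rid & top$atom == a)
      if (length(k)) xyz[k, ] else NULL
    }
    for (i in res) for (j in res) {
      if (i == j) next
      O <- at(i, "O"); N <- at(j, "N"); H <- at(j, "H")
      if (is.null(O) || is.null(N) || is.null(H)) next
      if (sqrt(sum((N - O)^2)) > cutoff) next
      u <- N - H; v <- O - H
      ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
      if (ang > min_angle) hits <- hits + 1L
    }
  }
  hits
}

# quaternion (Horn) closed-form minimal RMSD: an oracle independent of the
# Kabsch SVD route
quaternion_rmsd <- function(X, Y) {
  X0 <- sweep(X, 2, colMeans(X))
  Y0 <- sweep(Y, 2, colMeans(Y))
  M <- crossprod(X0, Y0)
  K <- matrix(0, 4, 4)
  K[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  K[1, 2] <- K[2, 1] <- M[2, 3] - M[3, 2]
  K[1, 3] <- K[3, 1] <- M[3, 1] - M[1, 3]
  K[1, 4] <- K[4, 1] <- M[1, 2] - M[2, 1]
  K[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  K[2, 3] <- K[3, 2] <- M[1, 2] + M[2, 1]
  K[2, 4] <- K[4, 2] <- M[3, 1] + M[1, 3]
  K[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  K[3, 4] <- K[4, 3] <- M[2, 3] + M[3, 2]
  K[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lambda <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(X0^2) + sum(Y0^2) - 2 * lambda) / nrow(X)
  sqrt(max(msd, 0))
}

# tiny two-residue "dumbbell" structure for contact/H-bond edge cases:
# two single-atom residues at a fixed separation
two_point_structure <- function(separation, chain2 = "A") {
  top <- data.frame(chain = c("A", chain2), resid = c(1L, 2L),
                    resname = "GLY", atom = "CA", element = "C",
                    solvent = FALSE, stringsAsFactors = FALSE)
  idp_structure(rbind(c(0, 0, 0), c(separation, 0, 0)), top)
}

# hand-built donor/H/acceptor triple at prescribed distance and D-H-A angle
hbond_probe <- function(distance, angle_deg) {
  # donor N at origin, H along +x at 1.0 A; acceptor placed so that the
  # angle at H between donor and acceptor equals angle_deg and |D-A| is the
  # requested distance (solved in the xy-plane).
  Hp <- c(1, 0, 0)
  th <- angle_deg * pi / 180
  dir <- c(cos(pi - th), sin(pi - th), 0)   # from H, at angle th to H->D
  f <- function(r) sqrt(sum((Hp + r * dir)^2)) - distance
  r <- stats::uniroot(f, c(1e-6, distance + 2))$root
  A <- Hp + r * dir
  top <- data.frame(chain = c("A", "A", "A"), resid = c(1L, 1L, 2L),
                    resname = "GLY", atom = c("N", "H", "O"),
                    element = c("N", "H", "O"), solvent = FALSE,
                    stringsAsFactors = FALSE)
  idp_structure(rbind(c(0, 0, 0), Hp, A), top)
}
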