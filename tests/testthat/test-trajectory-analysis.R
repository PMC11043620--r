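# Trajectory statistics against brute-force and closed-form oracles.

test_that("Kabsch superposition is exact, rigid-invariant and matches the quaternion oracle", {
  h <- make_ideal_helix(12)
  expect_equal(kabsch_superpose(h, h)$rmsd, 0, tolerance = 1e-12)

  # rigid motion: rotate 90 deg about z and translate
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- idp_structure(h$coords %*% t(R90) +
                           matrix(c(12, -7, 3), nrow(h$coords), 3, byrow = TRUE),
                         h$topology)
  fit <- kabsch_superpose(moved, h)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  # random clouds vs the closed-form quaternion eigenvalue solution
  set.seed(31)
  for (rep in 1:5) {
    X <- matrix(rnorm(30), 10, 3)
    Y <- matrix(rnorm(30), 10, 3)
    top <- data.frame(chain = "A", resid = 1:10, resname = "GLY", atom = "CA",
                      element = "C", solvent = FALSE)
    got <- kabsch_superpose(idp_structure(X, top), idp_structure(Y, top),
                            atom_selection = "CA")$rmsd
    expect_equal(got, quaternion_rmsd(X, Y), tolerance = 1e-6)
  }

  expect_error(kabsch_superpose(make_ideal_helix(6), h), "match")
})

test_that("RMSD timeseries: zeros on static input, rising trend on unraveling fixture", {
  p <- helix_coil_params(30, 5, unravel_rate = 0, seed = 1)
  tr <- make_helix_coil_trajectory(p)
  r <- rmsd_timeseries(tr, trajectory_frame(tr, 1))
  expect_true(all(r < 1e-8))
  expect_length(rmsd_timeseries(
    idp_trajectory(tr$frames[1], tr$topology), trajectory_frame(tr, 1)), 1L)

  # replicate-averaged trend is increasing (Spearman rho > 0)
  avg <- Reduce(`+`, lapply(1:4, function(s) {
    t2 <- make_helix_coil_trajectory(
      helix_coil_params(60, 40, unravel_rate = 0.2, core_span = c(25, 35), seed = s))
    rmsd_timeseries(t2, trajectory_frame(t2, 1))
  })) / 4
  expect_gt(cor(seq_along(avg), avg, method = "spearman"), 0)
})

test_that("hydrogen-bond criteria are honored exactly at the cutoffs", {
  crit <- hbond_criteria()
  expect_equal(nrow(detect_hbonds(hbond_probe(3.4, 150), crit)), 1L)
  expect_equal(nrow(detect_hbonds(hbond_probe(3.6, 170), crit)), 0L)
  expect_equal(nrow(detect_hbonds(hbond_probe(3.4, 110), crit)), 0L)

  # ideal 18-residue helix: brute-force enumeration gives 14 i->i+4 bonds
  h <- make_ideal_helix(18)
  expect_identical(brute_force_backbone_hbonds(h), 14L)
  hb <- detect_hbonds(h, crit)
  expect_equal(nrow(hb), 14L)
  top <- h$topology
  shift <- top$resid[hb$acceptor] - top$resid[hb$donor]
  expect_true(all(shift == -4L))

  # missing hydrogens: instructive error, fixed by geometric placement
  noH <- idp_structure(h$coords[top$atom != "H", ],
                       top[top$atom != "H", ])
  expect_error(detect_hbonds(noH, crit), "place_amide_hydrogens")
  withH <- place_amide_hydrogens(noH)
  expect_equal(nrow(detect_hbonds(withH, crit)), 14L)
})

test_that("hbond timeseries partitions protein-protein and protein-water", {
  p <- helix_coil_params(20, 4, unravel_rate = 0.3, core_span = c(8, 12),
                         seed = 5, n_waters = 25)
  tr <- make_helix_coil_trajectory(p)
  ts <- hbond_timeseries(tr)
  expect_equal(ts$protein_protein + ts$protein_water + ts$water_water, ts$total)

  dry <- make_helix_coil_trajectory(helix_coil_params(20, 3, seed = 2))
  ts0 <- hbond_timeseries(dry)
  expect_true(all(ts0$protein_water == 0))

  # replicate-mean protein-protein series decreases as the helix unravels
  reps <- sapply(1:5, function(s) {
    t2 <- make_helix_coil_trajectory(
      helix_coil_params(40, 25, unravel_rate = 0.35, core_span = c(18, 22), seed = s))
    hbond_timeseries(t2)$protein_protein
  })
  m <- rowMeans(reps)
  expect_lt(mean(m[21:25]), mean(m[1:5]))
})

test_that("contact probabilities equal the brute-force distance scan", {
  # two single-atom residues in contact for 8 of 10 frames
  s_in <- two_point_structure(3.0)
  s_out <- two_point_structure(5.0)
  frames <- c(replicate(8, s_in$coords, simplify = FALSE),
              replicate(2, s_out$coords, simplify = FALSE))
  tr <- idp_trajectory(frames, s_in$topology)
  cm <- contact_probability_map(tr, cutoff = 3.5)
  expect_equal(cm$probability[1, 2], 0.8)
  expect_equal(cm$probability[2, 1], 0.8)

  # always in contact
  tr1 <- idp_trajectory(list(s_in$coords), s_in$topology)
  expect_equal(contact_probability_map(tr1)$probability[1, 2], 1)

  # symmetry and [0,1] bounds on a real fixture; replicate order irrelevant
  t1 <- make_helix_coil_trajectory(helix_coil_params(25, 6, unravel_rate = 0.3,
                                                     core_span = c(10, 15), seed = 1))
  t2 <- make_helix_coil_trajectory(helix_coil_params(25, 6, unravel_rate = 0.3,
                                                     core_span = c(10, 15), seed = 2))
  m12 <- contact_probability_map(list(t1, t2))
  m21 <- contact_probability_map(list(t2, t1))
  expect_identical(m12$probability, m21$probability)
  off <- m12$probability[upper.tri(m12$probability)]
  expect_true(all(off >= 0 & off <= 1))
  expect_identical(m12$probability, t(m12$probability))

  expect_error(contact_probability_map(list()), "empty")
})

test_that("top_contacts filters, sorts and excludes sequence-adjacent pairs", {
  t1 <- make_helix_coil_trajectory(helix_coil_params(20, 4, unravel_rate = 0, seed = 1))
  cm <- contact_probability_map(t1)
  all_pairs <- top_contacts(cm, 0)
  expect_true(all(abs(all_pairs$resid_i - all_pairs$resid_j) > 2 |
                    all_pairs$chain_i != all_pairs$chain_j))
  expect_identical(nrow(top_contacts(cm, 1.01)), 0L)
  tc <- top_contacts(cm, 0.75)
  expect_true(all(tc$probability >= 0.75))
  expect_true(all(diff(tc$probability) <= 0))
  # inter-chain labeling on a closely packed dimer
  td <- make_helix_coil_trajectory(helix_coil_params(20, 3, n_chains = 2,
                                                     unravel_rate = 0, seed = 3,
                                                     axial_separation = 6))
  tcd <- top_contacts(contact_probability_map(td), 0.5)
  expect_true(any(tcd$label == "inter"))
})

test_that("helicity assignment separates helix from coil", {
  h89 <- make_ideal_helix(89)
  tr <- idp_trajectory(list(h89$coords), h89$topology)
  hel <- assign_helicity(tr)
  expect_gte(hel$helix_fraction[1], 0.9)

  # fully extended chain (beta dihedrals) is all coil
  ext <- idpcryo:::.build_backbone(rep(-140, 30), rep(135, 30))
  tre <- idp_trajectory(list(ext), idpcryo:::.backbone_topology(30, "A"))
  expect_equal(assign_helicity(tre)$helix_fraction[1], 0)

  # forced-limit fixture: final helical set within the core span
  t1 <- make_helix_coil_trajectory(
    helix_coil_params(89, 60, unravel_rate = 1, core_span = c(40, 60), seed = 4))
  hel1 <- assign_helicity(t1)
  final <- which(hel1$indicator[, 60])
  expect_true(all(final >= 40 & final <= 60))

  expect_warning(assign_helicity(
    make_helix_coil_trajectory(helix_coil_params(5, 1, seed = 1))), NA)
  short_top <- idpcryo:::.backbone_topology(30, "A")
  expect_true(all(hel1$helix_fraction >= 0 & hel1$helix_fraction <= 1))
  expect_equal(hel1$helix_fraction + hel1$coil_fraction, rep(1, 60))
})

test_that("orientational correlation: rod = 1, orthogonal = 0, isotropic ~ 0", {
  # straight rod: CA atoms on a line, several frames
  n <- 8
  top <- data.frame(chain = "A", resid = 1:n, resname = "GLY", atom = "CA",
                    element = "C", solvent = FALSE)
  rod <- matrix(c(3.8 * (0:(n - 1)), rep(0, 2 * n)), n, 3)
  tr <- idp_trajectory(list(rod, rod + 5), top)
  oc <- orientational_correlation(tr)
  expect_true(all(abs(oc$matrix - 1) < 1e-12))

  # two vectors held orthogonal in every frame -> off-diagonal 0
  zig <- matrix(c(0, 0, 0, 1, 0, 0, 1, 1, 0), 3, 3, byrow = TRUE)
  t3 <- idp_trajectory(list(zig, zig * 2), top[1:3, ])
  oc3 <- orientational_correlation(t3)
  expect_equal(oc3$matrix[1, 2], 0, tolerance = 1e-12)

  # independent isotropic vectors: Monte-Carlo over 1e4 frames
  set.seed(77)
  nvec <- 6; nf <- 1e4
  acc <- matrix(0, nvec, nvec)
  for (f in seq_len(nf)) {
    V <- matrix(rnorm(3 * nvec), nvec, 3)
    V <- V / sqrt(rowSums(V^2))
    acc <- acc + tcrossprod(V)
  }
  M <- abs(acc / nf); diag(M) <- 1
  expect_true(all(M[upper.tri(M)] < 0.05))

  # single CA segment -> empty matrix
  t_one <- idp_trajectory(list(rod[1:1, , drop = FALSE]), top[1, , drop = FALSE])
  expect_equal(nrow(orientational_correlation(t_one)$matrix), 0L)
})

test_that("orientational correlation is invariant under global rigid rotation", {
  p <- helix_coil_params(20, 6, unravel_rate = 0.3, core_span = c(8, 12), seed = 6)
  tr <- make_helix_coil_trajectory(p)
  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  tr_rot <- idp_trajectory(lapply(tr$frames, function(f) f %*% t(R)), tr$topology)
  expect_equal(orientational_correlation(tr)$matrix,
               orientational_correlation(tr_rot)$matrix, tolerance = 1e-10)
})

test_that("hydrophobic moment matches the direct vector-sum oracle", {
  expect_lt(hydrophobic_moment(strrep("L", 18))$magnitude, 1e-9)
  expect_equal(hydrophobic_moment("W")$magnitude, 0.81)

  # amphipathic 18-mer: L and E alternating around the wheel
  seqs <- paste(rep(c("L", "E"), 9), collapse = "")
  got <- hydrophobic_moment(seqs)
  scale <- c(L = 1.06, E = -0.74)
  ang <- (0:17) * 100 * pi / 180
  hval <- scale[strsplit(seqs, "")[[1]]]
  oracle <- sqrt(sum(hval * cos(ang))^2 + sum(hval * sin(ang))^2) / 18
  expect_equal(got$magnitude, oracle, tolerance = 1e-9)

  expect_error(hydrophobic_moment("LXE"), "unknown residue")
})

test_that("net charge and counterion bookkeeping", {
  expect_equal(peptide_net_charge("KKRR"), 4L)
  expect_equal(peptide_net_charge("DDEE"), -4L)
  expect_equal(peptide_net_charge("GASTNQ"), 0L)
  ci <- counterions_needed("DDEEKR")   # net -2
  expect_equal(ci$count, 2L)
  expect_equal(ci$ion, "Na+")
  expect_equal(counterions_needed("DDEEKR", n_copies = 2)$count, 4L)
  expect_equal(counterions_needed("GG")$ion, "none")
})
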