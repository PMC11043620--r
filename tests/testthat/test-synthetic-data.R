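# Generators: geometry of the ideal helix, the terminal-erosion helix-coil
# trajectory, Guinier-Porod curves, DLS correlograms and assay tables.

test_that("ideal helix has canonical alpha-helix geometry and is deterministic", {
  h <- make_ideal_helix(18)
  ca <- h$coords[h$topology$atom == "CA", ]
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d - 3.8) < 0.1))

  # rise over one full turn (3.6 residues), measured from the generated
  # coordinates via the principal CA axis (brute-force oracle)
  ctr <- scale(ca, scale = FALSE)
  ax <- svd(ctr, nu = 0, nv = 1)$v[, 1]
  rise <- abs(mean(diff(ctr %*% ax)))
  expect_equal(rise * 3.6, 5.4, tolerance = 0.05)

  expect_identical(make_ideal_helix(18)$coords, h$coords)
  expect_error(make_ideal_helix(4), "n_res")
})

test_that("helix-coil trajectory honors unravel-rate limits", {
  # rate 0: helicity timeline constant
  p0 <- helix_coil_params(30, 10, unravel_rate = 0, seed = 1)
  t0 <- make_helix_coil_trajectory(p0)
  truth <- attr(t0, "helix_truth")[[1]]
  expect_true(all(truth))

  # rate 1: final frame helical residues exactly the core span
  p1 <- helix_coil_params(89, 60, unravel_rate = 1, core_span = c(40, 60), seed = 2)
  t1 <- make_helix_coil_trajectory(p1)
  final <- attr(t1, "helix_truth")[[1]][, 60]
  expect_identical(which(final), 40:60)
})

test_that("mean final helicity matches the terminal-erosion Markov chain", {
  # Monte-Carlo oracle for the same chain: two independent binomial erosion
  # counters capped at the core boundaries
  n_res <- 89L; core <- c(40L, 60L); rate <- 0.1; n_frames <- 100L
  set.seed(99)
  mc <- replicate(20000, {
    eL <- min(sum(runif(n_frames - 1) < rate), core[1] - 1L)
    eR <- min(sum(runif(n_frames - 1) < rate), n_res - core[2])
    (n_res - eL - eR) / n_res
  })
  oracle_mean <- mean(mc)

  seeds <- 1:10
  obs <- vapply(seeds, function(s) {
    tr <- make_helix_coil_trajectory(
      helix_coil_params(n_res, n_frames, unravel_rate = rate,
                        core_span = core, seed = s))
    mean(attr(tr, "helix_truth")[[1]][, n_frames])
  }, numeric(1))
  se <- sd(mc) / sqrt(length(seeds))
  expect_lt(abs(mean(obs) - oracle_mean), 3 * se)
})

test_that("generators are pure functions of (params, seed)", {
  p <- helix_coil_params(20, 5, n_chains = 2, seed = 7, n_waters = 4)
  expect_identical(make_helix_coil_trajectory(p)$frames,
                   make_helix_coil_trajectory(p)$frames)
  g <- guinier_porod_truth(25, 3, noise_frac = 0.02, seed = 5)
  expect_identical(make_guinier_porod_curve(g)$I, make_guinier_porod_curve(g)$I)
  d <- dls_truth(data.frame(R_S_nm = 3, weight = 1), noise = 1e-3, seed = 11)
  expect_identical(make_dls_correlogram(d)$g2m1, make_dls_correlogram(d)$g2m1)
  # generator RNG never leaks into the caller's stream
  set.seed(42); before <- runif(1)
  set.seed(42); invisible(make_helix_coil_trajectory(p)); after <- runif(1)
  expect_identical(before, after)
})

test_that("Guinier-Porod curve is C1-continuous and algebraically exact", {
  tr <- guinier_porod_truth(30, 2, q_grid = sort(c(10^seq(-2.3, -0.3, length.out = 300),
                                                   sqrt(3) / 30 * (1 + c(-1e-9, 1e-9)))))
  cv <- make_guinier_porod_curve(tr)
  Q1 <- sqrt(3 * 2 / 2) / 30
  near <- which(abs(cv$q - Q1) < 2e-9 * Q1)
  expect_gte(length(near), 2L)
  expect_lt(diff(range(cv$I[near])) / mean(cv$I[near]), 1e-8)

  # d = 2, noise-free: q^2 I constant beyond the crossover
  above <- cv$q > Q1 * (1 + 1e-6)
  y <- cv$q[above]^2 * cv$I[above]
  expect_lt(diff(range(y)) / mean(y), 1e-9)

  # a q grid entirely above the crossover is flagged
  expect_warning(
    out <- make_guinier_porod_curve(
      guinier_porod_truth(30, 2, q_grid = seq(0.1, 0.5, length.out = 50))),
    "crossover")
  expect_true(isTRUE(attr(out, "no_guinier_points")))
})

test_that("DLS correlogram follows the Stokes-Einstein forward model", {
  t1 <- dls_truth(data.frame(R_S_nm = 2, weight = 1))
  c1 <- make_dls_correlogram(t1)
  keep <- c1$g2m1 > max(c1$g2m1) * 1e-4
  fit <- lm(log(c1$g2m1[keep]) ~ c1$tau_s[keep])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fit by design
  expect_gt(r2, 1 - 1e-9)                         # single exponential: ln linear

  # decay rate scales inversely with radius (2:1 for 2 nm vs 4 nm)
  rate_of <- function(rs) {
    cc <- make_dls_correlogram(dls_truth(data.frame(R_S_nm = rs, weight = 1)))
    k <- cc$g2m1 > max(cc$g2m1) * 1e-4
    -coef(lm(log(cc$g2m1[k]) ~ cc$tau_s[k]))[[2]]
  }
  expect_equal(rate_of(2) / rate_of(4), 2, tolerance = 1e-6)
})

test_that("assay tables reproduce the 4PL ground truth", {
  x <- seq(-2, 2, length.out = 12)
  noise_free <- make_assay_table(assay_truth(80, 20, 0.3, x, replicate_sd = 0),
                                 "cf_leakage")
  fit <- dose_response_fit(noise_free$x, noise_free$y)
  expect_equal(fit$low, 80, tolerance = 1e-6)
  expect_equal(fit$high, 20, tolerance = 1e-6)
  expect_equal(fit$logEC50, 0.3, tolerance = 1e-6)

  # far above the EC50 the observations sit at the high-x asymptote
  far <- make_assay_table(assay_truth(80, 20, 0, x_values = c(6, 7, 8, 9, 10),
                                      replicate_sd = 0), "cf_leakage")
  expect_true(all(abs(far$y - 20) < 1e-4))

  # LDH kind adds a 0-5 cycle dimension with multiplicative decay
  ldh <- make_assay_table(assay_truth(10, 90, 0, x, replicate_sd = 0,
                                      cycle_decay = 0.8), "ldh_activity")
  expect_setequal(unique(ldh$cycle), 0:5)
  hi <- ldh[ldh$x == max(x), ]
  expect_equal(mean(hi$y[hi$cycle == 5]) / mean(hi$y[hi$cycle == 0]),
               0.8^5, tolerance = 1e-9)
})

test_that("assay EC50 recovery under replicate noise is unbiased at scale", {
  # repeated-fit simulation: sd = 2 (% units), n = 3, 12 x-values
  x <- seq(-2, 2, length.out = 12)
  errs <- vapply(1:60, function(s) {
    tab <- make_assay_table(assay_truth(80, 20, 0, x, replicate_sd = 2,
                                        n_replicates = 3, seed = s),
                            "cf_leakage")
    fit <- dose_response_fit(tab$x, tab$y)
    abs(10^fit$logEC50 - 1)          # truth EC50 = 10^0 = 1
  }, numeric(1))
  expect_lt(median(errs), 0.15)      # median |EC50 error| < 15% of truth
})
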