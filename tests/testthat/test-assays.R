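# Surface occupancy and dose-response analysis of the protection assays.

test_that("lipids_per_vesicle matches the direct arithmetic oracle", {
  g <- liposome_geometry(fractions = c(X = 1), head_area_nm2 = c(X = 0.64),
                         radius_nm = 50, thickness_nm = 4)
  oracle <- (4 * pi * 50^2 + 4 * pi * 46^2) / 0.64
  expect_equal(lipids_per_vesicle(g), oracle, tolerance = 1e-12)

  # halving the head-group area doubles the count
  g2 <- liposome_geometry(fractions = c(X = 1), head_area_nm2 = c(X = 0.32),
                          radius_nm = 50, thickness_nm = 4)
  expect_equal(lipids_per_vesicle(g2), 2 * lipids_per_vesicle(g))

  # mixed fractions with equal areas degenerate to the single-species value
  g4 <- liposome_geometry(fractions = c(A = 0.4, B = 0.3, C = 0.15, D = 0.15),
                          head_area_nm2 = c(A = 0.64, B = 0.64, C = 0.64, D = 0.64),
                          radius_nm = 50, thickness_nm = 4)
  expect_equal(lipids_per_vesicle(g4), lipids_per_vesicle(g))

  # monotone: bigger vesicle, more lipids; bigger areas, fewer
  g_big <- liposome_geometry(fractions = c(X = 1), head_area_nm2 = c(X = 0.64),
                             radius_nm = 60, thickness_nm = 4)
  expect_gt(lipids_per_vesicle(g_big), lipids_per_vesicle(g))

  expect_error(liposome_geometry(fractions = c(X = 0.9)), "sum to 1")
  expect_error(liposome_geometry(fractions = c(X = 1), head_area_nm2 = c(X = 0.6),
                                 radius_nm = 3, thickness_nm = 4), "radius")
})

test_that("surface occupancy: linearity, the disc/sphere ratio, and the worked case", {
  base <- surface_occupancy(1, 2.6, 32500, target = "protein",
                            c_target_mg_ml = 0.15)
  expect_equal(surface_occupancy(2, 2.6, 32500, target = "protein",
                                 c_target_mg_ml = 0.15), 2 * base)
  expect_equal(surface_occupancy(1, 2.6, 32500, target = "protein",
                                 c_target_mg_ml = 0.30), base / 2)

  # equal radii and equal molar concentrations: pi R^2 / (4 pi R^2) = 0.25
  expect_equal(surface_occupancy(1, 3, 1000, target = "protein",
                                 c_target_mg_ml = 1, MW_target = 1000,
                                 R_S_target_nm = 3), 0.25, tolerance = 1e-12)

  # worked liposome case against a spreadsheet-style evaluation
  geom <- liposome_geometry(fractions = c(X = 1), head_area_nm2 = c(X = 0.64),
                            radius_nm = 50, thickness_nm = 4)
  got <- surface_occupancy(1.0, 2.6, 32500, target = "liposome",
                           geometry = geom, c_lipid_mg_ml = 0.32,
                           MW_lipid = 800)
  n_tot <- (4 * pi * 50^2 + 4 * pi * 46^2) / 0.64
  manual <- 1.0 * (pi * 2.6^2) * n_tot * 800 / ((4 * pi * 50^2) * 0.32 * 32500)
  expect_equal(got, manual, tolerance = 1e-9)

  expect_error(surface_occupancy(1, 2.6, 32500, target = "protein",
                                 c_target_mg_ml = 0), "zero target")
})

test_that("CF leakage normalization", {
  expect_equal(as.numeric(cf_leakage_percent(10, 10, 110)), 0)
  expect_equal(as.numeric(cf_leakage_percent(10, 110, 110)), 100)
  expect_equal(as.numeric(cf_leakage_percent(10, 55, 110)), 45)
  over <- cf_leakage_percent(10, 130, 110)
  expect_equal(as.numeric(over), 100)
  expect_equal(attr(over, "raw"), 120)
  expect_error(cf_leakage_percent(10, 5, 9), "exceed")
})

test_that("4PL dose-response fit: recovery, degeneracy and reparameterization stability", {
  x <- seq(-2, 2, length.out = 12)
  tab <- make_assay_table(assay_truth(80, 20, 0, x, replicate_sd = 0), "cf_leakage")
  fit <- dose_response_fit(tab$x, tab$y)
  expect_equal(c(fit$low, fit$high, fit$logEC50), c(80, 20, 0), tolerance = 1e-6)
  expect_equal(fit$capacity, fit$high)
  # half response at the EC50
  expect_equal(fit$fitted(fit$logEC50), (fit$low + fit$high) / 2, tolerance = 1e-9)

  expect_warning(dg <- dose_response_fit(x, rep(50, 12)), "degenerate")
  expect_true(dg$degenerate)
  expect_equal(dg$low, dg$high)

  # ascending data give the mirrored curve with swapped asymptotes
  tab_up <- make_assay_table(assay_truth(20, 80, 0, x, replicate_sd = 0), "cf_leakage")
  fit_up <- dose_response_fit(tab_up$x, tab_up$y)
  expect_equal(fit_up$low, 20, tolerance = 1e-6)
  expect_equal(fit_up$high, 80, tolerance = 1e-6)
  expect_equal(fit_up$logEC50, fit$logEC50, tolerance = 1e-6)

  # EC50 equivariance under shifting the x grid
  tab_s <- make_assay_table(assay_truth(80, 20, 1.5, x + 1.5, replicate_sd = 0),
                            "cf_leakage")
  fit_s <- dose_response_fit(tab_s$x, tab_s$y)
  expect_equal(fit_s$logEC50, fit$logEC50 + 1.5, tolerance = 1e-6)

  expect_error(dose_response_fit(c(1, 2, 3, 4), c(1, 2, 3, 4)), "5 distinct")
})

test_that("LT50 recovery from conductivity tables", {
  tab <- make_electrolyte_table(lt50 = -8, sd = 0, seed = 1)
  res <- lt50_from_electrolyte_leakage(tab)
  expect_equal(res$lt50_C, -8, tolerance = 1e-6)

  # leakage at the fitted LT50 is 50% of the span
  fit <- attr(res, "fits")[[1]]
  expect_equal(fit$fitted(res$lt50_C), (fit$low + fit$high) / 2, tolerance = 1e-9)

  # two genotypes fitted independently
  tab2 <- rbind(make_electrolyte_table(lt50 = -6, sd = 0, genotype = "a", seed = 1),
                make_electrolyte_table(lt50 = -10, sd = 0, genotype = "b", seed = 2))
  res2 <- lt50_from_electrolyte_leakage(tab2)
  expect_equal(sort(res2$lt50_C), c(-10, -6), tolerance = 1e-5)

  no_ctrl <- tab[!tab$control, ]
  no_ctrl$control <- NULL
  no_ctrl <- no_ctrl[no_ctrl$temperature_C < -1, ]  # max-temperature fallback
  expect_error(lt50_from_electrolyte_leakage(tab[0, ]), "control|temperatures")
})

test_that("LDH retention normalization", {
  acts <- expand.grid(variant = c("wt", "mut"), occupancy = c(1, 4),
                      cycle = 0:5, replicate = 1:6, KEEP.OUT.ATTRS = FALSE)
  acts$activity <- 100 * 0.8^acts$cycle
  ret <- ldh_retention(acts, unfrozen_control = 100)
  expect_equal(ret$retention[ret$cycle == 0][1], 1)
  at5 <- ret$retention[ret$cycle == 5]
  expect_equal(at5, rep(0.8^5, length(at5)), tolerance = 1e-12)

  zero <- acts; zero$activity <- 0
  expect_true(all(ldh_retention(zero, 100)$retention == 0))
  expect_error(ldh_retention(acts, 0), "> 0")
})
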