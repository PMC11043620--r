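# Forward models with known ground truth: Guinier-Porod scattering curves,
# DLS correlograms and dose-response assay tables.

#' Ground truth for a synthetic Guinier-Porod scattering curve
#'
#' @param R_G radius of gyration (Angstrom), > 0.
#' @param d power-law scaling exponent, in `[1, 4]` (2 = Gaussian coil,
#'   4 = compact globule).
#' @param G forward-scattering scale (default 1).
#' @param noise_frac relative (multiplicative) Gaussian noise SD (default 0).
#' @param q_grid strictly increasing positive q values (1/Angstrom);
#'   default 200 log-spaced points over 0.005-0.5.
#' @param seed RNG seed (mandatory when `noise_frac > 0`).
#' @return A list of class `guinier_porod_truth`.
#' @export
guinier_porod_truth <- function(R_G, d, G = 1, noise_frac = 0,
                                q_grid = NULL, seed = 1L) {
  .stopifnot_scalar_pos(R_G, "R_G")
  if (d < 1 || d > 4) stop("`d` must be in [1, 4]")
  .stopifnot_scalar_pos(G, "G")
  if (noise_frac < 0) stop("`noise_frac` must be >= 0")
  if (is.null(q_grid)) q_grid <- 10^seq(log10(0.005), log10(0.5), length.out = 200L)
  if (any(q_grid <= 0) || any(diff(q_grid) <= 0)) {
    stop("`q_grid` must be strictly increasing and positive")
  }
  structure(list(R_G = R_G, d = d, G = G, noise_frac = noise_frac,
                 q_grid = q_grid, seed = as.integer(seed)),
            class = "guinier_porod_truth")
}

# C1-continuous Guinier-Porod intensity (Hammouda form, s = 0):
# crossover Q1 = sqrt(3 d / 2) / R_G, power-law prefactor fixed by
# continuity of I and dI/dq at Q1.
.guinier_porod_intensity <- function(q, G, R_G, d) {
  Q1 <- sqrt(3 * d / 2) / R_G
  D <- G * exp(-d / 2) * Q1^d
  ifelse(q <= Q1, G * exp(-q^2 * R_G^2 / 3), D * q^(-d))
}

#' Generate a synthetic Guinier-Porod scattering curve
#'
#' Evaluates the C1-continuous two-regime model (Guinier exponential below
#' the crossover `Q1 = sqrt(3 d / 2) / R_G`, `q^-d` power law above) and
#' applies multiplicative Gaussian noise.  The sigma column is
#' `noise_frac * I_model`.
#'
#' @param truth a [guinier_porod_truth()] object.
#' @return A [scattering_curve()].  If the q grid has no points below the
#'   crossover the attribute `no_guinier_points` is set to TRUE.
#' @export
make_guinier_porod_curve <- function(truth) {
  stopifnot(inherits(truth, "guinier_porod_truth"))
  q <- truth$q_grid
  I0 <- .guinier_porod_intensity(q, truth$G, truth$R_G, truth$d)
  I <- if (truth$noise_frac > 0) {
    with_seed(truth$seed, I0 * (1 + truth$noise_frac * stats::rnorm(length(q))))
  } else I0
  sigma <- if (truth$noise_frac > 0) truth$noise_frac * I0 else NULL
  curve <- scattering_curve(q, I, sigma,
                            metadata = list(generator = "guinier_porod",
                                            truth = truth[c("R_G", "d", "G")]))
  Q1 <- sqrt(3 * truth$d / 2) / truth$R_G
  if (min(q) > Q1) {
    warning("q grid spans no points below the Guinier-Porod crossover Q1")
    attr(curve, "no_guinier_points") <- TRUE
  }
  curve
}

# ---------------------------------------------------------------------------
# DLS

#' Instrument settings for light scattering
#'
#' Defaults describe a 532 nm, 90 degree instrument with aqueous buffer at
#' 23 C (viscosity 0.932 mPa s, refractive index 1.332); all values are
#' explicit inputs, never hidden constants.
#'
#' @param wavelength_nm laser wavelength in vacuo (nm).
#' @param angle_deg scattering angle (degrees).
#' @param refractive_index solvent refractive index.
#' @param temperature_K absolute temperature.
#' @param viscosity_Pa_s solvent viscosity (Pa s).
#' @return list of class `dls_instrument`.
#' @export
dls_instrument <- function(wavelength_nm = 532, angle_deg = 90,
                           refractive_index = 1.332, temperature_K = 296.15,
                           viscosity_Pa_s = 0.932e-3) {
  structure(list(wavelength_nm = wavelength_nm, angle_deg = angle_deg,
                 refractive_index = refractive_index,
                 temperature_K = temperature_K,
                 viscosity_Pa_s = viscosity_Pa_s), class = "dls_instrument")
}

.KB <- 1.380649e-23  # J/K

# scattering vector magnitude in 1/m
.q_vector <- function(inst) {
  4 * pi * inst$refractive_index /
    (inst$wavelength_nm * 1e-9) * sin(inst$angle_deg * pi / 360)
}

# Stokes-Einstein: R_S (m) <-> D (m^2/s)
.stokes_einstein_D <- function(R_S_m, inst) {
  .KB * inst$temperature_K / (6 * pi * inst$viscosity_Pa_s * R_S_m)
}

#' Ground truth for a synthetic DLS correlogram
#'
#' @param components data.frame or matrix with columns `R_S_nm` and
#'   `weight` (intensity weights, positive, normalized internally to sum 1).
#' @param instrument a [dls_instrument()].
#' @param beta coherence factor (intercept of g2 - 1; default 0.8).
#' @param noise additive Gaussian noise SD on g2 - 1 (default 0).
#' @param tau_s lag-time grid (s); default 200 log-spaced points over
#'   1e-7 .. 1 s.
#' @param seed RNG seed.
#' @return list of class `dls_truth`.
#' @export
dls_truth <- function(components, instrument = dls_instrument(), beta = 0.8,
                      noise = 0, tau_s = NULL, seed = 1L) {
  components <- as.data.frame(components)
  if (!all(c("R_S_nm", "weight") %in% names(components))) {
    stop("`components` needs columns R_S_nm and weight")
  }
  if (any(components$R_S_nm <= 0) || any(components$weight <= 0)) {
    stop("R_S and weights must be positive")
  }
  components$weight <- components$weight / sum(components$weight)
  if (is.null(tau_s)) tau_s <- 10^seq(-7, 0, length.out = 200L)
  structure(list(components = components, instrument = instrument,
                 beta = beta, noise = noise, tau_s = tau_s,
                 seed = as.integer(seed)), class = "dls_truth")
}

#' Generate a synthetic DLS correlogram
#'
#' Forward model `g2(tau) - 1 = beta * (sum_i w_i exp(-Gamma_i tau))^2`
#' with `Gamma_i = D_i q^2`, `q = (4 pi n / lambda) sin(angle / 2)` and
#' `D_i` from the Stokes-Einstein relation, plus additive Gaussian noise.
#'
#' @param truth a [dls_truth()] object.
#' @return A list of class `correlogram` with `tau_s`, `g2m1` and
#'   `instrument`.
#' @export
make_dls_correlogram <- function(truth) {
  stopifnot(inherits(truth, "dls_truth"))
  q <- .q_vector(truth$instrument)
  gamma <- .stokes_einstein_D(truth$components$R_S_nm * 1e-9,
                              truth$instrument) * q^2
  g1 <- drop(exp(-outer(truth$tau_s, gamma)) %*% truth$components$weight)
  g2m1 <- truth$beta * g1^2
  if (truth$noise > 0) {
    g2m1 <- with_seed(truth$seed, g2m1 + truth$noise * stats::rnorm(length(g2m1)))
  }
  structure(list(tau_s = truth$tau_s, g2m1 = g2m1,
                 instrument = truth$instrument),
            class = "correlogram")
}

#' Construct a correlogram object from data
#'
#' @param tau_s increasing positive lag times (s).
#' @param g2m1 values of g2(tau) - 1.
#' @param instrument a [dls_instrument()].
#' @return list of class `correlogram`.
#' @export
correlogram <- function(tau_s, g2m1, instrument = dls_instrument()) {
  if (any(tau_s <= 0) || any(diff(tau_s) <= 0)) {
    stop("`tau_s` must be strictly increasing and positive")
  }
  if (length(g2m1) != length(tau_s)) stop("length mismatch")
  structure(list(tau_s = tau_s, g2m1 = g2m1, instrument = instrument),
            class = "correlogram")
}

# ---------------------------------------------------------------------------
# Assay tables

#' Ground truth for a synthetic dose-response assay
#'
#' Four-parameter logistic with Hill slope 1 on a base-10 abscissa:
#' `y(x) = low + (high - low) / (1 + 10^(logEC50 - x))`, where `low` is the
#' low-x and `high` the high-x asymptote.
#'
#' @param low_x_asymptote,high_x_asymptote response asymptotes (assay units,
#'   typically percent).
#' @param logEC50 abscissa value of half response.
#' @param x_values design points (log10 occupancy for leakage assays,
#'   temperature in C for electrolyte leakage).
#' @param replicate_sd Gaussian replicate noise SD (>= 0).
#' @param n_replicates replicates per design point (>= 1).
#' @param cycle_decay multiplicative per-freeze-thaw-cycle activity decay
#'   used only by the `ldh_activity` kind (default 0.8).
#' @param seed RNG seed.
#' @return list of class `assay_truth`.
#' @export
assay_truth <- function(low_x_asymptote, high_x_asymptote, logEC50,
                        x_values, replicate_sd = 0, n_replicates = 3L,
                        cycle_decay = 0.8, seed = 1L) {
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1")
  if (replicate_sd < 0) stop("`replicate_sd` must be >= 0")
  structure(list(low_x_asymptote = low_x_asymptote,
                 high_x_asymptote = high_x_asymptote, logEC50 = logEC50,
                 x_values = x_values, replicate_sd = replicate_sd,
                 n_replicates = as.integer(n_replicates),
                 cycle_decay = cycle_decay, seed = as.integer(seed)),
            class = "assay_truth")
}

# the shared 4PL forward model (Hill slope 1, base 10)
.logistic4 <- function(x, low, high, logEC50) {
  low + (high - low) / (1 + 10^(logEC50 - x))
}

#' Generate a synthetic assay table
#'
#' Draws replicate observations from the four-parameter logistic plus
#' Gaussian noise.  For `kind = "ldh_activity"` a freeze-thaw cycle
#' dimension (0-5) with multiplicative per-cycle decay is added.
#'
#' @param truth an [assay_truth()] object.
#' @param kind one of `"cf_leakage"`, `"electrolyte"`, `"ldh_activity"`.
#' @return data.frame with columns `x`, `replicate`, `y` (and `cycle` for
#'   LDH), carrying the truth as attribute `truth`.
#' @export
make_assay_table <- function(truth, kind = c("cf_leakage", "electrolyte",
                                             "ldh_activity")) {
  stopifnot(inherits(truth, "assay_truth"))
  kind <- match.arg(kind)
  mu <- .logistic4(truth$x_values, truth$low_x_asymptote,
                   truth$high_x_asymptote, truth$logEC50)
  with_seed(truth$seed, {
    if (kind == "ldh_activity") {
      grid <- expand.grid(replicate = seq_len(truth$n_replicates),
                          cycle = 0:5, x = truth$x_values,
                          KEEP.OUT.ATTRS = FALSE)
      grid$y <- mu[match(grid$x, truth$x_values)] *
        truth$cycle_decay^grid$cycle +
        truth$replicate_sd * stats::rnorm(nrow(grid))
      tab <- grid[, c("x", "cycle", "replicate", "y")]
    } else {
      grid <- expand.grid(replicate = seq_len(truth$n_replicates),
                          x = truth$x_values, KEEP.OUT.ATTRS = FALSE)
      grid$y <- mu[match(grid$x, truth$x_values)] +
        truth$replicate_sd * stats::rnorm(nrow(grid))
      tab <- grid[, c("x", "replicate", "y")]
    }
    attr(tab, "truth") <- truth
    attr(tab, "kind") <- kind
    tab
  })
}

# ---------------------------------------------------------------------------
# SLS forward model (inverse of apparent_mass) for mass-recovery fixtures

#' Forward-model static light scattering intensities
#'
#' Produces toluene-normalized excess scattering intensities for a species
#' of molar mass `M` at the given concentrations, optionally with a linear
#' interaction slope (second-virial-like), so that [apparent_mass()] and
#' [extrapolate_zero_concentration()] recover `M` at infinite dilution.
#'
#' @param M molar mass (g/mol).
#' @param c_mg_ml concentrations (mg/mL).
#' @param dndc refractive index increment (mL/g).
#' @param optics an [sls_optics()] list.
#' @param interaction_slope relative change of apparent mass per mg/mL
#'   (default 0).
#' @return data.frame with `c_mg_ml` and `intensity_ratio`.
#' @export
make_sls_series <- function(M, c_mg_ml, dndc = 0.185, optics = sls_optics(),
                            interaction_slope = 0) {
  M_app <- M * (1 + interaction_slope * c_mg_ml)
  K <- .sls_K(dndc, optics)
  R_theta <- K * (c_mg_ml / 1000) * M_app
  data.frame(c_mg_ml = c_mg_ml,
             intensity_ratio = R_theta / optics$R_toluene)
}
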