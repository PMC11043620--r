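# Solution biophysics: DLS cumulant and regularized inversion, SLS apparent
# masses, infinite-dilution extrapolation, crowder volume fractions and
# CD-based helicity.

#' Cumulant analysis of a DLS correlogram
#'
#' Fits `ln sqrt(g2 - 1) = ln sqrt(beta) - Gamma tau (+ mu2 tau^2 / 2)` to
#' lags above the noise floor, converts the mean decay rate to a diffusion
#' coefficient `D = Gamma / q^2` and to a hydrodynamic radius via the
#' Stokes-Einstein relation `R_S = kB T / (6 pi eta D)`.
#'
#' @param corr a [correlogram()] (carries its instrument settings).
#' @param order 1 or 2 (second order adds the polydispersity term; default 2).
#' @param floor_frac lags with `g2 - 1` below `floor_frac * max` are
#'   dropped (default 1e-3).
#' @return list of class `hydro_result`: `Gamma_s` (1/s), `PDI`, `D_m2_s`,
#'   `R_S_nm`, `R_S_se_nm`, `beta`, `method = "cumulant"`, `n_points`.
#' @export
cumulant_fit <- function(corr, order = 2L, floor_frac = 1e-3) {
  stopifnot(inherits(corr, "correlogram"))
  if (!order %in% c(1L, 2L)) stop("`order` must be 1 or 2")
  keep <- corr$g2m1 > max(corr$g2m1) * floor_frac & corr$g2m1 > 0
  tau <- corr$tau_s[keep]
  y <- 0.5 * log(corr$g2m1[keep])
  if (length(tau) < 10L) stop("fewer than 10 usable lags above the noise floor")
  fm <- if (order == 1L) stats::lm(y ~ tau) else stats::lm(y ~ tau + I(tau^2))
  co <- stats::coef(fm)
  Gamma <- -co[[2L]]
  if (Gamma <= 0 || Gamma * max(tau) < 1e-3) {
    stop("correlogram does not decay over the fitted range")
  }
  mu2 <- if (order == 2L) 2 * co[[3L]] else 0
  q <- .q_vector(corr$instrument)
  D <- Gamma / q^2
  inst <- corr$instrument
  R_S <- .KB * inst$temperature_K / (6 * pi * inst$viscosity_Pa_s * D)
  se_G <- suppressWarnings(sqrt(stats::vcov(fm)[2L, 2L]))
  structure(list(Gamma_s = Gamma, PDI = mu2 / Gamma^2, D_m2_s = D,
                 R_S_nm = R_S * 1e9, R_S_se_nm = R_S * 1e9 * se_G / Gamma,
                 beta = exp(2 * co[[1L]]), method = "cumulant",
                 n_points = length(tau)), class = "hydro_result")
}

#' @export
print.hydro_result <- function(x, ...) {
  cat(sprintf("%s: R_S = %.3f nm, D = %.4g m^2/s, Gamma = %.4g 1/s, PDI = %.3f\n",
              x$method, x$R_S_nm, x$D_m2_s, x$Gamma_s, x$PDI))
  invisible(x)
}

# Lawson-Hanson non-negative least squares: min ||Ax - b||, x >= 0.
.nnls <- function(A, b, tol = NULL) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * .norm(as.numeric(w)) * n
  iter <- 0L
  max_iter <- 30L * n
  while (any(!passive) && max(w[!passive]) > tol && iter < max_iter) {
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      iter <- iter + 1L
      s <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- qr.coef(qr(Ap), b)
      s[passive][is.na(s[passive])] <- 0
      if (all(s[passive] > 0)) { x <- s; break }
      neg <- passive & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
      if (iter >= max_iter) break
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Regularized inversion of a DLS correlogram
#'
#' Recovers a non-negative decay-time distribution from `g1 = sqrt((g2 - 1)
#' / beta)` by Tikhonov-regularized non-negative least squares,
#' `min ||g1 - A w||^2 + alpha^2 ||L w||^2` with a second-difference
#' penalty L on a log-spaced decay-time grid -- the same contract the
#' classical constrained regularization method fulfills.  Decay times map
#' to radii through `R = kB T t q^2 / (6 pi eta)`.
#'
#' @param corr a [correlogram()].
#' @param grid optional decay-time grid (s); default 80 log-spaced nodes
#'   spanning the data's lag range.
#' @param alpha regularization strength (default 0.1).
#' @return list of class `dls_distribution`: `decay_time_s`, `R_S_nm`,
#'   `weight` (normalized), `mean_R_S_nm` (intensity-weighted), `modes`
#'   (data.frame of log-parabolically interpolated peaks), `residual`,
#'   `alpha`, and a `hydro_result` for the mean.
#' @export
regularized_inversion <- function(corr, grid = NULL, alpha = 0.1) {
  stopifnot(inherits(corr, "correlogram"))
  g2m1 <- corr$g2m1
  beta <- max(g2m1[seq_len(max(3L, length(g2m1) %/% 50L))])
  # truncate fully decayed lags: positive-clipped sqrt noise in the tail
  # otherwise masquerades as slow decay modes
  tail_idx <- seq(max(1L, length(g2m1) - max(5L, length(g2m1) %/% 20L)),
                  length(g2m1))
  noise_est <- stats::sd(g2m1[tail_idx])
  floor_lvl <- max(3 * noise_est, 1e-6 * beta)
  sm <- stats::runmed(g2m1, 5L)
  above <- which(sm > floor_lvl)
  last <- if (length(above)) max(above) else length(g2m1)
  keep <- seq_len(max(last, 30L))
  g2m1 <- g2m1[keep]
  g1 <- sqrt(pmax(g2m1 / beta, 0))
  tau <- corr$tau_s[keep]
  if (is.null(grid)) {
    grid <- 10^seq(log10(min(tau)), log10(max(tau)), length.out = 80L)
  }
  if (length(grid) < 30L) stop("decay-time grid needs >= 30 nodes")
  A <- exp(-outer(tau, grid, `/`))
  m <- length(grid)
  L <- matrix(0, m - 2L, m)
  for (i in seq_len(m - 2L)) L[i, i:(i + 2L)] <- c(1, -2, 1)
  Aaug <- rbind(A, alpha * L)
  baug <- c(g1, numeric(m - 2L))
  w <- .nnls(Aaug, baug)
  if (all(w == 0)) stop("all-zero solution; try a smaller alpha")
  inst <- corr$instrument
  q <- .q_vector(inst)
  R_nm <- .KB * inst$temperature_K * grid * q^2 / (6 * pi * inst$viscosity_Pa_s) * 1e9
  wn <- w / sum(w)
  mean_R <- sum(wn * R_nm)
  # local maxima with log-parabolic interpolation for sub-grid peak position
  peaks <- list()
  for (i in 2:(m - 1L)) {
    if (w[i] > w[i - 1L] && w[i] >= w[i + 1L] && w[i] > 0.02 * max(w)) {
      lx <- log(R_nm[(i - 1L):(i + 1L)])
      ly <- w[(i - 1L):(i + 1L)]
      denom <- (ly[1L] - 2 * ly[2L] + ly[3L])
      shift <- if (abs(denom) > 0) 0.5 * (ly[1L] - ly[3L]) / denom else 0
      shift <- max(-1, min(1, shift))
      lpk <- lx[2L] + shift * (lx[3L] - lx[2L])
      peaks[[length(peaks) + 1L]] <- data.frame(R_S_nm = exp(lpk),
                                                weight = wn[i])
    }
  }
  modes <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(R_S_nm = numeric(), weight = numeric())
  D_mean <- .KB * inst$temperature_K / (6 * pi * inst$viscosity_Pa_s * mean_R * 1e-9)
  hydro <- structure(list(Gamma_s = D_mean * q^2, PDI = NA_real_,
                          D_m2_s = D_mean, R_S_nm = mean_R,
                          R_S_se_nm = NA_real_, beta = beta,
                          method = "regularized", n_points = length(tau)),
                     class = "hydro_result")
  structure(list(decay_time_s = grid, R_S_nm = R_nm, weight = wn,
                 mean_R_S_nm = mean_R, modes = modes,
                 residual = sum((g1 - A %*% w)^2), alpha = alpha,
                 hydro = hydro), class = "dls_distribution")
}

# ---------------------------------------------------------------------------
# Static light scattering

#' Optical constants for static light scattering
#'
#' @param refractive_index solvent refractive index.
#' @param wavelength_nm laser wavelength (nm).
#' @param R_toluene Rayleigh ratio of the toluene standard (1/cm); the
#'   default 2.79e-5 is the customary value at 532 nm and is configurable.
#' @return list of class `sls_optics`.
#' @export
sls_optics <- function(refractive_index = 1.332, wavelength_nm = 532,
                       R_toluene = 2.79e-5) {
  structure(list(refractive_index = refractive_index,
                 wavelength_nm = wavelength_nm, R_toluene = R_toluene),
            class = "sls_optics")
}

.AVOGADRO <- 6.02214076e23

# optical constant K in cm^2 mol / g^2 (cgs; c in g/mL, dn/dc in mL/g)
.sls_K <- function(dndc, optics) {
  lambda_cm <- optics$wavelength_nm * 1e-7
  4 * pi^2 * optics$refractive_index^2 * dndc^2 /
    (.AVOGADRO * lambda_cm^4)
}

#' Apparent molar mass from toluene-normalized SLS intensity
#'
#' `M_app = R_theta / (K c)` with the optical constant
#' `K = 4 pi^2 n^2 (dn/dc)^2 / (N_A lambda^4)` and the excess Rayleigh
#' ratio `R_theta` obtained from the toluene-standard intensity ratio.
#'
#' @param intensity_ratio sample excess intensity normalized to toluene.
#' @param c_mg_ml protein concentration (mg/mL), > 0.
#' @param dndc refractive index increment (mL/g).
#' @param optics an [sls_optics()] list.
#' @return apparent molar mass (g/mol).
#' @export
apparent_mass <- function(intensity_ratio, c_mg_ml, dndc = 0.185,
                          optics = sls_optics()) {
  if (any(c_mg_ml <= 0)) stop("concentration must be > 0")
  R_theta <- intensity_ratio * optics$R_toluene
  R_theta / (.sls_K(dndc, optics) * (c_mg_ml / 1000))
}

#' Linear extrapolation to infinite dilution
#'
#' Ordinary least-squares fit of a measured quantity against concentration;
#' the intercept estimates the infinite-dilution value free of residual
#' intermolecular interactions.
#'
#' @param c_mg_ml concentrations (>= 3 distinct values).
#' @param value measured quantity (apparent mass, R_S, ...).
#' @return list with `intercept`, `intercept_se`, `slope`, `slope_se`.
#' @export
extrapolate_zero_concentration <- function(c_mg_ml, value) {
  if (length(unique(c_mg_ml)) < 3L) stop("need >= 3 distinct concentrations")
  fm <- stats::lm(value ~ c_mg_ml)
  co <- stats::coef(fm)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fm))))
  list(intercept = co[[1L]], intercept_se = se[[1L]],
       slope = co[[2L]], slope_se = se[[2L]])
}

#' Crowder volume fraction from mass concentration
#'
#' `phi = c * nu / 10` (% v/v) for `c` in g/L and the partial specific
#' volume `nu` in mL/g (0.735 mL/g for serum albumin by default).
#'
#' @param c_g_l crowder concentration (g/L), >= 0.
#' @param nu_ml_g partial specific volume (mL/g).
#' @return volume fraction in % v/v.
#' @export
volume_fraction <- function(c_g_l, nu_ml_g = 0.735) {
  if (any(c_g_l < 0)) stop("concentration must be >= 0")
  c_g_l * nu_ml_g / 10
}

#' Alpha-helix fraction from mean-residue ellipticity at 222 nm
#'
#' Linear interpolation between coil and full-helix reference ellipticities:
#' `f_H = (theta222 - theta_coil) / (theta_helix - theta_coil)`.  The fixed
#' default constants (`theta_coil = -2340`, `theta_helix = -32640`
#' deg cm^2/dmol) give `f_H = -(theta222 + 2340) / 30300`; passing
#' `n_residues` switches to the chain-length-corrected helix reference
#' `theta_helix = -39500 (1 - 2.57 / n)` + coil offset.
#'
#' @param theta222 mean-residue ellipticity at 222 nm (deg cm^2/dmol).
#' @param theta_coil,theta_helix reference ellipticities (overridable).
#' @param n_residues optional chain length for the corrected variant.
#' @return list with `f_H` (clipped to `[0, 1]`), `f_H_raw` and the
#'   constants used.  Clipping raises a warning.
#' @export
cd_helicity <- function(theta222, theta_coil = -2340, theta_helix = -32640,
                        n_residues = NULL) {
  if (!is.null(n_residues)) {
    theta_helix <- -39500 * (1 - 2.57 / n_residues) + theta_coil
  }
  f_raw <- (theta222 - theta_coil) / (theta_helix - theta_coil)
  f <- pmin(pmax(f_raw, 0), 1)
  if (any(f != f_raw)) warning("helix fraction outside [0, 1]; clipped")
  list(f_H = f, f_H_raw = f_raw, theta_coil = theta_coil,
       theta_helix = theta_helix)
}
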