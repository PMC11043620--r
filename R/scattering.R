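# Small-angle scattering analysis: Guinier fits with self-consistent window
# selection, the Guinier-Porod generalized model, and dimensionless Kratky
# diagnostics.

#' Construct a scattering curve
#'
#' @param q scattering vector magnitudes (1/Angstrom),
#'   `q = 4 pi / lambda * sin(theta / 2)`; strictly increasing, positive.
#' @param I intensities (arbitrary or absolute units).
#' @param sigma optional positive uncertainties.
#' @param metadata optional named list (instrument, contrast, ...).
#' @return list of class `scattering_curve`.
#' @export
scattering_curve <- function(q, I, sigma = NULL, metadata = list()) {
  if (any(q <= 0) || any(diff(q) <= 0)) {
    stop("`q` must be strictly increasing and positive")
  }
  if (length(I) != length(q)) stop("q and I length mismatch")
  if (!is.null(sigma)) {
    if (length(sigma) != length(q)) stop("sigma length mismatch")
    if (any(sigma < 0)) stop("sigma must be >= 0")
    if (all(sigma == 0)) sigma <- NULL
  }
  structure(list(q = as.numeric(q), I = as.numeric(I),
                 sigma = if (is.null(sigma)) NULL else as.numeric(sigma),
                 metadata = metadata), class = "scattering_curve")
}

#' Guinier fit with self-consistent window selection
#'
#' Weighted linear regression of `ln I` on `q^2` over a low-q window chosen
#' self-consistently: starting from the lowest usable q, the window is the
#' largest prefix satisfying `q_max * R_G(fit) <= limit`, iterating
#' window -> fit -> window until stable (at most 50 rounds, with stall
#' detection).  `R_G = sqrt(3 |slope|)`; the standard error follows by
#' error propagation.  Fits are sigma-weighted when uncertainties are
#' present, unweighted otherwise.
#'
#' @param curve a [scattering_curve()].
#' @param limit dimensionless validity bound on `q_max * R_G`; 1.3 is the
#'   customary SAXS limit, 1.1 the stricter SANS one.
#' @param min_points smallest admissible window (default 5).
#' @return list of class `guinier_result`: `R_G`, `R_G_se`, `I0`, `window`
#'   (q_min, q_max), `limit`, `qmaxRG` (realized product), `n_points`,
#'   `weighted`.
#' @export
guinier_fit <- function(curve, limit = 1.3, min_points = 5L) {
  stopifnot(inherits(curve, "scattering_curve"))
  usable <- curve$I > 0
  q <- curve$q[usable]
  I <- curve$I[usable]
  sg <- if (!is.null(curve$sigma)) curve$sigma[usable] else NULL
  if (length(q) < 8L) stop("need at least 8 usable low-q points")
  w <- if (!is.null(sg) && all(sg > 0)) (I / sg)^2 else rep(1, length(q))
  fit_window <- function(n) {
    idx <- seq_len(n)
    fm <- stats::lm(log(I[idx]) ~ I(q[idx]^2), weights = w[idx])
    slope <- stats::coef(fm)[[2L]]
    if (!is.finite(slope) || slope >= 0) return(NULL)
    se_slope <- suppressWarnings(sqrt(stats::vcov(fm)[2L, 2L]))
    R_G <- sqrt(-3 * slope)
    list(R_G = R_G, R_G_se = 3 * se_slope / (2 * R_G),
         I0 = exp(stats::coef(fm)[[1L]]))
  }
  n <- length(q)       # start wide, shrink self-consistently
  seen <- integer(0)
  fit <- NULL
  for (round in seq_len(50L)) {
    fit <- fit_window(n)
    if (is.null(fit)) stop("Guinier fit failed: non-negative slope in window")
    n_new <- sum(q * fit$R_G <= limit)
    n_new <- min(max(n_new, min_points), length(q))
    if (n_new == n) break
    if (n_new %in% seen) {            # oscillation: take the smaller window
      n <- min(n, n_new)
      fit <- fit_window(n)
      break
    }
    seen <- c(seen, n)
    n <- n_new
  }
  if (is.null(fit) || n < min_points) {
    stop("no stable Guinier window with >= ", min_points, " points")
  }
  qmax <- q[n]
  structure(list(R_G = fit$R_G, R_G_se = fit$R_G_se, I0 = fit$I0,
                 window = c(q_min = q[1L], q_max = qmax), limit = limit,
                 qmaxRG = qmax * fit$R_G, n_points = n,
                 weighted = !is.null(sg) && all(sg > 0)),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier fit: R_G = %.3f +/- %.3f A, I0 = %.4g, %d points, qmax*R_G = %.3f (limit %.2f)\n",
              x$R_G, x$R_G_se, x$I0, x$n_points, x$qmaxRG, x$limit))
  invisible(x)
}

#' Guinier-Porod (generalized Gauss) fit
#'
#' Least-squares fit of the C1-continuous two-regime model over
#' `(G, R_G, d)`: Guinier exponential below the crossover
#' `Q1 = sqrt(3 d / 2) / R_G` and a `q^-d` power law above, with the
#' power-law prefactor fixed by continuity of the intensity and its first
#' derivative.  The fit runs in log-intensity space, sigma-weighted when
#' uncertainties are available, with multi-start over
#' `d in {1.5, 2, 3, 4}` and best-residual selection.
#'
#' @param curve a [scattering_curve()].
#' @param d_bounds admissible exponent range (default `c(1, 4.5)`); a fit
#'   pinned at a bound raises a warning.
#' @return list of class `guinier_porod_result`: `G`, `R_G`, `d`, `Q1`,
#'   `residual` (weighted SSR in log space), `converged`.
#' @export
guinier_porod_fit <- function(curve, d_bounds = c(1, 4.5)) {
  stopifnot(inherits(curve, "scattering_curve"))
  usable <- curve$I > 0
  q <- curve$q[usable]
  I <- curve$I[usable]
  sg <- if (!is.null(curve$sigma)) curve$sigma[usable] else NULL
  w <- if (!is.null(sg) && all(sg > 0)) (I / sg)^2 else rep(1, length(q))
  logI <- log(I)
  obj <- function(p) {
    m <- .guinier_porod_intensity(q, exp(p[1L]), exp(p[2L]), p[3L])
    sum(w * (logI - log(m))^2)
  }
  rg0 <- tryCatch(guinier_fit(curve)$R_G, error = function(e) 1 / stats::median(q))
  g0 <- I[1L]
  best <- NULL
  for (d0 in c(1.5, 2, 3, 4)) {
    op <- tryCatch(
      stats::optim(c(log(g0), log(rg0), d0), obj, method = "L-BFGS-B",
                   lower = c(-Inf, log(1e-3), d_bounds[1L]),
                   upper = c(Inf, log(1e6), d_bounds[2L]),
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  if (is.null(best)) stop("Guinier-Porod fit did not converge")
  d_hat <- best$par[3L]
  if (abs(d_hat - d_bounds[1L]) < 1e-6 || abs(d_hat - d_bounds[2L]) < 1e-6) {
    warning("power-law exponent d pinned at its bound")
  }
  R_G <- exp(best$par[2L])
  structure(list(G = exp(best$par[1L]), R_G = R_G, d = d_hat,
                 Q1 = sqrt(3 * d_hat / 2) / R_G, residual = best$value,
                 converged = best$convergence == 0L),
            class = "guinier_porod_result")
}

#' @export
print.guinier_porod_result <- function(x, ...) {
  cat(sprintf("Guinier-Porod fit: R_G = %.3f A, d = %.3f, G = %.4g, Q1 = %.4f 1/A (residual %.4g)\n",
              x$R_G, x$d, x$G, x$Q1, x$residual))
  invisible(x)
}

#' Dimensionless Kratky transform
#'
#' Computes `x = q R_G`, `y = (q R_G)^2 I(q) / I0`.  A peak is reported as
#' the interior argmax of a 3-point running-median smoothed y when such an
#' interior maximum exists (strictly above both smoothed endpoints);
#' otherwise the curve is flagged peakless.  For an ideal Guinier curve the
#' peak sits at `q R_G = sqrt(3) ~ 1.732`.
#'
#' @param curve a [scattering_curve()].
#' @param R_G radius of gyration (Angstrom), > 0.
#' @param I0 forward intensity, > 0.
#' @return list of class `kratky_curve`: `x`, `y`, `peak_x` (or NA),
#'   `has_peak`.
#' @export
kratky_transform <- function(curve, R_G, I0) {
  stopifnot(inherits(curve, "scattering_curve"))
  .stopifnot_scalar_pos(R_G, "R_G")
  .stopifnot_scalar_pos(I0, "I0")
  x <- curve$q * R_G
  y <- x^2 * curve$I / I0
  ys <- stats::runmed(y, 3L)
  i <- which.max(ys)
  n <- length(ys)
  prom <- 1e-6 * max(abs(ys))        # guards against float jitter on flat curves
  has_peak <- i > 1L && i < n && ys[i] > ys[1L] + prom && ys[i] > ys[n] + prom
  structure(list(x = x, y = y, peak_x = if (has_peak) x[i] else NA_real_,
                 has_peak = has_peak), class = "kratky_curve")
}

#' Tabulate Guinier / Guinier-Porod results across conditions
#'
#' @param results list of entries, each a list with elements `condition`,
#'   `guinier` (a `guinier_result`) and `gp` (a `guinier_porod_result`);
#'   `gp` may be NULL.
#' @return data.frame (class `condition_table`) with one row per condition
#'   and attributes `rg_nondecreasing`, `rg_nonincreasing`,
#'   `d_nondecreasing`, `d_nonincreasing` flagging monotone trends (within
#'   one propagated SE for R_G).
#' @export
compare_conditions <- function(results) {
  if (!length(results)) stop("no conditions supplied")
  rows <- lapply(results, function(r) {
    data.frame(condition = r$condition,
               R_G = r$guinier$R_G, R_G_se = r$guinier$R_G_se,
               d = if (!is.null(r$gp)) r$gp$d else NA_real_,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  mono <- function(v, tol = 0) {
    if (length(v) < 2L || anyNA(v)) return(c(up = NA, down = NA))
    dd <- diff(v)
    c(up = all(dd >= -tol), down = all(dd <= tol))
  }
  se_tol <- if (nrow(tab) > 1L) stats::na.omit(tab$R_G_se) else 0
  mrg <- mono(tab$R_G, tol = if (length(se_tol)) max(se_tol) else 0)
  md <- mono(tab$d)
  attr(tab, "rg_nondecreasing") <- unname(mrg["up"])
  attr(tab, "rg_nonincreasing") <- unname(mrg["down"])
  attr(tab, "d_nondecreasing") <- unname(md["up"])
  attr(tab, "d_nonincreasing") <- unname(md["down"])
  class(tab) <- c("condition_table", "data.frame")
  tab
}
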