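# Surface-occupancy normalization and dose-response analysis of
# cryoprotection assays: carboxyfluorescein (CF) leakage from liposomes,
# LDH activity retention, and electrolyte-leakage freezing tolerance (LT50).

# Default head-group areas (nm^2) for the inner-chloroplast-membrane mimic
# lipids.  These are packaged literature-style defaults, configurable per
# call; they are inputs of the geometry, not fitted quantities.
.DEFAULT_HEAD_AREAS <- c(MGDG = 0.66, DGDG = 0.80, SQDG = 0.66, EPG = 0.64)

#' Liposome geometry
#'
#' @param fractions named numeric vector of lipid mole fractions (sum 1);
#'   default the inner-chloroplast-membrane mimic 40% MGDG, 30% DGDG,
#'   15% SQDG, 15% EPG.
#' @param radius_nm hydrodynamic radius of the vesicle (nm); default 50
#'   (100 nm extrusion pore).
#' @param thickness_nm bilayer thickness `d_bl` (nm); default 4.
#' @param head_area_nm2 named per-species head-group areas (nm^2);
#'   defaults packaged, overridable.
#' @return list of class `liposome_geometry`.
#' @export
liposome_geometry <- function(fractions = c(MGDG = 0.4, DGDG = 0.3,
                                            SQDG = 0.15, EPG = 0.15),
                              radius_nm = 50, thickness_nm = 4,
                              head_area_nm2 = NULL) {
  if (abs(sum(fractions) - 1) > 1e-6) stop("lipid fractions must sum to 1")
  if (is.null(head_area_nm2)) {
    head_area_nm2 <- .DEFAULT_HEAD_AREAS[names(fractions)]
    if (anyNA(head_area_nm2)) stop("no default head-group area for: ",
                                   paste(names(fractions)[is.na(head_area_nm2)],
                                         collapse = ", "))
  }
  if (length(head_area_nm2) != length(fractions)) {
    stop("one head-group area per lipid species required")
  }
  if (any(head_area_nm2 <= 0)) stop("head-group areas must be > 0")
  if (radius_nm <= thickness_nm || thickness_nm <= 0) {
    stop("need radius > bilayer thickness > 0")
  }
  structure(list(fractions = fractions, radius_nm = radius_nm,
                 thickness_nm = thickness_nm,
                 head_area_nm2 = head_area_nm2),
            class = "liposome_geometry")
}

#' Lipids per vesicle
#'
#' Composition-weighted count of lipids in a spherical unilamellar vesicle:
#' outer plus inner leaflet area divided by the per-species head-group
#' area, `n_l,tot = sum_l f_l [4 pi R^2 + 4 pi (R - d_bl)^2] / a_l`.
#'
#' @param geom a [liposome_geometry()].
#' @return total lipid count (not rounded).
#' @export
lipids_per_vesicle <- function(geom) {
  stopifnot(inherits(geom, "liposome_geometry"))
  R <- geom$radius_nm
  d <- geom$thickness_nm
  area <- 4 * pi * R^2 + 4 * pi * (R - d)^2
  sum(geom$fractions * area / geom$head_area_nm2)
}

#' Target surface occupancy of a protectant
#'
#' The fraction of the target surface area theoretically covered by the
#' protectant at a given protectant:target ratio, normalizing dose by both
#' molecular mass and size.  The protectant contact area is the disc
#' `a_prot = pi R_S,prot^2`; the target area is the sphere
#' `a_target = 4 pi R_S,target^2`.  For liposome targets the lipid mass
#' concentration is converted to vesicles through the per-vesicle lipid
#' count, giving
#' `occupancy = c_prot a_prot n_l,tot MW_lipid / (a_target c_lipid MW_prot)`;
#' for protein targets (LDH by default, R_S = 4.3 nm)
#' `occupancy = c_prot a_prot MW_target / (a_target c_target MW_prot)`.
#'
#' @param c_prot_mg_ml protectant concentration (mg/mL).
#' @param R_S_prot_nm protectant hydrodynamic radius (nm).
#' @param MW_prot molar mass of the protectant (g/mol).
#' @param target `"liposome"` or `"protein"`.
#' @param geometry a [liposome_geometry()] (liposome target).
#' @param c_lipid_mg_ml lipid concentration (mg/mL, liposome target).
#' @param MW_lipid mean lipid molar mass (g/mol, liposome target).
#' @param c_target_mg_ml target protein concentration (mg/mL).
#' @param MW_target target protein molar mass (g/mol; default tetrameric
#'   LDH, 140000).
#' @param R_S_target_nm target protein radius (nm; default 4.3, LDH).
#' @return dimensionless occupancy (can exceed 1 at protein excess).
#' @export
surface_occupancy <- function(c_prot_mg_ml, R_S_prot_nm, MW_prot,
                              target = c("liposome", "protein"),
                              geometry = liposome_geometry(),
                              c_lipid_mg_ml = NULL, MW_lipid = NULL,
                              c_target_mg_ml = NULL, MW_target = 140000,
                              R_S_target_nm = 4.3) {
  target <- match.arg(target)
  for (v in c(c_prot_mg_ml, R_S_prot_nm, MW_prot)) {
    if (any(v <= 0)) stop("protectant parameters must be positive")
  }
  a_prot <- pi * R_S_prot_nm^2
  if (target == "liposome") {
    if (is.null(c_lipid_mg_ml) || is.null(MW_lipid)) {
      stop("liposome target needs c_lipid_mg_ml and MW_lipid")
    }
    if (any(c_lipid_mg_ml <= 0)) stop("zero target concentration")
    a_target <- 4 * pi * geometry$radius_nm^2
    n_tot <- lipids_per_vesicle(geometry)
    c_prot_mg_ml * a_prot * n_tot * MW_lipid /
      (a_target * c_lipid_mg_ml * MW_prot)
  } else {
    if (is.null(c_target_mg_ml)) stop("protein target needs c_target_mg_ml")
    if (any(c_target_mg_ml <= 0)) stop("zero target concentration")
    a_target <- 4 * pi * R_S_target_nm^2
    c_prot_mg_ml * a_prot * MW_target / (a_target * c_target_mg_ml * MW_prot)
  }
}

#' Carboxyfluorescein leakage percentage
#'
#' Self-quenching release normalization
#' `100 (F_post - F_pre) / (F_triton - F_pre)`, where F_pre/F_post are the
#' fluorescence readings before/after the freeze-thaw cycle and F_triton
#' after full detergent lysis.  Clipped to `[0, 100]`; the raw value is
#' kept as attribute `raw`.
#'
#' @param F_pre,F_post,F_triton fluorescence readings,
#'   `F_triton > F_pre >= 0`.
#' @return leakage percentage(s) with attribute `raw`.
#' @export
cf_leakage_percent <- function(F_pre, F_post, F_triton) {
  if (any(F_pre < 0)) stop("F_pre must be >= 0")
  if (any(F_triton <= F_pre)) stop("F_triton must exceed F_pre")
  raw <- 100 * (F_post - F_pre) / (F_triton - F_pre)
  out <- pmin(pmax(raw, 0), 100)
  attr(out, "raw") <- raw
  out
}

#' Four-parameter logistic dose-response fit (Hill slope 1)
#'
#' Least-squares fit of
#' `y = low + (high - low) / (1 + 10^(logEC50 - x))` with multi-start
#' initialization from data quantiles.  `low`/`high` are the low-x and
#' high-x asymptotes, which accommodates descending CF-leakage curves and
#' ascending electrolyte-leakage curves in one model.  For CF assays on a
#' log10-occupancy abscissa the high-x asymptote is the stabilization
#' capacity.
#'
#' @param x abscissa (log10 occupancy, or temperature for LT50 data);
#'   >= 5 distinct values.
#' @param y response observations (replicates allowed).
#' @return list of class `dose_response_fit`: `low`, `high`, `logEC50`,
#'   per-parameter `se`, `residuals`, `fitted` function, `capacity`
#'   (alias of `high`), `degenerate` flag, `ec50_in_range` flag.
#' @export
dose_response_fit <- function(x, y) {
  if (length(unique(x)) < 5L) stop("need >= 5 distinct x values")
  if (length(x) != length(y)) stop("x/y length mismatch")
  if (stats::sd(y) < .Machine$double.eps^0.5 * (abs(mean(y)) + 1)) {
    m <- mean(y)
    warning("constant response: degenerate fit")
    return(structure(list(low = m, high = m, logEC50 = NA_real_,
                          se = c(low = NA, high = NA, logEC50 = NA),
                          residuals = y - m,
                          fitted = function(x) rep(m, length(x)),
                          capacity = m, degenerate = TRUE,
                          ec50_in_range = NA), class = "dose_response_fit"))
  }
  df <- data.frame(x = x, y = y)
  lo_q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  y_lo <- mean(y[x <= stats::quantile(x, 0.2)])
  y_hi <- mean(y[x >= stats::quantile(x, 0.8)])
  best <- NULL
  for (e0 in lo_q) {
    fm <- tryCatch(
      suppressWarnings(
        stats::nls(y ~ low + (high - low) / (1 + 10^(logEC50 - x)),
                   data = df, start = list(low = y_lo, high = y_hi, logEC50 = e0),
                   control = stats::nls.control(maxiter = 200L, warnOnly = TRUE),
                   algorithm = "port")),
      error = function(e) NULL)
    if (!is.null(fm)) {
      rss <- sum(stats::residuals(fm)^2)
      if (is.null(best) || rss < best$rss) best <- list(fm = fm, rss = rss)
    }
  }
  if (is.null(best)) stop("dose-response fit did not converge")
  co <- stats::coef(best$fm)
  se <- tryCatch(sqrt(diag(stats::vcov(best$fm))),
                 error = function(e) rep(NA_real_, 3L))
  in_range <- co[["logEC50"]] >= min(x) && co[["logEC50"]] <= max(x)
  if (!in_range) warning("fitted EC50 lies outside the data range")
  structure(list(low = co[["low"]], high = co[["high"]],
                 logEC50 = co[["logEC50"]],
                 se = c(low = se[[1L]], high = se[[2L]], logEC50 = se[[3L]]),
                 residuals = stats::residuals(best$fm),
                 fitted = function(x) .logistic4(x, co[["low"]], co[["high"]],
                                                 co[["logEC50"]]),
                 capacity = co[["high"]], degenerate = FALSE,
                 ec50_in_range = in_range), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("4PL fit: low = %.3f, high = %.3f, logEC50 = %.4f\n",
              x$low, x$high, x$logEC50))
  invisible(x)
}

#' LT50 from electrolyte-leakage conductivity tables
#'
#' Leakage per sample is `100 * cond_before / cond_after` (conductivity
#' before / after boiling); it is normalized to the unfrozen control by
#' `100 (L - L0) / (100 - L0)` with L0 the mean control leakage, then
#' fitted per genotype by the four-parameter logistic against temperature.
#' LT50 is the fitted EC50: the temperature releasing 50% of the span of
#' electrolytes.
#'
#' @param table data.frame with columns `temperature_C`, `cond_before`,
#'   `cond_after`, optional `genotype`, `replicate`, and either a logical
#'   `control` column or unfrozen controls identified as the maximum
#'   temperature rows.
#' @return data.frame of class `freezing_tolerance`: one row per genotype
#'   with `lt50_C`, `lt50_se`, `n_replicates`, plus attribute `fits`.
#' @export
lt50_from_electrolyte_leakage <- function(table) {
  need <- c("temperature_C", "cond_before", "cond_after")
  if (!all(need %in% names(table))) {
    stop("table needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(table$genotype)) table$genotype <- "sample"
  if (is.null(table$control)) {
    table$control <- table$temperature_C == max(table$temperature_C)
  }
  if (!any(table$control)) stop("no unfrozen control rows present")
  out <- list(); fits <- list()
  for (g in unique(table$genotype)) {
    tb <- table[table$genotype == g, ]
    if (length(unique(tb$temperature_C[!tb$control])) < 5L) {
      stop("need >= 5 test temperatures for genotype ", g)
    }
    leak <- 100 * tb$cond_before / tb$cond_after
    L0 <- mean(leak[tb$control])
    norm <- 100 * (leak - L0) / (100 - L0)
    fit <- dose_response_fit(tb$temperature_C, norm)
    if (is.finite(fit$logEC50) &&
        (fit$logEC50 < min(tb$temperature_C) ||
         fit$logEC50 > max(tb$temperature_C))) {
      warning("LT50 outside the tested temperature range for ", g)
    }
    out[[g]] <- data.frame(genotype = g, lt50_C = fit$logEC50,
                           lt50_se = unname(fit$se["logEC50"]),
                           n_replicates = length(unique(tb$replicate %||% 1L)),
                           stringsAsFactors = FALSE)
    fits[[g]] <- fit
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "fits") <- fits
  class(res) <- c("freezing_tolerance", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalized LDH activity retention
#'
#' Divides each activity by the unfrozen no-protectant control and averages
#' over technical replicates with standard errors.
#'
#' @param activities data.frame with columns `variant`, `occupancy`,
#'   `cycle`, `replicate`, `activity`.
#' @param unfrozen_control positive scalar: mean activity of the unfrozen
#'   control without protectant.
#' @return data.frame with one row per (variant, occupancy, cycle):
#'   `retention`, `retention_se`, `n`.
#' @export
ldh_retention <- function(activities, unfrozen_control) {
  if (!is.numeric(unfrozen_control) || unfrozen_control <= 0) {
    stop("`unfrozen_control` must be > 0")
  }
  need <- c("variant", "occupancy", "cycle", "activity")
  if (!all(need %in% names(activities))) {
    stop("activities needs columns: ", paste(need, collapse = ", "))
  }
  key <- interaction(activities$variant, activities$occupancy,
                     activities$cycle, drop = TRUE)
  agg <- lapply(split(activities, key), function(g) {
    r <- g$activity / unfrozen_control
    data.frame(variant = g$variant[1L], occupancy = g$occupancy[1L],
               cycle = g$cycle[1L], retention = mean(r),
               retention_se = if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else NA_real_,
               n = length(r), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, agg)
  rownames(res) <- NULL
  res[order(res$variant, res$occupancy, res$cycle), , drop = FALSE]
}
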