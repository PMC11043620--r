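# Orchestration and file I/O: scattering/correlogram/assay file formats,
# run configuration, the end-to-end synthetic pipeline and JSON reporting.

#' Read an ASCII scattering curve
#'
#' Parses the common `.dat` dialect: 2-3 whitespace- or comma-delimited
#' columns (q, I[, sigma]), `#` comment lines and blank lines skipped.
#' Rows with non-positive intensity are dropped with a warning carrying the
#' count.  nm^-1 input is converted to the package-standard 1/Angstrom.
#'
#' @param path input file.
#' @param units `"A^-1"` (default) or `"nm^-1"`.
#' @return A [scattering_curve()].
#' @export
read_scattering_file <- function(path, units = c("A^-1", "nm^-1")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no data rows in ", path)
  fields <- strsplit(lines, "[,[:space:]]+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L || ncol[1L] < 2L) stop("need >= 2 numeric columns")
  mat <- matrix(as.numeric(unlist(fields)), ncol = ncol[1L], byrow = TRUE)
  if (anyNA(mat)) stop("non-numeric data in ", path)
  q <- mat[, 1L]
  if (units == "nm^-1") q <- q / 10
  keep <- mat[, 2L] > 0
  if (any(!keep)) warning(sum(!keep), " rows with non-positive intensity dropped")
  if (any(diff(q[keep]) <= 0)) stop("q values are not strictly increasing")
  scattering_curve(q[keep], mat[keep, 2L],
                   sigma = if (ncol[1L] >= 3L) mat[keep, 3L] else NULL,
                   metadata = list(path = path, input_units = units))
}

#' Write a scattering curve as 3-column ASCII
#'
#' @param curve a [scattering_curve()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scattering_file <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  sg <- curve$sigma %||% rep(0, length(curve$q))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# q[A^-1] I sigma", con)
  writeLines(sprintf("%.17g %.17g %.17g", curve$q, curve$I, sg), con)
  invisible(path)
}

#' Write / read a correlogram as CSV
#'
#' Columns `tau_s`, `g2m1`; instrument settings are stored in `#key=value`
#' header comments.
#'
#' @param corr a [correlogram()].
#' @param path file path.
#' @return `path` (write) or a [correlogram()] (read).
#' @export
write_correlogram_csv <- function(corr, path) {
  stopifnot(inherits(corr, "correlogram"))
  con <- file(path, "w")
  on.exit(close(con))
  inst <- corr$instrument
  for (k in names(inst)) writeLines(sprintf("#%s=%.17g", k, inst[[k]]), con)
  writeLines("tau_s,g2m1", con)
  writeLines(sprintf("%.17g,%.17g", corr$tau_s, corr$g2m1), con)
  invisible(path)
}

#' @rdname write_correlogram_csv
#' @export
read_correlogram_csv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#", "", hdr), "=")
  inst <- dls_instrument()
  for (p in kv) if (p[1L] %in% names(inst)) inst[[p[1L]]] <- as.numeric(p[2L])
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  correlogram(df$tau_s, df$g2m1, inst)
}

# ---------------------------------------------------------------------------
# Run configuration

.KNOWN_STAGES <- c("simulate", "traj", "guinier", "gpfit", "kratky", "dls",
                   "sls", "occupancy", "dose", "lt50", "cd")

.CONFIG_KEYS <- c("stages", "seed", "out_dir", "n_res", "n_frames",
                  "n_chains", "unravel_rate", "core_span", "R_G", "d",
                  "noise_frac", "guinier_limit", "dls_components",
                  "dls_noise", "monomer_mass", "oligomer_state",
                  "dose_truth", "lt50_truth", "theta222", "occupancy_inputs")

#' Validate a pipeline run configuration
#'
#' Unknown keys are rejected before any computation; every stochastic stage
#' draws from sub-seeds derived deterministically from the single `seed`.
#'
#' @param config named list of configuration entries; see `.CONFIG_KEYS`
#'   in the source for the accepted keys.  Minimal config: `seed`,
#'   `out_dir`.
#' @return the validated config (class `run_config`) with defaults filled.
#' @export
run_config <- function(config = list()) {
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(stages = .KNOWN_STAGES, seed = 1L, out_dir = tempfile("idpcryo_run_"),
                   n_res = 89L, n_frames = 30L, n_chains = 2L,
                   unravel_rate = 0.15, core_span = NULL, R_G = 30, d = 2,
                   noise_frac = 0.01, guinier_limit = 1.3,
                   dls_components = data.frame(R_S_nm = 2.6, weight = 1),
                   dls_noise = 1e-4, monomer_mass = 32500,
                   oligomer_state = 2,
                   dose_truth = list(low = 80, high = 20, logEC50 = 0),
                   lt50_truth = list(low = 95, high = 5, logEC50 = -8),
                   theta222 = -17490,
                   occupancy_inputs = list(c_prot_mg_ml = 1, R_S_prot_nm = 2.6,
                                           MW_prot = 32500,
                                           c_lipid_mg_ml = 0.32,
                                           MW_lipid = 800))
  cfg <- utils::modifyList(defaults, config)
  bad <- setdiff(cfg$stages, .KNOWN_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.numeric(cfg$seed)) stop("`seed` must be an integer")
  class(cfg) <- "run_config"
  cfg
}

#' Run the synthetic end-to-end pipeline
#'
#' Generates the synthetic study inputs with known ground truth and runs
#' every requested analysis stage in dependency order, writing TSV/JSON
#' artifacts under `config$out_dir`.  Re-running with the same seeds gives
#' byte-identical numeric outputs.  Logging goes to standard error.
#'
#' @param config a [run_config()] (or plain list passed through it).
#' @param quiet suppress progress messages (default FALSE).
#' @return list of stage results (class `pipeline_result`), invisibly
#'   including the report path.
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- function(...) if (!quiet) message(sprintf(...))
  sub_seed <- function(stage) {
    (as.integer(cfg$seed) * 1009L + sum(utf8ToInt(stage))) %% 2147483647L
  }
  results <- list()

  needs <- function(stage) stage %in% cfg$stages
  sim <- NULL
  if (any(c("simulate", "traj", "guinier", "gpfit", "kratky", "dls", "sls") %in% cfg$stages)) {
    log("stage simulate: seed %d", sub_seed("simulate"))
    hc <- helix_coil_params(cfg$n_res, cfg$n_frames, n_chains = cfg$n_chains,
                            unravel_rate = cfg$unravel_rate,
                            core_span = cfg$core_span,
                            seed = sub_seed("simulate"))
    traj <- make_helix_coil_trajectory(hc)
    gp <- guinier_porod_truth(cfg$R_G, cfg$d, noise_frac = cfg$noise_frac,
                              seed = sub_seed("simulate"))
    curve <- make_guinier_porod_curve(gp)
    dls_t <- dls_truth(cfg$dls_components, noise = cfg$dls_noise,
                       seed = sub_seed("simulate"))
    corr <- make_dls_correlogram(dls_t)
    sim <- list(trajectory = traj, curve = curve, correlogram = corr)
    if (needs("simulate")) {
      write_pdb_trajectory(traj, file.path(cfg$out_dir, "trajectory.pdb"))
      write_scattering_file(curve, file.path(cfg$out_dir, "scattering.dat"))
      write_correlogram_csv(corr, file.path(cfg$out_dir, "correlogram.csv"))
      results$simulate <- list(n_frames = n_frames(traj),
                               n_q = length(curve$q),
                               n_tau = length(corr$tau_s))
    }
  }
  if (needs("traj")) {
    log("stage traj")
    cm <- contact_probability_map(sim$trajectory)
    hel <- assign_helicity(sim$trajectory)
    ref <- trajectory_frame(sim$trajectory, 1L)
    rms <- rmsd_timeseries(sim$trajectory, ref)
    utils::write.table(round(cm$probability, 6),
                       file.path(cfg$out_dir, "contact_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE, na = "NA")
    utils::write.table(data.frame(frame = seq_along(rms), rmsd_A = round(rms, 6),
                                  helix_fraction = round(hel$helix_fraction, 6)),
                       file.path(cfg$out_dir, "timeline.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$traj <- list(
      mean_helix_fraction = mean(hel$helix_fraction),
      final_rmsd_A = rms[length(rms)],
      n_top_contacts = nrow(top_contacts(cm, 0.75)),
      units = list(rmsd = "Angstrom"))
  }
  gu <- NULL
  if (needs("guinier") || needs("kratky")) {
    log("stage guinier")
    gu <- guinier_fit(sim$curve, limit = cfg$guinier_limit)
    results$guinier <- list(R_G_A = gu$R_G, R_G_se_A = gu$R_G_se,
                            qmaxRG = gu$qmaxRG, limit = gu$limit,
                            n_points = gu$n_points, units = list(R_G = "Angstrom"))
  }
  if (needs("gpfit")) {
    log("stage gpfit")
    gp_fit <- guinier_porod_fit(sim$curve)
    results$gpfit <- list(R_G_A = gp_fit$R_G, d = gp_fit$d,
                          Q1_invA = gp_fit$Q1, residual = gp_fit$residual,
                          units = list(R_G = "Angstrom", Q1 = "1/Angstrom"))
  }
  if (needs("kratky")) {
    log("stage kratky")
    kr <- kratky_transform(sim$curve, gu$R_G, gu$I0)
    utils::write.table(data.frame(qRG = round(kr$x, 6), y = round(kr$y, 6)),
                       file.path(cfg$out_dir, "kratky.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$kratky <- list(peak_qRG = kr$peak_x, has_peak = kr$has_peak)
  }
  if (needs("dls")) {
    log("stage dls")
    cu <- cumulant_fit(sim$correlogram)
    results$dls <- list(R_S_nm = cu$R_S_nm, D_m2_s = cu$D_m2_s,
                        PDI = cu$PDI, method = cu$method,
                        units = list(R_S = "nm", D = "m^2/s"))
  }
  if (needs("sls")) {
    log("stage sls")
    conc <- c(1, 2, 3, 4, 5)
    ser <- make_sls_series(cfg$monomer_mass * cfg$oligomer_state, conc,
                           interaction_slope = -0.01)
    m_app <- apparent_mass(ser$intensity_ratio, ser$c_mg_ml)
    ext <- extrapolate_zero_concentration(ser$c_mg_ml, m_app)
    results$sls <- list(M_g_mol = ext$intercept, M_se = ext$intercept_se,
                        M_rel = ext$intercept / cfg$monomer_mass,
                        units = list(M = "g/mol"))
  }
  if (needs("occupancy")) {
    log("stage occupancy")
    oi <- cfg$occupancy_inputs
    occ <- surface_occupancy(oi$c_prot_mg_ml, oi$R_S_prot_nm, oi$MW_prot,
                             target = "liposome",
                             c_lipid_mg_ml = oi$c_lipid_mg_ml,
                             MW_lipid = oi$MW_lipid)
    results$occupancy <- list(occupancy = occ,
                              inputs = oi, units = list(occupancy = "dimensionless"))
  }
  if (needs("dose")) {
    log("stage dose: seed %d", sub_seed("dose"))
    dt <- cfg$dose_truth
    at <- assay_truth(dt$low, dt$high, dt$logEC50,
                      x_values = seq(-2, 2, length.out = 12L),
                      replicate_sd = 2, n_replicates = 3L,
                      seed = sub_seed("dose"))
    tab <- make_assay_table(at, "cf_leakage")
    fit <- dose_response_fit(tab$x, tab$y)
    results$dose <- list(capacity_pct = fit$capacity,
                         capacity_se = unname(fit$se["high"]),
                         logEC50 = fit$logEC50,
                         truth_capacity_pct = dt$high,
                         units = list(capacity = "percent CF leakage"))
  }
  if (needs("lt50")) {
    log("stage lt50: seed %d", sub_seed("lt50"))
    lt <- cfg$lt50_truth
    tab <- make_electrolyte_table(lt50 = lt$logEC50, seed = sub_seed("lt50"))
    res <- lt50_from_electrolyte_leakage(tab)
    results$lt50 <- list(lt50_C = res$lt50_C[1L], lt50_se = res$lt50_se[1L],
                         truth_lt50_C = lt$logEC50, units = list(lt50 = "deg C"))
  }
  if (needs("cd")) {
    log("stage cd")
    ch <- cd_helicity(cfg$theta222)
    results$cd <- list(f_H = ch$f_H, theta222 = cfg$theta222,
                       units = list(theta222 = "deg cm^2/dmol"))
  }
  if (!length(results)) stop("no stages produced results")
  report_path <- file.path(cfg$out_dir, "report.json")
  write_report(results, report_path)
  log("report: %s", report_path)
  out <- structure(list(results = results, report = report_path,
                        out_dir = cfg$out_dir), class = "pipeline_result")
  invisible(out)
}

#' Synthetic electrolyte-leakage conductivity table
#'
#' Forward model for the LT50 assay: five replicates over a temperature
#' ramp plus unfrozen controls, conductivities consistent with a
#' four-parameter-logistic leakage curve.
#'
#' @param lt50 true LT50 (deg C).
#' @param low,high leakage asymptotes (percent) at warm / deep-frozen ends.
#' @param temperatures test temperatures (deg C).
#' @param control_leakage leakage of the unfrozen control (percent).
#' @param n_replicates replicates per temperature.
#' @param sd replicate noise SD on leakage (percent).
#' @param genotype label column value.
#' @param seed RNG seed.
#' @return data.frame ready for [lt50_from_electrolyte_leakage()].
#' @export
make_electrolyte_table <- function(lt50, low = 95, high = 0,
                                   temperatures = seq(-20, -1, by = 1),
                                   control_leakage = 5, n_replicates = 5L,
                                   sd = 0, genotype = "synthetic", seed = 1L) {
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        temperature_C = temperatures, KEEP.OUT.ATTRS = FALSE)
    # normalized leakage follows the 4PL; invert the control normalization
    norm <- .logistic4(grid$temperature_C, low, high, lt50)
    if (sd > 0) norm <- norm + sd * stats::rnorm(nrow(grid))
    L0 <- control_leakage
    leak <- norm * (100 - L0) / 100 + L0
    ctrl <- expand.grid(replicate = seq_len(n_replicates),
                        temperature_C = 4, KEEP.OUT.ATTRS = FALSE)
    ctrl_leak <- rep(L0, nrow(ctrl))
    tab <- rbind(
      data.frame(genotype = genotype, replicate = grid$replicate,
                 temperature_C = grid$temperature_C,
                 cond_after = 100, cond_before = leak,
                 control = FALSE, stringsAsFactors = FALSE),
      data.frame(genotype = genotype, replicate = ctrl$replicate,
                 temperature_C = ctrl$temperature_C,
                 cond_after = 100, cond_before = ctrl_leak,
                 control = TRUE, stringsAsFactors = FALSE))
    tab
  })
}

#' Write a schema-versioned JSON report
#'
#' All numeric results from the pipeline stages, each stage carrying its
#' units, serialized at full precision.
#'
#' @param results non-empty named list of stage results.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (!length(results)) stop("empty stage list")
  payload <- list(schema_version = "1.0", package = "idpcryo",
                  created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stages = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
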