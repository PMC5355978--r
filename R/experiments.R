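# shallow-modify an opponent_config (rebuilds so validity checks rerun)
modify_config <- function(cfg, ...) {
  upd <- list(...)
  opponent_config(
    total_length = upd$total_length %||% cfg$geometry$l,
    r8_fraction = upd$r8_fraction %||% cfg$geometry$r8_fraction,
    degree = upd$degree %||% cfg$degree,
    flux = upd$flux %||% cfg$flux,
    sigma_in_sq = upd$sigma_in_sq %||% cfg$sigma_in_sq,
    tau_ms = upd$tau_ms %||% cfg$tau_ms,
    saturation = upd$saturation %||% cfg$saturation,
    dichroic = upd$dichroic %||% cfg$dichroic,
    array = upd$array %||% cfg$array,
    model = upd$model %||% cfg$model,
    theta_grid_n = upd$theta_grid_n %||% cfg$theta_grid_n
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all per-point metrics for one (l, r8_fraction, flux) configuration
point_metrics <- function(cfg, mi = FALSE) {
  g <- cfg$geometry
  ps7 <- polarization_sensitivity(7, g, cfg$dichroic, model = cfg$model)
  ps8 <- polarization_sensitivity(8, g, cfg$dichroic, model = cfg$model)
  st_bg <- opponent_state(cfg, 45)
  tau_s <- cfg$tau_ms / 1000
  out <- data.frame(
    ps7 = ps7, ps8 = ps8,
    snr7 = signal_range(ps7, cfg$degree) * sqrt(st_bg$m7_bg),
    snr8 = signal_range(ps8, cfg$degree) * sqrt(st_bg$m8_bg),
    delta_q = opponent_signal_range(cfg),
    delta_s = discriminable_angles(cfg)
  )
  # m*_bg are already counts per tau, so sqrt(count) is the Poisson SD
  if (mi) out$mi_bits <- mutual_information(cfg)
  out
}

#' Sweep metrics over the R8 length fraction
#'
#' Evaluates polarization sensitivities, SNRs, opponent signal range and
#' number of discriminable angles (optionally mutual information) on a
#' grid of R8 length fractions, for one or more incident fluxes.
#'
#' @param cfg Base [opponent_config()]; its `r8_fraction` and `flux` are
#'   overridden by the grids.
#' @param r8_fractions Grid of R8 length fractions in (0, 1).
#' @param flux_values Incident photon fluxes, photons s^-1.
#' @param mi Logical; also compute mutual information (slower)?
#' @return A data.frame with one row per (fraction, flux) combination,
#'   carrying the settings and all metric columns.
#' @export
#' @examples
#' sw <- sweep_length_fraction(opponent_config(),
#'                             r8_fractions = seq(0.1, 0.9, 0.2))
sweep_length_fraction <- function(cfg = opponent_config(),
                                  r8_fractions = seq(0.01, 0.99, by = 0.01),
                                  flux_values = cfg$flux, mi = FALSE) {
  stopifnot(all(r8_fractions > 0 & r8_fractions < 1),
            all(diff(r8_fractions) > 0))
  rows <- lapply(flux_values, function(ni) {
    res <- lapply(r8_fractions, function(f8) {
      point_metrics(modify_config(cfg, r8_fraction = f8, flux = ni), mi = mi)
    })
    cbind(data.frame(r8_fraction = r8_fractions, flux = ni,
                     total_length = cfg$geometry$l,
                     saturation = cfg$saturation,
                     sigma_in_sq = cfg$sigma_in_sq),
          do.call(rbind, res))
  })
  out <- do.call(rbind, rows)
  stopifnot(all(is.finite(as.matrix(out[sapply(out, is.numeric)]))))
  out
}

# golden-section maximization of f on [lo, hi] to absolute tolerance tol
golden_max <- function(f, lo, hi, tol = 1e-3) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 >= f2) {  # ties break toward the smaller argument
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
  }
  if (f1 >= f2) x1 else x2
}

#' Optimal R8 length fraction
#'
#' Grid-searches the R8 length fraction maximizing either the number of
#' discriminable polarization angles or the mutual information, then
#' refines by golden-section search to 1e-3. Ties break toward the
#' smaller fraction.
#'
#' @param metric `"delta_s"` or `"mi"`.
#' @param cfg Base [opponent_config()] (flux, noise and saturation settings
#'   are taken from it).
#' @param r8_fractions Search grid.
#' @param refine Logical; golden-section refinement after the grid search?
#' @return An object of class `optimum_report`: list with `argmax`,
#'   `value`, `resolution`, `metric`, `flat` (TRUE when the metric is
#'   constant across the grid) and the settings.
#' @export
#' @examples
#' optimal_length_fraction("delta_s", opponent_config(flux = 1e5),
#'                         r8_fractions = seq(0.05, 0.95, 0.05),
#'                         refine = FALSE)
optimal_length_fraction <- function(metric = c("delta_s", "mi"),
                                    cfg = opponent_config(),
                                    r8_fractions = seq(0.01, 0.99, by = 0.01),
                                    refine = TRUE) {
  metric <- match.arg(metric)
  eval_at <- function(f8) {
    c2 <- modify_config(cfg, r8_fraction = f8)
    if (metric == "delta_s") discriminable_angles(c2)
    else mutual_information(c2)
  }
  vals <- vapply(r8_fractions, eval_at, numeric(1))
  flat <- diff(range(vals)) <= 1e-12 * max(abs(vals), 1e-300)
  i <- which.max(vals)  # which.max returns the first (smallest) maximizer
  arg <- r8_fractions[i]
  val <- vals[i]
  res <- max(diff(r8_fractions))
  if (refine && !flat) {
    lo <- r8_fractions[max(i - 1L, 1L)]
    hi <- r8_fractions[min(i + 1L, length(r8_fractions))]
    arg <- golden_max(eval_at, lo, hi, tol = 1e-3)
    val <- eval_at(arg)
    res <- 1e-3
  }
  structure(list(argmax = arg, value = val, resolution = res,
                 metric = metric, flat = flat,
                 flux = cfg$flux, sigma_in_sq = cfg$sigma_in_sq,
                 saturation = cfg$saturation,
                 total_length = cfg$geometry$l),
            class = "optimum_report")
}

#' @export
print.optimum_report <- function(x, ...) {
  cat(sprintf("Optimum %s = %.4g at %s = %.4g (resolution %g)%s\n",
              x$metric, x$value,
              if (is.null(x$length_um)) "R8 fraction" else "length (um)",
              x$argmax, x$resolution,
              if (isTRUE(x$flat)) " [flat metric]" else ""))
  cat(sprintf("  N_i = %g photons/s, sigma_in^2 = %g, saturation %s\n",
              x$flux, x$sigma_in_sq, if (x$saturation) "on" else "off"))
  invisible(x)
}

#' Rhabdomere length maximizing single-photoreceptor SNR
#'
#' For an unconstrained single R7-type photoreceptor, SNR is
#' `2 d (PS - 1)/(PS + 1) sqrt(tau M_bg)`. Both the polarization
#' sensitivity and the quantum catch depend on length: self-screening
#' erodes PS while the catch saturates, so SNR peaks at a finite length.
#' The argmax does not depend on `d`, `tau` or the flux (they scale SNR
#' multiplicatively), which is asserted.
#'
#' @param dichroic A [dichroic_absorption()] object.
#' @param model Absorptance model.
#' @param lengths_um Search grid of rhabdomere lengths, micrometres.
#' @param report_resolution_um Reporting resolution (argmax is rounded to
#'   this grid), micrometres.
#' @return An `optimum_report` with `argmax`/`length_um` in micrometres.
#' @export
#' @examples
#' optimal_snr_length()$length_um  # 200
optimal_snr_length <- function(dichroic = dichroic_absorption(),
                               model = canonical_absorptance_model(dichroic),
                               lengths_um = seq(1, 400, by = 1),
                               report_resolution_um = 5) {
  snr_curve <- function(d, tau_s, ni) {
    fp <- absorptance(model, dichroic$k_par * lengths_um)
    fq <- absorptance(model, dichroic$k_perp * lengths_um)
    ps <- fp / fq
    m_bg <- ni * (fp + fq) / 2
    2 * d * (ps - 1) / (ps + 1) * sqrt(tau_s * m_bg)
  }
  ref <- snr_curve(0.1, 0.09, 1e5)
  # invariance of the argmax under d, tau, N_i rescaling
  stopifnot(which.max(ref) == which.max(snr_curve(0.2, 0.09, 1e5)),
            which.max(ref) == which.max(snr_curve(0.1, 0.9, 1e6)))
  i <- which.max(ref)
  arg <- round(lengths_um[i] / report_resolution_um) * report_resolution_um
  structure(list(argmax = arg, length_um = arg, value = ref[i],
                 resolution = report_resolution_um, metric = "snr7",
                 flat = FALSE, flux = NA_real_, sigma_in_sq = 0,
                 saturation = FALSE, total_length = NA_real_),
            class = "optimum_report")
}

#' Sweep metrics over total CRP length
#'
#' Evaluates the opponent signal range and the number of discriminable
#' angles over a grid of total CRP lengths with R7 and R8 kept equal
#' (`r8_fraction = 0.5`), for one or more fluxes, plus columns normalized
#' to the value at `norm_length`.
#'
#' @param cfg Base [opponent_config()].
#' @param lengths_um Grid of total lengths, micrometres.
#' @param flux_values Incident photon fluxes.
#' @param norm_length Reference length for the normalized columns.
#' @return A data.frame with columns `total_length`, `flux`, `delta_q`,
#'   `delta_s`, `delta_q_norm`, `delta_s_norm` and the settings.
#' @export
sweep_total_length <- function(cfg = opponent_config(),
                               lengths_um = seq(20, 300, by = 5),
                               flux_values = cfg$flux,
                               norm_length = 100) {
  stopifnot(all(diff(lengths_um) > 0))
  rows <- lapply(flux_values, function(ni) {
    dq <- numeric(length(lengths_um)); ds <- numeric(length(lengths_um))
    for (j in seq_along(lengths_um)) {
      c2 <- modify_config(cfg, total_length = lengths_um[j],
                          r8_fraction = 0.5, flux = ni)
      dq[j] <- opponent_signal_range(c2)
      ds[j] <- discriminable_angles(c2)
    }
    cref <- modify_config(cfg, total_length = norm_length,
                          r8_fraction = 0.5, flux = ni)
    data.frame(total_length = lengths_um, flux = ni,
               saturation = cfg$saturation, sigma_in_sq = cfg$sigma_in_sq,
               delta_q = dq, delta_s = ds,
               delta_q_norm = dq / opponent_signal_range(cref),
               delta_s_norm = ds / discriminable_angles(cref))
  })
  out <- do.call(rbind, rows)
  stopifnot(all(is.finite(as.matrix(out[sapply(out, is.numeric)]))))
  out
}

#' Benefit of elongating the CRP
#'
#' Percentage change in the number of discriminable polarization angles
#' when the CRP (equal R7/R8 halves) is extended from `l_from` to `l_to`.
#'
#' @param l_from,l_to Total CRP lengths, micrometres.
#' @param cfg Base [opponent_config()] providing flux, noise and
#'   saturation settings.
#' @return Percentage gain, `100 (delta_S(l_to)/delta_S(l_from) - 1)`.
#' @export
#' @examples
#' elongation_benefit(100, 300, opponent_config(flux = 1e5, sigma_in_sq = 0))
elongation_benefit <- function(l_from, l_to, cfg = opponent_config()) {
  s_from <- discriminable_angles(modify_config(cfg, total_length = l_from,
                                               r8_fraction = 0.5))
  s_to <- discriminable_angles(modify_config(cfg, total_length = l_to,
                                             r8_fraction = 0.5))
  100 * (s_to / s_from - 1)
}

#' Observed R8 length fractions across fly species
#'
#' Reference table of the fraction of the DRA central rhabdomere pair
#' occupied by R8 in ten Diptera species, for comparison with the model's
#' optimal band of length fractions (0.33--0.5 across light levels).
#'
#' @return A data.frame with columns `species`, `r8_fraction` and the
#'   constant columns `model_optimum_low`, `model_optimum_high`.
#' @export
#' @examples
#' species_comparison()
species_comparison <- function() {
  tab <- data.frame(
    species = c("Rhagio scolopacea", "Leptempis", "Ceratitis capitata",
                "Drosophila melanogaster", "Scatophaga stercoraria",
                "Musca domestica", "Calliphora vicina",
                "Sarcophaga carnaria", "Zeuxia", "Lipoptena cervi"),
    r8_fraction = c(0.42, 0.45, 0.37, 0.49, 0.57, 0.53, 0.42, 0.43,
                    0.48, 0.54),
    stringsAsFactors = FALSE
  )
  # Calliphora has two published values, 0.4 and 0.44; their midpoint is
  # carried in the numeric column and both are kept as a note
  tab$note <- ifelse(tab$species == "Calliphora vicina", "0.4, 0.44", "")
  tab$model_optimum_low <- 0.33
  tab$model_optimum_high <- 0.5
  tab
}

# ---- study driver -----------------------------------------------------

# canonical study configuration (defaults mirror opponent_config())
default_study_config <- function() {
  list(
    optics = list(F = 2, D_r = 1.55, k = 0.0075, delta = 10,
                  lambda_max = 335),
    transduction = list(microvilli_per_um = 360, t_d_ms = 30, tau_ms = 90,
                        segment_um = 1, saturation = FALSE),
    opponent = list(d = 0.1, sigma_in_sq = 5e-5, theta_grid_n = 900),
    sweeps = list(l = 100, flux = c(1e5, 3e5, 1e6, 3e6),
                  r8_step = 0.01, length_range = c(20, 300),
                  length_step = 5)
  )
}

#' Read a study configuration file
#'
#' YAML with sections `optics` (F, D_r, k, delta, lambda_max),
#' `transduction` (microvilli_per_um, t_d_ms, tau_ms, segment_um,
#' saturation), `opponent` (d, sigma_in_sq, theta_grid_n) and `sweeps`
#' (l, flux, r8_step, length_range, length_step). Unknown keys are an
#' error; missing keys fall back to the defaults.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_study_config()
  for (sec in names(cfg)) {
    if (!sec %in% names(defaults))
      stop("unknown config section: '", sec, "'")
    for (key in names(cfg[[sec]])) {
      if (!key %in% names(defaults[[sec]]))
        stop("unknown config key: '", sec, ".", key, "'")
      defaults[[sec]][[key]] <- cfg[[sec]][[key]]
    }
  }
  defaults
}

study_config_to_opponent <- function(sc, flux) {
  opponent_config(
    total_length = sc$sweeps$l, r8_fraction = 0.5,
    degree = sc$opponent$d, flux = flux,
    sigma_in_sq = sc$opponent$sigma_in_sq,
    tau_ms = sc$transduction$tau_ms,
    saturation = isTRUE(sc$transduction$saturation),
    dichroic = dichroic_absorption(sc$optics$k, sc$optics$delta,
                                   sc$optics$lambda_max),
    array = microvillar_array(sc$transduction$microvilli_per_um,
                              sc$transduction$t_d_ms,
                              sc$transduction$segment_um),
    theta_grid_n = sc$opponent$theta_grid_n
  )
}

#' Run the full study and write result tables
#'
#' Runs the length-fraction sweep, the total-length sweep, the optimal
#' length fraction search per flux and the species comparison, writing
#' tidy CSVs and a JSON manifest of all parameters to `out_dir`. Outputs
#' are deterministic for a given configuration.
#'
#' @param config Path to a YAML configuration file, a configuration list
#'   (see [read_study_config()]), or `NULL` for the defaults.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages?
#' @return Invisibly, the list of written file paths.
#' @export
run_study <- function(config = NULL, out_dir = "study_output",
                      quiet = FALSE) {
  sc <- if (is.null(config)) default_study_config()
        else if (is.character(config)) read_study_config(config)
        else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)

  base <- study_config_to_opponent(sc, sc$sweeps$flux[1])
  say("sweep: R8 length fraction")
  fr <- sweep_length_fraction(base,
                              seq(sc$sweeps$r8_step, 1 - sc$sweeps$r8_step,
                                  by = sc$sweeps$r8_step),
                              sc$sweeps$flux)
  say("sweep: total CRP length")
  ln <- sweep_total_length(base,
                           seq(sc$sweeps$length_range[1],
                               sc$sweeps$length_range[2],
                               by = sc$sweeps$length_step),
                           sc$sweeps$flux)
  say("optima: R8 length fraction per flux")
  opt <- do.call(rbind, lapply(sc$sweeps$flux, function(ni) {
    r <- optimal_length_fraction("delta_s",
                                 study_config_to_opponent(sc, ni),
                                 refine = FALSE)
    data.frame(flux = ni, optimum_r8_fraction = round(r$argmax, 2),
               delta_s = r$value)
  }))

  paths <- file.path(out_dir, c("fraction_sweep.csv", "length_sweep.csv",
                                "optima.csv", "species.csv",
                                "manifest.json"))
  utils::write.csv(fr, paths[1], row.names = FALSE)
  utils::write.csv(ln, paths[2], row.names = FALSE)
  utils::write.csv(opt, paths[3], row.names = FALSE)
  utils::write.csv(species_comparison(), paths[4], row.names = FALSE)
  manifest <- list(package = "tieredpol",
                   version = as.character(utils::packageVersion("tieredpol")),
                   config = sc)
  jsonlite::write_json(manifest, paths[5], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  say("wrote ", length(paths), " files to ", out_dir)
  invisible(paths)
}
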