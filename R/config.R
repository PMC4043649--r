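#' Generator configuration
#'
#' Builds the configuration object that drives the synthetic whole-blood
#' generator and the downstream pipeline defaults. The cohort statistics
#' default to the wild-type C57BL/6 reference cohort: per-population mean
#' absolute concentrations (cells/ul) with their between-animal CVs, and the
#' mean monocyte subset composition (52.4 / 7.2 / 40.4 % classical /
#' intermediate / non-classical of the MHC-II-negative monocyte compartment).
#'
#' Total monocyte concentration `total_mono_mean` is a free calibration
#' parameter (the subset composition and two of the three subset means pin the
#' third); see [calibrate_cohort_preset()].
#'
#' @param cohort_mean named numeric, mean concentration (cells/ul) per
#'   population. The intermediate-monocyte mean may be `NA`; it is implied by
#'   calibration as `total_mono_mean` minus the other two subset means.
#' @param cohort_cv named numeric, between-animal CV (SD/mean) per population.
#' @param fractions named numeric, mean monocyte subset fractions (must sum
#'   to 1 over the three MHC-II-negative subsets).
#' @param fraction_sd named numeric, between-animal SD of each subset fraction.
#' @param total_mono_mean mean total MHC-II-negative monocyte concentration
#'   (cells/ul).
#' @param total_mono_cv between-animal CV of the total monocyte concentration.
#' @param eta day-level biological noise CV (dimensionless).
#' @param tau named numeric, technical (duplicate-level) multiplicative noise
#'   CV per population; `NULL` derives defaults from the printed inter-assay
#'   CVs by Poisson deconvolution at the duplicate design (see vignette).
#' @param interassay_cv named numeric, target total inter-assay CV per
#'   population used when deriving `tau`.
#' @param beads_per_tube nominal bead count per tube (lot constant).
#' @param acq_fraction fraction of the tube content actually acquired,
#'   in (0, 1].
#' @param volume_ul default sample volume (ul).
#' @param templates population templates, see [default_templates()].
#' @param spillover spillover matrix to mix generated events with,
#'   see [default_spillover()].
#' @param cofactor bi-exponential transform cofactor (a.u.), scalar or named
#'   per channel.
#' @param kinetics kinetics anchor tables, see [default_kinetics()].
#' @param instrument_range upper intensity bound (a.u.); generated events are
#'   capped here and the cap count is flagged.
#' @param base_seed integer base seed; per-animal streams are derived as
#'   `base_seed + animal index`.
#'
#' @return An object of class `cyto_config` (a list), not yet calibrated;
#'   pass through [calibrate_cohort_preset()] before sampling animals.
#' @export
cyto_config <- function(cohort_mean = NULL,
                        cohort_cv = NULL,
                        fractions = c(classical_mono = 0.524,
                                      intermediate_mono = 0.072,
                                      nonclassical_mono = 0.404),
                        fraction_sd = c(classical_mono = 0.134,
                                        intermediate_mono = 0.027,
                                        nonclassical_mono = 0.134),
                        total_mono_mean = 240,
                        total_mono_cv = 0.5,
                        eta = 0.10,
                        tau = NULL,
                        interassay_cv = c(neutrophil = 0.038, eosinophil = 0.051,
                                          classical_mono = 0.021,
                                          intermediate_mono = 0.021,
                                          nonclassical_mono = 0.046,
                                          activated_monomac = 0.030,
                                          lymphocyte = 0.030),
                        beads_per_tube = 50000,
                        acq_fraction = 0.5,
                        volume_ul = 50,
                        templates = default_templates(),
                        spillover = default_spillover(),
                        cofactor = 150,
                        kinetics = default_kinetics(),
                        instrument_range = 262144,
                        base_seed = 20140603) {
  pops <- cyto_populations()
  if (is.null(cohort_mean)) {
    cohort_mean <- c(neutrophil = 654.2, eosinophil = 144,
                     classical_mono = 135.6, intermediate_mono = NA_real_,
                     nonclassical_mono = 86.1, activated_monomac = 18.7,
                     lymphocyte = 4267)
  }
  if (is.null(cohort_cv)) {
    cohort_cv <- c(neutrophil = 0.858, eosinophil = 0.533,
                   classical_mono = 0.688, intermediate_mono = NA_real_,
                   nonclassical_mono = 0.511, activated_monomac = 0.697,
                   lymphocyte = 0.382)
  }
  if (!all(pops %in% names(cohort_mean)) || !all(pops %in% names(cohort_cv)))
    stopf("cohort_mean and cohort_cv must cover all populations")
  if (any(cohort_cv < 0, na.rm = TRUE)) stopf("negative CV in cohort_cv")
  if (abs(sum(fractions) - 1) > 1e-9)
    stopf("monocyte subset fraction means must sum to 1 (got %g)", sum(fractions))
  if (acq_fraction <= 0 || acq_fraction > 1)
    stopf("acq_fraction must be in (0, 1]")
  if (any(cofactor <= 0)) stopf("cofactor must be > 0")
  check_templates(templates)

  cfg <- structure(list(
    populations = pops,
    cohort_mean = cohort_mean[pops],
    cohort_cv = cohort_cv[pops],
    fractions = fractions[mono_subsets()],
    fraction_sd = fraction_sd[mono_subsets()],
    total_mono_mean = total_mono_mean,
    total_mono_cv = total_mono_cv,
    eta = eta,
    tau = tau,
    interassay_cv = interassay_cv,
    beads_per_tube = beads_per_tube,
    acq_fraction = acq_fraction,
    volume_ul = volume_ul,
    templates = templates,
    spillover = spillover,
    cofactor = cofactor,
    kinetics = kinetics,
    instrument_range = instrument_range,
    base_seed = as.integer(base_seed),
    calibration = NULL
  ), class = "cyto_config")
  cfg
}

#' @export
print.cyto_config <- function(x, ...) {
  cat("<cyto_config>\n")
  cat("  populations:", paste(x$populations, collapse = ", "), "\n")
  cat(sprintf("  total monocytes E[T] = %g cells/ul (CV %.2f)\n",
              x$total_mono_mean, x$total_mono_cv))
  cat(sprintf("  volume %g ul, acquisition fraction %g, %d beads/tube\n",
              x$volume_ul, x$acq_fraction, x$beads_per_tube))
  cat(sprintf("  calibrated: %s\n", !is.null(x$calibration)))
  invisible(x)
}

#' Calibrate the cohort generator
#'
#' Solves the joint animal-level construction so that simultaneously (a) the
#' expected per-animal monocyte subset fractions equal the configured fraction
#' means and (b) the expected absolute subset concentrations equal the
#' configured cohort means. Writing `T` for the per-animal total monocyte
#' concentration and `f_s` for the subset fraction, the identity
#' `E[f_s T] = E[f_s] E[T] + cov(f_s, T)` forces `cov_s = mean_s - frac_s * E[T]`
#' with `sum(cov_s) = 0`; fractions are generated as
#' `f_s = frac_s + b_s (T - E[T]) / E[T] + e_s` with slope
#' `b_s = cov_s E[T] / Var(T)` and a mean-zero residual `e_s` (summing to zero
#' across subsets) sized so the per-subset fraction SDs match `fraction_sd`.
#'
#' The classical-monocyte covariance is positive (monocytosis is driven by the
#' Ly6C-high subset), non-classical compensates negatively. An unprinted
#' intermediate subset mean is implied as `E[T]` minus the two printed means.
#' Also derives the technical-noise CVs `tau` from the configured inter-assay
#' targets when not set explicitly (Poisson deconvolution at the duplicate
#' design: full acquisition of a `volume_ul` sample).
#'
#' @param config a [cyto_config()] object.
#' @return The config with a `calibration` element (slopes, residual SDs,
#'   implied intermediate mean, covariances) and `tau` filled in.
#' @export
calibrate_cohort_preset <- function(config) {
  stopifnot(inherits(config, "cyto_config"))
  ms <- mono_subsets()
  ET <- config$total_mono_mean
  mean_s <- config$cohort_mean[ms]
  # imply the unprinted intermediate mean from the calibration identity
  if (is.na(mean_s[["intermediate_mono"]])) {
    others <- setdiff(ms, "intermediate_mono")
    mean_s[["intermediate_mono"]] <- ET - sum(mean_s[others])
    if (mean_s[["intermediate_mono"]] <= 0)
      stopf("implied intermediate-monocyte mean is non-positive; increase total_mono_mean")
    config$cohort_mean[["intermediate_mono"]] <- mean_s[["intermediate_mono"]]
  }
  if (abs(sum(mean_s) - ET) > 1e-6 * ET)
    stopf("monocyte subset means (%.6g) must sum to total_mono_mean (%.6g)",
          sum(mean_s), ET)
  cov_s <- mean_s - config$fractions * ET
  sdT <- ET * config$total_mono_cv
  varT <- sdT^2
  if (varT == 0) {
    bad <- ms[abs(cov_s) > 1e-9 * ET]
    if (length(bad))
      stopf("calibration error: zero between-animal variance requires cov = 0 but subset '%s' implies cov = %.4g",
            bad[[1]], cov_s[[bad[[1]]]])
    b_s <- setNames(rep(0, length(ms)), ms)
  } else {
    # feasibility: |corr(f_s, T)| <= 1
    rho <- cov_s / (config$fraction_sd * sdT)
    bad <- ms[!is.finite(rho) | abs(rho) > 1]
    if (length(bad))
      stopf("calibration error: subset '%s' implies |correlation| = %.3f > 1 between its fraction and total monocytes",
            bad[[1]], abs(rho[[bad[[1]]]]))
    b_s <- cov_s * ET / varT
  }
  # residual fraction noise on top of the T-driven component
  var_from_T <- (b_s * config$total_mono_cv)^2
  resid_var <- pmax(config$fraction_sd^2 - var_from_T, 0)
  calibration <- list(
    mean_s = mean_s, cov_s = cov_s, b_s = b_s, a_s = config$fractions,
    resid_sd = sqrt(resid_var), ET = ET, sdT = sdT
  )
  config$calibration <- calibration
  # the (0,1) clamp on drawn fractions slightly distorts the subset means in
  # the far total-monocyte tail (<1%); absorb it into the intercepts with a
  # fixed-seed internal Monte-Carlo so the clamped system is mean-exact
  if (config$total_mono_cv > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    for (iter in 1:2) {
      set.seed(999983L)
      d <- draw_mono_fractions(config$calibration, 200000)
      bias <- colMeans(d$f * d$T) - mean_s
      a_new <- config$calibration$a_s - bias / ET
      config$calibration$a_s <- a_new / sum(a_new)
    }
  }
  if (is.null(config$tau)) config$tau <- derive_tau(config)
  config
}

# joint draw of total monocytes and subset fractions under a calibration
draw_mono_fractions <- function(cal, n) {
  cv_T <- cal$sdT / cal$ET
  T <- rlnorm_mean(n, cal$ET, cv_T)
  e_c <- stats::rnorm(n, 0, cal$resid_sd[["classical_mono"]])
  e_i <- stats::rnorm(n, 0, cal$resid_sd[["intermediate_mono"]])
  f <- cbind(
    classical_mono    = cal$a_s[["classical_mono"]] +
      cal$b_s[["classical_mono"]] * (T - cal$ET) / cal$ET + e_c,
    intermediate_mono = cal$a_s[["intermediate_mono"]] +
      cal$b_s[["intermediate_mono"]] * (T - cal$ET) / cal$ET + e_i,
    nonclassical_mono = NA_real_
  )
  f[, "nonclassical_mono"] <- 1 - f[, "classical_mono"] - f[, "intermediate_mono"]
  f <- clamp(f, 0.001, 0.999)
  f <- f / rowSums(f)
  list(T = T, f = f)
}

# technical CV from a target total inter-assay CV by removing the Poisson
# counting component expected at the duplicate design (full acquisition of one
# volume_ul tube). Animals vary log-normally, so the expected counting
# variance is E[1/N] = (1 + CV^2) / E[N], not 1 / E[N]. Infeasible targets
# (below the counting floor) give tau = 0.
derive_tau <- function(config) {
  pops <- config$populations
  mean_s <- config$cohort_mean[pops]
  cv_s <- config$cohort_cv[pops]
  ms <- mono_subsets()
  if (any(is.na(mean_s[ms])) && !is.null(config$calibration))
    mean_s[ms] <- config$calibration$mean_s[ms]
  cv_s[is.na(cv_s)] <- 0.5
  n_events <- mean_s * config$volume_ul          # f = 1 at the duplicate design
  n_beads <- config$beads_per_tube
  pois_var <- (1 + cv_s^2) / n_events + 1 / n_beads
  target <- config$interassay_cv[pops]
  tau2 <- pmax(target^2 - pois_var, 0)
  stats::setNames(sqrt(tau2), pops)
}

#' Default post-surgery kinetics anchors
#'
#' Per-subset multiplicative trajectory anchors m(t) at days 0, 1, 3, 5, 7, 14
#' and 21 (1 = baseline), interpolated log-linearly in between, plus the
#' individuality-retention exponent alpha(t) used in sequential mode (see
#' vignette). MI and sham share one anchor table (the systemic response is
#' surgery-driven); the sampling-control group is flat. The anchor magnitudes
#' are package defaults chosen for qualitative shape: an early dip most
#' pronounced for non-classical monocytes and eosinophils within the first
#' 24 h, followed by classical and non-classical monocytosis.
#'
#' @return List with elements `days`, `m` (list of population x day matrices
#'   per group) and `alpha` (list of day vectors per group).
#' @export
default_kinetics <- function() {
  days <- c(0, 1, 3, 5, 7, 14, 21)
  pops <- cyto_populations()
  m <- rbind(
    neutrophil        = c(1, 0.90, 1.30, 1.10, 1.00, 1.00, 1.00),
    eosinophil        = c(1, 0.40, 0.70, 0.90, 1.00, 1.00, 1.00),
    classical_mono    = c(1, 0.70, 2.50, 2.00, 1.60, 1.20, 1.00),
    intermediate_mono = c(1, 0.60, 1.40, 1.50, 1.30, 1.10, 1.00),
    nonclassical_mono = c(1, 0.40, 1.20, 1.80, 1.60, 1.20, 1.00),
    activated_monomac = c(1, 0.80, 1.30, 1.40, 1.20, 1.10, 1.00),
    lymphocyte        = c(1, 0.70, 0.90, 1.00, 1.00, 1.00, 1.00)
  )
  colnames(m) <- days
  flat <- matrix(1, nrow = length(pops), ncol = length(days),
                 dimnames = list(pops, days))
  alpha_op <- c(1, 0.40, 0.30, 0.25, 0.25, 0.40, 0.60)
  alpha_flat <- rep(1, length(days))
  list(days = days,
       m = list(MI = m[pops, ], SHAM = m[pops, ], CTRL = flat),
       alpha = list(MI = alpha_op, SHAM = alpha_op, CTRL = alpha_flat))
}

#' Evaluate the kinetics multiplier for a subset
#'
#' Log-linear interpolation of the anchor table between anchor days.
#'
#' @param config calibrated configuration.
#' @param population population identifier.
#' @param group `"MI"`, `"SHAM"` or `"CTRL"`.
#' @param day numeric day(s) within the anchor range.
#' @return Numeric multiplier(s), 1 at day 0.
#' @export
kinetics_multiplier <- function(config, population, group, day) {
  k <- config$kinetics
  if (!group %in% names(k$m)) stopf("unknown group '%s'", group)
  if (any(day < min(k$days)) || any(day > max(k$days)))
    stopf("day outside anchor range [%g, %g]", min(k$days), max(k$days))
  logm <- log(k$m[[group]][population, ])
  exp(stats::approx(k$days, logm, xout = day)$y)
}

kinetics_alpha <- function(config, group, day) {
  k <- config$kinetics
  if (!group %in% names(k$alpha)) stopf("unknown group '%s'", group)
  stats::approx(k$days, k$alpha[[group]], xout = day)$y
}

#' Named configuration presets
#'
#' * `wt_cohort_180`: the 180-animal wild-type cross-sectional cohort
#'   (50 ul samples, half the tube acquired).
#' * `duplicates_n12`: 12 animals measured in duplicate at 50 ul with full
#'   acquisition, technical noise matched to the printed inter-assay CVs.
#' * `timecourse_mi_sham_ctrl`: sequential 21-day design, 20 ul serial samples;
#'   groups MI (n = 15), SHAM (n = 7), CTRL (n = 4),
#'   days 0,1,2,3,4,5,6,7,14,21.
#' * `crosssection_d2357`: independent groups of 20 animals at days 2,3,5,7.
#' * `volume_pair_n10`: 10 animals measured at both 50 ul and 20 ul.
#'
#' @param name preset name.
#' @return A calibrated `cyto_config`, with a `design` attribute for the
#'   study-level presets.
#' @export
cyto_preset <- function(name = c("wt_cohort_180", "duplicates_n12",
                                 "timecourse_mi_sham_ctrl", "crosssection_d2357",
                                 "volume_pair_n10")) {
  name <- match.arg(name)
  cfg <- switch(name,
    wt_cohort_180 = cyto_config(),
    duplicates_n12 = cyto_config(acq_fraction = 1),
    timecourse_mi_sham_ctrl = cyto_config(volume_ul = 20),
    crosssection_d2357 = cyto_config(volume_ul = 20),
    volume_pair_n10 = cyto_config()
  )
  cfg <- calibrate_cohort_preset(cfg)
  design <- switch(name,
    wt_cohort_180 = list(mode = "cohort", n = 180),
    duplicates_n12 = list(mode = "duplicates", n = 12, n_pairs = 1),
    timecourse_mi_sham_ctrl = list(
      mode = "sequential",
      groups = data.frame(group = c("MI", "SHAM", "CTRL"), n = c(15, 7, 4)),
      days = c(0, 1, 2, 3, 4, 5, 6, 7, 14, 21)),
    crosssection_d2357 = list(
      mode = "cross-sectional",
      groups = data.frame(group = "MI", n = 20),
      days = c(2, 3, 5, 7)),
    volume_pair_n10 = list(mode = "volume_pair", n = 10, volumes = c(50, 20))
  )
  attr(cfg, "design") <- design
  attr(cfg, "preset") <- name
  cfg
}

#' Write / read a configuration as YAML
#'
#' Matrices (spillover, kinetics anchors) are stored with dimnames and
#' restored on read.
#'
#' @param config a `cyto_config`.
#' @param path file path.
#' @return `read_config` returns a calibrated `cyto_config`.
#' @export
write_config <- function(config, path) {
  ser <- unclass(config)
  # named vectors go out as maps so names survive the YAML round trip
  for (nm in c("cohort_mean", "cohort_cv", "fractions", "fraction_sd",
               "tau", "interassay_cv", "cofactor"))
    if (!is.null(ser[[nm]])) ser[[nm]] <- as.list(ser[[nm]])
  ser$templates <- lapply(ser$templates, function(t)
    list(median = as.list(t$median), cv = as.list(t$cv)))
  ser$spillover <- list(channels = rownames(config$spillover),
                        values = as.vector(config$spillover))
  ser$kinetics$m <- lapply(config$kinetics$m, function(m)
    list(populations = rownames(m), values = as.vector(m)))
  ser$calibration <- NULL
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ser <- yaml::read_yaml(path)
  fl <- ser$spillover$channels
  S <- matrix(unlist(ser$spillover$values), nrow = length(fl),
              dimnames = list(fl, fl))
  kin <- ser$kinetics
  kin$days <- unlist(kin$days)
  kin$m <- lapply(ser$kinetics$m, function(m) {
    pops <- m$populations
    matrix(unlist(m$values), nrow = length(pops),
           dimnames = list(pops, kin$days))
  })
  kin$alpha <- lapply(kin$alpha, unlist)
  cfg <- cyto_config(
    cohort_mean = unlist(ser$cohort_mean), cohort_cv = unlist(ser$cohort_cv),
    fractions = unlist(ser$fractions), fraction_sd = unlist(ser$fraction_sd),
    total_mono_mean = ser$total_mono_mean, total_mono_cv = ser$total_mono_cv,
    eta = ser$eta, tau = if (!is.null(ser$tau)) unlist(ser$tau),
    interassay_cv = unlist(ser$interassay_cv),
    beads_per_tube = ser$beads_per_tube, acq_fraction = ser$acq_fraction,
    volume_ul = ser$volume_ul,
    templates = lapply(ser$templates, function(t)
      list(median = unlist(t$median), cv = unlist(t$cv))),
    spillover = S, cofactor = unlist(ser$cofactor), kinetics = kin,
    instrument_range = ser$instrument_range, base_seed = ser$base_seed)
  calibrate_cohort_preset(cfg)
}
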