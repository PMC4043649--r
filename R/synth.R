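#' Draw per-animal true concentrations
#'
#' Non-monocyte populations are drawn log-normally around the configured cohort
#' means (sigma^2 = log(1 + CV^2), parameterized so the arithmetic mean is
#' preserved). The three MHC-II-negative monocyte subsets use the calibrated
#' fraction-total construction: the total monocyte concentration T is
#' log-normal, subset fractions move with T through the calibrated slopes
#' (classical positively, non-classical negatively) plus an independent
#' mean-zero residual, then concentrations are `f_s * T` so subsets sum to the
#' drawn total exactly. Fractions are clamped to (0.001, 0.999) and
#' renormalized in the rare tail where the linear construction would leave
#' [0, 1] (well under 1% of draws at the default preset).
#'
#' @param config calibrated configuration ([calibrate_cohort_preset()]).
#' @param n number of animals.
#' @param group group assignment recorded in the output.
#' @param seed optional integer seed.
#' @return `data.frame` with `animal_id`, `group`, one concentration column
#'   per population (cells/ul) and `total_mono`.
#' @export
sample_animal_params <- function(config, n = 1, group = "WT", seed = NULL) {
  if (is.null(config$calibration))
    stopf("config must be calibrated; run calibrate_cohort_preset() first")
  if (!is.null(seed)) set.seed(seed)
  cal <- config$calibration
  ms <- mono_subsets()
  out <- data.frame(animal_id = paste0(group, "_", seq_len(n)), group = group,
                    stringsAsFactors = FALSE)
  for (p in setdiff(config$populations, ms))
    out[[p]] <- rlnorm_mean(n, config$cohort_mean[[p]], config$cohort_cv[[p]])
  # total monocytes and calibrated fraction construction
  d <- draw_mono_fractions(cal, n)
  for (p in ms) out[[p]] <- d$f[, p] * d$T
  out$total_mono <- d$T
  out[, c("animal_id", "group", config$populations, "total_mono")]
}

# expected event-count rates for one acquisition (before Poisson draw)
acquisition_rates <- function(animal, volume_ul, config, multipliers) {
  pops <- config$populations
  conc <- unlist(animal[pops])
  mult <- rep(1, length(pops)); names(mult) <- pops
  if (!is.null(multipliers)) mult[names(multipliers)] <- multipliers
  rates <- conc * volume_ul * config$acq_fraction * mult
  c(rates, bead = config$beads_per_tube * config$acq_fraction)
}

# draw one population's event block from its template (log-normal per channel,
# zero spread reproduces the median exactly)
draw_population_events <- function(n, template) {
  ch <- cyto_channels()
  m <- matrix(0, nrow = n, ncol = length(ch), dimnames = list(NULL, ch))
  for (j in seq_along(ch)) {
    med <- template$median[[ch[j]]]
    cv <- template$cv[[ch[j]]]
    if (cv == 0) {
      m[, j] <- med
    } else {
      p <- lnorm_pars_median(med, cv)
      m[, j] <- stats::rlnorm(n, p$meanlog, p$sdlog)
    }
  }
  m
}

#' Simulate one acquisition
#'
#' For each population the acquired event count is Poisson with rate
#' `concentration x volume x acq_fraction x noise multipliers`; bead events are
#' Poisson with rate `beads_per_tube x acq_fraction` (beads live in the tube,
#' not the blood, so their count is volume-independent). Each event's true
#' channel vector is drawn log-normally from the population template, the true
#' fluorescence intensities are mixed through the configured spillover matrix
#' (scatter untouched), capped at the instrument range, and the events are
#' shuffled. Ground-truth labels are retained for testing.
#'
#' Day-level biological noise (CV `eta`) and technical staining noise (CV
#' `tau`, per population) enter as multiplicative log-normal factors on the
#' Poisson rate; either can be switched off.
#'
#' @param animal one row of [sample_animal_params()] output (or a named list
#'   with per-population concentrations).
#' @param volume_ul sample volume in ul (20 or 50 in the study designs; any
#'   positive value accepted).
#' @param config calibrated configuration.
#' @param seed optional integer seed.
#' @param multipliers optional named per-population rate multipliers (e.g.
#'   kinetics m(t)).
#' @param day_noise,tech_noise logical; apply the respective noise layer.
#' @param meta extra metadata stored on the event table.
#' @return A [cyto_events] object (raw, uncompensated intensities).
#' @export
simulate_sample <- function(animal, volume_ul = config$volume_ul, config,
                            seed = NULL, multipliers = NULL,
                            day_noise = TRUE, tech_noise = TRUE, meta = list()) {
  if (volume_ul <= 0) stopf("volume must be > 0")
  if (!length(config$templates)) stopf("empty template set")
  if (!is.null(seed)) set.seed(seed)
  pops <- config$populations
  rates <- acquisition_rates(animal, volume_ul, config, multipliers)
  if (day_noise && config$eta > 0)
    rates[pops] <- rates[pops] * rnoise(1, config$eta)
  if (tech_noise)
    rates[pops] <- rates[pops] * vapply(config$tau[pops],
                                        function(t) rnoise(1, t), numeric(1))
  counts <- stats::rpois(length(rates), rates)
  names(counts) <- names(rates)

  blocks <- vector("list", length(counts))
  labels <- character(sum(counts))
  templates <- config$templates
  pos <- 0
  for (k in seq_along(counts)) {
    nm <- names(counts)[k]
    n <- counts[k]
    if (n == 0) { blocks[[k]] <- NULL; next }
    tpl_name <- if (nm == "bead") "bead" else nm
    blocks[[k]] <- draw_population_events(n, templates[[tpl_name]])
    labels[pos + seq_len(n)] <- nm
    pos <- pos + n
  }
  exprs <- do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  if (is.null(exprs))
    exprs <- matrix(numeric(0), ncol = length(cyto_channels()),
                    dimnames = list(NULL, cyto_channels()))
  # spillover mixing on fluorescence channels
  fl <- cyto_fluor_channels()
  exprs[, fl] <- exprs[, fl, drop = FALSE] %*% config$spillover[fl, fl]
  n_sat <- sum(exprs > config$instrument_range)
  exprs <- pmin(exprs, config$instrument_range)
  ord <- sample.int(nrow(exprs))
  meta <- utils::modifyList(list(volume_ul = volume_ul,
                                 animal_id = animal[["animal_id"]] %||% NA,
                                 group = animal[["group"]] %||% NA,
                                 day = NA, duplicate = NA), meta)
  cyto_events(exprs[ord, , drop = FALSE], meta = meta,
              truth = labels[ord], n_saturated = n_sat)
}

#' Simulate a wild-type cohort
#'
#' Draws `n` animals and one acquisition each; per-animal RNG streams are
#' derived as `base_seed + animal index` so any animal is reproducible in
#' isolation.
#'
#' @param config calibrated configuration.
#' @param n cohort size.
#' @param seed base seed (defaults to `config$base_seed`).
#' @param volume_ul acquisition volume.
#' @return List with `animals` (the parameter table) and `samples`
#'   (list of `cyto_events`).
#' @export
simulate_cohort <- function(config, n = 180, seed = config$base_seed,
                            volume_ul = config$volume_ul) {
  animals <- sample_animal_params(config, n, group = "WT", seed = seed)
  samples <- lapply(seq_len(n), function(i)
    simulate_sample(animals[i, ], volume_ul, config, seed = seed + i))
  list(animals = animals, samples = samples)
}

#' Simulate duplicate acquisitions
#'
#' Each pair shares one animal's true concentrations and one day-level state
#' (duplicates are split from the same blood draw); the two members differ
#' only by independent technical multiplicative noise (log-normal, CV `tau`
#' per population) and Poisson counting.
#'
#' @param animal one animal parameter row.
#' @param n_pairs number of duplicate pairs for this animal.
#' @param config calibrated configuration.
#' @param seed optional integer seed.
#' @param volume_ul acquisition volume.
#' @return List of length `n_pairs`; each element is a list of two
#'   `cyto_events` with `duplicate` metadata 1 and 2.
#' @export
simulate_duplicates <- function(animal, n_pairs = 1, config, seed = NULL,
                                volume_ul = config$volume_ul) {
  if (n_pairs < 1) stopf("n_pairs must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pops <- config$populations
  lapply(seq_len(n_pairs), function(k) {
    day_mult <- if (config$eta > 0) rnoise(1, config$eta) else 1
    mult <- stats::setNames(rep(day_mult, length(pops)), pops)
    lapply(1:2, function(d)
      simulate_sample(animal, volume_ul, config, multipliers = mult,
                      day_noise = FALSE, tech_noise = TRUE,
                      meta = list(duplicate = d, pair = k)))
  })
}

#' Simulate a paired-volume acquisition
#'
#' Two tubes pipetted from one blood draw at different volumes (assay-standard
#' and volume-reduced). Both share the animal's truth and the draw's day-level
#' state; they differ by independent technical noise and Poisson counting —
#' the same sharing structure as duplicates.
#'
#' @param animal one animal parameter row.
#' @param volumes numeric vector of volumes (ul), default `c(50, 20)`.
#' @param config calibrated configuration.
#' @param seed optional integer seed.
#' @return Named list of `cyto_events`, one per volume.
#' @export
simulate_volume_pair <- function(animal, volumes = c(50, 20), config,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- config$populations
  day_mult <- if (config$eta > 0) rnoise(1, config$eta) else 1
  mult <- stats::setNames(rep(day_mult, length(pops)), pops)
  out <- lapply(volumes, function(v)
    simulate_sample(animal, v, config, multipliers = mult,
                    day_noise = FALSE, tech_noise = TRUE,
                    meta = list(volume_ul = v)))
  names(out) <- paste0("v", volumes)
  out
}

#' Simulate single-stain compensation controls
#'
#' One event table per fluorescence channel, each containing a bright
#' population positive only on that channel (pre-spillover) plus an unstained
#' negative population; the configured spillover is applied. Used to exercise
#' [estimate_spillover()].
#'
#' @param config configuration (calibration not required).
#' @param seed optional integer seed.
#' @param n_pos,n_neg events per population.
#' @param positive_median,negative_median channel medians (a.u.) of the
#'   stained and unstained populations.
#' @param spread log-normal CV of the control populations (0 gives exact
#'   medians).
#' @return Named list of `cyto_events`, one per fluorescence channel.
#' @export
simulate_single_stain_controls <- function(config, seed = NULL,
                                           n_pos = 10000, n_neg = 10000,
                                           positive_median = 20000,
                                           negative_median = 50,
                                           spread = 0.25) {
  if (!is.null(seed)) set.seed(seed)
  fl <- cyto_fluor_channels()
  ch <- cyto_channels()
  scatter_med <- c(FSC = 60000, SSC = 30000)
  make_pop <- function(n, bright_channel) {
    med <- stats::setNames(rep(negative_median, length(ch)), ch)
    med[names(scatter_med)] <- scatter_med
    if (!is.null(bright_channel)) med[bright_channel] <- positive_median
    tpl <- list(median = med, cv = stats::setNames(rep(spread, length(ch)), ch))
    draw_population_events(n, tpl)
  }
  out <- lapply(fl, function(chan) {
    exprs <- rbind(make_pop(n_pos, chan), make_pop(n_neg, NULL))
    exprs[, fl] <- exprs[, fl, drop = FALSE] %*% config$spillover[fl, fl]
    ord <- sample.int(nrow(exprs))
    cyto_events(exprs[ord, , drop = FALSE],
                meta = list(control_channel = chan),
                truth = c(rep("ungated", n_pos), rep("ungated", n_neg))[ord])
  })
  names(out) <- fl
  out
}

#' Simulate a longitudinal or cross-sectional study
#'
#' Sequential mode reuses each animal's baseline draw across days; the
#' concentration at day t is
#' `mean_s * m(t) * (baseline_i / mean_s)^alpha(t) * day noise`,
#' where `m(t)` is the group's kinetics multiplier and `alpha(t)` the
#' individuality-retention exponent (`alpha = 1` reproduces pure multiplicative
#' scaling of the baseline; `alpha < 1` post-operatively models the
#' convergence of the surgical mobilization response, see vignette).
#' Cross-sectional mode draws fresh animals per day with a per-animal
#' multiplicative response (`alpha = 1`). CTRL trajectories are flat in
#' expectation.
#'
#' @param design list with `groups` (data.frame of `group`, `n`), `days`
#'   (schedule) and `mode` (`"sequential"` or `"cross-sectional"`); the
#'   `design` attribute of [cyto_preset()] study presets has this shape.
#' @param config calibrated configuration.
#' @param seed base seed.
#' @param events if `TRUE` simulate full event tables; if `FALSE` return the
#'   per-animal-day true measured concentrations only (fast path for
#'   replicated power/CV studies).
#' @param volume_ul acquisition volume.
#' @return If `events`, a list with `animals`, `schedule` (data.frame) and
#'   `samples` (list of `cyto_events` aligned with `schedule` rows); otherwise
#'   a long data.frame `animal_id, group, day, population, conc`.
#' @export
simulate_timecourse <- function(design, config, seed = config$base_seed,
                                events = TRUE, volume_ul = config$volume_ul) {
  stopifnot(is.list(design), !is.null(design$groups), !is.null(design$days))
  mode <- design$mode %||% "sequential"
  if (!mode %in% c("sequential", "cross-sectional"))
    stopf("unknown study mode '%s'", mode)
  if (!all(design$groups$group %in% names(config$kinetics$m)))
    stopf("unknown group '%s'",
          setdiff(design$groups$group, names(config$kinetics$m))[1])
  days <- sort(design$days)
  pops <- config$populations
  means <- config$cohort_mean[pops]
  means[mono_subsets()] <- config$calibration$mean_s[mono_subsets()]
  set.seed(seed)

  conc_rows <- list()
  schedule <- list()
  idx <- 0
  for (g in seq_len(nrow(design$groups))) {
    grp <- design$groups$group[g]
    n_g <- design$groups$n[g]
    if (mode == "sequential") {
      base <- sample_animal_params(config, n_g, group = grp)
      base$animal_id <- paste0(grp, "_", seq_len(n_g))
      for (d in days) {
        m_d <- vapply(pops, function(p) kinetics_multiplier(config, p, grp, d),
                      numeric(1))
        a_d <- kinetics_alpha(config, grp, d)
        for (i in seq_len(n_g)) {
          conc <- means * m_d * (unlist(base[i, pops]) / means)^a_d
          idx <- idx + 1
          conc_rows[[idx]] <- data.frame(animal_id = base$animal_id[i],
                                         group = grp, day = d,
                                         population = pops, conc = unname(conc),
                                         row.names = NULL)
        }
      }
    } else {
      for (d in days) {
        fresh <- sample_animal_params(config, n_g, group = grp)
        fresh$animal_id <- paste0(grp, "_d", d, "_", seq_len(n_g))
        m_d <- vapply(pops, function(p) kinetics_multiplier(config, p, grp, d),
                      numeric(1))
        for (i in seq_len(n_g)) {
          conc <- unlist(fresh[i, pops]) * m_d
          idx <- idx + 1
          conc_rows[[idx]] <- data.frame(animal_id = fresh$animal_id[i],
                                         group = grp, day = d,
                                         population = pops, conc = unname(conc),
                                         row.names = NULL)
        }
      }
    }
  }
  conc_tab <- do.call(rbind, conc_rows)

  if (!events) {
    # apply day-level noise analytically on the concentration scale
    key <- interaction(conc_tab$animal_id, conc_tab$day, drop = TRUE)
    dn <- rnoise(nlevels(key), config$eta)[as.integer(key)]
    tn <- rnoise(nrow(conc_tab), config$tau[conc_tab$population])
    conc_tab$conc <- conc_tab$conc * dn * tn
    return(conc_tab)
  }

  wide <- stats::reshape(conc_tab, idvar = c("animal_id", "group", "day"),
                         timevar = "population", direction = "wide")
  names(wide) <- sub("^conc\\.", "", names(wide))
  samples <- vector("list", nrow(wide))
  for (r in seq_len(nrow(wide))) {
    samples[[r]] <- simulate_sample(wide[r, ], volume_ul, config,
                                    seed = seed + 1000L + r,
                                    meta = list(day = wide$day[r],
                                                animal_id = wide$animal_id[r],
                                                group = wide$group[r]))
  }
  list(animals = unique(conc_tab[, c("animal_id", "group")]),
       schedule = wide[, c("animal_id", "group", "day")],
       samples = samples)
}
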