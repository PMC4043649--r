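test_that("cohort calibration solves the fraction-total covariance identity", {
  cfg <- calibrate_cohort_preset(cyto_config())
  cal <- cfg$calibration
  # cov_s = mean_s - frac_s * E[T]; classical at the reference preset
  expect_equal(cal$cov_s[["classical_mono"]], 135.6 - 0.524 * 240)
  expect_equal(unname(sum(cal$cov_s)), 0, tolerance = 1e-12)
  # implied intermediate mean closes the total
  expect_equal(unname(sum(cal$mean_s)), 240)
  expect_equal(cal$mean_s[["intermediate_mono"]], 240 - 135.6 - 86.1)
  # classical co-moves positively with total monocytes, non-classical negatively
  expect_gt(cal$b_s[["classical_mono"]], 0)
  expect_lt(cal$b_s[["nonclassical_mono"]], 0)
})

test_that("infeasible covariance is a calibration error naming the subset", {
  cfg <- cyto_config(fraction_sd = c(classical_mono = 0.001,
                                     intermediate_mono = 0.001,
                                     nonclassical_mono = 0.001))
  expect_error(calibrate_cohort_preset(cfg), "classical_mono")
})

test_that("zero between-animal variance requires exact mean consistency", {
  # consistent: subset means are exactly frac * E[T]
  ok <- cyto_config(
    cohort_mean = c(neutrophil = 100, eosinophil = 50,
                    classical_mono = 0.524 * 240,
                    intermediate_mono = 0.072 * 240,
                    nonclassical_mono = 0.404 * 240,
                    activated_monomac = 20, lymphocyte = 200),
    cohort_cv = c(neutrophil = 0, eosinophil = 0, classical_mono = 0,
                  intermediate_mono = 0, nonclassical_mono = 0,
                  activated_monomac = 0, lymphocyte = 0),
    fraction_sd = c(classical_mono = 0, intermediate_mono = 0,
                    nonclassical_mono = 0),
    total_mono_cv = 0)
  ok <- calibrate_cohort_preset(ok)
  an <- sample_animal_params(ok, 5, seed = 1)
  for (p in cyto_populations())
    expect_equal(an[[p]], rep(unname(ok$cohort_mean[[p]]), 5))
  # inconsistent printed means cannot be met without covariance
  bad <- cyto_config(
    cohort_mean = c(neutrophil = 100, eosinophil = 50, classical_mono = 140,
                    intermediate_mono = 240 - 140 - 80,
                    nonclassical_mono = 80, activated_monomac = 20,
                    lymphocyte = 200),
    cohort_cv = ok$cohort_cv, fraction_sd = c(classical_mono = 0,
                                              intermediate_mono = 0,
                                              nonclassical_mono = 0),
    total_mono_cv = 0)
  expect_error(calibrate_cohort_preset(bad), "calibration error")
})

test_that("large cohorts reproduce configured means, CVs and fractions", {
  cfg <- calibrate_cohort_preset(cyto_config())
  n <- 1e5
  an <- sample_animal_params(cfg, n, seed = 101)
  # law-of-large-numbers checks (spec-scale n)
  expect_equal(mean(an$neutrophil), 654.2, tolerance = 0.01)
  expect_equal(sd(an$neutrophil) / mean(an$neutrophil), 0.858, tolerance = 0.02)
  # calibrated monocyte construction meets both constraint sets (3 SE)
  for (p in c("classical_mono", "nonclassical_mono", "intermediate_mono")) {
    se <- sd(an[[p]]) / sqrt(n)
    expect_lt(abs(mean(an[[p]]) - cfg$calibration$mean_s[[p]]), 3 * se)
  }
  fr <- an[mono_subsets()] / an$total_mono
  for (p in mono_subsets()) {
    se <- sd(fr[[p]]) / sqrt(n)
    # the (0,1) clamp and its mean-exactness correction displace the fraction
    # means by a few tenths of a percentage point at most
    expect_lt(abs(mean(fr[[p]]) - cfg$fractions[[p]]), 3 * se + 0.004)
  }
  # subset concentrations sum to the drawn total exactly
  expect_equal(rowSums(an[mono_subsets()]), an$total_mono, tolerance = 1e-12)
})

test_that("monocytosis is driven by the classical subset", {
  cfg <- calibrate_cohort_preset(cyto_config())
  an <- sample_animal_params(cfg, 1e4, seed = 102)
  expect_gt(cor(an$classical_mono, an$total_mono),
            cor(an$nonclassical_mono, an$total_mono))
})

test_that("acquired event counts are Poisson in concentration x volume x fraction", {
  cfg <- mini_config()
  animal <- mean_animal(cfg)
  lam <- 60 * 20 * 1  # classical: conc 60 cells/ul, 20 ul, f = 1
  counts <- vapply(1:20, function(s) {
    ev <- simulate_sample(animal, 20, cfg, seed = 200 + s, day_noise = FALSE,
                          tech_noise = FALSE)
    sum(ev$truth == "classical_mono")
  }, numeric(1))
  expect_true(all(abs(counts - lam) < 4 * sqrt(lam)))
  expect_lt(abs(mean(counts) - lam), 4 * sqrt(lam / 20))
})

test_that("acquisition thinning halves cells and beads symmetrically", {
  cfg <- mini_config()
  cfg_half <- cfg
  cfg_half$acq_fraction <- 0.5
  animal <- mean_animal(cfg)
  n_full <- n_half <- matrix(0, 10, 2)
  for (s in 1:10) {
    e1 <- simulate_sample(animal, 20, cfg, seed = 300 + s, day_noise = FALSE,
                          tech_noise = FALSE)
    e2 <- simulate_sample(animal, 20, cfg_half, seed = 400 + s,
                          day_noise = FALSE, tech_noise = FALSE)
    n_full[s, ] <- c(sum(e1$truth != "bead"), sum(e1$truth == "bead"))
    n_half[s, ] <- c(sum(e2$truth != "bead"), sum(e2$truth == "bead"))
  }
  expect_equal(mean(n_half[, 1]) / mean(n_full[, 1]), 0.5, tolerance = 0.05)
  expect_equal(mean(n_half[, 2]) / mean(n_full[, 2]), 0.5, tolerance = 0.05)
})

test_that("zero spreads and identity spillover reproduce template medians exactly", {
  cfg <- zero_spread(mini_config())
  cfg$spillover <- identity_spillover()
  ev <- simulate_sample(mean_animal(cfg), 20, cfg, seed = 7)
  for (p in c("classical_mono", "bead", "lymphocyte")) {
    rows <- which(ev$truth == p)
    tpl <- cfg$templates[[p]]$median[colnames(ev$exprs)]
    expect_true(all(abs(t(ev$exprs[rows, ]) - tpl) < 1e-9))
  }
})

test_that("duplicates share truth and differ only by technical noise and counting", {
  cfg <- mini_config()
  animal <- mean_animal(cfg)
  pairs <- simulate_duplicates(animal, n_pairs = 3, config = cfg, seed = 11)
  expect_length(pairs, 3)
  # tau = 0: count differences consistent with pure Poisson noise
  for (pr in pairs) {
    n1 <- sum(pr[[1]]$truth == "lymphocyte")
    n2 <- sum(pr[[2]]$truth == "lymphocyte")
    expect_lt(abs(n1 - n2), 6 * sqrt(n1 + n2))
  }
  expect_error(simulate_duplicates(animal, 0, cfg), "n_pairs")
})

test_that("duplicate pairs are exchangeable", {
  cfg <- mini_config()
  cfg$tau[] <- 0.05
  pairs <- simulate_duplicates(mean_animal(cfg), 4, cfg, seed = 12)
  tab <- do.call(rbind, lapply(seq_along(pairs), function(k)
    do.call(rbind, lapply(1:2, function(d) {
      counts <- table(pairs[[k]][[d]]$truth)
      data.frame(animal_id = "A1", pair = k, duplicate = d,
                 population = "lymphocyte",
                 cells_per_ul = unname(counts[["lymphocyte"]]))
    }))))
  swapped <- tab
  swapped$duplicate <- 3 - swapped$duplicate
  expect_equal(inter_assay_cv(tab)$cv, inter_assay_cv(swapped)$cv)
})

test_that("single-stain controls encode the configured spillover by construction", {
  cfg <- mini_config()
  cfg$spillover <- identity_spillover()
  ctl <- simulate_single_stain_controls(cfg, seed = 13, spread = 0)
  # identity spillover: off-channel medians of positives equal negatives
  ev <- ctl[["CD43"]]
  bright <- ev$exprs[, "CD43"] > 1000
  expect_equal(median(ev$exprs[bright, "Ly6C"]),
               median(ev$exprs[!bright, "Ly6C"]))
  # a 10% leak shifts the receiving channel by 10% of the source signal
  S <- identity_spillover(); S["CD43", "Lin"] <- 0.10
  cfg$spillover <- S
  ctl <- simulate_single_stain_controls(cfg, seed = 14, spread = 0)
  ev <- ctl[["CD43"]]
  bright <- ev$exprs[, "CD43"] > 1000
  shift <- median(ev$exprs[bright, "Lin"]) - median(ev$exprs[!bright, "Lin"])
  src <- median(ev$exprs[bright, "CD43"]) - median(ev$exprs[!bright, "CD43"])
  expect_equal(shift / src, 0.10, tolerance = 1e-9)
})

test_that("kinetics anchors: baseline 1, CTRL flat, early dip where expected", {
  cfg <- cyto_preset("timecourse_mi_sham_ctrl")
  for (p in cyto_populations()) {
    expect_equal(kinetics_multiplier(cfg, p, "MI", 0), 1)
    expect_equal(kinetics_multiplier(cfg, p, "CTRL", c(0, 3, 14)), c(1, 1, 1))
    expect_equal(kinetics_multiplier(cfg, p, "MI", 3),
                 kinetics_multiplier(cfg, p, "SHAM", 3))
  }
  expect_lt(kinetics_multiplier(cfg, "nonclassical_mono", "MI", 1), 1)
  expect_lt(kinetics_multiplier(cfg, "eosinophil", "MI", 1), 1)
  # log-linear interpolation between anchors
  expect_equal(kinetics_multiplier(cfg, "classical_mono", "MI", 2),
               sqrt(0.70 * 2.50))
  expect_error(kinetics_multiplier(cfg, "classical_mono", "MI", 30), "anchor range")
  expect_error(kinetics_multiplier(cfg, "classical_mono", "LPS", 3), "unknown group")
})

test_that("sequential sampling is flat for controls and repeatable within animal", {
  cfg <- mini_config()
  design <- list(mode = "sequential", days = c(0, 1, 3, 5),
                 groups = data.frame(group = "CTRL", n = 6))
  tc <- simulate_timecourse(design, cfg, seed = 15, events = FALSE)
  # eta = tau = 0 and alpha = m = 1: trajectories exactly constant
  for (a in unique(tc$animal_id)) {
    v <- tc[tc$animal_id == a & tc$population == "neutrophil", "conc"]
    expect_equal(v, rep(v[1], length(v)))
  }
  expect_error(simulate_timecourse(
    list(mode = "sequential", days = 0:3,
         groups = data.frame(group = "LPS", n = 3)), cfg, seed = 1),
    "unknown group")
})

test_that("within-animal day-to-day correlation exceeds the cross-sectional one", {
  cfg <- calibrate_cohort_preset(cyto_config())
  groups <- data.frame(group = "MI", n = 40)
  seq_tc <- simulate_timecourse(list(mode = "sequential", days = c(0, 7),
                                     groups = groups), cfg, seed = 16,
                                events = FALSE)
  cross_tc <- simulate_timecourse(list(mode = "cross-sectional", days = c(0, 7),
                                       groups = groups), cfg, seed = 17,
                                  events = FALSE)
  pick <- function(tc, d) {
    sub <- tc[tc$day == d & tc$population == "classical_mono", ]
    sub$conc[order(sub$animal_id)]
  }
  r_seq <- cor(pick(seq_tc, 0), pick(seq_tc, 7), method = "spearman")
  # cross-sectional mode draws fresh animals per day: pair arbitrarily by rank index
  r_cross <- cor(pick(cross_tc, 0), pick(cross_tc, 7), method = "spearman")
  expect_gt(r_seq, 0.5)
  expect_gt(r_seq, r_cross)
})

test_that("generated samples flag saturation and carry truth labels for all events", {
  cfg <- mini_config()
  ev <- simulate_sample(mean_animal(cfg), 20, cfg, seed = 18)
  expect_length(ev$truth, n_events(ev))
  expect_false(anyNA(ev$truth))
  cfg$instrument_range <- 1000
  ev2 <- simulate_sample(mean_animal(cfg), 20, cfg, seed = 18)
  expect_gt(ev2$n_saturated, 0)
  expect_lte(max(ev2$exprs), 1000)
})
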