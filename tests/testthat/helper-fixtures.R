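# Shared fixtures, all generated in code.

# Small, fast configuration: low concentrations, few beads, full acquisition,
# self-consistent monocyte calibration (fractions equal subset means / total,
# so the fraction-total covariances are zero and any CV is feasible).
mini_config <- function(eta = 0, tau0 = TRUE, ...) {
  cfg <- cyto_config(
    cohort_mean = c(neutrophil = 100, eosinophil = 50, classical_mono = 60,
                    intermediate_mono = 20, nonclassical_mono = 40,
                    activated_monomac = 20, lymphocyte = 200),
    cohort_cv = c(neutrophil = 0.5, eosinophil = 0.4, classical_mono = 0.5,
                  intermediate_mono = 0.5, nonclassical_mono = 0.4,
                  activated_monomac = 0.5, lymphocyte = 0.3),
    fractions = c(classical_mono = 0.5, intermediate_mono = 20 / 120,
                  nonclassical_mono = 40 / 120),
    fraction_sd = c(classical_mono = 0.08, intermediate_mono = 0.04,
                    nonclassical_mono = 0.08),
    total_mono_mean = 120, total_mono_cv = 0.4,
    eta = eta, beads_per_tube = 2000, acq_fraction = 1, volume_ul = 20,
    ...
  )
  cfg <- calibrate_cohort_preset(cfg)
  if (tau0) cfg$tau[] <- 0
  cfg
}

# remove all stochastic layers from a configuration: zero template spreads,
# zero day-level and technical noise
zero_spread <- function(cfg) {
  for (p in names(cfg$templates)) cfg$templates[[p]]$cv[] <- 0
  cfg$eta <- 0
  cfg$tau[] <- 0
  cfg
}

identity_spillover <- function() {
  fl <- c("CD43", "Lin", "MHCII", "F480", "CD11b", "Ly6C")
  S <- diag(length(fl))
  dimnames(S) <- list(fl, fl)
  S
}

# a deterministic animal with the configured mean concentrations
mean_animal <- function(cfg, id = "A1", group = "WT") {
  out <- data.frame(animal_id = id, group = group, stringsAsFactors = FALSE)
  for (p in cfg$populations) out[[p]] <- unname(cfg$cohort_mean[[p]])
  out$total_mono <- sum(unlist(out[mono_subsets()]))
  out
}

# one synthetic event row with explicit transformed-scale positions;
# remaining channels sit at a low baseline
event_at <- function(gs, ..., baseline = 50) {
  ch <- c("FSC", "SSC", "CD43", "Lin", "MHCII", "F480", "CD11b", "Ly6C")
  m <- matrix(baseline, nrow = 1, ncol = length(ch), dimnames = list(NULL, ch))
  pos <- list(...)
  for (nm in names(pos)) m[1, nm] <- biexp_inverse(pos[[nm]], gs$cofactor)
  m
}

events_from_matrix <- function(m, ...) cyto_events(m, compensated = TRUE, ...)
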