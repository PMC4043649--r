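test_that("bead identification is exact on noiseless fixtures and order-invariant", {
  cfg <- zero_spread(mini_config())
  ev <- simulate_sample(mean_animal(cfg), 20, cfg, seed = 31)
  comp <- compensate(ev, cfg$spillover)
  gs <- default_gateset(cfg)
  mask <- identify_beads(comp, gs)
  expect_identical(mask, ev$truth == "bead")
  # permutation invariance of the flag rate
  ord <- sample.int(n_events(ev))
  perm <- comp; perm$exprs <- comp$exprs[ord, ]
  expect_identical(identify_beads(perm, gs), mask[ord])
  # no beads present: empty mask, no error
  animal0 <- mean_animal(cfg)
  cfg0 <- cfg; cfg0$beads_per_tube <- 0
  ev0 <- compensate(simulate_sample(animal0, 20, cfg0, seed = 32), cfg$spillover)
  expect_equal(sum(identify_beads(ev0, gs)), 0)
})

test_that("data-driven gates sit in the density valley between modes", {
  cfg <- mini_config()
  gs <- default_gateset(cfg)
  # constructed mixture: MHCII modes at transformed 1.0 and 3.0
  set.seed(33)
  n <- 3000
  t_mhc <- c(rnorm(n, 1.0, 0.15), rnorm(n, 3.0, 0.15))
  m <- matrix(50, nrow = 2 * n, ncol = 8,
              dimnames = list(NULL, c("FSC", "SSC", "CD43", "Lin", "MHCII",
                                      "F480", "CD11b", "Ly6C")))
  m[, "MHCII"] <- biexp_inverse(t_mhc, cfg$cofactor)
  ev <- events_from_matrix(m)
  g1 <- derive_gates(ev, cfg, method = "kde")
  expect_gt(g1$mhc2_pos_cut, 1.5)
  expect_lt(g1$mhc2_pos_cut, 2.5)
  # deterministic rerun
  g2 <- derive_gates(ev, cfg, method = "kde")
  expect_identical(unclass(g1), unclass(g2))
  # config mode ignores the data and returns the template-midpoint cuts
  expect_identical(unclass(derive_gates(ev, cfg, method = "config")),
                   unclass(gs))
  # too few events for data-driven placement
  small <- events_from_matrix(m[1:100, ])
  expect_error(derive_gates(small, cfg, method = "kde"), "at least")
})

test_that("phenotype definitions classify constructed events", {
  gs <- default_gateset(cyto_config())
  lo <- function(cuts) cuts[1] - 0.3
  int <- function(cuts) mean(cuts)
  hi <- function(cuts) cuts[2] + 0.5
  ssc_lo <- gs$ssc_high_cut - 0.5
  pos <- function(cut) cut + 0.5
  neg <- function(cut) cut - 0.5
  cases <- list(
    classical_mono = event_at(gs, SSC = ssc_lo, Lin = neg(gs$lin_pos_cut),
                              CD11b = pos(gs$cd11b_pos_cut),
                              MHCII = neg(gs$mhc2_pos_cut),
                              Ly6C = hi(gs$ly6c_cuts), CD43 = lo(gs$cd43_cuts)),
    nonclassical_mono = event_at(gs, SSC = ssc_lo, Lin = neg(gs$lin_pos_cut),
                                 CD11b = pos(gs$cd11b_pos_cut),
                                 MHCII = neg(gs$mhc2_pos_cut),
                                 Ly6C = lo(gs$ly6c_cuts), CD43 = hi(gs$cd43_cuts)),
    intermediate_mono = event_at(gs, SSC = ssc_lo, Lin = neg(gs$lin_pos_cut),
                                 CD11b = pos(gs$cd11b_pos_cut),
                                 MHCII = neg(gs$mhc2_pos_cut),
                                 Ly6C = int(gs$ly6c_cuts), CD43 = int(gs$cd43_cuts)),
    activated_monomac = event_at(gs, SSC = ssc_lo, Lin = neg(gs$lin_pos_cut),
                                 CD11b = pos(gs$cd11b_pos_cut),
                                 MHCII = pos(gs$mhc2_pos_cut),
                                 Ly6C = lo(gs$ly6c_cuts), CD43 = hi(gs$cd43_cuts)),
    neutrophil = event_at(gs, SSC = gs$ssc_high_cut + 0.5,
                          Lin = pos(gs$lin_pos_cut),
                          CD11b = pos(gs$cd11b_pos_cut),
                          F480 = neg(gs$f480_pos_cut)),
    eosinophil = event_at(gs, SSC = gs$ssc_high_cut + 0.5,
                          Lin = neg(gs$lin_pos_cut),
                          CD11b = pos(gs$cd11b_pos_cut),
                          F480 = pos(gs$f480_pos_cut)),
    lymphocyte = event_at(gs, SSC = ssc_lo, Lin = pos(gs$lin_pos_cut),
                          CD11b = neg(gs$cd11b_pos_cut))
  )
  for (expected in names(cases)) {
    lab <- classify_events(events_from_matrix(cases[[expected]]), gs)
    expect_identical(as.character(lab), expected)
  }
  # MHCII-pos with classical-like Ly6C-hi/CD43-lo pattern stays ungated
  odd <- event_at(gs, SSC = ssc_lo, Lin = neg(gs$lin_pos_cut),
                  CD11b = pos(gs$cd11b_pos_cut), MHCII = pos(gs$mhc2_pos_cut),
                  Ly6C = hi(gs$ly6c_cuts), CD43 = lo(gs$cd43_cuts))
  expect_identical(as.character(classify_events(events_from_matrix(odd), gs)),
                   "ungated")
})

test_that("events exactly on a cut go to the upper side", {
  gs <- default_gateset(cyto_config())
  # pin the cuts to the exact transformed values of fixed raw intensities so
  # the boundary comparison is bit-deterministic
  raw_ly6c <- 9354
  raw_mhc <- 707
  gs$ly6c_cuts[2] <- biexp_transform(raw_ly6c, gs$cofactor)
  gs$mhc2_pos_cut <- biexp_transform(raw_mhc, gs$cofactor)
  ssc_lo <- gs$ssc_high_cut - 0.5
  base <- list(SSC = ssc_lo, Lin = gs$lin_pos_cut - 0.5,
               CD11b = gs$cd11b_pos_cut + 0.5, MHCII = gs$mhc2_pos_cut - 0.5,
               CD43 = gs$cd43_cuts[1] - 0.3)
  # Ly6C exactly at the high cut: classical (>= hi)
  ev <- do.call(event_at, c(list(gs), base))
  ev[1, "Ly6C"] <- raw_ly6c
  expect_identical(as.character(classify_events(events_from_matrix(ev), gs)),
                   "classical_mono")
  # MHCII exactly at its cut: positive branch
  ev2 <- do.call(event_at, c(list(gs),
                             base[setdiff(names(base), c("MHCII", "CD43"))],
                             list(Ly6C = gs$ly6c_cuts[1] - 0.3,
                                  CD43 = gs$cd43_cuts[2] + 0.3)))
  ev2[1, "MHCII"] <- raw_mhc
  expect_identical(as.character(classify_events(events_from_matrix(ev2), gs)),
                   "activated_monomac")
})

test_that("classification matches ground truth on generated samples", {
  # noiseless: exact agreement
  cfg0 <- zero_spread(cyto_preset("wt_cohort_180"))
  ev0 <- simulate_sample(mean_animal(cfg0), 50, cfg0, seed = 34)
  lab0 <- classify_events(compensate(ev0, cfg0$spillover), default_gateset(cfg0))
  expect_gte(mean(as.character(lab0) == as.character(ev0$truth)), 0.999)
  # default noise: < 1% misclassification per subset
  cfg <- cyto_preset("wt_cohort_180")
  ev <- simulate_sample(mean_animal(cfg), 50, cfg, seed = 35)
  lab <- classify_events(compensate(ev, cfg$spillover), default_gateset(cfg))
  truth <- as.character(ev$truth)
  for (p in c("bead", cyto_populations())) {
    rows <- truth == p
    expect_gt(mean(as.character(lab[rows]) == p), 0.99)
  }
  # labels partition the events
  expect_equal(sum(table(lab)), n_events(ev))
  expect_false(anyNA(lab))
})

test_that("thresholds agree between transformed and raw scales", {
  cfg <- mini_config()
  gs <- default_gateset(cfg)
  ev <- simulate_sample(mean_animal(cfg), 20, cfg, seed = 36)
  te <- biexp_transform(ev$exprs[, "Ly6C"], gs$cofactor)
  raw_cut <- biexp_inverse(gs$ly6c_cuts[2], gs$cofactor)
  expect_identical(te >= gs$ly6c_cuts[2], ev$exprs[, "Ly6C"] >= raw_cut)
})

test_that("boolean gate combination is AND, commutative, and errors when empty", {
  set.seed(37)
  a <- runif(1e4) > 0.4
  b <- runif(1e4) > 0.6
  c3 <- runif(1e4) > 0.2
  expect_identical(boolean_combine(list(a, b, c3)), a & b & c3)
  expect_identical(boolean_combine(list(c3, b, a)), boolean_combine(list(a, b, c3)))
  expect_true(all(boolean_combine(list(rep(TRUE, 10), rep(TRUE, 10)))))
  # brute-force intersection oracle
  expect_identical(which(boolean_combine(list(a, b))),
                   intersect(which(a), which(b)))
  expect_error(boolean_combine(list()), "empty")
  # function predicates are evaluated on the events
  cfg <- mini_config()
  ev <- simulate_sample(mean_animal(cfg), 20, cfg, seed = 38)
  f <- function(e) e$exprs[, "SSC"] > 1000
  expect_identical(boolean_combine(list(f), ev), f(ev))
})

test_that("monocyte subset labels add up to the MHCII-negative monocyte gate", {
  cfg <- cyto_preset("wt_cohort_180")
  ev <- simulate_sample(mean_animal(cfg), 50, cfg, seed = 39)
  comp <- compensate(ev, cfg$spillover)
  gs <- default_gateset(cfg)
  lab <- classify_events(comp, gs)
  te <- biexp_transform(comp$exprs, gs$cofactor)
  # recompute the parent gate from raw predicates
  parent <- !identify_beads(comp, gs) &
    te[, "SSC"] < gs$ssc_high_cut & te[, "Lin"] < gs$lin_pos_cut &
    te[, "CD11b"] >= gs$cd11b_pos_cut & te[, "MHCII"] < gs$mhc2_pos_cut
  in_bins <- (te[, "Ly6C"] >= gs$ly6c_cuts[2] & te[, "CD43"] < gs$cd43_cuts[1]) |
    (te[, "Ly6C"] < gs$ly6c_cuts[1] & te[, "CD43"] >= gs$cd43_cuts[2]) |
    (te[, "Ly6C"] >= gs$ly6c_cuts[1] & te[, "Ly6C"] < gs$ly6c_cuts[2] &
       te[, "CD43"] >= gs$cd43_cuts[1] & te[, "CD43"] < gs$cd43_cuts[2])
  expect_equal(sum(lab %in% mono_subsets()), sum(parent & in_bins))
})
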