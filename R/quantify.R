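#' Bead-based absolute concentration
#'
#' TruCount-style single-platform quantification:
#' `(n_subset_events / n_bead_events) * (beads_per_tube / volume_ul)`.
#' The acquisition fraction cancels through the bead ratio, which is what
#' makes the estimator unbiased under Poisson acquisition thinning.
#'
#' @param n_subset_events acquired events of the subset.
#' @param n_bead_events acquired bead events (> 0).
#' @param beads_per_tube nominal beads per tube (lot constant).
#' @param volume_ul blood volume in the tube (ul).
#' @return Concentration in cells/ul.
#' @export
absolute_count <- function(n_subset_events, n_bead_events, beads_per_tube,
                           volume_ul) {
  if (any(volume_ul <= 0)) stopf("volume must be > 0")
  if (any(n_bead_events <= 0))
    stopf("zero bead events: sample fails bead QC, absolute counts undefined")
  (n_subset_events / n_bead_events) * (beads_per_tube / volume_ul)
}

#' Monocyte subset composition
#'
#' Expresses classical, intermediate and non-classical counts as percentages
#' of their sum (the MHC-II-negative monocyte compartment).
#'
#' @param counts named numeric (or a `cyto_sample_result`); must contain the
#'   three monocyte subsets.
#' @return Named numeric percentages summing to 100, or all-`NA` (with a
#'   warning attribute consumed downstream) when no monocyte events exist.
#' @export
subset_fractions <- function(counts) {
  if (inherits(counts, "cyto_sample_result"))
    counts <- stats::setNames(counts$counts$events, counts$counts$population)
  ms <- mono_subsets()
  if (!all(ms %in% names(counts))) stopf("counts must cover the monocyte subsets")
  tot <- sum(counts[ms])
  if (tot <= 0) {
    out <- stats::setNames(rep(NA_real_, 3), ms)
    attr(out, "reason") <- "zero monocyte events"
    return(out)
  }
  100 * counts[ms] / tot
}

#' Median fluorescence intensity of a gated subset
#'
#' Median of the compensated, untransformed intensities of one subset on one
#' channel. Subsets below the minimum event count yield `NA` with a reason
#' attribute (medians over a handful of events are unstable).
#'
#' @param events compensated `cyto_events`.
#' @param labels per-event labels from [classify_events()].
#' @param subset subset label.
#' @param channel channel name.
#' @param min_events minimum events required (default 20).
#' @return Scalar MFI (a.u.) or `NA`.
#' @export
median_fluorescence <- function(events, labels, subset, channel,
                                min_events = 20) {
  sel <- labels == subset
  if (sum(sel) < min_events) {
    out <- NA_real_
    attr(out, "reason") <- sprintf("only %d '%s' events (min %d)",
                                   sum(sel), subset, min_events)
    return(out)
  }
  stats::median(events$exprs[sel, channel])
}

#' Process one acquisition through gating and quantification
#'
#' Compensates (unless already compensated), classifies every event, runs QC,
#' and derives per-subset event counts, bead-based absolute concentrations,
#' monocyte subset composition and per-subset MFIs on all fluorescence
#' channels.
#'
#' @param events a `cyto_events` object (raw or compensated).
#' @param spillover spillover matrix used for compensation (ignored when the
#'   table is already compensated).
#' @param gateset gate set; default template-midpoint gates.
#' @param config configuration (bead lot constant, cofactor, QC thresholds
#'   defaults).
#' @param min_mfi_events minimum events per subset for an MFI.
#' @param min_leukocytes,min_beads QC thresholds.
#' @return Object of class `cyto_sample_result`: `counts` (data.frame with
#'   `population`, `events`, `cells_per_ul`), `fractions`, `mfi` (subset x
#'   channel matrix), `qc`, `labels`, `meta`.
#' @export
process_sample <- function(events, spillover = config$spillover,
                           gateset = default_gateset(config),
                           config = cyto_config(), min_mfi_events = 20,
                           min_leukocytes = 30000, min_beads = 3000) {
  comp <- if (events$compensated) events else compensate(events, spillover)
  labels <- classify_events(comp, gateset)
  qc <- qc_check(labels, min_leukocytes, min_beads)
  pops <- cyto_populations()
  n_bead <- sum(labels == "bead")
  ev_counts <- stats::setNames(
    vapply(pops, function(p) sum(labels == p), numeric(1)), pops)
  vol <- comp$meta$volume_ul %||% config$volume_ul
  cells <- if (n_bead > 0)
    absolute_count(ev_counts, n_bead, config$beads_per_tube, vol)
  else stats::setNames(rep(NA_real_, length(pops)), pops)
  fr <- subset_fractions(ev_counts)
  fl <- cyto_fluor_channels()
  mfi <- matrix(NA_real_, nrow = length(pops), ncol = length(fl),
                dimnames = list(pops, fl))
  for (p in pops) for (chn in fl)
    mfi[p, chn] <- median_fluorescence(comp, labels, p, chn, min_mfi_events)
  structure(list(
    counts = data.frame(population = pops, events = unname(ev_counts),
                        cells_per_ul = unname(cells), row.names = NULL),
    n_bead_events = n_bead,
    n_ungated = sum(labels == "ungated"),
    fractions = fr, mfi = mfi, qc = qc, labels = labels,
    meta = comp$meta
  ), class = "cyto_sample_result")
}

#' @export
print.cyto_sample_result <- function(x, ...) {
  cat("<cyto_sample_result>\n")
  print(x$counts, row.names = FALSE)
  cat(sprintf("  beads: %d, ungated: %d, QC %s\n", x$n_bead_events,
              x$n_ungated, if (x$qc$pass) "pass" else "FAIL"))
  if (!any(is.na(x$fractions)))
    cat(sprintf("  monocyte composition: %.1f / %.1f / %.1f %% (cl/int/ncl)\n",
                x$fractions[["classical_mono"]],
                x$fractions[["intermediate_mono"]],
                x$fractions[["nonclassical_mono"]]))
  invisible(x)
}

#' Process a list of acquisitions
#'
#' @param samples list of `cyto_events`.
#' @param config configuration.
#' @param spillover spillover matrix for compensation (e.g. estimated from
#'   controls); defaults to the configured truth.
#' @param gateset gate set.
#' @param ... passed to [process_sample()].
#' @return List with `results` (list of `cyto_sample_result`) and `table`
#'   (tidy long data.frame: one row per sample x population with events,
#'   cells/ul, fraction, QC flag and metadata).
#' @export
process_study <- function(samples, config = cyto_config(),
                          spillover = config$spillover,
                          gateset = default_gateset(config), ...) {
  results <- lapply(samples, process_sample, spillover = spillover,
                    gateset = gateset, config = config, ...)
  table <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    fr <- stats::setNames(rep(NA_real_, length(cyto_populations())),
                          cyto_populations())
    fr[mono_subsets()] <- r$fractions
    data.frame(sample = i,
               animal_id = r$meta$animal_id %||% NA,
               group = r$meta$group %||% NA,
               day = r$meta$day %||% NA,
               duplicate = r$meta$duplicate %||% NA,
               volume_ul = r$meta$volume_ul %||% NA,
               population = r$counts$population,
               events = r$counts$events,
               cells_per_ul = r$counts$cells_per_ul,
               fraction_pct = unname(fr[r$counts$population]),
               qc_pass = r$qc$pass, row.names = NULL)
  }))
  list(results = results, table = table)
}

#' Compare paired acquisitions at two volumes
#'
#' Per-subset rank correlation (Spearman) and mean ratio of absolute counts
#' between the assay-standard and volume-reduced samples of the same animals.
#'
#' @param results_a,results_b lists of `cyto_sample_result` for the same
#'   animals in the same order (e.g. 50 ul and 20 ul).
#' @return data.frame per population: n, `rho` (rank correlation, `NA` when
#'   fewer than 3 informative pairs), `mean_ratio` (a over b).
#' @export
volume_equivalence <- function(results_a, results_b) {
  if (length(results_a) != length(results_b))
    stopf("unpaired inputs: %d vs %d samples", length(results_a), length(results_b))
  ids_a <- vapply(results_a, function(r) as.character(r$meta$animal_id %||% NA),
                  character(1))
  ids_b <- vapply(results_b, function(r) as.character(r$meta$animal_id %||% NA),
                  character(1))
  if (!all(is.na(ids_a)) && !identical(ids_a, ids_b))
    stopf("unpaired inputs: animal ids differ")
  pops <- cyto_populations()
  get <- function(results, p) vapply(results, function(r)
    r$counts$cells_per_ul[r$counts$population == p], numeric(1))
  do.call(rbind, lapply(pops, function(p) {
    a <- get(results_a, p); b <- get(results_b, p)
    ok <- is.finite(a) & is.finite(b)
    rho <- if (sum(ok) >= 3 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0)
      stats::cor(a[ok], b[ok], method = "spearman") else NA_real_
    data.frame(population = p, n = sum(ok), rho = rho,
               mean_ratio = mean(a[ok]) / mean(b[ok]), row.names = NULL)
  }))
}
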