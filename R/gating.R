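#' Gate set
#'
#' Axis-aligned thresholds on the bi-exponentially transformed scale realizing
#' the sequential gating hierarchy: an SSC-high granulocyte branch (Ly6G via
#' the PE lineage dump channel) and an SSC-low monocytic branch split on
#' MHC-II and then on Ly6C/CD43 intervals, plus a counting-bead gate on the
#' CD11b carrier channel within a low-scatter band. All interval gates use the
#' half-open convention `[lo, hi)`: an event exactly on a cut goes to the
#' upper side.
#'
#' @param ssc_high_cut,lin_pos_cut,cd11b_pos_cut,f480_pos_cut,mhc2_pos_cut
#'   scalar cuts (transformed scale).
#' @param ly6c_cuts,cd43_cuts length-2 increasing vectors: the low/int and
#'   int/high boundaries.
#' @param bead_cd11b_cut bead brightness cut on CD11b.
#' @param bead_ssc_band length-2 scatter band for beads.
#' @param cofactor transform cofactor(s) the cuts refer to.
#' @return Object of class `cyto_gateset`.
#' @export
cyto_gateset <- function(ssc_high_cut, lin_pos_cut, cd11b_pos_cut,
                         f480_pos_cut, mhc2_pos_cut, ly6c_cuts, cd43_cuts,
                         bead_cd11b_cut, bead_ssc_band, cofactor = 150) {
  g <- list(ssc_high_cut = ssc_high_cut, lin_pos_cut = lin_pos_cut,
            cd11b_pos_cut = cd11b_pos_cut, f480_pos_cut = f480_pos_cut,
            mhc2_pos_cut = mhc2_pos_cut, ly6c_cuts = ly6c_cuts,
            cd43_cuts = cd43_cuts, bead_cd11b_cut = bead_cd11b_cut,
            bead_ssc_band = bead_ssc_band, cofactor = cofactor)
  validate_gateset(g)
  structure(g, class = "cyto_gateset")
}

validate_gateset <- function(g) {
  for (nm in c("ly6c_cuts", "cd43_cuts", "bead_ssc_band")) {
    v <- g[[nm]]
    if (length(v) != 2 || !all(is.finite(v)) || v[1] >= v[2])
      stopf("%s must be two finite strictly increasing values", nm)
  }
  scalars <- c("ssc_high_cut", "lin_pos_cut", "cd11b_pos_cut", "f480_pos_cut",
               "mhc2_pos_cut", "bead_cd11b_cut")
  if (!all(vapply(scalars, function(nm) is.finite(g[[nm]]), logical(1))))
    stopf("all gate cuts must be finite")
  invisible(g)
}

#' @export
print.cyto_gateset <- function(x, ...) {
  cat("<cyto_gateset> (transformed scale)\n")
  cat(sprintf("  SSC high >= %.3f | Lin+ >= %.3f | CD11b+ >= %.3f | F4/80+ >= %.3f | MHCII+ >= %.3f\n",
              x$ssc_high_cut, x$lin_pos_cut, x$cd11b_pos_cut, x$f480_pos_cut,
              x$mhc2_pos_cut))
  cat(sprintf("  Ly6C lo/int/hi cuts: %.3f, %.3f | CD43: %.3f, %.3f\n",
              x$ly6c_cuts[1], x$ly6c_cuts[2], x$cd43_cuts[1], x$cd43_cuts[2]))
  cat(sprintf("  beads: CD11b >= %.3f in SSC [%.3f, %.3f)\n",
              x$bead_cd11b_cut, x$bead_ssc_band[1], x$bead_ssc_band[2]))
  invisible(x)
}

#' Default gates from the population templates
#'
#' Places every cut at the transformed midpoint between the medians of the
#' nearest negative and positive template populations; deterministic and
#' independent of any data, which is what the acceptance experiments use.
#'
#' @param config configuration carrying templates and cofactor.
#' @return A `cyto_gateset`.
#' @export
default_gateset <- function(config = cyto_config()) {
  tp <- config$templates
  cf <- config$cofactor
  mid <- function(a, b) (biexp_transform(a, cf) + biexp_transform(b, cf)) / 2
  med <- function(p, chn) tp[[p]]$median[[chn]]
  cyto_gateset(
    ssc_high_cut = mid(med("classical_mono", "SSC"), med("neutrophil", "SSC")),
    lin_pos_cut = mid(med("classical_mono", "Lin"), med("neutrophil", "Lin")),
    cd11b_pos_cut = mid(med("lymphocyte", "CD11b"), med("classical_mono", "CD11b")),
    f480_pos_cut = mid(med("neutrophil", "F480"), med("eosinophil", "F480")),
    mhc2_pos_cut = mid(med("classical_mono", "MHCII"), med("activated_monomac", "MHCII")),
    ly6c_cuts = c(mid(med("nonclassical_mono", "Ly6C"), med("intermediate_mono", "Ly6C")),
                  mid(med("intermediate_mono", "Ly6C"), med("classical_mono", "Ly6C"))),
    cd43_cuts = c(mid(med("classical_mono", "CD43"), med("intermediate_mono", "CD43")),
                  mid(med("intermediate_mono", "CD43"), med("nonclassical_mono", "CD43"))),
    bead_cd11b_cut = mid(med("classical_mono", "CD11b"), med("bead", "CD11b")),
    bead_ssc_band = c(biexp_transform(100, cf),
                      mid(med("bead", "SSC"), med("lymphocyte", "SSC"))),
    cofactor = cf
  )
}

# minimum-density valley between the two largest modes of a KDE; NULL when
# effectively unimodal
kde_valley <- function(values, bw = "nrd0", n_grid = 512) {
  if (stats::sd(values) == 0) return(NULL)
  d <- stats::density(values, bw = bw, n = n_grid)
  y <- d$y
  # interior local maxima
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  is_max <- is_max[y[is_max] > 0.05 * max(y)]
  if (length(is_max) < 2) return(NULL)
  top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  d$x[between[which.min(y[between])]]
}

#' Derive gates from data or configuration
#'
#' With `method = "config"` the template-midpoint gates are returned verbatim
#' and the data are ignored. With `method = "kde"` each single cut is placed
#' at the minimum-density valley between the two nearest modes of a kernel
#' density estimate of the transformed channel (falling back to the config
#' default when the channel is unimodal); the Ly6C and CD43 interval cuts use
#' the two valleys between the three largest modes. Deterministic given
#' bandwidth and grid.
#'
#' @param events a `cyto_events` object (compensated), or `NULL` with
#'   `method = "config"`.
#' @param config configuration providing fallback cuts and the cofactor.
#' @param method `"config"` or `"kde"`.
#' @param min_events minimum events for data-driven placement.
#' @param bw,n_grid kernel density bandwidth rule and grid size.
#' @return A `cyto_gateset`.
#' @export
derive_gates <- function(events = NULL, config = cyto_config(),
                         method = c("config", "kde"),
                         min_events = 1000, bw = "nrd0", n_grid = 512) {
  method <- match.arg(method)
  gs <- default_gateset(config)
  if (method == "config") return(gs)
  if (is.null(events) || n_events(events) < min_events)
    stopf("data-driven gating needs at least %d events", min_events)
  te <- transform_exprs(events$exprs, config$cofactor)
  for (spec in list(c("SSC", "ssc_high_cut"), c("Lin", "lin_pos_cut"),
                    c("CD11b", "cd11b_pos_cut"), c("MHCII", "mhc2_pos_cut"))) {
    v <- kde_valley(te[, spec[1]], bw, n_grid)
    if (!is.null(v)) gs[[spec[2]]] <- v
  }
  for (spec in list(c("Ly6C", "ly6c_cuts"), c("CD43", "cd43_cuts"))) {
    vals <- te[, spec[1]]
    if (stats::sd(vals) == 0) next
    d <- stats::density(vals, bw = bw, n = n_grid)
    y <- d$y
    peaks <- which(diff(sign(diff(y))) == -2) + 1
    peaks <- peaks[y[peaks] > 0.05 * max(y)]
    if (length(peaks) >= 3) {
      top3 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:3])
      cuts <- vapply(1:2, function(k) {
        between <- seq(top3[k], top3[k + 1])
        d$x[between[which.min(y[between])]]
      }, numeric(1))
      gs[[spec[2]]] <- cuts
    }
  }
  validate_gateset(gs)
  structure(gs, class = "cyto_gateset")
}

#' Identify counting-bead events
#'
#' Beads are events above the bead brightness cut on the CD11b carrier channel
#' within the bead scatter band; the mask is removed from all downstream
#' leukocyte gates.
#'
#' @param events compensated `cyto_events`.
#' @param gateset a `cyto_gateset`.
#' @return Logical mask, one entry per event.
#' @export
identify_beads <- function(events, gateset) {
  te <- transform_exprs(events$exprs, gateset$cofactor)
  te[, "CD11b"] >= gateset$bead_cd11b_cut &
    te[, "SSC"] >= gateset$bead_ssc_band[1] &
    te[, "SSC"] < gateset$bead_ssc_band[2]
}

#' Combine interval gates with Boolean AND
#'
#' Event-wise logical AND of channel-interval predicates, mirroring the
#' software "Boolean gating tool" used for continuous populations such as
#' intermediate monocytes. Predicates may be logical vectors or functions of
#' the event table; the combination is commutative.
#'
#' @param gates non-empty list of predicates.
#' @param events optional `cyto_events`, required when any predicate is a
#'   function.
#' @return Logical vector.
#' @export
boolean_combine <- function(gates, events = NULL) {
  if (!length(gates)) stopf("empty gate list")
  vecs <- lapply(gates, function(g) if (is.function(g)) g(events) else g)
  Reduce(`&`, vecs)
}

#' Classify every event in the gating hierarchy
#'
#' Applies the sequential hierarchy: (1) beads out; (2) SSC-high branch:
#' CD11b+ Lin+ F4/80- is neutrophil, CD11b+ Lin- F4/80+ is eosinophil;
#' (3) SSC-low Lin- CD11b+ MHCII- monocytes split on Ly6C/CD43: high/low is
#' classical, low/high is non-classical, the Boolean combined interval gate
#' (both intermediate bins) is intermediate; (4) SSC-low Lin- CD11b+ MHCII+
#' with Ly6C in the low or intermediate bin and CD43 in the intermediate or
#' high bin is the activated monocyte/macrophage subset; (5) SSC-low Lin+
#' CD11b- is lymphocyte; (6) anything else remains `ungated`. Labels are
#' mutually exclusive and exhaustive. Cut membership follows the `[lo, hi)`
#' convention.
#'
#' @param events compensated, `cyto_events` (beads are masked internally).
#' @param gateset a `cyto_gateset`.
#' @return Factor of labels (levels: bead, the seven populations, ungated).
#' @export
classify_events <- function(events, gateset) {
  validate_gateset(gateset)
  te <- transform_exprs(events$exprs, gateset$cofactor)
  n <- nrow(te)
  lab <- rep("ungated", n)

  bead <- identify_beads(events, gateset)
  ssc_hi <- te[, "SSC"] >= gateset$ssc_high_cut
  lin_pos <- te[, "Lin"] >= gateset$lin_pos_cut
  cd11b_pos <- te[, "CD11b"] >= gateset$cd11b_pos_cut
  f480_pos <- te[, "F480"] >= gateset$f480_pos_cut
  mhc2_pos <- te[, "MHCII"] >= gateset$mhc2_pos_cut
  ly6c_lo <- te[, "Ly6C"] < gateset$ly6c_cuts[1]
  ly6c_int <- te[, "Ly6C"] >= gateset$ly6c_cuts[1] & te[, "Ly6C"] < gateset$ly6c_cuts[2]
  ly6c_hi <- te[, "Ly6C"] >= gateset$ly6c_cuts[2]
  cd43_lo <- te[, "CD43"] < gateset$cd43_cuts[1]
  cd43_int <- te[, "CD43"] >= gateset$cd43_cuts[1] & te[, "CD43"] < gateset$cd43_cuts[2]
  cd43_hi <- te[, "CD43"] >= gateset$cd43_cuts[2]

  granulo <- !bead & ssc_hi & cd11b_pos
  lab[granulo & lin_pos & !f480_pos] <- "neutrophil"
  lab[granulo & !lin_pos & f480_pos] <- "eosinophil"

  monocytic <- !bead & !ssc_hi & !lin_pos & cd11b_pos
  mono_neg <- monocytic & !mhc2_pos
  lab[mono_neg & ly6c_hi & cd43_lo] <- "classical_mono"
  lab[mono_neg & ly6c_lo & cd43_hi] <- "nonclassical_mono"
  lab[mono_neg & boolean_combine(list(ly6c_int, cd43_int))] <- "intermediate_mono"
  lab[monocytic & mhc2_pos & (ly6c_lo | ly6c_int) & (cd43_int | cd43_hi)] <-
    "activated_monomac"

  lab[!bead & !ssc_hi & lin_pos & !cd11b_pos] <- "lymphocyte"
  lab[bead] <- "bead"
  factor(lab, levels = cyto_labels())
}

#' Write / read a gate set as YAML
#' @param gateset a `cyto_gateset`.
#' @param path file path.
#' @return `read_gateset` returns a `cyto_gateset`.
#' @export
write_gateset <- function(gateset, path) {
  yaml::write_yaml(unclass(gateset), path, precision = 15)
  invisible(path)
}

#' @rdname write_gateset
#' @export
read_gateset <- function(path) {
  g <- yaml::read_yaml(path)
  cyto_gateset(g$ssc_high_cut, g$lin_pos_cut, g$cd11b_pos_cut, g$f480_pos_cut,
               g$mhc2_pos_cut, unlist(g$ly6c_cuts), unlist(g$cd43_cuts),
               g$bead_cd11b_cut, unlist(g$bead_ssc_band), unlist(g$cofactor))
}
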