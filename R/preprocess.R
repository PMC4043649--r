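#' Estimate a spillover matrix from single-stain controls
#'
#' Entry (i, j) is `(median_j(pos_i) - median_j(neg_i)) / (median_i(pos_i) -
#' median_i(neg_i))` where the positive and negative populations of control i
#' are split on its primary channel; the diagonal is forced to 1. Medians
#' rather than means are used for outlier robustness. Controls are keyed by
#' their primary channel (via `meta$control_channel` or the list names), so
#' input order is irrelevant.
#'
#' @param controls named list of `cyto_events`, one per fluorescence channel.
#' @param min_separation minimum positive/negative separation on the primary
#'   channel, in transformed units (default 1 decade-equivalent).
#' @param cofactor transform cofactor used for the separation check.
#' @return K x K `spillover` matrix over the fluorescence channels.
#' @export
estimate_spillover <- function(controls, min_separation = 1, cofactor = 150) {
  fl <- cyto_fluor_channels()
  keys <- vapply(seq_along(controls), function(i)
    controls[[i]]$meta$control_channel %||% names(controls)[i], character(1))
  if (!all(fl %in% keys))
    stopf("missing single-stain control for channel(s): %s",
          paste(setdiff(fl, keys), collapse = ", "))
  S <- diag(length(fl)); dimnames(S) <- list(fl, fl)
  for (chan in fl) {
    ev <- controls[[which(keys == chan)[1]]]
    x <- ev$exprs[, chan]
    t <- biexp_transform(x, cofactor)
    # deterministic 1-D split: 2-means initialized at the observed extremes
    km <- stats::kmeans(t, centers = matrix(range(t), ncol = 1))
    hi <- which.max(km$centers)
    pos <- km$cluster == hi
    if (abs(diff(range(km$centers))) < min_separation)
      stopf("control for channel '%s': positive/negative populations not separable",
            chan)
    med_pos <- apply(ev$exprs[pos, fl, drop = FALSE], 2, stats::median)
    med_neg <- apply(ev$exprs[!pos, fl, drop = FALSE], 2, stats::median)
    denom <- med_pos[[chan]] - med_neg[[chan]]
    S[chan, ] <- (med_pos - med_neg) / denom
    S[chan, chan] <- 1
  }
  S[S < 0] <- 0
  S
}

#' Compensate fluorescence channels
#'
#' The generator mixes true intensities as `observed = true %*% S`;
#' compensation applies the exact linear inverse `observed %*% solve(S)`.
#' Negative compensated values are retained (truncation would bias median
#' fluorescence intensities). Scatter channels are never touched.
#'
#' Compensation is not idempotent: compensating already-compensated data
#' applies the inverse twice.
#'
#' @param events a `cyto_events` object.
#' @param spillover K x K spillover matrix (diagonal 1, invertible).
#' @return The compensated `cyto_events` (flag `compensated = TRUE`).
#' @export
compensate <- function(events, spillover) {
  fl <- cyto_fluor_channels()
  if (!all(fl %in% rownames(spillover)))
    stopf("spillover matrix must cover all fluorescence channels")
  S <- spillover[fl, fl]
  inv <- tryCatch(solve(S), error = function(e)
    stopf("singular spillover matrix: %s", conditionMessage(e)))
  out <- events
  out$exprs[, fl] <- events$exprs[, fl, drop = FALSE] %*% inv
  out$compensated <- TRUE
  out
}

#' Bi-exponential display/analysis transform
#'
#' `f(x) = asinh(x / cofactor) / ln(10)`: strictly monotone, defined for
#' negative (compensated) values, linear-like near zero and within ~0.2% of
#' `log10(2x / cofactor)` for large x. [biexp_inverse()] is the exact inverse.
#'
#' @param x numeric values (a.u.).
#' @param cofactor positive scale parameter (a.u.); default 150.
#' @return Transformed values (decade-like units).
#' @export
biexp_transform <- function(x, cofactor = 150) {
  if (any(cofactor <= 0)) stopf("cofactor must be > 0")
  asinh(x / cofactor) / log(10)
}

#' @rdname biexp_transform
#' @param y transformed values.
#' @export
biexp_inverse <- function(y, cofactor = 150) {
  if (any(cofactor <= 0)) stopf("cofactor must be > 0")
  sinh(y * log(10)) * cofactor
}

# transform an event matrix channel-wise (used by gating); cofactor may be a
# scalar or a named per-channel vector
transform_exprs <- function(exprs, cofactor) {
  out <- exprs
  ch <- colnames(exprs)
  cf <- if (length(cofactor) == 1) stats::setNames(rep(cofactor, length(ch)), ch)
        else cofactor
  for (j in ch) out[, j] <- biexp_transform(exprs[, j], cf[[j]])
  out
}

#' Acquisition quality control
#'
#' A sample passes when at least `min_leukocytes` leukocyte (non-bead) events
#' and at least `min_beads` bead events were acquired; "at least" is read as
#' inclusive. Failed samples are excluded from cohort statistics by default
#' downstream (overridable there).
#'
#' @param labels factor of per-event labels ([classify_events()]).
#' @param min_leukocytes,min_beads inclusive thresholds.
#' @return A `cyto_qc` list: `n_leukocyte_events`, `n_bead_events`, `pass`,
#'   `reasons`.
#' @export
qc_check <- function(labels, min_leukocytes = 30000, min_beads = 3000) {
  n_bead <- sum(labels == "bead")
  n_leuko <- sum(labels != "bead")
  reasons <- character(0)
  if (n_leuko < min_leukocytes) reasons <- c(reasons, "leukocytes")
  if (n_bead < min_beads) reasons <- c(reasons, "beads")
  structure(list(n_leukocyte_events = n_leuko, n_bead_events = n_bead,
                 pass = length(reasons) == 0, reasons = reasons),
            class = "cyto_qc")
}

#' @export
print.cyto_qc <- function(x, ...) {
  cat(sprintf("<cyto_qc> %s: %d leukocytes, %d beads%s\n",
              if (x$pass) "PASS" else "FAIL",
              x$n_leukocyte_events, x$n_bead_events,
              if (length(x$reasons)) paste0(" (", paste(x$reasons, collapse = ", "), ")")
              else ""))
  invisible(x)
}
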