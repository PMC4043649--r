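#' Event table
#'
#' One acquisition's events-by-channels matrix of raw intensities (arbitrary
#' units) plus channel and acquisition metadata. Counting-bead events are part
#' of the table; when the table was generated synthetically the ground-truth
#' per-event population labels travel alongside in `truth`.
#'
#' @param exprs numeric matrix, n_events x n_channels, finite values; column
#'   names must be the panel channel names.
#' @param meta named list of acquisition metadata (`volume_ul`, `animal_id`,
#'   `day`, `group`, `duplicate`, ...).
#' @param truth optional factor of ground-truth labels, one per event.
#' @param compensated logical flag, set by [compensate()].
#' @param n_saturated number of intensity values capped at the instrument range.
#'
#' @return Object of class `cyto_events`.
#' @export
cyto_events <- function(exprs, meta = list(), truth = NULL,
                        compensated = FALSE, n_saturated = 0L) {
  if (!is.matrix(exprs) || !is.numeric(exprs)) stopf("exprs must be a numeric matrix")
  if (!all(cyto_channels() %in% colnames(exprs)))
    stopf("exprs must have all panel channels as columns")
  if (any(!is.finite(exprs))) stopf("intensities must be finite")
  if (!is.null(truth)) {
    truth <- factor(as.character(truth), levels = cyto_labels())
    if (length(truth) != nrow(exprs)) stopf("truth labels must match event count")
  }
  structure(list(
    exprs = exprs[, cyto_channels(), drop = FALSE],
    channels = data.frame(
      name = cyto_channels(),
      detector = unname(cyto_detectors()[cyto_channels()]),
      type = ifelse(cyto_channels() %in% cyto_scatter_channels(), "scatter", "fluor")
    ),
    meta = meta,
    truth = truth,
    compensated = compensated,
    n_saturated = as.integer(n_saturated)
  ), class = "cyto_events")
}

#' @export
print.cyto_events <- function(x, ...) {
  cat(sprintf("<cyto_events> %d events x %d channels (%s)\n",
              nrow(x$exprs), ncol(x$exprs),
              if (x$compensated) "compensated" else "raw"))
  if (length(x$meta)) {
    keep <- !vapply(x$meta, is.null, logical(1))
    cat("  meta:", paste(names(x$meta)[keep],
                         vapply(x$meta[keep], function(v) paste(format(v), collapse = ","),
                                character(1)),
                         sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$truth)) cat("  ground-truth labels attached\n")
  if (x$n_saturated > 0) cat(sprintf("  %d saturated values\n", x$n_saturated))
  invisible(x)
}

#' Number of events
#' @param x a `cyto_events` object.
#' @return Integer event count.
#' @export
n_events <- function(x) nrow(x$exprs)
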