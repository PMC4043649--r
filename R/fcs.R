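# Minimal FCS 3.1 list-mode reader/writer for the declared panel.
# Float ($DATATYPE F) data are written so compensated negatives survive
# round-trips; the reader additionally accepts integer ($DATATYPE I) data and
# FCS 3.0 headers.

FCS_DELIM <- "|"

#' Write an event table as FCS 3.1
#'
#' One file per acquisition; panel markers go into the $PnS keywords,
#' acquisition metadata into custom keywords (`CYTO$VOL`, `CYTO$ANIMAL`,
#' `CYTO$GROUP`, `CYTO$DAY`, `CYTO$DUP`). Data are 32-bit little-endian
#' floats, list mode, row-major.
#'
#' @param events a `cyto_events` object.
#' @param path output file path.
#' @param spillover optional spillover matrix stored as the $SPILLOVER
#'   keyword.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path, spillover = NULL) {
  m <- events$exprs
  n <- nrow(m); par <- ncol(m)
  det <- cyto_detectors()
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0", "$BEGINSTEXT" = "0",
    "$ENDSTEXT" = "0", "$NEXTDATA" = "0", "$MODE" = "L", "$DATATYPE" = "F",
    "$BYTEORD" = "1,2,3,4", "$PAR" = as.character(par), "$TOT" = as.character(n)
  )
  for (j in seq_len(par)) {
    chn <- colnames(m)[j]
    kw[sprintf("$P%dN", j)] <- unname(det[chn])
    kw[sprintf("$P%dS", j)] <- chn
    kw[sprintf("$P%dB", j)] <- "32"
    kw[sprintf("$P%dE", j)] <- "0,0"
    kw[sprintf("$P%dR", j)] <- "262144"
  }
  meta <- events$meta
  put <- function(key, v) if (!is.null(v) && !is.na(v)) kw[key] <<- as.character(v)
  put("CYTO$VOL", meta$volume_ul)
  put("CYTO$ANIMAL", meta$animal_id)
  put("CYTO$GROUP", meta$group)
  put("CYTO$DAY", meta$day)
  put("CYTO$DUP", meta$duplicate)
  if (!is.null(spillover)) kw["$SPILLOVER"] <- spillover_to_keyword(spillover)

  data_bytes <- 4L * n * par
  # two-pass offset computation with fixed-width data offsets
  build_text <- function(begin_data, end_data) {
    kw2 <- c(kw, "$BEGINDATA" = sprintf("%010d", begin_data),
             "$ENDDATA" = sprintf("%010d", end_data))
    paste0(FCS_DELIM,
           paste0(names(kw2), FCS_DELIM, unname(kw2), FCS_DELIM, collapse = ""))
  }
  text0 <- build_text(0, 0)
  header_len <- 58L
  text_start <- header_len
  text_end <- text_start + nchar(text0, type = "bytes") - 1L
  begin_data <- text_end + 1L
  end_data <- begin_data + data_bytes - 1L
  text <- build_text(begin_data, end_data)
  stopifnot(nchar(text, type = "bytes") == nchar(text0, type = "bytes"))
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end,
                    if (end_data <= 99999999) begin_data else 0,
                    if (end_data <= 99999999) end_data else 0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.vector(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an FCS 3.0/3.1 file
#'
#' Parses the TEXT segment, maps detectors to panel markers through the $PnS
#' (falling back to $PnN) keywords, and returns the events. Channels outside
#' the declared panel are preserved in the matrix but unused downstream; a
#' missing required panel marker is an explicit error naming it.
#'
#' @param path FCS file path.
#' @param require_panel error when a panel marker is absent (default TRUE).
#' @return A `cyto_events` object; keywords are attached as attribute
#'   `keywords`.
#' @export
read_fcs <- function(path, require_panel = TRUE) {
  raw <- readBin(path, "raw", file.size(path))
  magic <- rawToChar(raw[1:6])
  if (!magic %in% c("FCS3.0", "FCS3.1"))
    stopf("not an FCS 3.0/3.1 file (magic '%s')", magic)
  off <- function(a, b) as.integer(trimws(rawToChar(raw[a:b])))
  text_start <- off(11, 18); text_end <- off(19, 26)
  if (is.na(text_start) || is.na(text_end) || text_end <= text_start ||
      text_end > length(raw))
    stopf("corrupt segment offsets in FCS header")
  text <- rawToChar(raw[(text_start + 1):(text_end + 1)])
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- as.list(stats::setNames(parts[seq(2, length(parts), 2)],
                                parts[seq(1, length(parts), 2)]))
  par <- as.integer(kw[["$PAR"]]); tot <- as.integer(kw[["$TOT"]])
  begin_data <- as.integer(kw[["$BEGINDATA"]] %||% off(27, 34))
  dtype <- kw[["$DATATYPE"]] %||% "F"
  if (!dtype %in% c("F", "I")) stopf("unsupported $DATATYPE '%s'", dtype)
  endian <- if ((kw[["$BYTEORD"]] %||% "1,2,3,4") == "4,3,2,1") "big" else "little"
  bits <- as.integer(kw[["$P1B"]] %||% "32")
  size <- bits %/% 8L
  need <- begin_data + size * par * tot
  if (is.na(begin_data) || need > length(raw))
    stopf("corrupt segment offsets: data segment exceeds file size")
  vals <- readBin(raw[(begin_data + 1):length(raw)],
                  what = if (dtype == "F") "numeric" else "integer",
                  n = par * tot, size = size, endian = endian)
  m <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)
  nm <- vapply(seq_len(par), function(j)
    kw[[sprintf("$P%dS", j)]] %||% kw[[sprintf("$P%dN", j)]], character(1))
  colnames(m) <- nm
  if (require_panel) {
    missing <- setdiff(cyto_channels(), nm)
    if (length(missing))
      stopf("file is missing required panel marker(s): %s",
            paste(missing, collapse = ", "))
  }
  num <- function(k) if (!is.null(kw[[k]])) as.numeric(kw[[k]]) else NA
  chr <- function(k) if (!is.null(kw[[k]])) kw[[k]] else NA
  ev <- cyto_events(m[, cyto_channels(), drop = FALSE],
                    meta = list(volume_ul = num("CYTO$VOL"),
                                animal_id = chr("CYTO$ANIMAL"),
                                group = chr("CYTO$GROUP"),
                                day = num("CYTO$DAY"),
                                duplicate = num("CYTO$DUP")))
  attr(ev, "keywords") <- kw
  ev
}

#' Spillover matrix serialization
#'
#' `$SPILLOVER`-style keyword string (`K,names...,values...` row-major) and
#' CSV import/export.
#'
#' @param spillover K x K matrix with channel dimnames.
#' @return `spillover_to_keyword`: the keyword string.
#' @export
spillover_to_keyword <- function(spillover) {
  k <- nrow(spillover)
  paste(c(k, rownames(spillover),
          format(as.vector(t(spillover)), digits = 10, trim = TRUE)),
        collapse = ",")
}

#' @rdname spillover_to_keyword
#' @param keyword a `$SPILLOVER` keyword string.
#' @export
keyword_to_spillover <- function(keyword) {
  parts <- strsplit(keyword, ",", fixed = TRUE)[[1]]
  k <- as.integer(parts[1])
  nms <- parts[2:(k + 1)]
  vals <- as.numeric(parts[-seq_len(k + 1)])
  matrix(vals, nrow = k, byrow = TRUE, dimnames = list(nms, nms))
}

#' @rdname spillover_to_keyword
#' @param path CSV path (channels as header and row names).
#' @export
write_spillover_csv <- function(spillover, path) {
  utils::write.csv(as.data.frame(spillover), path, row.names = TRUE)
  invisible(path)
}

#' @rdname spillover_to_keyword
#' @export
read_spillover_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
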