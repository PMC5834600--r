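#' Minimal FCS list-mode file support
#'
#' Writes FCS 3.1 (list mode, 32-bit float, little-endian) and reads FCS
#' 2.0/3.0/3.1 files with `$DATATYPE` F (float), D (double) or I (integer,
#' uniform 16- or 32-bit widths), applying the per-parameter `$PnE`
#' log-amplification transform where present. Compensation, analysis
#' segments and multi-dataset files (`$NEXTDATA` > 0) are not supported:
#' data are assumed pre-compensated, as produced by modern instruments.
#'
#' @name fcs-io
NULL

.fcs_pad <- function(x, width) {
  formatC(as.character(x), width = width, flag = " ")
}

#' Write an event table to an FCS 3.1 file
#'
#' @param events numeric matrix or data.frame; columns are channels, column
#'   names become `$PnN` short channel names
#' @param path output path
#' @param extra_keywords named character vector of additional TEXT keywords
#'   (e.g. plate/well annotations)
#' @return `path`, invisibly
#' @export
write_fcs <- function(events, path, extra_keywords = NULL) {
  m <- as.matrix(events)
  if (!is.numeric(m)) stop("events must be numeric")
  if (is.null(colnames(m))) stop("events must have channel (column) names")
  n_par <- ncol(m)
  n_tot <- nrow(m)
  data_len <- n_par * n_tot * 4L

  kw <- c(
    "$DATATYPE" = "F", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot),
    "$NEXTDATA" = "0",
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0"
  )
  for (i in seq_len(n_par)) {
    rng <- if (n_tot > 0) max(m[, i], 0) else 0
    kw[paste0("$P", i, "N")] <- colnames(m)[i]
    kw[paste0("$P", i, "B")] <- "32"
    kw[paste0("$P", i, "E")] <- "0,0"
    kw[paste0("$P", i, "R")] <- as.character(ceiling(rng) + 1)
  }
  if (!is.null(extra_keywords)) {
    if (is.null(names(extra_keywords)) || any(names(extra_keywords) == ""))
      stop("extra_keywords must be named")
    kw[names(extra_keywords)] <- as.character(extra_keywords)
  }
  if (any(grepl("/", c(names(kw), kw), fixed = TRUE)))
    stop("keyword names/values must not contain the delimiter '/'")

  # BEGINDATA/ENDDATA are fixed-width so the TEXT length is known up front
  build_text <- function(begin, end) {
    kw2 <- c(kw, "$BEGINDATA" = sprintf("%010d", begin),
             "$ENDDATA" = sprintf("%010d", end))
    paste0("/", paste0(names(kw2), "/", unname(kw2), "/", collapse = ""))
  }
  text_start <- 58L
  text_len <- nchar(build_text(0L, 0L), type = "bytes")
  text_end <- text_start + text_len - 1L
  data_start <- text_end + 1L
  data_end <- if (data_len > 0) data_start + data_len - 1L else 0L
  text <- build_text(data_start, data_end)

  header <- paste0(
    "FCS3.1    ",
    .fcs_pad(text_start, 8), .fcs_pad(text_end, 8),
    if (data_end <= 99999999L) {
      paste0(.fcs_pad(data_start, 8), .fcs_pad(data_end, 8))
    } else {
      paste0(.fcs_pad(0, 8), .fcs_pad(0, 8))
    },
    .fcs_pad(0, 8), .fcs_pad(0, 8)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  if (n_tot > 0)
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  invisible(path)
}

.parse_fcs_text <- function(raw_text) {
  txt <- rawToChar(raw_text)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  stats::setNames(as.list(vals), trimws(keys))
}

#' Read an FCS file into an event matrix
#'
#' @param path path to an FCS 2.0/3.0/3.1 file
#' @param channels optional character vector of channel (`$PnN`) names that
#'   must be present; a missing one raises a channel-mapping error
#' @return numeric matrix (events x channels) with `$PnN` column names and
#'   attributes `keywords` (TEXT segment list) and `version`
#' @export
read_fcs <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("FCS file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS2.0", "FCS3.0", "FCS3.1"))
    stop("not a supported FCS file (bad header): ", path)
  # header offset fields: text begin/end, data begin/end, analysis begin/end
  offs <- suppressWarnings(sapply(0:5, function(i)
    as.numeric(trimws(substr(header, 11 + 8 * i, 18 + 8 * i)))))
  if (any(is.na(offs[1:2]))) stop("corrupt FCS header offsets in ", path)
  text_start <- offs[1]; text_end <- offs[2]
  seek(con, text_start)
  kw <- .parse_fcs_text(readBin(con, "raw", n = text_end - text_start + 1))

  need <- function(key) {
    v <- kw[[key]]
    if (is.null(v)) stop("FCS file lacks required keyword ", key, ": ", path)
    v
  }
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  dtype <- need("$DATATYPE")
  byteord <- need("$BYTEORD")
  endian <- if (startsWith(byteord, "1")) "little" else "big"

  data_start <- offs[3]; data_end <- offs[4]
  if (is.na(data_start) || data_start == 0) {
    data_start <- as.numeric(need("$BEGINDATA"))
    data_end <- as.numeric(need("$ENDDATA"))
  }

  pnn <- vapply(seq_len(n_par), function(i) {
    v <- kw[[paste0("$P", i, "N")]]
    if (is.null(v)) paste0("P", i) else v
  }, character(1))

  n_values <- n_par * n_tot
  if (n_values == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = n_par,
                dimnames = list(NULL, pnn))
  } else {
    seek(con, data_start)
    if (dtype %in% c("F", "D")) {
      size <- if (dtype == "F") 4L else 8L
      vals <- readBin(con, "double", n = n_values, size = size,
                      endian = endian)
    } else if (dtype == "I") {
      bits <- unique(vapply(seq_len(n_par), function(i)
        as.integer(need(paste0("$P", i, "B"))), integer(1)))
      if (length(bits) != 1 || !bits %in% c(16L, 32L))
        stop("integer FCS data require a uniform 16- or 32-bit width: ", path)
      vals <- readBin(con, "integer", n = n_values, size = bits / 8L,
                      signed = bits == 32L, endian = endian)
      vals <- as.numeric(vals)
      if (bits == 32L && any(vals < 0))
        vals[vals < 0] <- vals[vals < 0] + 2^32
      # per-parameter log amplification: value = 10^(e1 * x / range) * e2
      idx <- rep(seq_len(n_par), times = n_tot)
      for (i in seq_len(n_par)) {
        pe <- strsplit(need(paste0("$P", i, "E")), ",")[[1]]
        e1 <- as.numeric(pe[1]); e2 <- as.numeric(pe[2])
        if (!is.na(e1) && e1 > 0) {
          rng <- as.numeric(need(paste0("$P", i, "R")))
          if (is.na(e2) || e2 == 0) e2 <- 1
          sel <- idx == i
          vals[sel] <- 10^(e1 * vals[sel] / rng) * e2
        }
      }
    } else {
      stop("unsupported $DATATYPE '", dtype, "' in ", path)
    }
    if (length(vals) != n_values)
      stop("truncated FCS data segment in ", path)
    m <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE,
                dimnames = list(NULL, pnn))
  }
  if (!is.null(channels)) {
    absent <- setdiff(channels, colnames(m))
    if (length(absent) > 0)
      stop("channel-mapping error: channel(s) ",
           paste(absent, collapse = ", "), " absent from ", path)
  }
  attr(m, "keywords") <- kw
  attr(m, "version") <- version
  m
}
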