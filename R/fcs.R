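#' FCS 3.x input and output
#'
#' Minimal, standards-conformant FCS support for list-mode floating-point
#' event data: reads FCS 3.0/3.1 files (`$DATATYPE` F or D, either byte
#' order) and writes FCS 3.1 (32-bit float, little-endian, list mode).
#' Compensation/spillover is deliberately not applied anywhere in the
#' pipeline.
#'
#' @name fcs_io
NULL

FCS_DELIM <- "/"

fcs_parse_text <- function(raw_text) {
  txt <- rawToChar(raw_text)
  delim <- substr(txt, 1, 1)
  body <- substr(txt, 2, nchar(txt))
  # Doubled delimiters inside values are the FCS escape for a literal
  # delimiter; splitting on the delimiter leaves empty tokens we rejoin.
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  toks <- character(0)
  i <- 1L
  while (i <= length(parts)) {
    tok <- parts[i]
    while (i < length(parts) && parts[i + 1L] == "") {
      tok <- paste0(tok, delim)
      i <- i + 1L
      if (i <= length(parts) - 1L) {
        tok <- paste0(tok, parts[i + 1L])
        i <- i + 1L
      }
    }
    toks <- c(toks, tok)
    i <- i + 1L
  }
  if (length(toks) %% 2L == 1L) toks <- toks[-length(toks)]
  kw <- toks[seq(1, length(toks), by = 2)]
  vals <- toks[seq(2, length(toks), by = 2)]
  stats::setNames(as.list(trimws(vals)), toupper(trimws(kw)))
}

fcs_read_raw <- function(path) {
  if (!file.exists(path)) stop("FCS file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!grepl("^FCS3\\.", version)) {
    stop("not an FCS 3.x file (header '", version, "'): ", path,
         call. = FALSE)
  }
  off <- suppressWarnings(as.numeric(c(
    substr(header, 11, 18), substr(header, 19, 26),
    substr(header, 27, 34), substr(header, 35, 42)
  )))
  if (any(is.na(off[1:2]))) stop("malformed FCS header: ", path, call. = FALSE)
  seek(con, off[1])
  text <- readBin(con, "raw", n = off[2] - off[1] + 1)
  kw <- fcs_parse_text(text)

  need <- function(k) {
    if (is.null(kw[[k]])) stop("FCS file lacks required keyword ", k,
                               call. = FALSE)
    kw[[k]]
  }
  if (toupper(need("$MODE")) != "L") {
    stop("only list-mode ($MODE L) FCS data is supported", call. = FALSE)
  }
  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("F", "D")) {
    stop("only floating-point FCS data ($DATATYPE F or D) is supported, got ",
         dtype, call. = FALSE)
  }
  npar <- as.integer(need("$PAR"))
  ntot <- as.integer(need("$TOT"))
  byteord <- gsub(" ", "", need("$BYTEORD"))
  endian <- if (byteord %in% c("1,2,3,4", "1,2", "1,2,3,4,5,6,7,8")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1", "8,7,6,5,4,3,2,1")) "big"
            else stop("unsupported $BYTEORD: ", byteord, call. = FALSE)
  data_beg <- off[3]
  data_end <- off[4]
  if (is.na(data_beg) || data_beg == 0) {
    data_beg <- as.numeric(need("$BEGINDATA"))
    data_end <- as.numeric(need("$ENDDATA"))
  }
  pnn <- vapply(seq_len(npar), function(i) need(sprintf("$P%dN", i)),
                character(1))
  pnb <- vapply(seq_len(npar),
                function(i) as.integer(need(sprintf("$P%dB", i))), integer(1))
  word <- if (dtype == "F") 4L else 8L
  if (any(pnb != word * 8L)) {
    stop("parameter bit widths inconsistent with $DATATYPE", call. = FALSE)
  }
  vals <- numeric(0)
  if (ntot > 0L) {
    seek(con, data_beg)
    nval <- npar * ntot
    vals <- readBin(con, "double", n = nval, size = word, endian = endian)
    if (length(vals) != nval) {
      stop("FCS data segment truncated (expected ", nval, " values)",
           call. = FALSE)
    }
  }
  mat <- matrix(vals, nrow = ntot, ncol = npar, byrow = TRUE,
                dimnames = list(NULL, pnn))
  list(data = mat, keywords = kw, version = version,
       data_segment = c(data_beg, data_end))
}

#' Read an FCS file into an event table
#'
#' Channels are selected and renamed nowhere: the channel map's
#' `instrument_name`s must match the file's `$PnN` values and become the
#' event-table column names. Unmapped file channels are ignored; a mapped
#' channel absent from the file is an error naming the missing triple.
#'
#' @param path Path to an FCS 3.x file.
#' @param map A [channel_map()] of the channels to ingest.
#' @param metadata An [ev_metadata()] for the sample.
#' @param sample_id Sample identifier; defaults to the file name.
#' @return An [ev_events()] table; event order is the file's.
#' @export
read_fcs <- function(path, map = default_channel_map(),
                     metadata = ev_metadata(),
                     sample_id = tools::file_path_sans_ext(basename(path))) {
  raw <- fcs_read_raw(path)
  have <- colnames(raw$data)
  miss <- !(map$instrument_name %in% have)
  if (any(miss)) {
    m <- map[which(miss)[1], ]
    stop(sprintf(
      "mapped channel (%s, %d, %d) ['%s'] not present in %s",
      m$feature_kind, m$excitation_nm, m$emission_nm, m$instrument_name,
      basename(path)), call. = FALSE)
  }
  d <- tibble::as_tibble(raw$data[, map$instrument_name, drop = FALSE])
  if (nrow(d) == 0L) {
    d <- tibble::as_tibble(stats::setNames(
      lapply(map$instrument_name, function(.) numeric(0)),
      map$instrument_name))
  }
  ev_events(d, sample_id = sample_id, metadata = metadata, channels = map)
}

#' Write an event table to an FCS 3.1 file
#'
#' Emits list-mode, 32-bit float, little-endian FCS 3.1. The `.population`
#' ground-truth sidecar column (when present) is not an instrument channel
#' and is written to `<path>.population.csv` instead, keeping the FCS file
#' standard.
#'
#' @param x An [ev_events()] table with at least one channel.
#' @param path Output path.
#' @param sidecar Write the `.population` sidecar CSV when present.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(x, path, sidecar = TRUE) {
  stopifnot(inherits(x, "ev_events"))
  chans <- event_channels(x)
  if (length(chans) == 0L) {
    stop("cannot write an FCS file with zero channels", call. = FALSE)
  }
  mat <- as.matrix(x$data[, chans, drop = FALSE])
  npar <- ncol(mat)
  ntot <- nrow(mat)

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(npar), "$TOT" = as.character(ntot),
    "$FIL" = basename(path), "$SRC" = x$sample_id
  )
  for (i in seq_len(npar)) {
    rng <- max(1, ceiling(max(0, mat[, i], na.rm = TRUE)) + 1)
    kw[sprintf("$P%dN", i)] <- chans[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- format(rng, scientific = FALSE)
  }
  build_text <- function(kw) {
    paste0(FCS_DELIM,
           paste0(names(kw), FCS_DELIM, unname(kw), FCS_DELIM,
                  collapse = ""))
  }
  # Offsets are zero-padded to fixed width so the TEXT length is stable.
  text0 <- build_text(kw)
  text_beg <- 58L
  text_end <- text_beg + nchar(text0, type = "bytes") +
    2L * (10L - 4L) - 1L  # %BD%/%ED% placeholders grow to 10 digits
  data_beg <- text_end + 1L
  data_end <- if (ntot > 0L) data_beg + 4L * npar * ntot - 1L else 0L
  kw["$BEGINDATA"] <- sprintf("%010d", if (ntot > 0L) data_beg else 0L)
  kw["$ENDDATA"] <- sprintf("%010d", data_end)
  text <- build_text(kw)
  stopifnot(nchar(text, type = "bytes") == text_end - text_beg + 1L)

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_end,
                    if (ntot > 0L && data_end <= 99999999) data_beg else 0L,
                    if (ntot > 0L && data_end <= 99999999) data_end else 0L,
                    0L, 0L)
  con <- suppressWarnings(
    tryCatch(file(path, "wb"),
             error = function(e) stop("cannot open '", path,
                                      "' for writing", call. = FALSE)))
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  if (ntot > 0L) {
    writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  }
  if (sidecar && ".population" %in% names(x$data)) {
    readr::write_csv(tibble::tibble(population = x$data$.population),
                     paste0(path, ".population.csv"), progress = FALSE)
  }
  invisible(path)
}
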