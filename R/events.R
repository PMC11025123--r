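#' Per-event tables of single-vesicle measurements
#'
#' An `ev_events` object holds one acquired (or simulated) sample: a tibble
#' with one row per detected event and one column per mapped channel, the
#' channel map used, a sample identifier, and acquisition metadata (condition,
#' control role, dilution factor, acquisition time, flow rate). Simulated
#' tables may carry a `.population` sidecar column with the ground-truth
#' population label; it is not a channel and is dropped on FCS export.
#'
#' @param data Tibble/data.frame of event measurements; columns named by
#'   instrument channel names, optionally plus `.population`.
#' @param sample_id Sample identifier (length-1 character).
#' @param metadata An [ev_metadata()] list.
#' @param channels The [channel_map()] describing the measurement columns.
#' @return An object of class `ev_events`.
#' @export
ev_events <- function(data, sample_id, metadata = ev_metadata(),
                      channels = default_channel_map()) {
  data <- tibble::as_tibble(data)
  meas <- setdiff(names(data), ".population")
  missing <- setdiff(meas, channels$instrument_name)
  if (length(missing)) {
    stop("event columns not described by the channel map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- vapply(data[meas], is.numeric, logical(1))
  if (!all(num)) stop("all channel columns must be numeric", call. = FALSE)
  if (nrow(data) && any(!vapply(data[meas], function(x) all(is.finite(x)),
                                logical(1)))) {
    stop("channel measurements must be finite", call. = FALSE)
  }
  structure(
    list(
      data = data,
      sample_id = as.character(sample_id)[1],
      metadata = validate_metadata(metadata),
      channels = channels[channels$instrument_name %in% meas, , drop = FALSE]
    ),
    class = "ev_events"
  )
}

#' Acquisition metadata for one sample
#'
#' @param condition Condition label (e.g. `"Scr"`, `"KD1"`, `"10K"`).
#' @param role Control role: `"none"` for an analytical sample, or one of
#'   `"buffer"`, `"isotype"`, `"unstained"`, `"lysed"`.
#' @param dilution Dilution factor applied before acquisition (>= 1).
#' @param acquisition_minutes Acquisition time in minutes (> 0).
#' @param flow_rate_ul_per_min Volumetric flow rate in microliters per minute;
#'   the default 3.66 is the instrument's SLOW small-particle setting.
#' @return A named list of class `ev_metadata`.
#' @export
ev_metadata <- function(condition = "none",
                        role = c("none", "buffer", "isotype", "unstained",
                                 "lysed"),
                        dilution = 1,
                        acquisition_minutes = 1,
                        flow_rate_ul_per_min = 3.66) {
  role <- match.arg(role)
  structure(
    list(condition = as.character(condition)[1], role = role,
         dilution = as.numeric(dilution),
         acquisition_minutes = as.numeric(acquisition_minutes),
         flow_rate_ul_per_min = as.numeric(flow_rate_ul_per_min)),
    class = "ev_metadata"
  )
}

validate_metadata <- function(m) {
  if (!inherits(m, "ev_metadata")) m <- do.call(ev_metadata, as.list(m))
  stopifnot(m$dilution >= 1, m$acquisition_minutes > 0,
            m$flow_rate_ul_per_min > 0)
  m
}

#' @exportS3Method print ev_events
print.ev_events <- function(x, ...) {
  cat(sprintf("<ev_events> sample '%s' (%s, role=%s): %d events x %d channels\n",
              x$sample_id, x$metadata$condition, x$metadata$role,
              nrow(x$data), length(event_channels(x))))
  cat(sprintf("  dilution %gx, %g min @ %g uL/min\n", x$metadata$dilution,
              x$metadata$acquisition_minutes,
              x$metadata$flow_rate_ul_per_min))
  invisible(x)
}

#' @exportS3Method dim ev_events
dim.ev_events <- function(x) c(nrow(x$data), length(event_channels(x)))

#' Measurement channel names of an event table
#' @param x An `ev_events` object.
#' @return Character vector of channel column names (excludes `.population`).
#' @export
event_channels <- function(x) setdiff(names(x$data), ".population")

#' Number of events
#' @param x An `ev_events` object.
#' @export
n_events <- function(x) nrow(x$data)

#' Subset events by row index
#'
#' @param x An `ev_events` object.
#' @param i Integer or logical row index.
#' @return An `ev_events` with the selected rows, metadata unchanged.
#' @export
subset_events <- function(x, i) {
  stopifnot(inherits(x, "ev_events"))
  x$data <- x$data[i, , drop = FALSE]
  x
}

#' Extract the 20-column di8 feature matrix
#'
#' Pure column projection of the 488 nm-excited dye block in the canonical
#' fixed order (see [di8_channel_names()]); scatter, antibody and sidecar
#' columns are excluded. Row order follows event order.
#'
#' @param x An `ev_events` object containing all 20 di8 channels.
#' @param map Channel map giving instrument names; defaults to the map stored
#'   in `x`.
#' @return Numeric matrix with `n_events(x)` rows and 20 columns named by
#'   instrument channel name, with attribute `sample_id`.
#' @export
select_di8_features <- function(x, map = NULL) {
  stopifnot(inherits(x, "ev_events"))
  if (is.null(map)) map <- x$channels
  cols <- di8_channel_names(map)
  absent <- setdiff(cols, names(x$data))
  if (length(absent)) {
    stop("di8 channels missing from event table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(x$data[, cols, drop = FALSE])
  attr(m, "sample_id") <- x$sample_id
  m
}

#' Bind several samples' events into one long tibble
#'
#' @param tables List of `ev_events`.
#' @param channels Channels to keep (default: intersection of all tables).
#' @return Tibble with `sample_id`, `event` (row index within its sample) and
#'   the channel columns (plus `.population` when present in all tables).
#' @export
bind_events <- function(tables, channels = NULL) {
  stopifnot(length(tables) > 0)
  if (is.null(channels)) {
    channels <- Reduce(intersect, lapply(tables, event_channels))
  }
  keep_pop <- all(vapply(tables, function(t) ".population" %in% names(t$data),
                         logical(1)))
  cols <- c(channels, if (keep_pop) ".population")
  dplyr::bind_rows(lapply(tables, function(t) {
    d <- t$data[, cols, drop = FALSE]
    tibble::add_column(d, sample_id = t$sample_id,
                       event = seq_len(nrow(d)), .before = 1)
  }))
}
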