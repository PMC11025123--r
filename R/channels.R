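#' Channel maps: semantic features to instrument channel names
#'
#' The pipeline works on a semantic feature set: four image-derived feature
#' kinds (`Intensity`, `RawMaxPixel`, `Area`, `AspectRatio`) measured at five
#' emission wavelengths for the lipophilic dye di-8-ANEPPS excited at 488 nm,
#' plus side scatter and optional antibody channels. A channel map ties each
#' (feature kind, excitation, emission) triple to the channel name as it
#' appears in an FCS file, so instrument-specific naming never leaks past I/O.
#'
#' @details
#' The five 488 nm-excited di8 emission bands are 528, 583, 611, 702 and
#' 773 nm; the 456 nm band belongs to the 405 nm-excited antibody channel
#' (e.g. BV421) and is not part of the dye block. Each (kind, excitation,
#' emission) triple may map to at most one instrument name.
#'
#' @param feature_kind Character vector in
#'   `c("Intensity", "RawMaxPixel", "Area", "AspectRatio", "SSC")`.
#' @param excitation_nm Integer excitation wavelengths (nm).
#' @param emission_nm Integer emission wavelengths (nm).
#' @param instrument_name Channel name as stored in the FCS file (`$PnN`).
#' @return A tibble of class `channel_map` with one row per channel.
#' @examples
#' cm <- default_channel_map()
#' di8_channel_names(cm)
#' @export
channel_map <- function(feature_kind, excitation_nm, emission_nm,
                        instrument_name) {
  kinds <- c("Intensity", "RawMaxPixel", "Area", "AspectRatio", "SSC")
  if (!all(feature_kind %in% kinds)) {
    stop("unknown feature_kind: ",
         paste(setdiff(feature_kind, kinds), collapse = ", "), call. = FALSE)
  }
  map <- tibble::tibble(
    feature_kind = as.character(feature_kind),
    excitation_nm = as.integer(excitation_nm),
    emission_nm = as.integer(emission_nm),
    instrument_name = as.character(instrument_name)
  )
  key <- paste(map$feature_kind, map$excitation_nm, map$emission_nm)
  if (anyDuplicated(key)) {
    stop("channel map assigns more than one instrument name to a ",
         "(feature_kind, excitation, emission) triple", call. = FALSE)
  }
  if (anyDuplicated(map$instrument_name)) {
    stop("duplicated instrument_name in channel map", call. = FALSE)
  }
  class(map) <- c("channel_map", class(map))
  map
}

#' @rdname channel_map
#' @export
DI8_EMISSIONS <- c(528L, 583L, 611L, 702L, 773L)

#' @rdname channel_map
#' @export
DI8_FEATURE_KINDS <- c("Intensity", "RawMaxPixel", "Area", "AspectRatio")

#' Default channel map
#'
#' Twenty di8 channels (4 feature kinds x 5 emissions at 488 nm excitation),
#' side scatter, and two antibody detection channels (405ex/456em for BV421,
#' 642ex/702em for APC). Instrument names follow the
#' `<Kind>_<ex>-<em>` convention; remap for other instruments by building a
#' [channel_map()] with the same triples and your file's names.
#'
#' @param antibodies Logical; include the two antibody channels.
#' @return A `channel_map`.
#' @export
default_channel_map <- function(antibodies = TRUE) {
  kinds <- rep(DI8_FEATURE_KINDS, each = length(DI8_EMISSIONS))
  ems <- rep(DI8_EMISSIONS, times = length(DI8_FEATURE_KINDS))
  fk <- c(kinds, "SSC")
  ex <- c(rep(488L, 20L), 488L)
  em <- c(ems, 488L)
  nm <- c(paste0(kinds, "_488-", ems), "SSC")
  if (antibodies) {
    fk <- c(fk, "Intensity", "Intensity")
    ex <- c(ex, 405L, 642L)
    em <- c(em, 456L, 702L)
    nm <- c(nm, "Intensity_405-456", "Intensity_642-702")
  }
  channel_map(fk, ex, em, nm)
}

#' Canonical 20-column di8 feature order
#'
#' Feature kinds in the order Intensity, RawMaxPixel, Area, AspectRatio;
#' within each kind, emissions ascending (528, 583, 611, 702, 773). The order
#' is fixed so that embeddings are reproducible run to run.
#'
#' @param map A `channel_map` containing the full di8 block.
#' @return Character vector of 20 instrument names in canonical order.
#' @export
di8_channel_names <- function(map = default_channel_map()) {
  out <- character(0)
  for (k in DI8_FEATURE_KINDS) {
    for (e in DI8_EMISSIONS) {
      hit <- map$instrument_name[map$feature_kind == k &
                                   map$excitation_nm == 488L &
                                   map$emission_nm == e]
      if (length(hit) != 1L) {
        stop("channel map lacks di8 channel (", k, ", 488, ", e, ")",
             call. = FALSE)
      }
      out <- c(out, hit)
    }
  }
  out
}

#' Look up one instrument channel name
#'
#' @param map A `channel_map`.
#' @param feature_kind,excitation_nm,emission_nm The semantic triple.
#' @return The instrument name (length-1 character).
#' @export
channel_name <- function(map, feature_kind, excitation_nm = 488L,
                         emission_nm = NULL) {
  sel <- map$feature_kind == feature_kind & map$excitation_nm == excitation_nm
  if (!is.null(emission_nm)) sel <- sel & map$emission_nm == emission_nm
  hit <- map$instrument_name[sel]
  if (length(hit) != 1L) {
    stop("channel (", feature_kind, ", ", excitation_nm, ", ",
         if (is.null(emission_nm)) "*" else emission_nm,
         ") not uniquely present in channel map", call. = FALSE)
  }
  hit
}
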