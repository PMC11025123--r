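#' Inverse hyperbolic sine transform of a feature matrix
#'
#' Cytometry intensities span decades and are variance-stabilized with
#' `asinh(x / cofactor)` before embedding; the transform is linear near zero
#' and logarithmic for large arguments. Statistics such as MFI, GP and tFL
#' are always computed on the raw scale; asinh is used only for embedding
#' and display.
#'
#' @param x Numeric matrix (events x features).
#' @param cofactor Positive scale cofactor; the default 1 applies plain
#'   `asinh`.
#' @return Matrix of the same shape and dimnames.
#' @export
asinh_transform <- function(x, cofactor = 1) {
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0) {
    stop("cofactor must be a single positive number", call. = FALSE)
  }
  y <- asinh(x / cofactor)
  attributes(y) <- attributes(x)
  y
}

#' Gate events against a buffer control
#'
#' Retains events whose 488-611 intensity exceeds the given quantile of the
#' buffer control's 488-611 distribution, separating dye-positive particles
#' from instrument/buffer background.
#'
#' @param sample,buffer [ev_events()] tables sharing the gate channel.
#' @param quantile Buffer quantile defining the threshold (default 0.99).
#' @param min_buffer_events Minimum buffer events required (default 100).
#' @param map Channel map used to locate Intensity\@611.
#' @return The gated `ev_events`, with attributes `threshold` (intensity
#'   cutoff) and `retained_fraction`.
#' @export
gate_events <- function(sample, buffer, quantile = 0.99,
                        min_buffer_events = 100,
                        map = default_channel_map()) {
  stopifnot(inherits(sample, "ev_events"), inherits(buffer, "ev_events"))
  ch <- channel_name(map, "Intensity", 488L, 611L)
  if (n_events(buffer) < min_buffer_events) {
    stop("buffer control has fewer than ", min_buffer_events, " events",
         call. = FALSE)
  }
  thr <- stats::quantile(buffer$data[[ch]], probs = quantile, names = FALSE,
                         type = 7)
  keep <- sample$data[[ch]] > thr
  out <- subset_events(sample, keep)
  attr(out, "threshold") <- thr
  attr(out, "retained_fraction") <- mean(keep)
  out
}

#' Quantitative-range QC of a dilution series
#'
#' Event rate must scale linearly with 1/dilution and the 488-611 MFI must
#' stay consistent across the accepted window; deviations flag detector
#' saturation (swarm artifact) at low dilution or loss of signal at high
#' dilution. The accepted window is the largest contiguous run of dilution
#' points whose events/min vs 1/dilution fit reaches `r2_min` and whose MFI
#' coefficient of variation stays at or below `mfi_cv_max`; ties favor the
#' window containing the higher dilutions (lower event rates, farther from
#' saturation).
#'
#' @param series List of [ev_events()] with distinct `metadata$dilution`.
#' @param r2_min Minimum R-squared for linearity (default 0.98).
#' @param mfi_cv_max Maximum MFI coefficient of variation (default 0.20).
#' @param map Channel map used to locate Intensity\@611.
#' @return A list of class `qc_range`: per-dilution table, accepted window,
#'   and the window's R-squared and MFI CV.
#' @export
qc_dilution_series <- function(series, r2_min = 0.98, mfi_cv_max = 0.20,
                               map = default_channel_map()) {
  if (length(series) < 3) {
    stop("dilution-series QC needs at least 3 dilution points", call. = FALSE)
  }
  ch <- channel_name(map, "Intensity", 488L, 611L)
  tab <- dplyr::arrange(dplyr::bind_rows(lapply(series, function(t) {
    tibble::tibble(
      sample_id = t$sample_id,
      dilution = t$metadata$dilution,
      events_per_min = n_events(t) / t$metadata$acquisition_minutes,
      mfi_611 = stats::median(t$data[[ch]])
    )
  })), dilution)
  if (anyDuplicated(tab$dilution)) {
    stop("dilution factors must be distinct", call. = FALSE)
  }

  window_stats <- function(idx) {
    x <- 1 / tab$dilution[idx]
    y <- tab$events_per_min[idx]
    fit <- stats::lm(y ~ x)
    r2 <- summary(fit)$r.squared
    cv <- stats::sd(tab$mfi_611[idx]) / mean(tab$mfi_611[idx])
    c(r2 = r2, cv = cv)
  }
  n <- nrow(tab)
  best <- NULL
  for (len in n:3) {
    for (start in rev(seq_len(n - len + 1))) {  # prefer higher dilutions
      idx <- start:(start + len - 1)
      s <- window_stats(idx)
      if (s["r2"] >= r2_min && s["cv"] <= mfi_cv_max) {
        best <- list(idx = idx, stats = s)
        break
      }
    }
    if (!is.null(best)) break
  }
  structure(list(
    table = tab,
    accepted = if (is.null(best)) tab$dilution[0] else tab$dilution[best$idx],
    r_squared = if (is.null(best)) NA_real_ else unname(best$stats["r2"]),
    mfi_cv = if (is.null(best)) NA_real_ else unname(best$stats["cv"]),
    r2_min = r2_min, mfi_cv_max = mfi_cv_max
  ), class = "qc_range")
}

#' @exportS3Method print qc_range
print.qc_range <- function(x, ...) {
  cat("<qc_range>\n")
  print(x$table)
  cat(sprintf("accepted window: %s (R2 = %.4f, MFI CV = %.3f)\n",
              if (length(x$accepted)) paste(x$accepted, collapse = ", ")
              else "none", x$r_squared, x$mfi_cv))
  invisible(x)
}

#' Detergent-lysis specificity check
#'
#' Di8 only fluoresces in lipid bilayers, so detergent lysis must abolish
#' vesicle detection: the time-normalized gated event rate of the lysed
#' control divided by that of the stained sample must stay at or below
#' `max_ratio`.
#'
#' @param stained,lysed [ev_events()] gated identically.
#' @param max_ratio Pass ceiling on the lysed/stained rate ratio
#'   (default 0.10).
#' @return List with `ratio`, `pass`, and the two event rates.
#' @export
lysis_check <- function(stained, lysed, max_ratio = 0.10) {
  rate <- function(t) n_events(t) / t$metadata$acquisition_minutes
  rs <- rate(stained)
  if (rs == 0) stop("stained sample has zero events; ratio undefined",
                    call. = FALSE)
  rl <- rate(lysed)
  ratio <- rl / rs
  list(ratio = ratio, pass = ratio <= max_ratio,
       stained_rate = rs, lysed_rate = rl)
}

#' Dilution-corrected particle concentration
#'
#' `count / (minutes * flow_rate_uL_per_min) * dilution * 1000`, i.e. the
#' event rate divided by the analyzed volume, scaled back to the undiluted
#' sample and expressed per mL.
#'
#' @param count Gated event count (>= 0).
#' @param minutes Acquisition minutes (> 0).
#' @param flow_rate_ul_per_min Volumetric flow rate (> 0).
#' @param dilution Dilution factor (> 0).
#' @return Particles per mL.
#' @export
dilution_corrected_concentration <- function(count, minutes,
                                             flow_rate_ul_per_min = 3.66,
                                             dilution = 1) {
  if (any(minutes <= 0) || any(flow_rate_ul_per_min <= 0) ||
      any(dilution <= 0) || any(count < 0)) {
    stop("minutes, flow rate and dilution must be positive and count >= 0",
         call. = FALSE)
  }
  count / (minutes * flow_rate_ul_per_min) * dilution * 1000
}
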