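#' Antibody positivity threshold from negative controls
#'
#' An event counts as antibody-positive only above an intensity that at most
#' `fp_rate` (default 1 percent) of the events in *every* negative control
#' (antibody-stained buffer, isotype-stained sample) exceed. Per control the
#' threshold is the smallest measured intensity with at most that exceedance
#' — the empirical `1 - fp_rate` order statistic — and the final threshold
#' is the worst (maximum) across controls.
#'
#' @param controls List of [ev_events()] negative controls (each >= 100
#'   events).
#' @param channel Antibody channel name (e.g. `"Intensity_642-702"`).
#' @param fp_rate Tolerated control false-positive rate (default 0.01).
#' @return The threshold, with attribute `control_fp` giving each control's
#'   achieved exceedance rate.
#' @export
positivity_threshold <- function(controls, channel, fp_rate = 0.01) {
  if (length(controls) == 0) stop("no negative controls given", call. = FALSE)
  per <- vapply(controls, function(ct) {
    stopifnot(inherits(ct, "ev_events"))
    x <- ct$data[[channel]]
    if (is.null(x)) stop("control lacks channel ", channel, call. = FALSE)
    if (length(x) < 100) {
      stop("negative control needs at least 100 events", call. = FALSE)
    }
    sort(x)[ceiling((1 - fp_rate) * length(x))]
  }, numeric(1))
  thr <- max(per)
  fp <- vapply(controls, function(ct) mean(ct$data[[channel]] > thr),
               numeric(1))
  structure(thr, control_fp = fp)
}

#' Classify per-event cargo status for two antibody channels
#'
#' Events are `dual+` when both channels exceed their thresholds, `A+`/`B+`
#' on single exceedance, else `negative`; the four statuses are mutually
#' exclusive and exhaustive.
#'
#' @param x An [ev_events()] table.
#' @param thresholds Named numeric length-2 vector: names are cargo labels
#'   (e.g. `c(CD63 = ..., CD81 = ...)`).
#' @param channels Named character length-2 vector mapping the same cargo
#'   labels to channel names.
#' @return Factor of length `n_events(x)` with levels
#'   `negative, <A>+, <B>+, dual+`.
#' @export
classify_cargo <- function(x, thresholds, channels) {
  stopifnot(length(thresholds) == 2, length(channels) == 2,
            setequal(names(thresholds), names(channels)))
  a <- names(thresholds)[1]; b <- names(thresholds)[2]
  for (ch in channels) {
    if (is.null(x$data[[ch]])) {
      stop("antibody channel missing from events: ", ch, call. = FALSE)
    }
  }
  pa <- x$data[[channels[a]]] > thresholds[a]
  pb <- x$data[[channels[b]]] > thresholds[b]
  lv <- c("negative", paste0(a, "+"), paste0(b, "+"), "dual+")
  factor(dplyr::case_when(pa & pb ~ lv[4], pa ~ lv[2], pb ~ lv[3],
                          TRUE ~ lv[1]),
         levels = lv)
}

#' Cargo partitioning by cluster
#'
#' Stacked per-cluster counts and within-cluster proportions of each cargo
#' status, in size-rank order; proportions per cluster sum to 1 and status
#' counts per cluster sum to the cluster's event count.
#'
#' @param status Factor from [classify_cargo()], one value per assigned
#'   event (parallel to `clusters`).
#' @param clusters Integer cluster id per event (0 = noise, excluded).
#' @param profiles Optional `cluster_profiles` supplying the size-rank
#'   ordering.
#' @return Tibble of `cluster`, `status`, `n`, `proportion`, ordered by
#'   size rank when profiles are given.
#' @export
cargo_partition_by_cluster <- function(status, clusters, profiles = NULL) {
  stopifnot(length(status) == length(clusters))
  keep <- clusters > 0L
  d <- tibble::tibble(cluster = clusters[keep], status = status[keep])
  out <- dplyr::count(d, .data$cluster, .data$status, .drop = FALSE,
                      name = "n")
  out <- dplyr::mutate(dplyr::group_by(out, .data$cluster),
                       proportion = .data$n / sum(.data$n))
  out <- dplyr::ungroup(out)
  if (!is.null(profiles)) {
    ord <- profiles$pooled$cluster[order(profiles$pooled$size_rank)]
    out <- out[order(match(out$cluster, ord), out$status), , drop = FALSE]
  }
  out
}

#' Regression of cargo status against population size
#'
#' Ordinary least squares of per-cluster percent positive against a cluster
#' size metric (tFL or 488-611 MFI), one equally weighted point per
#' population.
#'
#' @param percent_positive Numeric per-cluster percentages.
#' @param size_metric Numeric per-cluster size values (same order).
#' @return List with `slope`, `intercept`, `r_squared` (0 by convention for
#'   a constant response), and `n`.
#' @export
status_vs_size_regression <- function(percent_positive, size_metric) {
  ok <- stats::complete.cases(percent_positive, size_metric)
  if (sum(ok) < 3) {
    stop("regression needs at least 3 populations", call. = FALSE)
  }
  y <- percent_positive[ok]
  x <- size_metric[ok]
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) {
    # constant response: slope 0 and R^2 = 0 by convention
    return(list(slope = 0, intercept = mean(y), r_squared = 0, n = sum(ok)))
  }
  fit <- stats::lm(y ~ x)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sstot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n = sum(ok))
}

#' Quadrant gate on scatter vs 488-611 intensity
#'
#' Partitions events at the given (SSC, Intensity\@611) thresholds —
#' conventionally the medians of a 400 nm sizing liposome, so the upper
#' right quadrant holds particles at or above that size — and reports
#' quadrant counts plus the large/small ratio (events at or above both
#' thresholds vs all others).
#'
#' @param x An [ev_events()] table.
#' @param ssc_threshold,i611_threshold Finite gate thresholds.
#' @param map Channel map.
#' @return List with `counts` (named `ll`, `lr`, `ul`, `ur`: low/high SSC x
#'   low/high intensity), `ratio_large_small`, and the thresholds.
#' @export
quadrant_gate <- function(x, ssc_threshold, i611_threshold,
                          map = default_channel_map()) {
  stopifnot(is.finite(ssc_threshold), is.finite(i611_threshold))
  ssc <- x$data[[channel_name(map, "SSC")]]
  i611 <- x$data[[channel_name(map, "Intensity", 488L, 611L)]]
  hi_s <- ssc >= ssc_threshold
  hi_i <- i611 >= i611_threshold
  counts <- c(ll = sum(!hi_s & !hi_i), lr = sum(!hi_s & hi_i),
              ul = sum(hi_s & !hi_i), ur = sum(hi_s & hi_i))
  large <- counts[["ur"]]
  small <- sum(counts) - large
  list(counts = counts,
       ratio_large_small = if (small > 0) large / small else NA_real_,
       ssc_threshold = ssc_threshold, i611_threshold = i611_threshold)
}
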