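#' Generalized polarization from the two peak emission channels
#'
#' `GP = (I_611 - I_702) / (I_611 + I_702)`: the normalized balance between
#' di8's ordered-membrane (611 nm) and disordered-membrane (702 nm) peak
#' emissions. GP is scale-invariant and lies in `[-1, 1]`; events with both
#' channels zero have undefined GP and are returned as `NA` (they are
#' excluded from, but counted alongside, GP summaries).
#'
#' @param i_lo Intensity at 611 nm (ordered peak), >= 0.
#' @param i_ld Intensity at 702 nm (disordered peak), >= 0.
#' @return Numeric vector of GP values (`NA` where both inputs are zero).
#' @export
gp_value <- function(i_lo, i_ld) {
  if (any(i_lo < 0, na.rm = TRUE) || any(i_ld < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  tot <- i_lo + i_ld
  out <- (i_lo - i_ld) / tot
  out[tot == 0] <- NA_real_
  out
}

#' Total di8 fluorescence (tFL) per event
#'
#' Sum of the five 488 nm-excited Intensity channels; fluorescence scales
#' with membrane lipid content, so tFL is a relative size proxy.
#'
#' @param x An [ev_events()] table, or a numeric matrix whose columns
#'   include the five Intensity channels.
#' @param map Channel map used to locate the Intensity channels.
#' @return Numeric vector, one value per event.
#' @export
total_fluorescence <- function(x, map = default_channel_map()) {
  cols <- vapply(DI8_EMISSIONS,
                 function(e) channel_name(map, "Intensity", 488L, e),
                 character(1))
  d <- if (inherits(x, "ev_events")) x$data else as.data.frame(x)
  absent <- setdiff(cols, names(d))
  if (length(absent)) {
    stop("Intensity channels missing: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  rowSums(as.matrix(d[, cols, drop = FALSE]))
}

per_event_table <- function(tables, assignment, map) {
  ch611 <- channel_name(map, "Intensity", 488L, 611L)
  ch702 <- channel_name(map, "Intensity", 488L, 702L)
  ev <- dplyr::bind_rows(lapply(tables, function(t) {
    tibble::tibble(sample_id = t$sample_id,
                   event = seq_len(n_events(t)),
                   i611 = t$data[[ch611]],
                   gp = gp_value(t$data[[ch611]], t$data[[ch702]]),
                   tfl = total_fluorescence(t, map))
  }))
  dplyr::inner_join(ev, assignment, by = c("sample_id", "event"))
}

#' Profile clusters as EV populations
#'
#' Summarizes each cluster: per-sample event counts and dilution-corrected
#' counts, pooled 488-611 MFI (median raw intensity), GP median and
#' quartiles, median total fluorescence, abundance fractions, and size rank
#' (1 = highest MFI). Intensity statistics are pooled across all non-buffer
#' samples and computed on raw intensities; buffer controls contribute
#' counts only.
#'
#' @param tables List of [ev_events()] covering every sample in
#'   `assignment`.
#' @param assignment Tibble with columns `sample_id`, `event`, `cluster`
#'   (0 = noise), e.g. from [reexamine_clusters()]. Events of a sample
#'   absent from `assignment` are treated as unassigned noise.
#' @param map Channel map.
#' @return A list of class `cluster_profiles`: `pooled` (one row per
#'   cluster) and `per_sample` (one row per cluster x sample, noise
#'   included as cluster 0).
#' @export
profile_clusters <- function(tables, assignment,
                             map = default_channel_map()) {
  stopifnot(all(c("sample_id", "event", "cluster") %in% names(assignment)))
  meta <- lapply(tables, `[[`, "metadata")
  names(meta) <- vapply(tables, `[[`, character(1), "sample_id")
  totals <- tibble::tibble(
    sample_id = names(meta),
    total_events = vapply(tables, n_events, integer(1))
  )
  ev <- per_event_table(tables, assignment, map)
  # unassigned events count as noise so abundance fractions close to 1
  assigned <- dplyr::count(ev, .data$sample_id, name = "n_assigned")
  per_sample <- dplyr::summarise(
    dplyr::group_by(ev, .data$sample_id, .data$cluster),
    n = dplyr::n(), .groups = "drop"
  )
  noise_pad <- dplyr::mutate(
    dplyr::left_join(totals, assigned, by = "sample_id"),
    n = .data$total_events - dplyr::coalesce(.data$n_assigned, 0L),
    cluster = 0L
  )[, c("sample_id", "cluster", "n")]
  per_sample <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(per_sample, noise_pad),
                    .data$sample_id, .data$cluster),
    n = sum(.data$n), .groups = "drop"
  )
  per_sample <- dplyr::mutate(
    per_sample,
    condition = vapply(meta[.data$sample_id], `[[`, character(1),
                       "condition"),
    role = vapply(meta[.data$sample_id], `[[`, character(1), "role"),
    corrected_count = mapply(function(n, sid) {
      m <- meta[[sid]]
      dilution_corrected_concentration(n, m$acquisition_minutes,
                                       m$flow_rate_ul_per_min, m$dilution)
    }, .data$n, .data$sample_id),
    abundance = .data$n /
      totals$total_events[match(.data$sample_id, totals$sample_id)]
  )

  pool <- dplyr::filter(ev,
                        .data$cluster > 0L,
                        vapply(meta[.data$sample_id], `[[`, character(1),
                               "role") != "buffer")
  pooled <- dplyr::summarise(
    dplyr::group_by(pool, .data$cluster),
    n_pooled = dplyr::n(),
    mfi_611 = stats::median(.data$i611),
    gp_median = stats::median(.data$gp, na.rm = TRUE),
    gp_q1 = stats::quantile(.data$gp, 0.25, na.rm = TRUE, names = FALSE),
    gp_q3 = stats::quantile(.data$gp, 0.75, na.rm = TRUE, names = FALSE),
    gp_undefined = sum(is.na(.data$gp)),
    tfl = stats::median(.data$tfl),
    .groups = "drop"
  )
  all_ids <- sort(setdiff(unique(assignment$cluster), 0L))
  pooled <- dplyr::left_join(tibble::tibble(cluster = all_ids), pooled,
                             by = "cluster")
  pooled$n_pooled[is.na(pooled$n_pooled)] <- 0L
  denom <- sum(totals$total_events[
    vapply(meta[totals$sample_id], `[[`, character(1), "role") != "buffer"])
  pooled$abundance <- pooled$n_pooled / denom
  pooled$size_rank <- rank(-pooled$mfi_611, ties.method = "first",
                           na.last = "keep")
  structure(list(pooled = pooled, per_sample = per_sample),
            class = "cluster_profiles")
}

#' @exportS3Method print cluster_profiles
print.cluster_profiles <- function(x, ...) {
  cat(sprintf("<cluster_profiles> %d clusters, %d samples\n",
              nrow(x$pooled), length(unique(x$per_sample$sample_id))))
  print(x$pooled)
  invisible(x)
}

#' Keep clusters holding at least a minimum share of the data
#'
#' Population-level analyses examine clusters containing at least
#' `min_fraction` (default 1 percent) of the pooled non-buffer events;
#' minor clusters are kept separately for reference.
#'
#' @param profiles A `cluster_profiles` object.
#' @param min_fraction Minimum pooled abundance (default 0.01).
#' @return The filtered `cluster_profiles`, with the dropped pooled rows in
#'   `$minor`.
#' @export
filter_minor_clusters <- function(profiles, min_fraction = 0.01) {
  keep <- profiles$pooled$abundance >= min_fraction
  out <- profiles
  out$minor <- profiles$pooled[!keep, , drop = FALSE]
  out$pooled <- profiles$pooled[keep, , drop = FALSE]
  out$per_sample <- dplyr::filter(
    profiles$per_sample,
    .data$cluster %in% c(0L, out$pooled$cluster))
  out
}

#' Classify populations as S-EV or L-EV from pellet enrichment
#'
#' Small EVs pellet at 100,000g and large EVs at 10,000g, so a cluster's
#' share of dilution-corrected counts in the 100K pellet indicates its size
#' class: S-EV when the 100K share is at least 0.5 *and* its 488-611 MFI
#' lies in the lower quartile of the observed cluster MFI range; L-EV when
#' the 100K share is below 0.5; otherwise unclassified.
#'
#' @param profiles A `cluster_profiles` covering both pellet samples.
#' @param pellet_10k,pellet_100k Sample ids of the 10K and 100K pellets.
#' @return The pooled profile table with `share_100k` and `sev_lev` columns.
#' @export
classify_sev_lev <- function(profiles, pellet_10k, pellet_100k) {
  ps <- profiles$per_sample
  if (!all(c(pellet_10k, pellet_100k) %in% ps$sample_id)) {
    stop("both pellet samples must be present in the profiles",
         call. = FALSE)
  }
  get_counts <- function(sid) {
    d <- ps[ps$sample_id == sid & ps$cluster > 0L, ]
    stats::setNames(d$corrected_count, d$cluster)
  }
  c10 <- get_counts(pellet_10k)
  c100 <- get_counts(pellet_100k)
  out <- profiles$pooled
  key <- as.character(out$cluster)
  n10 <- unname(c10[key]); n10[is.na(n10)] <- 0
  n100 <- unname(c100[key]); n100[is.na(n100)] <- 0
  out$share_100k <- ifelse(n10 + n100 > 0, n100 / (n10 + n100), NA_real_)
  rng <- range(out$mfi_611, na.rm = TRUE)
  lower_q <- rng[1] + 0.25 * diff(rng)
  out$sev_lev <- dplyr::case_when(
    is.na(out$share_100k) ~ "unclassified",
    out$share_100k < 0.5 ~ "L-EV",
    out$mfi_611 <= lower_q ~ "S-EV",
    TRUE ~ "unclassified"
  )
  out
}

#' Per-cluster abundance as a percentage of a control sample
#'
#' `100 * corrected condition count / corrected control count`, per cluster;
#' clusters with zero control count are flagged incalculable (`NA`).
#'
#' @param profiles A `cluster_profiles`.
#' @param control_id Sample id of the control.
#' @return Tibble of `cluster`, `sample_id`, `condition`,
#'   `percent_of_control`.
#' @export
percent_of_control <- function(profiles, control_id) {
  ps <- dplyr::filter(profiles$per_sample, .data$cluster > 0L)
  if (!control_id %in% ps$sample_id) {
    stop("control sample '", control_id, "' not present", call. = FALSE)
  }
  ctrl <- ps[ps$sample_id == control_id, ]
  ctrl_counts <- stats::setNames(ctrl$corrected_count, ctrl$cluster)
  cond <- ps[ps$sample_id != control_id, ]
  denom <- unname(ctrl_counts[as.character(cond$cluster)])
  tibble::tibble(
    cluster = cond$cluster,
    sample_id = cond$sample_id,
    condition = cond$condition,
    percent_of_control = ifelse(!is.na(denom) & denom > 0,
                                100 * cond$corrected_count / denom,
                                NA_real_)
  )
}

#' Reference ladder of liposome standards
#'
#' Ordered reference records for membrane-order standards (DSPC liposomes
#' with increasing cholesterol, increasing GP) or sizing standards (90, 200,
#' 400 nm liposomes, increasing 488-611 MFI).
#'
#' @param label Rung labels (e.g. `"chol_00"`, or `"90nm"`).
#' @param value Measured GP or MFI per rung; must be monotone in rung order.
#' @param kind `"gp"` or `"mfi"`.
#' @return Tibble of class `standard_ladder`.
#' @export
standard_ladder <- function(label, value, kind = c("gp", "mfi")) {
  kind <- match.arg(kind)
  d <- diff(value)
  if (!(all(d > 0) || all(d < 0))) {
    stop("ladder values must be strictly monotone", call. = FALSE)
  }
  structure(tibble::tibble(label = label, value = value),
            kind = kind, class = c("standard_ladder", class(tibble::tibble())))
}

#' Annotate cluster profiles against a standard ladder
#'
#' Each cluster is assigned the bracketing ladder interval for the ladder's
#' statistic (GP for membrane-order standards, MFI for sizing standards);
#' values beyond the ladder ends are labeled below/above the end standard.
#' The MFI of `gate_rung` (default the last rung, e.g. the 400 nm liposome)
#' is returned as the size-threshold gate value.
#'
#' @param profiles A `cluster_profiles`.
#' @param ladder A [standard_ladder()].
#' @param gate_rung Label of the rung whose value becomes the size gate
#'   (used for `kind = "mfi"` ladders; default last rung).
#' @return Pooled profile table with a `ladder_interval` column; attribute
#'   `gate_value` holds the designated rung's value.
#' @export
map_to_ladder <- function(profiles, ladder,
                          gate_rung = ladder$label[nrow(ladder)]) {
  stopifnot(inherits(ladder, "standard_ladder"))
  stat <- if (attr(ladder, "kind") == "gp") profiles$pooled$gp_median
          else profiles$pooled$mfi_611
  lv <- ladder$value
  ll <- ladder$label
  if (lv[1] > lv[length(lv)]) { lv <- rev(lv); ll <- rev(ll) }
  interval <- vapply(stat, function(g) {
    if (is.na(g)) return(NA_character_)
    if (g < lv[1]) return(paste0("below ", ll[1]))
    if (g > lv[length(lv)]) return(paste0("above ", ll[length(ll)]))
    hit <- which(abs(g - lv) < 1e-12)
    if (length(hit)) return(ll[hit[1]])
    i <- findInterval(g, lv)
    paste0(ll[i], "..", ll[i + 1])
  }, character(1))
  out <- profiles$pooled
  out$ladder_interval <- interval
  attr(out, "gate_value") <- ladder$value[match(gate_rung, ladder$label)]
  out
}

#' Size/membrane-order change map of a condition
#'
#' One record per cluster combining its size proxy (488-611 MFI), membrane
#' order (median GP), abundance and percent-of-control for the chosen
#' condition sample — the table behind the bubble-plot view — plus an
#' ordinary least-squares regression of percent change against a chosen
#' covariate.
#'
#' @param profiles A `cluster_profiles`.
#' @param control_id,condition_id Sample ids of control and condition.
#' @param covariate Which covariate to regress percent-of-control on:
#'   `"gp_median"`, `"mfi_611"` or `"tfl"`.
#' @return Tibble with one row per cluster; attribute `regression` holds
#'   `list(slope, intercept, r_squared)` (`NULL` with fewer than 2 usable
#'   clusters, flagged undefined).
#' @export
size_order_change_map <- function(profiles, control_id, condition_id,
                                  covariate = c("gp_median", "mfi_611",
                                                "tfl")) {
  covariate <- match.arg(covariate)
  pc <- percent_of_control(profiles, control_id)
  pc <- pc[pc$sample_id == condition_id, c("cluster", "percent_of_control")]
  out <- dplyr::left_join(
    profiles$pooled[, c("cluster", "mfi_611", "gp_median", "tfl",
                        "abundance")],
    pc, by = "cluster")
  usable <- stats::complete.cases(out[, c(covariate, "percent_of_control")])
  reg <- NULL
  if (sum(usable) >= 2) {
    fit <- stats::lm(out$percent_of_control[usable] ~ out[[covariate]][usable])
    r2 <- summary(fit)$r.squared
    reg <- list(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                r_squared = if (is.nan(r2)) 0 else r2,
                covariate = covariate)
  }
  attr(out, "regression") <- reg
  out
}
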