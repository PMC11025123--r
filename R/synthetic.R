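#' Spectral model for simulated di8 emission
#'
#' Simulated di8 emission across the five 488 nm-excited bands
#' (528/583/611/702/773 nm) is a convex mixture of two basis spectra: an
#' ordered-membrane (Lo) basis peaked at 611 nm and a disordered-membrane
#' (Ld) basis peaked at 702 nm, reproducing the dye's 702 to 611 nm peak
#' shift as membrane order increases. Each basis lies on the probability
#' simplex. The defaults give GP(Lo) = +0.5 and GP(Ld) = -0.5 under the
#' pipeline's two-channel GP (611 vs 702), so that generalized polarization
#' targets in roughly (-0.5, 0.5) are reachable; they are simulator
#' conventions, not measured spectra.
#'
#' @param w_lo,w_ld Nonnegative 5-vectors summing to 1 (emission order
#'   528, 583, 611, 702, 773 nm), peaked at 611 and 702 nm respectively.
#' @param channel_cv Per-channel multiplicative log-normal noise coefficient
#'   of variation (>= 0).
#' @return A list of class `spectral_model`.
#' @export
spectral_model <- function(w_lo = c(0.10, 0.12, 0.45, 0.15, 0.18),
                           w_ld = c(0.08, 0.10, 0.15, 0.45, 0.22),
                           channel_cv = 0.08) {
  stopifnot(length(w_lo) == 5, length(w_ld) == 5, all(w_lo >= 0),
            all(w_ld >= 0), channel_cv >= 0)
  w_lo <- w_lo / sum(w_lo)
  w_ld <- w_ld / sum(w_ld)
  if (which.max(w_lo) != 3L) stop("w_lo must peak at 611 nm", call. = FALSE)
  if (which.max(w_ld) != 4L) stop("w_ld must peak at 702 nm", call. = FALSE)
  m <- structure(list(w_lo = w_lo, w_ld = w_ld, channel_cv = channel_cv),
                 class = "spectral_model")
  if (!(gp_of_spectrum(w_lo) > 0 && gp_of_spectrum(w_ld) < 0)) {
    stop("basis spectra must satisfy GP(w_lo) > 0 > GP(w_ld)", call. = FALSE)
  }
  m
}

#' GP of a 5-channel emission spectrum (611 vs 702 nm bands)
#' @param w Numeric 5-vector over emissions (528, 583, 611, 702, 773).
#' @return Generalized polarization in `[-1, 1]`.
#' @export
gp_of_spectrum <- function(w) (w[3] - w[4]) / (w[3] + w[4])

#' GP range achievable by a spectral model
#' @param model A [spectral_model()].
#' @return `c(gp_ld, gp_lo)`.
#' @export
gp_range <- function(model) {
  c(gp_of_spectrum(model$w_ld), gp_of_spectrum(model$w_lo))
}

#' Mixing weight that realizes a target GP
#'
#' Solves the linear two-basis mixture for the Lo weight `alpha` such that
#' the spectrum `alpha * w_lo + (1 - alpha) * w_ld` has the requested GP.
#' Closed form: with d = w_lo - w_ld restricted to the 611/702 bands,
#' `alpha = (g * sum(ld_2ch) - diff(ld_2ch)) / (diff(d_2ch) - g * sum(d_2ch))`.
#'
#' @param g Target GP, inside `gp_range(model)`.
#' @param model A [spectral_model()].
#' @return Mixing weight in `[0, 1]`; the mixture's GP matches `g` to 1e-9.
#' @export
alpha_for_gp <- function(g, model = spectral_model()) {
  rng <- gp_range(model)
  if (any(g < rng[1] - 1e-12 | g > rng[2] + 1e-12)) {
    stop(sprintf("target GP outside achievable range [%.4f, %.4f]",
                 rng[1], rng[2]), call. = FALSE)
  }
  lo <- model$w_lo; ld <- model$w_ld
  d3 <- lo[3] - ld[3]; d4 <- lo[4] - ld[4]
  a <- (g * (ld[3] + ld[4]) - (ld[3] - ld[4])) / ((d3 - d4) - g * (d3 + d4))
  pmin(1, pmax(0, a))
}

mixture_spectrum <- function(alpha, model) {
  outer(alpha, model$w_lo) + outer(1 - alpha, model$w_ld)
}

#' Describe one simulated EV population
#'
#' @param name Population label (stored in the `.population` sidecar).
#' @param fraction Proportion of the sample's events (in `(0, 1]`); fractions
#'   across populations may sum to at most 1, any remainder becomes
#'   background events.
#' @param log_brightness_mean,log_brightness_sd Log-normal parameters
#'   (natural log) of total di8 intensity, the proxy for membrane area and
#'   hence particle size.
#' @param gp_target Population median generalized polarization; must lie in
#'   the spectral model's achievable range.
#' @param gp_sd Event-to-event GP standard deviation (>= 0).
#' @param cargo_probs Named per-antibody positivity probabilities in
#'   `[0, 1]`, e.g. `c(CD63 = 0.3, CD81 = 0.2)`.
#' @param cargo_meanlog,cargo_sdlog Log-normal intensity parameters for
#'   antibody-positive events.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(name, fraction, log_brightness_mean,
                            log_brightness_sd = 0.15, gp_target = 0,
                            gp_sd = 0.05, cargo_probs = numeric(0),
                            cargo_meanlog = log(300), cargo_sdlog = 0.5) {
  stopifnot(fraction > 0, fraction <= 1, log_brightness_sd >= 0, gp_sd >= 0,
            all(cargo_probs >= 0 & cargo_probs <= 1))
  structure(list(name = name, fraction = fraction,
                 log_brightness_mean = log_brightness_mean,
                 log_brightness_sd = log_brightness_sd,
                 gp_target = gp_target, gp_sd = gp_sd,
                 cargo_probs = cargo_probs, cargo_meanlog = cargo_meanlog,
                 cargo_sdlog = cargo_sdlog),
            class = "population_spec")
}

#' Simulation scenario defaults
#'
#' Nuisance-event rates and acquisition settings shared by the simulators.
#' Background events (dye aggregates, non-vesicular particles) are dim and
#' spectrally broad; free-dye events sit at the detection floor. Rates are
#' events per minute and do not scale with sample dilution, unlike EV events.
#'
#' @param background_rate,free_dye_rate Events/min of each nuisance class.
#' @param background_meanlog,background_sdlog Log-normal brightness of
#'   background events.
#' @param ab_floor_meanlog,ab_floor_sdlog Log-normal antibody-channel noise
#'   floor for antibody-negative events.
#' @param isotype_floor False-positive probability floor used for isotype
#'   controls.
#' @param ssc_exponent Exponent s in `SSC ~ brightness^s`.
#' @param area_exponent Exponent in `Area ~ brightness^e` (membrane area vs
#'   projected image area).
#' @param rawmax_packing RawMaxPixel / Intensity packing factor.
#' @param aspect_sd Half-normal spread of aspect ratio above 1.
#' @param swarm_ceiling Events/min above which coincident-event merging (the
#'   swarm artifact) is applied when enabled; `Inf` disables saturation.
#' @return A list of class `scenario_defaults`.
#' @export
scenario_defaults <- function(background_rate = 150, free_dye_rate = 75,
                              background_meanlog = log(6),
                              background_sdlog = 0.9,
                              ab_floor_meanlog = log(2), ab_floor_sdlog = 0.6,
                              isotype_floor = 0.005,
                              ssc_exponent = 0.7, area_exponent = 0.5,
                              rawmax_packing = 0.3, aspect_sd = 0.08,
                              swarm_ceiling = Inf) {
  structure(as.list(environment()), class = "scenario_defaults")
}

ab_channels_for <- function(cargo_names, map) {
  if (length(cargo_names) == 0) return(character(0))
  ab <- map$instrument_name[map$feature_kind == "Intensity" &
                              map$excitation_nm != 488L]
  if (length(ab) < length(cargo_names)) {
    stop("channel map has fewer antibody channels than cargo_probs entries",
         call. = FALSE)
  }
  stats::setNames(ab[seq_along(cargo_names)], cargo_names)
}

# Draw raw channel intensities for n events with total brightness B and
# per-event mixing weight alpha. Multiplicative log-normal noise has median 1
# so population median GP stays on target.
draw_channels <- function(B, alpha, model, defaults, map) {
  n <- length(B)
  spec <- mixture_spectrum(alpha, model)
  sdlog <- defaults_channel_sd(model)
  noise <- function() {
    if (sdlog == 0) matrix(1, n, 5) else
      matrix(exp(stats::rnorm(n * 5, 0, sdlog)), n, 5)
  }
  intensity <- B * spec * noise()
  rawmax <- intensity * defaults$rawmax_packing *
    (if (sdlog == 0) 1 else exp(stats::rnorm(n * 5, 0, sdlog)))
  area <- (B^defaults$area_exponent) *
    matrix(1, n, 5) * (if (sdlog == 0) 1 else
      matrix(exp(stats::rnorm(n * 5, 0, sdlog)), n, 5))
  aspect <- 1 + abs(matrix(stats::rnorm(n * 5, 0, defaults$aspect_sd), n, 5))
  ssc <- (B^defaults$ssc_exponent) *
    (if (sdlog == 0) rep(1, n) else exp(stats::rnorm(n, 0, sdlog)))
  out <- cbind(intensity, rawmax, area, aspect, ssc)
  colnames(out) <- c(di8_channel_names(map), channel_name(map, "SSC"))
  out
}

defaults_channel_sd <- function(model) {
  # log-normal sdlog giving approximately the requested CV for small CV
  if (model$channel_cv == 0) 0 else sqrt(log(1 + model$channel_cv^2))
}

truncated_gp <- function(n, target, sd, rng) {
  eps <- 1e-6
  lo <- rng[1] + eps
  hi <- rng[2] - eps
  if (sd == 0) return(rep(pmin(hi, pmax(lo, target)), n))
  g <- stats::rnorm(n, target, sd)
  while (any(bad <- g < lo | g > hi)) {
    g[bad] <- stats::rnorm(sum(bad), target, sd)
  }
  g
}

#' Simulate one stained single-EV sample
#'
#' Draws `n_events` EV events across the populations (multinomial by
#' `fraction`; any remainder becomes background events), then appends
#' rate-based background and free-dye events
#' (`rate * acquisition_minutes` each, background not diluted). Per EV
#' event, total brightness is log-normal, the emission spectrum realizes a
#' truncated-normal GP draw around `gp_target`, and image features follow
#' brightness with multiplicative log-normal channel noise. Ground-truth
#' labels are kept in the `.population` sidecar column.
#'
#' @param populations List of [population_spec()].
#' @param n_events Number of EV-slot events before rate-based nuisance events.
#' @param seed Integer seed; fully determines the output.
#' @param sample_id,metadata Sample identity and acquisition metadata; the
#'   metadata's `dilution` divides the expected EV count.
#' @param model A [spectral_model()].
#' @param defaults A [scenario_defaults()].
#' @param map Channel map (must include antibody channels when any
#'   population has `cargo_probs`).
#' @param swarm Apply coincident-event merging above
#'   `defaults$swarm_ceiling` events/min.
#' @return An [ev_events()] table.
#' @export
simulate_sample <- function(populations, n_events, seed,
                            sample_id = "sample",
                            metadata = ev_metadata(),
                            model = spectral_model(),
                            defaults = scenario_defaults(),
                            map = default_channel_map(),
                            swarm = FALSE) {
  stopifnot(n_events >= 0)
  if (inherits(populations, "population_spec")) populations <- list(populations)
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  if (length(fr) && sum(fr) > 1 + 1e-9) {
    stop("population fractions sum to more than 1", call. = FALSE)
  }
  metadata <- validate_metadata(metadata)
  rng <- gp_range(model)
  for (p in populations) {
    if (p$gp_target <= rng[1] || p$gp_target >= rng[2]) {
      stop(sprintf("gp_target %.3f of population '%s' outside achievable (%.3f, %.3f)",
                   p$gp_target, p$name, rng[1], rng[2]), call. = FALSE)
    }
  }
  set.seed(as.integer(seed %% .Machine$integer.max))

  n_ev_slot <- if (metadata$dilution > 1) {
    stats::rbinom(1, n_events, 1 / metadata$dilution)
  } else n_events
  probs <- c(fr, max(0, 1 - sum(fr)))
  counts <- if (n_ev_slot > 0) {
    as.integer(stats::rmultinom(1, n_ev_slot, probs))
  } else integer(length(probs))
  n_bg_extra <- counts[length(counts)]
  counts <- counts[-length(counts)]

  cargo_names <- unique(unlist(lapply(populations,
                                      function(p) names(p$cargo_probs))))
  ab_map <- ab_channels_for(cargo_names, map)

  blocks <- list()
  for (i in seq_along(populations)) {
    p <- populations[[i]]
    n <- counts[i]
    if (n == 0) next
    B <- stats::rlnorm(n, p$log_brightness_mean, p$log_brightness_sd)
    g <- truncated_gp(n, p$gp_target, p$gp_sd, gp_range(model))
    ch <- draw_channels(B, alpha_for_gp(g, model), model, defaults, map)
    ab <- matrix(0, n, length(ab_map),
                 dimnames = list(NULL, unname(ab_map)))
    for (a in cargo_names) {
      pos <- stats::runif(n) < (p$cargo_probs[a] %||% 0)
      v <- stats::rlnorm(n, defaults$ab_floor_meanlog, defaults$ab_floor_sdlog)
      v[pos] <- stats::rlnorm(sum(pos), p$cargo_meanlog, p$cargo_sdlog)
      ab[, ab_map[a]] <- v
    }
    blocks[[length(blocks) + 1L]] <-
      cbind(as.data.frame(ch), as.data.frame(ab),
            .population = rep(p$name, n))
  }

  n_bg <- n_bg_extra +
    stats::rpois(1, defaults$background_rate * metadata$acquisition_minutes)
  n_fd <- stats::rpois(1, defaults$free_dye_rate * metadata$acquisition_minutes)
  nuisance <- function(n, meanlog, sdlog, label) {
    if (n == 0) return(NULL)
    B <- stats::rlnorm(n, meanlog, sdlog)
    alpha <- stats::runif(n)  # spectrally incoherent
    ch <- draw_channels(B, alpha, model, defaults, map)
    ab <- matrix(stats::rlnorm(n * length(ab_map), defaults$ab_floor_meanlog,
                               defaults$ab_floor_sdlog),
                 n, length(ab_map), dimnames = list(NULL, unname(ab_map)))
    cbind(as.data.frame(ch), as.data.frame(ab),
          .population = rep(label, n))
  }
  blocks[[length(blocks) + 1L]] <-
    nuisance(n_bg, defaults$background_meanlog, defaults$background_sdlog,
             "background")
  blocks[[length(blocks) + 1L]] <-
    nuisance(n_fd, log(1.5), 0.4, "free_dye")

  d <- dplyr::bind_rows(Filter(Negate(is.null), blocks))
  if (nrow(d) > 0) d <- d[sample.int(nrow(d)), , drop = FALSE]
  if (nrow(d) == 0) {
    cols <- c(di8_channel_names(map), channel_name(map, "SSC"),
              unname(ab_map))
    d <- as.data.frame(stats::setNames(lapply(cols, function(.) numeric(0)),
                                       cols),
                       check.names = FALSE)
    d$.population <- character(0)
  }
  if (swarm && is.finite(defaults$swarm_ceiling)) {
    d <- apply_swarm(d, metadata$acquisition_minutes,
                     defaults$swarm_ceiling)
  }
  ev_events(d, sample_id = sample_id, metadata = metadata, channels = map)
}

`%||%` <- function(a, b) {
  if (is.null(a) || (length(a) == 1 && is.atomic(a) && is.na(a))) b else a
}

# Swarm/coincidence artifact: above the detector's event-rate ceiling,
# pairs of coincident particles register as one brighter event.
apply_swarm <- function(d, minutes, ceiling_rate) {
  cap <- floor(ceiling_rate * minutes)
  n <- nrow(d)
  excess <- n - cap
  if (excess <= 0) return(d)
  excess <- min(excess, floor(n / 2))
  idx <- seq_len(2L * excess)        # rows are already shuffled
  a <- idx[seq_len(excess)]
  b <- idx[excess + seq_len(excess)]
  meas <- setdiff(names(d), ".population")
  merged <- d[a, , drop = FALSE]
  merged[meas] <- d[a, meas] + d[b, meas]
  merged$.population <- paste0("swarm:", d$.population[a])
  rbind(merged, d[-idx, , drop = FALSE])
}

#' Simulate the standard control set for a sample
#'
#' Returns buffer (background only), lysed (background + free dye; detergent
#' removes all vesicles), unstained (free dye absent, vesicles at the
#' detection floor — represented as background only plus residual
#' autofluorescence), and isotype (full sample with antibody positivity at
#' the false-positive floor) controls.
#'
#' @inheritParams simulate_sample
#' @return Named list of [ev_events()]: `buffer`, `lysed`, `unstained`,
#'   `isotype`.
#' @export
simulate_controls <- function(populations, n_events, seed,
                              metadata = ev_metadata(),
                              model = spectral_model(),
                              defaults = scenario_defaults(),
                              map = default_channel_map()) {
  no_fd <- defaults; no_fd$free_dye_rate <- 0
  mk_meta <- function(role) {
    m <- metadata; m$role <- role; m
  }
  iso_pops <- lapply(if (inherits(populations, "population_spec"))
    list(populations) else populations, function(p) {
      p$cargo_probs[] <- defaults$isotype_floor
      p
    })
  list(
    buffer = simulate_sample(list(), 0, seed + 1L, "buffer",
                             mk_meta("buffer"), model, no_fd, map),
    lysed = simulate_sample(list(), 0, seed + 2L, "lysed",
                            mk_meta("lysed"), model, defaults, map),
    unstained = simulate_sample(list(), 0, seed + 3L, "unstained",
                                mk_meta("unstained"), model, no_fd, map),
    isotype = simulate_sample(iso_pops, n_events, seed + 4L, "isotype",
                              mk_meta("isotype"), model, defaults, map)
  )
}

#' Simulate a dilution series of one sample
#'
#' Expected EV event count scales as 1/dilution while the nuisance-event
#' rates stay constant. With `swarm = TRUE` and a finite
#' `defaults$swarm_ceiling`, low dilutions exceed the detector's event-rate
#' ceiling and coincident events are merged into fewer, brighter events.
#'
#' @inheritParams simulate_sample
#' @param factors Dilution factors (each >= 1); must be nonempty.
#' @return List of [ev_events()], one per factor, named by factor.
#' @export
simulate_dilution_series <- function(populations, n_events, factors, seed,
                                     metadata = ev_metadata(),
                                     model = spectral_model(),
                                     defaults = scenario_defaults(),
                                     map = default_channel_map(),
                                     swarm = FALSE) {
  if (length(factors) == 0) stop("empty dilution factor list", call. = FALSE)
  stopifnot(all(factors >= 1))
  out <- lapply(seq_along(factors), function(i) {
    m <- metadata
    m$dilution <- factors[i]
    simulate_sample(populations, n_events, seed + 101L * i,
                    sample_id = sprintf("dilution_%g", factors[i]),
                    metadata = m, model = model, defaults = defaults,
                    map = map, swarm = swarm)
  })
  stats::setNames(out, sprintf("%g", factors))
}
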