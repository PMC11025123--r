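#' Balance a pair of samples by downsampling
#'
#' Pairwise change detection compares equal numbers of events from each
#' sample: the larger sample is downsampled uniformly (seeded, without
#' replacement) to the smaller one's count.
#'
#' @param a,b [ev_events()] tables (both nonempty).
#' @param seed Integer seed.
#' @return List with the balanced tables `a` and `b` and the retained row
#'   indices `idx_a`, `idx_b`.
#' @export
equal_sample_pair <- function(a, b, seed = 1) {
  na <- n_events(a); nb <- n_events(b)
  if (na == 0 || nb == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- min(na, nb)
  idx_a <- if (na > n) sort(sample.int(na, n)) else seq_len(na)
  idx_b <- if (nb > n) sort(sample.int(nb, n)) else seq_len(nb)
  list(a = subset_events(a, idx_a), b = subset_events(b, idx_b),
       idx_a = idx_a, idx_b = idx_b)
}

#' Per-event KNN sample fraction
#'
#' For every event in the shared 2-D embedding of a balanced pair, the
#' fraction of its `k` nearest Euclidean neighbors (self excluded) that
#' originate from the second sample. Neighbor ties at the k-th distance are
#' broken by lowest event index, so the result is deterministic.
#'
#' @param coords Numeric n x 2 embedding coordinates of the combined pair.
#' @param from_b Logical vector: event originates from sample 2.
#' @param k Neighborhood size (default 60).
#' @return Numeric vector `f` in `[0, 1]`, one value per event.
#' @export
knn_fraction <- function(coords, from_b, k = 60) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(length(from_b) == n)
  if (n <= k) stop("need more events than k", call. = FALSE)
  kq <- min(n - 1L, k + 10L)  # small surplus so ties can be re-ordered
  nn <- FNN::get.knn(coords, k = kq)
  f <- numeric(n)
  fb <- as.numeric(from_b)
  for (i in seq_len(n)) {
    idx <- nn$nn.index[i, ]
    d <- nn$nn.dist[i, ]
    o <- order(d, idx)[seq_len(k)]
    f[i] <- sum(fb[idx[o]]) / k
  }
  f
}

#' Direction labels from KNN fractions
#'
#' Events are labeled as 85 or 95 percent hotspots of either sample:
#' `sample2_95` when `f >= 0.95`, `sample2_85` when `0.85 <= f < 0.95`,
#' symmetric labels for sample 1 via `1 - f`, and `none` otherwise.
#'
#' @param f KNN fractions from [knn_fraction()].
#' @param thresholds Two increasing thresholds (default `c(0.85, 0.95)`).
#' @return Factor with levels
#'   `none, sample1_85, sample1_95, sample2_85, sample2_95`.
#' @export
call_hotspots <- function(f, thresholds = c(0.85, 0.95)) {
  stopifnot(length(thresholds) == 2, diff(thresholds) > 0)
  t1 <- thresholds[1]; t2 <- thresholds[2]
  lab <- dplyr::case_when(
    f >= t2 ~ "sample2_95",
    f >= t1 ~ "sample2_85",
    f <= 1 - t2 ~ "sample1_95",
    f <= 1 - t1 ~ "sample1_85",
    TRUE ~ "none"
  )
  factor(lab, levels = c("none", "sample1_85", "sample1_95",
                         "sample2_85", "sample2_95"))
}

#' Cluster >=95 percent hotspot events into regions
#'
#' DBSCAN (default `eps = 1`, `minPts = 1`, eps in embedding coordinate
#' units) applied separately to each direction's >= 95 percent events; with
#' `minPts = 1` every hotspot event belongs to a region (no noise).
#'
#' @param coords Embedding coordinates of the combined pair.
#' @param labels Factor from [call_hotspots()].
#' @param eps,min_pts DBSCAN parameters.
#' @return Tibble of `event` (row index), `direction`, `region` (ids unique
#'   across directions); zero rows when no events reach 95 percent. The
#'   `regions` attribute summarizes each region (count, bounding box).
#' @export
cluster_hotspots <- function(coords, labels, eps = 1, min_pts = 1) {
  coords <- as.matrix(coords)
  out <- list()
  offset <- 0L
  for (dir in c("sample1_95", "sample2_95")) {
    idx <- which(labels == dir)
    if (length(idx) == 0) next
    reg <- dbscan_clusters(coords[idx, , drop = FALSE], eps = eps,
                           min_pts = min_pts)
    keep <- reg > 0L
    out[[dir]] <- tibble::tibble(event = idx[keep], direction = dir,
                                 region = reg[keep] + offset)
    offset <- offset + max(0L, attr(reg, "n_clusters"))
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(event = integer(0), direction = character(0),
                   region = integer(0))
  summ <- if (nrow(res)) dplyr::summarise(
    dplyr::group_by(res, .data$direction, .data$region),
    n = dplyr::n(),
    xmin = min(coords[.data$event, 1]), xmax = max(coords[.data$event, 1]),
    ymin = min(coords[.data$event, 2]), ymax = max(coords[.data$event, 2]),
    .groups = "drop"
  ) else NULL
  attr(res, "regions") <- summ
  res
}

#' Pairwise change detection on a shared embedding (T-REX)
#'
#' Runs the full pairwise comparison: balance the pair, embed the combined
#' events (asinh-transformed di8 features, UMAP), compute per-event KNN
#' sample fractions, call 85/95 percent hotspots, and cluster the >= 95
#' percent events into regions.
#'
#' @param a,b [ev_events()] tables to compare.
#' @param k Neighborhood size (default 60).
#' @param thresholds Hotspot thresholds (default `c(0.85, 0.95)`).
#' @param eps,min_pts Region-clustering DBSCAN parameters (defaults 1, 1).
#' @param cofactor asinh cofactor.
#' @param seed Integer seed driving downsampling and the embedding.
#' @param embedding Optional precomputed `ev_embedding` (or coordinate
#'   matrix) of the *balanced, concatenated* pair, a then b; when supplied
#'   the pair must already be balanced.
#' @param umap_params List of UMAP parameter overrides.
#' @return A list of class `trex_result`: `events` tibble (`sample_id`,
#'   `event`, coordinates, `f`, `label`, `region`), `regions` summary, and
#'   `params`.
#' @export
run_trex <- function(a, b, k = 60, thresholds = c(0.85, 0.95), eps = 1,
                     min_pts = 1, cofactor = 1, seed = 1, embedding = NULL,
                     umap_params = list()) {
  pair <- equal_sample_pair(a, b, seed = seed)
  feats <- rbind(select_di8_features(pair$a), select_di8_features(pair$b))
  from_b <- rep(c(FALSE, TRUE), c(n_events(pair$a), n_events(pair$b)))
  coords <- if (is.null(embedding)) {
    args <- c(list(features = asinh_transform(feats, cofactor),
                   seed = seed + 1L), umap_params)
    do.call(embed_events, args)$coords
  } else if (inherits(embedding, "ev_embedding")) embedding$coords
    else as.matrix(embedding)
  stopifnot(nrow(coords) == length(from_b))
  f <- knn_fraction(coords, from_b, k = k)
  lab <- call_hotspots(f, thresholds)
  regions <- cluster_hotspots(coords, lab, eps = eps, min_pts = min_pts)
  ev <- tibble::tibble(
    sample_id = c(rep(pair$a$sample_id, n_events(pair$a)),
                  rep(pair$b$sample_id, n_events(pair$b))),
    event = c(pair$idx_a, pair$idx_b),
    umap1 = coords[, 1], umap2 = coords[, 2],
    f = f, label = lab, region = NA_integer_
  )
  ev$region[regions$event] <- regions$region
  structure(list(events = ev, regions = attr(regions, "regions"),
                 params = list(k = k, thresholds = thresholds, eps = eps,
                               min_pts = min_pts, seed = seed)),
            class = "trex_result")
}

#' @exportS3Method print trex_result
print.trex_result <- function(x, ...) {
  n <- nrow(x$events)
  hot <- mean(x$events$label %in% c("sample1_95", "sample2_95"))
  cat(sprintf("<trex_result> %d events, k=%d; %.2f%% in >=95%% hotspots, %d regions\n",
              n, x$params$k, 100 * hot,
              if (is.null(x$regions)) 0L else nrow(x$regions)))
  invisible(x)
}
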