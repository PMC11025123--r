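#' Randomized exploration subsample
#'
#' Stage one of the fingerprinting workflow explores a randomized portion of
#' each sample: `ceiling(fraction * n)` events are drawn per sample without
#' replacement, uniformly, under the given seed, and concatenated with their
#' sample identity retained.
#'
#' @param tables List of [ev_events()].
#' @param fraction Sampling fraction in `(0, 1]`.
#' @param seed Integer seed; fully determines the selection.
#' @return Tibble with `sample_id`, `event` (row index in the source table)
#'   and all shared channel columns (plus `.population` when present).
#' @export
subsample_events <- function(tables, fraction, seed) {
  stopifnot(fraction > 0, fraction <= 1)
  set.seed(as.integer(seed %% .Machine$integer.max))
  long <- lapply(tables, function(t) {
    n <- n_events(t)
    take <- sort(sample.int(n, size = ceiling(fraction * n)))
    d <- t$data[take, , drop = FALSE]
    tibble::add_column(d, sample_id = t$sample_id, event = take, .before = 1)
  })
  dplyr::bind_rows(long)
}

#' Embed di8 features in two dimensions with UMAP
#'
#' @param features Numeric matrix of (asinh-transformed) di8 features, one
#'   row per event.
#' @param n_neighbors,min_dist,metric UMAP parameters (defaults 15, 0.1,
#'   Euclidean).
#' @param seed Integer seed; embeddings are reproducible for identical
#'   (input, parameters, seed).
#' @return An `ev_embedding`: list with `coords` (n x 2 matrix, columns
#'   `umap1`, `umap2`) and `params`.
#' @export
embed_events <- function(features, n_neighbors = 15, min_dist = 0.1,
                         metric = "euclidean", seed = 1) {
  features <- as.matrix(features)
  if (nrow(features) <= n_neighbors) {
    stop("embedding needs more events than n_neighbors", call. = FALSE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  coords <- uwot::umap(features, n_neighbors = n_neighbors,
                       min_dist = min_dist, metric = metric,
                       n_threads = 1, n_sgd_threads = 0, batch = FALSE,
                       verbose = FALSE)
  colnames(coords) <- c("umap1", "umap2")
  structure(list(coords = coords,
                 params = list(n_neighbors = n_neighbors,
                               min_dist = min_dist, metric = metric,
                               seed = seed)),
            class = "ev_embedding")
}

#' @exportS3Method print ev_embedding
print.ev_embedding <- function(x, ...) {
  cat(sprintf("<ev_embedding> %d events (n_neighbors=%d, min_dist=%g, seed=%d)\n",
              nrow(x$coords), x$params$n_neighbors, x$params$min_dist,
              x$params$seed))
  invisible(x)
}

#' Call populations on an embedding with HDBSCAN
#'
#' @param embedding An `ev_embedding` (or a 2-column coordinate matrix).
#' @param min_cluster_size Smallest population size; the default scales as
#'   `max(50, 0.001 * n)` so populations down to ~1 percent of the data are
#'   comfortably above it.
#' @param min_samples Core-distance neighborhood size (see
#'   [hdbscan_clusters()]).
#' @return Integer cluster labels (0 = noise, ids by decreasing size) with
#'   attributes `n_clusters` and `params`.
#' @export
cluster_embedding <- function(embedding, min_cluster_size = NULL,
                              min_samples = NULL) {
  coords <- if (inherits(embedding, "ev_embedding")) embedding$coords
            else as.matrix(embedding)
  if (nrow(coords) == 0) stop("empty embedding", call. = FALSE)
  if (is.null(min_cluster_size)) {
    min_cluster_size <- max(50L, ceiling(0.001 * nrow(coords)))
  }
  if (is.null(min_samples)) min_samples <- min(min_cluster_size, 25L)
  lab <- hdbscan_clusters(coords, min_cluster_size = min_cluster_size,
                          min_samples = min_samples)
  attr(lab, "params") <- list(min_cluster_size = min_cluster_size,
                              min_samples = min_samples)
  lab
}

#' Re-examine selected clusters on the full data
#'
#' Stage two of the workflow: a gradient-boosted tree classifier is trained
#' on the exploration subsample's features against its cluster labels
#' (noise included as its own class), then applied to every event of every
#' sample, and events predicted into the selected clusters are returned.
#'
#' @param tables List of [ev_events()] (the full, un-subsampled data).
#' @param sub_features Feature matrix the subsample was clustered on
#'   (asinh-transformed di8 block).
#' @param sub_labels Integer cluster labels for `sub_features` rows
#'   (0 = noise).
#' @param selected Integer ids of the clusters to extract; must exist in
#'   `sub_labels`. An empty selection returns an empty table.
#' @param cofactor asinh cofactor applied to the full data (must match the
#'   subsample's transform).
#' @param seed,nrounds,max_depth,eta XGBoost determinism and learning
#'   parameters (single-threaded, seeded).
#' @return Tibble with `sample_id`, `event` and `cluster` (predicted label)
#'   for all events predicted into `selected` clusters.
#' @export
reexamine_clusters <- function(tables, sub_features, sub_labels, selected,
                               cofactor = 1, seed = 1, nrounds = 60,
                               max_depth = 6, eta = 0.3) {
  sub_labels <- as.integer(sub_labels)
  if (length(selected) == 0) {
    return(tibble::tibble(sample_id = character(0), event = integer(0),
                          cluster = integer(0)))
  }
  if (!all(selected %in% sub_labels)) {
    stop("selected cluster ids absent from the subsample assignment: ",
         paste(setdiff(selected, sub_labels), collapse = ", "),
         call. = FALSE)
  }
  classes <- sort(unique(sub_labels))
  y <- match(sub_labels, classes) - 1L
  dtrain <- xgboost::xgb.DMatrix(as.matrix(sub_features), label = y,
                                 nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob",
                  num_class = length(classes), max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  out <- lapply(tables, function(t) {
    feat <- asinh_transform(select_di8_features(t), cofactor)
    if (nrow(feat) == 0) return(NULL)
    prob <- predict(booster, xgboost::xgb.DMatrix(as.matrix(feat),
                                                  nthread = 1))
    if (is.null(dim(prob))) {
      prob <- matrix(prob, nrow = nrow(feat), byrow = TRUE)
    }
    # ties in predicted class go to the lowest cluster id (first maximum)
    pred <- classes[max.col(prob, ties.method = "first")]
    keep <- pred %in% selected
    tibble::tibble(sample_id = t$sample_id,
                   event = which(keep), cluster = pred[keep])
  })
  dplyr::bind_rows(Filter(Negate(is.null), out))
}

#' Drop buffer-derived clusters
#'
#' Clusters dominated by buffer-control events are instrument/background
#' populations, not vesicles. A cluster is dropped when its time-normalized
#' buffer event rate accounts for at least `threshold` of its total
#' time-normalized rate; survivors are relabeled contiguously by size.
#'
#' @param labels Integer cluster labels for the concatenated events.
#' @param sample_ids Character sample id per event (parallel to `labels`).
#' @param roles Named character vector mapping sample id to control role
#'   (`"buffer"` marks buffer controls).
#' @param minutes Named numeric vector of acquisition minutes per sample id
#'   (defaults to equal time).
#' @param threshold Buffer-fraction removal threshold (default 0.5).
#' @return Relabeled integer labels (removed clusters become noise, 0),
#'   with attribute `removed` holding the dropped original ids.
#' @export
remove_buffer_clusters <- function(labels, sample_ids, roles,
                                   minutes = NULL, threshold = 0.5) {
  labels <- as.integer(labels)
  buf_samples <- names(roles)[roles == "buffer"]
  if (length(buf_samples) == 0) {
    stop("no buffer-role sample present in the embedding", call. = FALSE)
  }
  if (is.null(minutes)) {
    minutes <- stats::setNames(rep(1, length(roles)), names(roles))
  }
  w <- 1 / minutes[sample_ids]            # events/min weighting
  is_buf <- sample_ids %in% buf_samples
  ids <- setdiff(sort(unique(labels)), 0L)
  removed <- integer(0)
  for (i in ids) {
    in_cl <- labels == i
    frac <- sum(w[in_cl & is_buf]) / sum(w[in_cl])
    if (frac >= threshold) removed <- c(removed, i)
  }
  labels[labels %in% removed] <- 0L
  out <- relabel_by_size(labels)
  attr(out, "removed") <- removed
  out
}
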