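#' Run the two-stage fingerprinting workflow
#'
#' Stage one embeds a randomized subsample of all samples jointly
#' (asinh-transformed di8 features, UMAP) and calls populations with
#' HDBSCAN; buffer-derived clusters are removed when buffer controls are
#' present. Stage two re-examines the surviving clusters on the full data
#' with a gradient-boosted classifier, so population statistics are
#' computed from every event, not just the exploration subsample.
#'
#' @param tables List of [ev_events()] (analytical samples plus controls);
#'   all compared samples are embedded jointly so cluster ids and T-REX
#'   comparisons share one coordinate system.
#' @param config A [default_config()]; `config$seed` drives every stage.
#' @param reexamine Run stage two (default TRUE); with FALSE the subsample
#'   assignment is returned as the final assignment.
#' @return A list of class `ev_fingerprint`: `sub` (subsample tibble),
#'   `embedding`, `sub_labels`, `assignment` (tibble `sample_id`, `event`,
#'   `cluster` over the full data), `profiles`, and `config`.
#' @export
run_fingerprint <- function(tables, config = default_config(),
                            reexamine = TRUE) {
  stopifnot(length(tables) >= 1)
  seed <- as.integer(config$seed)
  sub <- subsample_events(tables, config$subsample$fraction, seed + 11L)
  map <- tables[[1]]$channels
  feat_cols <- di8_channel_names(map)
  feats <- asinh_transform(as.matrix(sub[, feat_cols]),
                           config$transform$cofactor)
  emb <- embed_events(feats, n_neighbors = config$umap$n_neighbors,
                      min_dist = config$umap$min_dist,
                      metric = config$umap$metric, seed = seed + 23L)
  labels <- cluster_embedding(emb,
                              min_cluster_size = config$hdbscan$min_cluster_size,
                              min_samples = config$hdbscan$min_samples)
  roles <- vapply(tables, function(t) t$metadata$role, character(1))
  names(roles) <- vapply(tables, `[[`, character(1), "sample_id")
  if (any(roles == "buffer")) {
    minutes <- vapply(tables, function(t) t$metadata$acquisition_minutes,
                      numeric(1))
    names(minutes) <- names(roles)
    labels <- remove_buffer_clusters(labels, sub$sample_id, roles, minutes,
                                     config$thresholds$buffer_cluster_fraction)
  }
  ids <- setdiff(sort(unique(labels)), 0L)
  assignment <- if (reexamine && length(ids)) {
    reexamine_clusters(tables, feats, labels, selected = ids,
                       cofactor = config$transform$cofactor,
                       seed = seed + 37L,
                       nrounds = config$classifier$nrounds,
                       max_depth = config$classifier$max_depth,
                       eta = config$classifier$eta)
  } else {
    tibble::tibble(sample_id = sub$sample_id, event = sub$event,
                   cluster = as.integer(labels))[labels > 0L, ]
  }
  profiles <- profile_clusters(tables, assignment, map)
  structure(list(sub = sub, embedding = emb, sub_labels = labels,
                 assignment = assignment, profiles = profiles,
                 config = config),
            class = "ev_fingerprint")
}

#' @exportS3Method print ev_fingerprint
print.ev_fingerprint <- function(x, ...) {
  cat(sprintf("<ev_fingerprint> %d samples, %d subsampled events, %d clusters\n",
              length(unique(x$sub$sample_id)), nrow(x$sub),
              nrow(x$profiles$pooled)))
  invisible(x)
}

#' Export the numeric artifacts of a run as CSV
#'
#' CSVs are the artifacts of record (figures are derived views): the
#' per-event subsample table (coordinates + cluster), the full-data
#' assignment, pooled and per-sample cluster profiles, plus a JSON run
#' manifest (seed, parameters, sample inventory) and the archived
#' configuration.
#'
#' @param fp An `ev_fingerprint`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
export_fingerprint <- function(fp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  sub_out <- tibble::tibble(
    sample_id = fp$sub$sample_id, event = fp$sub$event,
    umap1 = fp$embedding$coords[, 1], umap2 = fp$embedding$coords[, 2],
    cluster = as.integer(fp$sub_labels)
  )
  readr::write_csv(sub_out, p("subsample_embedding.csv"), progress = FALSE)
  readr::write_csv(fp$assignment, p("assignment.csv"), progress = FALSE)
  readr::write_csv(fp$profiles$pooled, p("cluster_profiles.csv"),
                   progress = FALSE)
  readr::write_csv(fp$profiles$per_sample, p("cluster_counts_per_sample.csv"),
                   progress = FALSE)
  write_config(fp$config, p("config.yaml"))
  manifest <- list(
    seed = fp$config$seed,
    n_subsample = nrow(fp$sub),
    samples = as.list(table(fp$sub$sample_id)),
    n_clusters = nrow(fp$profiles$pooled),
    umap = fp$embedding$params,
    hdbscan = attr(fp$sub_labels, "params"),
    package_version = as.character(utils::packageVersion("evfingerprint"))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(vapply(c("subsample_embedding.csv", "assignment.csv",
                     "cluster_profiles.csv", "cluster_counts_per_sample.csv",
                     "config.yaml", "manifest.json"), p, character(1)))
}
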