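#' Run configuration
#'
#' All tunable parameters of the workflow live in one serializable
#' configuration: transform cofactor, gating quantile, UMAP/HDBSCAN/
#' classifier parameters, T-REX parameters, analysis thresholds and the
#' global seed. A run's configuration is archived verbatim beside its
#' outputs so any stage can be reproduced exactly.
#'
#' @param ... Named overrides of the defaults, nested lists merged by name
#'   (e.g. `umap = list(n_neighbors = 30)`).
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    transform = list(cofactor = 1),
    gate = list(quantile = 0.99, min_buffer_events = 100),
    subsample = list(fraction = 0.2),
    umap = list(n_neighbors = 15, min_dist = 0.1, metric = "euclidean"),
    hdbscan = list(min_cluster_size = NULL, min_samples = NULL),
    classifier = list(nrounds = 60, max_depth = 6, eta = 0.3),
    trex = list(k = 60, thresholds = c(0.85, 0.95), eps = 1, min_pts = 1),
    thresholds = list(min_cluster_fraction = 0.01,
                      buffer_cluster_fraction = 0.5,
                      positivity_fp_rate = 0.01,
                      lysis_max_ratio = 0.10),
    qc = list(r2_min = 0.98, mfi_cv_max = 0.20)
  )
  structure(merge_config(cfg, list(...)), class = "run_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read / write a run configuration (YAML)
#'
#' Unknown keys are rejected so typos fail loudly; missing keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(default_config())
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(default_config, raw)
}

#' @rdname read_config
#' @param config A `run_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
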