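#' Figure and table export for a completed run
#'
#' Figures are derived views of the CSV artifacts: UMAP density plots per
#' sample, cluster heatmaps (abundance, MFI, GP, tFL), GP boxplots with an
#' optional membrane-order ladder overlay, stacked cargo bars, and a T-REX
#' hotspot overlay. Every figure's numeric content is also written as CSV.
#'
#' @name reporting
NULL

#' UMAP density plot per sample
#' @param sub Subsample tibble with `sample_id` and embedding coordinates
#'   `umap1`, `umap2` (as written by [export_fingerprint()]).
#' @return A ggplot object (facetted by sample).
#' @export
plot_umap_density <- function(sub) {
  ggplot2::ggplot(sub, ggplot2::aes(.data$umap1, .data$umap2)) +
    ggplot2::geom_bin2d(bins = 120) +
    ggplot2::scale_fill_viridis_c(option = "turbo", trans = "log10") +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", fill = "events") +
    ggplot2::theme_minimal()
}

#' Heatmap of a per-cluster statistic across samples
#' @param per_sample Per-sample profile table (`cluster`, `sample_id` and
#'   the statistic column).
#' @param stat Column to display (default `"abundance"`).
#' @return A ggplot object; clusters on the y axis in id order.
#' @export
plot_cluster_heatmap <- function(per_sample, stat = "abundance") {
  d <- dplyr::filter(per_sample, .data$cluster > 0L)
  ggplot2::ggplot(d, ggplot2::aes(.data$sample_id,
                                  factor(.data$cluster),
                                  fill = .data[[stat]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = "cluster", fill = stat) +
    ggplot2::theme_minimal()
}

#' GP boxplot per cluster with optional ladder overlay
#' @param event_gp Tibble with `cluster` and per-event `gp`.
#' @param ladder Optional GP [standard_ladder()] drawn as horizontal lines.
#' @return A ggplot object.
#' @export
plot_gp_boxplot <- function(event_gp, ladder = NULL) {
  d <- dplyr::filter(event_gp, .data$cluster > 0L, !is.na(.data$gp))
  p <- ggplot2::ggplot(d, ggplot2::aes(factor(.data$cluster), .data$gp)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = "cluster", y = "GP") +
    ggplot2::theme_minimal()
  if (!is.null(ladder)) {
    p <- p + ggplot2::geom_hline(yintercept = ladder$value,
                                 linetype = "dashed", colour = "grey50") +
      ggplot2::annotate("text", x = Inf, y = ladder$value,
                        label = ladder$label, hjust = 1.05, vjust = -0.3,
                        size = 2.5, colour = "grey40")
  }
  p
}

#' Stacked cargo-status bars per cluster
#' @param partition Output of [cargo_partition_by_cluster()].
#' @return A ggplot object (proportions stacked to 1 per cluster).
#' @export
plot_cargo_bars <- function(partition) {
  ggplot2::ggplot(partition,
                  ggplot2::aes(factor(.data$cluster), .data$proportion,
                               fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster (size-rank order)", y = "proportion",
                  fill = "cargo") +
    ggplot2::theme_minimal()
}

#' T-REX hotspot overlay
#' @param trex A `trex_result`.
#' @return A ggplot object: all events in grey, 85/95 percent hotspots in
#'   the direction colors.
#' @export
plot_trex_overlay <- function(trex) {
  ev <- trex$events
  cols <- c(none = "grey85", sample1_85 = "#9ecae1", sample1_95 = "#08519c",
            sample2_85 = "#fcae91", sample2_95 = "#a50f15")
  ggplot2::ggplot(ev, ggplot2::aes(.data$umap1, .data$umap2,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 0.3) +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Export the full report for a run
#'
#' Writes one PNG per available figure plus the matching CSVs into `dir`.
#' With an empty cluster set an explicit "no populations" panel is emitted
#' instead of the cluster figures.
#'
#' @param fp An `ev_fingerprint`.
#' @param dir Output directory.
#' @param event_gp Optional tibble of per-event GP by cluster (computed
#'   from the assignment when omitted).
#' @param tables The source [ev_events()] list (needed to derive
#'   `event_gp`).
#' @param ladder Optional GP [standard_ladder()].
#' @param cargo Optional [cargo_partition_by_cluster()] table.
#' @param trex Optional `trex_result`.
#' @return Invisible character vector of written files.
#' @export
export_report <- function(fp, dir, tables = NULL, event_gp = NULL,
                          ladder = NULL, cargo = NULL, trex = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- export_fingerprint(fp, dir)
  save <- function(plot, name, width = 7, height = 5) {
    path <- file.path(dir, name)
    ggplot2::ggsave(path, plot, width = width, height = height, dpi = 150)
    written <<- c(written, path)
  }
  sub_out <- tibble::tibble(sample_id = fp$sub$sample_id,
                            umap1 = fp$embedding$coords[, 1],
                            umap2 = fp$embedding$coords[, 2])
  save(plot_umap_density(sub_out), "umap_density.png")
  if (nrow(fp$profiles$pooled) == 0) {
    empty <- ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0, label = "no populations") +
      ggplot2::theme_void()
    save(empty, "clusters_none.png", width = 4, height = 3)
  } else {
    save(plot_cluster_heatmap(fp$profiles$per_sample, "abundance"),
         "heatmap_abundance.png")
    if (is.null(event_gp) && !is.null(tables)) {
      event_gp <- per_event_table(tables, fp$assignment,
                                  tables[[1]]$channels)
    }
    if (!is.null(event_gp)) {
      save(plot_gp_boxplot(event_gp, ladder), "gp_boxplot.png")
      readr::write_csv(event_gp, file.path(dir, "event_statistics.csv"),
                       progress = FALSE)
      written <- c(written, file.path(dir, "event_statistics.csv"))
    }
  }
  if (!is.null(cargo)) {
    save(plot_cargo_bars(cargo), "cargo_bars.png")
    readr::write_csv(cargo, file.path(dir, "cargo_partition.csv"),
                     progress = FALSE)
    written <- c(written, file.path(dir, "cargo_partition.csv"))
  }
  if (!is.null(trex)) {
    save(plot_trex_overlay(trex), "trex_overlay.png")
    readr::write_csv(trex$events, file.path(dir, "trex_events.csv"),
                     progress = FALSE)
    written <- c(written, file.path(dir, "trex_events.csv"))
  }
  invisible(written)
}
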