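#' @import ggplot2
NULL

# x-axis scale shared by the coordinate-proportional plots
cpg_x_scale <- function(ds, cpg_labels = c("coordinates", "numbers",
                                           "none")) {
  cpg_labels <- match.arg(cpg_labels)
  breaks <- ds$site_map$c_coordinate
  labels <- switch(cpg_labels,
                   coordinates = as.character(breaks),
                   numbers = as.character(ds$site_map$cpg_ordinal),
                   none = rep("", length(breaks)))
  scale_x_continuous(breaks = breaks, labels = labels,
                     guide = guide_axis(angle = 60))
}

# sample display order for lollipop rows
sample_order <- function(ds, order = c("group", "methylation", "cluster")) {
  order <- match.arg(order)
  means <- ds$data |>
    group_by(.data$sample_id, .data$group) |>
    summarise(mean_meth = mean(.data$meth_mean, na.rm = TRUE),
              .groups = "drop")
  ids <- switch(order,
    group = means |>
      arrange(.data$group, .data$sample_id) |>
      pull(.data$sample_id),
    methylation = means |>
      arrange(dplyr::desc(.data$mean_meth)) |>
      pull(.data$sample_id),
    cluster = {
      wide <- ds$data |>
        select("sample_id", "cpg_ordinal", "meth_mean") |>
        tidyr::pivot_wider(names_from = "cpg_ordinal",
                           values_from = "meth_mean")
      m <- as.matrix(wide[, -1])
      rownames(m) <- wide$sample_id
      m[is.na(m)] <- 50  # neutral fill so distances stay defined
      if (nrow(m) > 2) {
        hc <- stats::hclust(stats::dist(m), method = "average")
        rownames(m)[hc$order]
      } else {
        rownames(m)
      }
    })
  ids
}

methylation_fill <- function() {
  scale_fill_gradient(low = "white", high = "black", limits = c(0, 100),
                      name = "methylation (%)")
}

#' Lollipop plot of all samples
#'
#' One row per sample, one circle per CpG placed proportionally to its
#' genomic coordinate; the fill encodes the methylation level as a grey
#' gradient (direct-BSP) or the clone status in black and white
#' (cloning-BSP). Crosses mark CpGs without data for a sample.
#'
#' @param ds A `bsp_grouped`.
#' @param cpg_labels `"coordinates"`, `"numbers"` or `"none"`.
#' @param order Sample ordering: `"group"`, `"methylation"` (descending
#'   sample means) or `"cluster"` (average-linkage on Euclidean distance).
#' @return A ggplot.
#' @export
plot_samples_lollipop <- function(ds, cpg_labels = "coordinates",
                                  order = "group") {
  stopifnot(inherits(ds, "bsp_grouped"))
  ids <- sample_order(ds, order)
  data <- ds$data |>
    mutate(sample_id = factor(.data$sample_id, levels = rev(ids)))
  cloning <- ds$experiment_type == "cloning"
  missing <- if (cloning) {
    filter(data, .data$status == "not_available")
  } else {
    filter(data, is.na(.data$meth_mean))
  }
  p <- ggplot(data, aes(x = .data$c_coordinate, y = .data$sample_id))
  p <- if (cloning) {
    p +
      geom_point(data = filter(data, .data$status != "not_available"),
                 aes(fill = .data$status), shape = 21, size = 4) +
      scale_fill_manual(values = c(methylated = "black",
                                   unmethylated = "white"),
                        name = "clone status")
  } else {
    p +
      geom_point(data = filter(data, !is.na(.data$meth_mean)),
                 aes(fill = .data$meth_mean), shape = 21, size = 4) +
      methylation_fill()
  }
  p +
    geom_point(data = missing, shape = 4, size = 3, colour = "grey40") +
    cpg_x_scale(ds, cpg_labels) +
    labs(x = "CpG site (genomic coordinate)", y = NULL,
         title = ds$sequence_name) +
    theme_minimal()
}

#' Lollipop plot of group means
#'
#' @inheritParams plot_samples_lollipop
#' @return A ggplot.
#' @export
plot_group_lollipop <- function(ds, cpg_labels = "coordinates") {
  stopifnot(inherits(ds, "bsp_grouped"))
  means <- ds$data |>
    group_by(.data$group, .data$cpg_ordinal, .data$c_coordinate) |>
    summarise(meth = mean(.data$meth_mean, na.rm = TRUE), .groups = "drop")
  ggplot(means, aes(x = .data$c_coordinate, y = .data$group,
                    fill = .data$meth)) +
    geom_point(shape = 21, size = 5) +
    methylation_fill() +
    cpg_x_scale(ds, cpg_labels) +
    labs(x = "CpG site (genomic coordinate)", y = NULL,
         title = paste(ds$sequence_name, "- group means")) +
    theme_minimal()
}

#' Methylation profile plot
#'
#' Group-mean methylation along the sequence as a line plot, with
#' Kruskal-Wallis significance symbols per CpG.
#'
#' @param ds A `bsp_grouped`.
#' @param stats A `bsp_group_stats` from [group_statistics()], or `NULL`
#'   to omit the symbols.
#' @param cpg_labels `"coordinates"`, `"numbers"` or `"none"`.
#' @return A ggplot.
#' @export
plot_profile <- function(ds, stats = NULL, cpg_labels = "coordinates") {
  stopifnot(inherits(ds, "bsp_grouped"))
  means <- ds$data |>
    group_by(.data$group, .data$cpg_ordinal, .data$c_coordinate) |>
    summarise(meth = mean(.data$meth_mean, na.rm = TRUE), .groups = "drop")
  p <- ggplot(means, aes(x = .data$c_coordinate, y = .data$meth,
                         colour = .data$group)) +
    geom_line() +
    geom_point() +
    cpg_x_scale(ds, cpg_labels) +
    coord_cartesian(ylim = c(0, 108)) +
    labs(x = "CpG site (genomic coordinate)", y = "methylation (%)",
         colour = "group", title = ds$sequence_name) +
    theme_minimal()
  if (!is.null(stats)) {
    marks <- stats$kruskal_per_cpg |>
      filter(!is.na(.data$symbol) & .data$symbol != "ns")
    if (nrow(marks) > 0) {
      p <- p + annotate("text", x = marks$c_coordinate, y = 105,
                        label = marks$symbol, size = 3)
    }
  }
  p
}

#' Per-CpG boxplots
#'
#' Methylation distribution per group at each CpG (facets), with pairwise
#' t-test symbols when statistics are supplied (symbols of the first group
#' pair shown per facet strip).
#'
#' @inheritParams plot_profile
#' @return A ggplot.
#' @export
plot_cpg_boxplots <- function(ds, stats = NULL) {
  stopifnot(inherits(ds, "bsp_grouped"))
  data <- filter(ds$data, !is.na(.data$meth_mean))
  p <- ggplot(data, aes(x = .data$group, y = .data$meth_mean,
                        fill = .data$group)) +
    geom_boxplot(outlier.size = 0.8) +
    facet_wrap(~cpg_ordinal, labeller = label_both) +
    coord_cartesian(ylim = c(0, 110)) +
    labs(x = NULL, y = "methylation (%)", title = ds$sequence_name) +
    theme_minimal() +
    theme(legend.position = "none",
          axis.text.x = element_text(angle = 45, hjust = 1))
  if (!is.null(stats)) {
    marks <- stats$pairwise_per_cpg |>
      filter(!is.na(.data$symbol)) |>
      group_by(.data$cpg_ordinal) |>
      summarise(symbol = .data$symbol[[1]], .groups = "drop")
    p <- p + geom_text(data = marks,
                       aes(x = 1.5, y = 107, label = .data$symbol),
                       inherit.aes = FALSE, size = 3)
  }
  p
}

#' Boxplot of per-sample means over all CpGs
#'
#' @inheritParams plot_profile
#' @return A ggplot.
#' @export
plot_means_boxplot <- function(ds, stats = NULL) {
  stopifnot(inherits(ds, "bsp_grouped"))
  means <- ds$data |>
    group_by(.data$sample_id, .data$group) |>
    summarise(mean_meth = mean(.data$meth_mean, na.rm = TRUE),
              .groups = "drop")
  p <- ggplot(means, aes(x = .data$group, y = .data$mean_meth,
                         fill = .data$group)) +
    geom_boxplot() +
    geom_point(size = 1) +
    coord_cartesian(ylim = c(0, 110)) +
    labs(x = NULL, y = "mean methylation over CpGs (%)",
         title = ds$sequence_name) +
    theme_minimal() +
    theme(legend.position = "none")
  if (!is.null(stats) && nrow(stats$pairwise_overall) > 0) {
    sym <- stats$pairwise_overall$symbol[[1]]
    if (!is.na(sym)) {
      p <- p + annotate("text", x = 1.5, y = 107, label = sym)
    }
  }
  p
}

#' Genomic heatmap plot
#'
#' Methylation of every sample as grey-scale tiles along the genomic
#' coordinate, with tick marks at the CpG positions — a visual control
#' that CpG coordinates line up with the CG dinucleotides of the region.
#'
#' @param ds A `bsp_grouped`.
#' @return A ggplot.
#' @export
plot_genomic_heatmap <- function(ds) {
  stopifnot(inherits(ds, "bsp_grouped"))
  ggplot(ds$data, aes(x = .data$c_coordinate, y = .data$sample_id,
                      fill = .data$meth_mean)) +
    geom_tile(width = 2) +
    geom_rug(data = ds$site_map,
             aes(x = .data$c_coordinate), inherit.aes = FALSE,
             sides = "b", length = unit(0.03, "npc")) +
    methylation_fill() +
    labs(x = "genomic coordinate", y = NULL, title = ds$sequence_name) +
    theme_minimal()
}

#' Per-sample genomic plot
#'
#' The individual-analysis control figure: CpG positions of the reference
#' with the sample's methylation levels as a grey gradient along the
#' genomic coordinate.
#'
#' @param object A `bsp_sample`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bsp_sample <- function(object, ...) {
  rec <- object$records
  ggplot(rec, aes(x = .data$c_coordinate, y = 1)) +
    geom_point(data = filter(rec, !is.na(.data$meth_mean)),
               aes(fill = .data$meth_mean), shape = 21, size = 5) +
    geom_point(data = filter(rec, is.na(.data$meth_mean)), shape = 4,
               size = 3, colour = "grey40") +
    methylation_fill() +
    scale_y_continuous(breaks = NULL, limits = c(0.5, 1.5)) +
    labs(x = "genomic coordinate", y = NULL,
         title = sprintf("%s | %s / %s / %s",
                         object$key$sequence_name, object$key$collection,
                         object$key$group,
                         object$key$replicate_or_clone)) +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Render the grouped figure suite to files
#'
#' Writes the five grouped-analysis figures (all-samples lollipop, group
#' lollipop, profile plot, per-CpG boxplots, genomic heatmap) as PNG files.
#'
#' @param ds A `bsp_grouped`.
#' @param stats A `bsp_group_stats` or `NULL` (single-group datasets).
#' @param outdir Output directory.
#' @param cpg_labels,order Passed to the lollipop plots.
#' @return Named character vector of file paths.
#' @export
render_plots <- function(ds, stats = NULL, outdir = ".",
                         cpg_labels = "coordinates", order = "group") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  figs <- list(
    samples_lollipop = plot_samples_lollipop(ds, cpg_labels, order),
    group_lollipop = plot_group_lollipop(ds, cpg_labels),
    profile = plot_profile(ds, stats, cpg_labels),
    cpg_boxplots = plot_cpg_boxplots(ds, stats),
    genomic_heatmap = plot_genomic_heatmap(ds))
  figs$means_boxplot <- plot_means_boxplot(ds, stats)
  paths <- vapply(names(figs), function(nm) {
    path <- file.path(outdir, sprintf("%s_%s.png", ds$sequence_name, nm))
    ggsave(path, figs[[nm]], width = 8, height = 5, dpi = 120)
    path
  }, character(1))
  paths
}
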