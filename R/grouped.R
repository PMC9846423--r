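#' Clone-status parameters
#'
#' In cloning-BSP each sequenced clone is a single molecule, so its per-CpG
#' methylation should be near 0 or near 100. Levels up to
#' `unmethylated_max` call an unmethylated status, levels from
#' `methylated_min` a methylated one; anything strictly in between is
#' defective (partial) and reported as not available. A clone whose
#' fraction of partial CpGs exceeds `max_partial_fraction` is flagged as a
#' potential mix of clones and all its calls are voided.
#'
#' @param unmethylated_max Upper bound of the unmethylated band (default
#'   20, inclusive).
#' @param methylated_min Lower bound of the methylated band (default 80,
#'   inclusive).
#' @param max_partial_fraction Mixed-clone rule: strict `>` on the fraction
#'   of partial CpGs (default 0.20).
#' @return A `bsp_clone_params` list.
#' @export
clone_params <- function(unmethylated_max = 20, methylated_min = 80,
                         max_partial_fraction = 0.20) {
  stopifnot(unmethylated_max >= 0, unmethylated_max < methylated_min,
            methylated_min <= 100)
  structure(
    list(unmethylated_max = unmethylated_max,
         methylated_min = methylated_min,
         max_partial_fraction = max_partial_fraction),
    class = "bsp_clone_params")
}

#' Call the methylation status of clone CpGs
#'
#' @param meth Numeric vector of methylation percentages (`NA` allowed).
#' @param params A [clone_params()] list.
#' @param collapse_partial When `TRUE` (default), partially methylated
#'   sites are reported as `"not_available"`; with `FALSE` they keep the
#'   distinct label `"partial"` (needed by [flag_mixed_clone()]).
#' @return Character vector of statuses.
#' @export
#' @examples
#' call_clone_status(c(5, 95, 50, NA))
call_clone_status <- function(meth, params = clone_params(),
                              collapse_partial = TRUE) {
  status <- dplyr::case_when(
    is.na(meth) ~ "not_available",
    meth <= params$unmethylated_max ~ "unmethylated",
    meth >= params$methylated_min ~ "methylated",
    TRUE ~ "partial")
  if (collapse_partial) {
    status[status == "partial"] <- "not_available"
  }
  status
}

#' Apply the mixed-clone rule
#'
#' If the fraction of CpGs with a partial status exceeds
#' `max_partial_fraction` (strict `>`), the clone is considered a potential
#' mix of clones and every status becomes `"not_available"`; otherwise only
#' the partial sites are voided.
#'
#' @param statuses Character vector of statuses as produced by
#'   [call_clone_status()] with `collapse_partial = FALSE` (values among
#'   `unmethylated`, `methylated`, `partial`, `not_available`).
#' @param params A [clone_params()] list.
#' @return Character vector with values `unmethylated` / `methylated` /
#'   `not_available`.
#' @export
flag_mixed_clone <- function(statuses, params = clone_params()) {
  stopifnot(length(statuses) >= 1)
  frac_partial <- mean(statuses == "partial")
  if (frac_partial > params$max_partial_fraction) {
    rep("not_available", length(statuses))
  } else {
    ifelse(statuses == "partial", "not_available", statuses)
  }
}

#' Gather per-sample tables into a grouped dataset
#'
#' Collects the per-sample methylation tables for one sequence, renumbers
#' the CpG sites contiguously (1, 2, ...) over the union of sites covered
#' by at least one sample, ordered by genomic coordinate, and — for
#' cloning-BSP data — converts clone methylation levels into statuses with
#' the mixed-clone rule applied per clone.
#'
#' @param tbl A tibble in the per-sample schema (from [tidy()] on samples
#'   or [read_sample_csv()]), possibly many samples.
#' @param sequence_name Sequence to keep; default: the single sequence
#'   present.
#' @param clone A [clone_params()] list (cloning-BSP only).
#' @return A `bsp_grouped` object: `data` (per sample x CpG rows with
#'   `cpg_ordinal` and, for cloning, `status`), `site_map` (ordinal to
#'   coordinate), `sequence_name`, `groups`, `experiment_type`.
#' @export
group_dataset <- function(tbl, sequence_name = NULL,
                          clone = clone_params()) {
  stopifnot(all(SAMPLE_CSV_COLUMNS %in% names(tbl)))
  if (is.null(sequence_name)) {
    seqs <- unique(tbl$sequence_name)
    if (length(seqs) != 1) {
      bsp_abort(sprintf("several sequences present (%s); pick one",
                        paste(seqs, collapse = ", ")), "bad_argument")
    }
    sequence_name <- seqs
  }
  tbl <- filter(tbl, .data$sequence_name == !!sequence_name)
  if (nrow(tbl) == 0) {
    bsp_abort(sprintf("no sample table rows for sequence '%s'",
                      sequence_name), "no_samples")
  }
  experiment_type <- unique(tbl$experiment_type)
  if (length(experiment_type) != 1) {
    bsp_abort("samples mix direct and cloning experiment types",
              "bad_argument")
  }

  # CpG ordinals are reset over the union of covered sites
  site_map <- tbl |>
    filter(!is.na(.data$meth_mean)) |>
    distinct(.data$c_coordinate) |>
    arrange(.data$c_coordinate) |>
    mutate(cpg_ordinal = row_number())
  if (nrow(site_map) == 0) {
    bsp_abort("no CpG site is covered by any sample", "no_samples")
  }

  data <- tbl |>
    dplyr::inner_join(site_map, by = "c_coordinate") |>
    mutate(sample_id = paste(.data$collection, .data$group,
                             .data$replicate_or_clone, sep = "_")) |>
    arrange(.data$cpg_ordinal)

  if (experiment_type == "cloning") {
    data <- data |>
      group_by(.data$sample_id) |>
      mutate(status = flag_mixed_clone(
        call_clone_status(.data$meth_mean, clone, collapse_partial = FALSE),
        clone)) |>
      ungroup()
  }

  structure(
    list(data = data, site_map = site_map, sequence_name = sequence_name,
         groups = unique(data$group), experiment_type = experiment_type),
    class = "bsp_grouped")
}

#' @export
print.bsp_grouped <- function(x, ...) {
  cat(sprintf(
    "<bsp_grouped> %s (%s): %d sample(s), %d group(s), %d CpG site(s)\n",
    x$sequence_name, x$experiment_type,
    dplyr::n_distinct(x$data$sample_id), length(x$groups),
    nrow(x$site_map)))
  invisible(x)
}

#' Per-CpG group methylation proportions for cloning-BSP
#'
#' For each group and CpG, the methylation proportion estimated from clone
#' statuses: methylated clones over (methylated + unmethylated) clones,
#' excluding not-available calls.
#'
#' @param ds A `bsp_grouped` of cloning-BSP samples.
#' @return A tibble with `group`, `cpg_ordinal`, `c_coordinate`,
#'   `n_methylated`, `n_unmethylated`, `proportion`.
#' @export
clone_proportions <- function(ds) {
  stopifnot(inherits(ds, "bsp_grouped"))
  if (ds$experiment_type != "cloning") {
    bsp_abort("clone proportions are defined for cloning-BSP data only",
              "bad_argument")
  }
  ds$data |>
    group_by(.data$group, .data$cpg_ordinal, .data$c_coordinate) |>
    summarise(n_methylated = sum(.data$status == "methylated"),
              n_unmethylated = sum(.data$status == "unmethylated"),
              .groups = "drop") |>
    mutate(proportion = ifelse(
      .data$n_methylated + .data$n_unmethylated > 0,
      .data$n_methylated / (.data$n_methylated + .data$n_unmethylated),
      NA_real_))
}

# Welch two-sample t-test p-value with degenerate inputs returned as NA
safe_t_test <- function(x, y, pooled = FALSE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    return(NA_real_)
  }
  if (sd(x) == 0 && sd(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else NA_real_)
  }
  tryCatch(t.test(x, y, var.equal = pooled)$p.value,
           error = function(e) NA_real_)
}

safe_kruskal <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(droplevels(groups)) < 2 || length(values) < 3) {
    return(NA_real_)
  }
  tryCatch(kruskal.test(values, droplevels(groups))$p.value,
           error = function(e) NA_real_)
}

#' Group-comparison statistics
#'
#' Per CpG: two-by-two group comparisons with Student's t-test (Welch
#' variant by default) and an all-groups Kruskal-Wallis test. Per sample:
#' the mean over covered CpGs, compared between groups two-by-two with the
#' same t-test. Observations are the per-sample `meth_mean` values.
#' Significance symbols: `*` p <= 0.05, `**` 0.01, `***` 0.001, `****`
#' 0.0001. Tests with fewer than two observations in a group (or all-tied
#' zero-variance pathologies) are recorded as `NA`, not errors. No
#' multiple-testing correction is applied by default.
#'
#' @param ds A `bsp_grouped`.
#' @param pooled Use the pooled-variance (classic Student) t-test instead
#'   of Welch.
#' @param adjust_p Apply Benjamini-Hochberg correction across each table's
#'   p-values (default off, matching raw-p presentation).
#' @return A `bsp_group_stats` object with tibbles `pairwise_per_cpg`,
#'   `kruskal_per_cpg`, `sample_means`, `pairwise_overall`.
#' @export
group_statistics <- function(ds, pooled = FALSE, adjust_p = FALSE) {
  stopifnot(inherits(ds, "bsp_grouped"))
  groups <- sort(unique(ds$data$group))
  if (length(groups) < 2) {
    bsp_abort("group statistics need at least two groups", "need_groups")
  }
  pairs <- utils::combn(groups, 2, simplify = FALSE)

  per_cpg_values <- ds$data |>
    select("cpg_ordinal", "c_coordinate", "group", "sample_id",
           "meth_mean")

  pairwise_per_cpg <- purrr::map_dfr(pairs, function(pr) {
    per_cpg_values |>
      group_by(.data$cpg_ordinal, .data$c_coordinate) |>
      summarise(
        group1 = pr[[1]], group2 = pr[[2]],
        n1 = sum(.data$group == pr[[1]] & !is.na(.data$meth_mean)),
        n2 = sum(.data$group == pr[[2]] & !is.na(.data$meth_mean)),
        mean1 = mean(.data$meth_mean[.data$group == pr[[1]]], na.rm = TRUE),
        mean2 = mean(.data$meth_mean[.data$group == pr[[2]]], na.rm = TRUE),
        p_value = safe_t_test(.data$meth_mean[.data$group == pr[[1]]],
                              .data$meth_mean[.data$group == pr[[2]]],
                              pooled = pooled),
        .groups = "drop")
  }) |>
    arrange(.data$cpg_ordinal)

  kruskal_per_cpg <- per_cpg_values |>
    group_by(.data$cpg_ordinal, .data$c_coordinate) |>
    summarise(n = sum(!is.na(.data$meth_mean)),
              p_value = safe_kruskal(.data$meth_mean, .data$group),
              .groups = "drop")

  sample_means <- ds$data |>
    group_by(.data$sample_id, .data$collection, .data$group,
             .data$replicate_or_clone) |>
    summarise(mean_meth = mean(.data$meth_mean, na.rm = TRUE),
              n_cpg = sum(!is.na(.data$meth_mean)), .groups = "drop")

  pairwise_overall <- purrr::map_dfr(pairs, function(pr) {
    x <- sample_means$mean_meth[sample_means$group == pr[[1]]]
    y <- sample_means$mean_meth[sample_means$group == pr[[2]]]
    tibble(group1 = pr[[1]], group2 = pr[[2]],
           n1 = sum(!is.na(x)), n2 = sum(!is.na(y)),
           mean1 = mean(x, na.rm = TRUE), mean2 = mean(y, na.rm = TRUE),
           p_value = safe_t_test(x, y, pooled = pooled))
  })

  if (adjust_p) {
    pairwise_per_cpg$p_value <- stats::p.adjust(pairwise_per_cpg$p_value,
                                                "BH")
    kruskal_per_cpg$p_value <- stats::p.adjust(kruskal_per_cpg$p_value,
                                               "BH")
    pairwise_overall$p_value <- stats::p.adjust(pairwise_overall$p_value,
                                                "BH")
  }
  pairwise_per_cpg$symbol <- significance_symbol(pairwise_per_cpg$p_value)
  kruskal_per_cpg$symbol <- significance_symbol(kruskal_per_cpg$p_value)
  pairwise_overall$symbol <- significance_symbol(pairwise_overall$p_value)

  structure(
    list(pairwise_per_cpg = pairwise_per_cpg,
         kruskal_per_cpg = kruskal_per_cpg,
         sample_means = sample_means,
         pairwise_overall = pairwise_overall,
         groups = groups, sequence_name = ds$sequence_name),
    class = "bsp_group_stats")
}

#' @export
print.bsp_group_stats <- function(x, ...) {
  cat(sprintf("<bsp_group_stats> %s: %d group(s), %d CpG site(s)\n",
              x$sequence_name, length(x$groups),
              nrow(x$kruskal_per_cpg)))
  cat("overall pairwise comparisons:\n")
  print(as.data.frame(x$pairwise_overall), row.names = FALSE)
  invisible(x)
}

#' @describeIn group_statistics One row per test (pairwise t-tests per CpG
#'   and overall, Kruskal-Wallis per CpG) in a long tibble.
#' @param x A `bsp_group_stats`.
#' @param ... Unused.
#' @export
tidy.bsp_group_stats <- function(x, ...) {
  bind_rows(
    x$pairwise_per_cpg |>
      mutate(test = "t_per_cpg",
             contrast = paste(.data$group1, .data$group2, sep = " vs ")) |>
      select("test", "cpg_ordinal", "c_coordinate", "contrast", "p_value",
             "symbol"),
    x$kruskal_per_cpg |>
      mutate(test = "kruskal_per_cpg", contrast = "all groups") |>
      select("test", "cpg_ordinal", "c_coordinate", "contrast", "p_value",
             "symbol"),
    x$pairwise_overall |>
      mutate(test = "t_overall", cpg_ordinal = NA_integer_,
             c_coordinate = NA_integer_,
             contrast = paste(.data$group1, .data$group2, sep = " vs ")) |>
      select("test", "cpg_ordinal", "c_coordinate", "contrast", "p_value",
             "symbol"))
}

#' @describeIn group_statistics One-row summary: number of groups, samples,
#'   CpGs, and the smallest per-CpG and overall p-values.
#' @export
glance.bsp_group_stats <- function(x, ...) {
  tibble(
    sequence_name = x$sequence_name,
    n_groups = length(x$groups),
    n_samples = nrow(x$sample_means),
    n_cpg = nrow(x$kruskal_per_cpg),
    min_p_kruskal = suppressWarnings(min(x$kruskal_per_cpg$p_value,
                                         na.rm = TRUE)),
    min_p_pairwise = suppressWarnings(min(x$pairwise_per_cpg$p_value,
                                          na.rm = TRUE)),
    p_overall = suppressWarnings(min(x$pairwise_overall$p_value,
                                     na.rm = TRUE)))
}
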