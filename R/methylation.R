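#' Sample identity key
#'
#' Every sequencing run of one PCR product (or one clone) is identified by
#' the amplified sequence name, the collection (a separation above groups:
#' samples from different collections are never compared), the group (the
#' experimental condition to compare) and the replicate number (direct-BSP)
#' or clone number (cloning-BSP).
#'
#' @param sequence_name Name of the amplified sequence (primer pair).
#' @param collection Collection label (e.g. cell line or organ).
#' @param group Group label (e.g. treatment).
#' @param replicate_or_clone Replicate number (direct) or clone number
#'   (cloning).
#' @param experiment_type `"direct"` or `"cloning"`.
#' @return A `bsp_sample_key` list.
#' @export
sample_key <- function(sequence_name, collection, group, replicate_or_clone,
                       experiment_type = c("direct", "cloning")) {
  experiment_type <- match.arg(experiment_type)
  fields <- list(sequence_name = as.character(sequence_name),
                 collection = as.character(collection),
                 group = as.character(group),
                 replicate_or_clone = as.character(replicate_or_clone))
  if (any(vapply(fields, nchar, integer(1)) == 0)) {
    bsp_abort("all sample-key fields must be non-empty", "bad_sample_key")
  }
  structure(c(fields, list(experiment_type = experiment_type)),
            class = "bsp_sample_key")
}

#' Methylation percentage from peak heights
#'
#' At a CpG cytosine, the methylated fraction of the sequenced molecules
#' keeps a C signal while the unmethylated fraction reads T (forward) —
#' or G versus A in a reverse read. The methylation percentage is
#' `peakC / (peakC + peakT) * 100` for forward reads and
#' `peakG / (peakG + peakA) * 100` for reverse reads. Peak heights are
#' used as stored: no normalization is applied.
#'
#' @param heights Named numeric vector of the four heights (A, C, G, T).
#' @param direction `"forward"` or `"reverse"`.
#' @return Percentage in `[0, 100]`, or `NA` when the relevant denominator
#'   is zero (site flagged, not an error).
#' @export
#' @examples
#' methylation_pct(c(A = 0, C = 50, G = 0, T = 50), "forward")  # 50
methylation_pct <- function(heights, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  h <- heights[BASES]
  stopifnot(!anyNA(h), all(h >= 0))
  if (direction == "forward") {
    denom <- h[["C"]] + h[["T"]]
    if (denom == 0) NA_real_ else 100 * h[["C"]] / denom
  } else {
    denom <- h[["G"]] + h[["A"]]
    if (denom == 0) NA_real_ else 100 * h[["G"]] / denom
  }
}

#' Combine forward and reverse methylation measurements
#'
#' When both sequencing directions cover a CpG, the reported methylation is
#' their mean and the standard deviation (sample SD, n - 1 divisor) of the
#' two values; with a single direction the value is used as-is and the SD
#' is undefined.
#'
#' @param meth_fwd,meth_rev Percentages or `NA`.
#' @return A list with `mean`, `sd` and `n_reads`.
#' @export
#' @examples
#' combine_directions(71.13, 82.65)  # mean 76.89
combine_directions <- function(meth_fwd, meth_rev) {
  values <- c(meth_fwd, meth_rev)
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    return(list(mean = NA_real_, sd = NA_real_, n_reads = 0L))
  }
  list(mean = mean(values),
       sd = if (length(values) == 2) sd(values) else NA_real_,
       n_reads = length(values))
}

#' Analyze one sample end-to-end
#'
#' Runs the full individual-analysis pipeline for one sample: reads the
#' (unlabeled) chromatogram files, trims them, auto-detects each read's
#' direction by aligning against both converted templates, quality-controls
#' the alignments (bisulfite conversion rate among the gates), and computes
#' the per-CpG methylation percentages from the peak heights. Reads that
#' fail trimming or QC contribute no percentages; CpG sites outside the
#' covered region get `NA` records.
#'
#' @param key A [sample_key()].
#' @param ref A `bsp_reference`.
#' @param traces A list of 1-2 `.ab1` file paths and/or [bsp_trace]
#'   objects.
#' @param trim,align,qc Parameter lists ([trim_params()], [align_params()],
#'   [qc_params()]).
#' @return A `bsp_sample` object: `key`, `records` (tibble with one row
#'   per CpG: `cpg_index`, `c_coordinate`, `meth_fwd`, `meth_rev`,
#'   `meth_mean`, `meth_sd`, `n_reads`), `covered` (or `NULL`), `qc_fwd`,
#'   `qc_rev`, `read_log` (per-input processing outcome) and the
#'   templates used.
#' @export
analyze_sample <- function(key, ref, traces,
                           trim = trim_params(),
                           align = align_params(),
                           qc = qc_params()) {
  stopifnot(inherits(key, "bsp_sample_key"), inherits(ref, "bsp_reference"))
  if (!is.list(traces) || length(traces) < 1 || length(traces) > 2) {
    bsp_abort("supply a list of 1 or 2 traces (paths or bsp_trace objects)",
              "bad_argument")
  }
  templates <- bisulfite_convert(ref)

  slots <- list(forward = NULL, reverse = NULL)
  log_rows <- list()
  for (i in seq_along(traces)) {
    input <- traces[[i]]
    trace <- if (inherits(input, "bsp_trace")) input else read_abif(input)
    id <- attr(trace, "read_id")
    trimmed <- final_trim(trace, trim)
    if (!trimmed$valid) {
      log_rows[[i]] <- tibble(read_id = id, direction = NA_character_,
                              used = FALSE,
                              reason = trimmed$failure_reason)
      next
    }
    det <- tryCatch(detect_direction(trimmed, templates, align),
                    bspmeth_no_alignment = function(e) NULL)
    if (is.null(det)) {
      log_rows[[i]] <- tibble(read_id = id, direction = NA_character_,
                              used = FALSE,
                              reason = "no usable alignment to either template")
      next
    }
    read_qc <- assess_read(det$alignment, trimmed, templates,
                           det$direction, qc)
    if (!is.null(slots[[det$direction]])) {
      warn(sprintf("two %s reads supplied for sample %s; keeping the first",
                   det$direction, key$replicate_or_clone))
      log_rows[[i]] <- tibble(read_id = id, direction = det$direction,
                              used = FALSE,
                              reason = "duplicate direction; first read kept")
      next
    }
    slots[[det$direction]] <- list(trimmed = trimmed, aln = det$alignment,
                                   qc = read_qc)
    log_rows[[i]] <- tibble(
      read_id = id, direction = det$direction, used = read_qc$pass,
      reason = if (read_qc$pass) "" else
        paste("QC failed:", paste(read_qc$failed_gates, collapse = ", ")))
  }

  usable <- function(slot) {
    !is.null(slot) && slot$aln$valid && slot$qc$pass
  }
  fwd <- slots$forward
  rev <- slots$reverse

  covered <- if (usable(fwd) || usable(rev)) {
    covered_region(if (usable(fwd)) fwd$aln else NULL,
                   if (usable(rev)) rev$aln else NULL,
                   templates)
  } else {
    NULL
  }

  sites <- tibble(
    sense_pos = templates$cpg_positions_sense,
    c_coordinate = vapply(templates$cpg_positions_sense, function(p) {
      as.integer(sense_to_genomic(templates, p))
    }, integer(1))) |>
    arrange(.data$c_coordinate) |>
    mutate(cpg_index = row_number())

  meth_dir <- function(slot, direction, sense_pos) {
    if (!usable(slot)) {
      return(NA_real_)
    }
    t_pos <- if (direction == "forward") {
      sense_pos
    } else {
      mirror_position(templates, sense_pos)
    }
    if (t_pos < slot$aln$s_start || t_pos > slot$aln$s_end) {
      return(NA_real_)
    }
    read_pos <- map_position(slot$aln, t_pos)
    if (is.na(read_pos)) {
      return(NA_real_)
    }
    trace_pos <- slot$trimmed$start - 1L + read_pos
    methylation_pct(trace_heights(slot$trimmed$trace, trace_pos), direction)
  }

  records <- sites |>
    mutate(
      meth_fwd = map_dbl(.data$sense_pos, ~ meth_dir(fwd, "forward", .x)),
      meth_rev = map_dbl(.data$sense_pos, ~ meth_dir(rev, "reverse", .x))) |>
    mutate(combined = map2(.data$meth_fwd, .data$meth_rev,
                           combine_directions),
           meth_mean = map_dbl(.data$combined, "mean"),
           meth_sd = map_dbl(.data$combined, "sd"),
           n_reads = vapply(.data$combined, function(x) x$n_reads,
                            integer(1))) |>
    select("cpg_index", "c_coordinate", "meth_fwd", "meth_rev",
           "meth_mean", "meth_sd", "n_reads")

  structure(
    list(key = key, records = records, covered = covered,
         qc_fwd = if (!is.null(fwd)) fwd$qc else NULL,
         qc_rev = if (!is.null(rev)) rev$qc else NULL,
         read_log = bind_rows(log_rows),
         templates = templates),
    class = "bsp_sample")
}

#' @export
print.bsp_sample <- function(x, ...) {
  k <- x$key
  cat(sprintf("<bsp_sample> %s | %s / %s / %s (%s)\n", k$sequence_name,
              k$collection, k$group, k$replicate_or_clone,
              k$experiment_type))
  n_cov <- sum(!is.na(x$records$meth_mean))
  cat(sprintf("  %d CpG site(s), %d with methylation data\n",
              nrow(x$records), n_cov))
  invisible(x)
}

#' @describeIn analyze_sample Tidy the per-CpG records of a sample,
#'   prefixed with the sample key and per-direction QC columns (the frozen
#'   per-sample table schema).
#' @param x A `bsp_sample`.
#' @param ... Unused.
#' @export
tidy.bsp_sample <- function(x, ...) {
  k <- x$key
  qc_col <- function(qc, f) if (is.null(qc)) NA else f(qc)
  x$records |>
    mutate(
      sequence_name = k$sequence_name, collection = k$collection,
      group = k$group, replicate_or_clone = k$replicate_or_clone,
      experiment_type = k$experiment_type,
      qc_pass_fwd = qc_col(x$qc_fwd, function(q) q$pass),
      qc_pass_rev = qc_col(x$qc_rev, function(q) q$pass),
      conversion_rate_fwd =
        qc_col(x$qc_fwd, function(q) q$mean_conversion_rate),
      conversion_rate_rev =
        qc_col(x$qc_rev, function(q) q$mean_conversion_rate)) |>
    select("sequence_name", "collection", "group", "replicate_or_clone",
           "experiment_type", "cpg_index", "c_coordinate", "meth_fwd",
           "meth_rev", "meth_mean", "meth_sd", "n_reads", "qc_pass_fwd",
           "qc_pass_rev", "conversion_rate_fwd", "conversion_rate_rev")
}

# frozen column set of the per-sample CSV (consumed by the grouped stage)
SAMPLE_CSV_COLUMNS <- c(
  "sequence_name", "collection", "group", "replicate_or_clone",
  "experiment_type", "cpg_index", "c_coordinate", "meth_fwd", "meth_rev",
  "meth_mean", "meth_sd", "n_reads", "qc_pass_fwd", "qc_pass_rev",
  "conversion_rate_fwd", "conversion_rate_rev")

#' Write the per-sample methylation CSV
#'
#' Writes the frozen per-sample table (`tidy()` of the sample) to
#' `<collection>_<group>_<replicate>.csv` under `dir`. Percentages are
#' rendered with two decimals; conversion rates with three.
#'
#' @param sample A `bsp_sample`.
#' @param dir Output directory (created if needed).
#' @return The file path, invisibly.
#' @export
write_sample_csv <- function(sample, dir) {
  stopifnot(inherits(sample, "bsp_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  k <- sample$key
  path <- file.path(dir, sprintf("%s_%s_%s.csv", k$collection, k$group,
                                 k$replicate_or_clone))
  out <- tidy(sample) |>
    mutate(across(c("meth_fwd", "meth_rev", "meth_mean", "meth_sd"),
                  ~ round(.x, 2)),
           across(c("conversion_rate_fwd", "conversion_rate_rev"),
                  ~ round(.x, 3)))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read per-sample methylation CSVs back
#'
#' @param paths Paths to CSVs written by [write_sample_csv()].
#' @return A single tibble in the frozen per-sample schema.
#' @export
read_sample_csv <- function(paths) {
  spec <- readr::cols(
    sequence_name = "c", collection = "c", group = "c",
    replicate_or_clone = "c", experiment_type = "c", cpg_index = "i",
    c_coordinate = "i", meth_fwd = "d", meth_rev = "d", meth_mean = "d",
    meth_sd = "d", n_reads = "i", qc_pass_fwd = "l", qc_pass_rev = "l",
    conversion_rate_fwd = "d", conversion_rate_rev = "d")
  tables <- lapply(paths, function(p) {
    header <- names(readr::read_csv(p, n_max = 0, show_col_types = FALSE,
                                    progress = FALSE))
    missing <- setdiff(SAMPLE_CSV_COLUMNS, header)
    if (length(missing) > 0) {
      bsp_abort(sprintf("%s is not a per-sample methylation table (missing: %s)",
                        p, paste(missing, collapse = ", ")),
                "bad_sample_table")
    }
    tbl <- readr::read_csv(p, show_col_types = FALSE, progress = FALSE,
                           col_types = spec)
    tbl[SAMPLE_CSV_COLUMNS]
  })
  bind_rows(tables)
}
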