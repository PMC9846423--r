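#' Quality-control thresholds for aligned reads
#'
#' A sequencing read is only used for methylation computation when its
#' alignment is long enough, identical enough to the converted template,
#' and shows a near-complete bisulfite conversion at non-CpG cytosines.
#' Comparisons use `>=`, so a read exactly at a threshold passes.
#'
#' @param min_length Minimum aligned length in bases (default 30).
#' @param min_identity Minimum identity percentage (default 75).
#' @param min_conversion Minimum mean bisulfite conversion rate over
#'   non-CpG cytosine control sites (default 0.9).
#' @return A `bsp_qc_params` list.
#' @export
qc_params <- function(min_length = 30L, min_identity = 75,
                      min_conversion = 0.9) {
  structure(
    list(min_length = as.integer(min_length), min_identity = min_identity,
         min_conversion = min_conversion),
    class = "bsp_qc_params")
}

#' Bisulfite conversion rate at one read position
#'
#' At a non-CpG cytosine of the unconverted template, a complete bisulfite
#' reaction leaves only T signal in a forward read (A in a reverse read).
#' The per-site conversion rate is `peakT / (peakC + peakT)` for forward
#' reads and `peakA / (peakG + peakA)` for reverse reads.
#'
#' @param trace A [bsp_trace].
#' @param read_pos Position of the called base in the trace (1-based, in
#'   the full trace frame).
#' @param direction `"forward"` or `"reverse"`.
#' @return The rate in `[0, 1]`, or `NA` when the denominator is zero
#'   (the site is skipped, not an error).
#' @export
#' @examples
#' tr <- bsp_trace("T", 50, matrix(c(0, 10, 0, 90), 1,
#'                 dimnames = list(NULL, c("A", "C", "G", "T"))))
#' conversion_rate_at(tr, 1, "forward")  # 0.9
conversion_rate_at <- function(trace, read_pos,
                               direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  h <- trace_heights(trace, read_pos)
  if (direction == "forward") {
    denom <- h[["C"]] + h[["T"]]
    if (denom == 0) NA_real_ else h[["T"]] / denom
  } else {
    denom <- h[["G"]] + h[["A"]]
    if (denom == 0) NA_real_ else h[["A"]] / denom
  }
}

#' Quality-control a read's alignment
#'
#' Maps every conversion-control position of the template (non-CpG
#' cytosines of the unconverted amplified strand) through the alignment's
#' gap-corrected position map, computes the per-site bisulfite conversion
#' rates from the peak heights, averages them (unweighted over usable
#' sites; sites in gaps or with zero denominator are skipped), and applies
#' the three validity gates.
#'
#' @param aligned A `bsp_alignment` of the trimmed read against its
#'   template.
#' @param trimmed The `bsp_trimmed_read` the alignment came from (needed to
#'   locate peak heights in the full trace frame).
#' @param templates A `bsp_templates` pair.
#' @param direction `"forward"` or `"reverse"`.
#' @param params A [qc_params()] list.
#' @return A `bsp_read_qc` with fields `aligned_length`, `identity_pct`,
#'   `mean_conversion_rate`, `per_site` (tibble of control sites),
#'   `pass` and `failed_gates`.
#' @export
assess_read <- function(aligned, trimmed, templates,
                        direction = c("forward", "reverse"),
                        params = qc_params()) {
  direction <- match.arg(direction)
  stopifnot(inherits(aligned, "bsp_alignment"),
            inherits(trimmed, "bsp_trimmed_read"),
            inherits(templates, "bsp_templates"))

  control_sense <- templates$non_cpg_c_positions_sense
  control_tpos <- if (direction == "forward") {
    control_sense
  } else {
    sort(mirror_position(templates, control_sense))
  }
  control_tpos <- control_tpos[control_tpos >= aligned$s_start &
                                 control_tpos <= aligned$s_end]
  read_pos <- map_position(aligned, control_tpos)
  trace_pos <- trimmed$start - 1L + read_pos
  rate <- vapply(seq_along(control_tpos), function(i) {
    if (is.na(trace_pos[[i]])) {
      return(NA_real_)
    }
    conversion_rate_at(trimmed$trace, trace_pos[[i]], direction)
  }, numeric(1))

  sense_pos <- if (direction == "forward") {
    control_tpos
  } else {
    mirror_position(templates, control_tpos)
  }
  per_site <- tibble(
    template_pos = control_tpos,
    genomic_coord = vapply(sense_pos, function(p) {
      as.integer(sense_to_genomic(templates, p))
    }, integer(1)),
    read_pos = read_pos,
    rate = rate)

  usable <- !is.na(per_site$rate)
  mean_rate <- if (any(usable)) mean(per_site$rate[usable]) else NA_real_

  failed <- character()
  if (aligned$aligned_length < params$min_length) {
    failed <- c(failed, "min-length")
  }
  if (aligned$identity_pct < params$min_identity) {
    failed <- c(failed, "min-identity")
  }
  if (!any(usable)) {
    failed <- c(failed, "no-conversion-sites")
  } else if (mean_rate < params$min_conversion) {
    failed <- c(failed, "min-conversion")
  }

  structure(
    list(aligned_length = aligned$aligned_length,
         identity_pct = aligned$identity_pct,
         mismatch_positions = aligned$mismatch_positions,
         indel_positions = aligned$gap_events,
         mean_conversion_rate = mean_rate,
         per_site = per_site,
         pass = length(failed) == 0,
         failed_gates = failed,
         direction = direction),
    class = "bsp_read_qc")
}

#' @export
print.bsp_read_qc <- function(x, ...) {
  cat(sprintf(
    "<bsp_read_qc> %s read: %d bp aligned, identity %.1f%%, conversion %s -> %s\n",
    x$direction, x$aligned_length, x$identity_pct,
    if (is.na(x$mean_conversion_rate)) "NA"
    else sprintf("%.3f", x$mean_conversion_rate),
    if (x$pass) "PASS" else paste("FAIL:", paste(x$failed_gates,
                                                 collapse = ", "))))
  invisible(x)
}

#' @export
tidy.bsp_read_qc <- function(x, ...) {
  tibble(direction = x$direction, aligned_length = x$aligned_length,
         identity_pct = x$identity_pct,
         mean_conversion_rate = x$mean_conversion_rate,
         n_control_sites = sum(!is.na(x$per_site$rate)),
         pass = x$pass,
         failed_gates = paste(x$failed_gates, collapse = ";"))
}
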