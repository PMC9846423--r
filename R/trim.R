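#' Trimming parameters
#'
#' Read extremities carry off-scale signal and base-calling errors, so two
#' independent criteria locate the usable core of each read: a modified
#' Mott algorithm on Phred-derived error probabilities, and a mixed-peak
#' criterion on the primary-peak ratio of the four dye signals. The final
#' window is the intersection of the two, gated on minimum length, mean
#' Phred and non-mixed fraction.
#'
#' @param error_prob_cutoff Base-calling error-probability cutoff for Mott
#'   trimming; the default 0.001 corresponds to Phred Q30
#'   (`Q = -10 log10(P)`).
#' @param primary_ratio_threshold A base is *non-mixed* when its primary
#'   peak ratio is strictly above this (default 0.75).
#' @param non_mixed_fraction_threshold Minimum fraction of non-mixed bases
#'   a candidate window must contain (default 0.75).
#' @param boundary_run_min,boundary_run_max Range of `n`, the number of
#'   consecutive non-mixed bases required at both window boundaries
#'   (default 3 to 15).
#' @param min_length Minimum final-window length in bases (default 30).
#' @param min_mean_phred Minimum mean Phred score over the final window
#'   (default 30).
#' @return A `bsp_trim_params` list.
#' @export
trim_params <- function(error_prob_cutoff = 0.001,
                        primary_ratio_threshold = 0.75,
                        non_mixed_fraction_threshold = 0.75,
                        boundary_run_min = 3L,
                        boundary_run_max = 15L,
                        min_length = 30L,
                        min_mean_phred = 30) {
  stopifnot(error_prob_cutoff > 0, error_prob_cutoff < 1,
            primary_ratio_threshold > 0, primary_ratio_threshold <= 1,
            non_mixed_fraction_threshold > 0,
            non_mixed_fraction_threshold <= 1,
            boundary_run_min <= boundary_run_max, boundary_run_min >= 1)
  structure(
    list(error_prob_cutoff = error_prob_cutoff,
         primary_ratio_threshold = primary_ratio_threshold,
         non_mixed_fraction_threshold = non_mixed_fraction_threshold,
         boundary_run_min = as.integer(boundary_run_min),
         boundary_run_max = as.integer(boundary_run_max),
         min_length = as.integer(min_length),
         min_mean_phred = min_mean_phred),
    class = "bsp_trim_params")
}

#' Mott quality trimming
#'
#' Modified Mott algorithm (M1, reset-to-zero variant): each Phred score is
#' converted to an error probability `p = 10^(-q/10)`; a running score
#' accumulates `cutoff - p`, clipped below at zero, and the returned window
#' is the contiguous segment ending at the running-score maximum and
#' starting just after its last reset. This segment maximises the window
#' sum of `cutoff - p` over all contiguous windows.
#'
#' @param phred Numeric vector of per-base Phred scores.
#' @param error_prob_cutoff Error-probability cutoff (default 0.001, i.e.
#'   Q30).
#' @return Integer `c(start, end)` (1-based, inclusive), or `NULL` when no
#'   window has positive score.
#' @export
#' @examples
#' mott_trim(c(10, 10, 40, 40, 40, 10, 10))  # keeps the Q40 core
mott_trim <- function(phred, error_prob_cutoff = 0.001) {
  stopifnot(length(phred) >= 1)
  p <- 10^(-phred / 10)
  delta <- error_prob_cutoff - p
  s <- numeric(length(delta))
  run_start <- 1L
  best <- 0
  best_window <- NULL
  acc <- 0
  for (i in seq_along(delta)) {
    if (acc <= 0) {
      acc <- 0
      run_start <- i
    }
    acc <- acc + delta[[i]]
    s[[i]] <- max(acc, 0)
    if (acc > best) {
      best <- acc
      best_window <- c(run_start, i)
    }
  }
  if (is.null(best_window)) NULL else as.integer(best_window)
}

#' Primary peak ratio of one called base
#'
#' Ratio of the tallest of the four dye-signal heights to their sum;
#' values near 1 indicate a clean single peak, low values a mixed signal.
#'
#' @param heights Numeric vector of four non-negative heights (A, C, G, T).
#' @return The ratio in `[0, 1]`.
#' @export
#' @examples
#' primary_peak_ratio(c(10, 75, 10, 5))  # 0.75
primary_peak_ratio <- function(heights) {
  stopifnot(length(heights) == 4, all(heights >= 0))
  total <- sum(heights)
  if (total == 0) {
    bsp_abort("all four peak heights are zero: primary peak ratio undefined",
              "undefined_ratio")
  }
  max(heights) / total
}

# per-base non-mixed labels; all-zero bases count as mixed
non_mixed_labels <- function(trace, threshold) {
  hmat <- cbind(trace$height_A, trace$height_C, trace$height_G,
                trace$height_T)
  total <- rowSums(hmat)
  ratio <- ifelse(total > 0, apply(hmat, 1, max) / total, 0)
  ratio > threshold
}

#' Mixed-peak trimming
#'
#' Labels each base non-mixed when its primary peak ratio strictly exceeds
#' `primary_ratio_threshold`, then for each boundary-run length `n` (3 to
#' 15 by default) finds the longest contiguous window whose first `n` and
#' last `n` bases are all non-mixed. Among the candidates whose overall
#' non-mixed fraction reaches `non_mixed_fraction_threshold`, the one with
#' the smallest `n` is returned (ties: longer, then leftmost window).
#'
#' @param trace A [bsp_trace].
#' @param params A [trim_params()] list.
#' @return Integer `c(start, end)` or `NULL` when no window qualifies.
#' @export
mixed_peak_trim <- function(trace, params = trim_params()) {
  ok <- non_mixed_labels(trace, params$primary_ratio_threshold)
  L <- length(ok)
  prefix <- c(0L, cumsum(ok))
  run_ok <- function(s, n) s + n - 1L <= L && prefix[s + n] - prefix[s] == n
  for (n in seq(params$boundary_run_min, params$boundary_run_max)) {
    starts <- which(vapply(seq_len(L), run_ok, logical(1), n = n))
    if (length(starts) == 0) next
    ends <- starts + n - 1L  # window ends whose last n bases are non-mixed
    # longest span with qualifying boundaries at this n
    s <- min(starts)
    e <- max(ends)
    if (e - s + 1L < n) next
    frac <- (prefix[e + 1L] - prefix[s]) / (e - s + 1L)
    if (frac >= params$non_mixed_fraction_threshold) {
      return(c(s, e))
    }
  }
  NULL
}

#' Final read trimming
#'
#' Intersects the Mott quality window with the mixed-peak window and gates
#' the result on minimum length, mean Phred score and non-mixed fraction.
#' Failures are data, not errors: an invalid result carries its reason and
#' the read is excluded from methylation computation downstream.
#'
#' @param trace A [bsp_trace].
#' @param params A [trim_params()] list.
#' @return A `bsp_trimmed_read` with fields `trace`, `start`, `end`,
#'   `quality_window`, `mixed_window`, `mean_phred`, `frac_non_mixed`,
#'   `valid` and `failure_reason`.
#' @export
final_trim <- function(trace, params = trim_params()) {
  qw <- mott_trim(trace$phred, params$error_prob_cutoff)
  mw <- mixed_peak_trim(trace, params)
  out <- structure(
    list(trace = trace, start = NA_integer_, end = NA_integer_,
         quality_window = qw, mixed_window = mw,
         mean_phred = NA_real_, frac_non_mixed = NA_real_,
         valid = FALSE, failure_reason = ""),
    class = "bsp_trimmed_read")

  fail <- function(reason) {
    out$failure_reason <- reason
    out
  }
  if (is.null(qw)) {
    return(fail("quality trimming failed (no window above the error-probability cutoff)"))
  }
  if (is.null(mw)) {
    return(fail("mixed-peak trimming failed (no window with clean boundaries)"))
  }
  win <- intersect_window(qw, mw)
  if (is.null(win)) {
    return(fail("quality and mixed-peak windows do not overlap"))
  }
  idx <- win[[1]]:win[[2]]
  out$start <- win[[1]]
  out$end <- win[[2]]
  out$mean_phred <- mean(trace$phred[idx])
  out$frac_non_mixed <-
    mean(non_mixed_labels(trace, params$primary_ratio_threshold)[idx])
  if (length(idx) < params$min_length) {
    return(fail(sprintf("trimmed length %d below minimum %d",
                        length(idx), params$min_length)))
  }
  if (out$mean_phred < params$min_mean_phred) {
    return(fail(sprintf("mean Phred %.1f below minimum %s",
                        out$mean_phred, format(params$min_mean_phred))))
  }
  if (out$frac_non_mixed < params$non_mixed_fraction_threshold) {
    return(fail(sprintf("non-mixed fraction %.2f below minimum %s",
                        out$frac_non_mixed,
                        format(params$non_mixed_fraction_threshold))))
  }
  out$valid <- TRUE
  out
}

#' @export
print.bsp_trimmed_read <- function(x, ...) {
  if (x$valid) {
    cat(sprintf(
      "<bsp_trimmed_read> kept %d-%d of %d bases (mean Q %.1f, %.0f%% non-mixed)\n",
      x$start, x$end, nrow(x$trace), x$mean_phred, 100 * x$frac_non_mixed))
  } else {
    cat(sprintf("<bsp_trimmed_read> invalid: %s\n", x$failure_reason))
  }
  invisible(x)
}

#' @export
tidy.bsp_trimmed_read <- function(x, ...) {
  tibble(
    read_id = attr(x$trace, "read_id"),
    start = x$start, end = x$end,
    length = if (x$valid) x$end - x$start + 1L else NA_integer_,
    mean_phred = x$mean_phred, frac_non_mixed = x$frac_non_mixed,
    valid = x$valid, failure_reason = x$failure_reason)
}

# called sequence of the kept window
trimmed_seq <- function(trimmed) {
  paste(trimmed$trace$base[trimmed$start:trimmed$end], collapse = "")
}
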