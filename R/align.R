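#' Alignment parameters
#'
#' Scoring for the Smith-Waterman local alignment of trimmed reads against
#' the bisulfite-converted templates. The defaults favour long contiguous
#' alignments, appropriate for high-identity Sanger reads.
#'
#' @param match,mismatch Substitution scores (N never matches anything).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param min_aligned_length Minimum template span for an alignment to be
#'   considered usable at all (default 30 bases).
#' @param min_identity Minimum identity percentage over aligned columns for
#'   a valid alignment (default 75).
#' @return A `bsp_align_params` list.
#' @export
align_params <- function(match = 2, mismatch = -1, gap_open = 5,
                         gap_extend = 2, min_aligned_length = 30L,
                         min_identity = 75) {
  structure(
    list(match = match, mismatch = mismatch, gap_open = gap_open,
         gap_extend = gap_extend,
         min_aligned_length = as.integer(min_aligned_length),
         min_identity = min_identity),
    class = "bsp_align_params")
}

# substitution matrix over A/C/G/T/N with N matching nothing
bsp_submat <- function(params) {
  letters <- c(BASES, "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- params$match
  m["N", "N"] <- params$mismatch
  m
}

pairwise_local <- function(read_seq, template, params) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(read_seq),
    subject = Biostrings::DNAString(template),
    type = "local",
    substitutionMatrix = bsp_submat(params),
    gapOpening = params$gap_open,
    gapExtension = params$gap_extend)
}

#' Align a trimmed read to one converted template
#'
#' Smith-Waterman local alignment (affine gaps) of the read's called
#' sequence against a bisulfite-converted template. The result records the
#' alignment start on the template (`s_start`, the subject start in
#' pairwise-alignment terms) and on the read (`p_start`, pattern start:
#' the trimmed read is the pattern, the converted template the subject),
#' plus mismatches, gap
#' events, an identity percentage and a gap-corrected position map from
#' template positions to read positions (template positions falling in a
#' read gap map to `NA`). For an ungapped alignment the map reduces to the
#' closed form `read_pos = template_pos - s_start + p_start`.
#'
#' Columns at `variable_positions` (template positions where methylation
#' legitimately makes the read base differ, i.e. CpG cytosines) are
#' excluded from the identity computation so that the methylation level
#' cannot distort the quality verdict.
#'
#' @param read A `bsp_trimmed_read` (valid) or a plain character sequence.
#' @param template Template sequence string (sense or antisense).
#' @param variable_positions Template positions excluded from identity.
#' @param params An [align_params()] list.
#' @return A `bsp_alignment` with fields `s_start`, `s_end`, `p_start`,
#'   `p_end`, `aligned_length`, `identity_pct`, `mismatch_positions`,
#'   `gap_events`, `position_map` (tibble `template_pos`/`read_pos`),
#'   `valid`, `failure_reason`.
#' @export
align_to_template <- function(read, template,
                              variable_positions = integer(),
                              params = align_params()) {
  read_seq <- if (inherits(read, "bsp_trimmed_read")) {
    stopifnot(read$valid)
    trimmed_seq(read)
  } else {
    as.character(read)
  }
  al <- pairwise_local(read_seq, template, params)
  build_alignment(al, variable_positions, params)
}

build_alignment <- function(al, variable_positions, params) {
  p_gapped <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  s_gapped <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  s_start <- Biostrings::start(Biostrings::subject(al))
  p_start <- Biostrings::start(Biostrings::pattern(al))

  out <- structure(
    list(s_start = s_start, s_end = NA_integer_, p_start = p_start,
         p_end = NA_integer_, aligned_length = 0L, identity_pct = NA_real_,
         score = Biostrings::score(al),
         mismatch_positions = integer(),
         gap_events = tibble(frame = character(), position = integer(),
                             length = integer()),
         position_map = tibble(template_pos = integer(),
                               read_pos = integer()),
         valid = FALSE, failure_reason = ""),
    class = "bsp_alignment")

  if (length(p_gapped) == 0) {
    out$failure_reason <- "empty alignment"
    return(out)
  }

  # column walk: advance template/read counters over the gapped strings
  t_pos <- s_start - 1L
  r_pos <- p_start - 1L
  n_col <- length(p_gapped)
  template_pos <- integer(n_col)
  read_pos <- integer(n_col)
  for (i in seq_len(n_col)) {
    if (s_gapped[[i]] != "-") t_pos <- t_pos + 1L
    if (p_gapped[[i]] != "-") r_pos <- r_pos + 1L
    template_pos[[i]] <- if (s_gapped[[i]] == "-") NA_integer_ else t_pos
    read_pos[[i]] <- if (p_gapped[[i]] == "-") NA_integer_ else r_pos
  }
  out$s_end <- t_pos
  out$p_end <- r_pos
  out$aligned_length <- out$s_end - out$s_start + 1L
  out$position_map <- tibble(template_pos = template_pos,
                             read_pos = read_pos) |>
    filter(!is.na(.data$template_pos))

  both <- s_gapped != "-" & p_gapped != "-"
  eligible <- both & !(template_pos %in% variable_positions)
  matches <- eligible & p_gapped == s_gapped & p_gapped != "N"
  out$identity_pct <- if (sum(eligible) > 0) {
    100 * sum(matches) / sum(eligible)
  } else {
    0
  }
  out$mismatch_positions <-
    template_pos[eligible & !matches & !is.na(template_pos)]

  out$gap_events <- bind_rows(
    gap_runs(p_gapped == "-", template_pos, "read"),
    gap_runs(s_gapped == "-", read_pos, "template"))

  if (out$aligned_length < params$min_aligned_length) {
    out$failure_reason <- sprintf("aligned length %d below minimum %d",
                                  out$aligned_length,
                                  params$min_aligned_length)
  } else if (out$identity_pct < params$min_identity) {
    out$failure_reason <- sprintf("identity %.1f%% below minimum %s%%",
                                  out$identity_pct,
                                  format(params$min_identity))
  } else {
    out$valid <- TRUE
  }
  out
}

# runs of gap columns; position = counter value in the opposite frame at
# the first gapped column
gap_runs <- function(is_gap, opposite_pos, frame) {
  if (!any(is_gap)) {
    return(tibble(frame = character(), position = integer(),
                  length = integer()))
  }
  r <- rle(is_gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(frame = frame,
         position = opposite_pos[starts[keep]],
         length = r$lengths[keep])
}

#' @export
print.bsp_alignment <- function(x, ...) {
  cat(sprintf(
    "<bsp_alignment> template %d-%d, read %d-%d, %d bp, identity %.1f%%%s\n",
    x$s_start, x$s_end, x$p_start, x$p_end, x$aligned_length,
    x$identity_pct,
    if (x$valid) "" else sprintf(" [invalid: %s]", x$failure_reason)))
  invisible(x)
}

#' @export
tidy.bsp_alignment <- function(x, ...) {
  tibble(s_start = x$s_start, s_end = x$s_end, p_start = x$p_start,
         p_end = x$p_end, aligned_length = x$aligned_length,
         identity_pct = x$identity_pct, n_mismatches =
           length(x$mismatch_positions), n_gap_events = nrow(x$gap_events),
         valid = x$valid, failure_reason = x$failure_reason)
}

#' Map a template position into the read frame
#'
#' Gap-aware lookup in an alignment's position map. Template positions
#' inside a read gap return `NA`; positions outside the aligned span also
#' return `NA`.
#'
#' @param alignment A `bsp_alignment`.
#' @param template_pos Template position(s), 1-based.
#' @return Integer read position(s) or `NA`.
#' @export
#' @examples
#' # an ungapped alignment satisfies read_pos = template_pos - s_start + p_start
map_position <- function(alignment, template_pos) {
  idx <- match(template_pos, alignment$position_map$template_pos)
  alignment$position_map$read_pos[idx]
}

#' Detect sequencing direction of a read
#'
#' Sequencing files are unlabeled (the direction must not be specified), so
#' the trimmed read is locally aligned against both the sense and the
#' antisense converted template; the pairing with the longer aligned span
#' wins (ties: higher score, then sense), with a valid alignment (length
#' and identity gates) always preferred over an invalid one so that a
#' spurious gapped alignment to the wrong template cannot win on raw
#' length. A read matching the sense template is a forward read.
#'
#' @param read A valid `bsp_trimmed_read` or character sequence.
#' @param templates A `bsp_templates` pair from [bisulfite_convert()].
#' @param params An [align_params()] list.
#' @return A list with `direction` (`"forward"`/`"reverse"`),
#'   `template_used` (`"sense"`/`"antisense"`) and the winning
#'   `bsp_alignment`.
#' @export
detect_direction <- function(read, templates, params = align_params()) {
  stopifnot(inherits(templates, "bsp_templates"))
  cpg_sense <- templates$cpg_positions_sense
  cpg_anti <- sort(mirror_position(templates, cpg_sense))
  fwd <- align_to_template(read, templates$sense,
                           variable_positions = cpg_sense, params = params)
  rev <- align_to_template(read, templates$antisense,
                           variable_positions = cpg_anti, params = params)
  if (!fwd$valid && !rev$valid) {
    bsp_abort(
      "read aligns to neither template (no usable local alignment)",
      "no_alignment")
  }
  pick_sense <- if (fwd$valid != rev$valid) {
    fwd$valid
  } else if (fwd$aligned_length != rev$aligned_length) {
    fwd$aligned_length > rev$aligned_length
  } else {
    fwd$score >= rev$score
  }
  best <- if (pick_sense) fwd else rev
  list(direction = if (pick_sense) "forward" else "reverse",
       template_used = if (pick_sense) "sense" else "antisense",
       alignment = best)
}

#' Genomic region covered by the sequencing reads
#'
#' Union of the genomic spans covered by the valid alignments of the
#' forward and/or reverse read. Reverse-read (antisense-frame) positions
#' are mirrored into the sense frame before conversion to plus-strand
#' genomic coordinates. Internal stretches covered by neither read are
#' recorded as gaps.
#'
#' @param fwd,rev `bsp_alignment` objects or `NULL`.
#' @param templates A `bsp_templates` pair.
#' @return A list with `alg_coord_start`, `alg_coord_end` and a tibble
#'   `uncovered` of internal gaps (`start`, `end`, genomic coordinates).
#' @export
covered_region <- function(fwd, rev, templates) {
  spans <- list()
  if (!is.null(fwd) && fwd$valid) {
    spans <- c(spans, list(sort(sense_to_genomic(templates,
                                                 c(fwd$s_start, fwd$s_end)))))
  }
  if (!is.null(rev) && rev$valid) {
    sense_span <- mirror_position(templates, c(rev$s_start, rev$s_end))
    spans <- c(spans, list(sort(sense_to_genomic(templates,
                                                 sort(sense_span)))))
  }
  if (length(spans) == 0) {
    bsp_abort("no valid aligned read: covered region undefined",
              "no_valid_read")
  }
  starts <- vapply(spans, `[[`, numeric(1), 1)
  ends <- vapply(spans, `[[`, numeric(1), 2)
  ord <- order(starts)
  starts <- starts[ord]
  ends <- ends[ord]
  gaps <- tibble(start = integer(), end = integer())
  if (length(starts) == 2 && starts[[2]] > ends[[1]] + 1) {
    gaps <- tibble(start = as.integer(ends[[1]] + 1),
                   end = as.integer(starts[[2]] - 1))
  }
  list(alg_coord_start = as.integer(min(starts)),
       alg_coord_end = as.integer(max(ends)),
       uncovered = gaps)
}

# is a genomic coordinate covered by at least one read span?
coordinate_covered <- function(covered, coord) {
  inside <- coord >= covered$alg_coord_start &
    coord <= covered$alg_coord_end
  if (nrow(covered$uncovered) > 0) {
    in_gap <- vapply(coord, function(x) {
      any(x >= covered$uncovered$start & x <= covered$uncovered$end)
    }, logical(1))
    inside & !in_gap
  } else {
    inside
  }
}
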