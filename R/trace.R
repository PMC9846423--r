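#' Chromatogram trace objects
#'
#' A chromatogram trace holds, for one Sanger sequencing read, the called
#' bases, their Phred quality scores and the height of each of the four dye
#' signals (A/C/G/T) at every called-base position. It is represented as a
#' tibble with one row per called base and columns `base`, `phred`,
#' `height_A`, `height_C`, `height_G`, `height_T`, plus attributes `read_id`
#' and `source_path`.
#'
#' @param base Character vector of called bases (A/C/G/T/N).
#' @param phred Non-negative integer Phred quality score per base.
#' @param peak_heights Numeric matrix, one row per base, columns named
#'   A, C, G, T; non-negative dye-signal heights at each called position.
#' @param read_id Identifier for the read.
#' @param source_path Path the trace was read from, or `""`.
#'
#' @return A `bsp_trace` tibble with one row per called base.
#' @export
#' @examples
#' bsp_trace(c("A", "C"), c(50, 50),
#'           matrix(c(900, 0, 0, 900, 0, 0, 0, 0), 2, 4,
#'                  dimnames = list(NULL, c("A", "C", "G", "T"))))
bsp_trace <- function(base, phred, peak_heights, read_id = "read",
                      source_path = "") {
  base <- toupper(as.character(base))
  if (length(base) < 1) {
    bsp_abort("a trace needs at least one called base", "bad_trace")
  }
  if (!all(base %in% c("A", "C", "G", "T", "N"))) {
    bsp_abort("called bases must be A/C/G/T/N", "bad_trace")
  }
  phred <- as.integer(phred)
  if (length(phred) != length(base) || anyNA(phred) || any(phred < 0)) {
    bsp_abort("phred scores must be non-negative, one per base", "bad_trace")
  }
  peak_heights <- as.matrix(peak_heights)
  if (nrow(peak_heights) != length(base) || ncol(peak_heights) != 4) {
    bsp_abort("peak_heights must be an L x 4 matrix", "bad_trace")
  }
  if (!is.null(colnames(peak_heights))) {
    peak_heights <- peak_heights[, BASES, drop = FALSE]
  }
  if (anyNA(peak_heights) || any(peak_heights < 0)) {
    bsp_abort("peak heights must be non-negative", "bad_trace")
  }
  out <- tibble(
    base = base,
    phred = phred,
    height_A = as.numeric(peak_heights[, 1]),
    height_C = as.numeric(peak_heights[, 2]),
    height_G = as.numeric(peak_heights[, 3]),
    height_T = as.numeric(peak_heights[, 4])
  )
  attr(out, "read_id") <- as.character(read_id)
  attr(out, "source_path") <- as.character(source_path)
  class(out) <- c("bsp_trace", class(out))
  out
}

#' @export
print.bsp_trace <- function(x, ...) {
  cat(sprintf("<bsp_trace> %s: %d called bases, mean Q %.1f\n",
              attr(x, "read_id") %||% "?", nrow(x), mean(x$phred)))
  NextMethod()
}

# heights of one called base as a named A/C/G/T vector
trace_heights <- function(trace, i) {
  setNames(c(trace$height_A[[i]], trace$height_C[[i]],
             trace$height_G[[i]], trace$height_T[[i]]), BASES)
}

trace_seq <- function(trace) paste(trace$base, collapse = "")

## ---- ABIF binary format -------------------------------------------------
## ABIF 1.x: "ABIF" magic, big-endian, a directory of 28-byte tagged entries.
## Entries with datasize <= 4 store their payload inline in the offset field.

ABIF_TYPE_BYTE <- 1L
ABIF_TYPE_CHAR <- 2L
ABIF_TYPE_SHORT <- 4L
ABIF_TYPE_LONG <- 5L

abif_int <- function(raw, offset, size, signed = TRUE) {
  readBin(raw[(offset + 1):(offset + size)], "integer",
          n = 1L, size = size, signed = signed, endian = "big")
}

abif_read_dir_entry <- function(raw, offset) {
  list(
    name = rawToChar(raw[(offset + 1):(offset + 4)]),
    number = abif_int(raw, offset + 4, 4),
    etype = abif_int(raw, offset + 8, 2),
    esize = abif_int(raw, offset + 10, 2),
    nelem = abif_int(raw, offset + 12, 4),
    dsize = abif_int(raw, offset + 16, 4),
    # keep the raw bytes: they are the payload itself when dsize <= 4
    offset_raw = raw[(offset + 21):(offset + 24)],
    offset = abif_int(raw, offset + 20, 4)
  )
}

abif_entry_data <- function(raw, entry) {
  payload <- if (entry$dsize <= 4) {
    entry$offset_raw[seq_len(entry$dsize)]
  } else {
    if (entry$offset + entry$dsize > length(raw)) {
      bsp_abort(sprintf("ABIF field %s.%d points past end of file",
                        entry$name, entry$number), "abif_truncated")
    }
    raw[(entry$offset + 1):(entry$offset + entry$dsize)]
  }
  switch(as.character(entry$etype),
    "1" = readBin(payload, "integer", n = entry$nelem, size = 1L,
                  signed = FALSE),
    "2" = rawToChar(payload),
    "4" = readBin(payload, "integer", n = entry$nelem, size = 2L,
                  signed = TRUE, endian = "big"),
    "5" = readBin(payload, "integer", n = entry$nelem, size = 4L,
                  signed = TRUE, endian = "big"),
    bsp_abort(sprintf("unsupported ABIF element type %d in field %s.%d",
                      entry$etype, entry$name, entry$number), "abif_type")
  )
}

# prefer the edited field (tag number 1) over the basecaller original (2)
abif_find <- function(entries, name, numbers = c(1L, 2L)) {
  for (num in numbers) {
    hit <- Filter(function(e) e$name == name && e$number == num, entries)
    if (length(hit) > 0) {
      return(hit[[1]])
    }
  }
  NULL
}

abif_required <- function(entries, raw, name, numbers, what) {
  e <- abif_find(entries, name, numbers)
  if (is.null(e)) {
    bsp_abort(sprintf("ABIF file is missing the %s field (%s)", what, name),
              "abif_missing_field")
  }
  abif_entry_data(raw, e)
}

#' Read an ABIF chromatogram file
#'
#' Parses an Applied Biosystems trace file (`*.ab1`) into a [bsp_trace]:
#' called bases (`PBAS`), per-base Phred qualities (`PCON`), and the four
#' analyzed dye-signal channels (`DATA` 9-12) sampled at each base call's
#' peak location (`PLOC`). The channel-to-base assignment is taken from the
#' file's field-order record (`FWO_`), never assumed fixed. Edited fields
#' (tag number 1) are preferred over basecaller originals (tag number 2).
#'
#' @param path Path to an `.ab1` file.
#' @return A [bsp_trace] tibble.
#' @export
read_abif <- function(path) {
  if (!file.exists(path)) {
    bsp_abort(sprintf("trace file not found: %s", path), "missing_file")
  }
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 34 || rawToChar(raw[1:4]) != "ABIF") {
    bsp_abort(sprintf("not an ABIF file (bad magic): %s", path), "not_abif")
  }
  tdir <- abif_read_dir_entry(raw, 6L)
  n_entries <- tdir$nelem
  if (n_entries < 1 || tdir$offset + 28L * n_entries > length(raw)) {
    bsp_abort(sprintf("truncated or corrupt ABIF directory: %s", path),
              "abif_truncated")
  }
  entries <- lapply(seq_len(n_entries) - 1L, function(i) {
    abif_read_dir_entry(raw, tdir$offset + 28L * i)
  })

  bases <- strsplit(abif_required(entries, raw, "PBAS", c(1L, 2L),
                                  "base-call"), "")[[1]]
  phred <- abif_required(entries, raw, "PCON", c(1L, 2L), "per-base quality")
  ploc <- abif_required(entries, raw, "PLOC", c(1L, 2L), "peak-location")
  order_chars <- strsplit(abif_required(entries, raw, "FWO_", 1L,
                                        "channel field-order"), "")[[1]]
  if (length(order_chars) != 4 || !setequal(order_chars, BASES)) {
    bsp_abort("ABIF field order (FWO_) must be a permutation of ACGT",
              "abif_missing_field")
  }
  L <- length(bases)
  if (length(phred) != L || length(ploc) != L) {
    bsp_abort("ABIF base calls, qualities and peak locations differ in length",
              "abif_inconsistent")
  }

  heights <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, BASES))
  for (k in 1:4) {
    channel <- abif_required(entries, raw, "DATA", 8L + k,
                             sprintf("trace channel DATA.%d", 8L + k))
    if (any(ploc < 0L) || any(ploc >= length(channel))) {
      bsp_abort("ABIF peak locations fall outside the trace channels",
                "abif_inconsistent")
    }
    # PLOC indices are 0-based positions within the channel arrays
    heights[, order_chars[[k]]] <- channel[ploc + 1L]
  }

  bsp_trace(bases, phred, heights,
            read_id = sub("\\.ab1$", "", basename(path)),
            source_path = path)
}

#' Write a minimal ABIF chromatogram file
#'
#' Emits a minimal valid ABIF file holding the four fields a [read_abif()]
#' round-trip needs: base calls, per-base qualities, peak locations and the
#' four dye channels (one trace point per called base). Peak heights are
#' stored as 16-bit integers, so they must be whole numbers below 32768.
#'
#' @param trace A [bsp_trace].
#' @param path Output path (conventionally `*.ab1`).
#' @param channel_order Order in which the four dye channels are written to
#'   `DATA.9`-`DATA.12`, recorded in the file's `FWO_` field. Readers must
#'   honour it, so any permutation yields an equivalent file.
#' @return `path`, invisibly.
#' @export
write_abif <- function(trace, path, channel_order = "GATC") {
  stopifnot(inherits(trace, "bsp_trace"))
  order_chars <- strsplit(channel_order, "")[[1]]
  if (length(order_chars) != 4 || !setequal(order_chars, BASES)) {
    bsp_abort("channel_order must be a permutation of 'ACGT'", "bad_argument")
  }
  L <- nrow(trace)
  hmat <- as.matrix(trace[, paste0("height_", BASES)])
  colnames(hmat) <- BASES
  if (any(hmat != round(hmat)) || any(hmat > 32767)) {
    bsp_abort("ABIF stores peak heights as 16-bit integers; heights must be whole numbers < 32768",
              "bad_trace")
  }
  if (any(trace$phred > 255)) {
    bsp_abort("ABIF stores qualities as bytes; phred must be <= 255",
              "bad_trace")
  }

  pack <- function(values, etype) {
    con <- rawConnection(raw(0), "wb")
    on.exit(close(con))
    switch(as.character(etype),
      "1" = writeBin(as.integer(values), con, size = 1L),
      "2" = writeBin(charToRaw(paste(values, collapse = "")), con),
      "4" = writeBin(as.integer(values), con, size = 2L, endian = "big"),
      "5" = writeBin(as.integer(values), con, size = 4L, endian = "big")
    )
    rawConnection_value(con)
  }

  fields <- list(
    list(name = "PBAS", number = 1L, etype = ABIF_TYPE_CHAR, esize = 1L,
         nelem = L, data = pack(trace$base, ABIF_TYPE_CHAR)),
    list(name = "PCON", number = 1L, etype = ABIF_TYPE_BYTE, esize = 1L,
         nelem = L, data = pack(trace$phred, ABIF_TYPE_BYTE)),
    list(name = "PLOC", number = 1L, etype = ABIF_TYPE_SHORT, esize = 2L,
         nelem = L, data = pack(seq_len(L) - 1L, ABIF_TYPE_SHORT)),
    list(name = "FWO_", number = 1L, etype = ABIF_TYPE_CHAR, esize = 1L,
         nelem = 4L, data = pack(order_chars, ABIF_TYPE_CHAR))
  )
  for (k in 1:4) {
    fields[[length(fields) + 1L]] <- list(
      name = "DATA", number = 8L + k, etype = ABIF_TYPE_SHORT, esize = 2L,
      nelem = L, data = pack(hmat[, order_chars[[k]]], ABIF_TYPE_SHORT))
  }

  header_size <- 128L
  # lay payloads (> 4 bytes) out after the header, then the directory
  cursor <- header_size
  for (i in seq_along(fields)) {
    dsize <- length(fields[[i]]$data)
    fields[[i]]$dsize <- dsize
    if (dsize > 4) {
      fields[[i]]$offset <- cursor
      cursor <- cursor + dsize
    }
  }
  dir_offset <- cursor

  int_raw <- function(x, size) {
    writeBin(as.integer(x), raw(), size = size, endian = "big")
  }
  entry_raw <- function(f) {
    inline <- if (f$dsize <= 4) {
      c(f$data, raw(4 - f$dsize))
    } else {
      int_raw(f$offset, 4L)
    }
    c(charToRaw(f$name), int_raw(f$number, 4L), int_raw(f$etype, 2L),
      int_raw(f$esize, 2L), int_raw(f$nelem, 4L), int_raw(f$dsize, 4L),
      inline, int_raw(0L, 4L))
  }

  tdir <- c(charToRaw("tdir"), int_raw(1L, 4L), int_raw(1023L, 2L),
            int_raw(28L, 2L), int_raw(length(fields), 4L),
            int_raw(28L * length(fields), 4L), int_raw(dir_offset, 4L),
            int_raw(0L, 4L))
  header <- c(charToRaw("ABIF"), int_raw(101L, 2L), tdir,
              raw(header_size - 34L))

  body <- unlist(lapply(fields, function(f) {
    if (f$dsize > 4) f$data else raw(0)
  }))
  directory <- unlist(lapply(fields, entry_raw))

  ok <- tryCatch({
    writeBin(c(header, body, directory), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    bsp_abort(sprintf("cannot write ABIF file: %s", path), "unwritable")
  }
  invisible(path)
}

# rawConnectionValue with the connection still open
rawConnection_value <- function(con) {
  rawConnectionValue(con)
}
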