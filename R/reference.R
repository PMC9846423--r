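#' Reference region for a BSP amplicon
#'
#' Holds the genomic reference sequence of the amplified region together
#' with its genomic coordinates (1-based, fully closed) and the strand that
#' was PCR-amplified after bisulfite conversion. Because bisulfite treatment
#' makes the two strands non-complementary, a single primer pair amplifies
#' exactly one of them; all downstream templates derive from that strand.
#'
#' @param sequence Reference sequence (A/C/G/T/N) as a single string.
#' @param seq_start,seq_end Genomic coordinates of the first and last base.
#' @param amplified_strand `"plus"` or `"minus"`.
#' @param name Sequence name.
#' @return A `bsp_reference` object.
#' @export
#' @examples
#' reference_region("TACGTA", 6000, 6005, "plus", "demo")
reference_region <- function(sequence, seq_start, seq_end,
                             amplified_strand = c("plus", "minus"),
                             name = "region") {
  amplified_strand <- match.arg(amplified_strand)
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", sequence)) {
    bsp_abort("reference sequence may only contain A/C/G/T/N",
              "bad_reference")
  }
  seq_start <- as.integer(seq_start)
  seq_end <- as.integer(seq_end)
  if (seq_end - seq_start + 1L != nchar(sequence)) {
    bsp_abort(sprintf(
      "coordinate span %d-%d (%d bp) does not match sequence length %d bp",
      seq_start, seq_end, seq_end - seq_start + 1L, nchar(sequence)),
      "coordinate_mismatch")
  }
  structure(
    list(name = as.character(name), sequence = sequence,
         seq_start = seq_start, seq_end = seq_end,
         amplified_strand = amplified_strand),
    class = "bsp_reference")
}

#' @export
print.bsp_reference <- function(x, ...) {
  cat(sprintf("<bsp_reference> %s: %d bp, %d-%d, amplified strand %s\n",
              x$name, nchar(x$sequence), x$seq_start, x$seq_end,
              x$amplified_strand))
  invisible(x)
}

#' Load a reference region from a FASTA file
#'
#' The FASTA file must contain exactly one record. Coordinates and strand
#' are normally passed as arguments; alternatively a header of the form
#' `>name chrom:start-end strand` is parsed when they are omitted.
#'
#' @param fasta_path Path to a single-record FASTA file.
#' @param seq_start,seq_end Genomic coordinates of the region
#'   (1-based, closed). Taken from the header when `NULL`.
#' @param amplified_strand `"plus"` or `"minus"`; taken from the header
#'   (`+`/`-`/`plus`/`minus`) when `NULL`.
#' @return A `bsp_reference` object.
#' @export
load_reference <- function(fasta_path, seq_start = NULL, seq_end = NULL,
                           amplified_strand = NULL) {
  if (!file.exists(fasta_path)) {
    bsp_abort(sprintf("reference FASTA not found: %s", fasta_path),
              "missing_file")
  }
  set <- Biostrings::readDNAStringSet(fasta_path)
  if (length(set) != 1) {
    bsp_abort(sprintf("expected exactly one FASTA record, found %d",
                      length(set)), "bad_reference")
  }
  header <- names(set)[[1]]
  name <- strsplit(header, "\\s+")[[1]][[1]]
  if (is.null(seq_start) || is.null(seq_end) || is.null(amplified_strand)) {
    m <- regmatches(header,
                    regexec("(\\S+):(\\d+)-(\\d+)\\s+(\\+|-|plus|minus)",
                            header))[[1]]
    if (length(m) == 0) {
      bsp_abort(paste0("coordinates/strand not supplied and the FASTA ",
                       "header does not follow '>name chrom:start-end strand'"),
                "bad_reference")
    }
    seq_start <- seq_start %||% as.integer(m[[3]])
    seq_end <- seq_end %||% as.integer(m[[4]])
    amplified_strand <- amplified_strand %||%
      if (m[[5]] %in% c("+", "plus")) "plus" else "minus"
  }
  reference_region(as.character(set[[1]]), seq_start, seq_end,
                   amplified_strand, name = name)
}

#' Locate CpG sites on a reference region
#'
#' Scans the plus-strand reference for CG dinucleotides and reports the
#' cytosine of each site on both strands (the CpG is palindromic: the
#' plus-strand C pairs with a minus-strand C one base downstream). Genomic
#' coordinates follow `c_coordinate = seq_start + c_position - 1`. Only
#' complete CG dinucleotides inside the region count, and `N` never matches.
#'
#' @param ref A `bsp_reference`.
#' @return A tibble with one row per site and strand: `index` (ordinal of
#'   the CG dinucleotide, ascending position), `strand`, `c_position`
#'   (1-based position of the C on the plus-strand reference) and
#'   `c_coordinate`.
#' @export
find_cpg_sites <- function(ref) {
  stopifnot(inherits(ref, "bsp_reference"))
  starts <- cg_starts(ref$sequence)
  if (length(starts) == 0) {
    return(tibble(index = integer(), strand = character(),
                  c_position = integer(), c_coordinate = integer()))
  }
  bind_rows(
    tibble(index = seq_along(starts), strand = "plus",
           c_position = starts),
    tibble(index = seq_along(starts), strand = "minus",
           c_position = starts + 1L)
  ) |>
    mutate(c_coordinate = ref$seq_start + .data$c_position - 1L) |>
    arrange(.data$index, .data$strand == "minus")
}

# start positions of CG dinucleotides in a sequence string
cg_starts <- function(sequence) {
  hits <- gregexpr("CG", sequence, fixed = TRUE)[[1]]
  if (hits[[1]] == -1) integer() else as.integer(hits)
}

#' In-silico bisulfite conversion and PCR of the reference
#'
#' Reproduces the wet-lab steps on the amplified strand: every cytosine
#' outside a CpG context is deaminated to T (assuming complete conversion),
#' while CpG cytosines are kept as C because they may be methylated. PCR
#' then regenerates the opposite strand, giving the two sequencing
#' templates: the converted amplified strand (*sense*, template for forward
#' reads) and its reverse complement (*antisense*, template for reverse
#' reads).
#'
#' @param ref A `bsp_reference`.
#' @return A `bsp_templates` object with elements `sense`, `antisense`,
#'   `cpg_positions_sense` (positions of CpG cytosines on the sense
#'   template), `non_cpg_c_positions_sense` (conversion-control positions:
#'   cytosines of the unconverted amplified strand outside CpG context, in
#'   sense coordinates), `length` and the originating reference.
#' @export
bisulfite_convert <- function(ref) {
  stopifnot(inherits(ref, "bsp_reference"))
  amp <- if (ref$amplified_strand == "plus") {
    ref$sequence
  } else {
    revcomp(ref$sequence)
  }
  chars <- strsplit(amp, "")[[1]]
  n <- length(chars)
  is_c <- chars == "C"
  followed_by_g <- c(chars[-1] == "G", FALSE)
  cpg <- which(is_c & followed_by_g)
  control <- which(is_c & !followed_by_g)
  converted <- chars
  converted[control] <- "T"
  structure(
    list(sense = paste(converted, collapse = ""),
         antisense = revcomp(paste(converted, collapse = "")),
         cpg_positions_sense = cpg,
         non_cpg_c_positions_sense = control,
         length = n,
         ref = ref),
    class = "bsp_templates")
}

#' @export
print.bsp_templates <- function(x, ...) {
  cat(sprintf(
    "<bsp_templates> %d bp, %d CpG site(s), %d conversion-control C(s)\n",
    x$length, length(x$cpg_positions_sense),
    length(x$non_cpg_c_positions_sense)))
  invisible(x)
}

# genomic coordinate (plus strand of the genome) of sense-template position i
sense_to_genomic <- function(templates, i) {
  ref <- templates$ref
  if (ref$amplified_strand == "plus") {
    ref$seq_start + i - 1L
  } else {
    ref$seq_end - i + 1L
  }
}

# mirror between sense and antisense frames of the same template pair
mirror_position <- function(templates, i) {
  templates$length - i + 1L
}
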