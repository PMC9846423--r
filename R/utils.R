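# shared internal helpers

BASES <- c("A", "C", "G", "T")

# reverse-complement a plain character string (IUPAC A/C/G/T/N only)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# run code under a given seed without disturbing the caller's RNG stream;
# seed = NULL runs as-is
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# intersection of two closed integer intervals given as c(start, end);
# NULL when empty or when either input is NULL
intersect_window <- function(a, b) {
  if (is.null(a) || is.null(b)) {
    return(NULL)
  }
  lo <- max(a[[1]], b[[1]])
  hi <- min(a[[2]], b[[2]])
  if (lo > hi) NULL else c(lo, hi)
}

# structured errors: every condition carries a bspmeth-prefixed class so
# callers (and the CLI) can distinguish input problems from bugs
bsp_abort <- function(message, class) {
  abort(message, class = c(paste0("bspmeth_", class), "bspmeth_error"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# significance symbols used across plots/tables (boxplot/profile legends):
# p <= 0.0001 '****', 0.001 '***', 0.01 '**', 0.05 '*', else 'ns'
significance_symbol <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) {
      return(NA_character_)
    }
    if (pi <= 1e-04) "****"
    else if (pi <= 0.001) "***"
    else if (pi <= 0.01) "**"
    else if (pi <= 0.05) "*"
    else "ns"
  }, character(1))
}
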