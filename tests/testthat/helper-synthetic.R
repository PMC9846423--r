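# shared fixtures and independent brute-force oracles

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a reference with a guaranteed CpG every ~15 bp on average
random_reference <- function(n = 300, seq_start = 6000, strand = "plus",
                             name = "testseq") {
  reference_region(random_dna(n), seq_start, seq_start + n - 1L, strand,
                   name)
}

# build a trace directly from a heights matrix (bases called by max peak)
trace_from_heights <- function(heights, phred) {
  called <- c("A", "C", "G", "T")[max.col(heights, ties.method = "first")]
  bsp_trace(called, phred, heights)
}

# random trace for trimming property tests: runs of clean and mixed bases
random_trim_trace <- function(L = NULL) {
  L <- L %||% sample(30:200, 1)
  mixed <- runif(L) < 0.15
  heights <- matrix(0, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_len(L)) {
    if (mixed[[i]]) {
      heights[i, ] <- round(runif(4, 200, 400))
    } else {
      heights[i, sample(4, 1)] <- 1000
      heights[i, ] <- heights[i, ] + round(runif(4, 0, 60))
    }
  }
  phred <- sample(c(8L, 15L, 35L, 50L), L, replace = TRUE,
                  prob = c(0.03, 0.02, 0.15, 0.8))
  trace_from_heights(heights, phred)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# exhaustive-search oracle for Mott trimming: best window score over all
# O(L^2) contiguous windows of sum(cutoff - p)
mott_oracle <- function(phred, cutoff = 0.001) {
  p <- 10^(-phred / 10)
  S <- c(0, cumsum(cutoff - p))
  L <- length(phred)
  best <- 0
  win <- NULL
  for (s in seq_len(L)) {
    scores <- S[(s + 1):(L + 1)] - S[s]
    m <- max(scores)
    if (m > best + 1e-12) {
      best <- m
      win <- c(s, s - 1L + which.max(scores))
    }
  }
  list(window = win, score = best)
}

window_score <- function(phred, window, cutoff = 0.001) {
  if (is.null(window)) return(0)
  p <- 10^(-phred / 10)
  sum(cutoff - p[window[[1]]:window[[2]]])
}

# exhaustive-search oracle for mixed-peak trimming: enumerate all
# (start, end) pairs for each boundary-run length n, longest (leftmost)
# candidate per n, fraction gate, smallest qualifying n
mixed_oracle <- function(trace, params = trim_params()) {
  hmat <- cbind(trace$height_A, trace$height_C, trace$height_G,
                trace$height_T)
  total <- rowSums(hmat)
  ok <- ifelse(total > 0, apply(hmat, 1, max) / total, 0) >
    params$primary_ratio_threshold
  L <- length(ok)
  prefix <- c(0, cumsum(ok))
  nm <- function(s, e) prefix[e + 1] - prefix[s]
  for (n in params$boundary_run_min:params$boundary_run_max) {
    best <- NULL
    for (s in seq_len(L)) {
      if (s + n - 1 > L || nm(s, s + n - 1) != n) next
      ends <- seq(s + n - 1, L)
      valid <- ends[vapply(ends, function(e) nm(e - n + 1, e) == n,
                           logical(1))]
      if (length(valid) == 0) next
      e <- max(valid)
      if (is.null(best) || e - s + 1 > best[[2]] - best[[1]] + 1) {
        best <- c(s, e)
      }
    }
    if (!is.null(best) &&
        nm(best[[1]], best[[2]]) / (best[[2]] - best[[1]] + 1) >=
          params$non_mixed_fraction_threshold) {
      return(best)
    }
  }
  NULL
}

# mutate a sequence with substitution noise, keeping the alphabet
mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  chars[hit] <- vapply(chars[hit], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  paste(chars, collapse = "")
}

# a small fully-worked direct-BSP experiment on disk (memoised per session)
demo_experiment <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), "bspmeth-demo-exp")
    ref <- with_seed_helper(11, random_reference(260, 6000))
    exp <- simulate_experiment(
      ref,
      group_methylation = list(low = 5, high = 90),
      replicates = 3, outdir = dir, seed = 101)
    cache <<- list(dir = dir, ref = ref, exp = exp)
    cache
  }
})

with_seed_helper <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
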