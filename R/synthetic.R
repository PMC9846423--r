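#' Synthetic chromatogram parameters
#'
#' The simulator embodies the measurement model the peak-height ratio
#' inverts: at a CpG cytosine the C and T dye signals (G and A in a
#' reverse read) are proportional to the methylated and unmethylated
#' molecule fractions; at non-CpG cytosines the converted/unconverted
#' signal split follows the bisulfite conversion efficiency; every other
#' position shows one dominant peak. Additive Gaussian noise on the
#' heights mimics dye-signal noise, and both read extremities are degraded
#' (mixed peaks, low Phred) the way real Sanger reads are.
#'
#' @param ref A `bsp_reference`.
#' @param true_methylation Percentage per CpG site, ordered by genomic
#'   coordinate (recycled if length 1).
#' @param conversion_efficiency Fraction of non-CpG cytosines actually
#'   converted (default 0.99).
#' @param direction `"forward"` or `"reverse"`.
#' @param peak_scale Height of a clean peak (default 1000).
#' @param noise_sd Gaussian noise SD as a fraction of `peak_scale`
#'   (default 0.02).
#' @param bad_end_length Degraded bases at each extremity (default 15).
#' @param phred_good,phred_bad Phred scores of clean and degraded bases
#'   (defaults 50 and 8).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A `bsp_sim_params` list.
#' @export
sim_params <- function(ref, true_methylation = 50,
                       conversion_efficiency = 0.99,
                       direction = c("forward", "reverse"),
                       peak_scale = 1000, noise_sd = 0.02,
                       bad_end_length = 15L, phred_good = 50L,
                       phred_bad = 8L, seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(ref, "bsp_reference"),
            all(true_methylation >= 0), all(true_methylation <= 100),
            conversion_efficiency >= 0, conversion_efficiency <= 1,
            noise_sd >= 0)
  structure(
    list(ref = ref, true_methylation = true_methylation,
         conversion_efficiency = conversion_efficiency,
         direction = direction, peak_scale = peak_scale,
         noise_sd = noise_sd, bad_end_length = as.integer(bad_end_length),
         phred_good = as.integer(phred_good),
         phred_bad = as.integer(phred_bad), seed = seed),
    class = "bsp_sim_params")
}

#' Simulate one chromatogram trace
#'
#' Builds the bisulfite-converted template for the requested direction and
#' emits a full-length read over it with ground-truth labels: per-CpG
#' methylation splits of the C/T (or G/A) peaks, conversion-efficiency
#' splits at control cytosines, one dominant peak elsewhere, additive
#' Gaussian noise clipped at zero, and degraded extremities. Deterministic
#' for a given seed.
#'
#' @param params A [sim_params()] list.
#' @return A list with `trace` (a [bsp_trace]) and `truth` (a tibble with
#'   `cpg_index`, `c_coordinate`, `true_methylation`, plus the conversion
#'   efficiency as an attribute).
#' @export
simulate_trace <- function(params) {
  stopifnot(inherits(params, "bsp_sim_params"))
  with_seed(params$seed, simulate_trace_impl(params))
}

simulate_trace_impl <- function(params) {
  templates <- bisulfite_convert(params$ref)
  L <- templates$length

  # CpG sites in coordinate order, as the methylation table reports them
  sites <- tibble(
    sense_pos = templates$cpg_positions_sense,
    c_coordinate = vapply(templates$cpg_positions_sense, function(p) {
      as.integer(sense_to_genomic(templates, p))
    }, integer(1))) |>
    arrange(.data$c_coordinate) |>
    mutate(cpg_index = row_number(),
           true_methylation = rep_len(params$true_methylation, n()))

  forward <- params$direction == "forward"
  tmpl <- if (forward) templates$sense else templates$antisense
  tmpl_chars <- strsplit(tmpl, "")[[1]]
  site_pos <- if (forward) {
    sites$sense_pos
  } else {
    mirror_position(templates, sites$sense_pos)
  }
  control_pos <- if (forward) {
    templates$non_cpg_c_positions_sense
  } else {
    mirror_position(templates, templates$non_cpg_c_positions_sense)
  }

  scale <- params$peak_scale
  heights <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, BASES))
  plain <- setdiff(seq_len(L), c(site_pos, control_pos))
  for (i in plain) {
    b <- tmpl_chars[[i]]
    if (b %in% BASES) {
      heights[i, b] <- scale
    } else {
      heights[i, ] <- scale / 4  # N: no dominant dye
    }
  }
  hi <- if (forward) c("C", "T") else c("G", "A")  # methylated, unmethylated
  m_frac <- sites$true_methylation / 100
  heights[site_pos, hi[[1]]] <- scale * m_frac
  heights[site_pos, hi[[2]]] <- scale * (1 - m_frac)
  conv <- if (forward) c("T", "C") else c("A", "G")  # converted, residual
  heights[control_pos, conv[[1]]] <- scale * params$conversion_efficiency
  heights[control_pos, conv[[2]]] <- scale *
    (1 - params$conversion_efficiency)

  heights <- heights + rnorm(L * 4, 0, params$noise_sd * scale)

  bad <- params$bad_end_length
  bad_idx <- if (bad > 0) {
    unique(c(seq_len(min(bad, L)), seq(max(1L, L - bad + 1L), L)))
  } else {
    integer()
  }
  if (bad > 0) {
    # off-scale mixed signal: four channels of comparable height
    heights[bad_idx, ] <- scale * matrix(runif(length(bad_idx) * 4,
                                               0.25, 0.6),
                                         ncol = 4)
  }
  heights <- round(pmax(heights, 0))

  phred <- rep(params$phred_good, L)
  phred[bad_idx] <- params$phred_bad
  called <- BASES[max.col(heights, ties.method = "first")]

  truth <- sites |> select("cpg_index", "c_coordinate", "true_methylation")
  attr(truth, "conversion_efficiency") <- params$conversion_efficiency
  list(trace = bsp_trace(called, phred, heights,
                         read_id = paste0("sim_", params$direction)),
       truth = truth)
}

#' Simulate a whole BSP experiment on disk
#'
#' Generates forward and reverse chromatograms for every sample of a
#' groups-by-replicates layout, writes them as `.ab1` files via
#' [write_abif()], plus a batch manifest consumable by [cmd_batch()] /
#' [cmd_individual()], the reference FASTA, and a ground-truth table for
#' recovery tests. For cloning layouts, each clone's per-CpG methylation
#' is drawn as 0 or 100 from a Bernoulli draw of the group's methylation
#' proportion.
#'
#' @param ref A `bsp_reference`.
#' @param group_methylation Named list: one methylation vector (percent
#'   per CpG, coordinate order) per group. For cloning layouts the values
#'   are Bernoulli proportions (in percent) per CpG.
#' @param replicates Samples (or clones) per group.
#' @param outdir Directory to write into.
#' @param experiment_type `"direct"` or `"cloning"`.
#' @param collection Collection label for all samples.
#' @param sequence_name Sequence name; default: the reference's name.
#' @param base_params A [sim_params()] to take noise/efficiency settings
#'   from (its methylation/direction/seed are overridden per read).
#' @param seed Integer master seed; per-read seeds derive from it.
#' @return A list with `manifest` (tibble, one row per sample, also
#'   written to `manifest.csv`), `truth` (tibble, written to
#'   `truth.csv`) and `fasta` (reference path).
#' @export
simulate_experiment <- function(ref, group_methylation, replicates = 3,
                                outdir,
                                experiment_type = c("direct", "cloning"),
                                collection = "simulated",
                                sequence_name = NULL,
                                base_params = NULL, seed = 1L) {
  experiment_type <- match.arg(experiment_type)
  stopifnot(inherits(ref, "bsp_reference"), length(group_methylation) >= 1,
            !is.null(names(group_methylation)))
  sequence_name <- sequence_name %||% ref$name
  base_params <- base_params %||% sim_params(ref)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  fasta <- file.path(outdir, paste0(sequence_name, ".fasta"))
  writeLines(c(sprintf(">%s %s:%d-%d %s", sequence_name, sequence_name,
                       ref$seq_start, ref$seq_end,
                       if (ref$amplified_strand == "plus") "+" else "-"),
               ref$sequence), fasta)

  n_sites <- length(bisulfite_convert(ref)$cpg_positions_sense)
  manifest <- list()
  truth <- list()
  idx <- 0L
  for (g in names(group_methylation)) {
    m_group <- rep_len(group_methylation[[g]], n_sites)
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      sample_seed <- seed + 1000L * idx
      m_sample <- if (experiment_type == "cloning") {
        100 * with_seed(sample_seed,
                        rbinom(n_sites, 1L, m_group / 100))
      } else {
        m_group
      }
      paths <- vapply(c("forward", "reverse"), function(d) {
        p <- sim_params(ref, m_sample,
                        conversion_efficiency =
                          base_params$conversion_efficiency,
                        direction = d,
                        peak_scale = base_params$peak_scale,
                        noise_sd = base_params$noise_sd,
                        bad_end_length = base_params$bad_end_length,
                        phred_good = base_params$phred_good,
                        phred_bad = base_params$phred_bad,
                        seed = sample_seed + (d == "reverse"))
        sim <- simulate_trace(p)
        path <- file.path(outdir, sprintf("%s_%s_%d_%s.ab1", collection,
                                          g, r, substr(d, 1, 3)))
        write_abif(sim$trace, path)
        path
      }, character(1))
      manifest[[idx]] <- tibble(
        analysis = "individual", fasta = fasta,
        seq_start = ref$seq_start, seq_end = ref$seq_end,
        strand = ref$amplified_strand,
        ab1_1 = paths[[1]], ab1_2 = paths[[2]],
        sequence_name = sequence_name, collection = collection,
        group = g, replicate = as.character(r), type = experiment_type)
      truth[[idx]] <- tibble(
        group = g, replicate = as.character(r),
        cpg_index = seq_len(n_sites),
        true_methylation = m_sample)
    }
  }
  manifest <- bind_rows(manifest)
  truth <- bind_rows(truth)
  readr::write_csv(manifest, file.path(outdir, "manifest.csv"))
  readr::write_csv(truth, file.path(outdir, "truth.csv"))
  list(manifest = manifest, truth = truth, fasta = fasta)
}
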