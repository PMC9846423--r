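# bspmeth

Quantify region-specific CpG methylation from Sanger bisulfite-sequencing-PCR
(BSP) chromatograms.

## The problem

Bisulfite treatment deaminates unmethylated cytosines to uracil (read as T
after PCR) while 5-methylcytosines stay C. After PCR amplification of the
converted region and Sanger sequencing, methylation at each CpG site is
written into the chromatogram as the ratio of the C and T dye signals:

- direct-BSP sequences the PCR product pool, so a CpG with 70% methylated
  molecules shows a C peak at ~70% of the combined C+T signal;
- cloning-BSP sequences individual clones, so each CpG reads near 0 or 100
  and the proportion of methylated clones estimates the methylation level.

Reading those peak heights by hand is slow and error-prone, and none of the
classic cloning-oriented tools (QUMA, BiQ Analyzer, BISMA) uses the four-dye
signal at all. `bspmeth` automates the whole analysis from raw `.ab1` trace
files for both BSP flavours, with quality control at every step.

## The method

For each sample (1-2 unlabeled reads, forward and/or reverse):

1. **ABIF parsing** — called bases, Phred qualities and the four dye-signal
   heights at each base-call peak are read from the `.ab1` file, honouring
   the file's channel-order record.
2. **Trimming** — a modified Mott algorithm on error probabilities
   `p = 10^(-Q/10)` (cutoff 0.001, the Phred-30 point) is intersected with a
   mixed-peak criterion on the primary peak ratio
   `max(peak) / (peakA+peakC+peakG+peakT)` (non-mixed when > 0.75); the
   final window must be ≥ 30 bp, mean Q ≥ 30, ≥ 75% non-mixed.
3. **In-silico conversion and alignment** — every non-CpG C of the amplified
   strand becomes T, giving the sense template and its reverse complement;
   the read is Smith–Waterman-aligned to both and the direction is
   auto-detected. A gap-corrected position map links template, read and
   genomic coordinates (ungapped case:
   `read_pos = template_pos − s_start + p_start`).
4. **Quality control** — per-read bisulfite conversion rate at non-CpG
   cytosines, `peakT/(peakC+peakT)` forward or `peakA/(peakG+peakA)`
   reverse; the read is used only if aligned length ≥ 30 bp, identity ≥ 75%
   and mean conversion ≥ 0.9.
5. **Methylation** — at each CpG cytosine,
   `meth% = peakC/(peakC+peakT) × 100` (forward) or
   `peakG/(peakG+peakA) × 100` (reverse), combined across directions as
   mean ± SD. Peak heights are used exactly as stored: no normalization.

The grouped stage gathers per-sample tables, renumbers CpGs over the covered
sites, calls clone statuses (≤ 20 unmethylated, ≥ 80 methylated, otherwise
unavailable, with a > 20%-partial mixed-clone rule), computes per-CpG Welch
t-tests and Kruskal–Wallis tests plus per-sample-mean contrasts, and renders
lollipop, profile, boxplot and genomic-heatmap figures.

A synthetic chromatogram generator with known ground truth
(`simulate_trace()`, `simulate_experiment()`) makes the entire pipeline
testable end-to-end.

## Worked example

```r
library(bspmeth)

set.seed(5)
seq <- paste(sample(c("A","C","G","T"), 260, TRUE), collapse = "")
ref <- reference_region(seq, 6000, 6259, "plus", "PROM1")

truth <- c(0, 20, 40, 60, 80, 100)  # recycled over the region's CpGs
fwd <- simulate_trace(sim_params(ref, truth, seed = 1))
rev <- simulate_trace(sim_params(ref, truth, direction = "reverse", seed = 2))

s <- analyze_sample(sample_key("PROM1", "lineA", "treated", "1"),
                    ref, list(fwd$trace, rev$trace))
s
#> <bsp_sample> PROM1 | lineA / treated / 1 (direct)
#>   20 CpG site(s), 16 with methylation data

tidy(s)[, c("cpg_index", "c_coordinate", "meth_fwd", "meth_rev",
            "meth_mean", "meth_sd", "n_reads")]
#>    cpg_index c_coordinate meth_fwd meth_rev meth_mean meth_sd n_reads
#>  4         4         6030     59.3     57.7    58.5     1.10        2
#>  5         5         6079     80.3     82.2    81.2     1.35        2
#>  6         6         6088     99.5     98.3    98.9     0.856       2
#>  7         7         6113      0       1.36     0.682   0.964       2
#>  ...
```

Each row is one CpG: `meth_fwd`/`meth_rev` are the per-direction peak-height
percentages, `meth_mean`/`meth_sd` their combination, and `n_reads` how many
directions covered the site (the first/last sites fall in the trimmed read
extremities, hence `NA`). The read-level QC confirms why the data are
usable:

```r
tidy(s$qc_fwd)
#>   direction aligned_length identity_pct mean_conversion_rate n_control_sites pass
#> 1 forward              230          100                0.984              35 TRUE
```

A whole two-group experiment (3 replicates each, low vs high methylation)
runs through `simulate_experiment()` + `cmd_batch()` + `cmd_grouped()`, or
from a shell via the thin wrapper `inst/cli/bspmeth.R`. The overall group
contrast it printed for that simulation:

```
   group1    group2 n1 n2    mean1  mean2      p_value symbol
  treated untreated  3  3 85.15646 9.8775 1.986641e-11   ****
```

i.e. the treated group's per-sample mean methylation (85.2%) differs from
the untreated one (9.9%) with `****` significance (p ≤ 0.0001).

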