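---
title: "Peak-height methylation from BSP chromatograms: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak-height methylation from BSP chromatograms: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bspmeth)
```

## The measurement model

Bisulfite sequencing PCR (BSP) turns CpG methylation into a sequence
difference: unmethylated cytosines deaminate to uracil and are read as T
after PCR, while 5-methylcytosines remain C. In a direct-BSP chromatogram
the sequenced material is a *mixture* of molecules, so a CpG cytosine
appears as two superimposed dye peaks, C and T, whose heights we take as
proportional to the methylated and unmethylated molecule fractions. That
linearity is the model everything else inverts:

$$\mathrm{meth\%} = \frac{peakC}{peakC + peakT} \times 100
\quad\text{(forward read)},\qquad
\mathrm{meth\%} = \frac{peakG}{peakG + peakA} \times 100
\quad\text{(reverse read)}.$$

The reverse read sequences the complementary strand, where the CpG
cytosine's partner guanine carries the same information as a G/A mixture.
Peak heights are used exactly as the basecaller stored them: modern
basecallers no longer overscale the minority base, so no renormalization is
applied — any rescaling common to the two relevant channels cancels in the
ratio anyway (the ratio is scale-invariant, which the test suite checks).

Cloning-BSP is analysed with the identical machinery; because each clone is
a single molecule its per-CpG levels concentrate near 0 or 100 and are
discretised into statuses downstream.

## Pipeline stages and their parameters

### ABIF parsing

Traces come from `.ab1` (ABIF) files: big-endian tagged directories from
which we take base calls (`PBAS`), per-base qualities (`PCON`), peak
locations (`PLOC`) and the four analyzed signal channels (`DATA` 9–12).
Two choices deserve note:

* the channel-to-base assignment always comes from the file's field-order
  record (`FWO_`), never from a conventional "GATC" assumption — the tests
  write the same trace under two different channel orders and require
  identical decoded matrices;
* the *peak height at a called base* is the channel value at that base's
  peak-location index, not a windowed maximum — deterministic, and what
  trace viewers display;
* edited fields (tag number 1) are preferred over basecaller originals
  (tag 2), the sequencer convention;
* the analyzed (processed) channels are used rather than raw ones, as these
  are what viewers show and what manual peak-reading would use.

`write_abif()` emits minimal but valid ABIF files (16-bit heights, one
trace point per base), which makes the parser round-trip testable and the
synthetic data real files.

### Trimming

Read extremities are unreliable. Two independent windows are intersected:

| parameter | default | meaning |
|---|---|---|
| `error_prob_cutoff` | 0.001 | Mott cutoff on \(p = 10^{-Q/10}\); 0.001 is exactly Phred 30 |
| `primary_ratio_threshold` | 0.75 | base is *non-mixed* when \(\max(h)/\sum h\) is strictly above |
| `non_mixed_fraction_threshold` | 0.75 | minimum non-mixed fraction of a candidate window |
| `boundary_run_min/max` | 3 / 15 | boundary-run lengths *n* tried |
| `min_length` | 30 bp | final-window gate |
| `min_mean_phred` | 30 | final-window gate |

The Mott trimmer is the reset-to-zero (M1, Kadane-style) variant: running
sums of `cutoff − p` clipped at zero; the reported window is the segment
ending at the running-score maximum. This segment maximises the window sum
of `cutoff − p`, and the tests hold it to an exhaustive \(O(L^2)\)
window search.

The mixed-peak trimmer labels bases non-mixed by the primary peak ratio,
then for each boundary-run length `n` takes the longest window whose first
and last `n` bases are all non-mixed; among the per-`n` candidates meeting
the non-mixed-fraction threshold, the smallest `n` wins (ties: longer
window, then leftmost). Three deliberate resolutions of ambiguity: a ratio
exactly at 0.75 counts as mixed (strict "above the threshold"); the same
`n` is required at both boundaries; and "minimum of consecutive non-mixed
positions" is read as *smallest qualifying `n`*, which preserves the most
sequence while meeting the quality bar. The `min_mean_phred` gate needs a
number the trimming description never prints; 30 is used because Phred 30
is the only quality anchor the method states (it anchors the Mott cutoff
twice). The printed cutoff "0.001%" contradicts its own Q30 equivalence
(\(Q = -10\log_{10} P\) gives \(P = 0.001\) at Q30); the percent sign is
treated as a typo and 0.001 used.

### Alignment and direction detection

Reads are unlabeled, so the trimmed sequence is Smith–Waterman-aligned
(match +2, mismatch −1, gap open −5, gap extend −2 — no scheme is
prescribed by the method; these favour the long contiguous alignments
expected of high-identity Sanger reads) against both the converted sense
template and its reverse complement. The longer aligned span wins, with
two guards: a valid alignment (length ≥ 30, identity ≥ 75%) always beats
an invalid one, so a spurious gapped alignment to the wrong template
cannot win on raw length; exact ties fall back to score, then sense.

Identity is computed over aligned non-gap columns, *excluding* CpG columns:
at those positions the read base legitimately depends on methylation (C/T
forward, G/A reverse), and counting those mismatches would let the
biological signal fail the technical QC. `N` never counts as a match.

The position map is built by walking alignment columns; template positions
inside read gaps map to nothing and are skipped downstream rather than
scored. For ungapped alignments the map reduces to
`read_pos = template_pos − s_start + p_start`.

When the minus strand was amplified, the reference is reverse-complemented
first and all outputs are reported in plus-strand genomic coordinates, so
results stay comparable across strand choices; the reported cytosine
coordinate is that of the measured (amplified-strand) cytosine.

### Quality control

Three inclusive (`>=`) gates validate a read: aligned length ≥ 30 bp,
identity ≥ 75%, mean bisulfite conversion rate ≥ 0.9. "Higher than" in
prose is ambiguous at the boundary; `>=` keeps the printed defaults
attainable exactly at threshold, and the acceptance tests cover both sides
of each boundary. The conversion rate is measured at every non-CpG
cytosine of the unconverted amplified strand (where complete conversion
leaves only T/A signal); sites falling in alignment gaps or with zero
denominator are skipped, not scored zero, and the mean is unweighted
across usable sites. A read with no usable control site fails with its own
gate rather than passing vacuously.

### Combination and tables

Per CpG, the forward and reverse percentages are combined as their mean;
the standard deviation uses the sample (n−1) divisor — over two values
that is \(|x_f - x_r|/\sqrt{2}\) — chosen over the population divisor to
match how the downstream group tests treat observations. Percentages are
kept at full precision internally and rendered to two decimals in the
frozen per-sample CSV schema, which is the sole contract between the
individual and grouped stages.

### Grouped analysis

CpG ordinals are reset over the union of sites covered by at least one
sample, ordered by coordinate (a strictly increasing ordinal-to-coordinate
map, tested). Clone statuses use inclusive bands — ≤ 20 unmethylated,
≥ 80 methylated — with strictly-between values partial; a clone whose
partial fraction strictly exceeds 0.20 is voided entirely as a potential
clone mixture. Group proportions for cloning data are methylated over
(methylated + unmethylated), excluding unavailable calls.

The "Student's t-test" of the comparative layer is implemented as Welch's
unequal-variance variant (safe under variance heterogeneity; a pooled
switch exists), with Kruskal–Wallis across all groups per CpG; the
observations are per-sample `meth_mean` values. Zero-variance inputs
return p = 1 (identical means) or `NA` rather than infinite statistics;
groups with fewer than two observations yield `NA`, recorded not raised.
Raw p-values are annotated with the conventional symbols
(\*, \*\*, \*\*\*, \*\*\*\* at 0.05/0.01/0.001/0.0001); no multiple-testing
correction by default, with an optional Benjamini–Hochberg switch.
The "by cluster" sample ordering, unspecified in the method, uses
average-linkage hierarchical clustering on Euclidean distances of the
per-sample methylation profiles (missing values imputed at 50 for the
distance only).

## The synthetic-data generator

`simulate_trace()` emulates exactly the features the pipeline measures:

* per-CpG C/T (or G/A) peak splits linear in the methylation fraction —
  the model's core assumption, stated above;
* converted/residual splits at non-CpG cytosines following the bisulfite
  conversion efficiency (default 0.99, a typical successful reaction);
* one dominant peak (height 1000) elsewhere, additive Gaussian noise with
  SD 2% of peak scale clipped at zero (dye-signal noise acts on heights,
  not on ratios), heights rounded to the 16-bit integers ABIF stores;
* degraded extremities: 15 bases per end of near-uniform four-channel
  signal at Phred 8, so that trimming has real work to do;
* deterministic output for a given seed.

What it does **not** emulate: dye-dependent mobility shifts, peak-width
variation and local baseline drift of real chromatograms, context-dependent
incorporation biases, or primer sequences flanking the amplicon. Passing
the recovery tests therefore shows the *computational* chain is unbiased
and correctly plumbed; it does not certify accuracy on instruments whose
dye chemistry violates the linearity assumption.

`simulate_experiment()` writes whole groups-by-replicates layouts as real
`.ab1` files plus a batch manifest and truth table; cloning layouts draw
each clone's CpG pattern as Bernoulli statuses of the group proportion.

## Test problem sizes

The suite exercises references of 120–1000 bp (typical BSP amplicons are
150–500 bp), reads up to 400 bases, 500 random reads for the
trimming-versus-brute-force equivalence, an 11-point methylation grid
(0–100 by 10) for end-to-end recovery, and 2–3 groups × 3 replicates for
the comparative layer — sizes at which every property is checked
exhaustively in seconds. Recovery is asserted on the sample's recovered
methylation level per grid point (and the mean absolute per-site error),
the parameter the grouped stage actually consumes; individual site
estimates carry ~1-point noise SD under the default signal model, which
the per-sample combination averages out.

## Known limitations

* Only CpG context is analysed; CHG/CHH (plant) contexts are out of scope.
* One read per direction is used per sample; a second read of the same
  direction is reported but not merged.
* Batch manifests are CSV; spreadsheet files should be exported to CSV
  first.
* The ABIF writer emits the minimal field set the analysis needs; files it
  writes are valid for this package and for readers that honour the
  directory, but contain no instrument metadata.
* Methylation estimates inherit the linear peak-height assumption; strong
  dye imbalances in older chemistries would bias them, and no
  normalization layer is offered deliberately.
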