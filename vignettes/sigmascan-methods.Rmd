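---
title: "sigmascan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sigmascan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmascan)
```

`sigmascan` turns bacterial ChIP-seq coverage into a sigma-factor binding
motif and genome-wide binding-site predictions. This vignette explains the
models behind each stage, the parameters that matter, what the simulator
does and does not emulate, and the numerical choices we made where the
design was open.

## Coverage model and peak calling

ChIP coverage has a long right tail: a handful of strongly enriched bases
inflate the mean, so all tracks are scaled by their **median** per-base
coverage, computed over non-excluded bases only. Exclusion intervals
(e.g. a locus also present on an expression plasmid, whose reads pile up
on the chromosomal copy) are zeroed and flagged *before* the median is
taken — the excluded interval would otherwise bias the very scale used to
call it. Normalization is idempotent by contract: renormalizing a
normalized track is an error, not a silent no-op.

A base is peak territory iff

* normalized IP coverage `> ip_threshold` (default 4), **and**
* normalized coverage `< control_threshold` (default 3) in **every**
  provided control (input and mock IP alike — the strictest reading).

Maximal runs of qualifying bases become peaks, with two structural
parameters:

* `min_width` (default 1 at the function level): the literal predicate
  makes no width demand.
* `merge_gap` (default 0 at the function level; **30 bp in the pipeline
  default**). With count noise, coverage near the threshold crossing
  fluctuates — at an expected coverage of ~45 against a threshold of 40,
  a quarter of bases dip below — so a single binding event fragments into
  several runs. Merging runs separated by up to about half a fragment
  length restores one interval per event without ever bridging distinct
  sites, which in bacterial regulons are separated by hundreds of bases
  to kilobases. Users reproducing the literal per-base rule can set it
  back to 0.

The summit is the leftmost position attaining the run's maximum (ties
broken leftmost for determinism).

### The triangularity screen

Published analyses of this kind inspect each candidate visually for the
triangular shape of a localized ChIP peak. We automate this as the
Pearson correlation between the observed coverage on
`summit ± shape_flank` and an ideal isoceles triangle peaking at the
summit; a peak passes at `triangularity_min` (default 0.8). The score is
scale- and offset-free, so it needs no knowledge of depth or background.
`shape_flank` defaults to 60 bp: the comparison window should span the
peak footprint (roughly fragment length plus displacement spread). For an
ideal Laplace-displacement pileup the correlation with a triangle is
maximal (≈0.99) near this flank; much narrower windows see only the blunt
top, much wider ones mostly background. A constant window has no defined
correlation and is an error at the function level; inside `call_peaks` a
summit too close to a chromosome end yields `NA` and fails the screen
conservatively.

Site windows are the `window_width` (default 60) bases centered on the
summit, `[summit − ⌊w/2⌋, summit − ⌊w/2⌋ + w)` in 0-based half-open
coordinates — for even widths the extra base sits right of the summit.
Windows overrunning a contig end are dropped with a warning.

## Motif discovery: ZOOPS expectation-maximization

Windows are modelled with the "zero or one occurrence per sequence"
mixture used by MEME: sequence *i* of length `L_i` either contains
exactly one motif occurrence (probability `γ`, location uniform over the
`L_i − w + 1` offsets) or is pure background (a 0-order model with the
aggregate composition of the inputs). ZOOPS, rather than
one-per-sequence, is the right family here because one window in a batch
may carry no recoverable site. EM alternates posterior site-location
assignment with matrix and `γ` re-estimation.

Numerical choices:

* **Initialization** is data-driven and deterministic: every distinct
  w-mer in the windows becomes a candidate start (its letters at
  probability 0.7, the rest uniform), candidates are ranked by their
  one-step ZOOPS likelihood at `γ = 0.5`, and EM runs from the top
  `n_starts` (default 5). Because planted or real sites are themselves
  among the candidate words, the search starts near the truth whenever a
  motif is present.
* **The M-step is the exact maximizer** (no pseudocount), which
  guarantees the observed-data log likelihood is non-decreasing every
  iteration — an invariant the test suite asserts. Probabilities are
  floored at 1e-12 purely to keep logs finite. A smoothed M-step is a MAP
  step whose raw likelihood can genuinely decrease, which is why the
  default is exact.
* **The reported matrix** is the Dirichlet posterior mean
  (`report_pseudocount = 0.25` added to the converged expected counts).
  With a dozen contributing sites the maximum-likelihood matrix contains
  sampling zeros; downstream log-odds scoring would turn those into
  essentially minus-infinite penalties for what is merely an unobserved
  letter. Posterior-mean reporting is standard practice in this tool
  family; `report_pseudocount = 0` returns the raw ML matrix.
* **Forward strand only.** The windows this stage is meant for are short
  summit-centered extracts; we do not model the site appearing reverse
  complemented within a window. When sites sit on random strands (as in
  the full simulated pipeline) EM locks onto one orientation's subset —
  the scanning stage searches both strands, so downstream predictions are
  unaffected, but the discovery-stage posterior covers only the matching
  windows. This is the main gap relative to MEME.
* Convergence: the fit stops when the likelihood gain drops below `tol`
  (default 1e-6) or at `max_iter` (200), returning the best model so far
  with a warning in the latter case. Width is a parameter (no automatic
  width search).

## Information content and masking

Per-column information is `R_seq(i) = 2 + Σ_s p_is log2 p_is` bits
(2 minus the column entropy, i.e. the per-position height of a sequence
logo under a uniform background), with `0·log2 0 = 0`. No small-sample
correction is applied by default — the correction is available
(`small_sample_correction = TRUE`, first-order bias `3/(2 ln2 · n)`,
about 0.16 bits at n = 13) but which convention a given published value
used is rarely stated, so the uncorrected definition is the default and
the choice is explicit.

Masking replaces every column with `R_seq ≤ r_threshold` (default 1 bit)
by the background letter frequencies **of the query sequence about to be
scanned**. A masked column then satisfies `p_is = b_s` exactly, so every
log-odds cell in it is `log2((b_s+ε)/(b_s+ε)) = 0`: masked positions
contribute exactly nothing to any window's score, which is the point —
weak, undersampled columns must not inject spurious preferences into a
genome scan. Unmasked columns are left bit-identical.

## Scanning: exact p-values and FDR

The scoring matrix is `log2((p_is + ε)/(b_s + ε))` with smoothing
`ε = 1e-4` added to both numerator and denominator (zero cells with
`ε = 0` are an error, not `−Inf`). Scores are discretized to integer
multiples of `step = 0.001` bits (round-half-even); the null distribution
of the total score under the 0-order background is the exact convolution
of the per-position distributions, computed by dynamic programming.
Window scores are computed from the *same* discretized cells, so the
p-value of a score is exact on the discretized axis; the discretization
affects only the score coordinate, by at most `w·step/2` bits. The test
suite checks the DP against brute-force enumeration of all `4^w` words
for small widths, exactly.

Both strands are scanned by default (the minus strand via the
reverse-complemented matrix, reported in forward coordinates); windows
containing ambiguity codes are skipped; scanning is case-insensitive.
Hits are reported at `p ≤ p_threshold` (default 1e-4, the conventional
default of this tool family). All overlapping hits are reported — no
non-overlap pruning.

q-values are Benjamini–Hochberg, computed with the family size equal to
**all windows scored in the run** (not just reported hits), via the
step-up formula; the reporting cut is `q ≤ q_threshold` (default 0.6,
a deliberately permissive screen for candidate follow-up) and the full
unfiltered table is always produced alongside. The background for
scanning defaults to each query's own composition, matching the masking
rule; a uniform-background option exists for comparison.

Promoters are the `promoter_len` (default 100) bases immediately upstream
of each annotated CDS: `[s − 100, s)` forward of a plus-strand start
`s`, and the reverse complement of `[e, e + 100)` for a minus-strand end
`e`, truncated (and flagged) at contig edges.

## The simulator

The synthetic-regulon generator emulates exactly the data structure the
analysis assumes:

* a uniform-composition random genome (`gc_fraction`, default 0.5);
* `n_sites` (default 12) sites sampled column-independently from a motif
  (default: width 20, consensus letter at 0.9 — mean column information
  ≈1.37 bits, a well-determined sigma-factor-like site), planted on
  uniformly random strands (minus-strand sites as reverse complements) at
  uniform positions with a `min_separation` of 1 kb — regulon loci are
  well separated genome-wide, and separation beyond the peak footprint
  means one peak per site;
* CDS annotations, some placed so that a planted site falls in their
  100 bp promoter (`sites_in_promoters`, default 3), the rest well away
  from any site;
* coverage: the control track is Poisson at `background_depth` (default
  10); the IP track is Poisson around a deterministic expected pileup —
  background plus, per site, `enrichment` (default 200) fragments of
  `fragment_length` (50) bp whose midpoints are Laplace-displaced with
  scale `peak_spread` (25) bp. The Laplace choice gives the sharply
  peaked, near-triangular pileups the shape screen expects; the analytic
  overlap probability `F((x−c)+⌊l/2⌋) − F((x−c)+⌊l/2⌋−l)` makes the
  expected pileup maximal at the site center and monotonically decaying.
  With the defaults the expected normalized coverage at a site center is
  ≈13, comfortably above the peak threshold.

Everything is a pure function of the configuration and seed, and the
bundle writer emits FASTA / bedGraph / GFF3 / TSV that round-trip through
the package readers identically.

**What the simulator does not emulate** — and hence what passing recovery
tests do not show about real data: read-level artifacts (mapping
ambiguity, duplicates, strand bimodality of single-end reads), coverage
autocorrelation beyond the fragment footprint, non-uniform genomic
background (GC bias, copy-number gradients near origins), overdispersed
counts beyond Poisson, and closely spaced or overlapping binding sites.
The Poisson/Laplace choices are stand-ins for an empirical noise model
the source data do not pin down, and both are configurable.

## Problem sizes and determinism

The shipped tests run the study at desk scale: a 100 kb genome with 12
planted sites for peak recovery (3 seeds), 13×60 bp window sets for motif
recovery (20 seeds), widths ≤ 6 for exhaustive p-value enumeration (100
matrices), and 10^5-base tracks for the peak-caller oracle (50 pairs).
These sizes make every recovery claim checkable in minutes while keeping
the statistical conditions (depth, enrichment, information content)
fixed at the values stated above. All stochastic stages are seeded;
reruns with the same configuration are bit-identical for deterministic
stages and seed-pinned for stochastic ones.

## Known limitations

* Coordinates are single-chromosome per track; multi-contig genomes are
  handled per contig.
* The minimal MEME writer emits probabilities at 6 decimal places with
  largest-remainder rounding (columns sum to exactly 1.000000 on disk);
  round trips are exact to one unit in the sixth decimal, not beyond.
* Discovery does not search over motif widths or model reverse-complement
  occurrences within windows (see above).
* q-values are plain Benjamini–Hochberg; tools in the FIMO family apply
  additional interpolation, so values can differ slightly in the far
  tail.
* The peak caller is a thresholding rule, not a model-based test; it
  presumes the normalization and control structure described here and
  provides no enrichment p-values.
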