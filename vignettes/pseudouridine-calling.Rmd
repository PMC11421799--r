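---
title: "Calling pseudouridine sites from RT-stop profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling pseudouridine sites from RT-stop profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psistop)
```

## The measurement model

Pseudouridine (Ψ) is detected chemically: the carbodiimide CMC forms an
adduct on Ψ that survives alkaline stripping and blocks reverse
transcriptase, so cDNA synthesis terminates one nucleotide 3′ of the
modified uridine. In a CMC-treated sequencing library the read 5′ ends
therefore pile up at position *u + 1* (transcript orientation) for a
modified U at *u*, while a mock-treated library from the same RNA shows no
such pileup. Everything in psistop starts from this +1 offset convention: the
statistic is evaluated at the expected pileup position, and sites are
reported at the U itself. The offset is a single constant shared between the
simulator and the caller, and a simulate→call round trip must recover the
planted U positions exactly — this is asserted in the test suite.

Inputs are per-position, per-strand counts of read 5′ ends (bedGraph or
variableStep wiggle), a genome FASTA, gene annotations (GFF3 subset or
constructed in code), and transcript 5′/3′ end positions from end-enriched
RNA sequencing. Internally all coordinates are 0-based half-open;
conversion to the 1-based wiggle convention happens only at I/O.

## The winsorized Z-score

For each uridine we compare the count at the expected pileup position with
a 100-nt background window around it:

$$Z = \frac{c_{\text{target}} - \mu_w}{\sigma_w}$$

where $\mu_w$ and $\sigma_w$ are the mean and *population* standard
deviation of the 95%-winsorized background counts. Choices that matter:

* **Coverage gate.** A window (background plus target) with fewer than
  `coverage_min = 100` reads is *uncovered*: Z is undefined and the site is
  reported as `insufficient` rather than negative. Peak-height estimates
  are far too noisy below this depth.
* **Winsorization.** Counts above the window's 95th percentile are capped
  at that percentile, suppressing neighbouring outliers (other
  modifications, structure-induced stops, adjacent Ψs) that would otherwise
  inflate $\sigma_w$ and mask real sites. The target position is excluded
  from the background entirely, so a genuine peak is never capped and never
  deflates its own score. The percentile is the sort-based
  $\lceil 0.95\,n\rceil$-th order statistic (classical Tukey
  winsorization). We chose the order statistic over an interpolated
  percentile deliberately: capping at an interpolated value strictly
  between two order statistics lowers the percentile of the capped vector,
  so a second application keeps shrinking the tail — winsorization would
  not be idempotent. With the order statistic the cap is itself a data
  value that capping cannot move, so `winsorize(winsorize(v))` is exactly
  `winsorize(v)`. On 100-count windows the numerical difference between
  the two conventions is at most the gap between the 95th and 96th order
  statistics and has no practical effect on calls at $Z \ge 15$.
* **Raw counts.** Z is computed on raw counts, not transcript-normalized
  values. Within a single window the normalization constant cancels — the
  statistic is invariant to positive scaling of all counts, which the tests
  assert — and raw counts avoid isoform-assignment ambiguity.
* **Population sd.** The denominator uses $n$, not $n - 1$: the window *is*
  the background population of interest. Fixed for determinism.
* **Degenerate background.** If the winsorized background has zero
  dispersion, Z is undefined (`degenerate-background`) instead of being
  forced through an epsilon floor; manufacturing effectively infinite
  scores from empty windows would create artifacts at low coverage.

## End-aware window placement

Read coverage is strongly biased near transcript boundaries (5′-end read
pileups, coverage steps between overlapping isoforms), so a centred window
that straddles an annotated transcript end would produce a distorted
background. The window is therefore shifted, as little as possible, until
it satisfies all of:

* window 5′ boundary ≥ 40 nt downstream of the nearest upstream transcript
  5′ end,
* window 5′ boundary ≥ 5 nt downstream of the nearest upstream 3′ end,
* window 3′ boundary ≥ 25 nt upstream of the nearest downstream 3′ end,
* window 3′ boundary ≥ 5 nt upstream of the nearest downstream 5′ end.

Implementation detail: the four rules are enforced disjunctively per
annotated end — for every 5′ end $e$, either the window lies fully
downstream ($w_{5'} \ge e + 40$) or fully upstream ($w_{3'} \le e - 5$),
and analogously for 3′ ends with 25/5 nt. This closes the case the prose
rules leave implicit, an end falling *inside* the window, which violates
both branches and forces a shift. Among feasible placements the one with
the smallest displacement from centred wins; ties break toward the
transcript 3′ direction. If no placement inside the gene span satisfies
the constraints (e.g. a very short gene), the site is reported uncovered
rather than scored against a bad background. Windows are checked in the
tests against an independent constraint checker over an exhaustive grid of
end placements.

## The decision rules

A uridine is **called** when both libraries are covered, the CMC-treated
$Z \ge 15$, and the CMC-treated Z is at least 3-fold the mock-treated Z
(a mock Z ≤ 0 counts as satisfying the ratio). A called site is
**assigned** to a synthase when, in exactly one knockout library, the peak
is *absent* — knockout window covered, knockout $Z < 10$, and WT CMC Z at
least 4-fold the knockout Z — while every other knockout shows the peak
with coverage. Absence in two or more knockouts is **ambiguous** (no
secondary ranking; the redundancy may be biological or technical), and any
gap in knockout coverage, including an undersized panel, degrades the site
to **unassigned** — never to a different enzyme. The knockout coverage
threshold reuses the 100-read window cutoff, since the statistic is the
same.

These are fixed operating thresholds, not a multiple-testing procedure; no
FDR is estimated. The defaults live in `call_thresholds()` and every one of
them is configurable.

## The synthetic library generator

`make_transcriptome()` and `simulate_library()` exist so that every
downstream stage can be verified against planted ground truth. The
generative model:

* A genome of `n_transcripts` random transcripts (default 20 × 1000 nt,
  alternating strands, 100-nt gaps), expression weights log-normal
  (`sdlog = 1`) unless given explicitly. At each planted site a `UURAA`
  motif is written with the modified U at motif position 1.
* Each of `depth` reads (default 2 × 10⁵ per library) picks a transcript
  proportional to expression, a fragment 3′ start uniform along it, and
  walks 5′-ward. In the CMC condition the walk truncates at a planted site
  with probability `stop_efficiency × stoichiometry` (defaults 0.8 × 1.0),
  placing the 5′ end at *u + 1*; background termination occurs at
  10⁻³ per nt (drawn geometrically per read and resolved against site
  stops by taking the earliest event on the walk); otherwise the read runs
  to the transcript 5′ boundary. A 5% `end_pileup_weight` places reads
  directly at transcript starts, emulating the 5′-end artifacts the window
  shifting exists to avoid. Mock libraries ignore planted sites entirely
  (mock read-through signal at Ψ is configurable but defaults to none).
* Total read count equals the configured depth exactly, and tracks are
  bit-identical under a fixed seed.

What the generator does *not* emulate: sequencing error, RT processivity
that depends on fragment length, size selection, PCR duplication, or
structure-induced stop hotspots. Passing recovery tests therefore show the
caller's statistic and decision rules are implemented correctly and are
well-behaved under Poisson-like noise with end artifacts — not that the
thresholds are optimal for any particular real library.

The BID-seq simulator plants per-site deletion rates
`prop_const × stoichiometry` (1–2 nt deletions, counted at their 5′-most
position) over a uniform error floor; the calibration constant at 100%
stoichiometry is exposed as `prop_const` (default 0.9) because it is a
property of the chemistry, not of this analysis.

## Saturation analysis

`pool_tracks()` sums libraries; `subsample_track()` draws an exact read
count without replacement (a multivariate hypergeometric draw realised as a
chain of univariate hypergeometric draws — not binomial thinning, so depth
is exact). At each rung of the depth ladder the mock pool is subsampled to
the same *fraction* of its total as the CMC pool, keeping treated/mock
ratios comparable; one draw per depth per seed, with the seed exposed. The
curve reports peaks per subsample and the cumulative number of unique
(position, strand) peaks, which is non-decreasing by construction.

## Sequence and structure context

Motif classes over the strand-aware 5-mer starting at the site U:
`UURAA` (R = A/G), `UUYAA` (Y = C/U), `UURBA` (B ≠ A), `other` — a
mutually exclusive, exhaustive partition of all 1024 RNA 5-mers (verified
against a brute-force classifier). Codon context translates with the
standard genetic code from the annotated CDS frame. Background sites for
the structure comparison are all `UURAA` first-U positions in genes at or
above an expression floor (default RPKM ≥ 105), excluding anything within
100 nt of a called site on the same strand; the count of background sites
is data-dependent, so any cap (`n_max`) is a deterministic sample, not a
hard-coded number.

Structure context delegates folding to a pluggable engine
(sequence + optional per-position reactivities → symmetric base-pair
probability matrix at 37 °C). `vienna_engine()` adapts RNAfold in
partition-function mode with `--shape`/`--shapeMethod=Z` soft constraints;
`stub_engine()` returns configured matrices for deterministic tests.
Reactivity windows are 101 nt centred on the site (flank 50 on each side,
so relative offsets run −50..+50 symmetrically); only A/C positions carry
reactivities and everything else holds the placeholder −999. Per-position
pairing probabilities are column sums of the matrix, clipped at 1 — a
consistent ensemble matrix cannot exceed 1, so an unclipped excess above
0.05 raises a warning rather than an error. Aggregation across sites keeps
the raw per-site values and summarises each relative offset with the median
and quartiles, identically for target and background sets.

## Numerical and degenerate-input choices

* Ties in window displacement break toward the transcript 3′ direction.
* Overlapping genes: a position's containing transcript is the one whose
  span midpoint is nearest.
* Zero-depth positions in deletion traces have rate `NA`, not 0.
* Site-level BID-seq signal is the maximum deletion rate within ±2 nt,
  absorbing the 1–2 nt register spread of the deletion signature.
* All randomness flows through explicit integer seeds; per-library seeds
  are derived deterministically from a master seed.

## Problem sizes used in the tests

The test suite and the acceptance script run entirely on synthetic data
sized for a single CPU: 20 transcripts × 1 kb, 2 × 10⁵ reads per library
(recovery and assignment, 5 seeds), a 3-library pool of 6 × 10⁵ reads with
an 8-depth ladder from 5 × 10⁴ to 1.8 × 10⁶ reads (saturation over a
100-fold expression range), 250 randomized windows for the statistic
oracle, an exhaustive ±120 nt grid of end placements for the window
logic, and BID-seq pileups at depth 10⁴ over 20 sites. These sizes were
chosen so each stage exercises the same regimes as a bacterial
transcriptome experiment (window depths of 10²–10⁴ reads) while a full
run completes in minutes.

## Known limitations

* Calls use fixed thresholds; no error-rate calibration is attempted, so
  threshold choices must be revalidated for chemistries or organisms with
  different background stop behaviour.
* Single-isoform gene models: windows are confined to one annotated span,
  and overlapping-isoform coverage steps are handled only through the
  end-distance rules.
* The simulator's uniform fragmentation and position-independent background
  stop rate are simplifications; real libraries show sequence-dependent
  biases the caller has not been stress-tested against.
* Enzyme assignment assumes a complete, single-knockout panel; partial
  redundancy between synthases is not modelled.
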