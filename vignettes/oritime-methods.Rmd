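---
title: "Models and methods behind oritime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oritime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oritime)
```

# What the package computes

`oritime` implements the computational side of a replication-origin-firing
study in three strands:

1. **Timing-resolved chromatin enrichment.** Histone-mark and input-DNA
   read coverage over 1-kb intervals is normalized by library size, summed
   into 100 equal replication-timing bins (on the 0–100 smoothed
   Repli-Seq scale, where higher values mean earlier replication), the bin
   order reversed so bin 1 is earliest, and each mark's binned curve
   compared with the matched input curve by a one-sided two-sample
   Kolmogorov–Smirnov test.
2. **Molecular DNA combing.** From dual-pulse-labeled single DNA fibers
   (IdU 15 min, then CldU 30 min), the package measures replication fork
   velocity, inter-origin distances (IOD), and the distribution of the
   fiber-level replication structures over five classes, and runs
   Mann–Whitney and chi-square comparisons between conditions.
3. **Small quantifications.** ChIP-qPCR percent input, relative BrdU
   fluorescence from cytometry populations, and H3-normalized densitometry.

A synthetic-data generator produces all of these data types from an
explicit origin-firing genome model, so every stage of the pipeline is
testable end to end with no external data.

# The genome and firing model

`make_genome()` places origins on one chromosome as a Poisson process
(exponential inter-origin spacing; a `fixed` mode exists for exact-value
tests). Origins are grouped into contiguous **replication domains**
(replicon clusters, default 500 kb). Each domain activates at a time drawn
uniformly from an early or a late window, and its origins fire within a
small jitter (default 4 min) of the activation time. This domain structure
is the standard description of metazoan replication foci and is load-bearing
here for two reasons:

* a single synchronous firing wave would make inter-origin distances
  unmeasurable — a 45-minute pulse pair almost never catches two adjacent
  initiations unless neighbours fire at nearly the same time;
* fully independent origin times would scatter initiation so thinly along
  S phase that fibers would essentially never show two events.

The windows are constrained so that every early origin fires strictly
before every late origin. Per condition (e.g. control vs knockdown), each
origin fires **all-or-none** per molecule with the condition's firing
probability; dormant-origin compensation is deliberately not modeled, which
matches the interpretation that under knockdown a subgroup of origins
simply fails to activate.

Fork progression is deterministic at `fork_speed` (default 1.5 kb/min).
Converging forks stop where they meet; an origin overrun by a neighbouring
fork before its own firing time is passively replicated and contributes no
initiation (the package computes the exact piecewise-linear replication-time
envelope, so passive replication is handled analytically).

## Timing profiles and ChIP tracks

`make_timing_profile()` evaluates the population-average replication time
of every 1-kb interval (every origin firing) and rescales linearly so the
earliest interval maps to 100 and the latest to 0 — the convention of
smoothed Repli-Seq tracks, in which higher values are earlier.

`make_chip_track()` draws Poisson counts per interval around
`background_rate` (default 5 reads/interval). Within ±2 kb of each
**early** origin a histone mark's expectation is multiplied by an effective
fold `1 + (fold - 1) * knockdown_scale`, so `knockdown_scale = 1` is the
control, values above 1 model a demethylase knockdown that raises the mark,
and 0 collapses the track onto the input model. `mark = "input"` never sees
enrichment. Library size is exactly the number of reads emitted.

## The dual-pulse fiber simulator

`make_fibers()` models an **asynchronous culture**: each simulated molecule
receives a uniformly random pulse-start offset relative to its S phase, so
molecules are caught before, during, and after their local replication.
DNA replicated during the first 15 minutes is IdU-labeled, during the next
30 minutes CldU-labeled. Molecules are fragmented at Poisson breakpoints
into fibers of exponential length; labeled segments shorter than the
detection threshold (1 kb, the practical resolution of combing) are
dropped, and only fibers retaining label are collected — as on a real
slide, where unlabeled DNA is not scored.

An optional measurement-noise layer (`measurement_noise_kb`) jitters
segment boundaries with a Gaussian of sub-kilobase SD, emulating optical
measurement error. The default is 0 so that the geometric core stays exact
(a fired origin aligned with the pulse yields CldU tracks of exactly
`v × 30` kb flanking `v × 15` kb of IdU per side); the combing analyses in
`analysis/03_combing.R` enable 0.4 kb of noise, because a noise-free
simulator gives an unrealistic point-mass velocity distribution on which
rank tests behave pathologically.

# Scoring combed fibers

**Initiation events** are scored at (i) the midpoint of an IdU track
flanked on both sides by CldU within one labeled block — an origin that
fired before or during the first pulse — and (ii) the midpoint of an
*interior* CldU-only track (its own block, clear of both fiber ends, no
longer than `cldu_only_max_kb` = 100 kb) — an origin that fired during the
second pulse. The second rule deserves a note: with IdU-first labeling, an
ongoing fork that existed during pulse 1 must carry IdU at one end, so a
lone interior CldU patch can only arise from a new initiation; its two
divergent forks have fused CldU with no interior gap. CldU-only tracks
clipped by a fiber end remain ambiguous (fork or origin?) and are scored
as isolated forks, not events.

**Fork velocity** is CldU track length divided by the second-pulse
duration, measured only on CldU tracks adjacent to IdU on exactly one side:
CldU-only tracks (forks born mid-pulse) would undercount the pulse time,
CldU flanked by IdU on both sides is a termination (two forks' tracks
fused), and tracks touching a fiber end are clipped. This is the standard
ongoing-fork convention; the paper-level analyses use the second pulse
because it is the longer one and its start is conditioned on the fork
already existing.

**Inter-origin distances** are distances between consecutive events on the
same fiber, never across fibers; the count of IODs above 300 kb is reported
alongside. The velocity/IOD study selects long fibers (fragment mean 1.5 Mb)
— standard practice for IOD measurements, since short fibers censor long
IODs and compress between-condition differences — and tests the IOD shift
with a one-sided Mann–Whitney, the hypothesis being directional a priori
(a firing deficit can only increase IOD).

**Replication figures** are scored per structure into five classes:

| class | rule |
|---|---|
| `isolated_fork` | a labeled block with no initiation event (lone fork, old fork with unlabeled origin-proximal DNA, clipped figure piece, edge-clipped CldU-only track) |
| `one_origin_bidirectional` | exactly one event on the fiber, figure fully interior |
| `single_origin_only` | exactly one event, figure truncated by a fiber end |
| `interspersed_origins` | two or more events on one fiber (one structure) |
| `termination` | a CldU track flanked by IdU on both sides (converging forks met) |

These rules are a stated convention: the study that motivated them defined
the classes only pictorially. Structures, not fibers, are counted, and a
bounded number of structures can be scored from a randomly ordered fiber
sample (`max_structures`, `fiber_order`), the way a fixed n is scored off
a slide.

# The binned KS comparison

`timing_distribution()` conserves mass exactly: summed bin mass equals the
track's total normalized in-interval coverage, with zero-coverage intervals
keeping their bins at zero mass. Bin edges are closed-left/open-right with
100 folded into the top bin, then the bin order is reversed.

`ks_compare()` computes the one-sided statistic
\(D^+ = \max_b\,(F_a(b) - F_b(b))\) over the 100 bins (sample *a* leading
means *a* is shifted toward earlier timing). Because the inputs are binned
summaries rather than raw observations, p-values use an assumed sample size
of \(n = 100\) per curve — one pseudo-observation per bin — with
\(m = n^2/(2n) = 50\): one-sided \(p = e^{-2 m D^2}\), two-sided p from the
Kolmogorov series. Both are clamped to \([0, 1]\). The tests cross-check
this approximation against a binned permutation oracle where a 10,000-draw
oracle can resolve the tail (\(D \lesssim 0.22\)) and against the exact
equal-n enumeration \(P(D^+ \ge k/n) = \binom{2n}{n-k}/\binom{2n}{n}\)
across \(D\) up to 0.4; agreement is within a factor of two throughout.
`mark_vs_input_report()` flags a mark as early-shifted when
\(D^+(\text{mark}, \text{input}) > D^+(\text{input}, \text{mark})\).

# Statistics

`mann_whitney()` computes U from rank sums with midranks. For tie-free
samples with \(n_a n_b \le 400\) the p-value is exact, from the full null
distribution of U built as the Gaussian-binomial generating polynomial
(equivalent to enumerating every arrangement); otherwise the normal
approximation with tie and continuity corrections is used. One-sided
alternatives are available for directional hypotheses.

`chi_square_counts()` uses pooled-proportion expected counts,
\(X^2 = \sum (O - E)^2 / E\) over both samples, \(df = k - 1\); classes
with pooled expected count zero are dropped with a warning and df adjusted.

`box_summary()` reports the median and 10–90 percentile whiskers (type-7
linear interpolation), with values strictly outside the whiskers as
outliers — the box convention used for the combing figures.

Percent input is \(100 \times 2^{(\mathrm{Ct}_{\text{input}} -
\log_2(1/f)) - \mathrm{Ct}_{\text{IP}}}\) with an explicit input-aliquot
fraction \(f\) (default 1, i.e. pre-adjusted Cts) — the dilution convention
must be fixed somewhere, and the package makes it a visible parameter.
Relative BrdU fluorescence is the S-population mean minus the BrdU-negative
G1/G2M mean, normalized to the control's net signal (means, not medians —
configurable upstream, means chosen as the plain reading of "signal
intensity"). Densitometry is band density over H3 density of the same lane.

# Study conditions and their rationale

The generator's defaults are the package's study conditions. Values the
underlying experimental literature fixes are hard-wired (pulse durations
15/30 min; 1-kb intervals; 0–100 reversed timing scale; 100 bins; assumed
KS n of 100; n = 200 velocities, n = 100 IODs, n = 200 structures). The
free parameters were chosen once, on biological grounds plus prospective
power arithmetic, and are not tuned per run:

* **Fork speed 1.5 kb/min** — a typical human fork speed.
* **Combing genome**: fired-origin spacing 100 kb, 500-kb domains, early
  fraction 0.7, control firing efficiency 0.7, knockdown 0.15. Metazoan
  origin firing efficiency is well below 1; a chi-square on five classes
  that reaches \(p < 0.01\) at n = 200 per arm — as the motivating study
  reports — mathematically requires a composition shift of this magnitude,
  so the knockdown deficit is set to ~4–5×. The velocity/IOD sub-study
  contrasts firing 1.0 vs 0.5 at 70-kb fired-origin spacing on 1.5-Mb
  fibers (long-fiber selection) with 0.4-kb measurement noise.
* **Chromatin genome**: licensed-origin spacing 15 kb (MCM loading is an
  order of magnitude denser than per-cell firing; population ChIP sees all
  licensed origins), early-domain activation within 0–3 min, H3K4me3 8×,
  H3K4me2 4×, H3K4me1 2× at early origins within ±2 kb — promoter-grade
  H3K4me3 enrichment. With the assumed-n = 100 KS p-value, \(p < 0.05\)
  requires \(D > 0.17\); these conditions put the expected D near 0.33.
* **Problem sizes**: chromatin runs use a 2-Mb chromosome at 1-kb
  resolution; combing runs use 2–5 Mb chromosomes and a few hundred to a
  thousand fibers per condition. These sizes give stable statistics at
  interactive runtimes; all scale linearly if increased.

# What the simulations do and do not show

The generator reproduces the statistical structure the analyses assume:
timing-stratified coverage with origin-proximal enrichment, Poisson
counting noise, dual-pulse label geometry with fragmentation, detection
thresholds and fiber-end censoring, Ct noise on the log2 scale, lognormal
cytometry intensities. It does **not** model sequence-level reads, GC or
mappability bias, nucleosome positioning, dormant-origin activation,
checkpoint effects on fork speed, stretching-factor calibration (inputs
are already in kb), or inter-cell heterogeneity in fork speed. Passing
tests therefore demonstrate that the pipeline's computations are correct
and powered under the stated model — not that the model captures every
property of real HeLa data.

# Numerical and degenerate-input choices

Coordinates are 0-based half-open (bedGraph/BED convention) throughout;
reads are assigned to the interval containing their 5′ start, one interval
per read (the per-read vs per-base choice is flagged in the reader).
A timing value of exactly 100 folds into the top bin. Zero-mass
distributions, zero library sizes, empty fiber sets, unreplicated genomes
and empty value lists raise errors rather than returning silent defaults.
The KS p is clamped to \([0,1]\); fp round-off at the profile extremes is
clamped to the \([0,100]\) scale. Identical constant samples give
Mann–Whitney p = 1 by convention. Every generator derives its RNG stream
deterministically from the config seed and a stable per-call key, so any
single call is reproducible and distinct calls (e.g. a mark and its
matched input) are independent.

# Known limitations

* The five-class figure rules are an interpretation of a pictorial
  definition; other conventions (e.g. counting each event of a multi-event
  fiber separately) would change the class proportions, though not the
  direction of the firing-deficit shift.
* The assumed-n KS p-value is an approximation whose agreement with a
  permutation null degrades in the far tail (factor ~1.9 at D = 0.3);
  it is the procedure's stated convention, and the package reports D
  alongside p so users can apply their own calibration.
* IOD measurements inherit the same-fiber selection bias of real combing:
  long IODs are censored by fiber length, and medians compress toward the
  fiber scale. The long-fiber study design mitigates but does not remove
  this.
* With all-or-none firing and no dormant origins, the knockdown arm leaves
  genome stretches unreplicated within the simulated window; the package
  treats them as unlabeled DNA, which is what combing would show.
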