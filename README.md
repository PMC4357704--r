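# oritime

Analysis pipeline for studies of DNA-replication-origin firing — for
genomicists asking *when* chromatin marks are replicated and *how* a
perturbation changes origin usage. It implements three connected analyses:

1. **Histone marks over replication timing.** Per-interval ChIP and
   input-DNA coverage on 1-kb intervals carrying smoothed Repli-Seq timing
   values (0–100, higher = earlier) is library-normalized, summed into 100
   equal timing bins, and the bin order reversed so bin 1 is earliest. A
   mark's binned curve is compared with the input curve by a one-sided
   two-sample Kolmogorov–Smirnov test: D⁺ = max over bins of
   (F_mark − F_input), with p = exp(−2·m·D²), m = n²/2n and an assumed
   sample size n = 100 (one pseudo-observation per bin). A mark is called
   early-shifted when D⁺(mark, input) > D⁺(input, mark).
2. **Molecular DNA combing.** From fibers pulse-labeled with IdU (15 min)
   then CldU (30 min): fork velocity = CldU track length / 30 min on
   ongoing forks; inter-origin distances between consecutive initiation
   events on one fiber; five replication-figure classes (isolated fork,
   one-origin bidirectional, single origin only, interspersed origins,
   termination). Conditions are compared with Mann–Whitney (velocity, IOD)
   and a chi-square over class counts; box summaries use the median with
   10–90 percentile whiskers.
3. **Quantifications.** ChIP-qPCR percent input
   (100·2^((Ct_input − log2(1/f)) − Ct_IP), f = input aliquot fraction),
   relative BrdU fluorescence ((S-mean − BrdU-negative mean)/control net),
   and H3-normalized densitometry.

A synthetic-data generator (`make_genome()`, `make_timing_profile()`,
`make_chip_track()`, `make_fibers()`, `make_qpcr()`, `make_facs()`) builds
all input data types from an explicit origin-firing model — origins on a
Poisson-spaced chromosome, grouped into replication domains that activate
across S phase, all-or-none per-molecule firing, deterministic forks — so
the entire pipeline runs and is tested without any external download.
`vignettes/oritime-methods.Rmd` documents the models, conventions and the
rationale for every default.

## Worked example

Simulate a chromatin study — a 2-Mb chromosome at licensed-origin density
with H3K4me3 enriched at early origins — and ask whether the mark is
shifted toward early-replicating DNA relative to input:

```r
library(oritime)

cfg    <- sim_config(seed = 42, origin_spacing_mean = 15)
genome <- make_genome(cfg, chrom_length = 2e6, early_window = c(0, 3))
profile <- make_timing_profile(genome)
input <- timing_distribution(make_chip_track(genome, "input",   cfg), profile)
mark  <- timing_distribution(make_chip_track(genome, "H3K4me3", cfg), profile)
mark_vs_input_report(list(H3K4me3 = mark), input)
#>     mark         D            p direction early_shift
#>  H3K4me3 0.3528935 3.904496e-06         a        TRUE
```

`D = 0.353` is the maximum lead of the H3K4me3 cumulative timing curve
over the input curve; at the assumed n = 100 this gives p ≈ 3.9e-06, and
`early_shift = TRUE` records that the mark's curve, not the input's, is
the leading one — the mark sits on early-replicating DNA.

Percent input from a simulated origin/flank qPCR plate (true enrichment
3% at the origin, 1% at ±5-kb flanks; Ct noise SD 0.15 cycles):

```r
tab <- make_qpcr(c(TOP1_m5kb = 1, TOP1_ori = 3, TOP1_p5kb = 1),
                 sim_config(seed = 42))
percent_input_table(tab)
#>   amplicon percent_input
#>  TOP1_m5kb     0.8749119
#>   TOP1_ori     2.5475274
#>  TOP1_p5kb     0.9547984
```

The origin amplicon recovers ~2.5–3% input against ~0.9–1% at the flanks —
the 3× origin enrichment within Ct noise.

## The analysis workflow

The `analysis/` scripts chain the studies end to end (seed via the
`ORITIME_SEED` environment variable, default 1), writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R            # datasets + run manifest
Rscript analysis/02_timing_enrichment.R   # mark-vs-input KS report
Rscript analysis/03_combing.R             # velocity, IOD, figure classes
Rscript analysis/04_quantification.R      # % input, relative BrdU, densitometry
```

`run_pipeline()` exposes the same stages programmatically
(`simulate`, `timing-dist`, `combing`, `qpcr`) with a machine-readable
manifest per stage; two runs with the same configuration are
byte-identical.

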