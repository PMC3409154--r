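---
title: "Models and methods: conserved motif scanning, mutant-null ChIP occupancy, and fold-scanning FDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicoidchip)
```

This vignette is the package's own account of its models: what each stage
assumes, which parameters matter, what the synthetic generators do and do
not emulate, and where genuinely open design choices were settled.

## 1. Conserved core-motif scanning

Bicoid-class homeodomain proteins (Pitx2 among them) recognise a short core,
the hexamer consensus `TAATCY`. The scanner treats the motif as an exact
IUPAC match — deliberately not a position weight matrix — because at six
informative positions a PWM adds parameters without adding discrimination,
and because candidate selection rests on *conservation depth*, not on match
score.

**Assumptions.** The alignment is anchored to a gap-free reference sequence;
orthology is taken from the alignment columns. A species conserves a site
iff its characters at the six reference-base columns, read on the site's
strand, match the consensus with no gap and no `N`. We do not re-search
nearby sequence for a displaced motif: a motif that moved is not, for this
purpose, conserved. Under this columnar rule removing a species can never
increase a conservation count (a property the tests check).

**Strand handling.** Homeodomain cores are orientation-independent, so both
strands are scanned by default and the strand is recorded; pass
`both_strands = FALSE` to restore forward-only scanning. Sites are sorted by
start with `+` before `-` at ties.

**Coordinates.** 0-based half-open everywhere internally and in BED output;
the BED score column carries the conservation count.

**Parameters.**

| parameter | default | unit | rationale |
|---|---|---|---|
| `motif` | `TAATCY` | IUPAC | the bicoid-class core |
| `min_species` | 6 | species | conservation depth required of candidate sites; the reference itself is counted (no convention exists for excluding it, and each conserving species is evidence of function) |
| `target_len` | 110 | bp | middle of the admissible 70–150 bp qPCR amplicon range |
| `exclusion` | 1000 | bp | margin around control regions that must be free of any motif site, at any conservation level |

Amplicon windows are centered on the motif midpoint, with the left flank
rounded down when the split is odd; windows are clipped to the sequence and
shifted inward only when clipping would drop them below 70 bp. Control
regions are chosen by a deterministic left-to-right greedy scan, so the
same inputs always give the same regions.

When a locus arrives as multiple MAF blocks, `concat_blocks()` joins them in
reference order; reference bases between non-contiguous blocks are not in
the file, so they are filled with `N` (where no motif can match) and `-` for
the other species. Sites can therefore only be called inside aligned blocks.

## 2. qPCR signal model

Threshold cycles are logarithmic in starting template, so Cts are never
averaged. Each Ct is converted to a linear signal

$$\mathrm{signal} = 10^{10}\,E^{-C_t},$$

with per-cycle efficiency $1 < E \le 2$ ($E = 2$, perfect doubling, is the
default when no calibration is supplied). The $10^{10}$ prefactor only makes
the numbers pleasant; every downstream quantity is a ratio and invariant to
it. Triplicates are summarised by the arithmetic mean and *sample* SD
($n-1$) of the signals; the mean of signals exceeds the signal of the mean
Ct whenever replicates differ (Jensen's inequality — a test asserts the
direction). A triplicate with fewer than two amplified wells is declared
`nd` (not detected); that threshold is a declared convention: one well gives
no dispersion estimate, so nothing downstream could be tested.

## 3. Mutant-null occupancy quantification

The design hinges on the mutant genotype lacking the assayed protein
entirely, which makes the mutant immunoprecipitate a *matched background
measurement*: same antibody lot, same day, same qPCR plate. The estimator
chain is

1. $k = \overline{\mathrm{WT}_{in}}/\overline{\mathrm{MUT}_{in}}$ per
   extract pair (all input wells pooled), correcting chromatin-amount
   imbalance. Values outside $[0.5, 2]$ warn but do not stop the analysis.
2. $\mathrm{specific} = \overline{\mathrm{WT}_{ppt}}/k -
   \overline{\mathrm{MUT}_{ppt}}$, SDs combined in quadrature. Negative
   values are reported as-is; clamping would bias the null distribution.
3. $\%\,\mathrm{occupancy} = 100\,\mathrm{specific} / \overline{I}$ where
   $\overline{I}$ pools $\{\mathrm{WT}_{in}/k\}$ with
   $\{\mathrm{MUT}_{in}\}$. Dividing by the same-amplicon input cancels
   amplicon-specific PCR efficiency.
4. Two-tailed equal-variance Student's t between the $k$-normalized WT and
   raw MUT precipitate triplicates (3 vs 3 wells, 4 df), so the test and
   the point estimate describe identical quantities; codes follow the fixed
   table `****` $p<10^{-4}$, `***` $p<0.01$, `**` $p<0.05$, `*` $p<0.1$,
   `±` $p<0.3$, else `ne`. The `±`/`ne` boundary is taken literally as
   $p < 0.3$ (confidence $>70\%$). Degenerate zero-variance triplicates map
   to $p=1$ (equal means) or the $p=0$ limit.

**Error propagation choices.** First-order (delta-method) propagation:
differences add variances, ratios add relative variances. $k$ is treated as
a fixed plug-in constant by default — the occupancy contrast is a
precipitate contrast, and folding input noise into it both correlates the
test statistic with its own normalizer and obscures what the error bars
mean. Since the choice is genuinely open, `percent_occupancy(...,
propagate_input_error = TRUE)` adds the pooled-input-mean variance term.
Triplicate SDs (not SEMs) drive the reported error bars; the mean's
uncertainty (SD/√3) enters the propagation of derived quantities.

No multiple-testing correction is applied across amplicons: results are
per-site codes, and a correction would depend on a site-family definition
the analysis does not impose. When an amplicon is measured in several
extract pairs, all are reported and the lowest-p pair is flagged `primary`.

For co-factors present in both genotypes (e.g. HDAC1/HDAC3), background
subtraction is meaningless; `hdac_differential()` applies the same t
machinery to ask whether co-factor occupancy *differs* between genotypes.

## 4. Expression contrast and fold scanning

Signed folds use the mutant-positive convention: $r =
\overline{\mathrm{MUT}}/\overline{\mathrm{WT}}$, reported as $r$ when $r \ge
1$ and $-1/r$ otherwise, so no value lies strictly inside $(-1, 1)$ and
swapping labels is an involution $f \mapsto -f$. T-tests run on $\log_2$
intensities (variance stabilization); p-values are reported unadjusted.
Probe sets collapse to the one with the highest mean intensity over all
arrays (ties: lexicographically first probe id).

**Fold-scan null.** The FDR at cutoff $c$ is estimated as
$\mathrm{E}_{\pi}[N_\pi(c)] / N_{obs}(c)$, where $N_{obs}$ counts probes
with $|f| > c$ under the true labels and $\pi$ ranges over *balanced mixed
relabelings*: equal-size regroupings of the arrays that mix genotypes,
excluding the true labeling and its mirror, with mirror-equivalent
relabelings counted once (for 3 vs 3 there are 9). Mixing labels destroys
the genotype contrast while preserving per-array noise, which is exactly
the null required. The ratio is undefined (`NA`) when nothing clears the
cutoff. On pure-null data the curve calibrates to FDR ≈ 1 at low cutoffs
(the tests check a [0.8, 1.25] band at cutoff 1.2 averaged over 20 seeds).

Printed percentages of regulated probes round half-up to an integer — the
ordinary convention for percentages quoted in text.

An outlier replicate set is excluded *manually* by set id
(`exclude_set` in the pipeline configuration), never automatically:
outlier status is a judgement about the experiment, not a statistic the
pipeline should decide.

## 5. What the generators emulate — and what they do not

`simulate_chip_pair()` realises the additive model the estimator inverts:
WT precipitate copies $= N(b + f\,\kappa)$, MUT precipitate $= Nb$ (the
mutant has zero occupancy by genotype), inputs $= N$, with a
chromatin-amount imbalance drawn so the realized $k$ falls in $[0.6,
1.55]$ — the envelope of well-matched extract pairs. Copies become ideal
Cts by inverting the signal equation, and Gaussian noise (default SD 0.15
cycles) is added per well, on the Ct scale, because that is where qPCR
measurement error lives (pipetting and threshold-crossing errors are
multiplicative in template). Defaults: true occupancy $f = 0.02$, background
$b = 0.005$, $N = 3\times10^4$ genomes (placing input Cts near 18 and
precipitate Cts in the mid-20s at $E=2$), capture $\kappa = 1$. With zero
noise the analysis inverts the generator *exactly*; that identity is the
strongest structural test in the suite. Sheared-fragment length metadata
(200–500 bp, centered at 300) is emitted for realism and verified inert.

`simulate_expression()` emulates the pooled-replicate array design: three
replicate arrays per genotype, log-normal baselines (meanlog $\log 500$,
sdlog 1), mean-one multiplicative noise at 10% CV, a 5% regulated fraction
with log-normal fold magnitudes (meanlog $\log 2$, sdlog 0.4, floored at
1.2), and an optional outlier set with 3× noise. Planted folds for specific
genes can be forced exactly via `planted_folds`.

`simulate_alignment()` plants motif hexamers at chosen positions with
chosen conserving subsets, scrubs the background of accidental matches on
either strand, and mutates/gaps the other species away from the planted
windows, so scanner and annotator must recover the truth table exactly.
The default configuration — 12 placeholder vertebrates, 6 kb, sites at
conservation counts {4, 6, 7} — is the demo locus used throughout the
tests; with threshold 6 it yields exactly two candidates.

**Limits of the simulations.** Real qPCR noise has occasional gross well
failures and efficiency drift between amplicons; real arrays have
probe-level effects, intensity-dependent variance and batch structure; real
alignments evolve under a phylogeny, not independent per-species
mutation, so conservation counts on real data are correlated across
neighbouring sites in ways the generator does not produce. Passing the
suite therefore demonstrates that the estimators are *correct inversions of
their stated models* and calibrated under those models — not that the
models capture every pathology of bench data.

Because the normalization coefficient is itself estimated from noisy input
triplicates, dividing the WT precipitate by $\hat k$ adds a small
correlated error to all three WT values; with six amplicons' input wells
per pair this inflates the t statistic by a few percent, so the pure-null
`ne` rate sits slightly below the nominal 70%. The calibration test bands
account for this known, quantified effect.

## 6. Reproducibility and problem sizes

Every generator is a pure function of its integer seed (identical seeds ⇒
byte-identical outputs), and `run_pipeline()` stamps each table with the
seed and a hash of the analysis-relevant configuration (the output
directory is excluded from the hash, so relocating a run does not change
its identity). The test suite and the acceptance script use deliberately
modest problem sizes — 100 seeded simulations for fold recovery, 500 for
occupancy bias, 1000 random sequences for the scanner oracle, 20 seeds for
FDR calibration, 500-gene matrices — chosen so the full suite runs in
about a minute while keeping Monte-Carlo error well inside the tested
tolerances.
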