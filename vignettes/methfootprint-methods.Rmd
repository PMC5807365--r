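---
title: "Models and methods behind methfootprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methfootprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(methfootprint)
```

## The measurement problem

A dCas9–methyltransferase fusion deposits CpG methylation wherever its
catalytic domain meets unmethylated DNA, not only at the locus addressed by
its sgRNA. In a normally methylated genome this off-target activity is
invisible: most CpGs are already methylated, so there is nothing left to
gain. The experimental trick this package is built around is a methylation
*depleted* but maintenance *competent* cell system: the endogenous de novo
enzymes are absent, global CpG methylation is reduced to a few percent, and
DNMT1 is retained so that any methyl group the fusion deposits is propagated
through division. Against that background, every gained methyl group is a
footprint of the fusion protein, and bisulfite sequencing over a time course
of induction reads the footprints out.

`methfootprint` implements the downstream analysis of such an experiment —
from per-CpG bisulfite call tables to significant tiles, matched off-target
backgrounds, gain curves, and read-level hemimethylation evidence — together
with a simulator that generates the whole experiment with known ground
truth, so that every stage of the analysis can be validated quantitatively
rather than by inspection.

## The analysis model

### Units, filters, tiles

The observation unit is the CpG dyad, keyed by the 0-based coordinate of its
plus-strand cytosine; calls from the two strands are summed under that one
key. Descriptive summaries (tile means, feature means, gain curves) use
CpGs with at least 5 reads (`min_cov_summary`); the differential test uses
a stricter 10 reads in *both* samples (`min_cov_test`). The genome is
partitioned into fixed 200 bp tiles (`tile_width`), `[k·w, (k+1)·w)` per
chromosome with the trailing partial tile retained; a dyad belongs to the
tile containing its plus-strand coordinate. Tile means are unweighted means
of per-CpG levels: the filters have already bounded the per-CpG noise, and
unweighted means keep a deeply covered CpG from dominating a tile. A
`read_weighted` switch provides the coverage-weighted alternative.

### The paired tile test

For two samples, dyads present in both at test coverage are paired
positionally and the per-CpG level differences within each tile are tested
with a two-sided paired t-test (`n − 1` degrees of freedom). Tiles with
fewer than 3 shared CpGs (`min_cpgs`) are excluded, not tested. P-values
are adjusted by the Benjamini–Hochberg step-up over **all** tested tiles
genome-wide — one experiment, one family. A tile is significant when
`p_adj < 0.05` **and** `|Δ| > 0.10`; both inequalities are strict. The same
test grouped by CpG island drops the delta cutoff, because island-level
changes of interest (partial protection, small but consistent gains) are
often below 10 points.

Degenerate tiles are resolved as the continuous limits of the t statistic:
all differences zero gives `t = 0, p = 1`; a constant non-zero difference
gives `p = 0` with a signed infinite `t`. Variances within `1e-12`
(relative) of zero are snapped to the degenerate branch so floating-point
dust cannot manufacture astronomical finite t values. The `gain_only`
switch restricts significance to methylation gains; the default is
two-sided, since losses are informative for reversal experiments.

### On-target windows and matched background

The on-target window is the 200 bp immediately downstream of the
protospacer — 3′ of the protospacer on its own strand, i.e. `[end, end+200)`
for a plus-strand guide and `[start−200, start)` for a minus-strand guide.
"Downstream" is not self-defining for a double-stranded target, so the
orientation rule is configurable (`downstream = "plus"` always extends to
the right). The window is the literal 200 bp span, not snapped to the tile
grid; the background universe, by contrast, is grid tiles.

The off-target background for a guide is every tile whose *wild-type* mean
methylation lies within ±0.05 (`match_tol`) of the on-target window's
wild-type mean — tiles with the same potential to become methylated —
excluding tiles overlapping the window itself. The contrast statistic is
the day-`d` minus day-0 change of the on-target window against the mean ±
SD of the same change over background tiles, summarised per clone and
across clones.

### Ranked overlap, CGI classes, H3K4me3 scores, histograms

Top-k overlap ranks tiles eligible in every sample by mean level
(descending, ties by coordinate) and intersects the top 100 between
samples. CpG islands are classified by wild-type mean — hypermethylated
strictly above 0.8, hypomethylated at or below 0.2, intermediate otherwise —
and each class is summarised in the test sample. H3K4me3 ChIP counts per
island are divided by island length; the 99th-percentile density
(nearest-rank — the paper-style "top 1 % scaled to 100" rule needs a
concrete percentile definition, and nearest-rank keeps the scale anchored
to an observed value) maps to a score of 100, larger densities are capped.
Delta histograms bin per-tile differences of 1 kb tiles at width 0.05 over
[−1, 1], left-closed right-open with the last bin closed.

### Read-level none/some classification

A read is eligible for a window only if at least one of its CpG dyads lies
inside it; mere interval overlap contributes no evidence and would dilute
the fraction. Eligible reads with no methylated in-window CpG are "none",
the rest "some". Over loci that are fully methylated on exactly one strand,
strand-uniform reads split approximately 50/50 — the signature of either
hemimethylated DNA or a half-methylated cell population; bisulfite reads
cannot distinguish the two, and the report quantifies only the observable
fraction. The pooled fraction carries a 95 % Wilson score interval
(well-behaved near 0 and 1, where the Wald interval collapses).

### Smoothed tracks

`loess_smooth()` fits, at every input position, a tricube-weighted local
polynomial of degree 2 over the `⌈span·n⌉` nearest neighbours by coordinate
distance, with `span = 0.4` and no robustness iterations. The SD band is
the square root of the same smoother applied to squared residuals, floored
at zero — a pragmatic pointwise spread estimate, not a formal variance
band. Local polynomials can overshoot the data range; the tests therefore
assert agreement with an independent per-point weighted-least-squares
oracle and exact reproduction of polynomials, not range bounds. Smoothing
never crosses region boundaries.

## The simulator

### Landscape

One synthetic chromosome carries CpG dyads placed by a renewal process
(inter-dyad gap = 2 bp footprint + a geometric gap at the local per-bp
rate, 0.01 background / 0.08 inside islands), `n_cgis` disjoint CpG
islands, and a 5 % minority of non-island 200 bp tiles labelled
enhancer-like. Per-dyad wild-type baselines are drawn per class: island
dyads low (range [0, 0.18]), bulk dyads high (Beta(6, 1.2)), enhancer-like
dyads intermediate (range [0.25, 0.75]); a 10 % minority of islands is
forced hypermethylated (range [0.82, 1]). Per-island H3K4me3 densities are
anti-correlated with island methylation by construction (hypomethylated
islands draw from [0.6, 1], hypermethylated from [0, 0.4]), which encodes
the biological claim that trimethylated H3K4 excludes de novo methylation.
In depleted mode all baselines are scaled to a global mean of 0.04, the
depleted regime the system emulates. Cells are initialised symmetrically:
each dyad is `mm` with the baseline probability, else `uu` — the depleted
state is the remnant of a once-symmetric methylome, not a hemimethylated
one.

### Dynamics

The simulator tracks `n_cells = 200` independent lineages with explicit
per-strand states, because read-level strand structure is the point of the
hemimethylation analysis and cannot be recovered from per-site fractions.
Each day, every unmethylated eligible cytosine gains methylation with
probability `1 − exp(−h)` where the hazard is

```
h(x) = r_off · s(x) + Σ_g r_on · exp(−d(x, g)/λ) · [d(x, g) ≤ 1 kb]
```

with `s(x)` the susceptibility — the *wild-type* baseline floored at 0.05,
times `1 − k4_protection · k4(x)` inside islands. Gain potential follows
the prior methylation state even when the actual landscape is depleted:
that is the central observation the simulator is built to reproduce. The
on-target term decays exponentially (`λ = 250` bp) within a 2 kb window
centred on each protospacer — the scale on which targeted gain is visible
around a guide.

After gain, each of `divisions_per_day` divisions keeps one template strand
per cell (chosen uniformly — semiconservative replication sends the two
strands to different daughters and the simulation follows one); the nascent
strand is methylated opposite a methylated template with probability
`maintenance_fidelity = 0.95`, or never when maintenance is off. Gain is
applied before division within a day; the kinetics of deposition versus
replication are not observable at daily sampling, so the order is a
convention. Note that imperfect fidelity erodes fully methylated dyads
slowly (the followed daughter loses the nascent-strand methyl with
probability 0.05); exact day-0 preservation under null dynamics holds at
fidelity 1. In `cpg_and_cpa` mode, CA sites additionally gain at 0.25 times
the local hazard; CA methylation is strand-borne, has no palindromic
partner, and is never maintained — it survives a division only when its
strand is the template.

The off-target rate itself is a free parameter: the source experiments
report no rate, so `r_off = 0.1`/day was chosen once to put the simulated
induction time course in the observed qualitative regime (a few percent to
tens of percent over a week) and is not fitted.

### Observation layer

Reads sample a start uniformly, a cell uniformly, and a strand uniformly;
every dyad whose two bases fall inside the read yields one binary call from
the chosen strand's state, flipped with probability `1 − conversion_rate =
0.005` (false methylation) or `1 − protection_rate = 0.005` (false
unmethylation). Per-site tables merge both strands under the dyad
coordinate. Conditional on the truth, read calls at a site are i.i.d.
Bernoulli, so `sample_calls()` draws the per-site counts directly from the
exact marginal binomial law — used wherever read identity is not needed,
at a fraction of the cost. The simulator emits a single uniform-coverage
observation layer: the analysis consumes call tables and is indifferent to
whether they came from whole-genome, reduced-representation or capture
protocols, so protocol-specific coverage structure is deliberately not
modelled. There are no sequence-realistic reads, quality scores, PCR
duplicates, or alignment artefacts.

## Calibration and validation design

Two validation experiments deserve explanation because their configuration
differs from the default dynamics:

* **Rate recovery.** `estimate_r_off()` inverts the observation floor and
  regresses `−log(1 − level)` through the origin on day. This closed form
  holds under uniform susceptibility with maintenance and division
  disabled, so recovery runs use exactly that identifiable regime
  (`susceptibility_mode = "uniform"`, zero baseline, divisions off) — a
  calibration design, not the default biology. Under the default
  heterogeneous susceptibility the genome-wide curve mixes site-specific
  rates and a single rate is not identifiable from the mean alone. The
  tests recover rates of 0.02–0.10/day from 2 Mb genomes at coverage 30.

* **False-discovery control.** Null comparisons re-sample reads twice from
  one intermediate-methylation truth (day 2 of the default dynamics) at
  2 Mb and coverage 30, and the realised fraction of significant 200 bp
  tiles is checked across 20 samplings. The dual threshold makes the test
  conservative: a null tile must clear both an adjusted p-value and a
  10-point delta.

Problem sizes used across the test suite — 2 Mb genomes for genome-wide
properties, 0.1–0.2 Mb for targeted contrasts, 200 cells, coverage 30 —
are the package's chosen validation scales; they keep every property
estimable with comfortable statistical margins.

## What passing tests do and do not show

The simulator is faithful to the *structure* of the experiment (landscape
bimodality, state-dependent susceptibility, strand-level maintenance,
bisulfite error), not to any genome's sequence composition, repeat content,
or coverage biases. Passing tests demonstrate that the analysis recovers
known truth under that structure; they do not certify effect sizes on real
data, where susceptibility is shaped by chromatin features the simulator
summarises in two numbers (wild-type baseline and H3K4me3 density). The
hemimethylation fraction in particular sits slightly above one half in
finite samples because conversion failures convert a few "none" reads into
"some"; the analytic expectation, not exactly 50 %, is the right reference
for strict comparisons.

## Known limitations

* Pairing is positional; the test has no shrinkage across tiles and no
  covariates, by design — it mirrors a simple, auditable procedure.
* The matched background assumes the wild-type mean is a sufficient
  matching variable; chromatin covariates beyond H3K4me3 are not modelled.
* CA tracking stores explicit per-cell states for every CA site and is
  memory-hungry on multi-megabase genomes; context analyses are intended
  to run on sub-megabase regions.
* The simulator's single chromosome is a convenience; all analysis
  functions are multi-chromosome capable and are tested with multiple
  chromosomes in the I/O layer.
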