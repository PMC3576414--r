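---
title: "Analysing evolve-and-resequence fossil records with clonetrace"
author: "clonetrace maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing evolve-and-resequence fossil records with clonetrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrace)
```

## The setting

Serial-transfer evolution experiments with periodic cryopreservation leave a
"fossil record": whole-population samples frozen at intervals that can later
be pool-sequenced, alongside individual clones isolated near the end of the
experiment. clonetrace implements the computational chain that turns such
data into evolutionary-dynamics statements:

1. **Reporting filters** on pooled variant calls (`apply_reporting_filters()`,
   `filter_reads()`),
2. **Clone genealogies** under the single-origin assumption, with
   fossil-record dating (`build_genealogy()`, `date_genealogy()`),
3. **Nested-lineage (Muller) band tables** (`assign_lineages()`,
   `build_muller_table()`),
4. a **Wright-Fisher drift null** for classifying allele-frequency changes
   (`drift_variance()`, `classify_trajectory()`),
5. **cross-population parallelism** summaries (`parallelism_levels()`,
   `paired_t_test()`), and
6. a **forward Wright-Fisher simulator** with full ground truth
   (`simulate_wf()`), which every downstream test is scored against.

The package is organised around tabular data: variant tables and clone tables
come in as TSV, every result is a tibble (or a small object with `tidy()` /
`glance()` methods), and plotting goes through `autoplot()`.

## The day/generation axes

Experiments are bookkept in days; population genetics happens in
generations. With daily transfers at roughly a 100-fold dilution the regrowth
corresponds to about 6.7 generations per day, so a 183-day experiment spans
about 1,230 generations. `day_to_generation()` uses
`floor(day * gens_per_day)`; with the default 6.7 this maps day 156 (the
clone-extraction day) to generation 1045 and day 72 to generation 482, the
anchors used throughout. Flooring was chosen because it reproduces both
anchors simultaneously; the convention only matters at the sub-generation
level, far below the dating resolution of the record.

## Reporting filters

Pooled sequencing of a whole population produces many low-frequency calls of
uncertain provenance. The reporting rules implemented are:

* a variant must be detected (at least one supporting read) in **at least two
  time points** of the same population *and* reach **5% frequency** in at
  least one sample;
* variants carried by a sequenced clone are reported **regardless** of their
  pooled frequency;
* an observation supported by a **single read** is treated as undetected
  unless the next time point has two or more supporting reads.

One ordering question the rules leave open is whether single-read masking is
applied before or after the two-sample/5% evaluation. clonetrace masks
first: a single unsupported read is the hallmark of a sequencing artefact,
and letting it count towards "detected in two samples" would let artefacts
rescue themselves. The choice is conservative (it can only remove
mutations) and is documented at the function level.

Zero-coverage time points are treated as *missing*, not as frequency zero:
a mutation cannot be declared absent where nothing was sequenced. The FASTQ
read filter (`filter_reads()`) keeps reads with at most 5 bases below Q20,
assuming Phred+33 encoding (the output of every modern Illumina pipeline).

## Genealogy reconstruction and dating

Endpoint clones are related under the assumption that each mutation arose
exactly once and never reverted (infinite sites, no homoplasy). The binary
clone-by-mutation matrix then admits a perfect phylogeny exactly when no
mutation pair shows all three patterns 11/10/01 across clones
(`check_perfect_phylogeny()`); mutations carried by identical clone subsets
share an edge, nested subsets give nested edges, and clones sharing nothing
attach independently at the ancestral root. Conflicts (possible with
miscalled linkage in pooled data) fail loudly by default; an explicit greedy
fallback drops the conflicting mutation with the lowest maximum observed
frequency first, on the logic that the weakest-evidenced call is the most
likely artefact.

Dating uses the fossil record: a mutation is assumed to have arisen at the
**midpoint between its first detection and the previous sample**; a mutation
found only in clones (never in the pooled record) is dated near the end, at
the midpoint between the clone-extraction generation and the last sample
before it, and flagged `"near-end"`. Divergences between clones are dated
midway between the last mutation they share and the first they do not.
All midpoints are computed on the generation axis. Two conventions the rules
do not determine were fixed as follows:

* *Ties in within-edge mutation order* (equal first-detection time) are
  broken by descending mean frequency, then lexicographic id — higher mean
  frequency indicates an earlier or faster-rising mutation, and the final
  tie-break just makes output deterministic.
* *Mutations that disappear and reappear* in the record are dated from their
  first detection only; the midpoint rule gives no guidance for gaps, and
  first detection is the only observation that bounds the origin from above.

These dates are bracket midpoints, so their error is bounded by half the
local inter-sample spacing whenever the mutation truly arose between the
bracketing samples — a property the test suite verifies against simulated
ground truth.

## Muller tables

Each genealogy edge that carries mutations defines a lineage; nesting
follows the genetic backgrounds. A lineage's frequency at a time point is
the frequency of its **earliest defining mutation**: that mutation tags the
whole background, and (under single origin) every later mutation of the
lineage segregates inside its carrier set, so the earliest mutation is
provably the most frequent on its edge. A mean-of-defining-mutations proxy
is available behind `freq_proxy = "mean"` for sensitivity checks.

Band widths are lineage frequency minus the summed frequencies of child
lineages, floored at zero; the residual ancestral band absorbs the rest.
Flooring is bookkept, not hidden: every band records the clipped mass, and
`sum(band) - sum(floored)` is exactly 1 at every time point. A child
exceeding its parent by more than `tolerance` (default 0.05, the scale of
binomial noise at typical pooled coverage of a few hundred reads) is recorded
as a nesting violation and warned about, but does not abort: pooled
frequency estimates are noisy and the table is still interpretable.

For display, `lump_similar()` merges adjacent within-lineage mutations whose
trajectories differ by at most `max_gap` at every time point (greedy, so
clusters can chain) and averages the merged trajectories. `max_gap` has no
default anywhere user-facing: it is a presentation decision, not a
scientific constant.

## The drift null

Under the haploid Wright-Fisher model, drift accumulates allele-frequency
variance
$$V(t) = p\,q\,\bigl(1 - e^{-t/N_e}\bigr),$$
which is `pq/Ne` after one generation and saturates at `pq`. At the
reference conditions — `p = q = 0.5` (fastest drift), `t = 82` generations
(the average spacing of 16 samples over 1,226 generations), and
`Ne = 3.3e7` — the variance is 6.21e-7 (s.d. 7.88e-4, i.e. about 0.08%).
With the normal approximation, the probability that drift moves an allele by
1% or more between consecutive samples is below 1e-12, which is why observed
jumps of tens of percentage points are attributed to selection.

```{r drift}
drift_variance(p = 0.5, t = 82, ne = 3.3e7)
drift_sd(p = 0.5, t = 82, ne = 3.3e7)
drift_change_probability(0.01, p = 0.5, t = 82, ne = 3.3e7)
```

Numerical choices:

* the tail is computed in log space (`pnorm(..., log.p = TRUE)`), so extreme
  z-scores never underflow silently — a p-value of 0 always comes with a
  finite `log10_p` attribute or an explicit `"degenerate_null"` flag
  (`t = 0` or `p` at a boundary);
* the test is two-tailed by default, since "a change of at least 1%" is
  directionless; one-tailed is available;
* the null ignores binomial sequencing noise by design (it is a statement
  about the population, not the sampling); `coverage_noise = TRUE` adds a
  `pq/coverage` term for users who want the combined null;
* multiple testing is Bonferroni-corrected across all interval tests in the
  population by default — with p-values this extreme any correction gives
  the same answer, and raw p-values are always reported.

`classify_trajectory()` applies the test to every mutation over every pair
of consecutive samples, using the interval-start frequency for `p`, skipping
(and logging) intervals with missing frequencies.

## Parallelism

`parallelism_levels()` scores, for each ecotype-associated mutation, the
finest resolution at which another population carries a same-ecotype
mutation: identical position and alleles (nucleotide), same gene and codon
(codon), same gene or intergenic label (gene), else none. Identity at the
nucleotide level requires the alleles, not just the site; IS-element
insertions match when element and insertion site coincide. Whether
clone-only ("starred") mutations belong in the denominator is ambiguous, so
totals are reported with and without them whenever the input flags them.

The FS-versus-SS mutation-count comparison uses a paired t-test restricted
to genealogically independent comparisons: within each population, clones
are grouped into independent origins (`count_independent_origins()` — the
transitive closure of mutation sharing), counts are averaged within an
origin, and one pair is formed per FS-origin x SS-origin combination. A
population whose two SS clones share nothing therefore contributes two
comparisons, giving n = 4 pairs for the canonical three-population,
two-clones-per-ecotype design.

## The simulator and what passing tests mean

`simulate_wf()` is a discrete-generation Wright-Fisher simulator on whole
genotypes (asexual, no recombination, infinite sites — so simulated truth
always satisfies the genealogy module's single-origin precondition).
Offspring counts are multinomial with fitness-weighted expected proportions;
beneficial mutations arise at rate `mu` per genome per generation with
selection coefficients from a configurable distribution; an optional
two-ecotype model adds `a_E - b_E x_E` to fitness — the simplest negative
frequency dependence consistent with reciprocal niche construction, used as
a clearly-labelled stand-in because no quantitative fitness function for the
real interaction is available. Defaults mirror the experimental design the
analysis targets: `Ne = 3.3e7`, 6.7 generations/day, 16 sampling days from
day 0 to 183, clone extraction at day 156, and a beneficial supply
`mu * Ne` of order 0.3 per generation (a realistic scale for large-effect
beneficial mutations in glucose-limited *E. coli*); coverage defaults to
500x, inside the 72-2,500x range typical of pooled resequencing.

What the simulator emulates: drift at configurable `Ne`, selective sweeps
and clonal interference, ecotype branching with protected coexistence,
binomial sequencing noise, and clone sampling. What it does not: explicit
resource dynamics (the glucose/acetate cycle), the daily dilution bottleneck
(collapsed into constant-`Ne` generations, exactly as the drift null
assumes), alignment/calling artefacts, and linkage miscalls. Passing the
recovery tests therefore shows the *inference chain* is correct under the
model's own assumptions, not that those assumptions hold for any particular
real dataset.

Test problem sizes were chosen to make each check statistically meaningful
at desk scale: 1e5 neutral replicate trajectories for the drift-variance
calibration (Monte-Carlo relative error ~0.45%, against deviations an order
of magnitude smaller), 1,000 trajectories for the type-I-error check, 20
replicates for the coexistence property (with `switch_prob = 0.3` and
`mu = 2e-5` at `Ne = 1e4` the probability that the second ecotype never
establishes in 400 generations is below 1%), and small
(`Ne` in the hundreds-to-thousands) populations for end-to-end genealogy
recovery.

## Known limitations

* The perfect-phylogeny fallback is greedy; with many interacting conflicts
  it may drop more mutations than the minimum necessary.
* Dating assumes the first detection bounds the origin; a mutation that
  lingered below the detection limit for a long time will be dated too late
  (flagged `"near-end"` in the extreme clone-only case).
* The lineage-frequency proxy is exact under single origin and noise-free
  frequencies; with noisy pooled estimates nested bands can transiently
  invert, which is reported as a tolerance-bounded violation rather than
  corrected, since any correction would invent data.
* `parallelism_levels()` treats annotation labels as ground truth; disagreeing
  gene models between populations would silently reduce matching.
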