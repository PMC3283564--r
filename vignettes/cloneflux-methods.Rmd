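---
title: "Quantifying gene flow between incipient microbial species with cloneflux"
author: "cloneflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene flow between incipient microbial species with cloneflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneflux)
```

## The problem

Clonally reproducing microbes (the motivating system is a sympatric
population of the thermoacidophilic archaeon *Sulfolobus islandicus*, but
nothing in the package is organism-specific) exchange genetic material by
homologous recombination: a donor lineage replaces a tract of homologous
sequence in a recipient lineage. When a sample of genomes splits into two
lineages that recombine more within than between themselves, the population
may be speciating. `cloneflux` provides the quantitative machinery for that
question:

* a **clonal genealogy** model (rooted, binary, ultrametric, times in
  coalescent units: one unit equals the effective population size times the
  generation length);
* a generative **coalescent-with-gene-conversion** model of recombination
  events on that genealogy, used both as a synthetic-data generator and as
  the *neutral prior* against which observed recombination flux is judged;
* **flux matrices** (observed vs expected events per ordered donor/recipient
  branch pair), their change through coalescent time, and the r/m summary;
* genome-scan statistics of differentiation (**Hudson-type F_ST** per SNP,
  gene and sliding window, permutation tests, low-differentiation region
  calling) and selection (**NG86 dN/dS**, **McDonald–Kreitman**);
* minimum **gain/loss parsimony** for variable (non-core) genome segments.

## The recombination model

Conditional on the clonal genealogy, recombination events form a Poisson
process of intensity $\rho$ per site per unit of branch length. An event
*arrives* at a point uniform over (branch length $\times$ sites); its tract
starts at the arrival site and has geometric length with mean $\delta$
(support $\ge 1$, truncated at the alignment end; genomes are treated as
linear). The *donor* is found by tracing a lineage backwards from the
arrival time: while $k(t)$ clonal lineages exist it coalesces with them at
total rate $k(t)$ (uniformly among them); above the root it coalesces with
the root lineage at rate 1 and is recorded as the `ABOVE_ROOT`
pseudo-donor. This is exactly the origin process whose posterior
genealogy-based inference tools (ClonalOrigin-style) approximate, which is
why Monte-Carlo draws from it (`expectedFlux()`) are the correct null for
observed event tables.

Two conventions are worth stating because they are easy to get wrong:

* **Intensities carry no hidden factor of 1/2**: $\rho$ is events per site
  per unit branch length, matching the scale on which absolute
  recombination rates are printed by inference tools; the package default,
  $2.41\times10^{-4}$ events per site per coalescent unit, is of the
  magnitude estimated for natural *S. islandicus* populations.
* **Expected counts are scaled by the global observed total**, not by
  per-recipient totals. The alternative conditioning is defensible; the
  global choice keeps the matrix a single multinomial and is what the
  ratio heat maps assume.

### The barrier

A barrier to gene flow with strength $m \in [0,1]$ is implemented as
post-hoc thinning: an event whose donor and recipient branches belong to
different groups (both attributable via `branchGroup()`) is retained with
probability $m$. Thinning, rather than rate rescaling, preserves the
arrival/departure geometry of the retained events, so the prior remains the
valid null and the flux *ratios* directly display the barrier. `barrier`
may also be a function of arrival time, which lets one simulate a barrier
that strengthens toward the present — the signature of progressive
divergence that the temporal-flux table (`temporalFlux()`, ten equal-width
bins of $[0, T_{MRCA}]$, bin 10 most recent) is designed to detect.

### Sequence layer

Alignments are simulated per site on the *marginal genealogy*: the clonal
tree with, for every event covering the site, the recipient lineage
detached at its arrival time and re-attached at the donor point. Events are
treated as independent deviations from the clonal genealogy (the same
approximation the inference tools make); when tracts of two events overlap
on one recipient lineage the younger (later-arriving) event wins at each
site. Mutations follow Jukes–Cantor with intensity $\theta$ per site — the
same model the NG86 correction assumes downstream. Coding mode runs the
analogous neutral chain on the 61 sense codons with substitutions into stop
codons excluded; this matches the stop-excluded site counting of NG86, so
neutral coding simulations have expected $d_N/d_S = 1$ by construction. The
root codon sequence is drawn uniformly from sense codons excluding the
start codon.

## Default study conditions of the generator

The defaults emulate a small sample of two recently diverged clonal
lineages:

| parameter | default | rationale |
|---|---|---|
| sample | 7 + 3 strains | two-lineage sample of ten genomes (two further strains may be labeled `excluded` and are dropped from contrasts) |
| split time | 0.5 coalescent units | recent divergence |
| within-lineage $N_e$ | 0.1 of ancestral | shallow, well-separated lineages |
| $\theta$ per site | $10^{-3}$ | pairwise diversity 0.01%–0.35%: within-lineage pairs land near the bottom, between-lineage pairs near the top of that range |
| $\rho$ per site | $2.41\times10^{-4}$ | printed absolute recombination rate |
| $\delta$ | 2000 bp | conversion-tract scale typical of genealogy-based estimates |
| alignment length | 30 kb | large enough for sliding windows, small enough for quick simulation |

These were chosen once, from the study conditions the generator emulates,
and are not tuned to test outcomes. What the generator does *not* emulate:
real gene boundaries and codon usage, rate heterogeneity along the genome,
indels and missing data (simulated alignments are gap-free; the SNP
extractor's gap handling is exercised on constructed alignments instead),
selection, and uncertainty in the genealogy or in event inference — real
event tables come with posterior uncertainty that the package treats as
given. Passing calibrations therefore demonstrate internal consistency of
the estimators under the model, not robustness to inference error.

## Differentiation statistics

`hudsonFst()` implements the haploid two-group estimator
$F_{ST} = 1 - H_w/H_b$, with $H_w$ the unweighted mean over the two groups
of the mean pairwise difference within each group (pairs of distinct
strains, i.e. an $n(n-1)$ denominator) and $H_b$ the mean pairwise
difference between groups. Windows and genes pool $H_w$ and $H_b$ across
their SNPs before the ratio (averaging per-SNP ratios is a flag-free
alternative we deliberately did not default to, because pooling weighs
SNPs by information rather than equally). The estimator is undefined when
$H_b = 0$ and negative values are reported, not clamped: with the unbiased
within-group estimator, identical allele compositions in both groups give
$F_{ST} < 0$, which is informative (more diversity within than between).
This is a deliberate departure from AMOVA-style $\Phi_{ST}$: the
closed-form pairwise-difference estimator is exactly testable by
enumeration.

Windows are anchored at reference position 0 (10 kb size, 5 kb step by
default, 0-based half-open, partial terminal windows dropped) and are not
computed when empty or when they overlap positions absent from any strain.
Low-differentiation regions start and end with a window below the 0.5
threshold; low runs separated by a differentiated stretch shorter than
`mergeGap` (default 250 kb, chosen so that differentiated "continents" of a
few hundred kb separate regions) are merged, and complementary
differentiated stretches of at least `mergeGap` are reported as continents.

The permutation test reports $p = (1 + \#\{F_{ST}^{perm} \ge
F_{ST}^{obs}\}) / (1 + n_{perm})$, which cannot return 0 and is exact under
exchangeability.

"Informative SNP" defaults to *any* clean polymorphic column (gap- and
ambiguity-free across included strains); a minor-allele-count $\ge 2$
switch is available since the term is used both ways in the literature.

## Selection statistics

`ng86Sites()`/`ng86Pair()` implement Nei–Gojobori (1986) counting:
potential synonymous sites are the per-position fractions of
single-nucleotide changes that are synonymous, with changes to stop codons
excluded from the denominator, so $s + n = 3$ per sense codon; multi-step
codon differences average over all orderings of single-step pathways,
excluding pathways through stops (with an all-pathways fallback in the
degenerate case where every ordering is blocked); proportions are corrected
as $d = -\tfrac34\ln(1 - \tfrac43 p)$, undefined at $p \ge \tfrac34$.

For neutrality calibrations the package-level summary is the *pooled* ratio
$\overline{d_N}/\overline{d_S}$ across genes rather than the mean of
per-gene ratios: a ratio of small noisy counts is biased upward by the
convexity of $1/d_S$, while pooling is consistent. Per-gene ratios are
still reported (`geneGroupDnds()`), both between-group and over all pairs,
since published summaries do not always state the pairing scheme.

`mkTest()` classifies each clean, singly-segregating, biallelic codon
position as fixed vs polymorphic between the two groups (the same
monomorphism semantics as `classifySnps()`) and synonymous vs
nonsynonymous in its codon context; codons with more than one segregating
position are excluded by default to avoid ambiguous calls. The p-value is
the standard exact two-sided Fisher test (summing tables of probability at
most that observed), with no continuity or multiple-testing correction.

## Gene content

`minGainLoss()` is Sankoff parsimony for a binary presence/absence
character with unit gain and loss costs, minimized over root states; ties
are broken deterministically (absence preferred at the root, a child keeps
its parent's state when optimal), so reconstructions are reproducible. A
cost ratio is exposed for sensitivity analyses. Segments are filtered with
`keep iff length >= 5 kb and variable-gene fraction >= 0.5` — the inclusive
boundary is a choice, exposed as arguments, since "longer than" and
"smaller than ... excluded" conventions differ by one segment at the
boundary. Multi-event segments present in part of each group are flagged as
candidates for between-group exchange; segments with heterogeneous internal
presence must be pre-split (rows marked `partial` are rejected).

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; 1-based
  inclusive gene tables are converted on read.
* Branch IDs are assigned by a deterministic post-order traversal, so event
  tables are portable across sessions; polytomies are rejected rather than
  silently resolved (flux matrices assume binary branching), and
  ultrametricity is enforced within a relative tolerance of $10^{-6}$.
* Every stochastic operation takes an explicit seed; identical seeds and
  inputs give byte-identical output tables.
* The flux significance mask greys cells with fewer than four observed
  **and** fewer than four expected events. Reading the rule as *or* would
  mask cells with a large observed excess over a tiny expectation, which
  ratio heat maps visibly color; *and* was chosen for that reason.
* Per-cell Poisson p-values are descriptive and unadjusted.
* Temporal-flux bins are equal-width in time (not per-event deciles); the
  equal-width rule makes the bin boundaries independent of the event
  sample.
* In the barrier calibrations, within- and between-group flux are compared
  through aggregate ratios $\sum$observed/$\sum$expected over the
  corresponding cells, which are stable at realistic event counts where
  per-cell medians are dominated by zero cells.

## Problem sizes used by the test suite

The calibration tests run, per property: 4 tree shapes at 50,000
Monte-Carlo draws against the closed-form flux prior; 200 replicate event
draws on a 12-leaf genealogy at 100 kb for the null flux calibration; 100
replicates each for the barrier, temporal and monotonicity properties (the
latter at 20 kb across $m \in \{1, 0.3, 0.1, 0\}$); 1,000 small simulations
for parameter recovery; 1,000 random tables for the F_ST oracle; and 500
neutral coding genes of 300 codons at $\theta = 0.02$ (chosen for
per-gene difference counts in the tens) for the selection calibration. The
barrier-monotonicity comparison uses common random numbers: every
replicate shares its genealogy, its pre-barrier event draw, its thinning
uniforms and its mutation seed across the four barrier strengths, so the
kept event sets nest as $m$ decreases and tree-to-tree noise cancels from
the contrast. The exact Fisher p-value of the MK test is discrete — under
neutrality it carries an atom at $p = 1$ whenever the observed table is
the modal one — so its null distribution is conservative (sub-uniform)
rather than uniform; the suite asserts validity ($P(p \le \alpha) \le
\alpha$) at several thresholds.

## Known limitations

* The simulator conditions on a single clonal genealogy; it does not model
  genealogy uncertainty or joint inference of tree and events.
* Circular genomes are not modeled (tracts truncate at the alignment end).
* The coalescent prior assumes a constant-size neutral population above the
  sampled structure; demographic growth would change $k(t)$.
* `exclusiveIslands()` grows runs greedily from each exclusive gene; it is
  a documented interpretation of "contiguous regions in which more than
  half of the genes are group-exclusive", not the unique formalization.
* XMFA support covers the Mauve-style header convention
  `> name:start-end strand`; exotic header dialects need a sidecar table.
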