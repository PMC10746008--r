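---
title: "Demarcating bacterial ecotypes from 16S rRNA surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demarcating bacterial ecotypes from 16S rRNA surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecotypesim)
```

## The problem

Environmental 16S rRNA surveys of closely related bacteria — for example
green sulfur bacteria (*Chlorobaculum* spp.) sampled from hot-spring mats —
routinely recover clouds of near-identical sequence variants separated by a
few percent divergence. The taxonomic question is where, inside such a
cloud, the ecologically meaningful population boundaries lie. `ecotypesim`
implements a simulation-based answer built on the Stable Ecotype Model: a
lineage diversifies through occasional *ecotype formation* events and
recurrent *periodic selection* events, the latter purging the sequence
diversity of one ecotype each time an adaptive mutant sweeps it. Under this
model an "ecotype" is a population whose internal diversity is transient;
sequence clusters that persist across sweeps mark distinct ecotypes (or, for
geographically isolated populations with no ecological distinction,
*geotypes* — the machinery cannot tell these apart and the interpretation is
left to subsequent environmental analysis).

## The observable: binning curves

All inference is driven by one summary of the alignment, the **binning
curve**: the number of sequence clusters as a function of the identity
criterion used to define clusters. At criterion 1 each distinct sequence is
its own bin; as the criterion is relaxed, bins merge, eventually into one.
Clustering is complete-linkage — every pair inside a bin must meet the
criterion — computed on uncorrected identities (`1 - p`-distance), since the
curve summarizes *observed* relatedness. Agglomeration breaks ties by
merging the lexicographically smallest pair first, so curves are
deterministic. The default grid
`{1.000, 0.995, 0.99, 0.98, 0.97, 0.96, 0.95, 0.90, 0.85, 0.80}` brackets
the 0–5% divergence range typical of within-genus surveys; it is
configurable because no canonical grid exists.

## The model and its parameters

The simulator (`simulate_replicate()`) runs backward in time from `n`
sampled lineages assigned uniformly to `npop` ecotypes (conditioned on no
ecotype being empty; when a uniform draw fails repeatedly the assignment
falls back to a random one-per-ecotype seeding, which only matters when
`npop` approaches `n`). Three parameters matter:

* `omega` — ecotype formation rate, events per ecotype per unit branch
  length (expected substitutions/site). Backward in time a formation event
  merges one ecotype into another.
* `sigma` — periodic selection rate, same units. Backward in time a sweep
  coalesces *all* lineages of the affected ecotype at once.
* `npop` — the number of ecotype populations, an integer `>= 1`.

Waiting times are exponential with the usual competing-rates construction;
the process stops at a fixed backward horizon `depth`, where surviving
lineages join at the root. The default `depth` is half the maximum
Jukes–Cantor-corrected pairwise distance of the observed alignment (time to
the root is roughly half the deepest divergence); it is configurable.
Sequences of length `L` then evolve down the genealogy under Jukes–Cantor,
with per-branch substitution probability `(3/4)(1 - exp(-4b/3))` and
substituted sites switching to one of the three other bases uniformly. Drift
coalescence is deliberately *not* a separate parameter: within-ecotype
coalescence is dominated by sweeps under this model, so drift is subsumed by
`sigma` and the model stays three-dimensional — the three quantities the
analysis ultimately reports.

The **likelihood** of a parameter triple is the fraction of Monte-Carlo
replicates whose binning curve matches the observed one at every criterion,
within a multiplicative band (`match_rule()`): the observed count must lie
in `[floor(sim/t), ceiling(sim*t)]` with tolerance `t = 1.1` by default
(`t = 1` gives exact equality). Replicate `i` always uses a substream
derived from `(seed, i)`, so raising the replicate count `R` never
reshuffles earlier replicates and every estimate is bit-reproducible.

## Fitting and confidence intervals

`fit_parameters()` minimizes the negative likelihood over
`(log10 omega, log10 sigma, log10 npop)` with Nelder–Mead's downhill
simplex, rounding `npop` to the nearest integer inside every evaluation. All
evaluations of one fit share the same replicate substreams (common random
numbers), which makes the noisy objective deterministic given the seed. The
starting point is heuristic — `npop` from the bin count just below full
identity, `sigma` from the microheterogeneity scale (`L/2`), `omega` a few
events per `depth` — with jittered restarts, followed by a deterministic
integer scan of `npop` around the simplex solution (ties going to fewer
ecotypes).

`profile_ci()` computes approximate 95% intervals by varying one parameter
over a grid (two log-decades; for `npop`, additionally the contiguous
integers around the estimate, since the likelihood of an integer parameter
is not smooth) while holding the others fixed, keeping values whose relative
likelihood stays above `exp(-qchisq(0.95, 1)/2) ~ 0.1465`. When the fitted
likelihood is zero the interval is reported as the full grid span and
flagged unbounded rather than invented.

## Recursive demarcation

`demarcate()` walks a rooted tree depth-first. For each clade it computes
the clade's own binning curve and scans `npop = 1..min(|S|, 12)` with
`omega` and `sigma` held at the global fit (full per-clade refitting would
be quadratic in tree size and is not what the recursion needs — only the
`npop = 1` decision). A clade whose maximum-likelihood ecotype number is one
is demarcated whole; otherwise the walk descends. Two deliberate departures
from the global matching rule apply *within clades*:

* the match is exact (`tolerance = 1`). Per-clade curves involve small
  integer counts, and a ±10% band rounded outward to integers degenerates to
  ±1 there — under it, a simulated count of 1 "matches" an observed count of
  2, so one ecotype could never be rejected for a two-cluster clade.
* the full-identity criterion (the distinct-sequence count) is dropped from
  the per-clade grid. That point measures pure microheterogeneity, which the
  globally fitted rates already absorb, and it is the one curve point whose
  exact reproduction is essentially a coin flip; requiring it would starve
  every clade of likelihood and fragment the partition.

Monte-Carlo noise makes strict argmax selection unstable when several
`npop` values explain a clade equally well (e.g. a clade of identical
sequences at a depth too shallow for the criteria to resolve). Ties are
therefore resolved parsimoniously: the smallest `npop` with positive
likelihood within two binomial standard errors of the maximum wins. Trees
come either from the user (newick) or from neighbor joining on the
Jukes–Cantor matrix with midpoint rooting (outgroup rooting available via
`root_outgroup()`); NJ's occasional negative branch lengths are clamped to
zero and reported.

## Distances and sequence bookkeeping

Pairwise comparisons use *pairwise deletion*: columns where either sequence
carries a gap or an IUPAC ambiguity code are excluded (a `strict` mode
errors on them instead). The distance correction is Jukes–Cantor,
`d = -(3/4) log(1 - 4p/3)` — the canonical one-parameter similarity
correction, monotone in `p`, so every ordering statement made on corrected
distances holds on uncorrected ones too. Percent-divergence summaries
(`group_divergence()`) report uncorrected `100 * p`, the natural scale at
0–5% where the correction is negligible and within-group zeros stay exactly
zero. `clone_tally()` treats degapped, uppercased equality as clone
identity. `dilution_density_bound()` converts a dilution-to-extinction
endpoint into a lower bound on source density, `1/(dilution x volume)`, with
a default inoculum volume of 0.1 mL (an explicit, configurable assumption).

## In-silico PCR and RFLP

Primer matching expands IUPAC codes to base sets and calls a position a
match when the sets intersect; both strands are scanned (the reverse
primer's reverse complement on the plus strand). Mismatch counting is
positionally uniform — no 3'-end weighting — which suffices for
perfect-match screening; melting behavior is out of scope. Coordinates are
0-based half-open, minus-strand hits reported in plus-strand coordinates.
Restriction digestion knows MspI (`C^CGG`) and HhaI (`GCG^C`), cuts at every
(possibly overlapping) site, and always conserves total length. RFLP typing
groups digestion profiles whose size-ordered fragments agree within a
relative 5% (absolute floor 4 nt, mimicking 2% agarose gel resolution) per
enzyme, taking the transitive closure — exactly how bands would be called
equivalent on a gel; tolerance 0 demands identity.

## Fragment-based ANI

`ani_twoway()` follows the fragment-based convention: 1020-nt
non-overlapping query fragments, retained when they map at >= 70% identity
over >= 70% of their length; one-way ANI is the mean identity of retained
fragments, two-way ANI the mean of both directions. The mapper is a
k-mer-seeded (k = 15, probed every 5 bases) banded aligner: fragment k-mers
vote on reference diagonals, the best few diagonals are aligned with a band
of 5% of the fragment length (fragment global, reference window local), and
identity is matches over fragment length. Pure substitution divergence keeps
hits on one diagonal, so the band mainly buys robustness; with heavy
indels a practitioner should expect slightly conservative identities
relative to a full local aligner. Fragments never span record boundaries in
multi-record genomes.

## Clade-by-environment association

The demarcation itself uses no environmental data; whether demarcated
clades *mean* anything ecologically is a separate question. The package
formalizes it with eta-squared (`SS_between/SS_total`) of an environmental
variable (temperature, pH) across the demarcated groups, with a permutation
null from random relabeling and the add-one p-value estimator
`(1 + #{perm >= obs}) / (1 + n_perm)`, which is never exactly zero.
Eta-squared is affine-invariant in the variable. This is a formalization
supplied by the package — reports label it as such — not a re-derivation of
any published effect size.

## What the synthetic generators emulate — and what they do not

`simulate_ecotype_alignment()` builds ground-truthed alignments in the
survey's regime: each ecotype receives a disjoint block of diagnostic
positions (guaranteeing the configured minimum between-ecotype divergence,
default 3%), and each sequence up to `within_div * L / 2` private mutations
at non-diagnostic positions (microheterogeneity of a few nucleotides,
default max 0.3%). Realized divergences are re-measured and the draw
retried within a bounded budget, so the advertised bounds are guarantees,
not expectations. This is a *structural* emulation: real 16S data add
alignment error, chimeras, rate heterogeneity across sites, and
intermediate divergences that blur cluster boundaries; recovery results on
synthetic data therefore demonstrate correctness of the machinery, not
field performance. Genome pairs are i.i.d.-substituted (no rearrangements,
no indels, no horizontally transferred islands), which is exactly the
regime where fragment ANI should equal `100(1 - divergence)`; clone
libraries reproduce copy-number structure exactly; site metadata draws
independent normals per ecotype, with zero spreads giving exact profile
means.

## Numerical choices and degenerate inputs

* Jukes–Cantor saturates at `p = 0.75`; such pairs return a configurable
  `saturated` value with a warning rather than `NaN`.
* Clustering thresholds compare with a `1e-12` slack so criterion
  boundaries behave predictably on exactly-representable distances.
* A clade of identical sequences has no natural coalescent depth; per-clade
  depth is floored at half an expected substitution over the alignment
  (`0.5/L`).
* Complete-linkage merge heights are non-decreasing, so binning curves are
  monotone by construction; the constructor asserts it anyway.
* All stochastic entry points take integer seeds and derive substreams
  reproducibly; two runs with the same seed are byte-identical end to end,
  including pipeline artifacts.

## Problem sizes

The recovery experiments shipped with the package run at 40 sequences of
750 nt, ecotype counts 1–6, 200 Monte-Carlo replicates per likelihood
evaluation and 100 per demarcation scan — sizes at which a full
fit-plus-demarcation completes in seconds thanks to the compiled simulator,
while remaining in the regime the surveys themselves occupy (tens of clones
per site, partial 16S fragments). Larger alignments scale as the square of
the sample count in the distance and linkage steps.

## Known limitations

* The model has no recombination, no selection coefficients, and no
  per-site rate heterogeneity; `npop` is assumed constant over the depth.
* Demarcation inherits the tree: a wrong topology (e.g. from NJ on
  saturated distances) misleads the clade walk.
* The match-fraction likelihood is a simulated, banded pseudo-likelihood;
  its profile intervals are approximate by construction.
* The ANI aligner is tuned for the >= 70% identity regime; far below that,
  seeding fails by design (fragments are reported unmapped rather than
  force-aligned).
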