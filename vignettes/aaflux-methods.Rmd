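---
title: "Methods: parsimony polarization, flux and duplication-clade asymmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parsimony polarization, flux and duplication-clade asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaflux)
```

## What the package computes

`aaflux` turns per-family protein alignments plus rooted gene trees and one
rooted species tree into a relational table of polarized amino-acid
substitutions, and derives from it four families of genome-scale
descriptors of protein evolution:

1. **Flux** — for each amino acid, how often it was created (`C`, as a
   substitution destination) versus removed (`R`, as a source), summarised
   as the net relative gain `D = (C − R) / (C + R)`; analogously per
   reciprocal amino-acid pair.
2. **Radicality** — per unambiguous substitution, the signed and absolute
   polarity change `ΔP = polarity(dest) − polarity(source)` and an
   exchangeability value `EX[source, dest]` (low = radical).
3. **Ka/Ks by duplication status** — per family, amino-acid substitutions
   per retained site (`Ka`) over the branch-length sum in units of
   synonymous substitutions per 4-fold degenerate site (`Ks`), computed
   separately for duplicated branches, single-copy branches of families
   with duplications, and families without any duplication.
4. **Duplication-clade asymmetry** — for the two clades descending from
   each duplication node, heterogeneity of substitution counts
   (chi-square) and of radicality (Welch t), under Benjamini–Hochberg and
   Bonferroni control.

## Polarization by most-parsimonious reconstructions

Substitutions are inferred per alignment column under unordered (Fitch)
parsimony on the rooted gene tree. Gaps retained after masking and `X`
are wildcards: they carry the full state set at zero cost and never
nominate events on their own terminal branch.

A site's *most-parsimonious reconstructions* (MPRs) are all ancestral
labelings attaining the minimum change count. An event — a branch plus a
source→destination direction — is **unambiguous** when it is identical in
every MPR; because the tree is rooted, this is equivalent to polarization
by the outgroup side of each branch. Every remaining event slot (the
parsimony score minus the number of unambiguous events) is emitted once
as an **ambiguous** record carrying all candidate (branch, direction)
placements as alternatives. A direct corollary is that a change whose
direction flips across the root — e.g. a two-leaf tree with states A and
C — is always ambiguous.

Rather than materialising the MPR list, classification uses an
inside–outside dynamic program: for the branch from parent *u* into node
*v*, the joint cost of fixing `u = x, v = y` over the whole tree is

```
J[x, y] = outside(u = x | v excluded) + [x ≠ y] + inside(v = y)
```

An event `x → y` is in *some* MPR iff `J[x, y]` attains the global
minimum, and in *every* MPR iff `(x, y)` is the unique minimiser of `J`.
This is exact for any number of MPRs, so the enumeration cap
(`mpr_cap`, default 10,000 labelings per site in `enumerate_mprs()`)
only truncates the explicit labeling list, never the event
classification. The tests verify the DP against full enumeration and
against brute-force labeling search on small random instances.

Record emission order is deterministic (site, then branch preorder
index), which is what makes database round-trips byte-comparable.

### Indel masking

Columns lying inside a run of **two or more** consecutive gap characters
in *any* sequence are excluded from the analysis; isolated single-gap
columns are retained with the gap read as missing data. Only the gapped
run's own columns are masked — no flanking context is removed, the
minimal reading of an "area with more than one indel in a row". Masked
columns are excluded from the substitution search and from the site
counts entering `Ka`; the latter choice (rather than raw alignment
length) keeps the `Ka` denominator consistent with the space actually
searched for substitutions.

## Reconciliation and duplication contexts

Gene trees are labeled by standard LCA reconciliation: each node maps to
the species-tree LCA of its descendant species, and a node is a
duplication iff its mapping equals that of at least one child. This is
deterministic and exact when the gene tree is taken as correct; a
pre-reconciled tree with `D`-suffixed internal labels can be supplied
instead (`use_labels = TRUE`) for workflows that run a rearrangement-aware
reconciler upstream. No gene loss is inferred.

Branch contexts implement the rule that a substitution belongs to a
duplicated gene when its placement is *more terminal* than the
duplication: branches strictly below a duplication node are `duplicated`;
the duplication node's own incoming branch is not (its substitutions
predate the duplication). All other branches are single-copy, qualified
by whether the family contains any duplication. `depth_ks`, the
branch-length sum from the root to the duplication node, is reported as
an explicit age *proxy* in Ks units; no absolute dating is attempted.

"Terminal" duplications — both clades being single terminal branches —
are flagged so the asymmetry battery can be rerun without them
(`exclude_terminal = TRUE`), the variant that guards against pseudogene
contamination of terminal branches.

## Counting ambiguous substitutions

Ambiguous substitutions enter rate and count statistics; they are only
excluded from radicality (whose source/destination identity they lack).
Two weighting modes are available (`ambiguous_weighting`):

* `"split"` (default): each alternative placement receives weight
  `1/n_alternatives`, so each event contributes one unit in total and
  flux conservation `ΣC = ΣR = N` holds exactly for any branch filter;
* `"unit"`: each alternative counts 1, the generous upper bound.

Family-level whole-tree totals always count each ambiguous event once;
per-class and per-clade tallies distribute it across the classes of its
alternative placements under the chosen mode.

## The test battery

Per duplication, four statistics are tested between clade 1 and clade 2
(clade 1 holds the lexicographically smallest leaf, a pure tie-break):

* total and unambiguous substitution counts: chi-square heterogeneity
  with expected counts proportional to the clades' Ks sums
  (`chi2_null = "ks_weighted"`; `"equal"` gives the equal-split null),
  df = 1, no continuity correction by default (`chi2_yates`);
* mean |ΔP| and mean EX: Welch's unequal-variance t-test (pooled optional
  via `pooled_t`), performed only when both clades hold at least two
  unambiguous substitutions — smaller clades are skipped as ineligible,
  not tested.

All p-values are two-sided. Multiple-test control (BH at
`fdr_levels`, default 0.01 and 0.05; Bonferroni at `bonferroni_alpha`,
default 0.01) is applied per statistic with *m* equal to the number of
tests actually performed; skipped tests stay `NA` and do not inflate
*m*. The clade-asymmetry summary statistic is `A = |x1 − x2|/(x1 + x2)`,
chosen for boundedness in [0, 1] and symmetry under clade exchange
(0/0 is left undefined).

The sign test is exact binomial, two-tailed by doubling the smaller
tail (capped at 1), with ties excluded by the caller.

## Radicality scales

The default polarity scale is the Grantham (1974) polarity (AAIndex
GRAR740102), bundled as a plain-text table together with the companion
composition and volume scales. Exchangeability lookups are
direction-sensitive (`EX[source, destination]`) and any 20×20 matrix can
be supplied via `aa_scales(exchangeability_file = )`. The bundled
default, `synthetic_exchangeability()`, is a synthetic stand-in
constructed from the Grantham chemical distance,
`EX(x, y) = exp(−d(x, y)/100)`: it reproduces the conservative-to-radical
ordering of replacements (Leu→Ile ≈ 0.95, Cys→Trp ≈ 0.12) but is
symmetric, unlike experimentally measured exchangeability — analyses
that depend on direction-sensitive exchangeability should load a
measured matrix.

## The simulator: what it emulates and what it does not

`simulate_family()` generates families with a fully known history for
validation: duplications arise as a Poisson birth process (rate
`dup_rate` per lineage per unit branch length) along a species tree,
copying the whole sequence, with both copies evolving independently and
no loss; sequences evolve site-independently under a 20-state Markov
model whose intensity is `subst_rate` × branch length, so branch lengths
double as Ks and whole-tree Ka/Ks is recoverable against the known rate.
Events are drawn with exponential waiting times and logged with their
branch and within-branch time. The `"biased"` model scales rates by
`exp(−strength · ΔP)`, favouring polarity-lowering replacements, to
reproduce the negative flux–polarity correlation in silico.

Defaults emulate the magnitudes of a 12-genome insect-scale study:
12 species, root-to-tip depth 1.5 Ks, `subst_rate = 0.08` (so whole-tree
substitutions per site land near 0.4 and whole-tree Ka/Ks near 0.08),
`dup_rate = 0.08`, 500 columns. Tests and the acceptance script use
smaller, explicitly stated sizes (8 species, 150–200 columns, 50
replicate families; 5,000 columns for the rate-convergence check) so the
whole suite runs in about a minute.

What the simulator does **not** model — and what passing tests therefore
do not establish about real data: gene loss (so reconciliation is exact
by construction; real gene trees violate this), indel evolution (gap
blocks are injected post hoc only to exercise the mask), rate
heterogeneity across sites, selection, and gene-tree estimation error.
The recovery results (100% of single-event sites in the low-rate regime)
are a correctness check of the polarization machinery, not a statement
about the error rate on empirical alignments.

## Numerical and degenerate-input conventions

* Alignment columns are 1-based in every output table, 0-based only
  internally.
* `D` and `A` statistics are undefined (NA) at 0/0 and excluded from
  means; pairs with zero total count are dropped from pairwise analyses
  with the dropped count reported.
* `Ka/Ks` is NA when the class's Ks sum is 0; substitutions present with
  zero Ks additionally log a warning.
* Chi-square tests with an expected count below 1 are computed but
  flagged `low_expectation`; both-counts-zero is flagged `undefined`.
* Zero-variance-in-both-groups t-tests return t = 0, p = 1 when means
  agree (and p = 0 otherwise), flagged `degenerate`.
* A basal trifurcation (unrooted tree) is rejected with instructions to
  supply a root rather than auto-rooted.
* All randomness is seed-mandatory; a fixed seed reproduces simulations
  byte-identically.

## Relational output

`write_database()` emits `families`, `tree_nodes`, `substitutions` (one
row per unambiguous *and* ambiguous substitution),
`substitution_alternatives` (one row per candidate placement of an
ambiguous record), `duplications`, `dup_clades`, `family_stats`, `flux`
(+ `flux_pairs`) and `asymmetry_tests`, as SQLite (canonical; queryable
with any SQL client) or as TSV mirrors, plus a `meta` table carrying the
species tree and the full configuration. Reading back returns identical
records, and `check_integrity()` verifies the foreign-key relations.
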