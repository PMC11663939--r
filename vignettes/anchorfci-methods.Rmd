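---
title: "Anchored causal discovery under latent confounding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored causal discovery under latent confounding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorfci)
```

## The problem

Constraint-based causal discovery infers, from observational data alone,
which statistical associations among a set of variables are plausibly causal
and which are spurious. When latent confounders cannot be excluded — the
normal situation in epidemiology and systems biology — the appropriate
search space is the space of *maximal ancestral graphs* (MAGs): mixed graphs
with directed edges (`x -> y`: x is a cause of y) and bidirected edges
(`x <-> y`: a latent common cause, no causal relation in either direction),
constrained to have no directed or almost-directed cycles. What is
learnable from data is the Markov equivalence class of MAGs, summarised by
a *partial ancestral graph* (PAG): an edge mark is a tail when every model
in the class has an ancestral relation there, an arrowhead when none does,
and a circle when the class disagrees.

FCI-family algorithms learn a PAG from conditional-independence (CI) tests.
This package implements the conservative RFCI variant — order-independent
stable skeleton, RFCI's unshielded-triple retention, majority-rule triple
classification, and the complete orientation rules R1–R10 — and extends it
with *anchors*: variables known a priori not to be caused by any variable
of interest. Genotypes relative to phenotypes are the canonical case: a
SNP's genotype may cause a trait, never the reverse. The anchored
algorithm, `anchorfci()`, makes three adaptations:

1. **Reliable-anchor selection.** Anchor candidates are screened for
   association with the interest set (a covariate-adjusted nested LRT,
   threshold `screen_alpha`, default `1e-5` to mimic a genome-wide
   suggestive threshold). A first-pass discovery run then keeps only
   candidates adjacent to the interest set whose every unshielded triple is
   unambiguous under the majority rule. We read "forms unambiguous
   triples" universally — one ambiguous triple disqualifies — because a
   single ambiguous triple at an anchor can corrupt the very orientations
   the anchor is meant to secure; the weaker existential reading admits
   anchors that carry unusable orientation information.
2. **Adapted skeleton.** No CI test between two anchors may condition on an
   interest variable. A minimal separating set can always be shrunk to
   ancestors of the tested pair, and interest variables are non-ancestors
   of every anchor, so the restriction never costs correctness; it removes
   exactly the tests with the least power to be informative.
3. **Enforced arrowheads.** After v-structure orientation, every
   anchor–interest edge receives an arrowhead at the interest endpoint; the
   orientation rules then run with those marks fixed, and the result is
   checked for ancestral validity. Anchor–interest edges in the output can
   therefore only be `<->` (spurious), `->` (causal) or `o->`
   (undecided origin, decided direction). A pre-existing tail at an
   interest endpoint contradicts the declared partial order; the run aborts
   with diagnostics rather than silently overriding, since such a
   contradiction signals unfaithfulness that the user must see.

The two-phase architecture (selection pass, then a final pass on interest
variables plus the selected anchors only) keeps unreliable candidates out
of the final graph entirely. Phase 1 runs unfiltered; the filter only
matters for anchor–anchor pairs and applying it in phase 1 would be
harmless, but the unfiltered first pass keeps the selection diagnostics
comparable with a plain conservative run.

## The mixed-data CI test

Pairs are tested symmetrically: for variables $V_i, V_j$ and conditioning
set $S$, two nested likelihood-ratio tests compare the regression of $V_i$
on $S$ against $S \cup \{V_j\}$, and vice versa, using the family implied
by the outcome's type — Gaussian linear for continuous, logistic for
binary, multinomial log-linear for multinomial (SNP-coded) variables.
Discrete predictors enter as level-indicator contrasts. The two p-values
are merged as

$$p = \min\big(2\min(p_1, p_2),\ \max(p_1, p_2)\big),$$

which is symmetric in the pair, never exceeds the Bonferroni-2 bound, and
equals $p$ at the fixed point $p_1 = p_2 = p$. Continuous variables are
passed through the rank-based inverse-normal transform (Blom offset
$c = 3/8$) once, up front, for use as Gaussian outcomes; raw values serve
as predictors. Transforming once rather than per-test keeps the test
deterministic in the pair and lets results be cached, which in turn makes
the symmetry exact rather than asymptotic. Fixed covariates (e.g. sex,
age, age², ancestry components) are appended to every conditioning set and
never count toward the conditioning-size cap.

Numerical policies: a non-convergent or separated regression is treated as
evidence of *dependence* (p-value 0, flagged), because a falsely accepted
independence cascades into wrong orientations while a falsely kept edge
only costs informativeness. Tests run at `alpha = 0.05` with no
multiplicity correction, for the same asymmetry-of-risk reason: corrections
designed to limit false dependencies inflate false independencies. Missing
values are rejected outright — imputation quality is a modelling decision
that should happen upstream, not silently inside a discovery loop.

## Conservative orientation

Every unshielded triple is classified by majority vote over all separating
subsets (up to the conditioning cap) drawn from either endpoint's adjacency
set: with $q$ the fraction containing the middle node, $q < 1/2$ is a
collider, $q > 1/2$ a non-collider, and $q = 1/2$ ambiguous. Ambiguous
triples block every orientation that would use them (v-structures, R1, R3).
When no separating subset is found in the vote, the stored skeleton sepset
decides membership — an unshielded pair always has one. Conflicting
demands on an already-invariant mark keep the earlier mark and log a
conflict; the fit is flagged unstable. Ties in processing order are broken
lexicographically, so the output is invariant to the input column order.

R5–R7 orient selection-bias (undirected) edges; this package models no
selection bias (the graph class forbids tail–tail edges) and gates those
rules off. R4 (discriminating paths) consults the stored separating sets
and logs every firing so orientation provenance can be audited.

Plain `rfci()` returns its PAG unchecked, attaching any ancestral-validity
violations as a diagnostic — on unfaithful finite samples the rule closure
can produce cycles, and the classic algorithm's output is defined anyway.
`anchorfci()` validates and aborts, as the enforcement step demands.

## What the generator emulates

`random_anchored_mag()` draws the benchmark's data-generating systems:
three exogenous three-level multinomial anchors, each with one interest
child; five Gaussian interest variables with each ordered pair connected
with probability 0.4 along a random topological order; one latent
confounder over a random interest pair, present with probability 0.5.
Structural coefficients have magnitude uniform on $[0.3, 1.0]$ with random
sign; anchors enter children through per-level shifts; noise is unit
Gaussian; anchor level probabilities are $(0.5, 0.3, 0.2)$, a plausible
minor-allele-frequency-like skew. These values are fixed package defaults:
published descriptions of such benchmarks rarely print edge densities or
coefficient laws, and all downstream comparisons are made within this
design, never across designs.

Two features of real cohort data are deliberately absent: measurement
error, and weak effects below the $0.3$ coefficient floor. The floor keeps
most edges detectable at $N \ge 500$, so absolute error levels here are
lower than in benchmarks whose coefficient laws include near-zero effects
(where some edges remain undetectable at any realistic sample size, and
absolute scores stay high even at $N = 10^4$). Passing the benchmark
therefore certifies the *comparative* claims — anchored discovery
dominates the plain conservative baseline at every sample size, both
improve with $N$, anchor counts grow with $N$ — not any absolute error
level on real data.

The benchmark scores a run by the SHD-difference over interest-pair edges:
$\mathrm{SHD}(\text{inferred}, \text{true MAG}) -
\mathrm{SHD}(\text{population PAG}, \text{true MAG})$, where SHD counts 1
per adjacency disagreement and 1 per differing endpoint mark on shared
edges, and the population PAG is computed by running the same engine with
an m-separation oracle. Zero means "as informative as the equivalence
class allows"; negative values are possible only with background knowledge
and mark genuine gains beyond the class. One data seed serves each
(system, replicate) pair across all sample sizes, so trends in $N$ are
paired comparisons. Paired one-sided Wilcoxon signed-rank tests compare
the algorithms on per-run score differences. Failed runs (an aborted
anchored fit on an unfaithful draw — a few percent at $N = 500$) are
excluded pairwise and reported.

Desk-scale defaults used by the acceptance script and tests are 10 systems
× 5 replicates at $N \in \{500, 1000\}$, a size chosen so the whole
benchmark completes in minutes while the paired Wilcoxon comparison is
still decisive.

## Effects

For each definitely directed edge `x -> y` among interest variables the
package checks *visibility* (a graphical guarantee that x and y share no
latent cause), searches for a generalized-backdoor adjustment set $Z$ —
non-descendants of x blocking every definite-status backdoor path —
preferring smaller sets (cap 4 by default), re-validates the set
independently of how it was found, and estimates
$E(Y \mid do(X = x))$ (or $P(Y = 1 \mid do(X = x))$ for binary outcomes)
by averaging fitted regression responses over the observed adjustment and
covariate values. The estimator divides by $N$ (an empirical average):
interventional probabilities must lie in $[0, 1]$. Confidence intervals
are nonparametric bootstrap percentiles (default $B = 500$), chosen for
its distribution-free coverage at these sample sizes rather than any
closed-form delta-method variant, which would need case-by-case derivation
per family. Continuous outcomes can be modelled on a log or rank-INT scale
(`transform=`), with naive smearing back-transformation (`smearing =
TRUE`) for the log scale; more refined back-transformations are out of
scope and estimates are otherwise reported on the modelling scale. Default
grids are observed deciles for continuous treatments and observed levels
for discrete ones, so estimates stay within support; extrapolation warns.

## Known limitations

* The conditioning-size cap trades informativeness for robustness; the
  cohort-style workflow caps at 2 while the benchmark runs uncapped.
  The cap never compromises soundness, only completeness.
* The discriminating-path rule uses stored sepsets rather than re-testing
  along the path; under the m-separation oracle this is exact, and every
  firing is logged for audit on finite samples.
* Bidirected-edge-rich true graphs make anchored gains smaller: enforcement
  adds arrowheads that the equivalence class often already implies there.
* Effect estimation supports continuous and binary outcomes; multinomial
  outcomes are reported as skipped.
* No selection-bias modelling anywhere (graph class, rules, generator).
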