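# anchorfci

Causal discovery for mixed genotype/phenotype data under latent
confounding, with **reliable anchors**.

## The problem

Given observational data on a set of *interest variables* (phenotypes,
clinical traits) we want to know which associations are causal, in which
direction, and which are spurious — without assuming that all common
causes were measured. Constraint-based algorithms of the FCI family answer
this by testing conditional independencies and returning a **partial
ancestral graph** (PAG) over the variables: `x -> y` means x causes y in
every model compatible with the data, `x <-> y` means the association is
purely due to latent confounding, and a circle mark (`o`) means the data
cannot decide that endpoint.

This package implements the conservative RFCI variant of that family
(order-independent stable skeleton, majority-rule triple classification,
complete orientation rules R1–R10) and extends it with *anchors*:
variables known a priori not to be caused by any interest variable — SNP
genotypes relative to phenotypes being the canonical example. The anchored
algorithm:

1. screens anchor candidates for association with the interest set
   (covariate-adjusted nested likelihood-ratio tests, default threshold
   10⁻⁵);
2. keeps as **reliable anchors** the candidates that are adjacent to the
   interest set and form only unambiguous triples under the majority rule;
3. re-runs the skeleton search with anchor–anchor tests never conditioning
   on interest variables (which provably loses nothing), enforces an
   arrowhead at the interest end of every anchor edge, completes the
   orientations, and validates the result as an ancestral graph.

Anchor–interest edges in the output are only ever `SNP <-> trait`
(spurious), `SNP -> trait` (causal) or `SNP o-> trait` (direction known,
origin undecided) — and the added arrowheads let the rules recover tails
(definite causal statements) that are unreachable without background
knowledge.

Independence on mixed data is tested symmetrically: both
`P(Vi|S) = P(Vi|Vj,S)` and `P(Vj|S) = P(Vj|Vi,S)` via nested
likelihood-ratio tests (Gaussian / logistic / multinomial log-linear by
outcome type, rank-based inverse-normal transform for continuous
outcomes), merged as `min(2·min(p1,p2), max(p1,p2))`.

The package also scores inferred graphs (structural Hamming distance and
an SHD-difference benchmark against the population PAG), assesses edge
stability by bootstrap, and estimates identified causal effects
(`E(Y|do(X=x))`) by edge visibility, the generalized backdoor criterion
and covariate adjustment with bootstrap intervals.

## Worked example

An 8-node system with three SNP-like anchors (`G1..G3`, multinomial) and
five Gaussian traits (`A..E`), including latent confounders:

```r
library(anchorfci)
sys <- toy_anchor_system()        # known MAG: G1->A, G2->D, G3->B,
                                  # A->C, B->C, B<->D, B<->E, C<->E
dat <- simulate_mixed_data(sys, 5000, seed = 1)
fit <- anchorfci(dat, sys$roles, attr(dat, "types"), screen_alpha = 1)
fit
```

```
anchorFCI fit
  5 interest variables, 3/3 anchor candidates selected
  alpha = 0.05, max conditioning size = Inf
  PAG edges:
    A --> C
    B --> C
    B <-> D
    B <-> E
    C <-> E
    A <-o G1
    D <-o G2
    B <-o G3
    E <-o G3
```

Reading the output: all three candidates were selected as reliable
anchors; every anchor edge points into the trait (`A <-o G1` is
`G1 o-> A`); the latent-confounded pairs were recognised as spurious
(`<->`); and the tails on `A --> C` and `B --> C` are *definite causal*
statements that plain RFCI could not orient — on this data the
unanchored run leaves them as `o->` at best. The extra `E <-o G3` edge is
a finite-sample artifact of this particular draw; `bootstrap_stability()`
quantifies how reproducible each edge type is across resamples, and
`effects_report()` turns the visible directed edges into interventional
estimates.

The same functions accept real data: `read_dataset("data.csv",
"roles.yaml")` validates column types (continuous / binary / multinomial),
roles (interest / anchors / fixed covariates such as sex, age, age²,
ancestry components) and completeness, and `anchorfci(..., max_cond = 2)`
caps conditioning-set sizes as is advisable for cohort-sized samples.

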