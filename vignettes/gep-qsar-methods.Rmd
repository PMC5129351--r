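---
title: "Methods: evolving symbolic carcinogenicity rules with gepqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolving symbolic carcinogenicity rules with gepqsar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gepqsar)
```

## Scope and model

`gepqsar` classifies aromatic amines as rat-liver carcinogens (label 1) or
non-carcinogens (label 0) from eight molecular descriptors, by evolving a
single arithmetic expression — a symbolic rule — with gene expression
programming (GEP), and compares it against a single-hidden-layer
perceptron. The modelling assumptions are minimal but worth stating:

* the descriptors carry enough signal that a threshold on one arithmetic
  expression separates the classes usefully;
* the decision convention is fixed: a compound is called a carcinogen
  exactly when the rule value is *strictly* positive. A value of exactly 0
  is assigned to class 0 — with real-valued descriptors ties have measure
  zero, and when they do occur (integer-valued descriptors, degenerate
  rules) the conservative reading for a screen is chosen deliberately;
* the training labels are binary and both classes are present; single-class
  inputs are rejected as errors everywhere.

## Genotype, decoding and protected evaluation

A chromosome is a fixed-length token string over an operator/terminal
alphabet: head of length $h$ (operators or terminals), tail of length
$t = h(n-1)+1$ (terminals only), where $n$ is the maximum operator arity.
The tail formula guarantees that breadth-first (level-order) decoding — the
Karva convention: the first symbol is the root, each level is filled left
to right, one token per open child slot — always closes before the string
ends; trailing unused tokens are legal and ignored.

Level-order decoding is *not* the same as prefix (recursive-descent)
reading. The two happen to coincide on the classic worked example
`* b + a - c d` → `b*(a+(c-d))`, but diverge in general (e.g.
`Q * + - a b c d` is `Q((a+b)*(c-d))` level-order and `Q((a-b+c)*d)` as
prefix). The test suite therefore validates the shipped index-offset
decoder against an independently written queue-based *level-order* decoder,
not a prefix reader.

Two stock alphabets are provided: the basic set $\{+,-,*,/,Q\}$ ($Q$ =
square root) and the extended set $\{+,-,*,/,\mathrm{mod},\exp,\log,\sin,
\tan\}$ used for rule evolution over the eight descriptors. Numeric
constant terminals are supported but disabled by default; tokens are
case-insensitive and stored lowercase.

Every operator is *protected* so that any genotype evaluates to a finite
number on any finite input — standard genetic-programming practice, since
the source material does not specify the behaviour of partial operations:

| operation | protection |
|---|---|
| $a/0$ | 1 |
| $\log a$, $a \le 0$ | 0 |
| $Q(a)$, $a<0$ | $\sqrt{|a|}$ |
| $\exp a$ | exponent clamped to $\pm 700$ |
| $\mathrm{mod}(a,0)$ | 0 (else floating remainder) |
| $\tan a$ | clamped to $\pm 10^6$ |
| any NaN / overflow | 0 / magnitude capped at $10^{300}$ |

The final clamp (applied at every node) is what turns the per-operator
protections into a global finiteness guarantee, which the suite checks by
property testing over random chromosomes and extreme inputs.

## Fitness: the published form and the operational form

The published rule-significance components are
$$\mathrm{consig}(R) = \left(\frac{p}{p+n} - \frac{P}{P+N}\right)\frac{P}{P+N},
\qquad \mathrm{compl}(R) = \frac{p}{P},$$
with $p, n$ the covered positives/negatives and $P, N$ the training class
totals. Two readings in the source material required decisions:

* the prose definition of $p,n,P,N$ is not usable as written (it describes
  all four symbols as whole-set counts); the adopted reading — coverage
  counts vs class totals — is the only one under which the formulas are
  informative, and it is flagged here rather than silently assumed;
* the published composite fitness, $\mathrm{consig}(R)\cdot
  \ln(\mathrm{compl}(R)-1)$ for $\mathrm{consig} \ge 0$, is degenerate:
  $\mathrm{compl}\le 1$ always, so the log argument is never positive and
  the protected log makes the product identically zero. The package keeps
  this form verbatim behind `rule_fitness(..., mode = "printed")` for
  fidelity (a test pins the degeneracy), and drives the actual evolution
  with `mode = "hits"` — the count of correctly classified training
  compounds — which is the simplest fitness consistent with the published
  classification rule. `consig` is defined as 0 when a rule covers nothing
  (the limit of the base-rate comparison).

A brute-force test verifies `consig`/`compl` against independent arithmetic
on every coverage grid with $P, N \le 12$, including the bound
$\mathrm{consig} \le \frac{P}{P+N}\bigl(1-\frac{P}{P+N}\bigr)$ with
equality exactly for rules with pure positive coverage.

## The generational loop and its parameters

Each generation: evaluate fitness; copy the elites; refill the population
by roulette (fitness-proportionate) selection — uniform when all fitness is
zero; apply point mutation, IS and RIS transposition per individual and
one-/two-point recombination per adjacent pair. Gene transposition and
gene recombination are retained in the interface as the single-gene
degenerate cases (identity and whole-chromosome swap) — the published
model exhibits a single expression, so multi-gene chromosomes with linking
functions are out of scope. Defaults (`gep_control()`):

| parameter | default | rationale |
|---|---|---|
| population | 100 | canonical desk-scale GEP setting |
| generations | 500 | upper budget; runs stop early at a perfect fit |
| head length | 7 | tail 8 with binary operators; rich enough for the planted rules used here |
| mutation | 0.05 / position | keeps ~1 edit per chromosome |
| IS / RIS transposition | 0.1 each | canonical |
| one- / two-point recombination | 0.3 each | canonical |
| elitism | 1 | makes best-ever fitness non-decreasing (tested) |

The source material states none of these values (only a runtime
anecdote), so they are this package's own choices, made once. Operator
closure — every operator maps valid chromosomes to valid chromosomes — is
property-tested over $10^4$ random cases; cut indices are shared between
recombination parents, so tail positions only ever receive tail material.
Evolution is bit-reproducible given `seed`, and `stop_when_perfect`
(default on) ends a run when a rule classifies every training compound
correctly.

## Descriptor preprocessing and allocation

`prefilter()` operationalizes the two vague descriptor-selection rules
(descriptors must be "common to most compounds" and non-degenerate) with
explicit defaults: coverage $\ge 0.9$ and $\ge 2$ distinct values, both
configurable. `collinearity_filter()` implements the $|r| < 0.8$ rule
greedily and deterministically: take the offending pair with the largest
$|r|$, drop the member with the larger mean absolute correlation to the
remaining descriptors, ties to the later column. On the packaged
correlation matrix (max off-diagonal $|r| = 0.730$) it retains all eight
descriptors, matching the benchmark's selection.

`random_split()` reproduces the published allocation procedure — encode
compounds 1..128, draw 35 distinct random encodings as the test set — as
seeded sampling without replacement; the original software's random stream
is unrecoverable, so only the procedure, sizes and exactness of the
partition are preserved.

## The perceptron baseline

`mlp()` is a from-scratch single-hidden-layer perceptron: sigmoid hidden
units, sigmoid output, online (per-pattern) backpropagation with momentum
on z-scored descriptors, hidden size from the conventional rule
$a = \lfloor(\text{attribs}+\text{classes})/2\rfloor$ (minimum 1), up to
500 epochs with early stopping after 20 consecutive epochs without
validation improvement on a 20% split, best-validation weights restored.
Learning rate 0.3 and momentum 0.2 are the standard defaults of the
desktop data-mining tool this baseline emulates; that tool's exact
behaviour is not reproduced bit-for-bit and is not a goal. With
`epochs = 0` the model degenerates to the majority-class prior —
well-defined rather than an error, so epoch sweeps can start at zero.
Training is seed-reproducible including the shuffling order; the classic
jittered-XOR task is the nonlinear sanity check. Margins — probability of
the actual class minus the best wrong-class probability, $2p_\text{actual}
- 1$ in the binary case — are computed by the same `margin_score()` used
for any classifier in the package, and GEP and MLP results flow through
the identical `confusion()`/`screening_metrics()` path.

## Screening metrics

The 2×2 layout is fixed as A = true positives, B = false positives, C =
false negatives, D = true negatives, which makes the published formulas
the textbook sensitivity $A/(A+C)$ and specificity $D/(B+D)$. The source
prose describing B and C contradicts its own formulas and is overridden —
this is the only place the package knowingly departs from the source's
words, in favour of its mathematics. Reports round to 3 decimals
(round-half-even). Note one subtlety pinned by tests: Youden's index
computed exactly from counts can differ in the third decimal from the
index computed from *already-rounded* sensitivity/specificity (0.853 vs
0.852 on the training-set counts consistent with the reported table); the
reported tables follow the rounded-inputs convention.

## Data fixtures and a documented discrepancy

The package ships, verbatim as plain text: the 8×8 descriptor correlation
matrix (including its one truncated entry, −0.18, normalized numerically
on load), the reported headline metrics per model and split, and the
per-compound experimental labels with reported GEP/MLP predictions for
both splits. Two published inconsistencies are preserved rather than
repaired, and a regression test asserts the larger one so it cannot be
silently "fixed":

* recomputing accuracies from the per-compound prediction columns gives
  0.656 (train) and 0.686 (test) for GEP — far from the reported 0.914 and
  0.829. The headline metrics table is therefore treated as the metric
  ground truth and the per-compound columns as a fixture with documented
  provenance;
* the stated split (35 test of 128, leaving 93) and the stated training
  class composition (24 + 64 = 88) disagree; the tables as shipped have 93
  training rows with 25 positives.

The published evolved rule itself is shipped as a frozen expression tree
(`aromatic_amine_rule()`), not re-parsed from text: its typography is
ambiguous where an operand abuts the two-argument `mod` and where a
fraction collapsed. The default interpretation reads juxtaposition as
multiplication; an alternative (`"bare"`, dropping the juxtaposed left
operand) is available for comparison. Both are finite everywhere under
protection; with no published descriptor values, neither can be validated
against the per-compound predictions, and no claim is made that either
matches the original software's internal genome.

## The synthetic generator: what it does and does not show

`synthetic_spec()`/`make_study()` emulate the *statistical shape* of the
study: 128 compounds of standard-Gaussian descriptors with the benchmark's
correlation structure (Cholesky factorization of the target; eigenvalue
clipping and diagonal renormalization repair a non-PSD target — a no-op
for the packaged matrix, which is positive definite), labels planted by a
known rule (default NCOS + NNOS > 0, balanced under the correlated
Gaussian law), optional independent label flips, and the 93/35 seeded
allocation. Real descriptors are not Gaussian — atom counts are small
integers, topological indices are skewed — and an optional rounding
post-step is deliberately left off by default. Consequently, passing
planted-rule recovery shows that the evolutionary machinery can find a
known signal through the package's whole pipeline; it does not certify
accuracy on real aromatic amines, whose descriptor values are not
published.

Recovery checks are stochastic; they use three fixed retry seeds declared
up front and accept the best run, which the acceptance machinery reports
as computed.

## Problem sizes and numerical choices in the shipped checks

The test suite and acceptance script size their simulations for a desk
run: 1000-chromosome decoder/oracle comparisons, $10^4$ operator-closure
cases, exhaustive metric identities over all 2×2 tables with $\le 30$
compounds and all fitness grids with class totals $\le 12$, 93/35 studies
for planted-rule recovery with population 100 and a 500-generation budget
(early-stopped), 5000-row tables for correlation-target verification
(entrywise tolerance ±0.05), and 200-pattern XOR fits. Comparisons
against hand oracles use tolerance $10^{-12}$; probabilistic assertions
use 3σ binomial bounds.

## Known limitations

* The real benchmark accuracies cannot be reproduced without the
  unpublished descriptor values; everything quantitative about real data
  in this package is confined to the shipped published tables.
* The hits fitness ignores class imbalance; on strongly imbalanced data a
  cost-sensitive fitness would be preferable.
* Single-gene chromosomes only; no parsimony pressure, niching or
  multi-objective fitness.
* The perceptron is intentionally minimal (one hidden layer, MSE loss,
  fixed learning rate); it is a comparator, not a competitive neural
  baseline.
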