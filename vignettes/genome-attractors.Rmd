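---
title: "Measuring genome attractors: semihomologous comparison and randomly encoded network ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genome attractors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqAttractors)
```

## The problem

When the same protein — cytochrome b is the motivating case — is compared
across a broad panel of organisms, groups of related organisms often show
very similar distances to a chosen reference organism, as if each group's
genomes had settled into a stable configuration: a *genome attractor*.
This package provides two independent instruments for quantifying such
structure, plus the orbit geometry built on their outputs. Group
membership is always a user decision (taxonomic), never inferred by
clustering: the instruments measure, they do not classify.

## The semihomologous model

An aligned pair of amino acids is judged through the genetic code. Let
$C(a)$ be the set of codons of residue $a$ (stop codons excluded — a
mutational path through a stop is not a one-point amino-acid
substitution). The position class is

* **R** if $a = b$;
* **#** (transition-semihomologous) if some $x \in C(a)$, $y \in C(b)$
  differ at exactly one nucleotide and that exchange is
  A$\leftrightarrow$G or C$\leftrightarrow$T;
* **\$** (transversion-semihomologous) if a single-nucleotide path exists
  but only of transversion type;
* **−** otherwise (every codon pair is two or three point mutations
  apart).

The premise is that one-point codon mutations are the dominant mechanism
in homologous proteins, so positions one point mutation apart carry more
evolutionary signal than a plain identical/different dichotomy admits.

Three conventions deserve explicit statement, because the underlying
idea does not fix them:

* **Tie-break.** When both a transition and a transversion single-point
  path exist, the position is classified **#**. Transitions are the more
  frequent mutation type, so the transition path is the more plausible
  event; the choice also makes the I/M pair under the standard code a
  **#**, which only the transition path ATA↔ATG supports.
* **Genetic code.** The classification depends on the translation table.
  Both table 1 (standard) and table 2 (vertebrate mitochondrial) are
  built in — cytochrome b is mitochondrially encoded, so table 2 is the
  natural choice for that protein — and any table can be loaded from a
  two-column file. The matrices differ in exactly seven unordered pairs
  (those touching AGA/AGG/ATA, which change role between the tables).
* **Denominators.** Positions where either symbol is not one of the 20
  standard residues — the pad character `-` introduced by length
  normalisation, ambiguity codes, stops — are *non-comparable*: they are
  excluded from the comparable length and from every percentage. Pads
  are an artifact of normalisation, not biology. The `#/$` factor is
  reported as undefined (`NA`) when the `$` count is zero, and undefined
  factors are excluded from group averages rather than silently entered
  as 0 or infinity, which would bias them.

Internally the DNA alphabet is used (U normalised to T on input).
Sequences are never aligned by the package: they are padded with `-` at
the end or cut to the common length, which mirrors how the network input
is prepared and keeps both instruments on identical footing.

## The network model

A sequence of length $L$ (default 400) is encoded by replacing each
character with a random five-bit word, giving $n = 5L$ input bits. The
encoding is drawn once per ensemble member under a seed; by default the
28 alphabet symbols (20 residues, pad, ambiguity codes) receive
*distinct* words sampled without replacement from the 32 possible, so
the encoding is information-preserving and invertible. An iid mode
(independent draws, collisions possible) is available for strict
literalism about "randomly generated" codes.

The recogniser is a fully connected three-layer perceptron
$n \to m \to k$ with sigmoid transfer $y = 1/(1+e^{-x})$ at every layer
(an option treats the input layer as pass-through, since many
frameworks do; the default applies the sigmoid to the raw bits). Hidden
and output units carry biases — the model class is needlessly
constrained without them. The hidden size follows the geometric pyramid
rule $m = \mathrm{round}(\sqrt{nk})$; at full scale
($n = 2000$, $k = 36$) this is 268.

Teaching is on-line backpropagation of the squared error with momentum:
after each pattern, $\Delta w(t) = -\eta\, \nabla E + \alpha\, \Delta
w(t-1)$ with $\eta = 0.3$, $\alpha = 0.1$ by default. Teaching sequence
$i$ (file order) takes the one-hot target with 1 at output $i$; the
orientation of the one-hot scheme is a display convention, any
consistent bijection being equivalent. Patterns are presented in fixed
order each epoch (a seeded shuffle is optional) for maximal determinism.
After each epoch the RMSE over all patterns and output units is
evaluated, and teaching stops when it drops below the target (0.001 at
full scale) or at the epoch cap (default 10,000, a safety net rather
than a tuning device; RMSE is also evaluated once before the first
update so an already-converged model is returned untouched). Weights are
initialised uniformly in $[-0.5, 0.5]$ under a per-member seed. On-line
updates may oscillate, so no per-epoch monotonicity is assumed anywhere;
what is checked is convergence itself.

Because any single random coding is arbitrary, the whole teaching is
repeated for `nVersions` members (50 at full scale), each with its own
coding and initialisation seed, both derived deterministically from one
master seed. The recognised similarity of an examined organism to
teaching organism $j$ is the arithmetic mean over members of output $j$
— a value in $[0,1]$, 0 meaning minimal and 1 maximal recognised
similarity. The gradient implementation is verified against central
finite differences in the test suite.

## Orbits, distance factors, disturbances

For ordered groups $G_1, \dots, G_r$ (nearest first, user-supplied
order) and a reference teaching output, the group similarity $s(G)$ is
the mean member similarity at that output. Picturing each attractor on a
circular orbit around the reference, the orbit radius is defined as
$1/s(G)$ and the distance factor between consecutive orbits as the
ratio of the farther to the nearer radius, which is always $\ge 1$ and
reduces to the ratio of the two mean similarities. This reciprocal
convention was a genuine design choice: the verbal definition
"inner orbit / outer orbit" conflicts with factors printed above 1, and
the ratio-of-similarities reading reproduces that numeric pattern while
keeping the geometry consistent. Factors are scale-invariant — rescaling
all similarities by a common constant cancels — which matters because
absolute ensemble outputs for non-teaching organisms are small.

A *disturbance* of a group is its mean similarity toward a teaching
organism outside its own lineage. Which outputs count as "own lineage"
is an explicit user input (no rule could be stated that decides it
automatically); the remaining outputs are ranked by mean similarity,
ties broken by teaching order.

## The synthetic generator

`generateFamily()` emulates what the real data provide: families of
protein sequences derived from a common ancestor at controlled
divergence. A random ancestor of `nCodons` codons is drawn uniformly
over non-stop codons; each descendant receives a Poisson number of
substitution events with mean `substitutionsPerSite × 3 × nCodons`;
each event picks a nucleotide site uniformly and proposes a transition
with probability $\kappa/(\kappa+2)$, otherwise one of the two
transversions; events creating a stop codon are redrawn. This is a
deliberate simplification — a codon-resampling scheme with
stop-rejection rather than a calibrated continuous-time Markov model:
the analyses need plausible, monotone divergence structure and a
verifiable transition/transversion dial, not branch-length estimates.
Defaults are 400 codons (the cytochrome b scale) and $\kappa = 2$, a
typical empirical transition bias. The generator has no selection, no
indels, no site-rate heterogeneity, and only star phylogenies; passing
tests on its output therefore demonstrate the pipeline's mechanics and
internal consistency, not performance on real, alignment-bearing,
selectively constrained data.

## Problem sizes used in tests and the acceptance script

The full-scale configuration (36 teaching organisms at 400 residues,
50 versions, RMSE < 0.001) is a multi-day computation by design. The
package's own checks run the identical code at sizes where behaviour is
already diagnostic: teaching sets of 6 organisms at 60 residues
(hidden size by the same pyramid rule), 1–5 ensemble members, RMSE
target 0.01, and synthetic families at substitution loads 0.05 / 0.2 /
0.8 per site. At these sizes teaching converges in a few thousand
epochs and a few seconds per member, self-recognition is exact, and
5%-mutated variants are still recognised at the parent output. The
semihomology statistics in the acceptance script use 400-codon families,
the real scale, since that computation is cheap.

## Known limitations

* The semihomologous statistics depend on the translation table; users
  comparing mitochondrial proteins should select table 2 explicitly.
* Length normalisation by pad-or-cut assumes the sequences are already
  broadly colinear, as orthologous single-gene proteins are; it is not a
  substitute for alignment in the general case.
* Ensemble outputs for organisms far from every teaching organism are
  small and noisy; distance factors between such orbits inherit that
  noise (their scale-invariance mitigates, but does not remove, it).
* The orbit radius convention (reciprocal mean similarity) is one
  defensible reading of an informally specified geometry; radii should
  be compared only within one analysis, never across ensembles.
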