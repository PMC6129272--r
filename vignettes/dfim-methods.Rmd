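---
title: "Estimating epistatic feature interactions from sequence models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating epistatic feature interactions from sequence models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfim)
```

## The problem and the score

Transcription factors bind regulatory DNA combinatorially, and neural
networks trained to map sequence to binding or accessibility learn not only
which motifs matter but how they interact -- synergy, buffering,
flank-dependent affinity. Per-nucleotide attribution methods expose the
first part (which positions matter) but say nothing about the second.

This package scores pairwise epistasis learned by any differentiable
sequence model through the **Feature Interaction Score (FIS)**. Let
$X_0 \in \{0,1\}^{4 \times L}$ be a one-hot sequence (rows A, C, G, T) and
$C_{X_0}$ a backpropagation-based importance matrix for the model output
$Y$ ($Y$ is the regression output or, for classifiers, the pre-sigmoid
logit -- working on the probability scale would let the sigmoid's
saturation crush every gradient). For a source nucleotide $(\alpha, s)$
mutated to $\gamma$ and a target nucleotide $(\beta, t)$, $t \neq s$,

$$\mathrm{FIS}\big((\beta,t)\,\big|\,(\alpha,\gamma,s)\big)
  = C_{X_0}[\beta, t] - C_{X_0'}[\beta, t],$$

where $X_0'$ is $X_0$ with only position $s$ mutated. A positive score
means the source supports the target's importance (synergy); a negative
score means it masks it (buffering). The score is *directional*:
$\mathrm{FIS}(t\,|\,s)$ and $\mathrm{FIS}(s\,|\,t)$ are computed
independently and never symmetrised.

Because one attribution pass prices *all* targets against one source
mutation, an all-pairs map costs $3L + 1$ attribution passes (one for
$X_0$, three mutants per source position), and $F$ pre-specified features
cost $F + 1$ -- linear in the number of features, where pairwise in-silico
mutagenesis (ISM) is quadratic. `backendCalls()` exposes the counter so
this contract is user-visible, and the test suite asserts it exactly.

Three derived quantities complete the engine:

* **maxFIS** marginalises over the three mutant bases. Both the literal
  signed maximum and the largest-magnitude score (sign retained) are
  implemented; maps default to the magnitude policy because interaction
  strength is what a map displays. Ties break alphabetically by mutant
  base. The diagonal $t = s$ is masked: after mutating $s$ the "observed"
  target base at $s$ no longer exists, so the score is ill-posed there.
* **Motif-target FIS** sums the target motif's per-nucleotide scores; it
  is exactly the sum of the per-position FIS (the natural question for a
  regulatory variant: which motif does this SNV act on?).
* **Motif-motif FIS** replaces the source span with the expected
  background composition in a *single* mutant sequence: C and G rows get
  $f_{GC}/2$, A and T rows $(1-f_{GC})/2$, so columns still sum to one and
  the C+G mass equals $f_{GC}$. This avoids the combinatorial explosion of
  point-mutating a whole motif.

## Attribution backends

Two backends ship, behind one signature:

* `gradInputBackend()` -- gradient times input, the first-order Taylor
  decomposition of $Y$. One forward+backward pass per matrix.
* `refDiffBackend()` -- reference-based contributions computed as
  integrated gradients: the path integral of the gradient from a neutral
  reference to the input (midpoint rule, `nSteps` interpolation points),
  times $(X_0 - \mathrm{ref})$, averaged over references. References are
  either dinucleotide-shuffled versions of the sequence (`nReferences` of
  them, regenerated from `shuffleSeed` at every call so that a mutated
  sequence receives its own references from the same seed stream -- the
  mutation, not reference resampling, drives the score difference) or the
  constant fixed-GC matrix, which is the right neutral point for sequences
  generated on a fixed-GC background.

Defaults: 10 shuffled references and 50 steps. The number of references is
a package choice, not an empirically sanctified constant; the linear-model
tests show the backend is exact for additive models at any step count, and
the completeness gap $|\sum C - (Y(X_0) - \bar Y(\mathrm{ref}))|$ shrinks
as steps increase. Other attribution methods (e.g. a DeepLIFT
implementation) can be registered as plug-in backends with
`registerImportanceBackend()`; everything downstream only consumes the
importance-matrix contract. For fractional (background-mutated) inputs in
dinucleotide mode, references shuffle the argmax-decoded string with a
deterministic first-row tie-break -- in practice the fixed-GC mode is the
appropriate choice for such inputs.

## The model contract, and the networks in the package

Any model enters through two generics: `modelPredict()` (batched scalar
outputs) and `inputGradient()` (exact $\partial Y/\partial X$, batched,
accepted on fractional inputs). `gradientCheck()` verifies the gradient
against central finite differences; the contract requires agreement to a
relative 1e-3 on random inputs. Multi-task models expose `taskIndex`, and
`cloneTask()` must (and does, tested) give bit-identical predictions and
gradients to selecting that task.

The package implements its own small networks -- a one-convolutional-layer
CNN (ReLU convolution, windowed max pooling, one ReLU dense hidden layer,
linear logit) and a dense regressor -- with exact analytic
backpropagation and Adam, in plain matrix arithmetic. Exact gradients are
a feature here, not an optimisation: the engine's oracle tests demand
bit-exact reproducibility. Two architecture choices matter for
interaction analysis and are worth stating explicitly:

* a hidden ReLU layer after pooling is what allows the logit to encode a
  motif-pair interaction at all -- a purely linear readout of pooled
  filters is additive and would carry no interaction to attribute;
* pooling is *windowed* (width 25 by default), not global. Under global
  pooling a second copy of a motif is invisible (only the maximal
  activation survives), so the network cannot represent the buffering
  between redundant copies, and -- worse for benchmarking -- mutating one
  of two copies produces no importance change anywhere. Windowed pooling
  keeps copies in different windows separately visible. Global pooling
  remains available (`poolSize = Inf`) and generalises better on very
  small training sets, where the windowed feature map overfits.

## Significance: the dinucleotide-shuffle null

Observed FIS values get p-values against an empirical null: input
sequences are dinucleotide-shuffled (Euler-path algorithm; all 16
dinucleotide counts preserved exactly, terminal bases fixed -- a property
of the method, documented so nobody expects full randomisation), FIS is
recomputed on the shuffled sequences, and a Gaussian $(\mu, \sigma)$ is
fitted by maximum likelihood. P-values are two-sided,
$p = 2\,\Phi(-|x-\mu|/\sigma)$ -- buffering and synergy are both real
biology, so neither tail is privileged -- and Benjamini-Hochberg q-values
are computed over all records in one `fisSignificance()` call (the call
defines the correction family; callers batch accordingly). Defaults: 10
shuffles per sequence, pooled across sequences, at least 1000 null scores
before a fit is accepted. A full all-pairs null is quadratic in $L$, so
the default scope subsamples 50 source positions per shuffled sequence;
the full scope is a flag away. A degenerate null (every null score equal,
as on a linear model) is an error, not a silent $\sigma \to 0$.

Calibration is tested, not assumed: the fit recovers $(\mu, \sigma)$ of
$10^5$ standard-normal scores within $\pm 0.01$, q-values match the
hand-computed step-up on fixed lists, and the realised false-positive rate
at $\alpha = 0.05$ under the fitted null stays within three binomial
standard errors of nominal.

## The synthetic benchmark: what it emulates, what it does not

`simulateBenchmark()` builds the study conditions end to end: three sets
of sequences (default 2000 each, 200 bp, i.i.d. background with
$P(C) = P(G) = 0.23$), Set 1 with 1-2 planted ELF1 consensus instances,
Set 2 with 1-2 SIX5, Set 3 -- the positive class -- with 1-2 of each, and
each sequence independently carrying 0 or 1 AP1 and TAL1 instances
(probability 0.5) as label-irrelevant decoys. Placements are uniform among
non-overlapping arrangements (overlapping plants would make ground-truth
pair scoring ambiguous, so they are rejected and resampled). The motif
strings are consensus approximations of the published PWMs'
highest-affinity sequences; the benchmark validates the interaction
scorer, not motif biology, so any fixed distinct strings serve.

A note on scale: the original design of this simulation uses 20000
sequences per set; the package default is 2000 per set, which trains in
about two minutes on one CPU and leaves the conclusions unchanged -- the
classifier is near-perfect either way, and the FIS evaluation subsamples
300 positive sequences. The vignette and tests state these sizes as the
package's operating point.

The chain then is: train `trainBenchmarkCnn()` (error below 95%
validation accuracy -- attribution on a badly predicted example is
meaningless, so the gate is hard). The default training recipe combines
Adam with a geometric learning-rate decay and a decoupled weight decay of
0.3 on the weight matrices. The weight decay is not cosmetic: at this
benchmark's sample size an unregularised network keeps small spurious
weights on the label-irrelevant AP1/TAL1 decoys, and mutating a decoy then
measurably perturbs the large ELF1/SIX5 attributions -- false interaction
signal that the shuffled-sequence null cannot absorb. Decay prunes what
more training data would prune. Then: score every ordered pair of planted
motif instances in positive sequences with the fixed-GC reference backend
at the generator's $f_{GC}$; classify pairs as *true* (ELF1-SIX5 in either
direction), *decoy* (involving AP1 or TAL1) or *homotypic* (two instances
of one motif, excluded from the separation statistic since buffering
between copies is expected, not a false positive); and report the
true-vs-decoy AUC of $|\mathrm{FIS}|$ plus the significant fractions after
the dinucleotide-shuffle null (built at the same span coordinates on
shuffled copies, where the motif content is destroyed). The package's
end-to-end tests assert AUC > 0.9, a majority of true pairs significant,
and a decoy significant fraction below the nominal level -- and that the
separation conclusion replicates under plain gradient saliency (asserted
as rank-sum stochastic dominance; gradient saliency understates saturated
contributions, so its AUC runs below the reference-based backend's).

What the generator does **not** emulate: PWM-sampled (non-consensus) motif
instances, reverse-strand instances, positional preferences, chromatin
context, or label noise. Passing these tests therefore demonstrates that
the engine recovers interactions a model has learned from clean,
unambiguous signal; it does not certify performance on in-vivo data, where
model quality itself becomes the binding constraint.

## The flank-library analogue

For aggregate maps the package emulates an in-vitro flank-affinity
experiment: length-10 variable flanks with a response generated from a
fixed mononucleotide energy matrix (N(0, 0.3) coefficients frozen under an
internal seed) plus one strong planted pairwise term -- T at flank
position $-1$ with A at $+1$, coefficient 1.5 -- and N(0, 0.1) noise. A
dense regressor (64, 32 hidden units) is trained (validation $R^2$ gate
0.9), all-pairs FIS records are computed across 600 library sequences, and
`marginalizedAggregateMap()` builds the $40 \times 40$ map: mean $|FIS|$
per (source position, source base, mutant, target position, target base)
context -- each cell averaging only sequences that actually show that
source/target base combination -- then maximised over the three mutant
bases. The test asserts the map's top cell is the planted pair (either
direction; FIS is directional) and that an interaction-free,
mononucleotide-only library yields a map at least three-fold weaker at its
top cell -- a scale-free statement of the zero-interaction law under
training and sampling noise.

## Numerical choices and degenerate inputs

* Row order A, C, G, T is the only supported convention, validated on
  every object.
* Coordinates are 1-based inside R; BED input and all written record
  tables are 0-based half-open, converted at the boundary.
* Ambiguity codes (N) are rejected at encoding time rather than imputed.
* Only plus-strand features are scored; reverse-complement features are
  the caller's job to construct.
* Point mutations require strictly one-hot source columns and a mutant
  base different from the observed one; self-interaction ($t = s$) is an
  error, and map diagonals are NA.
* Overlapping source/target features are rejected everywhere (the score
  is undefined, not zero).
* Mutation operators are pure (inputs never modified) and order-independent
  at distinct positions; batch size never changes any number (bit-exact
  batching contract).
* All stochastic steps take explicit seeds; library internals restore the
  caller's RNG state.

## Limitations

Interaction scores inherit every vulnerability of the attribution method
and of the model: wrong models yield confidently wrong interaction maps,
which is why the training gates are errors rather than warnings, and why
replicating conclusions across two backends (as the benchmark tests do) is
recommended practice. The built-in networks are deliberately small; for
state-of-the-art genomics architectures, wrap the external model behind
the two-generic contract instead. The Gaussian null is an approximation to
the empirical shuffle distribution -- adequate in the tested regimes, but
heavy-tailed score distributions would call for more shuffles or an
explicitly empirical quantile.
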