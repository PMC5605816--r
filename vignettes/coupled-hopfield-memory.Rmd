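---
title: "Auxiliary-network memory rescue in Hopfield networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auxiliary-network memory rescue in Hopfield networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auxmem)
```

## The model

`auxmem` simulates memory retrieval in a binary Hopfield associative
network that has been wired, before injury, to a smaller auxiliary
network — a stand-in for an external memory prosthesis such as a
microelectronic device or a cerebral organoid. The question the
simulator addresses is quantitative: how much connectivity damage can
the original network sustain before memory retrieval collapses, and how
much of that loss can a pre-calibrated auxiliary network recover?

### Single-network dynamics

The original network has $N$ binary neurons with states
$S_i \in \{-1, +1\}$. A collection of $K$ memories
$\mathbf{m}^1, \dots, \mathbf{m}^K$ (columns of $\mathbf{M}$) is stored
by the Hebbian outer-product rule

$$\mathbf{W} = \mathbf{M}\mathbf{M}^{\mathsf T}, \qquad w_{ii} = 0,$$

and the state evolves by the sign-threshold map

$$S_i(t+1) = g\!\left(\sum_{j \neq i} w_{ij} S_j(t)\right), \qquad
  g(x) = \begin{cases} +1 & x \ge 0 \\ -1 & x < 0. \end{cases}$$

Assumptions worth making explicit:

* **Ties go to $+1$.** $g(0) = +1$ exactly; there is no stochastic
  tie-break. This matters in degenerate situations (zero interface
  columns, fully lesioned networks), which therefore have deterministic,
  documented outcomes.
* **No weight normalization.** $\mathbf{W}$ is not divided by $N$; the
  sign nonlinearity makes the dynamics invariant under any positive
  rescaling of $\mathbf{W}$, and a property test locks this in.
* **Self-coupling is excluded** by zeroing the diagonal, so the input
  potential is the single product $\mathbf{W}\mathbf{S}$.
* **Update scheme.** The printed map is synchronous, and synchronous
  updating (with period-2 cycle detection) is the default. A synchronous
  sign network with symmetric weights can only converge to a fixed point
  or fall into a 2-cycle, so cycle detection makes termination exact. An
  asynchronous mode (one seeded random-order sweep per iteration,
  potentials recomputed from the partially updated state) is provided
  because it carries the classical Lyapunov guarantee: the energy
  $E = -\tfrac12 \mathbf{S}^{\mathsf T}\mathbf{W}\mathbf{S}$ never
  increases under single-spin updates, which the test suite verifies
  across a thousand seeded trajectories.
* **Convergence** means exact state repetition between consecutive
  sweeps; the iteration cap defaults to 50 sweeps, far above the
  handful of sweeps retrieval needs at the loads studied here.
* **Retrieval is exact match.** A trial counts as retrieved only when
  the final state equals the cued memory in every pixel; convergence to
  the negated memory (an equally stable attractor of $\pm1$ dynamics)
  counts as failure. This is deliberately strict; the `overlap` column
  reported with every trial lets any laxer criterion be recomputed.

### The coupled system

The auxiliary network of $N_a$ neurons ($200$ or $400$, i.e. 20% or 40%
of the original $N = 1000$) is attached through block connectivity

$$\widetilde{\mathbf{W}} =
  \begin{pmatrix} \mathbf{A} & \mathbf{B} \\ \mathbf{C} & \mathbf{D} \end{pmatrix},$$

where $\mathbf{A}$ is the original Hebbian matrix, $\mathbf{C}$
($N_a \times N$) the sparse original-to-auxiliary interface,
$\mathbf{D}$ the auxiliary's own Hebbian matrix and $\mathbf{B}$
($N \times N_a$) the sparse auxiliary-to-original feedback. Training
proceeds in five stages on the *healthy* network — the interface is
inserted, each stored memory (with the original clamped at it) imprints
one auxiliary code $\mathbf{m}_a^\mu = g(\mathbf{C}\,\mathbf{m}_o^\mu)$,
the codes are stored in $\mathbf{D}$, the interface is withdrawn and
each code is verified to be a fixed point of $\mathbf{D}$, and finally
$\mathbf{B}$ is built. Recovery after injury mirrors the sequence with
the lesioned $\mathbf{A}_{\mathrm{inj}}$ in place of $\mathbf{A}$: the
damaged original converges on the cue alone, seeds the auxiliary
through $\mathbf{C}$, the auxiliary cleans its code up under
$\mathbf{D}$, and the original then re-converges under
$\mathbf{A}_{\mathrm{inj}}$ plus the constant field
$\mathbf{B}\,\mathbf{S}_a$.

Two points were genuinely open and are resolved as package defaults
with switches:

* **Interface and feedback weights.** The interface is described only
  as sparse, novel and random, while the block form of
  $\widetilde{\mathbf{W}}$ suggests Hebbian cross-terms. Default:
  $\mathbf{C}$ carries sign-balanced random $\pm1$ weights on an
  exact-count sparse mask — random projections give nearly orthogonal
  auxiliary codes for distinct memories, which is what the auxiliary
  store needs. $\mathbf{B}$ carries the Hebbian cross-term
  $\sum_\mu \mathbf{m}_o^\mu (\mathbf{m}_a^\mu)^{\mathsf T}$ under its
  mask, because feedback must carry memory information to steer the
  damaged network (a random $\mathbf{B}$ provably cannot, and is kept
  only as a control via `b_weights = "random"`). A masked-Hebbian
  interface, rebuilt after calibration, is available via
  `c_weights = "hebbian"`.
* **Clamping.** The staged arrows imply sequential phases but do not
  say whether the passive population evolves. Default: the original is
  clamped while the auxiliary converges, and vice versa — the minimal
  reading in which each stage has a well-defined, testable dynamical
  system. Joint co-evolution is available with `clamp = FALSE`.

### Damage

A lesion removes a fraction $p$ of the network's *connections*. Since a
Hopfield connection is bidirectional, a connection is an unordered pair
$\{i, j\}$ with $w_{ij} \neq 0$, and damage zeroes exactly
$\mathrm{round}(p \cdot n_{\text{pairs}})$ of them on both sides
(preserving symmetry); an asymmetric per-entry option exists for
sensitivity analysis. Counting nonzero pairs rather than all pairs is
nearly the same thing for a Hebbian matrix at $K = 20$ (about 82% of
entries are nonzero) but makes the accounting exact, and the test suite
asserts the exact counts at every damage level of the reference grid.
Lesions are redrawn per trial from the trial seed, so failure rates
average over lesion topologies; because the underlying draw is a
sequential sample, the lesions at increasing $p$ under one seed are
nested, which smooths the damage axis.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_orig` | 1000 | neurons | 40 x 25 bitmap patterns |
| `k_memories` | 20 | patterns | memory load 0.02, far below the ~0.138 Hopfield capacity |
| `n_aux` | 200 (or 400) | neurons | 20%/40% of the original network |
| `density_C` | 0.05 | fraction of possible edges | sparse read-out; enough for near-orthogonal auxiliary codes |
| `density_B` | 0–0.5 | fraction of possible edges | the swept "prosthesis bandwidth" axis |
| noise | 0–0.5 | fraction of cue pixels flipped | 0.5 is the information-free limit |
| damage | 0–0.8 | fraction of connections removed | collapse of retrieval happens in the upper half |
| `max_sweeps` | 50 | sweeps | retrieval converges in < 10 sweeps at these loads |

Noise flips *exactly* $\mathrm{round}(\varepsilon N)$ pixels (not
per-pixel Bernoulli), so every trial has a deterministic cue overlap
$1 - 2\,\mathrm{round}(\varepsilon N)/N$ and the noise axis has no
sampling jitter of its own.

## What the synthetic memory sets emulate

The reference memory sets are binary symbol bitmaps: 20 memories chosen
from a 30-symbol pool as the *most orthogonal* subset, compared against
a *nonoptimal* set sharing 15 of its 20 members, with the replacements
drawn at random from the pool. Real symbol bitmaps are strongly
correlated — rendering this package's own dot-matrix font gives mean
pairwise overlap ≈ 0.34 with maxima near 0.9, which exceeds what exact
Hebbian retrieval tolerates at $K = 20$. The synthetic candidate pool
(`generate_candidate_pool()`) therefore emulates the *structure* of a
symbol pool at a retrievable correlation level: 22 independent random
patterns plus a cluster of 8 sharing a common template (20% of pixels
flipped each, pairwise overlap ≈ 0.36 within the cluster). Greedy
subset selection then behaves as it does on symbols: the optimal set
sheds the correlated cluster, while the nonoptimal set's random
replacements reintroduce parts of it and pay for that with a higher
failure rate.

What the generator does **not** emulate: the spatial structure of
glyphs (strokes, contiguous ink regions) — its correlations are
pixelwise exchangeable — and any semantic relation between symbols.
Passing trend tests on synthetic sets therefore demonstrate the
*mechanisms* (correlation hurts, feedback rescues, size helps), not
pixel-level agreement with any particular symbol rendering. A bitmap
font renderer (`render_glyph_patterns()`) is included for illustration
and produces deterministic, platform-independent patterns, but
synthetic sets are the canonical experimental input.

The subset-optimality score is the sum of absolute pairwise overlaps,
minimized by greedy elimination (repeatedly dropping the pattern with
the largest summed absolute overlap, ties to the lowest index). Greedy
is deterministic and cheap; on exhaustive small-pool oracles it attains
the true minimum in over 90% of random instances and never trails it by
much, which the test suite asserts. Exact minimization over
$\binom{30}{20} \approx 3\times10^7$ subsets would be possible but buys
nothing for the questions studied here.

## Numerical and degenerate-input choices

* Potentials of Hebbian integer weights are integer-valued, so the
  $g(x \ge 0)$ threshold involves no floating-point ambiguity; the
  energy monotonicity assertion uses a $10^{-9}$ slack purely
  defensively.
* A zero interface column (possible at low `density_C`) maps to $+1$
  via $g(0)$; an all-zero $\mathbf{C}$ maps every memory to the same
  all-$+1$ auxiliary code and the package warns that the auxiliary
  store is degenerate.
* Sparse masks and lesions use exact counts
  ($\mathrm{round}(\text{density} \times n)$), never per-entry
  Bernoulli draws, so densities are reproducible to one entry.
* Stage-4 verification reports (rather than silently accepts)
  auxiliary codes that fail to be fixed points of $\mathbf{D}$ — at
  $N_a = 200$ and $K = 20$ the auxiliary load is 0.1, close to
  capacity, and a few non-fixed codes per run are expected physics:
  they are one reason the 400-neuron auxiliary outperforms the
  200-neuron one.
* All randomness flows from user-visible integer seeds through a
  multiplicative seed-derivation hash; every function that consumes
  randomness restores the caller's RNG state.

## Problem sizes used by the test suite

Unit tests run on reduced geometries (40–400 neurons) chosen so each
property is still sharply testable; exhaustive dynamics oracles go up
to $2^{12}$ states. The trend study runs at the full geometry
($N = 1000$, $K = 20$, auxiliary 200/400) with 5 seeds × 20 memories ×
5 noise/lesion realizations per grid cell on a coarsened grid
concentrated at damage 0.6–0.8, where the feedback effect lives; the
paired one-sided tests across seeds are decisive there. The bundled
acceptance script re-derives the healthy-retrieval count (20/20) at
full size in seconds.

## Known limitations

* Exact-match retrieval makes failure rates conservative; overlap-based
  performance is reported alongside to keep both views available.
* The noise level at which auxiliary feedback turns from helpful to
  harmful (seen at high noise in the reference results) depends on the
  interface weight convention and replicate counts; the package
  reproduces the qualitative ordering but does not pin the crossover's
  location.
* No plasticity after injury: the lesioned $\mathbf{A}_{\mathrm{inj}}$
  is frozen, and no retraining or homeostasis is modelled.
* Deterministic threshold dynamics only; no finite-temperature
  (Glauber) variant, and no continuous-valued or modern-Hopfield
  extensions.
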