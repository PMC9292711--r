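---
title: "Methods: linear gene networks, phenotypic equivalence, and system drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear gene networks, phenotypic equivalence, and system drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sysdrift)
```

## The model and its assumptions

A gene regulatory network is modelled as a linear time-invariant (LTI)
system: the kryptotype $\kappa(t) \in \mathbb{R}^n$ (molecular
concentrations, measured as deviations from the initial state, so
$\kappa(0)=0$) obeys $\dot\kappa = A\kappa + Bu$, and selection sees
only the linear read-out $\phi = C\kappa \in \mathbb{R}^\ell$ driven by
the environmental input $u(t)\in\mathbb{R}^m$. Linearity is the
strongest assumption: real regulatory kinetics saturate, so this is a
local approximation around an operating point. What linearity buys is
an *exact* characterization of all networks with identical
input–output behaviour, where nonlinear models only offer simulation.

The entire input–output map is the impulse response
$h(t) = Ce^{At}B$; the phenotype for any input is the convolution
$\phi(t) = \int_0^t h(t-s)u(s)\,ds$. Two systems are phenotypically
equivalent when $h \equiv \bar h$ on $t \ge 0$ — identical phenotypes
for *every* admissible input, not just one test stimulus.

### The equivalence certificate

Time-sampled comparison of $h$ can never certify equality for all $t$.
Instead `phenotypically_equivalent()` compares the Markov parameters
$CA^kB$, $k = 0, \dots, n_1+n_2-1$: by Cayley–Hamilton these finitely
many coefficients determine both (entire) impulse responses, so
agreement is an exact certificate in exact arithmetic. In floating
point the discrepancy is normalised by the largest parameter magnitude
and compared against a single relative tolerance, default `1e-8`
(exact equality is a measure-zero event numerically; `1e-8` sits far
above accumulated roundoff for the $n \le 50$ dense systems the
package targets and far below any genuine coefficient perturbation the
genetics ever produces, which is $\ge 10^{-3}$ in the worked
examples). Property tests confirm the certificate agrees with dense
time sampling of $h$ on $[0, 4\pi]$ across fixture pools.

### Kalman decomposition and minimal realization

`reachable_subspace()` is the column span of
$[B, AB, \dots, A^{n-1}B]$; `unobservable_subspace()` is the null
space of the stacked $[C; CA; \dots; CA^{n-1}]$. The four Kalman
classes are built by intersection and complement, ordered (reachable &
unobservable, reachable & observable, unreachable & unobservable,
unreachable & observable); invariance of the reachable and
unobservable subspaces forces the block-triangular zero pattern of the
transformed $A$, which the tests check entrywise to
$10^{-8}\,\lVert A \rVert$. Rank decisions drop singular values below
`rank_tol` (default `1e-9`) times the largest; singular values within
a factor of 10 of that threshold are reported as `rank_warnings`
rather than silently resolved. All bases are kept orthonormal so the
change of basis $P$ stays well conditioned. One subtlety: residuals of
orthonormal bases are measured against an absolute scale of 1, not
against their own largest singular value — otherwise a residual that
is zero up to roundoff would be renormalised into a spurious
direction.

Whether the off-diagonal blocks printed as zero must vanish or are
merely unconstrained is a convention; the construction here produces
and enforces the zero pattern, which is the stricter reading.

The minimal system is the reachable-and-observable block; its
dimension is independently certified in tests by the rank of the
block-Hankel matrix of Markov parameters. The degenerate case of an
identically zero response (no reachable-and-observable part) is
represented by a 1-state zero system rather than a 0-state object.

`pad_nonminimal()` inverts the reduction: it embeds a system in a
larger one, randomizing only blocks the Kalman form leaves free
(couplings drawn uniform on $[-1,1]$ under a fixed seed), then hides
the structure behind a random well-conditioned conjugation. By
construction the impulse response is untouched, which gives the
round-trip oracle used throughout the tests.

### Neutral directions and the dimension count

Perturbing by an infinitesimal change of basis $V = I + \epsilon Z$
moves $(A, B, C)$ in the direction $(ZA - AZ,\; ZB,\; -CZ)$ while
leaving the phenotype unchanged to first order. When $B$ and $C$ are
held fixed (mode `fixed_BC`), admissible generators satisfy $ZB = 0$
and $CZ = 0$; `neutral_tangent()` computes an orthonormal basis of
this space as the null space of the stacked Kronecker constraints.

A naive count treats the $nm + n\ell$ scalar constraints as
independent, giving $n^2 - n(m+\ell) = n(n-\ell-m)$ degrees of
freedom. That count is an undercount: the $\ell m$ functionals
$Z \mapsto (CZB)_{ij}$ are implied by *both* constraint sets, so the
generic constraint rank is $nm + n\ell - \ell m$ and the generic
dimension is $(n-\ell)(n-m)$. The two-gene oscillator already shows
this: the naive count gives $0$, yet its equivalent fixed-$B,C$
rewirings form a visible one-parameter family, matching
$(2-1)(2-1) = 1$. The package therefore reports the computed
null-space dimension as authoritative and exposes the naive formula
only as `generic_dimension`, a reference value. An independent oracle
(the rank of the Jacobian of the first $2n$ Markov parameters with
respect to $A$) confirms the computed count on random minimal systems.

First-order neutrality is verified behaviourally: stepping any
generator by $\epsilon$ yields a distance to optimum whose log–log
slope in $\epsilon$ is $2.0 \pm 0.1$ (quadratic, not linear).

## Genetics over system coefficients

The default architecture (`locus_map_A()`) gives every entry of $A$
its own unlinked, nonrecombining biallelic locus, with $B$ and $C$
genetically invariant — the simplest assumption, and the one under
which all worked examples run. Multi-coefficient loci (e.g. a whole
promoter row of $A$ inherited in cis) are expressible through
multi-address loci, and loci may be placed on $B$ or $C$ addresses,
but neither is the default. Inheritance conventions for which
coefficients travel together are genuinely underdetermined
biologically — regulatory rows (promoters, in cis) versus regulator
columns (the factor's own locus) both have a reading — so addresses
and chromosome assignments are fully explicit and the X-linked layout
used in the Haldane construction (a regulator column on the X) is just
one locus map among many.

A diploid's system is the coefficient-wise average of its two
haplotypes. A hemizygous male X allele contributes
$(d/2) \times$ allele with dosage compensation factor $d = 2$ by
default, so a hemizygote contributes like a homozygote (full
compensation, as in *Drosophila*); $d$ is a free parameter.

`f2_enumerate()` produces all $3^L$ per-locus states of an F2 between
homozygous parents (capped at $3^{12}$; beyond that, sample with
`cross()`). Two weightings are stored for every ensemble: Mendelian
($1/4, 1/2, 1/4$ per locus, multiplied across loci) and uniform over
the $3^L$ classes. Mean statistics default to Mendelian weights —
which is the distribution actual F2 offspring follow — with uniform
available as a switch, since averaging conventions for "mean F2
breakdown" are a genuine free choice. Conservation laws are tested:
the Mendelian-weighted mean coefficient equals the F1 midpoint, and
every F2 coefficient lies within the parental interval.

## The distance functional

Fitness-relevant mismatch is
$D(h) = \big(\int_0^T e^{-\sigma t}\lVert h - h_0\rVert^2 dt\big)^{1/2}$
with $\sigma = 1/4\pi$, weighting the first few multiples of $2\pi$ of
the dynamics. Internally $h - h_0$ is the impulse response of a
block-stacked system, and $e^{-\sigma t}$ is folded in by shifting its
$A$ by $-\sigma/2$. Three evaluators:

- **gramian** (default for finite $T$): the finite-horizon
  observability Gramian via a Van Loan block exponential on a short
  panel ($\lVert A\rVert\,\delta \le 0.5$) followed by interval
  doubling $W(2\delta) = W(\delta) + e^{A'\delta}W(\delta)e^{A\delta}$.
  Closed form, quadrature-free, no overflow for stable systems at long
  horizons; one evaluation costs a single small matrix exponential
  plus $O(\log T)$ products, which is what makes $10^4$-distance
  experiments cheap. Strongly unstable systems at long horizons can
  genuinely overflow to `Inf` — their truncated distance is
  astronomically large anyway.
- **quadrature**: adaptive integration of the integrand (evaluated
  from the matrix exponential) with relative tolerance `1e-10`; works
  on finite or infinite horizons and serves as the independent
  cross-check of both other methods.
- **lyapunov** (default for $T = \infty$): solves the continuous-time
  Lyapunov equation of the shifted stacked system — via a dense
  Kronecker vectorization solve, adequate at these sizes — and reads
  $D^2$ as a quadratic form. Valid only when the shifted system is
  strictly stable.

With $T = \infty$ the integral diverges whenever the shifted stacked
system has an eigenvalue real part $\ge 0$ (margin `1e-12`); the
distance is then `+Inf` with a `divergent` attribute — a model
statement (the hybrid's dynamics run away faster than the weight
decays), not a numerical failure. Figure-style experiments default to
a truncated horizon $T = 40\pi$ (weight $e^{-10}$ at $T$) so that
unstable hybrids at moderate $\epsilon$ still receive finite, ranked
distances; the fraction of F2s that are divergent under the unbounded
criterion is reported alongside every breakdown row so truncation
effects stay visible. $D^2$ is a quadratic form, so distances below
$\sim 10^{-8}$ (i.e. $D^2 < 10^{-16}$) sit at the floor of double
precision; scaling tests pick $\epsilon$ grids that keep distances
above that floor.

### Breakdown scaling

`breakdown_curve()` sweeps parents $A(0)$ vs $A(\epsilon)$ along the
equivalent-oscillator family, builds the deterministic F1 and the
enumerated F2 ensemble per $\epsilon$, and `scaling_exponents()` fits
log–log slopes. On $\epsilon \in [10^{-3}, 3\times10^{-2}]$ (6
log-spaced points) the slopes come out $2.0$ (F1) and $1.0$ (F2) to
within $0.1$: F1s lie at the parental midpoint and miss the optimum
only through the curvature of the neutral set; F2 segregation throws
individual coefficients off the set by the full parental difference.
Absolute curve heights depend on the weighting and truncation
conventions above and are not meaningful beyond their scaling.

## Neutral drift and the speciation clock

`drift_walk()` implements drift along the neutral set as a random walk
in the symmetry *group*: per generation, coordinates drawn
i.i.d. $N(0, V_G/N_e)$ on an orthonormal generator basis define
$Z$, and the system is conjugated by $e^{Z}$. Because conjugation is
an exact symmetry of $h$, every visited system is exactly equivalent
to the start (tests bound the certificate discrepancy by $10^{-6}$,
observing $\sim 10^{-16}$) — there is no tangent-step-plus-projection
retraction error. $V_G$ is interpreted as additive variance *per
neutral direction*; total displacement variance scales with the
tangent dimension. When the generator algebra is abelian (always true
for the oscillator's 1-dimensional fixed-$B,C$ algebra) the group
element at any generation is a single exponential of the summed
generator, which makes replicate experiments cheap; non-abelian
algebras fall back to sequential per-generation conjugation.

The quantitative-genetic step size is the standard neutral result: a
population-mean trait with additive variance $V_G$ and effective size
$N_e$ moves with per-generation variance $V_G/N_e$, hence variance
$t V_G/N_e$ after $t$ generations and $2t V_G/N_e$ for the difference
of two independent lineages. `drift_coordinate_samples()` checks this
by genuinely summing per-generation increments across replicates.

`divergence_experiment()` composes the pieces: two lineages drift from
a common ancestor; at checkpoints each lineage mean is treated as a
homozygous parental population (an idealization — within-population
segregating variation is not simulated), hybrids are formed, and
distances plus the quadratic fitness $w = \max(0, 1 - cD^2)$ (default
$c = 1$; locally quadratic fitness at an optimum, $c$ configurable)
are recorded. Since mean F2 distance is linear in parental separation
and squared separation grows like $t$, mean F2 $D^2$ grows linearly in
$t$: the speciation clock. Tests fit a through-origin regression on
checkpoint means and require $R^2 > 0.9$.

### Default study conditions

Drift experiments need numeric $V_G$ and $N_e$, for which no canonical
values exist; intrapopulation regulatory variation on the order of a
few percent per coefficient motivates per-generation coordinate steps
of sd $\sim 10^{-2}$, i.e. $V_G = 0.01$, $N_e = 100$ for the
variance-law checks ($t \in \{10^2, 10^3\}$, 2000 replicates). The
clock experiment uses $V_G = 10^{-3}$, $N_e = 1000$ (step sd
$\sim 3\times10^{-5}$ per generation, checkpoints 50–400, 60 replicate
pairs) so checkpoint displacements stay in the small-$\epsilon$ regime
where the quadratic/linear expansion is accurate. These sizes keep the
full suite within a desktop-minutes budget while leaving Monte-Carlo
error well inside the 3-standard-error and $R^2$ bands tested.

## What the synthetic systems do and do not emulate

Fixtures are the worked two-gene oscillator, its equivalent family,
random dense systems (optionally stability-shifted), and random
paddings. They exercise the mathematics fully but idealize the
biology: coefficients are unbounded reals (no saturation or sign
constraints), all loci are unlinked and nonrecombining, populations
are monomorphic means, environments are stationary, and selection acts
only through $D$. Passing tests therefore validate the model's internal
claims — equivalence, geometry, segregation arithmetic, drift scaling —
not the fidelity of any particular biological network.

## Known limitations

- Linearity: no saturating or sigmoidal kinetics; conclusions are
  local statements near an operating point.
- No within-population variation, mutation, linkage, or selection on
  robustness; drift acts on population means only.
- Dimension-changing evolution (gene duplication/deletion) appears
  only as static padding, not as a dynamic move.
- The dense Lyapunov/Kronecker solver and eigenvalue-based stability
  checks target small networks ($n \lesssim 50$); none of the
  algorithms exploit sparsity.
- Stochastic acceptance-style checks (variance laws, clock $R^2$) are
  statistical statements with 3-standard-error/fixed-band tolerances;
  individual unlucky seeds can land outside them with small
  probability.
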