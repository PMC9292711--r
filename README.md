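# sysdrift

Linear gene-network models of developmental system drift, hybrid
incompatibility and the speed of speciation.

## The problem

Distinct molecular mechanisms can realize identical phenotypes. If a
gene regulatory network is under stabilizing selection on its
*output* only, the set of networks producing that exact output forms a
high-dimensional neutral ridge in parameter space. Two isolated
populations can wander far apart along this ridge without any
phenotypic change — yet their hybrids, which mix coefficients from two
differently wired networks, can fall off the ridge and break down. This
package implements that model end to end, for theoreticians studying
speciation, hybrid incompatibility, Haldane's rule, and the geometry of
genotype–phenotype maps.

## The model

A network of $n$ interacting molecules (e.g. transcription factors) is
a linear time-invariant system

$$\dot\kappa(t) = A\,\kappa(t) + B\,u(t), \qquad \phi(t) = C\,\kappa(t),
\qquad \kappa(0) = 0,$$

where $\kappa(t) \in \mathbb{R}^n$ is the hidden *kryptotype* (molecular
concentrations), $u(t) \in \mathbb{R}^m$ the environmental input, and
$\phi(t) \in \mathbb{R}^\ell$ the *phenotype* seen by selection.
$A_{ij}$ is the regulatory effect of molecule $j$ on molecule $i$. All
input–output behaviour is captured by the impulse response
$h(t) = C e^{At} B$; two systems are **phenotypically equivalent** iff
their impulse responses coincide for all $t \ge 0$, which the package
certifies exactly through the first $n_1 + n_2$ Markov parameters
$CA^kB$. The Kalman decomposition splits the state space into
reachable/unreachable × observable/unobservable blocks; only the
reachable-and-observable block shapes the phenotype, every other block
is an evolutionary degree of freedom, and the minimal realization
$(A_{ro}, B_{ro}, C_{ro})$ is the smallest equivalent network.

On top of this sit:

- **diploid genetics**: each coefficient (by default each entry of $A$)
  is an unlinked, nonrecombining locus; a diploid's phenotype is
  determined by the coefficient-wise average of its two haplotypes;
  F1/F2 crosses, exhaustive $3^L$ F2 enumeration, and X-linked loci
  with dosage compensation (Haldane's rule);
- **a distance-to-optimum functional**
  $D(h) = \left(\int_0^T e^{-\sigma t}\,\lVert h(t)-h_0(t)\rVert^2 dt\right)^{1/2}$
  with $\sigma = 1/4\pi$, evaluated by closed-form Gramians, adaptive
  quadrature, or a Lyapunov solve;
- **neutral drift**: populations random-walk along the equivalence set
  by conjugation with $e^{Z}$, $Z$ drawn from the neutral generator
  algebra with per-generation variance $V_G/N_e$, so after $t$
  generations a lineage has drifted a random amount of variance
  $t V_G / N_e$ — and mean F2 hybrid breakdown grows linearly in $t$.

## Worked example

The two-gene oscillator (gene 2 upregulates gene 1, gene 1 represses
gene 2, only gene 1 is visible to selection) has phenotype
$\sin t + \cos t$. Rewired versions with very different coefficients
are phenotypically identical — but their hybrids need not be:

```r
library(sysdrift)
osc <- oscillator()                       # A = [[0,1],[-1,0]], B = (1,1)', C = (1,0)

# A(-2) = [[2,-1],[5,-2]]: different wiring, same phenotype
phenotypically_equivalent(osc, oscillator_family(-2))
#> [1] TRUE

# F1 hybrid of homozygous A(0) and A(-2) parents: averages the coefficients
map <- locus_map_A(oscillator_family(0))  # one unlinked locus per A entry
g0  <- homozygous_genotype(map, oscillator_family(0))
gm2 <- homozygous_genotype(map, oscillator_family(-2))
f1  <- diploid_system(diploid_genotype(map, g0$hap1, gm2$hap1))
f1$A
#>      [,1] [,2]
#> [1,]    1    0
#> [2,]    2   -1
drop(impulse_response(f1, 0:3)$values)    # e^t: the hybrid fails to oscillate
#> [1]  1.000000  2.718282  7.389056 20.085537
distance_to_optimum(f1, distance_spec(osc, method = "lyapunov"))
#> [1] Inf            # exponential runaway: divergent distance to optimum

# Hybrid breakdown as parents diverge along the neutral family
breakdown_curve(c(0.01, 0.05, 0.1, 0.2))[, 1:4]
#>    eps genetic_distance f1_distance f2_mean_distance
#> 1 0.01           0.0199     0.00159            0.196
#> 2 0.05           0.0977     0.03820            1.025
#> 3 0.10           0.1916     0.14562            2.680
#> 4 0.20           0.3712     0.52891           54.929
```

F1s sit at the coefficient-wise midpoint of their parents and miss the
optimum only through the curvature of the neutral set (distance
$\propto \epsilon^2$); F2s can be homozygous for different parents at
different loci and miss it by the parental separation itself (distance
$\propto \epsilon$) — which is why F2 breakdown dominates, and why
X-hemizygous F1 males, whose coefficient states are F2-like, do worse
than their sisters.

A thin command-line interface over the same functions is installed at
`inst/cli/sysdrift.R` (subcommands `impulse`, `equivalent`, `kalman`,
`minreal`, `tangent`, `distance`, `f2`, `haldane`, `curve`, `drift`,
`figure`).

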