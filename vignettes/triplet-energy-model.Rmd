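---
title: "The extended nearest-neighbor (triplet) energy model in TripletFold"
author: "TripletFold authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The extended nearest-neighbor (triplet) energy model in TripletFold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TripletFold)
```

## The model

A secondary structure on an RNA sequence $s_1 \dots s_n$ is a set of
canonical base pairs (Watson-Crick AU, UA, GC, CG or wobble GU, UG) in which
each base pairs at most once, no two pairs cross (no pseudoknots), and every
hairpin loop contains at least $\theta = 3$ unpaired bases.  Both energy
models implemented here are additive over the loops of a structure: hairpin,
bulge and internal-loop initiation terms tabulated by loop size, and an
affine multiloop term $a + b\,m + c\,u$ for a junction with $m$ branching
helices (the closing pair included) and $u$ unpaired bases.  Exterior bases
carry no energy, and neither dangling-end nor coaxial-stacking terms are
included anywhere: the nearest-neighbor (NN) mode is a Turner-style model
*without dangles*, which is the condition under which the two models are
comparable.

The models differ in how helices are scored.

* **NN**: every pair of directly stacked base pairs $(i,j),(i{+}1,j{-}1)$
  contributes the tabulated stack free energy
  $\mathrm{stack}(t_{ij}, t_{i+1,j-1})$, a function of the two pair types.
* **ENN (triplet)**: every window of *three* contiguous stacked pairs
  contributes a triplet free energy
  $\Delta G_3(t_{\text{outer}}, t_{\text{mid}}, t_{\text{inner}})$, and a
  helix of $h \ge 2$ pairs retains a single NN stack at its loop-terminating
  (inner) end.  A helix of $h$ pairs therefore contributes $h-2$ triplet
  terms plus one stem-end stack; a 2-pair helix contributes the stack only.

A bulge of size one is treated, as in the Turner convention, as part of a
continuing helix: it contributes the size-1 bulge penalty plus the NN stack
across the bulge, and it interrupts triplet windows (no window spans a
bulge).  Terminal non-GC penalties (for AU/GU closing pairs) attach at helix
ends adjacent to hairpin, internal, bulge ($\ge 2$), multiloop and exterior
loops — never inside a helix and never at a size-1 bulge — and can be
disabled via `modelConfig(useTerminalNonGC = FALSE)`.

## Where the triplet energies come from

No experimentally determined triplet stacking energies exist, so the 6×6×6
table is inferred from the 6×6 stack table:

1. **Boltzmann conversion.**  Treating triplet-stack motifs as Boltzmann
   distributed in their energy, the joint probability of the ordered pair
   types $(x, y, z)$ of a stacked triple is
   $p(x,y,z) \propto e^{-[\mathrm{stack}(x,y) + \mathrm{stack}(y,z)]/RT}$.
2. **Marginalization.**  The left (over $(y,z)$), middle (over $(x,z)$) and
   right (over $(x,y)$) marginals are extracted.
3. **Maximum entropy.**  Iterative proportional fitting (IPF), starting from
   the uniform distribution and rescaling each marginal in turn (left,
   middle, right per cycle), converges to the maximum-entropy joint
   consistent with the three marginals.  Because the Boltzmann joint lies in
   the pairwise-interaction exponential family, it is itself the fixed
   point; the acceptance tests verify recovery to below $10^{-6}$ per cell
   at the default tolerance ($10^{-9}$, $L_\infty$ over marginal cells).
4. **Inverse Boltzmann with calibration.**  $-RT\,\ln \hat p$ is positive
   for every cell of a normalized distribution, so a calibration maps the
   raw values onto the stacking energy scale.

The calibration is the one genuinely open design choice, and it is exposed
as a configuration mode rather than hard-coded:

* `"avg_stacks"` (shipped default): $-\tfrac{RT}{2}\ln \hat p$, shifted so
  the table mean equals the mean of
  $[\mathrm{stack}(x,y)+\mathrm{stack}(y,z)]/2$.  Consecutive triplet
  windows along a helix overlap in one stack, so each interior stack is
  covered by two windows; the factor $\tfrac12$ corrects that double
  counting, and at the IPF fixed point the triplet energy equals the
  *average* of its two constituent stacks — the scale on which a triplet
  energy is naturally expected to sit.  ENN and NN energies are then
  commensurate (helices differ by a half-stack end correction), which keeps
  minimum-free-energy magnitudes physically sensible.
* `"mean_avg_stacks"`: $-RT\ln \hat p$ with a single additive shift to the
  same mean.  Each window then carries the *sum* of its two stacks plus a
  constant: strong windows become markedly stronger and weak windows (e.g.
  adjacent GU wobbles) become net destabilizing.  This produces visibly
  more cooperative folding but also systematically deeper ENN minima and
  larger structural deviations from the NN model.
* `"none"`: the unshifted $-RT\ln \hat p$ (all positive; useful only for
  inspecting the raw inverse-Boltzmann output).

Under either anchored mode the triplet table correlates perfectly with the
mean of the constituent stacks; the modes differ in slope, not ranking.

## The dynamic program

Seven constrained quantities are filled over all subintervals, in either the
sum-product semiring (partition functions, kept in log space) or the
min-plus semiring (minimum free energies): the unconstrained $Z$; $Z^b$
(contains the pair $(i,j)$); $Z^{bb}$ (contains $(i,j)$ and $(i{+}1,j{-}1)$);
$Z^{bl}, Z^{br}$ (contains $(i,j)$ and a size-1-bulge-shifted inner pair);
and the multiloop accumulators $Z^m$ ($\ge 1$ branch) and $Z^{m1}$ (exactly
one branch anchored at the interval's 5' end).  The ENN-specific
"2-look-ahead" lives in $Z^{bb}$: when $(i,j)$ stacks on $(i{+}1,j{-}1)$ the
contribution uses the triplet energy if $(i{+}1,j{-}1)$ stacks directly
onward, and the NN stem-end stack if it terminates the helix (closes a
hairpin, a loop of size $\ge 2$, a multiloop, or continues only across a
size-1 bulge).  An auxiliary array $Z^{nt} = Z^b \ominus Z^{bb}$ (the
loop-closing part of $Z^b$) keeps that branch split exact in both
semirings.  In NN mode the same engine runs with the triplet term replaced
by the plain stack, so the NN fold is the standard Zuker/McCaskill recursion
without dangles.

Numerical conventions:

* Internal loops and bulges are capped at `maxInternal = 30` unpaired bases
  (the run-time convention of the reference implementations); loop tables
  extend beyond size 30 by the Jacobson-Stockmayer form
  $E(n) = E(30) + 1.07856\,\ln(n/30)$ kcal/mol at 37 °C, rescaled with the
  size-30 enthalpy.
* Temperature enters through
  $\Delta G(T) = \Delta H - T(\Delta H - \Delta G_{37})/310.15$ applied to
  every table cell; loop entries whose enthalpy is not reported are treated
  as purely entropic ($\Delta H = 0$).  In ENN mode the triplet table is
  re-inferred at each working temperature from the rescaled stacks
  (`reinferTriplets = FALSE` freezes the 310.15 K table instead).
* The sum-product fill stores natural logarithms and combines branches by
  log-sum-exp, so partition functions for sequences of several hundred
  nucleotides cannot overflow.
* Exact structure counting runs the identical recursion in a counting
  semiring with all energies zero and the loop cap lifted; counts are exact
  integers as long as they fit an IEEE double ($< 2^{53}$).
* The MFE traceback breaks ties deterministically, testing branches in the
  fixed order hairpin, triplet extension, size-1 bulges, stem-end stack,
  internal/bulge loops by increasing size then increasing 5' gap,
  multiloop decompositions by increasing branch start.
* Multiloop decomposition is unique (decompose on the start of the last
  branch), so the zero-energy count weights every structure exactly once.

Stochastic traceback sampling draws structures from
$e^{-E(S)/RT}/Z$ using R's RNG (one stream, seeded per call), so identical
seeds give identical samples; base-pair probabilities are empirical
frequencies over `m` samples (default 10000), with an exact
enumeration-based alternative (`method = "exact_small"`) for sequences up
to 30 nt.  Sampling rather than an outside pass is used because the outside
recursions for the ENN helix contract are not part of this implementation;
an exact outside algorithm is an acknowledged extension.

## Synthetic data and test oracles

The test suite relies on two generators and a set of deliberately naive
reference implementations that are shipped in the package (so users can
validate custom parameter files at small scale):

* `generateFixture()` draws i.i.d. random sequences at a chosen GC content,
  or emits a designed GC stem-loop whose unique enumeration optimum is the
  designed helix (verified in the tests).  Random suites used by the oracle
  checks are 200 sequences of length 5-20 at GC 0.5, a scale at which
  exhaustive enumeration is exact and fast; melting-curve checks use the
  two ~70-nt snoRNA sequences shipped in `inst/extdata` with 2000 samples
  per temperature over a 0-100 °C grid in 1° steps.
* `enumerateStructures()` generates every valid structure (capped at 25 nt
  by default); `bruteMFE`, `brutePartition` and `bruteBPP` fold the
  enumeration through the whole-structure evaluator `evaluateEnergy()`,
  which implements the helix contract by direct loop decomposition,
  independently of the DP fill.  The DP and the evaluator agree to
  $10^{-9}$ on the random suites for both models; the zero-energy count
  equals both the enumeration size and a second, classical counting
  recursion.

What these fixtures emulate — and what they do not: i.i.d. sequences probe
the algebra of the recursions, not the statistics of biological RNA
(no covariation, no composition bias, no modified bases); the snoRNA
melting runs exercise realistic lengths but sampling noise of order
$1/\sqrt{m}$ remains in each curve point.  Passing these tests shows the
implementation computes its model exactly; it does not certify predictive
accuracy on real structures, which for this model class is known to trail
mismatch-aware nearest-neighbor engines.

## Parameters

The shipped `turner99` and `turner04` sets are transcriptions of the
published Turner 1999 and Turner 2004 nearest-neighbor tables (stacks with
enthalpies, loop-size tables, multiloop affine coefficients, terminal
non-GC penalty, optional tetraloop bonuses) into the package's documented
JSON schema; `loadParameters()`/`writeParameters()` round-trip custom
files.  Tetraloop bonuses are config-gated and default to off, matching the
recursion contract, which carries no sequence-specific hairpin terms.
Mismatch-specific tables (terminal mismatches, 1×1/1×2/2×2 internal loops)
and the Ninio asymmetry correction are deliberately not part of the model.

## Known limitations

* The NN baseline, lacking mismatch tables, does not bit-reproduce
  mismatch-aware engines: on the 148-nt XPT riboswitch worked example the
  published reference NN structure corresponds to an optimum that those
  terms select, while this package's NN optimum arranges the 17-59 interior
  differently.  Consequently the NN/ENN structural difference on that
  sequence is larger here (10 pairs under the default calibration) than the
  two-wobble-pair difference the mismatch-aware baseline exhibits —
  although the underlying mechanism (adjacent GU-wobble windows becoming
  unfavorable under the triplet model) is reproduced and can be observed
  directly with `calibration = "mean_avg_stacks"`.
* Base-pair probabilities are sampled, not computed by an outside pass.
* No pseudoknots, no constraint folding, no suboptimal structure lists
  beyond Boltzmann sampling.

## A worked example

```{r example}
xpt <- exampleSequence("xpt")
nn  <- mfeFold(xpt, "turner99", modelConfig("nn"))
enn <- mfeFold(xpt, "turner99", modelConfig("enn"))
foldEnergy(nn)
foldEnergy(enn)
## pairs predicted by NN but not by ENN
key <- function(p) paste(p[, 1], p[, 2])
setdiff(key(basePairs(nn)), key(basePairs(enn)))
```

```{r melt, eval = FALSE}
## melting profile of the 72-nt platypus snoRNA under both models
sno <- exampleSequence("snorna_platypus")
mcN <- meltingCurve(sno, "turner99", modelConfig("nn"),  m = 2000, seed = 1)
mcE <- meltingCurve(sno, "turner99", modelConfig("enn"), m = 2000, seed = 1)
plot(mcN$temperature_C, mcN$expected_bp_per_nt, type = "l",
     xlab = "temperature (C)", ylab = "expected base pairs / nt")
lines(mcE$temperature_C, mcE$expected_bp_per_nt, lty = 2)
legend("topright", c("NN", "ENN"), lty = 1:2)
```
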