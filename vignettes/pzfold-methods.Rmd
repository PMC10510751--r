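---
title: "Thermodynamic models and design methods in pzfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic models and design methods in pzfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pzfold)
```

# Scope

pzfold implements nearest-neighbor (NN) secondary-structure thermodynamics
for DNA extended with the synthetic AEGIS bases P
(2-amino-imidazo[1,2-a]-1,3,5-triazin-4(8H)-one, a purine analog) and Z
(6-amino-5-nitro-2(1H)-pyridone, a pyrimidine analog). The `DNA-PZ`
alphabet allows C-G, A-T, the three-hydrogen-bond P-Z pair, and the G-Z
wobble; G-T is treated as a mismatch in this alphabet because it is less
stable than both A-T and G-Z. On top of the parameter tables the package
provides two-state duplex prediction, staged OLS fitting of stack
parameters from melting summaries, global fitting of two-concentration
optical melting curves, a partition-function folding engine with
normalized-ensemble-defect (NED) evaluation, and stochastic inverse design.

# Parameter tables

## Stacks

The canonical Watson-Crick-Franklin stacks, duplex initiation (+1.96
kcal/mol), terminal A-T penalty (+0.05 per end) and symmetry correction
(+0.43, self-complementary duplexes only) are the unified oligonucleotide
DNA set. The 11 unique P-Z stacks and 15 G-Z stacks are free-energy values
at 37 C fit by linear regression against optical melting data; both tables
ship as plain-text files under `inst/extdata/params/`. All 36 unique stacks
of the DNA-PZ alphabet resolve after loading; lookups are invariant under
the 180-degree rotation of a stack. Terminal P-Z pairs carry no end
penalty: regressions with an end-correction column estimate a coefficient
smaller in magnitude than its standard error once a single outlier duplex
is removed, so the penalty is fixed at zero. Terminal G-Z pairs default to
zero as well, by analogy with wobble and modified pairs that needed no end
correction.

No enthalpy/entropy values are packaged for P-Z or G-Z stacks: P-Z
enthalpies can be overlaid by the user (or refit with `fit_stage()` in its
`enthalpy-PZ`/`entropy-PZ` modes), and G-Z enthalpies are deliberately not
parameterized, since single-experiment coverage per stack would make them
unreliable. Consequently `duplex_dH_dS()` refuses duplexes containing
stacks without enthalpy entries, and folding is parameterized at the
310.15 K reference only.

## Loop tables and the extrapolation rules

Measured main-text loop increments are packaged verbatim (kcal/mol):
terminal mismatches Z-Z on T-A (-0.91), Z-Z on G-C (-0.76), P-P on T-A
(-0.51); 5' dangling Z on A-T (-0.80) and 5' dangling P on C-G (-0.37).
Every other entry over the expanded alphabet is produced by fixed rules,
applied in order of precedence:

1. measured values verbatim (both orientations of the closing pair, since
   the orientation of a symmetric mismatch is not resolved by a melt);
2. dangling ends: A/C/G/T dangles on P-Z or Z-P closings default to the
   measured mean -0.1; unmeasured P dangles are +0.1 (3') and -0.5 (5');
   unmeasured Z dangles are -0.1 (3') and -0.7 (5');
3. terminal mismatches: unmeasured P-P mismatches -0.5 and Z-Z mismatches
   -0.8 (their measured means); any other mismatch on a P-Z, Z-G or G-Z
   closing -0.2 (the mean of mismatches measured on Z-P closings);
4. 1x1, 2x1 and 2x2 internal loops: map P-Z closings to G-C and G-Z
   closings to A-T (orientation preserved), map loop P to G and loop Z to
   C; if a mapped mismatch column becomes a Watson-Crick-Franklin pair,
   remap it to A-C preserving purine-pyrimidine orientation; look up the
   canonical entry and stabilize by -0.6 kcal/mol per mismatch (for 2x1
   loops: per loop) that contained P or Z;
5. hairpin first-mismatch, large-internal-loop end-mismatch and coaxial
   tables equal the terminal-mismatch table.

Two gaps the rules do not cover are filled by documented package choices:
A/C/G/T dangles on G-Z closings use the canonical entry after the G-Z to
A-T mapping, and mismatches containing one P or Z on canonical closings
use the loop-base mapping of rule 4 without the -0.6 stabilizer (the
stabilizer is calibrated on internal loops, not helix-end stacks).

## Canonical loop-sequence surrogates

The canonical DNA terminal-mismatch, dangling-end and internal-loop
sequence tables are not printed anywhere the package can quote, so they
are generated in code (`canonical_*_synthetic()`) as additive models -
closing-pair class term plus per-nucleotide stacking increments -
calibrated against the canonical aggregates that are printed alongside the
P/Z measurements (purine/pyrimidine mismatch means on G-C and T-A
closings, example canonical dangles). They are synthetic surrogates, not
transcriptions. Two consequences matter for interpretation: absolute
folding free energies of loops carry the surrogate's (unquantified) error,
and every quantity defined *relative* to the canonical tables - the
extrapolation offsets, the -0.6 stabilizer, the measured overlays - is
exact by construction. Loop-length initiations (hairpin/bulge/internal,
sizes to 10, Jacobson-Stockmayer extension `1.75*RT*log(n/top)` beyond)
and the multibranch linear model (offset 3.4, per-branch 0.4, per-unpaired
0.0 kcal/mol) are packaged defaults of the usual magnitudes.

# The folding energy model

`fold_energy()` (R) and the dynamic-programming engine (C++) implement the
same decomposition; the test suite holds them to 1e-9 agreement against
exhaustive enumeration, which only proves internal consistency, not
accuracy of any individual parameter. The model:

* helix stacks between adjacent pairs;
* hairpins (minimum loop 3): length initiation + first mismatch
  (terminal-mismatch table) + end penalty;
* bulges: length initiation only; both flanking pairs take end penalties
  (single bulges are not treated as continuing stacks);
* 1x1/2x1/2x2 internal loops from the sequence tables; larger internal
  loops (capped at 30 unpaired nucleotides): initiation + an end mismatch
  on each side;
* multibranch loops: linear model plus a terminal-stack term per helix
  end, in the "d2" convention - the mismatch/dangle energy uses the
  immediate sequence neighbours of the helix end regardless of whether
  those neighbours are themselves paired;
* exterior helix ends: terminal mismatch when both neighbours exist,
  otherwise a single 5'/3' dangle;
* the terminal-pair penalty is charged once per helix-end side that does
  not stack on an adjacent pair.

The d2 convention and the local end-penalty rule were chosen because they
make the model strictly local: the partition function, base-pair
probabilities (inside-outside), and MFE traceback then decompose exactly,
with no heuristic dangle assignment. Coaxial stacking is not included.
Probabilities satisfy `q(i) + sum_j p(i,j) = 1` to numerical precision on
every instance; MFE tracebacks are deterministic with ties broken in
enumeration order. Energies are kcal/mol at 310.15 K with
R = 1.987e-3 kcal/(mol K); indices are 1-based at every interface.

The normalized ensemble defect of sequence s against target T is
`NED = mean_i (1 - P_i)`, where P_i is the probability that position i
pairs its exact target partner (paired positions) or is unpaired
(unpaired positions), under the Boltzmann ensemble.

# Duplex thermodynamics

`duplex_dG37()` handles fully paired antiparallel duplexes with at most
one overhanging nucleotide per end, terminal mismatches, and interior
1x1/2x2 motifs; anything larger belongs to the folding engine. Two-state
melting temperatures use `Tm = 1000*dH / (dS + R ln(C_T/x))`, x = 1 for
self-complementary duplexes (strict complements only: C-G, A-T, P-Z -
never G-Z) and 4 otherwise. Loop-motif increments are reference
subtractions: measured duplex stability minus the NN-predicted motif-free
reference. Whether the reference includes terminal A-T penalties is the
caller's choice of reference duplex; `duplex_dG37()` applies the penalty
to whatever core it is given, which is the documented convention.

# Stack-parameter fitting

`fit_stage()` performs the staged regression: the response is each
duplex's experimental value minus all fixed contributions (initiation,
symmetry, terminal A-T penalties, fixed-family stacks), and the design
matrix counts free-family canonical stacks per duplex. Stages: `PZ` fits
P-Z-containing stacks with canonical values fixed; `GZ` fits
G-Z-containing stacks with canonical and P-Z values fixed;
`enthalpy-PZ`/`entropy-PZ` repeat the PZ design on the dH/dS channels.
Uncertainties are standard errors of the regression (not robust errors),
matching how the packaged stack uncertainties are defined. Outlier removal
is manual-by-id (`exclude_and_refit()`); the end-penalty report ranks
residuals but applies no automatic threshold, because the underlying
procedure is a judgement call, not a rule. OLS itself is delegated to R's
QR least squares; an independent optimizer cross-checks it in the tests.
Weighted fits are not implemented; an uncertainty-weighted variant would
be the natural extension if per-duplex errors become available.

# Global melt fitting

The forward model for a pair of melts at nominal 1 and 5 uM total strand:
mass-action A+B duplex fraction with K(T) from dH and dS; observed
absorbance = free-strand baselines plus duplex absorbance
`(1-h)*(epsA(T)+epsB(T)) + slope*(T - 50 C)` per mole of duplex, so the
hypochromic duplex inherits the strands' temperature dependence and h = 0
with zero slope reduces to the baseline sum. The exact split of duplex
absorbance between the hypochromicity h and the linear slope is this
package's definition (the functional form is not uniquely dictated by the
fit concept). Six parameters are shared across
both curves: dH, dS, h, slope, and one free strand concentration per melt;
the partner concentration is derived from the total absorbance near the
top of the melt (averaged over the hottest 40 points, with a small
fixed-point correction for residual duplex). Residuals are relative
(photometric noise scales with the signal), with a penalty term that keeps
the labelled excess strand genuinely in excess so that the four
excess-strand assignments are distinct hypotheses.

The fit is repeated for the four assignments. Numerically, the optimum
basin is determined almost entirely by the starting concentrations - the
total-absorbance constraint creates ridges - so each assignment is
optimized from a grid of concentration multipliers (0.94/1.00/1.06 per
melt, plus two enthalpy brackets) on temperature-thinned curves,
candidates are refined on the full data, and finally each assignment
retries from every other assignment's optimum (with concentration
multipliers also reflected about the nominal split). Selection follows the
two published criteria, quantified as: assignments whose fitted
concentrations deviate more than 15% from nominal are rejected (pipetting
errors are typically about 5%), and the lowest sum of squared residuals
among the survivors wins.

# Synthetic data and what passing tests show

`gen_duplex_dataset()` plants NN truth values in random 6-12 bp helix
duplexes with Gaussian noise (0.3 kcal/mol by default, the scale of
inter-laboratory reproducibility) and guarantees every free stack occurs
at least twice. `gen_melt_fixture()` simulates the melt forward model with
0.3% relative photometric noise and planted pipetting errors; the
validation conditions use individual strand errors of 4-6% (within the
typical 5% range) which leaves strand A in roughly 10% excess, melts
sampled every 0.25 C from 10 to 95 C, and spectrally distinct strand
baselines. Under these conditions 100 seeded simulate-then-fit rounds
recover dH and dS to within a few percent and identify the planted excess
strand in at least 95 of 100 runs; the handful of failures are genuine
likelihood flips (the wrong hypothesis fits that noise realization
better), not optimizer artifacts - this was verified by intensive
multistart refits. None of this exercises real-instrument drift,
wavelength effects, or non-two-state melting.

`gen_cross_target()` builds the symmetric multi-arm targets used to probe
design: `arms` helices radiating from a central loop, optionally ending in
three-way junctions with two hairpins each - a scaled-down analog of the
fourfold-symmetric benchmark topology whose three-base-pair helices
exhaust the canonical sequence space.

# Design

`refine()` is a single-level stochastic NED minimizer: positions are
selected with probability proportional to their defect contribution
(pairs counted jointly), identities are redrawn from the biases (DNA-PZ
pairs: G-C 0.50, A-T 0.30, P-Z 0.20, orientation uniform; loops: A/C/G/T
0.60/0.10/0.10/0.20, never P or Z; canonical mode: G-C and A-T 0.50
each), and a change is kept only if the NED strictly decreases. The
hierarchical decomposition used by full-scale design software is
deliberately not reproduced; this simplification trades efficiency on
long sequences for transparency, and is the main reason the package's
design results should be read at fixture scale (tens to ~150 nt), not
benchmark scale. Defaults: threshold NED 0.01, 2000 iterations, no wall
clock limit; the validation suite uses threshold 0.05 with 250-500
iterations on targets of 40-150 nt, sizes chosen so a full design
campaign (5 attempts x 2 alphabets x 11 targets) completes in minutes.
Both alphabets are evaluated with the DNA+PZ parameter tables - the mode
only restricts which pair types the designer may assign - so differences
between modes isolate the value of the extra pair, not a change of energy
model. Every attempt records its seed; clock seeding is used only when no
seed is given. Paired one-sided t tests (matched targets) and Welch tests
(independent groups) at alpha = 0.05 compare design metrics.

# Known limitations

* Canonical loop-sequence tables are calibrated surrogates (above);
  absolute loop energies inherit their error.
* Single-mismatch parameters ignore the pronounced helix-position
  dependence of mismatch stability; entries reflect the most
  destabilizing, center-of-helix values.
* No coaxial stacking, pseudoknots, salt or pH corrections (everything
  refers to pH 7), and no temperature extrapolation for folding.
* The designer does not support sequence constraints at specified
  positions.
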