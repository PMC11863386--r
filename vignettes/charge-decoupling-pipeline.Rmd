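---
title: "Decoupling net-charge effects with machine-learned CVs and adaptive-bias sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoupling net-charge effects with machine-learned CVs and adaptive-bias sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opescv)
```

## The scientific problem

Conserved charged residues ring the active sites of many enzymes without ever
touching the catalytic machinery. Such a residue can influence the reaction in
two separable ways: through its *net charge*, which contributes to the
electrostatic field over the reacting atoms (electrostatic preorganization),
and through its *local interactions* — hydrogen bonds, packing, backbone
positioning. Telling the two apart requires an intervention that removes the
charge while holding everything else fixed, followed by an accurate free-energy
comparison of the reaction with and without the charge.

`opescv` implements that workflow as a desk-scale, fully testable pipeline:

1. **Charge-neutralization topology transforms** that zero a residue's net
   charge while preserving either its polarity (halve-and-shift) or removing it
   outright (common rescale), with restraint builders that pin the rest of the
   system so the intervention stays purely electrostatic.
2. **Featurization**: switch-normalized pairwise distances between
   reaction-center atoms.
3. **A machine-learned discriminant collective variable** (targeted
   discriminant analysis, TDA): a small feed-forward network trained so the CV
   distribution of each metastable state matches a prescribed Gaussian.
4. **Adaptive-bias enhanced sampling** (on-the-fly probability enhanced
   sampling, explore variant) along the CV, with multi-walker bias sharing.
5. **Reweighted free-energy profiles** with replicate uncertainties, state
   energetics (RS → TS1 / INT / TS2 / PS), charge-perturbation ΔΔG, and a
   transition-state degeneracy audit of the learned CV.
6. **Conservation mapping**: triad-anchored structural superposition,
   charge-proxy clustering, and alignment-column conservation frequencies that
   identify where evolution keeps charges around an active site.

Because the production version of such a study runs on a QM/MM engine that is
far outside a desk budget, the sampling and estimation machinery here is
exercised on a **surrogate reactive system**: Langevin dynamics on analytic
multi-basin potentials whose exact free-energy surface is computable by
quadrature. Every estimator in the package can therefore be audited against
ground truth.

## The surrogate reactive system

The surrogate is a 1-D coordinate $x$ in a smooth potential

$$U(x) = \sum_i p_i x^i + \sum_j A_j e^{-(x-c_j)^2/2w_j^2} + q\,\phi(x),$$

in reduced units ($k_BT = 1$). `double_well(barrier, x0)` gives the canonical
two-state system with an exactly known barrier; `triple_well()` reproduces the
five-state topology (RS, TS1, INT, TS2, PS) of a two-step reaction with
barriers in the 10–20 $kT$ range. The term $q\,\phi(x)$, with $\phi$ a narrow
Gaussian at a transition region, emulates a *spectator charge*: it shifts the
barrier by approximately $q\,[\phi(x_{TS}) - \phi(x_{RS})]$ without moving the
basins, the surrogate analogue of neutralizing an outer-shell charged residue.
The exact profile is

$$F_i = -k_BT \log \frac{\int_{\text{bin } i} e^{-U/k_BT}\,dx}{\Delta x},$$

computed by per-bin Gauss–Legendre quadrature (`exact_fes()`); it is the oracle
for every sampling test. The propagator is the BAOAB discretization of
underdamped Langevin dynamics, chosen for its accuracy of configurational
averages at practical time steps; any symplectic-stochastic scheme with the
Boltzmann-consistency property would do. A domain guard at 10× the outermost
basin center converts numerical blow-ups into named integration errors.

Feature ensembles for CV training are generated directly per state as Gaussian
clouds over raw distances (`generate_state_ensembles()`), rather than derived
from the particle trajectory. This deliberately decouples CV-training tests
from sampler tests: a defect in one cannot mask a defect in the other. The
default conditions (`surrogate_state_specs()`) are three states over 36
distances spanning 2–6 length units, between-state shifts of 0.6 and
within-state spread 0.1, i.e. cleanly separated states, which is the regime the
production training data occupies after unbiased state sampling. Both pooled
and per-replica generation modes exist because production training sets are
pooled from several short independent replicas.

**What the surrogate does not emulate:** real feature correlations (production
distances are curvilinear functions of a shared geometry, not independent
Gaussians), fat-tailed state distributions, multidimensional reaction
pathways, and any chemistry. Passing tests demonstrate the correctness of the
estimation machinery, not the transferability of the production CVs.

## Charge schemes and restraints

Two neutralization schemes act on a residue topology whose backbone charges
are first replaced by the neutral-form reference values:

- **Polar** (`apply_polar_scheme`): side-chain charges are divided by 2, then
  shifted by one uniform per-atom constant so the residue sums to exactly zero.
  The result is still polar but avoids unrealistic charges on aliphatic
  groups. The uniform additive shift is the minimal-assumption reading (a
  proportional shift would reorder charges); it preserves the relative
  ordering of side-chain charges and is recorded in the output attributes.
- **Apolar** (`apply_apolar_scheme`): side-chain charges are divided by one
  common factor chosen to zero the residue; when the required side-chain sum
  is itself zero the charges are zeroed outright (limit convention). This is
  effectively a substitution by an apolar residue.

Both guarantee $|\sum q| < 10^{-12}$ e. To keep charge-modified systems
otherwise identical, `build_positional_restraints()` pins all backbone atoms
beyond 7 Å of the catalytic-His imidazole center at 10 kcal/mol/Å², and
`build_hbond_walls()` places one-sided harmonic walls (k = 20 kcal/mol/Å²) on
the neutralized residue's hydrogen bonds at the 90th percentile of their
unbiased distance distributions. Percentiles use linear interpolation between
order statistics throughout the package (no convention is canonical; this one
is the common statistical default and is stated here once). The five wall
pairs are configuration, not hard-coded, since they derive from the specific
donor–acceptor geometry of the system under study. The backbone partition
defaults to the standard N, H, CA, HA, C, O set.

## Features and the training hull

`feature_spec()` fixes an ordered atom set; features are all $C(k,2)$ pairwise
distances in canonical order — 36 for a 9-atom stage, 28 for an 8-atom stage,
which is why the paired networks open with layers of width 36 and 28. Raw
distances are normalized with the rational switch

$$s(r) = \frac{1-(r/r_0)^n}{1-(r/r_0)^m},\qquad (n, m) = (6, 12)
\text{ by default},$$

with the removable singularity at $r = r_0$ filled by $n/m$. Defaults follow
the most common rational-switch convention; $r_0$ is configurable per pair and
echoed in run metadata. Because network CVs extrapolate poorly, `hull_walls()`
builds harmonic walls on the **raw distances** (not the normalized features)
at the 0.5% and 99.5% percentiles of the training set, k = 20; sampling then
stays inside the hull of what the CV has seen.

## The discriminant CV

`train_cv()` fits a feed-forward network ([36, 72, 36, 1] or [28, 56, 28, 1],
tanh hidden units, linear output) with the TDA loss

$$L = \sum_c (\mu_c - \tilde\mu_c)^2 + \alpha\,(\sigma_c - \tilde\sigma_c)^2,$$

where $\mu_c, \sigma_c$ are the batch mean and standard deviation of the CV in
class $c$ and the targets are centers $(-10, 0, 10)$ with widths
$(0.4, 0.3, 0.4)$. Only stable states enter training — transition states are
never labeled — yet a converged CV still resolves the barriers because the
narrow class targets force steep transitions between classes. Choices the
loss definition leaves open, fixed here and echoed in the model file:
$\alpha = 1$; sample (n−1) standard deviation; full-batch Adam at learning
rate 0.01; 80/20 stratified split; feature standardization by training-set
mean/sd stored in the model. Training stops at validation loss < 0.02 (the
conventional convergence level for this loss) or on a 300-epoch plateau with a
warning. Under the default synthetic conditions (3 × 2000 samples, 36
features) convergence takes on the order of 100 epochs and a few seconds.
Gradients are analytic (backprop through the per-class mean/sd), verified in
the tests against finite differences.

## Adaptive-bias sampling

`run_opes()` drives `n_walkers` (default 8) Langevin walkers sharing one bias
along the CV. Every `pace` = 200 steps each walker deposits a kernel at its
current CV value; the bias is the explore-variant form

$$V(s) = (\gamma - 1)\,k_BT\,\log\!\left(\frac{\hat P(s)}{Z} + \epsilon\right),
\qquad \gamma = \frac{\Delta E}{k_BT},\qquad
\epsilon = e^{-\Delta E/((\gamma-1) k_BT)},$$

where $\hat P$ is the kernel-density estimate of the **sampled** CV
distribution, $\Delta E$ the barrier parameter, and $Z$ the mean kernel
density over deposited kernel centers (a normalization over the explored
region). The fixed point of this update is the well-tempered distribution
$p(s)^{1/\gamma}$, and the $\epsilon$ floor bounds the bias depth by
$\Delta E$ exactly — note $(\gamma-1)k_BT = (1-1/\gamma)\Delta E$. Kernel
bandwidths shrink as $\hat\sigma\,n^{-1/5}$ (Silverman-style) with a floor at
`sigma_min` = 0.3 CV units; kernels closer than the current bandwidth merge
(height-weighted mean, pooled width), keeping the kernel count bounded.
Walker scheduling is synchronous at pace boundaries; deposits see all
walkers' current CV values, and no other concurrency semantics are promised.
Beyond a hull wall the bias is frozen at its wall value, so only the
restoring wall force acts there and excursions past the hull stay thermal.

An arbitrary monotone CV can drive the bias: a function $s(x)$ (e.g. a trained
`cv_model` wrapped over a feature map) is tabulated on a dense grid and
differentiated numerically for the chain-rule force. The reference surrogate
budget is $10^5$ steps per walker at $dt = 0.005$ — a desk-scale budget that
crosses a 10 $kT$ barrier hundreds of times under a barrier parameter of
4× the true barrier, while unbiased dynamics at the same budget never cross.

After each deposit the reweighting offset
$c(t) = k_BT \log \langle e^{V(s)/k_BT}\rangle_{\text{grid}}$ is recorded; its
stabilization marks the end of the bias transient. `detect_burn_in()` applies
the production convention — discard the initial segment — by scanning a
trailing window until the fitted slope, extrapolated over the run, falls below
the series range (cap: first 25% of the run). On a saturating series with time
constant 5% of the run this discards about the first 5%.

## Free-energy profiles and the ΔΔG contract

`reweighted_fes()` recovers the unbiased profile from the standard
reweighting identity $w = e^{(V(s) + V_{\text{wall}} - c(t))/k_BT}$ per frame:
per-replicate weighted histograms, $-k_BT \log$, per-replicate min-shift, then
the across-replicate mean and standard error per bin. The SEM is
between-replicate (5 independent replicates in the reference conditions), not
block-averaged within runs — both views exist in practice; between-replicate
is the more conservative and is the default reported. Never-visited bins are
`NA`, not zero. The grid default is 200 bins wall-to-wall.

`extract_state_energies()` turns a profile into Table-style energetics:
interior minima in basin windows, interior maxima in barrier (TS) windows,
all relative to the RS minimum, with SEM propagated as the root sum of squares
of the two bins. Windows default to the inter-basin intervals between labeled
state centers and are configuration. `delta_delta_g()` differences two such
tables; swapping its arguments negates every entry exactly. In the package's
validation, imposed spectator-charge shifts of +2.3 and −0.8 reduced units on
the 10 $kT$ double well are recovered within 2 pooled SEM of the quadrature
truth from 5 replicates per system — the desk-scale analogue of measuring the
catalytic contribution of an outer-shell aspartate (+) and lysine (−).

### The degeneracy audit

A learned CV is *degenerate* when chemically distinct configurations project
onto the transition-state CV values, corrupting barrier estimates.
`degeneracy_audit()` builds the reweighted 2-D free-energy surface over
(CV, rational variable) — the rational variable being a chemically
interpretable coordinate with a known transition-state range — and requires
that, inside the TS window of the CV, the minimum-free-energy rational value
falls in its expected range and no bin outside that range undercuts the TS
free energy by more than 0.5 $kT$ (configurable; well below the 2 $kT$ scale
of a chemically meaningful spurious channel). Zero TS-window occupancy yields
`"inconclusive"`, deliberately distinct from `"fail"`.

## Conservation mapping

`superpose()` implements Kabsch least-squares rigid superposition (proper
rotation, det = +1) on the catalytic-His side-chain anchor — which His atoms
anchor the fit is configuration, defaulting to the six side-chain/ring atoms.
`collect_proxies()` reduces each charged residue to one charge-proxy atom
(Lys NZ, Arg CZ → +; Asp CG, Glu CD → −), excluding catalytic residues;
`cluster_sites()` groups proxies per sign by single-linkage radius clustering
(equivalent to connected components of the radius graph) and reports
centroids with occupancy. `column_conservation()` maps reference-numbering
positions gap-aware to alignment columns and reports per-residue percent
frequencies; gap rows are excluded from denominators by default (counting
them is a flag), and thinly supported columns are flagged rather than
silently reported. Redundancy filtering is a greedy identity-threshold filter
on the provided sequences — a deliberate replacement for external
redundancy servers that preserves the pipeline stage; the threshold
(default 90% identity) is configurable.

## Numerical choices and limitations

- Reduced units throughout the surrogate ($k_BT = 1$); production-unit values
  (kcal/mol, Å) appear only in the restraint builders, where they are
  pass-through parameters.
- Quadrature: per-bin Gauss–Legendre (24 nodes); symmetric double-well
  profiles are symmetric to $10^{-8}$ and constructed barriers are recovered
  to $10^{-6}$ on fine grids.
- Problem sizes used in validation: $10^5$ steps × 8 walkers per replicate,
  5 replicates per charge state, 3 × 2000 training samples. These are the
  package's reference desk-scale conditions; all converge in seconds to
  minutes on one CPU.
- The test-driving CV tabulation (2001 grid points, linear interpolation) is
  exact only to interpolation error; a production implementation would
  differentiate the network analytically along its input coordinates.
- The surrogate is 1-D: multi-walker bias sharing, reweighting and auditing
  generalize unchanged, but nothing here tests CV quality on genuinely
  multidimensional landscapes.
- Absolute production energetics (e.g. a 17.9 kcal/mol barrier) require the
  QM/MM engine and are out of scope; the package validates the estimation
  machinery that would process such simulations.

## Reproducing the validation numbers

The tests (`tests/testthat/`) regenerate every number asserted above from
code. `scripts/acceptance.R --seed <int> --out <path>` reruns the headline
computation — ensemble generation, featurization, CV training — and writes the
final validation loss it obtains.
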