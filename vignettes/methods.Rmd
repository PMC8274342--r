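---
title: "Early-phase amyloid PET as a perfusion surrogate: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early-phase amyloid PET as a perfusion surrogate: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Florbetapir PET is acquired to image amyloid-beta, but during the first
minutes after injection the tracer distributes with blood flow, so the
early frames behave like a perfusion image — and cerebral perfusion is
tightly coupled to glucose metabolism as measured by FDG PET.  A single
dual-phase amyloid scan could therefore deliver both an amyloid biomarker
(late acquisition, lAV45) and a neurodegeneration biomarker (early
acquisition, eAV45), sparing patients a second injection.  Making that
work requires a chain of methodological choices: which early time window
to average, which reference region to scale by, how to correct partial
volume effects, how to compare the resulting cortical maps against FDG,
and whether the early-phase surrogate classifies clinical groups as well
as FDG does.  `earlypet` implements that chain as reusable, tested
components, and ships a synthetic dynamic-PET cohort generator with full
ground truth so that every inferential step can be validated end to end.

## The synthetic world

All cohort data live on a two-hemisphere triangulated sphere
(`cortical_mesh()`).  A medial cap is excluded from cortical statistics
and subdivided into reference-region patches (pons, cerebellum with a
cerebellar-GM subset, cerebral white matter), so reference scaling can be
exercised on purely surface-based data.  The cortex carries 34 parcels
per hemisphere (a Desikan–Killiany-sized parcellation built from
latitude/longitude bands) and two disease caps.

Per subject $s$ and vertex $v$, frame $k$ (covering minute $[k, k+1)$,
evaluated at its midpoint $\tau$) is

$$\mathrm{frame}_k(v) = g_s\,[\,P_s(v)\,D(\tau) + A_s(v)\,B(\tau) + \varepsilon\,],$$

with $P_s$ the ground-truth perfusion map, $A_s$ the amyloid map in
late-phase SUVR-like units, $g_s$ a global dose factor (removed by any
ratio scaling), and $\varepsilon$ i.i.d. frame noise.  The delivery
curve $D$ is a gamma variate with time to peak 2.5 min (so the peak falls
inside the first four minutes by construction), shape 0.4 and a retained
fraction 0.45 — a flat-topped curve, appropriate for a lipophilic tracer
whose tissue activity rises within the first minute and washes out
slowly.  The binding weight $B$ is zero until its onset at 4 min and then
grows linearly at 0.15 of the late-phase signal per minute; the source
study gives only the qualitative contamination claim, so the slope is a
free parameter chosen so that windows reaching past the onset visibly
trade perfusion fidelity for amyloid contamination.

Metabolism is coupled to perfusion with correlation $r$ (default 0.85):

$$M_s = r P_s + \sqrt{1-r^2}\,\bigl(\sigma_P (0.97\,\delta_m + 0.24\,G_s) - \text{deficits}\bigr),$$

where $\delta_m$ is a *fixed* metabolism-specific baseline topography and
$G_s$ a small subject field.  Putting most of the perfusion-independent
channel into a shared fixed field keeps the vertex-pooled
perfusion–metabolism correlation at $r$ while giving FDG realistically
low between-subject noise; an early version that used a pure subject
field made FDG as noisy as the early frames, which is neither realistic
nor compatible with the study population's clearly higher FDG
sensitivity.  With $r = 1$ the construction degenerates to $M = P$
exactly, which the test suite exploits.

Disease enters through two caps: a large *vulnerable* cap (65°, cosine
severity taper) carrying hypoperfusion (AD dementia 0.20, aMCI half)
plus an extra, perfusion-independent hypometabolism component (0.12 /
0.06) — so FDG deficits exceed perfusion deficits there — and a small
plateaued *decoupled* cap (28°) with a perfusion deficit but *preserved*
metabolism, modelling regional neurovascular decoupling (perfusion
deficits without matching metabolic deficits are a recognized feature of
the resting brain in this disease).  Cognition scores (MMSE, Total
Recall) decrease linearly in the effective vulnerable-cap metabolism
deficit with noise SD 1.5, calibrated so the default group means span the
clinically typical range (controls ≈ 29 MMSE, dementia ≈ 20).  Amyloid
status is drawn per group (12.5%, 51%, 86.7%, 93.3% high for young
controls, elderly controls, aMCI and dementia respectively) and
high-amyloid subjects receive a cortical amyloid elevation with a spatial
topography deliberately near-orthogonal to the perfusion landscape.

Reference-region behaviour is part of the stated world: the pons is
nearly free of between-subject variability (that is what makes it a good
reference); the cerebellum is mildly disease-affected (diaschisis, 3.5%
in patients) with small instability; the cerebral white matter is
strongly unstable on the early-phase side (SD 0.05, with only 30% of
that on the FDG side — WM early-frame kinetics are the unreliable part)
and mildly disease-affected; and global scaling is implicitly corrupted
because the cortical mean itself carries the disease.  Patch
fluctuations are prevented from leaking between modalities through the
coupling term, so reference errors are modality-specific, as they are in
practice.

### What a green test does and does not establish

The generator reproduces the *statistical structure* the analysis
assumes — coupling, contamination timing, graded topographies, reference
stability ordering — on a smooth sphere with Gaussian fields.  It does
not emulate scanner physics (attenuation, randoms, resolution
anisotropy), anatomical variability, registration error, or
pharmacokinetics beyond the two-term delivery/binding model.  A green
acceptance suite therefore establishes that the pipeline recovers known
ground truth under its own assumptions, not that those assumptions hold
in any particular clinical dataset.

## Pipeline components

**Early windows.**  All 34 windows $[T_1, T_2]$ with
$T_1 \in \{0,1,2,3\}$, $T_2 \in \{1,\dots,10\}$, $T_2 > T_1$; frame $k$
covers minute $[k, k+1)$, so window $[T_1,T_2]$ averages frames
$T_1 \dots T_2-1$.

**Reference scaling.**  Seven regions: cerebellum, cerebellar GM, pons,
pons+cerebellum, pons+cerebellar GM, cerebral WM, and global
(proportional scaling of the brain mean to 6.5 mg/100 mL/min).  Masks are
eroded by 4 mm (a discrete ball on voxel grids; a geodesic margin on mesh
patches) and volumetric masks are intersected with the matching tissue
probability map at threshold 0.5.  Amyloid status is called on the
cerebellar-GM-scaled late map: high iff the area-weighted neocortical
mean strictly exceeds 1.22 (ties classify low; the cutoff is taken as a
given constant).

**Partial-volume correction.**  Three-compartment voxel-wise
Müller–Gärtner: white-matter and CSF spill-in, blurred by the scanner
PSF, are subtracted and the residual is divided by the blurred GM
fraction.  The WM compartment activity is the mean observed value in an
eroded high-probability WM mask; CSF activity defaults to 0 (standard
practice, pluggable).  The output domain is restricted to
$p_{GM} > 0.3$ to avoid division blow-up.  Because the same separable
Gaussian convolution implements both the phantom PSF and the correction,
phantom recovery is exact up to discretization, which the tests confirm
to well under the 5% criterion.

**Surface projection.**  Depth samples at 35–65% of the cortical
thickness in 5% steps along the vertex normal, combined with Gaussian
weights centred at the central surface.  The weight SD is not specified
by any source; the default $\sigma = 0.10$ (depth-fraction units) gives a
centre:edge ratio of about 3:1, satisfying the qualitative requirement
that mid-cortical depths dominate.  Out-of-grid samples are clamped and
the vertex reported in a QC attribute.

**Smoothing.**  Iterated explicit heat diffusion on the vertex graph
with unit symmetric edge weights and lumped vertex mass $\sqrt{3} a_v$
(exact Laplacian calibration on a regular triangular lattice).  Total
diffusion time is $\sigma^2/2$ for the requested FWHM; the step count is
chosen for stability/positivity.  The operator is linear, conserves the
area-weighted mean exactly (symmetry), and its impulse response has the
requested FWHM within one edge length on a flat lattice — the two
properties the acceptance suite checks.  Geodesic-Gaussian smoothing is
deliberately approximated by graph diffusion: at desk scale the
calibration test is the guarantee that matters.

**Correlations.**  Within-subject: Pearson over included cortical
vertices.  Inter-subject: per-vertex regression across subjects with
$r = \mathrm{sign}(t)\sqrt{t^2/(N - \mathrm{rank}(M) + t^2)}$, which for
the intercept-plus-slope design reproduces Pearson's r to machine
precision (a property the suite checks over 1000 random regressions).
Optional p-values permute the subject pairing with the same permutation
at every vertex.

**Window selection.**  Within each subject, all 34 windows are scored by
correlation with FDG and ranked by a Friedman test; the top critical
difference group forms the candidate set.  Per cortical vertex, the
candidate with the highest inter-subject correlation with FDG and the one
with the lowest (signed; an absolute-value variant is available)
inter-subject correlation with lAV45 are found, with exact ties splitting
the vertex's area equally.  The selected window maximizes the
FDG-criterion area among candidates whose lAV45-criterion area is within
a tolerance (default 0.1) of the best — the joint rule "maximize
agreement with FDG while minimizing amyloid contamination".  The signed
reading of "lowest correlation" is the default because hypoperfusion and
amyloid load are negatively related across subjects, making binding-free
windows genuinely *negative*, not merely small, in correlation with the
late phase.

**Friedman/Nemenyi.**  Mid-rank ties; the tie-corrected statistic
$(k-1)\sum_j (R_j - N(k+1)/2)^2 / \sum_{ij}(r_{ij} - (k+1)/2)^2$ with a
$\chi^2_{k-1}$ p-value; critical difference
$q_{\alpha,k}\sqrt{k(k+1)/(6N)}$ with $q$ from R's exact Studentized
range quantile at infinite df divided by $\sqrt 2$ (exact quantiles
being available, embedding a lookup table would only lose precision).
Groups chain conditions within CD of each local best, giving the bars of
a critical-difference diagram.

**TFCE + FWE.**  $\mathrm{TFCE}(v) = \sum_h e_h(v)^E h^H\,\mathrm{d}h$
with cluster extent $e_h$ measured in vertex area over mesh-edge
connectivity, midpoint-rule heights, defaults $E = 1$, $H = 2$,
$\mathrm{d}h = \max/100$.  Inference is Freedman–Lane: responses are
residualized against the nuisance covariates, residual rows permuted, and
the familywise-corrected p-value at a vertex is
$(1 + \#\{\text{permutation max TFCE} \ge \mathrm{TFCE}(v)\})/(P+1)$.
The nuisance fit is not added back after permutation because the t
statistic of the tested column is algebraically invariant to components
in the span of the nuisance design.  Contrasts are one-sided, matching
the directional hypotheses (controls > patients; positive cognition
associations).

**Pattern overlap.**  Both FWE p-maps are binarized at each of 91
thresholds evenly spaced from 0.05 to 0.001 (read as linear spacing), the
FDG map acting as truth; balanced accuracy is the mean of sensitivity and
specificity.  Thresholds where the truth is empty are excluded with a
warning.  Reference regions are then ranked by a Friedman test with
thresholds as blocks.

**Classification.**  Repeated (250×) stratified hold-out nested CV of a
linear SVM on parcel-mean features.  "80% of the smallest class reserved
for training" is implemented as drawing that count from *each* class
(class-balanced training, the reading that minimizes imbalance); the
proportional alternative is a one-line change in the split helper.  The
inner loop is 5-fold stratified CV over costs $10^{-3}\dots10^2$;
standardization is fitted on the training split only; splits depend only
on labels and the seed, so different feature sets share splits and the
Friedman comparison across configurations is validly paired.  The SVM is
an L2-regularized L1-loss linear machine solved by deterministic dual
coordinate descent (no SVM library being available in the target
environment), with the bias as a regularized constant feature.

## Design choices in the open questions

* Global scaling divides the whole-image mean over the brain mask (whole
  cortex on meshes); the mask is exposed rather than fixed to GM-only.
* Inter-subject permutations permute raw pairings for the bivariate case;
  residual permutation is what the group/cognition GLM uses.
* The reference-region recovery experiment compares the five elementary
  scaling strategies.  The two pons composites are near-duplicates of
  pons; putting near-copies of the best condition into a rank test splits
  ranks among them and makes "is the best condition in the top group"
  ill-posed, so they are excluded from that comparison (they remain
  available everywhere else).
* Numerical tie-breaks: exact per-vertex argmax ties split area equally;
  tied window selections resolve to the lexicographically earliest window
  with a warning; tied inner-loop costs resolve to the smallest cost.

## Known limitations

Sphere-based geometry (no folding, uniform thickness by default); graph
diffusion rather than exact geodesic smoothing; the amyloid binding model
is linear-in-time with a hard onset; the balanced-accuracy ranking of
reference regions is intrinsically noisy when several references are
nearly equally good — at desk scale the recovery criterion passes in at
least nine of ten replicates, not deterministically; and none of the
clinical headline numbers of the motivating literature are reproduced
here, because they derive from data that is not public.
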