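---
title: "Methods: DBS connectomics on a synthetic phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DBS connectomics on a synthetic phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This package reimplements, at desk scale and with fully synthetic inputs, a
connectomic analysis of centromedian-nucleus (CM) deep brain stimulation
(DBS) in generalized epilepsy: electric-field modelling of the stimulated
tissue, streamline-based structural connectivity seeded from the volume of
tissue activated (VTA), discriminative scoring of single streamlines against
clinical outcomes, normative seed-based functional connectivity, and the
outcome statistics. Every stage runs on a phantom with known ground truth,
so each claim the pipeline makes can be checked against what was planted.

## The volume of tissue activated

A quadripolar lead (Medtronic 3389 geometry: four 1.5 mm contacts with
0.5 mm edge gaps, hence 2.0 mm centre spacing; the distal contact is taken
flush with the tip, centre at 0.75 mm) is placed by a tip position and unit
direction. Stimulation is monopolar cathodic at 60 Hz and 90 µs, amplitudes
programmed in volts up to 5 V.

Two field models are provided.

**Analytic point source.** Each active contact is an ideal monopole in a
homogeneous medium: \(|E|(r) = I/(4\pi\sigma r^2)\), with the
voltage-programmed amplitude converted to a current source through a
configurable access impedance, \(I = V/Z\), default \(Z = 1000\ \Omega\).
With several active contacts the total current is split equally and vector
fields superpose.

**Finite-difference solve.** \(\nabla\cdot(\sigma\nabla\phi) = 0\) is solved
on the voxel lattice (7-point stencil, harmonic-mean face conductivities,
successive over-relaxation to a relative residual of \(10^{-6}\), at most
10,000 sweeps; non-convergence is an error). Dirichlet patches sit at the
voxels containing the active contacts and the outer grid boundary is the
grounded return. Tissue conductivities are isotropic scalars: grey matter
0.33 S/m, white matter 0.14 S/m, CSF/background 2.0 S/m (configurable; no
value is standard for the background, and anisotropy tensors are out of
scope).

Two numerical choices matter here:

1. *Current normalization.* The solver uses unit contact potential,
   measures the delivered current discretely (sum of face currents out of
   the contact patch), and rescales the potential so the delivered current
   equals \(V/Z\). Both field models therefore share one source convention
   and can be compared like for like. A consequence worth stating
   explicitly: because the source is current-controlled, scaling the
   conductivity everywhere by a factor scales the field by its inverse —
   the potential *shape* is what remains invariant. Under pure
   voltage-control Dirichlet conditions the potential itself would be
   σ-invariant; the two conventions disagree and we adopt the
   current-controlled one throughout.
2. *Singularity subtraction.* \(|E| = \|\nabla\phi\|\) computed by plain
   central differences has \(O(h^2/r^2)\) relative error near a monopole
   (≈11% three voxels from a contact). The potential is therefore split
   into the known analytic monopole per contact plus a smooth remainder;
   only the remainder is differenced. The 7-point stencil's discrete
   monopole additionally deviates from \(C/r\) by
   \(\approx A\,C\,h^2 K(\theta)/r^3\) with the cubic harmonic
   \(K = (x^4+y^4+z^4)/r^4 - 3/5\) and \(A \approx 0.785\) (fitted once on
   an 81³ homogeneous reference solve); this lattice defect is subtracted
   from the remainder and not added back, so the reported field is
   continuum-consistent. With both corrections the field matches the closed
   form to within 2.4% (max) over the 3–10-voxel shell of a 40³ homogeneous
   test, and the error shrinks with voxel size.

The VTA is the set of voxels with \(|E| \ge e\), activation threshold
\(e = 0.2\) V/mm by default. VTA–nucleus metrics report overlap volume,
overlap as a fraction of the nucleus, and both centroid and minimal
voxel-centre distances — no single "distance" is privileged, since both are
plausible readings of distance-to-target and they answer slightly different
questions.

## Structural connectivity

A streamline is *connected* to a VTA when any of its vertices, after
arc-length resampling to at most half a voxel, falls inside the binary mask
(an optional dilation radius relaxes traversal to proximity). Bilateral
VTAs of one patient are united before selection because outcomes are per
patient. Regional profiles count connected streamlines by the parcellation
label of their *far* endpoint (the endpoint farther from the VTA centroid),
and report both raw counts and counts normalized by (total streamlines ×
region voxel count). The normalization scheme is a package convention — the
magnitudes of normalized counts are not comparable to any published values,
only the association structure across patients is meaningful.

## Discriminative fibertract analysis

For every streamline, patients split into connected and unconnected groups
and the streamline receives the pooled-variance two-sample t statistic of
their improvement values (Welch is available as an option; the pooled form
is the convention of the discriminative-fibertract literature). Scores are
undefined — excluded from ranking, not bottom-ranked — when either group
has fewer than 2 members or the pooled variance vanishes. The top
\(\lfloor 0.10\,n_\mathrm{defined}\rfloor\) streamlines by *signed* t are
retained (positive t = connected to better responders; ranking by |t| is an
option but not the default, matching the display convention of positive
outcome association). No multiple-testing correction is applied: the
procedure is a descriptive top-k selection, not an inferential test.
Recovery against the phantom's ground truth is summarized as precision and
recall of the planted bundle.

## Normative functional connectivity

Subject series are minimally preprocessed in the order smooth → regress →
filter: Gaussian smoothing at 6 mm FWHM (separable, edge-renormalized),
ordinary-least-squares residualization against mean white-matter and CSF
series plus an intercept, and a zero-phase (forward–backward) 4th-order
Butterworth band-pass at 0.01–0.08 Hz. The filter family and order are a
package choice; the band, kernel and confound set are the standard
protocol. Seed maps are Pearson correlations between the mean seed series
and every voxel; Fisher z (atanh, clamped at \(|r| = 1-10^{-7}\)) and a
voxelwise one-sample t across subjects give the group map.

## Outcome statistics

One-way within-subject (repeated-measures) ANOVA across follow-up
timepoints, with \(F = MS_\mathrm{time}/MS_\mathrm{error}\) on
\((t-1),\,(t-1)(n-1)\) degrees of freedom; sphericity is assumed (no
Greenhouse–Geisser correction — a documented limitation). Tukey–Kramer
post hocs use the studentized range with the ANOVA error mean square.
Associations are Pearson correlations with two-sided t-based p on \(n-2\)
degrees of freedom, plus least-squares slope and intercept. The last
follow-up is treated as an ordinary seventh timepoint.

## The phantom and what it does (not) emulate

The phantom lives directly in a common world space — there is no
registration stage, by design. RAS millimetres; 0-based voxel arithmetic
internally maps each world point to the half-open voxel cube that owns it.
The default grid is 64³ at 1 mm (the smallest field of view containing the
region layout); functional runs use 22³ at 3 mm, the normative acquisition
resolution.

* **Anatomy.** A brain sphere with a grey shell and white core; bilateral
  CM (3 mm) and parafascicular (2 mm) spheres at the stereotactic target
  (±9, −9, 0) and medial-posterior to it; six parcellation spheres
  (brainstem/cerebellum, pre/postcentral, SMA, middle and superior
  frontal) at fixed world coordinates, all labelled grey matter.
* **Tractogram.** 200,000 streamlines by default (the whole-brain
  connectome scale). A planted bundle (default 4%) runs from a
  sensorimotor region through a waypoint scattered around the CM centre
  (2.5 mm SD) down to the brainstem/cerebellum, as quadratic Bézier arcs;
  distractors are random smooth arcs rejected if any vertex enters the
  CM/Pf neighbourhood (nucleus radius + 1 mm), so ground truth is clean.
* **Cohort.** Each patient: bilateral placements at target + isotropic
  Gaussian jitter (1.75 mm SD), one random active contact, integer
  amplitude 1–5 V, analytic VTA at 0.2 V/mm. Planted connectivity is the
  bundle count through the unioned VTA; improvement at the 24-month
  endpoint is `effect × connectivity + N(0, noise_sd²)` truncated to
  [−100, 100] (default effect 5, noise 5), with earlier follow-ups ramping
  toward it — emulating the clinical time course of delayed, then stable,
  response.
* **fMRI.** Voxel series are unit-variance AR(1) noise plus a shared AR(1)
  latent signal loaded on the planted network (dilated CM/Pf seed
  neighbourhood, brainstem/cerebellum, sensorimotor regions) with loading
  \(\lambda = c/\sqrt{1-c^2}\), so the expected seed–network correlation
  approximates the coupling target \(c\) (default 0.6). All remaining
  grey-matter voxels carry a weak positive loading (15% of the coupling),
  emulating the broad cortical projection of an arousal network; white
  matter and CSF carry none, so the nuisance regressors stay signal-free.
  The background loading is what makes "no negative connectivity anywhere
  at nonnegative coupling" a structural property of the phantom rather
  than a coin flip over sampling noise in signal-free regions.

Determinism: every generator draws from its own named substream of the
master seed, so identical spec + seed reproduce outputs bit for bit and
adding one generator never perturbs another.

**Calibration.** The free phantom settings were fixed by a Monte-Carlo
calibration at the study conditions (10 patients, 2000 streamlines, effect
5, noise 5) before the test suite was finalized, and not revisited:
bundle fraction 0.04 and jitter 1.75 mm keep per-patient connectivity in a
range where improvements rarely saturate the ±100% bound, give each bundle
fiber enough connected patients for a defined score, and leave enough
connectable distractors that the defined-score pool is not trivially pure —
under outcome permutation, selection precision falls to the bundle share of
that pool, which is the correct chance level for the procedure.

**What passing tests show — and not.** The phantom has exact geometry,
Gaussian noise, no registration error, no scanner artefacts, no
partial-volume mixtures, and a single coherent bundle. Passing recovery and
association tests therefore demonstrates that the *procedures* are
implemented correctly and behave as designed under their own assumptions;
they say nothing about robustness to real tractography biases, real fMRI
noise structure, or anatomical variability.

## Problem sizes and runtime posture

The end-to-end pipeline default uses 2000 streamlines, 10 patients, 20
functional subjects of 124 frames on the 3 mm grid; the whole-brain
200,000-streamline default is exercised where the scale itself is the
claim. These sizes keep a full run and the complete test suite in the
minutes range on a single core while leaving every statistic estimable.

## Decisions on genuinely open points

* Only the Medtronic 3389 is registered; a second clinical lead is named in
  the source setting but its geometry is not published there, so it is not
  modelled.
* Both centroid and minimal VTA–CM distances are emitted; neither is
  privileged.
* "Top 10%" is taken over signed t, not |t| — an interpretation, exposed as
  an option.
* Per-patient seizure-burden style columns beyond the improvement
  percentages are not emulated numerically.
* The repeated-measures table is required complete; variable follow-up
  duration is metadata only.
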