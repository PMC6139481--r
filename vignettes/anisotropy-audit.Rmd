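---
title: "Auditing diffraction anisotropy: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing diffraction anisotropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anisoaudit)
```

## The problem

Macromolecular crystals often diffract anisotropically: the resolution to
which useful intensities extend depends on direction. The conventional
explanation ties weakly diffracting directions to directions poor in
crystal contacts. Auditing that claim across many entries needs a uniform,
automated recipe for both sides of the comparison: reciprocal-space
statistics quantifying the anisotropy of each data set, and real-space
statistics quantifying how the molecules pack. This vignette documents the
models behind each estimator in `anisoaudit`, the tunable parameters and
their defaults, the synthetic data used to validate everything, and the
places where a design choice was genuinely open.

## Conventions

One Debye–Waller convention is used throughout: with
s = sinθ/λ = 1/(2d), amplitudes attenuate as exp(−B s²) and intensities as
exp(−2 B s²). Coordinates live in the standard PDB orthogonalization frame
(crystal **a** along Cartesian x, **b** in the x–y plane), so packing
geometry and reciprocal geometry share one frame; all d-spacings and the
tensor eigen-spread are invariant to this choice (checked by test).

## The anisotropic tensor fit

For reflection *h* with unit scattering direction **n**, the model for the
shell-normalized log intensity is

y_h = ln(I_h / ⟨I⟩_shell(h)) ≈ c_shell(h) − 2 s_h² (**n**ᵀ B **n**),

linear in the six unique components of the symmetric tensor B. The fit is
plain least squares with outlier rejection: reflections with residuals
beyond 3·RMS are removed and the fit repeated, up to 5 cycles or until the
rejection set stabilizes. The reported `delta_b` is b₃ − b₁, the spread of
the eigenvalues.

Three numerical choices deserve explanation:

- **Per-shell scale intercepts.** The scale `c` is estimated per resolution
  shell rather than as one global constant. Shell normalization removes the
  radial mean falloff only up to the within-shell structure; with a single
  intercept, genuinely anisotropic data leaves a radial sawtooth in the
  residuals (largest in the wide low-resolution shells) that a 3·RMS rule
  then misreads as outliers. With per-shell intercepts the model is exact
  on noise-free data — zero residuals, zero rejections — which is the
  behaviour a rejection count should have when no outliers exist. This is
  also how binned scaling works in anisotropy-correction programs.
- **Isotropic indeterminacy.** Because the normalization absorbs any radial
  trend, the trace of B is not identified; only the anisotropic part is.
  `delta_b` is invariant under isotropic shifts (tested by fitting paired
  simulations with and without an added isotropic B), so nothing downstream
  depends on the indeterminate part.
- **Rejection-threshold floor.** The 3·RMS threshold is floored at 1e−8 in
  log units so that numerically exact fits do not reject reflections on
  floating-point jitter.
- **Point-group symmetrization.** The fitted tensor is averaged over the
  point-group rotations (B ← mean RᵀBR, rotations conjugated into the
  Cartesian frame), enforcing crystallographic admissibility without a
  constrained solver.

The fit is deterministic; it fails loudly (rather than returning garbage)
when the scattering directions are coplanar or fewer than 50 usable
positive intensities exist.

The rejection *percentage* reported by the audit is defined by this 3·RMS
rule. Likelihood-based anisotropy servers use their own rejection criteria,
so rejection counts are comparable across entries audited with this
package, not with numbers from other software. On Wilson-distributed data
the rule settles around 1–2.5%, driven by the heavy left tail of
log-exponential intensities.

## Wilson B

The Wilson B is the slope statistic of the classical Wilson plot: a
weighted least-squares line of per-shell ln⟨I⟩ against the shell mean s²,
weights equal to shell populations, B = −slope/2. Shells with mean
resolution coarser than 4.5 Å are excluded — the low-resolution regime is
dominated by solvent and molecular-transform structure and does not follow
Wilson statistics — and at least three shells must remain, so the
estimator degrades gracefully for low-resolution data sets. Twenty shells
of near-equal population are the default; shells with non-positive mean
intensity (possible with background-subtracted intensities) are dropped
with a warning. A negative fitted B is returned but flagged: it is a
diagnostic of non-Wilson falloff, not an error.

## Directional resolution limits and delta_res

For each principal axis of the fitted ellipsoid, reflections whose
scattering vector lies within a 20° half-angle cone of the axis (Friedel
mates pooled, so ±axis is one cone) are binned by resolution into 10
near-equal-population bins, ordered low to high resolution. Walking the
bins, the limit is the high-resolution edge of the last bin, before any
failure, whose mean F/σF is at or above 3.0; if the first bin already
fails the limit is the lowest-resolution d of the cone, and if no bin
fails it is the cone's dmin. `delta_res` is the spread of the three
limits.

Choices: 20° balances directional purity against per-cone population
(narrower cones starve the bins; cones under 20 reflections are flagged
unreliable but still reported). No interpolation is done between bins —
the limit is quantized to bin edges, about half a bin width, which keeps
the procedure deterministic and auditable. When a file carries only
intensities, amplitudes for this step are derived as F = √I,
σF = σI/(2F), excluding I ≤ 0; a full Bayesian (French–Wilson) conversion
is deliberately out of scope.

## Packing metrics

Crystal contacts are ordered atom pairs (ASU atom, symmetry-image atom)
within 4.0 Å, the atom-pair semantics of CCP4's `ncont`; each ASU atom may
contribute several contacts. Self-image pairs at distance ~0 (special
positions) are excluded; intra-ASU pairs are not crystal contacts. The
implementation uses a uniform cell-list grid and must agree exactly with
an exhaustive all-images scan — the two code paths are kept independent
and compared on randomized toy crystals at every test run. Lattice
translation ranges are derived per operator from fractional bounding boxes
plus an exact cutoff margin (cutoff × the reciprocal row norm), so the
count is invariant to where the deposited model sits relative to the
origin — models translated by whole cells are common in practice.

The contacts **ratio** divides by the total atom count including
heteroatoms and waters; waters are also allowed as contact partners on
both sides, since the deposited solvent network is part of the packing.
The asymmetric-unit mass for the Matthews coefficient, by contrast, sums
polymer atoms only, × 1.05 for the hydrogens absent from X-ray models
(hydrogen is ~5% of protein mass). V_M = V_cell/(Z·mass) and solvent
content 100·(1 − 1.23/V_M) follow the CCP4 `matthews_coef` convention
(1.23 is the reciprocal of the 0.74 cm³/g protein partial specific
volume in V_M units). Over-packed hypothetical cells yield negative
solvent percentages, flagged but not clamped, so the arithmetic stays
invertible.

## Curation and subsets

Four filters define the curated set: revision year ≥ 2006 ("after 2005"
read strictly), resolution ≤ 5.0 Å, amplitude-based delta-B ≤ 150 Å², and
contacts ratio ≤ 1 — the last three inclusive on the keep side, all four
boundary cases unit-tested. Records whose delta-B or contacts ratio could
not be computed are *not* dropped by those rules: the filters act on
computed values, not on missingness. Each dropped record carries its first
failing rule (checked in the order year, resolution, delta-B, ratio) so
per-reason counts are well defined.

Membrane/soluble classification is driven entirely by user-supplied
annotation tables (closed vocabularies for fold, crystallization,
function, topology); an entry absent from the table is soluble. One
inference rule exists: when a membrane entry's crystallization is
unannotated, lipidic-cubic-phase is inferred from keywords or het codes
("LIPIDIC CUBIC PHASE", "LCP", "MESO", monoolein-class lipid ids). The
marker list is configurable because the upstream LCP extraction procedure
is cited in the literature rather than printed; ours is an approximation
of it. The year filter uses the REVDAT revision year — the header field
this audit extracts — acknowledging that deposition and revision years can
differ.

## What the synthetic data does and does not emulate

`gen_reflections()` draws acentric Wilson intensities — exponential with
mean K·exp(−2 s² **n**ᵀB**n**) — on a complete Friedel-unique lattice to a
chosen dmin, with reported σI equal to a fraction of the shell mean
(default 0.1) and an optional per-axis σ-inflation mode to construct
directional F/σF crossings. The default cell is a 45 Å cube at dmin = 2 Å,
about 24,000 unique reflections — the scale of a typical well-measured
data set, and the problem size at which the recovery tests and the
acceptance script run (smaller 25 Å fixtures, ~4,100 reflections, are used
where speed matters more than asymptotics). Generation is byte-identical
under a fixed seed, and the simulated intensities pass a per-shell
Kolmogorov–Smirnov check against the exponential law.

Deliberately **not** modelled: centric zones (all statistics are
acentric), systematic absences (reflection generation defaults to P1;
non-P1 symmetry is exercised in the real-space module), twinning,
anomalous signal, resolution-dependent completeness, and
structure-factor calculation from coordinates. Passing tests therefore
demonstrate correctness of the estimators under the stated statistical
model, not robustness to every pathology of real deposited data; on real
files the pipeline degrades per entry (absent fields plus a QC log line)
rather than aborting.

`gen_crystal()` builds toy crystals whose ground-truth contact count comes
from the exhaustive scan, and `gen_audit_population()` plants per-rule
curation violations with values drawn just inside/outside each boundary,
so the filters are tested at population scale against known truth.

## Known limitations

- The tensor fit is least squares on log intensities, not maximum
  likelihood; with very weak high-resolution shells the log transform
  discards non-positive intensities, biasing those shells slightly. The
  eigen-spread recovery stays within a few percent under the conditions
  above (the acceptance script measures it), but rejection percentages are
  definitionally tied to the 3·RMS rule.
- The bundled space-group table covers the groups the audit exercises
  (P1, P2, P2₁, C2, P222, P2₁2₁2, P2₁2₁2₁, P4₃2₁2); unknown symbols raise
  an error rather than guessing. Extending the table is a data change, not
  a code change.
- Multi-model coordinate files are read first-model-only; alternate
  locations keep the first-listed conformer.
- mmCIF support is deliberately minimal: refln loops plus cell/symmetry
  items, the subset deposited structure-factor files actually use for
  this audit.
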