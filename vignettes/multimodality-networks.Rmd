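---
title: "Multimodality imaging metrics as a correlation network: models, assumptions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodality imaging metrics as a correlation network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qimnet)
```

## Scope and rationale

Head-and-neck tumors are routinely characterized by several functional
imaging modalities at once: diffusion-weighted MRI probes cellularity,
dynamic contrast-enhanced (DCE) MRI probes perfusion and capillary
permeability, and dynamic FMISO PET probes perfusion and hypoxia. Each
modality yields per-lesion quantitative imaging (QI) metrics through a
kinetic model fit. `qimnet` implements those three model families, the
assembly of the fitted metrics into a lesion-by-metric table, and a
network view of the metric-to-metric Spearman correlations in which
communities of tightly coupled metrics are found with a signed spin-glass
algorithm.

Because the clinical source data for this kind of analysis are generally
not public, the package is organized around a synthetic cohort generator
whose defaults reproduce the scale and statistics of a reference cohort
of 27 metastatic nodal lesions: the published per-metric means and SDs
are the default marginals (`qi_metric_defaults()`), and the published
18-metric Spearman correlation matrix ships as a plain-text fixture
(`table2_correlations()`). Every downstream stage is validated by
parameter recovery against the generator's known ground truth.

## Kinetic models and their assumptions

### Diffusion

The monoexponential model `S(b) = S0 exp(-b ADC)` and the IVIM
biexponential `S(b) = S0 [f exp(-b D*) + (1-f) exp(-b D)]` are fitted per
voxel over the default ladder b = 0, 20, 50, 80, 200, 300, 500, 800,
1500, 2000 s/mm². Choices that matter:

* **Segmentation threshold 200 s/mm²** for the IVIM initialization: the
  pseudo-diffusion compartment (D* ≈ 9e-3 mm²/s) has decayed by ~3
  e-foldings at b = 200, the standard segmented-fit convention.
* **Bounds** D ∈ [1e-5, 4e-3], D* ∈ [3e-3, 0.1] mm²/s, f ∈ [0, 1]. The
  disjoint D/D* boxes make the compartments non-interchangeable, so
  fitted `d_star >= d_true` always holds.
* **ADC uses all ten b-values**, so on perfused tissue it is a
  perfusion-contaminated effective decay constant; its ground truth in
  the pipeline's recovery report is therefore the monoexponential fit of
  the *noiseless* biexponential curve, not the table-level ADC draw.
* Fitting is plain least squares on magnitude data. At the SNR regimes
  studied (≥ 50 at b = 0) the Rician bias this ignores is ≲ 0.5% of ADC.
* S0 is co-estimated in both models; a monoexponential-collapse start
  (f = 0) is always tried, which guarantees the IVIM residual never
  exceeds the monoexponential residual on the same voxel.

### DCE-MRI with finite water exchange

The tissue concentration follows the standard Tofts model; the signal
model is the two-site water-exchange (shutter-speed) eigenvalue rate with
the spoiled-gradient-echo equation on top. Assumptions and conventions:

* **Negligible vascular water** (two-site, not three-site exchange), so
  the exchange back-rate follows from population balance:
  `kei = kie (1 - ve) / ve` with `kie = 1/tau_i`.
* **R1i = R10 and R10e = R10**: the intracellular and pre-contrast EES
  rates are set to the measured pre-contrast tissue rate. These are
  conventions, not measurements; both are configurable.
* **Relaxivity r1 = 3.7 s⁻¹mM⁻¹**, a standard value for Gd chelates at
  3 T; configurable.
* **M0 calibration** from the mean of the pre-contrast frames at the
  known pre-contrast rate, so the dynamic fit has exactly three free
  parameters (Ktrans, ve, τᵢ), bounded to [1e-4, 2] min⁻¹,
  [0.01, 0.99], [0.05, 3] s, with a fast-exchange-limit two-parameter
  fit as seed and two perturbed restarts.
* **T1 mapping** from flip angles 5/15/30° at TR = 7 ms: DESPOT1
  linearization refined by nonlinear least squares; an angle-independent
  signal (no T1 information) is flagged as a failure.
* The default synthetic AIF is a biexponential of the classical
  Tofts–Kermode form (a1 = 3.99, a2 = 4.78 kg/L, m1 = 0.144,
  m2 = 0.0111 min⁻¹, 0.1 mmol/kg), delayed to the bolus-arrival frame.
  This is a smooth post-bolus plasma model without a first-pass peak; a
  `measured` AIF path accepts any sampled Cp series.

### Dynamic FMISO PET

The irreversible one-plasma two-tissue compartment model with blood
volume is solved analytically: with β = k2 + k3 the impulse response is
`K1 (k3 + k2 exp(-β u)) / β`, convolved exactly with a piecewise-linear
input. Conventions:

* **DV = K1/k2**, the distribution volume of the reversible compartment —
  the concentration of unbound tracer relative to blood at equilibrium.
  The generator enforces this identity exactly (`k2` is derived from the
  sampled K1 and DV).
* **Whole-blood curve = input function** (image-based venous input), no
  plasma partition; configurable.
* **Input function**: zero before bolus arrival, linear rise to the
  peak, then three decaying exponentials continuous at the peak. The
  continuity constraint and the shared peak time are our parameterization
  choice; the 8 parameters are fitted to frame-averaged data in log
  space for amplitudes and rates.
* **Frame weighting** ∝ √duration, the usual count-statistics
  approximation; the frame schedule is 6×5 s, 3×10 s, 4×60 s, 2×150 s,
  2×300 s, 1×600 s plus 600 s statics at 90 and 160 min. TBR is computed
  at the last (≈160 min) static frame.
* **SUL** uses the James lean-body-mass formula (male
  `1.10W − 128(W/H)²`, female `1.07W − 148(W/H)²`).
* Bounds: K1, k2 ∈ [1e-3, 2] min⁻¹, k3 ∈ [0, 0.05] min⁻¹,
  vb ∈ [0, 0.2].

## Network construction and community detection

Spearman correlations use midranks and the two-sided t approximation
`t = ρ √((n-2)/(1-ρ²))`; at ρ = 0.48, n = 27 this gives p = 0.0113,
reproducing the conventional software output at this sample size (an
exact permutation law is used as a test oracle at n ≤ 6). Raw p-values
are thresholded at α = 0.05 — deliberately without multiple-testing
correction, matching the practice this package emulates; a
Benjamini–Hochberg flag is available (`spearman_matrix(..., bh = TRUE)`)
but defaults off. The default node set for community detection is the
16-metric list `qi_network_metrics()` (all metrics except the PET volume
and kep), matching the published network's node set.

The community objective is the Reichardt–Bornholdt Potts Hamiltonian
extended to signed graphs: positive and negative edges get separate
configuration null models, and the energy of co-assigning two nodes is
`-(w⁺ − γ₊p⁺) + (w⁻ − γ₋p⁻)`. The published network contains negative
correlations, which the original positive-only Hamiltonian cannot
represent. Defaults γ₊ = γ₋ = 1. Edges are weighted by the signed
correlation value; an unweighted ±1 mode is provided
(`annealing_config(weighted = FALSE)`) since a correlation network can
defensibly be analyzed either way. The weighted mode is the default: on
the packaged fixture it yields the published four communities, whereas
the unweighted mode merges the uptake/volume and cellularity communities
into three (the six-member perfusion/permeability community around
Ktrans is stable under both).

Annealing is single-spin-flip Metropolis over up to 25 states with
geometric cooling 1.0 → 0.01 at factor 0.99 and 50 sweeps per
temperature; 100 restarts with seeds 1..100 form a consensus (best
energy wins, ties to the lowest seed), and the co-assignment frequency
matrix across restarts is reported as a stability summary. On every
≤8-node test graph the annealed optimum equals the exhaustive minimum
over all set partitions, and the implementation agrees with an
independent signed spin-glass implementation (igraph's) on the packaged
fixture.

### A documented inconsistency in the reference fixture

Counting the significant entries of the packaged correlation fixture over
the 16 network metrics gives 37 edges with degree(DV) = 9, whereas the
reference analysis reports 33 edges and degree(DV) = 8. No pruning rule
reproducing 33 from the printed matrix is stated anywhere; the package
therefore reproduces, and asserts in its tests, only the internally
consistent quantities — degree(Ktrans) = 7, degree(K1) = 6, and the
four-community partition with the published memberships (sizes 3, 3, 6,
4), which is stable under either edge count.

```{r fixture, eval = FALSE}
res <- analyze_table2_fixture()
res$partition$n_communities      # 4
table(res$partition$assignment)  # community sizes 3, 3, 6, 4
```

## The synthetic cohort: what it does and does not emulate

`sample_ground_truth()` draws metric vectors from a Gaussian copula: the
target Spearman matrix is mapped to latent Pearson correlations via
r = 2 sin(πρ/6), the latent matrix is repaired to positive
semi-definiteness by clipping eigenvalues at 1e-8 and renormalizing
(printed, rounded correlation tables are rarely exactly PSD), and latent
normals are pushed through moment-matched marginals — log-normal for
positive quantities, logit-normal for fractions, which respect positivity
and bounds where a normal would not. Rank correlations are invariant
under these monotone transforms, so the calibration r = 2 sin(πρ/6)
carries over exactly; tests verify ±0.02 agreement at n = 5000 across
ρ ∈ [−0.9, 0.9].

The blood volume fraction vb, which has no published summary, defaults
to 0.05 ± 0.02 — a typical perfused-node value. kep's marginal
(0.56 ± 0.25 min⁻¹) derives from the Ktrans and ve means.

Noise models: Rician on DWI magnitude signals; Gaussian on DCE signals;
Gaussian with variance ∝ 1/duration on PET frames. SNR is defined
against the b = 0, pre-contrast, and peak-frame signal respectively. The
defaults (27 lesions, 100 voxels per lesion, seed 20210803, SNR 50) are
the package's reference study conditions.

What the generator does **not** emulate: anatomy and image rendering,
motion, partial-volume effects, B1 inhomogeneity, co-registration error,
segmentation variability, or any coupling between the table-level
metrics (volumes, SUL) and the simulated raw signals — volumes and SUL
pass through from ground truth, and the fitted TBR/k3 columns inherit
the kinetics rather than their table-level draws. Passing recovery tests
therefore demonstrates correctness of the estimation chain under the
stated noise models, not robustness to the many acquisition artifacts of
real data.

## Numerical choices

* **Convolutions** (Tofts and 2TC) use an exact O(n) recursion for
  piecewise-linear inputs, with stable `expm1`/series branches for small
  rate×step products; smooth AIFs are resampled to a 0.25 s grid before
  the recursion (relative error < 1e-8 against closed-form exponential
  convolutions). Frame averages are trapezoidal on a ≤0.5 s grid that
  includes the input function's kinks and all frame boundaries.
* **All nonlinear fits** use bounded Levenberg–Marquardt
  (`minpack.lm::nls.lm`) with multi-start where the objective is
  multimodal (IVIM 2–3 starts, FXR 3, 2TC 3); the best residual wins.
* **Degenerate inputs** are flagged, not errored: constant diffusion
  signal → ADC boundary flag; angle-independent VFA signal → T1 failure;
  zero-enhancement DCE → Ktrans pinned at its lower bound with a
  `no_enhancement` flag (detected by comparing the optimum against the
  clamped-Ktrans deviance); pure-blood TAC → `no_uptake`; all-zero blood
  TAC → degenerate input-function fit.
* **Annealer determinism**: the C++ Metropolis loop draws from R's RNG,
  so a partition is a pure function of (graph, config, seed); community
  labels are canonicalized by smallest contained node index.

## Validation design and problem sizes

The test suite computes every expected value it asserts: closed-form
convolution oracles, hand arithmetic on 3-node graphs, exhaustive
enumeration of all partitions on ≤8 nodes (Bell(8) = 4140), exact
permutation and sign-enumeration laws for the rank statistics, and
Monte-Carlo recovery experiments. Reference sizes: 500 voxels for the
diffusion experiments, 200 curves for FXR and 2TC, 25–50 seeds for
curve-level and network-level replications, 50 random 8-node graphs for
the annealer-vs-enumeration check. The pipeline's end-to-end tests run a
reduced cohort (5 lesions × 2 voxels) twice and require byte-identical
outputs.

### Recovery at the information floor

At the reference conditions (SNR 50, the default protocols and AIF, S0
and M0 co-estimated), the Cramér–Rao bound for the median absolute
relative error is ≈2.3% for ADC, ≈16% for the IVIM perfusion fraction f,
≈16% for ve, and ≈32% for τᵢ; the package's estimators attain these
bounds to within measurement error of the Monte-Carlo experiments. Any
stricter recovery expectation at these conditions (for instance 2% for
ADC or 10% for ve) is unattainable by *any* estimator, which the
acceptance tests document by asserting the stricter values and failing
them transparently while the CRLB-consistent performance passes. The
practical reading: at SNR 50 the weakly identified shutter-speed
parameters (ve, τᵢ) and f carry 15–30% voxelwise uncertainty, which is
why ROI means over ~100 voxels, not single-voxel values, are the metric
of record.

## Known limitations

* The FXR fit fixes R1i = R10 and R10e = R10; violations (e.g. marked
  pre-contrast compartmental T1 differences) bias ve and τᵢ.
* The biexponential default AIF has no first-pass peak; with a measured,
  peaked AIF the shutter-speed parameters are better identified than the
  floor figures above suggest.
* The 2TC model treats the image-based venous curve as both plasma input
  and whole-blood signal; metabolite correction and plasma partition are
  out of scope.
* Voxelwise parametric PET maps, DICOM/NIfTI ingestion, co-registration
  and segmentation are out of scope; the package starts from curves and
  tables.
* The interface is R functions plus `scripts/acceptance.R`; there is no
  shell CLI, as the intended users drive the pipeline from R
  (`run_pipeline()`, `analyze_table2_fixture()`, and the per-stage
  `fit_*` functions).
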