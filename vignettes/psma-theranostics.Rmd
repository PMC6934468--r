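---
title: "Whole-body PBPK modelling of PSMA-targeted imaging and therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body PBPK modelling of PSMA-targeted imaging and therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmapbpk)
```

## Scope

`psmapbpk` simulates the whole-body pharmacokinetics of small-molecule
ligands targeting the prostate-specific membrane antigen (PSMA) in virtual
metastatic prostate-cancer patients, and derives the two quantities that
matter for theranostic optimization:

* **imaging** — the normalized activity concentration
  $c_i(t) = A_i(t) / (A_0 V_i)$ of each organ 1 h after injection of a
  Ga-68-labelled ligand, without decay correction;
* **therapy** — MIRD absorbed doses $D_i(T) = A_0\,\tilde a_i(T)\,S_{i\leftarrow i}$
  for a ~7.3 GBq Lu-177-labelled injection integrated to $T = 30000$ min,
  and the tumour-to-kidney dose ratios derived from them.

A sweep engine varies the association rate $k_{on}$
(0.01–0.1 L nmol$^{-1}$ min$^{-1}$), dissociation rate $k_{off}$
(0.0001–0.1 min$^{-1}$), internalization rate $\lambda_{int}$
(0.0001–0.01 min$^{-1}$) and total ligand amount (1–1000 nmol in half-decade
steps) over a cohort, and summarizes cohort fold-changes, ratio tables and
optima.

## Model structure

Two chemically identical species circulate simultaneously: the
radiolabelled ("hot") ligand, whose molar amount is fixed by the injected
activity through $n = A_0/(\lambda_{phys} N_A)$, and the unlabelled ("cold")
carrier making up the remainder of the injected amount. Both compete for the
same receptors; physical decay converts hot into cold in place, in every
compartment including urine, so the species sum is exactly conserved.

Each of the ten tissues (two explicit tumour lesions, the merged remaining
tumour burden "tumour REST", kidneys, liver, gastrointestinal tract, lung,
red marrow, a lumped muscle-and-fat background, and rest-of-body) carries
three pools per species: free ligand $F$, receptor-bound ligand $B$ and
internalized ligand $N$. Per tissue $i$ and species $s$:

* flow-limited exchange with plasma,
  $Q_i\,(f_u P_s/V_p - C_{free,i,s})$, where $Q_i$ is the plasma flow
  (perfusion × mass), $f_u$ the unbound plasma fraction and
  $C_{free} = F/(\alpha_i V_i)$ with accessible fraction $\alpha_i$;
* second-order association $k_{on} C_{free} R_{free,i}$ to the shared free
  receptor pool $R_{free,i} = R_i V_i - \sum_s B_{i,s}$, dissociation
  $k_{off} B$, internalization $\lambda_{int} B$, and first-order release
  $\lambda_{rel,i} N$ returning internalized ligand intact to the tissue
  free pool (degradation is a configuration option, off by default);
* an optional affinity-independent ("unspecific") first-order uptake
  $\lambda_{ns,i} F$ into the internalized pool.

Systemically, glomerular filtration removes unbound plasma ligand into a
cumulative urine compartment at rate $GFR \cdot f_u P_s/V_p$. Serum protein
binding is an instantaneous equilibrium through $f_u$; the injection is a
plasma bolus. The tumours, kidneys, liver and gastrointestinal tract are
PSMA-positive (nonzero receptor density); internalization frees the surface
receptor, so total receptor capacity is constant.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| plasma volume $V_p$ | 3 | L | reference adult |
| unbound fraction $f_u$ | 0.3 | – | instantaneous serum-protein equilibrium |
| GFR | 0.1 | L/min | reference adult |
| accessible fraction $\alpha$ | 0.6 | – | ligand crossing the capillary wall is treated as instantaneously diffused with access to binding sites, so the effective space is larger than the vascular + interstitial volume alone |
| tumour $\lambda_{rel}$ | 2.5e-4 | 1/min | geometric mean of the Lu-177 decay constant and the reference internalization rate 0.001/min, giving an intermediate tumour effective half-life |
| kidney $\lambda_{rel}$ | 5e-4 | 1/min | release from kidney about twice that of tumour |
| kidney $\lambda_{ns}$ | 0.005 | 1/min | small affinity-independent kidney uptake; amino-acid co-infusion blocks most but not all unspecific uptake |
| background / rest $\lambda_{ns}$ | 0.005 | 1/min | slow deep-tissue distribution pool (non-receptor cellular uptake in muscle and fat) |
| kidney density / perfusion | 19 nmol/L, 1.7 ml/g/min | | exemplar-patient values |
| liver, GI density | 3, 6 nmol/L | | effective values; with the kidneys they form a normal-tissue receptor sink of ~19 nmol |

All organ volumes, masses and perfusions are ICRP-style reference-adult
values (`default_physiology()`) and are overridable per patient. Units are
fixed repo-wide to nmol, L, min, Bq and Gy; perfusion is entered in
ml g$^{-1}$ min$^{-1}$ and converted to a flow once at construction.

Nuclides: Lu-177 (half-life 6.647 d, mean electron energy 147.9 keV and
photon energy 35.0 keV per decay) and Ga-68 (67.71 min). For 7.3 GBq of
Lu-177 the hot molar amount is ~10 nmol, so therapy cells with a total
ligand amount below that are physically infeasible (the label alone would
exceed the amount); the sweep records them with a failure marker and
continues. For 150 MBq of Ga-68 the hot amount (~0.0015 nmol) is negligible
against 1–10 nmol imaging amounts, and the imaging metric is exactly
invariant to the injected activity at a fixed total amount, because the hot
dynamics are linear in the hot fraction given the species-sum trajectory.

## The synthetic cohort

The study cohort of the source data — 13 patients individually fitted to
PET and peri-therapeutic measurements — is not public, so
`generate_cohort()` emulates a 13-patient cohort from the reported
marginals: total tumour volume (median 0.4 L, range 0.02–5 L), tumour
receptor density (median 50 nmol/L, range 4–124 nmol/L) and tumour
perfusion (median 0.2 ml/g/min, range 0.02–1.6 ml/g/min), with injected
activity ~ N(7.3, 0.3) GBq truncated at zero.

Each quantity is drawn from a truncated log-normal: $\sigma$ is set so the
stated range spans the 1st–99th percentile, and because the ranges are
asymmetric around the median on the log scale, the location parameter is
solved numerically so that the *truncated* distribution has the stated
median. The total tumour volume is split into two explicit lesions (each
uniformly 5–20% of the total) and the REST remainder. REST receptor density
is a fresh draw times 2.0 and REST perfusion a fresh draw times 0.5,
mirroring the exemplar patient (66 vs 33 nmol/L, 0.04 vs 0.08 ml/g/min);
draws are resampled until REST is strictly denser and slower-perfused than
the lesion mean. This per-patient enforcement is stricter than the
on-average statement it encodes, which makes the property testable. Joint
correlations among volume, density and perfusion are unreported;
independence is assumed and flagged as a limitation. Non-tumour organs are
fixed at the physiology defaults; only tumour parameters and the injected
activity vary across patients.

Sampling is deterministic given (spec, seed) and stream-stable: each
patient draws from a substream derived from the seed and the patient index,
so enlarging a cohort preserves the earlier patients.

What the generator does *not* emulate: covariate structure (age, weight)
linked to physiology, the tumour-volume correction factor of the original
fitting procedure, inter-patient variation of non-tumour organs, and any
correlation between tumour burden and kidney function. Tests passing on
this cohort therefore demonstrate internal consistency of the model and
reproduction of cohort-level orderings, not agreement with any individual
real patient.

## Dosimetry

Time-integrated activity coefficients $\tilde a_i(T)$ are computed by
adaptive quadrature on a cubic-spline interpolant of the dense solver
output (300 log-spaced points over $[10^{-2}, 30000]$ min resolving the
bolus); no tail is extrapolated beyond $T$.

Sphere S-values are computed at build time from decay data rather than
copied from published tables: the electron component is absorbed locally
($S_e = 60\,\Delta_e/m$, a good approximation for Lu-177 betas in spheres
above a gram), and the photon component uses the small-sphere
self-absorption approximation $\phi_p \approx \min(0.9,\ 0.75\,\mu r)$ with
an effective attenuation coefficient $\mu = 0.105$ cm$^{-1}$ (soft tissue
at ~35 keV). The table spans 0.5 g to 6 kg — wide enough for the smallest
cohort lesions (~1 g) and the largest merged REST regions (several kg) —
and is interpolated log-log with no extrapolation. Tumour masses use unit
density; tumour REST is treated as a single sphere of its total mass; the
kidney uses the sphere value at the patient's kidney mass.

Tumour and kidney doses are self-dose only. The red-marrow dose is the
marrow sphere self-dose plus a simplified photon cross-dose from plasma,
kidneys, liver and the tumour regions: photon energy emitted in each
source times a lumped whole-body absorbed fraction (0.3), mass-weighted to
the marrow. This is a deliberate simplification of a full S-matrix
treatment; the marrow acceptance check is correspondingly a bound, not an
equality.

## Numerical choices

* Stiff integration (LSODA with a compiled right-hand side), rtol 1e-8,
  atol 1e-12 nmol; results are bit-reproducible for identical inputs.
* Negative excursions are clipped to zero only if smaller in magnitude than
  ten times the solver tolerance; anything larger raises an error rather
  than being silently truncated.
* The 1 h imaging readout is an explicit solver output time, not a nearest
  grid point.
* Ties in `find_optimum()` break toward the smaller ligand amount, then the
  smaller $k_{on}$.
* Cohort statistics are means and (n−1) standard deviations of per-patient
  ratios; a ratio-of-means alternative would weight patients by magnitude
  and is intentionally not the default.
* Problem sizes used by the test-suite: the full default therapy sweep
  (126 cells × 13 patients) plus a handful of imaging cells, about half a
  minute in total; the distributional checks of the generator use a
  2000-patient cohort.

## Design decisions and known limitations

* **Model equations.** The exact ODE structure of the originally fitted
  patient models is not public; this package fixes the flow-limited,
  bolus-input formulation described above, which is a good approximation
  for small, rapidly equilibrating PSMA ligands.
* **Calibration of unprinted constants.** The fitted per-patient models
  behind the reported cohort statistics are not published. The free
  constants here (accessible fraction, liver/GI receptor densities,
  release rates, unspecific uptake rates) were chosen once so that the
  model operates in the reported qualitative regime — increasing $k_{on}$
  increases the 1 h tumour concentration at typical imaging amounts, and
  the kidney dose retains an affinity-independent component — and then
  frozen.
* **Rebinding regime.** With the printed tumour receptor densities and
  perfusions, dissociated ligand in a tumour is far more likely to rebind
  than to wash out (rebinding factor $k_{on} R_{tot}/Q \approx 25$–40).
  Absorbed-dose fold-changes under a ten-fold $k_{off}$ change are
  therefore larger in this implementation (~3.5–4) than the reported ~2:
  compressing them would require diffusion-limited interstitial transport,
  which is deliberately out of scope, or affinity-independent dose
  components large enough to contradict the reported internalization-rate
  fold-changes. This is the main known quantitative deviation and is
  reflected by the corresponding checks in the acceptance suite.
* Salivary glands, explicit receptor synthesis/degradation, ligand–receptor
  recycling beyond a single effective internalization rate, voxel dosimetry
  and radiobiological dose measures are out of scope.

## Worked example

```{r example, eval = FALSE}
p5 <- patient5_exemplar()
kin <- ligand_kinetics(kon = 0.1, koff = 0.01, lambda_int = 0.001)

imaging_panel(p5, kin, amount = 10)       # 1 h Ga-68 panel, 1/L
therapy_report(p5, kin, amount = 100)     # Lu-177 MIRD report, Gy

cohort <- generate_cohort(cohort_spec(n_patients = 13, seed = 1))
sw <- run_sweep(cohort, sweep_grid(mode = "therapy"))
tumour_to_kidney_table(sw)
find_optimum(sw)
```
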