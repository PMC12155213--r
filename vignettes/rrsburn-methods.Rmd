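---
title: "Methods: resonance Raman decomposition and the Hemoglobin Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resonance Raman decomposition and the Hemoglobin Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrsburn)
```

## The measurement model

Burn depth determines how much of the dermal vasculature survives, and
surviving vasculature determines wound perfusion. Resonance Raman
spectroscopy at 441 nm sits near the heme Soret absorption, so the Raman
bands of hemoglobin are resonance-amplified far above the other skin
constituents; the hemoglobin content of a wound bed can therefore be read
out optically, without contact, in the first days after injury — exactly the
window in which superficial partial-thickness (PT-Superficial) and deep
partial-thickness (PT-Deep) burns are visually indistinguishable but require
different treatment.

A raw acquisition is a sequence of ~1 s CCD frames. Each averaged spectrum is
modeled as

$$ S_{\mathrm{raw}}(\nu) \;=\; a\,S_{\mathrm{HbR}}(\nu) + b\,S_{\mathrm{HbO}}(\nu)
   + m_r\,S_{\mathrm{MitoRed}}(\nu) + m_o\,S_{\mathrm{MitoOx}}(\nu)
   + F(\nu) + \varepsilon(\nu), $$

where the $S_\ell$ are max-normalized reference libraries, $F$ is a smooth
fluorescence background summarized by the scalar $c = \overline{F}$ (its mean
over the 600–1700 cm$^{-1}$ analysis window), and the weights
$a, b, m_r, m_o \ge 0$ are the *signal coefficients* — concentration proxies
for the corresponding species.

The pipeline per acquisition is: dark subtraction → cosmic-spike removal →
trailing 180-frame average → crop to 600–1700 cm$^{-1}$ → fluorescence
baseline extraction → non-negative library regression.

## Baseline extraction

"Fluorescence" here is everything smooth: a 5th-degree polynomial fitted
iteratively to the lower envelope (fit, clip the working spectrum at the
fit, refit — the ModPoly scheme) with defaults `max_iter = 100`,
`tol = 1e-4`. A single-pass least-squares polynomial would ride on top of
the Raman bands; the clipped iteration converges onto the peak-free floor.

The clipped iteration alone still absorbs a few percent of the band
intensity wherever bands crowd together (the envelope cannot dip to the true
floor between overlapping peaks). We therefore add a *peak-masked
refinement*: the converged envelope identifies peak channels (residual above
median + 3 robust SD, each peak run widened by 12 channels to cover
shoulders), and the polynomial is refit by plain least squares on the
remaining baseline-only channels. For peaks without long tails this removes
the bias entirely; the noiseless round trip through the full pipeline then
recovers the generator's $(a, b, m_r, m_o, c)$ at solver precision, which is
the property the index arithmetic downstream relies on.

Two-step (baseline, then libraries) is deliberate and matches the stated
order of the instrument's three-step algorithm; the masked refinement is an
internal detail of the baseline step, not a joint fit of baseline and
libraries.

## Library regression

The residual after baseline subtraction is regressed onto the four libraries
under non-negativity (negative concentrations are nonphysical; the
constraint also stabilizes the small design). With only four columns we
solve the non-negative least-squares problem *exactly* by enumerating all
$2^4$ support subsets, solving each unconstrained subproblem, and keeping
the feasible minimum — the NNLS optimum is always among these candidates by
the KKT conditions. The condition number of the library design is reported
with every fit, and a rank-deficient set is rejected naming the most
collinear pair. Whether the instrument's own regression is sign-constrained
is unknown; tests cover the boundary (a nonphysical anti-correlated input
yields all-zero weights) so the behavior is explicit rather than silent.

## Indices

For wound $x$ on pig $y$ and day $z$:

$$ \mathrm{HI}_{x,y,z} = \frac{(a + b)_{x,y,z}}
  {\tfrac14 \sum_{i=1}^{4} (a + b)_{\mathrm{healthy}_i,y,z}}, \qquad
  \mathrm{FI}_{x,y,z} = \frac{c_{x,y,z}}
  {\tfrac14 \sum_{i=1}^{4} c_{\mathrm{healthy}_i,y,z}}. $$

The denominator averages **exactly four** healthy-skin measurements from the
same pig on the same day; pooling across pigs or days is refused. This
normalization cancels laser power, collection efficiency and systemic
hemoglobin differences — the decomposition is scale-equivariant, so any
global intensity factor divides out. Healthy skin has HI = 1 by
construction.

Site values are screened per category per day by a ROUT-style robust
outlier rule at Q = 2% (median center; RSDR = 68.27th percentile of absolute
residuals × $n/(n-1)$; candidates tested outside-in against step-down
thresholds $Q(n-j+1)/n$ on t-type p-values with $n-1$ df). This follows the
published description of the method; the commercial implementation may
differ numerically, so the pipeline's guarantees are stated as invariants —
monotone removal in the robust residual, ≈Q-level false removal on clean
data, shift/scale equivariance — rather than value agreement. Surviving site
values (1 or 2) are averaged into one index per wound per day; a
single-survivor wound is flagged.

## Wound categorization and classification

Primary categorization follows the burn-creation protocol (45 °C →
Superficial; 63 °C at 15–20 s → PT-Superficial, at 30–45 s → PT-Deep; 96 °C
→ Full-thickness; other 63 °C contact times are a protocol gap and error).
The secondary criterion uses healing: PT-Superficial must close by POD 56,
PT-Deep must still be open at POD 64; violators are excluded with a recorded
reason. Histology depth scores gain 100 µm when the epidermis is missing and
are QC-filtered at <250 µm (Superficial), ≤680 µm (PT-Superficial), >680 µm
(PT-Deep) and >1750 µm (Full-thickness). The 680 µm boundary itself is
ambiguous in the stated rule ("above … removed" vs "below … removed"); we
assign it to PT-Superficial and expose the convention as an argument.

Fixed-cutoff classifiers use strict inequalities (HI > 3.54 ⇒
partial-thickness; HI < 6.58 ⇒ PT-Deep), so a value exactly at the cutoff is
negative. ROC analysis uses the Mann–Whitney AUC (rank formula, ties = ½)
with Hanley–McNeil standard errors; an independent pair-counting oracle
checks it in the tests. Whether the published cutoffs were Youden-optimal is
unstated, so [youden_cutoff()] reports the package's own optimum alongside
the fixed-cutoff confusion; Youden ties are broken toward the
higher-specificity midpoint (for perfectly separated groups this returns the
gap midpoint).

## The synthetic world

No raw spectra were published, so the generator *states* a world with the
study's structure and the printed category statistics, and every test is
explicit about being run in that world:

* **Libraries.** Pseudo-Voigt peak sets at heme-band-like positions (HbO ν4
  near 1375 cm$^{-1}$, HbR ν4 near 1357, cytochrome-like bands near
  750/1128/1314/1585). Defaults use the Gaussian limit (η = 0): Lorentzian
  tails put a slowly varying pedestal under the whole window that is
  mathematically indistinguishable from fluorescence, and the real
  instrument's libraries are measured, not parametric, so nothing is lost by
  choosing identifiable shapes. Positions are configuration, and the only
  contract is pairwise cosine similarity < 0.99.
* **Frames.** Clean signal = library sum + degree-5 baseline scaled so its
  window mean equals $c$; noise is i.i.d. Gaussian with SD a fraction
  (default 1%) of the clean-frame maximum; cosmic spikes hit single channels
  of single frames (default probability 2%/frame, amplitude 5× the signal
  maximum). All randomness is a pure function of the seed.
* **Study layout.** 3 pigs × 8 wounds (4 Superficial, 8 PT-Superficial,
  6 PT-Deep, 6 Full-thickness initially), 12 assessment days
  (POD 0–64), 2 central sites per wound and 4 healthy sites per pig per
  day. Healthy sites carry hemoglobin amplitude $A = 10$ (arbitrary units)
  and fluorescence $c = 50$ (fluorescence dominates tissue spectra); a wound
  of category $g$ on day $z$ carries amplitude $\text{multiplier}(g,z) × A$,
  so the recovered HI has the multiplier as its expectation. The HbO:HbR
  split is 70:30 — immaterial to HI, which uses the sum (asserted by test).
  Site-to-site heterogeneity is a multiplicative factor with CV 5%, a
  realistic local-perfusion spread that leaves category means unbiased.
* **Trajectories.** Published category means anchor the multiplier table
  (e.g. PT-Superficial POD 3 = 9.19, PT-Deep POD 3 = 6.54, Full-thickness
  POD 3 = 0.18 rising to 9.85 on POD 14 after escharotomy); unprinted cells
  are linear interpolations, with late unreported days relaxing toward the
  healthy baseline. The Superficial POD 3 value uses the maximum of the
  published cross-day range (0.8–1.67) since no individual value was
  printed. One source prints the Full-thickness POD 3 SEM as 0.21 and
  another as 0.09; the fixture uses 0.09 (the per-day plot context).
* **Deterministic fixtures.** Per-wound POD 3 HI values were never
  published; `pod3_fixture()` constructs, per category, the unique symmetric
  equally-spaced set matching the printed mean and SEM exactly. The
  Full-thickness set necessarily contains negative values (mean 0.18, SD
  0.22) — impossible for real indices, retained for exact moment matching,
  flagged, with a clamped variant. `wound_table_fixture()` encodes the
  attrition structure (14 partial-thickness attempts, 3 secondary-criterion
  failures).

What a green test does *not* establish: the synthetic spectra do not
reproduce true porcine line shapes, melanin/skin optics, instrument drift,
or the acetaminophen internal standard; the fixture-based ROC results are
exact consequences of the printed summary statistics, not new evidence about
the discriminative power on real wounds. The published PT-Superficial vs
PT-Deep AUC of 85% and the ±0.86 correlations depend on unpublished
per-wound data and are covered only qualitatively (direction and
non-degeneracy).

## Numerical choices

* Grid: raw 500–1800 cm$^{-1}$ at 2 cm$^{-1}$; crop closed on both ends;
  grids match by exact equality, with explicit linear-interpolation
  resampling (`resample_spectrum()`) at load time when they differ.
* Despiking: one-sided (spikes are positive), strict threshold of 8 robust
  SDs above the across-frame median, so identical noiseless frames are never
  altered; <3 frames passes through with a warning.
* The rolling window collapses to the single trailing-window average per
  acquisition (the analysis uses one spectrum per ≥180 s measurement).
* Dark subtraction is per-frame; under linearity this is equivalent to
  subtracting from the average.
* POD 7 imputation (mean of PODs 3 and 14) is applied in heatmap aggregation
  only, flagged, and never feeds per-day inference.
* Heatmap values are stored unclamped; the 0–10 saturation is a display
  convention in `plot_heatmap()`. Row clustering is hierarchical (Euclidean,
  average linkage); k-means (k = 2, seeded) is also emitted, but with four
  rows its labels are fragile, so the hierarchical ordering is the
  authoritative association statement.
* Per-day ANOVA/Tukey p-values are not adjusted across days (only within-day
  via Tukey), and with zero between-group variance the convention F = 0,
  p = 1 applies.

## A worked example

```{r example, eval = FALSE}
libs <- default_libraries()
frames <- simulate_frames(list(a = 1.2, b = 3.4, c = 10), libs,
                          sim_config(n_frames = 180, seed = 1))
decompose_frames(frames, libs)

study <- simulate_study(study_design(), sim_config(seed = 1), days = 3)
wounds <- index_table(decompose_study(study), q = 0.02)$wound
dplyr::count(wounds, category)
```

## Known limitations

Exact agreement with the commercial ROUT implementation is not guaranteed;
the generator's fluorescence is a single smooth polynomial rather than a
mixture of fluorophores (spectral unmixing of FI is explicitly out of
scope); no cross-validation is attempted (4–6 wounds per category support
only apparent performance); and mixed-effects modeling of pig as a random
effect is out of scope by design.
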