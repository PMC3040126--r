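---
title: "Quantifying DAB/haematoxylin immunohistochemistry with ihcquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DAB/haematoxylin immunohistochemistry with ihcquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcquant)
```

## The measurement problem

Immunohistochemistry (IHC) marks a target protein with a brown chromogen
(DAB) against a blue nuclear counterstain (haematoxylin). For a
proliferation marker like Ki-67 the clinically relevant quantity is how
much of the cellular material is positive, and how strongly. A human
scorer estimates this by eye; an automated scorer must first separate the
two stains, which overlap heavily in RGB space, and then reduce each spot
image to comparable numbers. `ihcquant` implements that pipeline for
pre-extracted spot images (e.g. tissue-microarray cores at roughly
0.26 µm/pixel), deliberately without any tumour/stroma segmentation or
nuclear segmentation: every stained pixel in the spot counts. That choice
keeps the method simple and fully reproducible, at the cost of letting
stromal staining dilute the score — a known, accepted property of this
family of algorithms that matters when comparing against studies that
score tumour parenchyma only.

## Model and assumptions

**Beer–Lambert mixing.** Transmitted brightfield light obeys
$v_c = I_0 \cdot 10^{-\mathrm{od}_c}$ per channel $c$, and the optical
densities of distinct stains add:
$\mathrm{od} = a_H \mathbf{v}_H + a_{DAB} \mathbf{v}_{DAB}$, where
$\mathbf{v}_s$ are unit OD vectors characterising each stain's colour
and $a_s \ge 0$ are stain amounts. `rgb_to_od()` inverts the first
relation with $I_0 = 255$ and pixel values clamped to a minimum of 1
(so the OD stays finite; the dynamic ceiling is
$\log_{10} 255 \approx 2.41$ OD). `unmix_amounts()` inverts the second by
multiplying with the inverse of the stain matrix — the two stain vectors
plus their normalized cross product as an orthogonal residual that
absorbs hue the two stains cannot explain. Negative unmixed amounts are
physically meaningless and are clamped to zero.

The default stain vectors are the widely used H–DAB pair
H = (0.650, 0.704, 0.286), DAB = (0.268, 0.570, 0.776) (unit-normalized).
Published H-DAB deconvolution implementations differ slightly in these
constants, and the true vectors vary with staining protocol and scanner;
both vectors are therefore overridable (`build_stain_matrix()`,
`read_stain_config()`). Results obtained with different vectors are not
numerically interchangeable.

**Channel rendering and thresholding.** Each unmixed amount is rendered
back to an 8-bit pseudo-transmittance $v = 255 \cdot 10^{-a}$, so 255
means no stain and darker means more stain. A pixel is stain-positive
when its channel value is strictly below the threshold. Strict `<` is a
convention (a pixel exactly at the threshold is negative); it is fixed,
documented and tested at the boundary, which is all that matters for a
batch statistic. The defaults `t_h = t_dab = 200` correspond to calling
any pixel above ~0.1 OD of a stain positive. Real material should be
calibrated by inspecting QC overlays (`run_analyze(qc_dir = ...)`) on a
handful of spots; the essential discipline is that thresholds are then
held constant across the entire series, since every spot's score moves
with them.

**Spot statistics.** With $H^+$ and $DAB^+$ the thresholded masks:

- extent $= 100 \cdot |DAB^+| / |H^+ \cup DAB^+|$ (missing when nothing
  is stained — emitted as a blank, never as 0);
- intensity $= 100 \cdot (255 - \overline{v}_{DAB^+}) / 255$, the mean
  DAB channel value over the DAB-positive area rescaled so that darker
  staining gives a higher percentage (missing when no pixel is
  DAB-positive).

The polarity of the intensity scale (darker = higher) is a package
convention: with mid-brown DAB around 0.3–0.8 OD it produces mid-scale
percentages, consistent with how such intensities are reported, but it
is a choice, not something the statistic's definition forces.

The QC result image colours DAB-positive pixels red (regardless of H
status — a doubly stained nucleus is a positive nucleus), H-only pixels
green, background white.

## Cohort procedures

**Aggregation.** With replicate cores per patient, the highest
non-missing extent and the highest non-missing intensity are kept,
independently per variable — the rationale being that the best-preserved,
most cellular core should dominate, and a core may be evaluable for one
variable only.

**Grouping.** `tertile_split()` and `proportion_split()` cut the cohort
into ordered low/moderate/high groups. Cut points are inverse-CDF
empirical quantiles — the smallest data value whose cumulative fraction
reaches the target — so cut points are always observed values and ties
fall into the lower group; group sizes then match the targets exactly on
tie-free data and within the tie-run length otherwise. This is one of
several defensible quantile conventions; it is declared and tested rather
than claimed to match any particular legacy software. Group assignment
(`assign_groups()`) rounds values to one decimal before the closed-interval
comparison, matching the granularity at which such cut points are
reported (a printed boundary pair 2.3/6.3 means 0–2.3 low, 2.4–6.3
moderate, 6.4–100 high). Proportions supplied as rounded printed
percentages may sum to slightly off 1 (e.g. 7.7% + 55.7% + 36.7% =
100.1%); sums within 0.01 of 1 are renormalized, anything further off is
an error.

**Agreement.** Automated groups versus visual ordinal categories are
cross-tabulated over the patients rated by both (dropped patients are
counted and reported). `weighted_agreement()` uses linear weights
$w(i,j) = 1 - |i-j|/(k-1)$: the *weighted* observed agreement
$\sum w_{ij} p_{ij}$ is the headline "percentage agreement", crediting
near-miss classifications between adjacent ordered categories, with the
raw diagonal fraction also reported; weighted kappa is
$(P_o^w - P_e^w)/(1 - P_e^w)$ with the chance term from the marginals.
Kappa is reported as missing when the marginals are degenerate
($P_e^w = 1$). Only point estimates are computed; standard errors and
confidence intervals are an extension point. Conventional rounding for
reports is integer percent and two-decimal kappa; machine outputs retain
full precision.

```{r table}
tab <- agreement_table(rbind(c(46, 53, 0), c(51, 554, 114), c(2, 112, 360)),
                       categories = c("low/negative", "moderate", "high"))
weighted_agreement(tab)
```

## The synthetic generator: what it emulates, what it does not

`render_spot()` builds a spot by the same forward physics the analysis
inverts: nuclei are filled ellipses (axes uniform in 8–16 px, loosely
nucleus-sized at TMA resolution) accumulating haematoxylin OD (all
nuclei, mean load 0.6) and DAB OD (a chosen fraction of nuclei, mean
load 0.8, both with ±15% per-nucleus jitter); OD loads add where nuclei
overlap; each channel is rendered to 8 bits and optional Gaussian sensor
noise (default σ = 0) is added and clamped. Ground-truth masks, extent
and intensity are recorded from the noise-free OD fields with the same
union formula the analysis uses. `generate_cohort()` wraps this into a
TMA-like dataset: 1–4 cores per patient with probabilities
(0.791, 0.188, 0.016, 0.005), matching the replicate structure of a large
published TMA series; patient target extents uniform on 0–95% (the
dynamic range reported for real Ki-67 material); between-core jitter of
2 percentage points; all randomness flowing from one seed, making
datasets bit-reproducible.

What passing recovery tests on these images shows is that the
deconvolution, thresholding and bookkeeping invert the forward model
correctly — the generator uses the same stain vectors the analysis
assumes, so stain-vector misspecification is exercised only if you
deliberately mismatch them. What it does *not* show is robustness to the
failure modes of real slides: stroma and cytoplasmic staining, folds,
debris, defocus, uneven illumination, chromogen saturation and the
non-linear DAB response. Those require real calibration material.

Simulation sizes in the shipped tests (spots of 256×256 px with 150
nuclei, cohorts of 25–60 patients) were chosen as the smallest at which
the recovery statistics are stable; the generator defaults are the same
conditions.

## Numerical limits and edge cases

**8-bit quantization bounds the round-trip accuracy.** Recovering stain
amounts from quantized RGB incurs an OD error of about
$0.217/v$ per channel transmitting $v$ of 255 counts (a half-count
rounding step), amplified by the unmixing inverse whose rows have norms
around 1.5 for the H–DAB pair. For amounts up to 1.0 OD per stain the
recovered amounts stay within 0.02 OD of truth; at the extreme of two
strong co-localized stains (both 1.5 OD) the darkest channel transmits
only ~3 counts and the worst-case error reaches ~0.06 OD. The mean error
over the full $[0, 1.5]^2$ range is below 0.01 OD. Segmentation-level
results are insensitive to this: thresholds sit far from the saturated
regime.

Other conventions: empty/degenerate images error early
(`"empty input image"`, grayscale rejected rather than promoted, alpha
channels dropped); a batch never aborts on an unreadable file (logged,
counted, emitted as a `failed` row with blank statistics); splits demand
at least 3 non-missing values and refuse all-identical input
(`"no variation"`); collinear stain vectors are refused
(`"degenerate stain pair"`).

## Known limitations

- No stroma exclusion and no nuclear segmentation: scores are
  area-based over the whole spot, so high-stroma samples read low and
  strongly stained debris reads high.
- Fixed global thresholds assume consistent staining and scanning across
  the series; they must be re-calibrated per protocol.
- Exactly three stain channels; no unsupervised stain-vector estimation.
- Intensity inherits the known non-linearity of DAB chromogen response;
  it is a comparative, not densitometric, measure.
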