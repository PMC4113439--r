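---
title: "Quantifying fundus tessellation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fundus tessellation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tessfundus)
```

## The measurement problem

Tessellation of the ocular fundus is the tigroid pattern produced when large
choroidal vessels become visible between patches of retinal pigment
epithelium. It accompanies choroidal thinning and axial elongation in myopia,
which makes it clinically interesting as an early, photograph-visible marker.
Its conventional assessment, however, is a three-step subjective grading
(non-tessellated / weakly / strongly tessellated, NT < WT < ST) by
experienced readers. This package implements an objective alternative: color
arithmetic on a fixed region of the photograph, validated with the
statistical battery such a study requires.

## The region of interest

A circle of 250 pixels diameter is placed between the fovea and the optic
disc. That location is a compromise: tessellation is most pronounced around
the disc, but the peripapillary zone also contains the large retinal vessels
and the disc conus, which contaminate a color average. The fovea-side
placement avoids both, and 250 px is about as large as the circle can be
without touching the arcades.

Conventions fixed by this package (the source protocol does not pin them
down, so they are stated here precisely because reproducibility demands it):

* Coordinates are 0-based integer pixel indices, x rightward, y downward.
  Landmarks (fovea center, disc center) are supplied externally in a CSV;
  automatic detection is out of scope.
* The ROI center is the exact midpoint of the fovea–disc segment, rounded
  half away from zero to an integer pixel. Midpoint placement is symmetric
  and reproducible; nothing in the index depends on sub-pixel placement at
  ROI sizes of ~49,000 pixels.
* A pixel belongs to the disk when its center `(px + 0.5, py + 0.5)` lies at
  Euclidean distance ≤ diameter/2 from the center pixel's center (closed
  boundary). This rule is exactly checkable against brute-force enumeration,
  which the test suite does for random centers and diameters.
* The whole disk must fit inside the image; a circle that does not fit is a
  hard geometry error, never silently cropped, because a cropped disk would
  bias the channel means.
* Statistics are computed on the disk, not its bounding square.
* Channel values are the raw 8-bit camera output; no gamma or white-balance
  correction. Higher bit depths are rejected at load rather than rescaled.
* The per-channel standard deviation uses the population divisor *n*,
  matching the histogram-summary semantics of image-analysis software. At
  ROI sizes of tens of thousands of pixels the difference from the sample
  divisor is immaterial, but a fixed convention is needed for exact tests.
* No vessel masking is applied inside the ROI; the protocol avoids large
  vessels by placement only.

## The indices

With R, G, B the mean channel intensities inside the circle,

$$\mathrm{TFI}_1 = \frac{R - G}{R}, \qquad
  \mathrm{TFI}_2 = \frac{R}{R+G+B}, \qquad
  \mathrm{TFI}_3 = \frac{R-G}{R+G+B}.$$

All are computed from the *means* over the ROI, not from per-pixel ratios
averaged afterwards. They are ratios because fundus photographs vary
substantially in overall brightness; scaling (R, G, B) by any c > 0 leaves
every index unchanged, which the suite verifies. The identity
$\mathrm{TFI}_3 = \mathrm{TFI}_1 \times \mathrm{TFI}_2$ holds algebraically
and is enforced to 1e-12 in tests. Indices are kept in full double precision
internally; the 3-decimal rounding (half away from zero) seen in reports is
presentation only.

Degenerate inputs fail loudly: R = 0 leaves TFI-1 undefined, and a fully
black ROI (R+G+B = 0) leaves all three undefined; both raise errors rather
than returning NaN.

## Subjective grades and consensus

Three raters grade each eye NT/WT/ST; the consensus is the grade shared by
at least two. A three-way split has no consensus and raises an error — in
the motivating study such a case never occurred, and silently imputing one
would corrupt the group comparison.

## The statistical battery

All four procedures are implemented from their defining formulas; base R
supplies only distribution functions (`ptukey`, `pt`, `pnorm`) and ranking.
Independent routes (`cor.test`, `aov`, exhaustive permutation) appear in the
test suite as oracles, never as the implementation.

**Spearman correlation.** Mid-ranks (average ranks for ties), Pearson
correlation of the ranks, two-sided p from
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom. The t
approximation is accurate in the n = 100 regime the pipeline targets. A
perfect correlation reports the smallest positive double rather than NaN or
a literal zero.

**Steel–Dwass all-pairs comparison.** For each unordered pair of groups the
two groups are pooled and mid-ranked. With $R_i$ the rank sum of group i,
$E = n_i(N+1)/2$ and the tie-corrected permutation variance
$V = \frac{n_i n_j}{N(N-1)}\left(\sum_k r_k^2 - \frac{N(N+1)^2}{4}\right)$,
the statistic $t = (R_i - E)/\sqrt{V}$ is referred to the studentized range:
$p = P(Q_{k,\infty} \ge |t|\sqrt{2})$ with k the total number of groups.
This is the standard large-sample version with tie correction; the exact
small-sample enumeration exists in the tests as an oracle only. With k = 2
the procedure collapses to the tie-corrected normal-approximation Wilcoxon
rank-sum test (the identity $P(Q_{2,\infty} \ge q) = 2\Phi(-q/\sqrt2)$),
which the suite checks to 1e-10. A pair whose pooled values are all
identical has V = 0 and is a degenerate-pair error.

One inherited ambiguity deserves a note: the study's abstract mentions a
Kruskal–Wallis test while its methods specify Steel–Dwass. The methods
version is implemented — an all-pairs procedure needs no omnibus gatekeeper,
and the reported pairwise p-values can only have come from it.

**Fleiss kappa.** For n items each rated by r raters into q categories,
$P_i = (\sum_j n_{ij}^2 - r)/(r(r-1))$, $\bar P$ its mean,
$p_j = \sum_i n_{ij}/(nr)$, $\bar P_e = \sum_j p_j^2$, and
$\kappa = (\bar P - \bar P_e)/(1 - \bar P_e)$. All ratings in a single
category make $\bar P_e = 1$ and kappa undefined (error). Kappa is invariant
under category relabeling and item permutation, which the suite checks.

**Intraclass correlation.** The phrase "two-way model, absolute agreement"
maps to a family; the single-measurement coefficient ICC(A,1) is used here
because each session yields exactly one index per eye:
$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
 {MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}.$$
The mean squares come from the standard two-way decomposition, computed
directly from row/column/grand means. Duplicated sessions give exactly 1;
degenerate 2×2 inputs follow the formula literally (the denominator can
vanish, yielding a signed infinity rather than a fabricated value); zero
total variance is an error.

**Multiplicity.** No correction is applied across the nine TFI × outcome
correlations — each is reported marginally, as is conventional for a
validation table. The 0.05 threshold labels significance in the printed
report and filters nothing.

## The synthetic cohort generator

No public dataset accompanies the protocol, so validation runs on a
generator whose defaults *are* the study conditions: 100 eyes, age
25.8 ± 3.9 y (22–39), axial length 25.3 ± 1.4 mm (22.4–30.4), spherical
equivalent −4.6 ± 3.3 D (−13–0), subfoveal choroidal thickness (SFCT)
261.8 ± 84.9 µm (76–500), nasal thickness 17.8 µm thinner with 30 µm of
independent noise (76–460). All covariates are truncated normals.

Design choices, made once:

* **SFCT from axial length.** SFCT is linear in AL plus Gaussian noise,
  with the slope set through the bivariate-normal relation
  $\rho_P = 2\sin(\pi\rho_S/6)$ so the realized Spearman correlation targets
  −0.382. The residual SD follows from the target total SD
  ($\beta = \rho_P\,\sigma_{SFCT}/\sigma_{AL} \approx -24\,\mu m/mm$,
  $\sigma_\varepsilon = \sigma_{SFCT}\sqrt{1-\rho_P^2}$). Truncation to the
  configured range attenuates the realized correlation slightly (a mean of
  about −0.37 across seeds).
* **Visibility.** Tessellation visibility is
  $v = \mathrm{clamp}\!\left(\frac{ct_{hi} - ct}{ct_{hi} - ct_{lo}}, 0, 1\right)$
  over the SFCT range (76–500 µm): the simplest strictly decreasing map
  realizing "thinner choroid, more visible choroidal vessels". The true
  physiological mapping is unknown (reported index–thickness correlations
  in real cohorts are weak, around −0.2); the generator makes no claim to
  that effect size, and the validation suite accordingly tests only signs,
  monotonicity and calibration of what the generator *does* control.
* **Rendering.** A uniform RPE-orange background (165, 110, 58 — chosen so
  the background alone reproduces a non-tessellated eye's index values),
  quasi-horizontal choroidal vessel bands (Gaussian-profile sinusoidally
  wandering stripes, union coverage) alpha-blended at opacity v with a
  redder vessel color (190, 95, 50), two dark retinal arcades masked out of
  the analysis circle, additive Gaussian noise (SD 3), clipped and quantized
  to 8 bits. Measured TFI-3 rises from ≈ 0.165 at v = 0 to ≈ 0.21 at v = 1.
  Geometry (560 × 420 px, fovea (420, 210), disc (140, 210)) keeps the
  250-px circle inside the frame with the disc center outside it.
* **Grades.** The true grade thresholds v < 0.60 → NT, v < 0.76 → WT,
  else ST are the normal quantiles that split the default cohort roughly
  57/27/16, the NT/WT/ST proportions of the motivating study. Each rater
  mis-grades one step with probability 0.12 (direction symmetric where both
  directions exist), giving realistic — not perfect — Fleiss kappas around
  0.6–0.7. The three draws are conditioned on a consensus existing (a
  redraw on the rare three-way split of a truly-WT eye): the grading
  protocol this emulates treats a full disagreement as a protocol failure
  and never produced one, and an unconditioned generator would make the
  downstream consensus step fail on a third of cohorts for no scientific
  gain.
* **Determinism.** A master seed drives covariate generation, and each eye's
  rendering runs on a seed derived arithmetically from the master seed and
  the eye index, so cohorts are bit-reproducible regardless of evaluation
  order. All RNG use is wrapped so the caller's RNG state is untouched.

What the generator does *not* emulate: optical blur, vignetting,
illumination gradients, peripapillary atrophy, real vessel branching
topology, and any tessellation variance independent of choroidal thickness.
Consequently the synthetic TFI–SFCT correlations are near −0.95, far
stronger than real cohorts show; passing pipeline tests demonstrates that
the measurement chain and statistics are correct and calibrated, not that
real-world effect sizes are reproduced.

## Validation choices and problem sizes

The suite's property checks run at sizes chosen to balance power against a
desk-scale runtime: exhaustive-permutation comparison of the Steel–Dwass
p-values on 50 random three-group datasets with group sizes 2–5 (pair
permutation counts up to 252); the familywise error rate on 2,000 null
replicates of three groups of 20 (the estimate's binomial SE is ≈ 0.5
percentage points); rendering monotonicity on a 5-point visibility grid
averaged over 10 seeds; and full-pipeline sign recovery over 50 independent
100-eye cohorts. The pooled-mean cross-check uses the published per-grade
means and group sizes directly as inputs.

The permutation-oracle comparison deserves a caveat: the implementation's
large-sample p and an exact permutation p cannot agree tightly at the
smallest group sizes, because the exact distribution is discrete with atoms
as large as 1/6 at n = 2 — a floor of several percentage points in |Δp| that
no correct implementation of the large-sample statistic can go below. The
oracle therefore uses the mid-p convention (half weight on the observed
atom), the standard way to compare a discrete exact tail with a continuous
approximation, and the remaining gap is an honest property of the
approximation at those sizes, shrinking as groups grow.

## Known limitations

* Landmarks are trusted input; mis-placed landmarks shift the ROI silently
  (only geometric violations are caught).
* The indices summarize color only; media opacities or exposure tints that
  alter R/G balance masquerade as tessellation change. The ratio form
  removes global brightness, not chromatic, variation.
* The ICC machinery assumes complete subject × session matrices; unbalanced
  repeatability designs are out of scope.
* The Steel–Dwass implementation is the large-sample approximation; with
  groups smaller than ~5 its p-values inherit the usual small-sample
  optimism/conservatism of rank approximations.
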