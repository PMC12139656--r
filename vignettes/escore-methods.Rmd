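---
title: "Classifying multifrequency backscatter with the Escore algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying multifrequency backscatter with the Escore algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(escore)
```

## The problem

Narrowband echosounders measure the volume backscattering strength
$S_v$ (dB re 1 m$^{-1}$) of everything in the water column, but a single
frequency cannot tell a krill swarm from a layer of gas-bearing
siphonophores. Because the backscattering cross-section of an organism
depends on frequency in a way governed by its size, shape and material
contrast, the *relative frequency response* — the difference of $S_v$
between each frequency and a 38 kHz reference,
$\Delta S_{v,f-38} = S_{v,f} - S_{v,38}$ — is a fingerprint of broad
scatterer type. This package classifies echo-integrated multifrequency
backscatter (18, 38, 70, 120 kHz) into *echo-classes* using that
fingerprint, via the Escore algorithm, and provides the theoretical
scattering models used to interpret what each echo-class may be
biologically.

## The model

Training is semi-supervised. Rectangular regions of interest (ROIs) are
drawn on RGB composite echograms around visually coherent layers; the
$\Delta S_v$ triplets of the pixels in each ROI are refined by K-means and a
single cluster — one *echo-type*, a single coherent acoustic structure — is
retained per ROI. The echo-type mean triplets form a library which
agglomerative clustering (Ward linkage, Euclidean distance) cuts into $K$
echo-classes; $K$ is chosen by a majority vote of five cluster-validity
indices (silhouette, Calinski–Harabasz, Davies–Bouldin, Dunn, gap
statistic), and the labelling is sanity-checked with a random forest's
out-of-bag error on the three $\Delta S_v$ features.

Each echo-class $k$ is then modelled as an axis-aligned Gaussian ellipsoid:
per axis $j$, a centroid $\mu_{kj}$ and standard deviation $\sigma_{kj}$
computed over the member echo-type means. A cell $i$ with triplet
$\Delta S_{v,ij}$ is scored against each class by

$$\mathrm{Escore}(i,k) = \sum_{j=1}^{3}
  \left(\frac{\Delta S_{v,ij} - \mu_{kj}}{\sigma_{kj}}\right)^2 ,$$

a sum of squared independent normal deviates, hence $\chi^2$ with three
degrees of freedom under the class's Gaussian model. The cell is assigned
to the class minimising the Escore unless that minimum is greater than or
equal to the *Ellipsoid-threshold* (default 25), in which case it is left
unclassified. The threshold is deliberately strict at the boundary
(min $=$ threshold is unclassified). At threshold 25 a cell truly drawn
from a class's Gaussian is retained with probability
$P(\chi^2_3 < 25) \approx 0.99998$, so the threshold mainly rejects cells
that belong to no trained class.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| ESDU | 3 pings × 1.5 m | – | echo-integration cell; standard survey resolution |
| integration threshold | −100 | dB re 1 m⁻¹ | samples below it contribute zero linear energy |
| surface exclusion | 15 | m | transducer near-field and surface turbulence |
| max depth per frequency | 1000/800/500/250/120 | m | usable range of 18/38/70/120/200 kHz |
| `k_roi` | 3 | – | K-means clusters within an ROI |
| Ellipsoid-threshold | 25 | – | $\chi^2_3$ cutoff for "belongs to no class" |
| $\sigma$ floor | 0.1 | dB | keeps tiny classes non-degenerate |

The −100 dB threshold semantics (zero linear contribution, not sample
exclusion, with an all-thresholded cell reported MISSING) is a documented
choice: it reproduces standard echo-integration behaviour where thresholded
samples still dilute the mean. MISSING propagates everywhere and is never
imputed; a $\Delta S_v$ triplet is MISSING as soon as any of the four
frequencies is MISSING in that cell.

Day/night/sunrise/sunset are banded at ±6° solar elevation from a
low-precision solar ephemeris; only day and night cells feed the diel
metrics. $\sigma_{kj}$ is estimated from echo-type *means*, not from raw
pixels: the ellipsoid describes variability between coherent structures,
which is the level at which the library is built. Class indices are ordered
by ascending centroid $\Delta S_{v,18-38}$ purely so numbering is
reproducible.

## Acoustic metrics

Per frequency the package reports total area backscatter
$\mathrm{Total}\,s_A = \sum_i s_{A,i}$ over all depth bins to the maximum
echo-integrated depth, the diel vertical migration strength
$1 - s_{A,\mathrm{meso,night}} / s_{A,\mathrm{meso,day}}$ (mesopelagic =
200 m to max depth; computed at 18/38/70 kHz only, the frequencies that
reach usefully below 200 m), NASC by depth category (surface 15–200 m,
intermediate 200–400 m, deep > 400 m; 120 kHz has no deep category and
200 kHz only a surface one), and eddy kinetic energy
$\mathrm{EKE} = \tfrac12(u^2+v^2)$ from current profiles. NASC is
$4\pi \cdot 1852^2 \int 10^{S_v/10}\,dz$ (m² nmi⁻²) and is exactly additive
over disjoint depth intervals, which the tests exploit as conservation
identities.

## Scattering models

To interpret echo-classes without trawl validation, forward models produce
TS$(f)$ at the four frequencies, converted to $S_v$ for one organism per
m³ (numerically equal) and thence to a $\Delta S_v$ triplet that is scored
like any other cell:

* **DWBA bent cylinder** (copepods, euphausiids): weak-scatterer volume
  integral along a uniformly bent cylinder, radius of curvature fixed at
  three body lengths, averaged over a Gaussian orientation distribution by
  64-node Gauss–Legendre quadrature weighted by the normal density over
  ±4 SD.
* **Randomly oriented fluid bent cylinder** (shrimp, salps): the same
  weak-scatterer kernel averaged uniformly over all tilts, blended into the
  geometric ray limit $\sigma_{geo} = R_{12}^2 a \rho_c / 4$ through the
  high-pass form $\sigma = \sigma_{ray}/(1 + \sigma_{ray}/\sigma_{geo})$,
  so the response rises as $f^4$ in the Rayleigh regime and saturates at
  large $ka$.
* **High-pass dense fluid sphere** (gastropods): Stanton-style
  interpolation between Rayleigh $a^6 f^4$ scattering and the geometric
  reflection $a^2 R^2/4$.
* **Gas bubble**: damped Minnaert resonance,
  $\sigma_{bs} = a^2 / \big[((f_0/f)^2 - 1)^2 + \delta^2\big]$, with
  radiation ($ka$), viscous ($4\mu/\rho\omega a^2$) and thermal
  (large-argument $3(\gamma-1)/X$) damping; surface tension is ignored and
  the internal gas pressure equals ambient. The ellipsoid variant raises
  the equal-volume sphere's resonance by the prolate-spheroid capacitance
  factor (the electrostatic analogy), which reduces to 1 at aspect 1.
* **Hybrid gas + body** (siphonophore pneumatophores, small swimbladdered
  fish): incoherent cross-section sum of a gas inclusion (default 5 % of
  body volume when not specified) and the DWBA body. Incoherent summation
  is a choice; phase-coherent interference between bladder and body is not
  modelled.

Sound speed comes from the nine-term Mackenzie (1981) polynomial. Default
material contrasts ($g, h \approx 1.02$–$1.06$) are typical fluid-like
zooplankton values and fully overridable through the model parameter file.
A 0.16 mm equivalent-radius bubble at 25 m depth resonates at ≈38 kHz,
which is the canonical interpretation of a 38-kHz-resonant echo-class.

## What the synthetic scenes emulate

Since no cruise data ship with the package, every pipeline stage is
exercised on generated scenes. A scene is a 24 h fixed-position track
(16.5° S, 41.5° E, late April — Mozambique Channel conditions) on the ESDU
lattice (one 3-ping ESDU per 9 s, 1.5 m bins, 15–250.5 m) with four
non-overlapping scattering layers over a −95 dB background. Each layer has
per-frequency mean Sv, independent Gaussian dB noise per cell and
frequency (SD 0.5 dB), and is split into 20 horizontal patches whose means
are jittered by a further 0.5 dB — the patch level is what ROIs select and
what gives the library its between-echo-type spread; without it the
ellipsoid SDs would collapse to the floor. Two layers migrate vertically
between a day band and a night band (step change at the ±6° solar-period
boundaries; transit is not simulated but is sufficient to exercise the
day/night metrics). The planted $\Delta S_v$ centroids,
$(-7,-1,-2)$, $(-14,-9,-13)$, $(+6,-5,-9)$ and $(-4,-7,-11)$ dB, follow
the qualitative frequency-response shapes of observed echo-classes (one
18-kHz-dominant falling response; three 38-kHz-peaked responses with
different high-frequency slopes) and are pairwise at least 10.4 dB apart —
about 6.5 combined noise SDs, so the planted partition is recoverable.

What the generator does *not* emulate: Rayleigh-distributed linear-domain
reverberation (a linear-domain noise option exists for robustness checks,
but the default is Gaussian in dB, matching the Escore model's normality
assumption), beam-pattern and TVG artefacts, school morphology, attenuation
and transient noise. Passing the end-to-end tests therefore demonstrates
correctness of the algorithmic chain under the model's own assumptions, not
field performance on real echograms.

## Numerical choices and degenerate inputs

* Echo-integration pools all constituent samples of an ESDU in the linear
  domain with thickness-weighted proportional overlap, so raw lattices that
  are not exact multiples of the ESDU bin are resampled, never truncated;
  a trailing partial ping group is integrated as-is.
* Ties at the minimum Escore break to the lowest class index; K-means
  retains the largest ROI cluster unless an explicit override is given;
  ties in the dominant frequency argmax go to the lower frequency; validity
  index votes tie toward smaller $k$.
* A library with zero variance is rejected by `select_k` rather than fed to
  indices that would divide by zero; single-member classes get the 0.1 dB
  $\sigma$ floor; a class with one member in the random forest triggers a
  warning, not an error.
* All stochastic steps (K-means restarts, gap-statistic bootstraps, random
  forest, scene generation) are seeded and bit-reproducible; reruns with
  the same configuration produce byte-identical model JSON.
* Problem sizes used by the shipped tests and the acceptance script — a
  9 600-ESDU scene, $10^5$ coverage samples, $10^4$ oracle cells, a
  400-echo-type forest library — were chosen to make every check
  statistically decisive while keeping a full run in tens of seconds on one
  CPU.

## Known limitations

The ellipsoids are axis-aligned by construction of the Escore formula;
correlated $\Delta S_v$ axes (common when one frequency dominates the
variance) are not modelled, and a full-covariance Mahalanobis variant is
intentionally out of scope. ROI selection is manual by design — there is no
automatic school extraction. The scattering library covers fluid-like,
dense-fluid and gas-bearing scatterers but not elastic shells (pteropods)
beyond the high-pass approximation, and narrowband TS only. Classification
quality on real data depends on the library's coverage: a scatterer type
absent from the training ROIs can only ever be unclassified or
misclassified, which is why the threshold's rejection behaviour matters.
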