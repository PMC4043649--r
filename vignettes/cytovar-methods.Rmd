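---
title: "Modelling variability in murine myeloid flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling variability in murine myeloid flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytovar)
```

## The problem

Circulating murine monocytes split into classical (Ly6C^hi^ CD43^low^),
intermediate (Ly6C^int^ CD43^int^) and non-classical (Ly6C^low^ CD43^high^)
subsets. In wild-type C57BL/6 mice their absolute blood concentrations are
strikingly variable between apparently identical animals (between-animal CVs
of 50–86%), while the *relative* composition of the monocyte pool is tightly
conserved (roughly 52/7/40% classical/intermediate/non-classical). After
experimental myocardial infarction the subsets move through a stereotyped
time course — an early pan-myeloid dip, then classical and non-classical
monocytosis — that is driven almost entirely by the surgical procedure
itself: sham-operated animals trace the same curves.

`cytovar` packages this measurement problem end to end: a synthetic
whole-blood listmode generator with the variance structure above, the
standard cytometry preprocessing (spillover compensation, bi-exponential
display transform), a deterministic implementation of the sequential gating
hierarchy, TruCount-style bead-based absolute quantification, and the
dispersion analytics used to compare cross-sectional with sequential
(repeated-measures) designs.

## The generator

### Animal level

Per-animal true concentrations are log-normal. A population with mean $\mu$
and between-animal CV $c$ is drawn as
$X \sim \mathrm{LogNormal}(\log\mu - \sigma^2/2,\ \sigma^2)$ with
$\sigma^2 = \log(1 + c^2)$, so the arithmetic mean is preserved and the
right-skewed, strictly positive shape matches CVs as large as 86%.

The three MHC-II^neg^ monocyte subsets are generated jointly so that two
constraint sets hold simultaneously: expected subset *fractions* equal the
configured composition means, and expected absolute *concentrations* equal
the configured cohort means. Writing $T$ for the per-animal total monocyte
concentration and $f_s$ for a subset fraction,

$$E[f_s T] = E[f_s]\,E[T] + \mathrm{cov}(f_s, T)
\quad\Rightarrow\quad
\mathrm{cov}_s = \mu_s - \bar f_s\,E[T], \qquad \textstyle\sum_s \mathrm{cov}_s = 0 .$$

Fractions are constructed as
$f_s = a_s + b_s (T - E[T])/E[T] + e_s$ with slope
$b_s = \mathrm{cov}_s E[T] / \mathrm{Var}(T)$ and a mean-zero residual $e_s$
(summing to zero across subsets) sized to the configured fraction SDs. The
classical slope is positive — monocytosis in this model, as in the data it
emulates, is a shift toward the Ly6C^hi^ subset — and non-classical
compensates negatively. The calibration is self-consistent for any choice of
$E[T]$; $E[T]$ is not identified by the published summary statistics and is
exposed as a free parameter with default 240 cells/µl, which implies an
intermediate-monocyte mean of $240 - 135.6 - 86.1 = 18.3$ cells/µl. The
total-monocyte CV defaults to 0.5, chosen once so that the implied classical
concentration CV matches the reported ~69%.

Drawn fractions are clamped to $(0.001, 0.999)$ and renormalized; the clamp
binds in well under 1% of draws but would still displace the subset means by
a few tenths of a cell/µl, so the calibration runs a short fixed-seed
internal Monte-Carlo and absorbs the distortion into the intercepts $a_s$.
After this step the clamped system is mean-exact to Monte-Carlo precision
(the fraction means move by $\le 0.3$ percentage points).

### Event level

Each acquisition draws, per population, a Poisson event count with rate
$\text{concentration} \times \text{volume} \times f$, where $f \in (0,1]$ is
the acquired fraction of the tube. Bead events are Poisson with rate
$\text{beads/tube} \times f$ — beads live in the tube, not the blood, which
is exactly why the bead-ratio estimator cancels $f$. Every event's channel
vector is log-normal around its population template median (zero spread
reproduces the medians exactly), the true fluorescence signals are mixed
through the configured spillover matrix, intensities are capped at the
instrument range (default 262,144 a.u., flagged), and events are shuffled.
Ground-truth labels travel with every synthetic event so gating can be
scored against the generator.

Template medians encode the published phenotype structure, including the
F4/80 maturation gradient (classical 421, intermediate 455, non-classical
794, MHC-II^pos^ activated 1350 a.u.) and the Ly6C/CD43 orderings. Spread
defaults (robust CV 0.25 on the classifier channels, 0.30 elsewhere, 0.20 on
scatter) put adjacent subsets ~5 SD apart on the transformed scale, so
default-noise misclassification is far below 1% per subset. Ly6G rides on
the PE lineage-dump channel, so "Lin^pos^" in the SSC^high^ branch
operationally encodes Ly6G positivity. Lymphocytes are one aggregate
Lin^pos^ CD11b^neg^ SSC^low^ population. Red-cell lysis chemistry, doublets,
debris, dead cells and autofluorescence are deliberately not modelled: the
generator reproduces the *statistical* structure the analytics consume, not
instrument physics, and passing tests therefore validate the pipeline's
arithmetic and gating logic, not its robustness to real-world artefacts.

### Noise layers

* **Day-level biological noise** (`eta`, default CV 0.10): one multiplicative
  log-normal factor per animal-day, shared by all populations of that
  acquisition. A plausible magnitude for circadian/stress fluctuation; it is
  small against the 50–86% between-animal CVs.
* **Technical (duplicate) noise** (`tau`, per population): independent
  multiplicative noise per stained tube, modelling pipetting and staining
  variation. Duplicates split from one blood draw share the day state and
  differ only by `tau` and Poisson counting. The defaults are derived from
  the reported inter-assay CVs by *Poisson deconvolution*: the printed
  inter-assay CV is a total repeatability, so
  $\tau^2 = \mathrm{CV}^2_{\text{printed}} - \bigl(E[1/N_s] + 1/N_b\bigr)$ at
  the duplicate design's event depths (50 µl, full acquisition, 50k beads),
  with $E[1/N_s] = (1 + \mathrm{CV}_s^2)/E[N_s]$ because animals vary
  log-normally around the cohort mean. For
  intermediate monocytes the printed 2.1% lies *below* the Poisson floor at
  the implied ~900 events per tube, so $\tau_{\text{int}} = 0$ and the
  simulated repeatability of that subset is counting-limited. Paired-volume
  acquisitions (50 µl vs 20 µl from one draw) share the day state exactly
  like duplicates and differ only by `tau` and counting.

### Kinetics

Post-surgery trajectories are anchored multipliers $m(t)$ at days
0, 1, 3, 5, 7, 14, 21, interpolated log-linearly. MI and sham share one
anchor table — the package's encoding of the finding that the systemic
myeloid response is surgery-driven — and the sampling-control group is flat.
The anchor magnitudes themselves are package defaults chosen for qualitative
shape only (the source reports no numbers): a day-1 dip that is deepest for
non-classical monocytes and eosinophils (multiplier 0.4), a classical peak
of 2.5 at day 3, non-classical monocytosis peaking later, and return to
baseline by day 21.

Sequential (repeated-measures) mode adds an *individuality-retention
exponent* $\alpha(t)$:

$$x_i(t) = \mu_s\, m(t)\, \bigl(x_i(0)/\mu_s\bigr)^{\alpha(t)}\,\varepsilon_{it},
\qquad \alpha(0) = 1 .$$

With $\alpha = 1$ this is pure multiplicative scaling of each animal's
baseline — which leaves the across-animal CV *unchanged*, and therefore
cannot reproduce the observed collapse of dispersion in sequentially
followed cohorts (up to four-fold for classical monocytes at day 7). Post-op
$\alpha < 1$ (default 0.25 at days 5–7) models the stereotyped surgical
mobilization response overriding individual set-points: the across-animal CV
shrinks to roughly $\alpha(t)$ times the cohort CV. Cross-sectional mode
keeps $\alpha = 1$ with fresh animals per day, so independent cohorts retain
the full between-animal dispersion at every day. The two modes thus have
different day-$t$ marginals by design; this is an explicit modelling choice
to emulate the observed contrast between the two experimental designs, not a
mechanistic claim about the animals.

## Preprocessing

Spillover is estimated from single-stain controls as the classic
median-ratio estimator: entry $(i,j)$ is the shift of channel $j$ medians
between positive and negative events of control $i$, normalized by the
channel-$i$ shift; medians rather than means for outlier robustness; the
positive/negative split is a deterministic two-means partition on the
transformed primary channel with a separation guard. Compensation inverts
the mixing exactly (`observed %*% solve(S)`); negative compensated values
are retained, because truncation would bias MFIs upward; scatter channels
are never compensated.

The display/analysis transform is the scaled inverse hyperbolic sine
$f(x) = \operatorname{asinh}(x/c)/\ln 10$ — a standard member of the
bi-exponential family: linear near zero (so compensated negatives are
representable), within a fraction of a percent of $\log_{10}$ for large
signals, with an exact inverse. The cofactor defaults to 150 a.u. per
channel (overridable per channel); no parameters were published for the
original display scales, and gating results are invariant to any monotone
re-parameterization with correspondingly mapped cuts.

Acquisition QC reads the protocol's "at least 30,000 leukocyte events and
3000 beads" inclusively; failed samples are flagged and excluded from cohort
summaries by default, never silently dropped.

## Gating

The hierarchy is realized with axis-aligned thresholds on the transformed
scale and Boolean interval combinations only — no polygon gates. All
interval membership uses the half-open convention $[\mathrm{lo},
\mathrm{hi})$: an event exactly on a cut goes to the upper bin (manual-gate
conventions are unpublished; this one is fixed and tested). The intermediate
monocyte gate is the Boolean AND of the two interval predicates, mirroring
the combined-gate tool used for continuous populations. The MHC-II^pos^
activated gate takes the union of the Ly6C low/int and CD43 int/high bins,
an interpretation of the descriptive "Ly6C^low/int^ CD43^int/high^"
phenotype. "Ungated" is a first-class label that is reported, and labels
always partition the events.

Default cuts are placed at transformed midpoints between the relevant
template medians — deterministic, data-independent, and what all acceptance
experiments use. A data-driven alternative places each cut at the
minimum-density valley between the two largest modes of a kernel density
estimate (bandwidth `nrd0`, 512-point grid, hence deterministic given the
sample), falling back to the config cut when a channel is effectively
unimodal; it is a convenience for imported FCS data, not part of the
reference analyses.

## Quantification

Absolute counts follow the bead-ratio protocol:
$(N_{\text{subset}}/N_{\text{beads}}) \times (\text{beads/tube} /
\text{volume})$. The acquisition fraction cancels, making the estimator
unbiased under Poisson thinning — a property the tests verify at
$f \in \{0.25, 0.5, 1\}$. Zero acquired beads is an error that points at QC,
never a silent division. MFIs are medians of compensated, *untransformed*
intensities (whether the original analyses compensated before extracting
medians is unstated; this package fixes the convention and documents it)
and require 20 events by default — medians over fewer events are too
unstable to report.

## Variability analytics

Cohort summaries use $n-1$ SDs, SE $= s/\sqrt n$, CV $= s/\bar x$, and
type-7 (linear interpolation) percentiles so box-whisker summaries are
bit-reproducible. The duplicate inter-assay statistic is the mean of
per-pair CVs; with $n = 2$ per pair that raw mean underestimates the
underlying CV by $c_4 = \sqrt{2/\pi} \approx 0.798$, so the default divides
it out (`correct = "none"` gives the literal mean, `"rms"` the
root-mean-square alternative). Delta kinetics subtract each animal's day-0
baseline; CV time courses are computed on absolute counts (not deltas),
matching how the dispersion comparison is defined for the two designs.
Group comparisons use Welch's t-test for two groups and one-way ANOVA with
Tukey HSD otherwise; the per-day MI-versus-sham comparisons are corrected
across days with Bonferroni — a deliberate simplification of two-way ANOVA
interaction contrasts that errs conservative.

## Reference experiment scales

The packaged presets reproduce the study designs at their original sizes:
180 wild-type animals at 50 µl with half the tube acquired (~130k leukocyte
events and 25k beads per sample), 12 duplicate pairs at full acquisition,
a sequential arm of MI $n=15$ / sham $n=7$ / control $n=4$ over days
0–7, 14, 21 at 20 µl, and cross-sectional groups of 20 at days 2, 3, 5, 7.
Replicated power-style checks (e.g. MI-versus-sham indistinguishability
across 40 simulation replicates) run on the generator's concentration scale
(`events = FALSE`), which is distributionally identical upstream of the
event layer and orders of magnitude faster.

## Known limitations

* Clamping makes the monocyte construction mean-exact but slightly narrows
  the extreme fraction tails; implied (non-configured) quantities such as
  the non-classical concentration CV come out somewhat below the printed
  value (~40% vs 51%) because only the mean constraints and the classical
  CV were targeted by calibration.
* The printed neutrophil SE (±63.8 at $n = 180$) is inconsistent with the
  printed neutrophil CV of 85.8%; the generator adopts the CV as truth and
  treats the SE as display-only.
* The sequential-mode dispersion collapse is phenomenological ($\alpha(t)$),
  not mechanistic, and its anchor values — like all kinetics anchors — are
  package defaults, asserted only qualitatively by the tests.
* The FCS layer implements the float/integer list-mode subset of FCS 3.0/3.1
  that this panel needs; exotic keywords, analysis segments and multi-data
  files are out of scope.
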