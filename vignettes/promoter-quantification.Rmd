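---
title: "Quantifying promoter strength from GFP reporter assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying promoter strength from GFP reporter assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoterglow)
```

## The measurement problem

Native plant promoters are screened by fusing each candidate upstream of a
`gfp` reporter and reading fluorescence in two complementary systems:

* **Transient expression** — constructs are bombarded into cotyledonary
  tissue and the explant is imaged hourly for about 100 h. Expression rises
  as GFP accumulates and falls as the extrachromosomal DNA is silenced and
  the protein turns over. Promoter strength is reported as the *percent of
  the peak fluorescence obtained with the CaMV35S reference promoter*, so
  numbers are comparable across experiments.
* **Stable expression in hairy roots** — *Agrobacterium rhizogenes*
  transformation yields independent transgenic root events. A single image
  of each root tip is reduced to one background- and control-corrected mean
  grayscale value, and promoters are compared by one-way ANOVA with a
  Tukey HSD compact letter display, then binned Low/Moderate/High relative
  to CaMV35S.

A phylogenetics sub-module supports family-level survey work: counting
tandem ubiquitin-coding units in polyubiquitin proteins, filtering
divergent gene models, and building Poisson-corrected neighbor-joining
trees with bootstrap supports.

Because raw screening images are rarely published, every input here can be
produced by synthetic generators with known ground truth; all quantitative
claims in the test suite are parameter-recovery claims against that truth.

## Transient time-course model

Each transformed cell (focus) follows

$$I(t) = A\,(1 - e^{-t/\tau_r})\,e^{-t/\tau_d},$$

a saturating rise (protein synthesis, time constant $\tau_r$) multiplied
by an exponential decline (silencing/turnover, $\tau_d$). The form is a
convenience: the published profiles show unimodal curves only, and this
choice has a closed-form peak time
$t^\* = \tau_r \log(1 + \tau_d/\tau_r)$, which gives the tests an analytic
oracle. The defaults $\tau_r = 18$ h, $\tau_d = 40$ h put the reference
peak near 21 h — consistent with a reference that peaks around a day after
bombardment — and leave roughly 20% of peak signal at 100 h, i.e. nearly
extinguished expression.

Two spatial modes reproduce the qualitative contrast seen between target
tissues:

* `retained` — the focus is a **uniformly bright disk**: a GFP-filled
  epidermal cell is approximately uniformly fluorescent across its
  footprint. The fluorophore stays in the transformed cell for the whole
  time course (lima-bean-like behaviour).
* `diffusing` — the focus is a normalized **Gaussian plume** whose width
  grows linearly in time while the frame-integrated signal still follows
  $I(t)$ (soybean-like spread into neighbouring cells). The paper-style
  observation does not quantify the spread, so the rate is a free
  parameter; photon conservation of the spreading step is tested to 0.5%
  (border/discretization loss only).

Pixels are 8-bit per channel: values live on $[0, 255]$ and additive
Gaussian read noise is clipped to that range. Camera gain is assumed
constant over the collection — exposure normalization across a 100 h robot
run is not modelled. Scene geometry (a golden-angle layout of foci) is a
deterministic function of the configuration; the seed drives only the
noise, so noise-free components are identical across seeds and every
generator is bit-reproducible for a fixed config + seed.

### Frame aggregation

How the original ImageJ analysis reduced each frame to a number is not
recorded, so the package fixes one defensible statistic: the **sum of
green-channel values over pixels strictly above a threshold**, with the
default threshold set to mean + 3 SD of the first (pre-expression) frame.
The sum responds to both the number of expressing cells and their
brightness, and for uniformly bright cells it is proportional to total
fluorescence, which is what makes peak *ratios* between promoters
recoverable. Profiles are smoothed by a centred moving average (default
window 5 h, edges truncated) before peak detection; peak ties resolve to
the earliest hour. The reference peak used for normalization is the peak
of the **smoothed mean** CaMV35S profile rather than a per-replicate peak,
so reference noise is not amplified into every normalized value.

With these conventions, synthetic two-promoter experiments with true peak
ratios 0.5, 2 and 7 (5 replicates each, read noise of ~1 gray level on
8-bit frames) recover the normalized-peak ratio within 10%; the residual bias comes
from threshold truncation near expression onset and offset.

## Hairy-root intensity model

The measurement follows the assay protocol order exactly:

1. split the RGB image and keep the **green channel**;
2. subtract the mean gray of a **100 × 100 px background box** placed in
   the medium adjacent to the root (this removes medium autofluorescence
   *and* the reflection halo that GFP-bright roots cast into the agar),
   clamping at zero;
3. **threshold** the subtracted channel to segment expressing pixels —
   Otsu's method by default, because the original "adjusted" manual
   threshold is irreproducible; the realized threshold is always recorded
   per image;
4. take the **masked mean** of the subtracted channel;
5. subtract the **negative-control baseline**, the mean of per-root means
   from roots induced without the reporter construct, processed by the
   identical pipeline; clamp at zero.

Clamping at zero after both subtractions mirrors 8-bit image arithmetic.
The corrected mean is shift-invariant (adding a constant to the whole
channel cancels in step 2) and monotone in the true signal.

The synthetic root scene is an ellipse ("capsule") of elevated green
signal on an autofluorescent background, with a halo ring bleeding
`halo_gain` of the root signal into adjacent medium. Synthetic cohorts add
a lognormal event effect (default CV ≈ 25%) on top of per-pixel noise,
emulating the large event-to-event variability of independent
transformation events; clonal secondary roots of one event are far less
variable, which `within_vs_between_variation()` quantifies as a ratio of
SDs. At 20 events per promoter and true folds {0.3, 1, 3} the
ANOVA + Tukey + classification chain returns {Low, Moderate, High} in
≥ 95% of seeded replicates.

What the generator does **not** emulate: chlorophyll autofluorescence
spectra, chimeric roots, optical point-spread, or focus variation between
images. Passing recovery tests therefore demonstrates correctness of the
measurement chain under the stated noise model, not robustness to every
real-world artefact.

## Statistics

* **ANOVA** is the classical one-way decomposition (`stats::lm`/`anova`);
  a zero within-group mean square is flagged `degenerate` rather than
  reported as a spurious F.
* **Tukey HSD** uses the studentized range with the Tukey–Kramer
  harmonic-mean correction for unequal group sizes (real cohorts ranged
  from 14 to 32 events per promoter). Letters come from the
  insert-and-absorb compact-letter-display algorithm; a property test
  decodes the letters back into a pairwise decision matrix and checks it
  against directly computed Tukey–Kramer tests on random datasets.
* **Classification** has no published rule, so the package adopts and
  documents one: *High* if the promoter mean exceeds the reference mean
  and shares no letter with the reference, *Low* if below and sharing no
  letter, *Moderate* otherwise. The reference itself is Moderate with fold
  1 by construction. α = 0.05 throughout.
* **Copy-number regression** is ordinary least squares of intensity on
  integer copy count (1–7, the range a single-cutter Southern blot can
  call), with a two-sided slope test; perfectly collinear input returns
  $R^2 = 1$ and $p = 0$ explicitly rather than relying on a zero-variance
  t statistic.
* Experiments are pooled by default; an explicit blocking analysis is out
  of scope.

## Phylogenetics

Distances between aligned amino-acid sequences are observed site
differences $p$ corrected for multiple hits by the Poisson formula
$d = -\ln(1-p)$; saturated pairs ($p \ge 1$) are flagged undefined.
Complete deletion (drop every column gapped in *any* sequence) is the
default, matching the classical default of the era's software; pairwise
deletion is available by flag.

Neighbor-joining is implemented in full — Q-criterion
$Q(i,j) = (n-2)d_{ij} - \sum_k d_{ik} - \sum_k d_{jk}$, standard
branch-length split, ties broken by the lexicographically smallest label
pair, negative branch lengths clamped to zero with the deficit recorded —
so its behaviour is testable against independent oracles: exact recovery
of additive matrices, agreement with brute-force least-squares over all
three quartet topologies, and agreement with `ape::nj`.

The bootstrap resamples alignment columns with replacement, reruns the
full distance + NJ pipeline per replicate, and reports the majority-rule
(> 50%) consensus. Supports are the percentage of usable replicates
containing each bipartition; replicates with a saturated distance are
skipped and counted (warning above 10%). Consensus internal branch lengths
are arithmetic means over the supporting replicates and pendant branches
average over all replicates — a display convention, chosen because the
published trees are drawn to scale. Each replicate draws from a seed
substream derived from (seed, replicate index), so replicate *r* is
reproducible in isolation.

Ubiquitin-unit scanning slides a 76-residue window (the canonical
eukaryotic ubiquitin monomer, shipped in `extdata`) left to right; windows
at ≥ 50% ungapped identity count as units and advance the scan by a full
unit. The 50% cut-off operationalizes "highly conserved" — random
sequences essentially never reach it, while true tandem units are nearly
identical. Family filtering (`filter_models()`) is an order-preserving set
difference; with the published 12-model exclusion list applied to the
371-model annotated set it retains 359 models. Since the full annotation
is not published as a list, `erf_annotated_ids()` reconstitutes a set of
the published size from the published identifiers padded with clearly
labelled synthetic placeholders — only the counts are scientifically
meaningful.

## Problem sizes and numerical choices

The shipped defaults and test problem sizes are the package's own
choices: transient scenes of 96 × 96 px with 15 foci and 100 hourly
frames; root scenes of 128 × 96 px with a 20 px background box for cohort
simulations (the full-resolution 1600 × 1200 geometry with the 100 px box
is the single-image default); 200-replicate bootstraps in examples and
tests, with 1000 the recommended analysis setting. Recovery statistics are
insensitive to image resolution because all statistics are means or sums
over regions; resolution mainly sets Monte-Carlo cost.

Degenerate inputs are handled explicitly rather than numerically: empty
segmentation masks return 0 with a flag, a zero reference peak is an error
naming the failed reference, all-constant ANOVA input is flagged, and a
mask touching the image border (leaving no room for a background box) is a
configuration error.

## Known limitations

* The frame-aggregation statistic and the strength-classification rule are
  this package's operationalizations of under-specified published
  procedure; both are documented and fixed, but other choices are
  defensible.
* The Poisson correction ignores back-substitution (its derivation assumes
  every hit changes the residue); at the divergences used here the bias is
  ≲ 4% and the round-trip tests budget for it.
* Transient replicates share the focus layout and differ only in noise;
  biological replicate-to-replicate variation in foci number and position
  is not modelled.
* `within_vs_between_variation()` reports SD ratios only; a mixed-effects
  treatment of the event hierarchy is deliberately out of scope.
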