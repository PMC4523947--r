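---
title: "A hierarchical competitive-network model of boundary-contour coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical competitive-network model of boundary-contour coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`contournet` simulates how neurons in the intermediate stages of the primate
ventral visual pathway (V4, TEO, posterior TE) could acquire their observed
response properties — selectivity for the conformation of a localized
boundary element at a particular position within an object, maintained as
the object shifts across the retina — through purely local, unsupervised
synaptic learning.  The architecture is of the VisNet family: a feed-forward
hierarchy of competitive neural sheets on top of a Gabor-filter retina.

**Retina.** An input image is convolved with a bank of Gabor kernels
modelling V1 simple cells,

$$g(x,y) = \exp\!\left(-\frac{x'^2+\gamma^2 y'^2}{2\sigma^2}\right)
  \cos\!\left(\frac{2\pi x'}{\lambda}+\psi\right),
  \qquad
  \begin{aligned} x' &= x\cos\theta + y\sin\theta\\
                  y' &= -x\sin\theta + y\cos\theta\end{aligned}$$

with wavelength $\lambda = 2$ px, bandwidth $b = 1.5$ octaves (from which
$\sigma$ follows by the standard octave relation), four orientations
$\theta \in \{0, \pi/4, \pi/2, 3\pi/4\}$, two phases $\psi \in \{0, \pi\}$
(white-on-black and black-on-white polarity) and aspect ratio
$\gamma = 0.5$ — eight kernels per retinal position.  Kernels are
mean-subtracted so blank regions produce no drive, and outputs are
half-rectified so the layer-1 inputs are firing-rate-like.  A configuration
option adds a second wavelength, doubling the bank to sixteen kernels for
users who want the deeper input volume; the default stays at the eight
shortest-wavelength kernels, which suffice for these line-drawing stimuli.

**Layers.** Each neuron $i$ of each sheet receives `n_conn` afferents from a
topologically corresponding neighborhood of the sheet below and computes a
linear activation $h_i = \sum_j w_{ij} y_j$.  Activations are then passed
through a lateral-interaction filter $I_{a,b}$ (convolution across the
sheet) and a sigmoid
$y = 1/(1+e^{-2\beta(r-\alpha)})$ whose threshold $\alpha$ is set to a fixed
percentile of the current activation distribution, directly controlling the
fraction of strongly active neurons (percentile 96 → 4% above 0.5).  Two
lateral modes are provided:

* *competitive*: a negative Gaussian surround
  $I_{a,b} = -\delta \exp(-(a^2+b^2)/\sigma^2)$ with the center coefficient
  defined as one minus the surround sum, so the kernel sums to exactly 1 and
  uniform activity is a fixed point;
* *SOM*: a Mexican-hat difference of Gaussians,
  $I_{a,b} = -\delta_I e^{-(a^2+b^2)/\sigma_I^2}
            + \delta_E e^{-(a^2+b^2)/\sigma_E^2}$,
  whose short-range excitation produces topographically organized feature
  maps.

**Learning.** Feed-forward weights adapt by one of two local rules,

$$\delta w_{ij} = k\, y_i\, y_j \quad\text{(Hebb)},\qquad
  \delta w_{ij} = k\, \bar r_i^{\,\tau-1} y_j,\;
  \bar r_i^{\,\tau} = (1-\eta)\,y_i^{\tau} + \eta\, \bar r_i^{\,\tau-1}
  \quad\text{(trace)},$$

with $\eta = 0.8$, followed by renormalization of each weight vector to unit
length.  The trace rule binds inputs that occur close together in time; when
an object is swept across retinal locations before the next object appears,
it drives translation-invariant selectivity.  The trace is reset to zero at
object boundaries so binding never spans two objects.

## Stimuli

Three generators cover the training regimes:

* **Polygon families** — `n` sides, each in one of `p` conformations
  (concave/straight/convex arcs with signed sagitta equal to a fraction of
  the chord), giving $p^n$ whole objects and $n\,p$ distinct boundary
  elements.  Training on all $p^n$ objects statistically decouples any two
  elements, which — because a competitive output layer can allocate far
  fewer dedicated neurons to element *pairs* than pairs exist
  (`capacity_threshold()`) — forces output neurons to code single elements.
* **Closed curvature shapes** in the style of the V4 physiology literature:
  five element types (sharp/medium/broad convex, medium/broad concave)
  combined between vertices at specified angular separations (including the
  135°/135°/90° set), rotated in 10° steps.
* **Smooth synthetic blobs** — random low-order Fourier descriptors of the
  radius function.  These stand in for photographs of real objects: they
  share the varied, smooth boundary-curvature statistics that drive
  element learning but none of the texture, shading or internal structure of
  real images, so results obtained with them speak to boundary coding only.

Shapes are white outlines (stroke 2 px) on black by default — matching the
polarity convention of the phase-0 filters — with a filled-silhouette flag;
the published figures are ambiguous on this point, so outline was fixed as
the default once and kept.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| layer dims | 128×128 (full), 32×32 (desk) | sheet size per layer |
| `n_conn` | 201 (layer 1), 100 | afferents per neuron |
| radius | 6/6/9/12 | topological radius containing ≈67% of afferents |
| lateral σ, δ | per-layer tables | competitive surround |
| SOM σ_E, δ_E, σ_I, δ_I | per-layer tables | Mexican-hat profile |
| sigmoid percentile | 99.2/98/88/91 | sparseness control per layer |
| sigmoid β | 190/40/75/26 | contrast slope per layer |
| `k` | 0.1 (Hebb), 0.5 (trace) | learning rate |
| `η` | 0.8 | trace decay |
| epochs | 50 per layer | passes of the training sequence |

The connectivity radius is calibrated deterministically: the naive
continuous-Gaussian scale (67% of probability mass within the radius)
under-delivers once draws are rounded to grid cells and required to be
distinct, so the scale is solved from an occupancy model of the discrete
without-replacement process.  At full-scale geometry the realized in-radius
fraction lands at 66–67%; at heavily scaled-down geometry the target can be
geometrically unattainable (fewer than 67% × `n_conn` cells lie within the
radius), in which case the closest feasible scale is used.

The trace studies use `k = 0.5` rather than the Hebb default 0.1.  The trace
drive is at most $(1-\eta)$ of the firing rate on the first shifted frame,
so at equal `k` the binding updates are roughly five times weaker than
Hebbian ones and cannot overcome the initial random-weight advantage of
location-specific winners within the four frames an object is seen per
sweep; the larger constant restores the balance.  The learning rate is not
specified in the source literature.

## Training schedule

Layers are trained sequentially, bottom-up, each for `epochs` full passes
with lower layers frozen (the classic schedule for this model family); a
`schedule = "simultaneous"` option trains every layer in one upward sweep
per presentation for users who prefer co-adaptation.  Sequential training
allows the outputs of frozen layers to be cached per unique stimulus, which
is exact and makes desk-scale runs fast.  The sigmoid threshold is
recomputed from each presentation's own activation distribution (the
alternative — a running percentile — is less local and was not adopted).

## Analyses

* **Strict element selectivity**: a cell counts for element $e$ iff its rate
  is in $[0.99995, 1]$ for *every* presentation of every object containing
  $e$ and in $[0, 0.00005)$ for every object lacking it — across all tested
  locations and orientations, so in invariance designs the criterion demands
  transform invariance for free.
* **Single-cell information**: $I(s, R) = \sum_r P(r|s)\log_2 P(r|s)/P(r)$
  per boundary element, with rates quantized into 10 equal-width bins on
  $[0,1]$ (the bin count is not stated in the source methods; 10 is the
  package default and configurable), maximum $\log_2 p$ bits in a
  $p$-conformation design.
* **Receptive-field backtracing**: effective weight of each retinal Gabor
  filter on a cell = sum over feed-forward paths of the product of path
  weights.
* **Curvature × angular-position tuning**: contours are resampled at uniform
  arc length, signed curvature is computed from the tangent-angle
  derivative, and the contour is cut where $|d\kappa/ds|$ exceeds a
  threshold (default 0.05 px⁻²: smooth arcs stay whole, polygon corners and
  conformation junctions cut; a corner's two $|d\kappa/ds|$ lobes are merged
  into one junction).  Heatmaps use 16 angular × 8 curvature bins by
  default; empty bins are flagged `NA`, never zero-filled.  Peaks are
  8-neighborhood local maxima (angle axis circular, strict inequality,
  plateaus counted once) above 60% of the heatmap mean.
* **Gaussian model-neuron correlation**: Pearson correlation between a
  heatmap and an idealized tuning surface over non-empty bins.
* **Feature maps**: per element, the grid positions of maximal-information
  cells and a clustering score against a permutation null — the SOM's
  topography shows as scores well below the null.

## Desk-scale presets and what the tests show

The `test_small*` presets use a 64×64 retina, 32×32 layers, 50 afferents
per neuron and connection radii halved; lateral kernels and sigmoid
parameters are per-neuron local properties and keep their full-scale
values.  The test suite trains these presets on the $n=3, p=2$ (8 objects)
and $n=3, p=4$ (64 objects) families for 50 epochs per layer, and the
translation study on a 2×2 grid of 10-px shifts with a 4-layer SOM —
problem sizes chosen so a full run of the suite completes in a couple of
minutes on one CPU.

Three qualitative results are reproduced at this scale: Hebbian training
multiplies the number of strictly element-selective cells several-fold over
the untrained baseline; trace training produces location-invariant element
detectors where untrained networks have none (a small-number stochastic
outcome, so it is assessed over three replicate simulations); and training
lifts the rank-ordered single-cell information curve toward the
$\log_2 p$ ceiling.  One published direction does **not** survive desk
scaling: at $p = 4$ the SOM preset does not exceed the competitive preset's
strict selective-cell count, because (i) the competitive architecture shows
no capacity collapse at $p=4$ on a 32×32 sheet, leaving no deficit for the
SOM to overcome, and (ii) the SOM's excitatory pooling drags map-neighbors
across the ultra-strict selectivity bands, a penalty that weighs far more
on a 32×32 map than on a 128×128 one.  The SOM's defining property —
topographic clustering of same-element cells — is confirmed
(permutation-null clustering scores are reliably lower than for competitive
training).  The corresponding acceptance check is left failing rather than
weakened.

## Known limitations

* Full-scale presets (256×256 retina, 128×128 layers) are provided and
  faithful to the published tables but are long-running; nothing in the test
  suite exercises them end to end.
* The blob generator does not model texture, shading, occlusion or depth;
  conclusions about "natural" objects from it are limited to boundary
  statistics.
* No top-down or recurrent connections; no spiking dynamics.
* The χ² statistics printed in the source literature for peak-count
  distributions are not reproduced; their computation method is ambiguous.
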