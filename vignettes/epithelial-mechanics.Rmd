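---
title: "Quantifying the mechanical status of epithelial monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the mechanical status of epithelial monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimech)
```

# Scope and model

Postmitotic epithelia such as the retinal pigment epithelium (RPE) hold a
mechanical balance between cortical tension and cell-cell adhesion. This
package implements the quantitative chain used to characterize that
balance from microscopy and indentation data:

1. **Monolayer morphometrics and topology.** Segmentation label masks are
   turned into a cell tessellation; each cell gets an area $A_i$,
   perimeter $P_i$, shape index $p_i = P_i/\sqrt{A_i}$, elongation and a
   neighbor count $n_i$. Monolayer-scale statistics follow: the
   rescaled-area distribution $A_i/\langle A\rangle$, Lewis' law (mean
   rescaled area vs $n$), Desch's law (mean rescaled perimeter vs $n$) and
   the Aboav-Weaire relation $b(n) = (n-6)\,\mu_m(n) - \sigma_n^2$, where
   $\mu_m(n)$ is the mean neighbor count among the neighbors of $n$-sided
   cells and $\sigma_n^2$ the variance of the neighbor-count
   distribution. In vertex-model terms the shape index discriminates
   solid-like ($p \lesssim 3.81$) from fluid-like monolayers; the regular
   hexagon sits at $6/\sqrt{3\sqrt3/2} \approx 3.7224$, the square at 4.
2. **Hertzian indentation.** Force-indentation curves are fitted with the
   sphere-on-half-space contact law
   $F(\delta) = \tfrac43 \tfrac{E}{1-\nu^2}\sqrt{R}\,(\delta-\delta_0)^{3/2}$
   under two protocols: the extracellular-matrix protocol (colloidal
   probe $R = 3.31$ µm, $\nu = 0.3$, linear baseline subtracted from the
   non-contact 45% of the record, whole-curve joint fit of $E$ and
   $\delta_0$) and the monolayer nanoindentation protocol ($R = 10$ µm,
   $\nu = 0.5$, contact point restricted to where the load is below 30%
   of its maximum, fit window 0-3 µm past contact, fits kept only when
   $R^2 > 0.95$). Populations are summarized by their most frequent
   (mode) stiffness.
3. **Traction and intercellular stress.** Bead displacement fields
   (measured by window cross-correlation, PIV) are inverted into traction
   with the Boussinesq surface Green tensor in Fourier space (FTTC), and
   intercellular stress follows from the two-dimensional force balance
   $h\,\partial_j \sigma_{ij} = t_i$ over a monolayer of height $h$, with
   stress-free boundaries; the average normal stress
   $(\sigma_{xx}+\sigma_{yy})/2$ is reported.
4. **Functional image quantification.** Phagocytosis efficiency (projected
   area of internalized particles over all particles), proliferation
   ratio (EdU-positive over DAPI nuclei in a central region), radial
   region binning along the visual axis (centre 300-1200 µm, mid
   periphery 1200-2000 µm, far periphery 2000-3000 µm from the optic
   nerve head) and per-eye maximum normalization of matrix
   immunofluorescence.

Every stage consumes synthetic inputs with exact ground truth from the
generator module, so the whole chain is testable without microscopy data.

# The synthetic-data generator

**Monolayers** are Voronoi tessellations of a hexagonal lattice whose
seeds are jittered by a Gaussian displacement of standard deviation
`disorder` lattice pitches. `disorder = 0` is an exact honeycomb; around
0.12 the mean shape index is near 3.8 (the in-vivo central region), and
0.25-0.35 reaches the 4.0+ of a disordered periphery with neighbor counts
spanning 3-10. The truth carries exact polygon areas, perimeters,
centroids and neighbor lists from half-plane clipping of each Voronoi
cell; the rendered mask assigns each pixel to its nearest seed and draws
zero-valued boundary lines, as a skeletonized segmentation would. A truth
neighbor relation is only recorded when the shared Voronoi edge is at
least half a rendered pixel long: shorter edges are below the rendering
resolution (see *Limitations*).

**Force curves** evaluate the Hertz law beyond a chosen contact point,
plus an optional linear instrumental background and additive Gaussian
force noise — the generative model the fitting protocols assume.

**Traction scenes** forward-compute bead displacement from balanced
traction patterns (Gaussian contractile dipole, inward annulus, a
moment-free dipole pair, or zero) through the Boussinesq Green tensor,
evaluated on an internal grid four times finer than the measurement grid
and zero-padded by a factor two against periodic wrap-around; the
displacement is then sampled at the measurement grid, emulating a finite-
resolution measurement of a continuum deformation.

**Particle stacks** place equal-radius spheres on the voxel grid without
overlap (rejection sampling, at most 1000 retries per particle), with
exactly `round(n * f)` centroids strictly below a reference surface — the
apical F-actin surface that separates internalized from bound particles.

What the generator does **not** emulate: optical blur and photon noise,
segmentation errors (labels are consumed as given; the pipeline's
filters for unnaturally large cells and over-connected cells exist
because real segmenters fail), curved or spatially varying reference
surfaces, bead detachment artefacts, or finite gel thickness. Passing
tests therefore certify the computation chain, not the upstream imaging.

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `trim_px` | 15 | px | border margin discarded before analysis; segmentation quality degrades at image edges |
| `gaussian_sd` | 2 | px | smoothing of skeleton input that seals single-pixel boundary gaps before labeling |
| `bulk_threshold_px` | 30 | px | a cell whose neighbors' mean position sits at or beyond this offset has an open (truncated) neighborhood and is edge-flagged |
| `max_rescaled_area` | 2 | — | removes merged-cell segmentation failures |
| `max_neighbors` | 10 | — | removes over-connected segmentation failures |
| `tail_fraction` | 0.45 | — | non-contact fraction of the approach record used for the baseline line |
| `depth_window_um` | (0, 3) | µm | monolayer protocol fit window past contact |
| `max_load_fraction` | 0.3 | — | admissible contact-point region (load below 30% of maximum) |
| `r2_min` | 0.95 | — | goodness-of-fit gate for monolayer fits |
| `poisson_gel` | 0.5 | — | polyacrylamide is nearly incompressible; configurable |
| `height_um` | 12 | µm | monolayer height entering the force balance as $1/h$; measured per sample in practice |
| `lambda` | 0 / L-curve | m/Pa | Tikhonov strength; 0 for noiseless synthetic data (windowed method), L-curve corner for measured data |
| `window_px`, `overlap` | 32, 0.5 | px, — | PIV interrogation window and overlap |

# Numerical choices

- **Perimeter and area** are measured on the marching-squares half-level
  contour of each cell support, simplified with Ramer-Douglas-Peucker at
  0.75 px tolerance. Digitization can only lengthen a contour
  (staircase), and 0.75 px sits just above the largest staircase
  excursion ($1/\sqrt2$), so straight stretches collapse to true chords
  while genuine corners (deviation $\ge 1$ px) survive. Using one polygon
  for both $P$ and $A$ keeps the shape index self-consistent: the
  honeycomb limit is recovered within 0.3% at ~80 px cells, and a
  rasterized square yields circularity $\pi/4$ to three digits. Accuracy
  degrades to about 1% for cells below ~30 px across.
- **Adjacency**: cells are neighbors when their gap-repaired supports
  touch under 8-connectivity, except that contacts carrying the
  signature of a four-fold pixel vertex (a 2x2 block of four distinct
  labels, or a one-pixel bridge flanked by two distinct third cells) are
  excluded — such pairs meet only at a point. Zero-valued boundary lines
  are first reassigned to their geodesically nearest cell; background
  pixels bordering a single cell are never filled, so an empty margin
  stays empty.
- **Rescaled areas** use $\langle A\rangle$ over border-free cells of the
  same image, computed before any filtering; their mean over that
  population is exactly 1.
- **$\sigma_n^2$** is the population (not $n-1$) variance, the central
  second moment of the neighbor-count distribution, taken per animal.
  Hence the identity $b(6) = -\sigma_n^2$ holds exactly on every sample.
- **Mode estimation** (perimeters, stiffness populations) uses a
  histogram with Freedman-Diaconis bins (log-spaced for stiffness, which
  is broad and right-skewed), a light 7-bin moving-average smoothing of
  the bin densities so sampling noise cannot displace the peak, and a
  local quadratic fit through the peak neighborhood. Ties return the
  smallest mode with a warning; effectively constant samples return
  their median. On $10^4$ lognormal draws the analytic mode is recovered
  within ~2-5%.
- **Whole-curve Hertz fits** run Levenberg-Marquardt from a linearized
  initialization ($F^{2/3}$ vs $z$ regression for $E$ and the contact
  point); the model force is identically zero before contact. Degenerate
  input (all-zero force) reports `converged = FALSE` rather than a
  modulus.
- **FTTC** defaults to the *windowed* inverse: the imaging window is part
  of the forward operator, and the Tikhonov problem
  $\min \lVert \mathrm{crop}(G*T) - u\rVert^2 + \lambda^2\lVert T\rVert^2$
  is solved by conjugate gradients with the Green convolution applied by
  FFT. The classical per-wavevector inverse is available as
  `method = "direct"` (with a raised-cosine extension across the padding
  band) and is the right choice for noisy measured displacement together
  with L-curve regularization; the windowed inverse with $\lambda = 0$
  is for noiseless synthetic data, where it round-trips a forward scene
  to ~0.1-0.7% with error falling as the grid is refined (16, 32, 64
  points per side are exercised in the tests). The zero-frequency
  component is removed throughout: tractions are net-force-free.
- **Monolayer stress** solves plane-stress equilibrium with body force
  $-t$ on a bilinear-quadrilateral finite-element mesh over the image
  frame, free boundaries, and rigid-body modes removed by Lagrange
  constraints; thickness-integrated stress is divided by $h$. The
  fictitious sheet modulus drops out of the equilibrium content; the
  fictitious Poisson ratio redistributes stress only weakly and defaults
  to 0, for which the one-dimensional force balance (a uniformly
  contracting strip has midline average normal stress $T_0 L/4h$) is
  reproduced within ~2% on a 64-point grid.
- **PIV** uses zero-padded (linear) window cross-correlation normalized
  by the overlap area — circular correlation and unnormalized linear
  correlation both bias the peak — with three-point Gaussian sub-pixel
  refinement, peak-ratio validation and neighbor-median inpainting, and
  drift removal by subtracting the median vector. RMS accuracy on
  rendered bead pairs is ~0.16 px at 32-px windows.

# Design decisions on genuinely open points

- *Baseline end of a force record.* Instrument exports differ in
  orientation; curves here are stored far-from-surface first, so the
  baseline is the head of the record and `subtract_background()` takes
  `baseline = "head"` by default, with `"tail"` for exports that store
  the deepest point first. The conventional "last 40-50% of the points"
  phrasing refers to the latter orientation.
- *Bulk criterion vs trim order.* The 30-px bulk criterion is applied
  after the 15-px trim, on trimmed coordinates.
- *Desch rescaling.* Perimeters are rescaled by the histogram-peak mode
  of the perimeter distribution (the most probable perimeter); rescaling
  by the mean is available via `desch_law(..., rescale = "mean")`.
- *Aboav central cells.* Edge cells are excluded as central cells (their
  neighborhoods are truncated) but still count as neighbors of bulk
  cells with their observed neighbor counts, as in real images.
- *Internalization rule.* A particle is internalized when its volume
  centroid lies below the apical reference surface at its position
  (`rule = "centroid"`); `rule = "entire"` requires every voxel below.
  Classification uses physical heights, so anisotropic confocal voxels
  (0.5 µm sections) do not affect it.
- *ECM-protocol depth cap.* The whole approach curve is fitted by
  default; `fit_hertz(depth_cap_um = )` restricts the fit to a chosen
  indentation depth where acquisitions indent only a few hundred nm.
- *Minimum particle size.* No size filter is applied by default;
  degenerate single-pixel regions are skipped with a message.

# Limitations

- A Voronoi edge shorter than about a pixel cannot survive rasterization:
  at a quasi-four-fold vertex the rendered mask shows either nothing or
  the crossing diagonal pair. With the four-fold-vertex contact rules,
  generator truth and mask-recovered neighbor lists agree for ~97% of
  interior cells (1024^2 px, 100 cells); the residual disagreements are
  edges in the half-to-one-pixel flip zone, which every jittered
  tessellation contains. Downstream topology statistics are insensitive
  to these single-edge flips at the sample level.
- Perimeter accuracy degrades for cells below ~30 px across; absolute
  shape indices of small cells carry ~1% estimator bias.
- Traction recovered from noisy PIV fields inflates mean magnitudes
  (noise rectification under the absolute value); comparisons across
  conditions should hold acquisition noise constant, as the drivers in
  `analysis/` do.
- The stress solver assumes a homogeneous, isotropic, elastically
  compatible sheet with stress-free frame boundaries — the standard
  monolayer-stress-microscopy idealization; absolute stresses inherit
  the uncertainty of the monolayer height $h$.

# Problem sizes

The test suite and acceptance script run monolayers of 40-150 cells at
256-1024 px, 50-curve-per-condition Hertz populations over five moduli
and three noise levels, traction grids of 16-128 points per side, and
$10^4$-draw mode-recovery samples; the full suite completes in a few
minutes on one CPU. The `analysis/` drivers use three animals times two
images per region at 768 px, 400-curve stiffness populations and
32-64-point traction grids.
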