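# phantomflow

Registration-based quantification of vascular wall motion, tested against
ground truth it cannot cheat: a digital flow phantom whose geometry never
moves.

## What problem this addresses, and for whom

Cardiac-cycle wall motion of cerebral vessels and aneurysms is quantified
in vivo by deformable registration: landmarks on the vessel border of the
first frame of a time-resolved acquisition (TWIST MRA, 4D-CTA, 3D-RA,
Flow MRI) are propagated through frame-to-reference deformation fields,
and their Euclidean displacements are read as wall motion. But in
contrast-enhanced imaging the lumen intensity tracks contrast
concentration and flow, not geometry — so intensity change alone can
produce *fictitious deformation* of the same order as reported in-vivo
wall motion (tenths of a millimetre, around one pixel).

phantomflow is for researchers developing or auditing such pipelines. It
provides:

* a **synthetic-data generator** emulating a rigid, perfused flow
  phantom: six vessel-like structures (straight tube, stenosis, helix,
  bifurcation, one-/two-sided aneurysm) at 2/3/4 mm inner diameter with
  1 mm walls, imaged as 2D+t sequences under a gamma-variate contrast
  bolus with 60 bpm pulsatile valve gating, with modality presets at
  the reconstructed in-plane resolutions 1.3 mm (TWIST), 1.0 mm (Flow),
  0.586 mm (CTA) and 0.253 mm (3D-RA), Rician or Gaussian noise — and
  exactly zero true motion (or injected, known motion for recovery
  experiments);
* the **quantification pipeline** itself: Sobel edge landmarks (150 per
  ROI, seeded), multi-resolution free-form-deformation registration with
  cubic B-splines and a Mattes-style mutual-information metric (Rcpp
  core), landmark propagation, displacement traces in mm and pixels;
* the **statistics** of the ground-truth study: bolus vs after-bolus
  paired t-tests, structure-vs-structure Welch tests,
  intensity–deformation correlation, and the per-(modality, size,
  structure) summary table.

## The model in brief

The deformation is a free-form B-spline transform
$T(x) = x + \sum_{ij} c_{ij}\, B_3(u_x - i)\, B_3(u_y - j)$
with displacements $c_{ij}$ at a regular control grid and $B_3$ the
cubic B-spline basis. Each frame is registered independently to frame 1
by maximizing mutual information
$\mathrm{MI} = \sum_{f,m} p(f,m) \log \frac{p(f,m)}{p(f)\,p(m)}$
estimated from a Parzen-windowed joint histogram of randomly sampled
intensities, via stochastic gradient ascent with an analytic gradient,
over a 3-level image pyramid. Candidate solutions are model-selected on
an independent evaluation sample set with a parsimony rule: a
deformation is accepted only when it beats the identity by more than the
measured null (noise-only) MI gain. The lumen intensity follows
$I(t) = [I_0 + (I_p - I_0)\gamma(t - t_0)]\,g(t)$ with a normalized
gamma-variate $\gamma$ and a periodic valve gate $g$. Details, defaults
and their rationale are in the methods vignette
(`vignettes/phantomflow-methods.Rmd`).

## Worked example

Simulate the headline experiment — a rigid 4 mm one-sided aneurysm under
a TWIST-like contrast bolus, 60 frames — and quantify its "wall motion":

```r
library(phantomflow)

res <- run_experiment(
  run_config(structure = "one_sided_aneurysm", inner_diameter = 4,
             modality = "twist_mri", n_frames = 60, seed = 1),
  out_dir = "aneurysm_run")

res$trace
#> displacement_trace: 150 landmarks x 60 frames; mean 0.195 mm (0.15 px), max 1.472 mm

round(unlist(res$report$window_means), 3)
#> bolus after
#> 0.547 0.051

window_compare(res$trace, res$windows)
#> paired t-test (landmark_mean): t(149) = 40.81, p = 9.17e-83

round(res$report$correlation_r, 2)
#> [1] 0.74
```

The structure never moved, yet the pipeline reports a mean displacement
of 0.55 mm during the contrast bolus — collapsing to 0.05 mm after
washout, and strongly correlated (r = 0.74) with the frame-to-frame
intensity change. That is the fictitious-deformation effect: an
artifact of intensity dynamics, of the same order as published in-vivo
wall-motion measurements. A static no-bolus control run
(`run_config(static = TRUE, ...)`) reports zero displacement and the
verdict `"no fictitious motion"`, and a known-translation sequence
(`apply_known_deformation()`) is recovered to a few hundredths of a
pixel — the pipeline errs only when the intensity, not the geometry,
changes.

`run_experiment()` writes the sequence (NIfTI + JSON provenance),
landmarks (CSV + sidecar), transforms (JSON), the tidy displacement
trace (CSV), a report (JSON), diagnostic plots and a checksummed
manifest; `run_grid()` sweeps modality x structure x size and assembles
the summary table. A thin command-line wrapper lives at
`inst/cli/phantomflow.R`.

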