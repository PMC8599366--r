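# eusTracker

Hardware-free endoscopic-ultrasound (EUS) probe tracking by Haar-feature
dictionary matching.

## The problem

Hydrogel spacers injected between the head of the pancreas and the duodenum
under EUS guidance can spare the duodenum during dose-escalated radiotherapy
of pancreatic cancer — but executing a pre-planned injection point requires
knowing where the 2D EUS imaging plane sits inside the diagnostic 3D CT/MRI
volume, a job usually delegated to external optical or electromagnetic
tracking hardware. `eusTracker` implements an image-only alternative for
researchers in image-guided intervention:

1. **Simulate a dictionary.** Over a grid of candidate probe poses
   (plane offsets at 5-mm spacing, rotations of 0° and ±15°), render a
   B-mode ultrasound image per pose with a convolution-model simulator
   driven by point-scatterer phantoms (geometric targets for a training
   phantom; intensity-weighted scatterers drawn from an interpolated CT/MRI
   slice for patient-style data).
2. **Encode with Haar features.** Each image becomes a multi-scale vector of
   Haar-like template responses `V(s,t) = ⟨I, φ_st⟩`, evaluated in constant
   time per feature from one integral image (eight base templates,
   black/white proportion variants, dyadic scales, support `12·2^s` px).
3. **Match by per-scale NCC.** A target EUS frame is localized as

   ```
   I_match = argmax_i  (1/N_s) Σ_s NCC( V_hi(s), h_target(s) )
   ```

   the pose whose vector maximizes the normalized cross-correlation averaged
   over scale blocks. The matched entry carries its pose and paired
   CT/MRI plane — that is the probe localization.

The package covers the full pipeline: volume IO (NIfTI, minimal DICOM) and
oblique slice extraction, scatterer-phantom generators (including a
synthetic EUS-training-phantom and an abdomen-like fixture generator),
linear/curvilinear probe presets with scan conversion, pose-grid builders
(including the patient-MRI 7-slices-per-point scheme), integral-image Haar
extraction, the NCC matcher, and marker-based localization-error
evaluation with scale/basis sweeps.

## Worked example

The default phantom study: four echogenic 5-mm spheres around a 25-mm scan
channel, 5 scatterers/mm³, 4 targets × 30 poses, 128×128 images.

```r
library(eusTracker)

study <- phantomStudy(seed = 1)          # geometry + scatterers + pose grid
basis <- haarBasisSet()                  # 8 templates, scales 0:3 -> 1560 features
dict  <- buildDictionary(study$field, study$grid, study$probe, study$psf,
                         basis)          # ~1.5 min on one core
dict
#> FeatureDictionary: 120 entries (120 valid), 1560 features each

## localize a noisy, independently re-seeded target at each sphere's
## central pose and measure sphere-centroid marker errors
ev <- evaluatePhantomLocalization(study, dict, basis)
ev$matches
#>   targetId trueIndex bestIndex correct     score
#> 1 target_1         6         6    TRUE 0.9984902
#> 2 target_2        36        36    TRUE 0.9988099
#> 3 target_3        66        66    TRUE 0.9987640
#> 4 target_4        96        96    TRUE 0.9985576
ev$report
#> MarkerErrorReport: max |error| 0.882 mm, mean |error| 0.516 mm
```

All four targets recover their true dictionary pose, and every per-axis
marker error is below 1 mm — the localization bound reported for the
physical phantom experiment. `ev$report@perMarker` holds the per-target
Δx (lateral) and Δy (axial) in mm, matched minus target.

A shell driver wrapping the same pipeline lives at `inst/cli/eustrack`
(`phantom`, `build-dict`, `match`, `eval`, `sweep` subcommands, YAML
config, deterministic under a fixed config + seed).

## Vignette

`vignettes/eus-probe-tracking.Rmd` documents the matching model and its
assumptions, the simulator's fidelity departures from full acoustic
simulation, every tunable parameter with units and defaults, the synthetic
study design, and known limitations.
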