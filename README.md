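# qpirbc — quantitative-phase red-blood-cell morphometry

Quantitative phase imaging (QPI) maps the optical path delay a transparent
cell imposes on transmitted light; for a red blood cell (RBC) at constant
refractive-index contrast Δn, the phase shift is the thickness projection
φ = 2π·Δn·T/λ, so a single off-axis hologram yields dry-mass and
morphology information for every cell in the field of view. `qpirbc` is an
R package for the full analysis chain behind the QPI study of
thalassemia-trait RBCs:

- **Holography** — Fourier sideband demodulation of off-axis
  interferograms, least-squares phase unwrapping via the discrete cosine
  transform (exact for residue-free phases), and background plane
  referencing.
- **Segmentation** — marker-controlled watershed instance masks on phase
  maps (Otsu threshold → hole filling → distance transform → h-maxima
  seeds), IoU-based matching against reference masks, rotation
  augmentation.
- **Features** — the 15-feature single-cell scheme: optical volume
  OV = Σφ·a_px, mean/P5/P95/SD of phase shift; projected area, perimeter,
  axis lengths, eccentricity; and five GLCM texture statistics (contrast,
  dissimilarity, homogeneity, energy, ASM) on in-mask pixel pairs.
- **3-D morphology** — volume V, surface-to-volume ratio S/V, sphericity
  SI = π^(1/3)(6V)^(2/3)/S, average and central thickness (Tavg, T0), and
  the doughnut signature Δ75 = T̄(0.75·R_eq) − T0, from thickness maps.
- **Classification & attribution** — a gradient-boosted tree classifier
  (xgboost) on the 15 features with grouped splits (augmented copies of a
  cell never cross partitions), Table-style metrics (sensitivity,
  specificity, F1, AUC, accuracy), and **exact** Shapley values by full
  2^M coalition enumeration under the interventional value function.
- **CCA** — canonical correlation analysis of the four dominant phase
  statistics against the six 3-D features, solved by SVD of the whitened
  cross-covariance Σxx^(−1/2) Σxy Σyy^(−1/2), with within-set loadings and
  shared variances ρ².
- **Synthetic phantoms** — Evans–Fung biconcave cells
  T(ρ) = √(1−ρ²)(c0 + c2ρ² + c4ρ⁴) with analytic volume and profile ground
  truth, a hologram forward model (carrier fringes, camera noise, 16-bit
  quantization), and multi-cell scene composition, so the whole pipeline
  is testable with no external data.

## Worked example

Simulate one healthy discocyte, image it through the hologram forward
model, and recover its morphology:

```r
library(qpirbc)

spec  <- phantom_spec()                      # classic discocyte, V = 94.1 um^3
cell  <- render_phantom(spec, pixel_size = 0.08, pad_um = 3)
holo  <- hologram_forward(cell$phase, rng_seed = 1)
phase <- reconstruct_phase(holo)
cells <- segment_cells(phase)
#> LabelMap 173 x 173 px, 1 instance(s)

extract_features(phase, cells, class = "healthy")[ ,
  c("ov_rad_um2", "phase_mean_rad", "phase_sd_rad", "area_um2", "eccentricity")]
#>   ov_rad_um2 phase_mean_rad phase_sd_rad area_um2 eccentricity
#> 1     67.446          1.515        0.341   44.525        0.012

mask  <- cells$labels == 1
thick <- thickness_from_phase(phase, mask, delta_n = 0.06, wavelength = 0.532)
vs    <- volume_and_surface(thick)
sprintf("volume %.1f um^3, sphericity %.3f",
        vs$volume, sphericity(vs$volume, vs$surface_area))
#> "volume 95.2 um^3, sphericity 0.848"
```

The recovered optical volume (67.4 rad µm²) is the phase integral over the
cell; dividing by 2πΔn/λ = 0.7086 rad/µm gives 95.2 µm³, within 1.2% of the
phantom's analytic 94.1 µm³ after the full hologram round trip.

At population scale — sample both classes, extract features from
watershed-segmented cells, train and explain the classifier, and relate 2-D
statistics to 3-D shape:

```r
specs <- sample_population(60, rng_seed = 7)       # 60 healthy + 60 thal
feats <- population_feature_table(specs, segment = "watershed", rng_seed = 7)
parts <- split_dataset(feats, ratios = c(4, 1) / 5, seed = 8)
model <- train_classifier(parts$train, seed = 9)
evaluate(model, parts$test)
#> sensitivity 1.000 | specificity 1.000 | accuracy 1.000 | F1 1.000 | AUC 1.000

cca_fit(feats[, c("ov_rad_um2", "phase_mean_rad", "phase_p5_rad", "phase_sd_rad")],
        feats[, c("volume_um3", "sv_ratio_per_um", "sphericity",
                  "t_avg_um", "t_0_um", "delta_75_um")])
#> Canonical correlations: 0.997 0.988 0.722 0.137
#> Shared variances:       0.994 0.977 0.522 0.019
```

The first canonical pair links optical volume with cell volume; the second
carries the doughnut signature (phase SD loading with S/V and Δ75, against
sphericity). `run_pipeline()` executes the same flow end-to-end from a YAML
config and writes every artifact plus a manifest;
`inst/cli/qpirbc.R` exposes each stage as a shell subcommand
(`simulate`, `reconstruct`, `segment`, `features`, `features3d`, `train`,
`evaluate`, `explain`, `cca`, `run`).

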