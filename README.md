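# ecmquant

Quantification toolkit for fibrous extracellular-matrix (ECM)
characterization, built for studies that compare scaffold or tissue states
(for example control versus irradiated mammary fat pad and the hydrogels
derived from it) across four measurement modalities:

* **Fiber-network architecture** from SEM-like micrographs: median-filter
  equalization, locally adaptive Otsu thresholding, half-maximum mask
  refinement, Zhang–Suen skeletonization, and graph tracing, yielding the
  six standard descriptors — covered area ratio, mean fiber diameter,
  node (intersection) density, mean pore size, porosity, and the
  orientation index (0 % isotropic → 100 % aligned).
* **Raman spectra**: Savitzky–Golay smoothing (order 5, 15-point window),
  iterative modified-polynomial fluorescence background subtraction
  (degree 7, threshold 1e-4), min–max normalization, collagen/lipid band
  ratios I(1650)/I(1300) and I(1265)/I(1300), and mean-centred PCA.
* **AFM force–distance curves**: Hertz spherical-indenter fits
  F = (4/3)·E/(1−ν²)·√R·δ^{3/2} with jointly estimated contact point and
  baseline, plus stiffness histograms with mode detection.
* **Oscillatory rheology**: Young's modulus from the gelation plateau via
  E = 2G(1+ν), with G = G′ + G″ (the conventional |G*| is available behind
  a flag).
* **Cell-level readouts**: elongation index and form factor (4πA/P²),
  pixel-overlap colocalization fractions, transwell invasion index,
  marker-positive fractions, raw integrated density, and ≥1.5-fold analyte
  filtering.

Because such studies rarely deposit raw micrographs or spectra, the
package ships seeded synthetic generators for every input type — fibrous
images, peak-plus-baseline spectra, Hertz force curves, mask pairs — each
emitting its exact ground truth, so the whole pipeline is validated by
parameter recovery.

## Worked example

```r
library(ecmquant)

spec <- fiber_image_spec(n_fibers = 80, fiber_width_um = 0.5,
                         fiber_length_um = 20, orientation_kappa = 2,
                         seed = 7)
sim <- generate_fiber_image(spec)
d   <- analyze_fibers(sim$image)
d[, c("covered_area_ratio", "mean_fiber_diameter_um",
      "node_density_per_mm2", "mean_pore_size_um2",
      "orientation_index_pct")]
#>   covered_area_ratio mean_fiber_diameter_um node_density_per_mm2
#> 1              0.252                  0.529             41961.67
#>   mean_pore_size_um2 orientation_index_pct
#> 1             10.247                63.934
```

A quarter of the field is fiber-covered; the recovered mean diameter
(0.529 µm) sits within 6 % of the generator's 0.5 µm ground truth; pores
average ~10 µm²; and the orientation index of 64 % reflects the moderately
aligned scene (concentration 2).  The fitted network itself is attached as
`attr(d, "network")` and plots with `autoplot()`.

```r
cv  <- generate_force_curve(force_curve_spec(E_pa = 1200,
                                             noise_sd_nN = 0.05, seed = 3))
fit_hertz(cv)
#> <hertz_fit> E = 1192 Pa, contact at 197.1 nm, R^2 = 0.9916

sp <- process_spectrum(generate_spectrum(spectrum_spec(noise_sd = 0.01,
                                                       seed = 2))$spectrum)
peak_ratios(sp)[, c("amide1_lipid", "amide3_lipid")]
#>   amide1_lipid amide3_lipid
#> 1         1.93        1.085

youngs_from_rheology(tibble::tibble(time_s = 1:60,
                                    storage_modulus_pa = 300,
                                    loss_modulus_pa = 60))[, c("G_pa", "E_pa")]
#>   G_pa E_pa
#> 1  360 1080
```

The Hertz fit recovers the 1200 Pa ground truth within 1 % despite force
noise; the band ratios track the generator's 2:1 amide-I/lipid and ~1.1:1
amide-III/lipid height ratios; and a plateau with G′ = 300 Pa, G″ = 60 Pa
converts to E = 3·(300+60) = 1080 Pa.

Reproducible, config-driven runs (with a CLI at
`inst/scripts/ecmquant`) go through `run_pipeline()`; every output
directory receives the resolved config and a log sufficient to replay the
run bit-identically.

## Package layout

| module | contents |
|---|---|
| `R/synthetic-data.R` | seeded generators + ground truth for every modality |
| `R/fiber-network.R`  | segmentation, skeleton graph, architecture descriptors |
| `R/raman.R`          | smoothing, background subtraction, ratios, PCA |
| `R/mechanics.R`      | Hertz fitting, stiffness histograms, rheology conversion |
| `R/cell-metrics.R`   | morphology, colocalization, invasion, positivity, RID, fold changes |
| `R/io.R`, `R/pipeline.R` | validated readers/writers and the config-driven runner |

See the methods vignette (`vignettes/ecm-quantification.Rmd`) for the
models, parameter choices, and validation design.
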