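# glandmark

Label-free markers of malignancy for breast tissue imaged by quantitative
phase microscopy (QPI / SLIM), and the machinery to evaluate them.

Standard breast histopathology reads stained tissue qualitatively, which
makes it sensitive to stain variability and to inter-observer variation.
Quantitative phase maps of *unstained* sections measure an intrinsic
physical property — the optical path-length difference, in radians, at
every pixel — and support markers that do not depend on staining at all.
`glandmark` implements such a marker pipeline for annotated epithelial
glands in tissue-microarray cores, for researchers in quantitative
microscopy and computational pathology:

- **Geometry** — the median perimeter curvature ⟨C⟩ of the gland outline,

  C(t) = |x′y″ − y′x″| / (x′² + y′²)^(3/2),

  computed by cyclic central differences on the annotation polygon,
  subsampled to probe the ~13 µm scale at which benign boundaries vary
  faster than malignant ones.
- **Scattering** — the median scattering mean free path ⟨l_s⟩ from the
  scattering-phase theorem, l_s = L / var[φ(x, y)], with local variance
  over a ~24 µm window (149 px at 6.2 px/µm; rescaled at other
  resolutions) and L the section thickness (5 µm). Heterogeneous benign
  glands scatter strongly (short l_s); homogeneous malignant sheets do not.
- **Texture** — a 50-dimensional texton-histogram descriptor ⟨T⟩: per-pixel
  responses to a 58-kernel Leung–Malik filter bank, clustered (k-means,
  K = 50) into textons on training cores only, with 60 × 60-pixel local
  label histograms medianed over the gland.

The concatenated 52-dimensional gland vectors are classified by a
shrinkage-regularized linear discriminant; gland likelihoods aggregate to
core-level malignancy scores (mean by default, median as a variant); and
performance is measured by three-fold cross-validated, pooled ROC analysis
with an equal-cost operating point. Because no QPI tissue-microarray data
are publicly deposited, the package includes a synthetic-core generator
whose class-conditional gland morphology and phase texture make every
stage testable end to end; see the methods vignette
(`vignettes/methods.Rmd`) for the model, the generator's parameters and
what it does and does not emulate.

## Worked example

```r
library(glandmark)

# a small synthetic cohort: 8 benign + 8 malignant cores,
# 512 px at 1.59 px/um, 2-3 annotated glands per core
scfg   <- synthetic_cohort_config(n_benign = 8, n_malignant = 8, seed = 11)
cohort <- generate_cohort(scfg)

# per-gland markers of one benign core
core <- cohort$cores[["b01"]]
core$image
#> <PhaseImage 'b01'> 512 x 512 px, 0.6289 um/px (1.59 px/um), L = 5 um
#>   phase range [-0.463, 1.769] rad, mean 0.3757 rad
median_curvature(perimeter_curvature(core$annotations[[1]]))
#> [1] 0.049057        # <C>, 1/px at 1.59 px/um
mask <- rasterize_gland_mask(core$annotations[[1]], dim(core$image$pixels))
median_ls(scattering_length_map(core$image), mask)
#> [1] 37.15588        # <ls>, um (malignant glands run far longer)

# full three-fold cross-validated evaluation
cv <- threefold_cv(cohort, pipeline_config(n_samples = 2000, seed = 11))
cv
#> <CVResult> 16 cores, 3 folds
#>   mean aggregation:   AUC 1.000, sens 1.00, spec 1.00
#>   median aggregation: AUC 1.000, sens 1.00, spec 1.00
```

The benign core's ⟨C⟩ (0.049 px⁻¹) reflects its wobbly acinar boundary and
its short ⟨l_s⟩ (37 µm) its heterogeneous interior; on this deliberately
strong-effect synthetic cohort the cross-validated separation is complete
(AUC 1.0). `cv$core_scores` holds the pooled per-core scores, labels, fold
assignments and per-core gland-score spread.

A thin CLI wraps the same functions
(`inst/exec/glandmark synth|features|cv|report`), and real data enter
through `read_phase_image()` (float32 TIFF), `read_annotations()`
(ImageJ `.roi`/`.zip` or polygon JSON) and `read_core_labels()` (CSV).

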