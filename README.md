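# seosdd

Automated segmentation and counting of nanoparticles and aggregates in
(cryo-)TEM micrographs with complex, uneven backgrounds.

Global threshold methods (Otsu-style histogram cuts, local adaptive means)
struggle on TEM images whose background varies across the field of view —
support-film holes, thickness gradients, stained cellular structure — and
whose particles differ in intensity. This package implements an
entropy-optimized slope difference distribution (SEO-SDD) segmenter that
addresses both problems:

1. **Candidate thresholds from histogram shape.** For each histogram
   position *n*, least-squares line slopes are fitted on either side and
   their difference *s(n) = a\_L(n) − a\_R(n)* is formed. Positive maxima of
   *s* (zero crossings of *ds/dn* with *s* > 0) mark the centers of the
   image's intensity clusters — the candidate thresholds.
2. **Automatic selection by Shannon entropy.** Each candidate *t* splits
   the intensity distribution into foreground and background; with
   per-class renormalization, the total entropy
   *H(t) = H\_fg(t) + H\_bg(t)* (bits) is maximized over the candidate set
   inside a search range [A, B], by exhaustive argmax (default) or the
   logarithmic bisection variant.

Around that core the package provides non-local means denoising, mask
post-processing (size, hole-filling and convexity filters, 8-connectivity
labeling, contour tracing, Canny edges), Otsu and adaptive-mean baseline
segmenters, count-based evaluation metrics
(accuracy = 100 % − |count − truth| / truth; RE = |count − manual| / manual ×
100 %), grid-cell counting for dense aggregates, and a synthetic
ground-truth micrograph generator for end-to-end validation. Everything is
driven by one auditable nested configuration (see `defaultConfig()`).

## Worked example

```r
library(seosdd)

# synthetic benchmark: 1028 dark particles of distinct sizes/intensities on
# an uneven background with a sharp bright ring, known ground truth
scene <- presetScene("uneven_1028", seed = 42)
ren   <- renderScene(scene)

# three-way comparison on the same denoised image
cmp <- compareMethods(ren$img, reference = 1028, referenceKind = "truth")
cmp$report
```

```
               method count  score score_kind
1        Ground truth  1028 100.00   accuracy
2             SEO-SDD   959  93.28   accuracy
3   Dynamic threshold   962  93.57   accuracy
4 Histogram threshold   948  92.21   accuracy
```

The SEO-SDD row means: the pipeline selected its threshold automatically
(candidates from the slope difference curve, entropy argmax), counted 959
connected components against 1028 true particles, i.e. 93.28 % counting
accuracy. A few percent are irrecoverable by any thresholder because
closely spaced particles genuinely touch and merge. On this scene the
adaptive-mean baseline ties with SEO-SDD to within a fraction of a percent;
the global histogram threshold trails it.

Individual stages are exported too:

```r
img  <- denoiseNLM(ren$img)
prof <- selectRange(findCandidates(slopeDifference(intensityHistogram(img))), "auto")
candidates(prof)
#>  [1]  45  56  65  83 100 108 116 171 180 195 214 229
tr <- binarySearchThreshold(img, prof, exhaustive = TRUE)
selectedThreshold(tr)
#> [1] 116
mask <- postprocessMask(binarize(img, selectedThreshold(tr), "dark"),
                        minArea = 9, fillHoles = TRUE)
nComponents(labelComponents(mask))
#> [1] 959
```

A command-line front end with `segment`, `simulate`, `evaluate` and
`compare` subcommands is installed at
`system.file("scripts", "seosdd.R", package = "seosdd")`.

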