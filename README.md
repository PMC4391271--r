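# xylemtrace

Quantifying **functional (water-conducting) xylem vessels** in *Arabidopsis
thaliana* inflorescence-stem cross sections, and the hydraulic
conductivities that depend on them.

Stem cross sections contain many vessels that conduct nothing: lignified
vessels not yet connected to the transpiration stream, still-expanding
vessel cells, embolized conduits. A dye-perfusion protocol makes the
functional ones visible — a cellulose-binding fluorescent brightener
perfused through the segment stains the secondary walls of exactly the
vessels that carried it — so the same section photographed in bright field
(BF) and epifluorescence (EF) supports two identification criteria:

* **BF**: conductive ⇔ fully developed secondary wall (wall completeness
  ≥ 0.9 of the perimeter), excluding expanding vessels;
* **EF**: conductive ⇔ strictly more than half of the wall perimeter is
  stained.

The package is aimed at plant hydraulics and xylem-development work where
these calls feed quantitative estimates:

```
K_h  = F L / ΔP                      experimental hydraulic conductivity
K_ht = Σ π D⁴ / (128 η)              theoretical (Hagen–Poiseuille) sum
                                     over the conductive vessels,
                                     η = 1.002e-9 MPa s (water, 20 °C)
```

with `F` the steady flow rate fitted from a balance trace, `L` the segment
length, `ΔP` the pressure gradient, and `D` the equivalent circular lumen
diameter, `D = 2√(A/π)`. Specific conductivities divide by total lumen
area; the relative contribution is `100 K_h / K_ht`.

What the package provides:

* **Segmentation** (`detect_lumens`, `measure_vessels`): lumen detection in
  BF (Otsu + watershed + shape gates), sub-pixel-accurate lumen areas
  (including an exact correction for the inward bias that optical blur
  imposes on any thresholded convex disc — a bias that `D⁴` amplifies), and
  per-vessel wall-completeness and stained-perimeter fractions measured on
  radial annuli around the lumen boundary.
* **Classification** (`classify_all`): both conductivity criteria, the
  expanding-vessel flag, and protoxylem/metaxylem assignment from bundle
  geometry.
* **Hydraulics** (`estimate_flow_rate`, `compute_kh`, `compute_kht`,
  `summarize_segment`): flow fitting and all conductivity arithmetic, per
  criterion.
* **Statistics** (`compare_bf_ef`, `paired_wilcoxon`, `paired_ttest`):
  paired BF-vs-EF comparison tables, percent count reductions, per-segment
  `K_h/K_ht` ratios with CVs, and `K_h ~ K_ht` regressions. The signed-rank
  test has an exact tie-capable null for small samples.
* **Synthetic data** (`generator_config`, `generate_cohort`): a seeded
  generator of ground-truth-annotated vascular-bundle images (16-bit TIFF),
  flow traces and cohorts, emulating collateral bundles with a protoxylem
  cluster and a radial metaxylem file, realistic between-plant
  heterogeneity, and lignified-but-nonconductive vessels.
* **IO / CLI** (`run_pipeline`, `inst/exec/xylemtrace`): TIFF/JSON/CSV
  formats and an end-to-end driver.

## Worked example

Simulate a cohort of 11 plants (one apical + one basal segment each),
analyze it, and compare the two identification criteria:

```r
library(xylemtrace)
segs     <- generate_cohort(11, seed = 42, render = FALSE)
analysis <- analyze_cohort(segs, from = "truth")
report   <- compare_bf_ef(analysis)
print(report)
```

```
-- Conductive vessel counts (pooled) --
 count mean_bf se_bf mean_ef se_ef pct_reduction p_wilcoxon
    px   50.95 3.779   37.95 3.928            26  4.768e-07
    mx   27.00 4.730   17.36 3.238            36  9.537e-07
 total   77.95 8.286   55.32 6.720            29  4.768e-07

-- Kh/Kht ratio (per-segment means, n = 22) --
  BF: 16.08 +/- 2.61 %   EF: 25.78 +/- 4.13 %   difference 9.70 % (p = 4.77e-07)
  CV of ratio: BF 0.76, EF 0.75

-- Kh ~ Kht regression --
  BF: slope 0.123, intercept 2e-12, R2 = 0.5589
  EF: slope 0.186, intercept 2.6e-12, R2 = 0.5263
```

Reading this: dye-based (EF) identification removes about a quarter to a
third of the vessels that bright-field inspection would count as conductive
(here 26 % of protoxylem and 36 % of metaxylem vessels, p < 1e-6, paired
signed-rank). Consequently the theoretical conductivity drops and the
experimental-to-theoretical ratio rises from ~16 % to ~26 % — the
theoretical estimate stops overshooting once the non-functional vessels are
excluded. This particular seed drew a below-average cohort (vigour and
counts vary strongly between plants, as they do between real stems).

With `render = TRUE` (the default) each segment also carries a co-registered
BF/EF image pair, and `analyze_cohort(..., from = "images")` runs the full
measurement path on the rendered micrographs:

```r
seg  <- generate_cohort(1, seed = 7)[[1]]
rec  <- classify_all(measure_vessels(seg$image_pair))
head(rec[, c("diameter_um", "wall_completeness", "stain_fraction",
             "conductive_bf", "conductive_ef", "type")])
```

A shell entry point mirrors the stages
(`xylemtrace simulate | segment | classify | hydraulics | report | run`);
see `inst/exec/xylemtrace`.

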