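# sporesort

Raman spore-sorting gates and cell-envelope morphometry for bacterial
specialized resting cells.

Five bacterial taxa survive hard times by differentiating into resting
cells — endospores (Firmicutes), exospores (Actinobacteria), myxospores
(Myxococcales), cysts (Azotobacteraceae) and akinetes (Cyanobacteria). Two
single-cell readouts distinguish them from their vegetative counterparts
without culturing: a Raman microspectroscopic chemical fingerprint, and the
thickened cell envelope visible in cryo-electron micrographs. `sporesort`
implements the computation behind both, for microbiologists building
Raman-activated cell-sorting (RACS) pipelines or quantifying envelope
morphology:

* **Sorting gate.** Two statistics on a single-cell spectrum, computed on
  raw intensities:

  $$P_c = \frac{A_{[1620,1670]}(\mathrm{cell})}{A_{[1620,1670]}(\mathrm{medium})},
  \qquad
  P_{CaDPA} = \frac{M_{[1370,1420]}(\mathrm{cell})}{M_{[1620,1670]}(\mathrm{cell})},$$

  where $A_W$ is the trapezoidal integrated intensity and $M_W$ the
  in-window maximum (or, optionally, the integral) over window $W$ in
  cm⁻¹. Stage 1: $P_c < 1$ → waste. Stage 2: $P_{CaDPA} \ge 1.1$ →
  endospore (the 1370–1420 cm⁻¹ window holds the strong 1395 cm⁻¹ band of
  calcium dipicolinate, CaDPA, an endospore-specific chelate), otherwise
  vegetative.
* **Marker scoring.** A catalog of phenotype-specific bands (CaDPA
  1017/1395/1446; exospore 1342/1586; myxospore 1120/1149/1550; cyst
  830/1150/1350; the vegetative-only cyanobacterial 2295 band; the shared
  ~2900 CH stretch) with prominence-based peak detection and per-phenotype
  signature scores.
* **Envelope morphometry.** Width-averaged (23-pixel) line profiles with
  bilinear interpolation, half-depth envelope-width measurement, and
  hierarchical per-cell/overall width summaries.
* **Synthetic generators.** Seeded spectrum and band-image generators with
  ground truth, so every stage is testable end to end.
* **CLI.** `exec/sporesort` with subcommands `simulate`, `simulate-image`,
  `sort`, `profile`, `summarize-widths`.

## Worked example

Simulate a labelled population, classify it against the medium spectrum, and
summarize envelope widths:

```r
library(sporesort)

medium <- generate_spectrum(phenotype_preset("medium"))
pop <- generate_population(c(endospore = 5, vegetative_firmicute = 5,
                             debris = 3), jitter = 0.1, seed = 11)
batch <- batch_classify(pop, medium)
batch
#> <sort_batch> 13 spectra (max mode): waste 3, vegetative 5, endospore 5, error 0
head(batch$results[, 1:4], 4)
#>         label       pc   pcadpa  decision
#> 1 endospore_1 2.086370 2.511602 endospore
#> 2 endospore_2 2.115674 2.336994 endospore
#> 3 endospore_3 2.205908 2.501071 endospore
#> 4 endospore_4 2.181950 2.421101 endospore
```

Every simulated endospore clears the endospore threshold ($P_{CaDPA} > 1.1$),
every particle with cellular signal clears the cell threshold ($P_c > 1$),
and the three debris spectra fall below it into waste.

```r
summarize_widths(list(cell_1 = 63.2, cell_2 = 41.6, cell_3 = 29.4,
                      cell_4 = 39.8, cell_5 = 49.6))
#> <envelope_width_set> 5 cells
#>   cell_1: mean 63.20 nm (1 measurement(s))
#>   ...
#>   overall mean: 44.72 nm
```

44.72 nm is the mean vegetative *B. subtilis* envelope width over five
cells; the same summary on the endospore row of the packaged reference
table (`envelope_width_reference()`) gives 213.70 nm — the ~5-fold envelope
thickening that accompanies sporulation.

Measuring a synthetic envelope of known width closes the morphometry loop:

```r
band <- generate_band_image(band_image_model(width_nm = 213.7, seed = 4))
prof <- extract_profile(band$image, band_profile_line(band))
dmax <- max(prof$distance_nm)
measure_envelope_width(prof, baseline_region = list(c(0, 20),
                                                    c(dmax - 20, dmax)))
#> measured 212.9 nm (truth 213.7)
```

See `vignettes/spore-sorting-methods.Rmd` for the full model description,
parameter defaults and design rationale.

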