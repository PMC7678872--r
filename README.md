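# alphaflash

Quantification of glucagon secretion from single pancreatic alpha cells
imaged by TIRF microscopy.

Alpha cells release glucagon when blood glucose falls. With a pH-sensitive
fluorophore co-packaged into glucagon granules, each granule fusion appears
in TIRF movies as a sudden localised flash, so secretion can be counted
event by event while the bath glucose is stepped through a ramp. This
package provides, for that assay:

* **a seeded simulator** of flash-exocytosis movies with ground-truth
  annotations, driven by a glucose dose–response model (two-fold
  stimulation at hypoglycaemic 1–3 mM glucose, suppression at ≥ 4 mM and
  in glucose-free buffer, flat intermediate release under glucokinase
  knockdown) and pharmacology regimes (arginine, glycolysis inhibitors,
  glucokinase activator, washouts);
* **the event-calling pipeline**: 10 × 10-pixel grid traces over the cell
  footprint, peak detection above a rolling-median baseline
  (5 × robust sd), rejection of same-frame lower-amplitude peaks in the 8
  neighbouring squares as spillover, and normalization to
  events · (100 µm²)⁻¹ · min⁻¹;
* **the dose–response analysis**: per-cell per-condition rates, fold
  change, and threshold detection by repeated-measures ANOVA with Scheffé
  post-hoc comparisons against the 11 mM reference — reporting the release
  threshold as a bracketing interval between adjacent tested
  concentrations;
* **the statistics themselves** (Student's t, one-/two-way ANOVA, Scheffé)
  implemented from their sum-of-squares formulas and cross-checked against
  independent oracles in the test suite.

The detection rate `r` for a condition window is

```
r = n_events / (area_um2 / 100) / duration_min        [events/100 µm²/min]
```

and a glucose level is called stimulatory when its Scheffé statistic
`(mean_i − mean_ref)² / (MS_within (1/n_i + 1/n_ref))` exceeds
`(k − 1) · F_crit(α; k − 1, df_within)` with the level's mean above the
reference.

## Worked example

Simulate an 8-cell wildtype glucose-ramp experiment (11, 5, 4, 3, 2, 1,
0 mM for 3 min each; 64 × 64 px movies at 0.277 µm/px and 90 ms/frame),
call events, and run the threshold analysis:

```r
library(alphaflash)

config <- run_config(n_cells = 8)          # wildtype ramp, all defaults
res <- run_experiment(config, seed = 1)

round(colMeans(res$rates), 2)
#> 11mM  5mM  4mM  3mM  2mM  1mM  0mM
#> 1.00 0.86 0.77 1.54 2.09 1.21 0.98

res$fold_change$ratio                      # stimulated (1-3 mM) vs inhibited (4-11 mM)
#> [1] 1.787234

res$threshold
#> glucose regulation: present (ANOVA F(6,42) = 8.66, p = 3.77e-06)
#> stimulatory glucose: 2 mM
#> release threshold between 3 and 2 mM
```

The per-condition means recover the simulated two-level dose–response
(hypoglycaemic 1–3 mM elevated about two-fold over ≥ 4 mM, glucose-free
buffer suppressed), and the omnibus ANOVA detects glucose regulation
decisively. The per-level Scheffé classification, however, is
conservative by construction, and with about 7–13 events per condition
per cell a single 8-cell experiment sits near the significance boundary:
in this run only 2 mM clears the family-wise criterion, so the bracketing
interval lands one step low. Replicate experiments (below) recover the
full stimulatory set {3, 2, 1} mM and the 3–4 mM threshold as the modal
outcome. A knockdown experiment (`run_config(n_cells = 9, model =
dose_response_model(genotype = "gk_knockdown"))`) yields
`regulated: absent`: complete loss of glucose control.

Single-cell artifacts (movie TIFF, mask, truth CSV) and full experiment
bundles (rates CSV, threshold JSON, manifest) can be written via
`simulate_cell()`/`run_experiment(out_prefix = ...)` or the thin CLI at
`inst/scripts/alphaflash-cli.R` (`simulate`, `detect`, `analyze`).

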