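# punctakit

Quantification of biomolecular condensates ("puncta") in multi-channel 3D
fluorescence microscopy z-stacks.

Proteins and RNAs that undergo liquid-liquid phase separation form
membrane-less condensates that appear as bright foci in images of
fluorescently-labeled cells. For anyone studying that process — how many
condensates a cell forms, how large they are, and how strongly the labeled
biomolecule partitions into them — punctakit provides the full image
analysis pipeline:

* **staging** of per-slice/per-channel TIFFs into compiled multi-channel
  z-stacks with physical voxel metadata;
* **ROI segmentation** of cells or nuclei (pluggable backend; a classical
  threshold backend is built in), with 2D-to-3D layer merging and
  small-ROI removal;
* **puncta detection** by a multiscale, anisotropy-aware
  Laplacian-of-Gaussian (LoG) detector with per-ROI background filtering,
  and **segmentation** by thresholding plus a seeded 3D watershed;
* **measurement** tables per punctum and per ROI, including
  colocalization statistics (Pearson with p-values, mutual information,
  mask overlap coefficients);
* **thermodynamics**: for each ROI, the dense- and light-phase levels DP
  and LP, the partition coefficient and Gibbs free energy of transfer,

  ```
  K_p = [DP] / [LP]        dG_Tr = -R T ln(K_p),   R = 1.9872e-3 kcal/(mol K)
  ```

  plus the puncta volume fraction F_vol and mole fraction F_mol, with
  optional intensity-to-concentration calibration;
* **statistics**: mixed-effects comparison of ROI-level features across
  biological conditions (condition fixed, image position random; Poisson
  log-link model for counts) with Wald confidence intervals and a
  plain-text narrative;
* a **synthetic-stack simulator** with exact ground truth, so every stage
  is testable without microscopy data.

Images are base-R arrays inside light containers; every measurement
function takes and returns tibbles, so results chain straight into dplyr
and ggplot2 (`plot_thermo_panels()`, `autoplot()`).

## A worked example

Simulate a small acquisition (two channels: a nucleus marker and a puncta
channel with a planted dense/light ratio of 5), run the pipeline, and
derive thermodynamic parameters:

```r
library(punctakit)

sim <- simulate_stack(simulation_params(seed = 7))
st  <- sim$stack

roi <- segment_rois(st, pipeline_params(channel = 0))
seg <- run_puncta_segmentation(st, roi, pipeline_params(puncta_channels = 1))

pr <- measure_puncta(st, seg$labels_by_channel, roi)
rr <- measure_rois(st, roi, seg$labels_by_channel, pr)
th <- compute_thermodynamics(rr, "puncta", temp_K = 310.15)
th[, c("roi_label", "dp", "lp", "kp", "dg_tr", "f_vol", "f_mol")]
```

```
# A tibble: 3 x 7
  roi_label    dp    lp    kp  dg_tr  f_vol f_mol
      <int> <dbl> <dbl> <dbl>  <dbl>  <dbl> <dbl>
1         1  483.  118.  4.10 -0.870 0.0923 0.294
2         2  590.  149.  3.97 -0.850 0.0872 0.275
3         3  458.  110.  4.15 -0.877 0.0928 0.298
```

Each row is one segmented nucleus: `dp`/`lp` are the mean puncta-channel
intensities inside and outside its puncta (camera counts here; micromolar
if a calibration factor is supplied), `kp ~ 4.0-4.2` recovers the planted
partition ratio of 5 to within the expected partial-volume bias, `dg_tr`
is the corresponding transfer free energy in kcal/mol (negative:
partitioning is favorable), and `f_vol`/`f_mol` say that puncta occupy
~9% of the nuclear volume but hold ~29% of the labeled molecules.

Compare a feature across conditions (here on simulated ROI tables):

```r
cmp <- compare_conditions(cells, y_var = "number of puncta puncta",
                          cond_var = "condition", subsamp_var = "Image name")
print(cmp)      # narrative with estimates, 95% CIs, p-values
tidy(cmp)       # contrasts as a tibble
```

A thin command-line front end over the same functions is installed at
`inst/cli/punctakit.R` (subcommands `simulate`, `stage`, `segment-rois`,
`segment-puncta`, `quantify`, `thermo`, `compare`).

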