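# hypoxica

Tumour oxygenation fluctuates on time scales of minutes. Dynamic
BOLD-sensitive MRI sees those fluctuations through the effective transverse
relaxation rate R2\* = 1/T2\* (ms⁻¹), which rises with local
deoxyhaemoglobin concentration — but a voxel's R2\* time-course mixes
oscillations inherited from *systemic* arterial oxygenation with
*tumour-specific* oscillations generated by the tumour's own unstable
microcirculation (cycling hypoxia / cycling oxygenation), plus noise.
`hypoxica` separates these sources for preclinical tumour MRI, using a
concurrently recorded pulse-oximetry trace of systemic arterial oxygen
saturation (O₂sat) as the external reference.

The core model is a spatial independent component analysis of the
time-by-voxel matrix of mean-centred R2\* time-courses,

    X = M · S

where the columns of the mixing matrix **M** are component time-courses and
the rows of **S** are spatially independent maps. Before ICA, the data are
rank-reduced by PCA, keeping all eigenvectors up to the *shoulder* of the
eigenvalue curve plus any later eigenvector with a dominant spectral peak.
Each component is then classified:

- **systemic** — time-course correlates with the O₂sat trace (Pearson r,
  two-sided t-transform, p < 0.01);
- **tumour-specific** — a dominant spectral peak (max periodogram power ≥ 30×
  the median bin), *or* a connected cluster of ≥ 5 voxels at |z| ≥ 2.2 in the
  normalised spatial map together with a distinctive (lag-1 autocorrelation
  ≥ 0.3) time-course;
- **noise** — everything else.

Class-wise fields are rebuilt as partial products of M and S (they sum
exactly to M·S), voxels are attributed to each class by per-voxel
correlation tests against O₂sat (p < 0.01 systemic; p > 0.05
tumour-specific, within the z-thresholded map support), and the thresholded
fields are summarised in the frequency domain (sub-mHz dominant
frequencies; 10⁻³ Hz = 3.6 cycles h⁻¹). The package also ships the exact
small-sample nonparametrics used for cohort comparisons (signed-rank,
Mann-Whitney and Spearman tests with full enumeration), a seeded
ground-truth phantom generator, and pixel-wise fluorescence quantification
for histology sections (marker coverage and pericyte coverage of vessels).

## Worked example

Simulate a one-hour acquisition (947 frames at 3.8 s, 32 × 32 × 5 grid)
with known ground truth, and run the full pipeline:

```r
library(hypoxica)

ph <- generate_phantom(phantom_config(seed = 1))
ph
#> <synthetic_dataset>
#> <r2star_series> 32 x 32 x 5 grid, 947 frames @ 3.8 s (60.0 min)
#>   mask: 1328 voxels; in-mask mean R2* 0.12 ms^-1
#>   truth: 685 systemic, 93 tumour-specific voxels (52 overlap)

report <- run_pipeline(ph$series, ph$o2sat)
#> PCA decomposition ...
#> selected 4 of 947 eigenvectors (shoulder at 4, 0 peak-rule)
#> spatial ICA (k = 4) ...
#> classifying components ...
#> components: 3 systemic, 1 tumour-specific, 0 noise

glance(report)
#> # A tibble: 2 x 7
#>   class           n_components n_voxels prevalence_pct mean_temporal_sd dominant_frequency_hz dominant_cycles_per_hour
#> 1 systemic                   3      664          50             0.00380              0.000556                     2.00
#> 2 tumour_specific            1       93           7.00          0.00705              0.000834                     3.00
```

Reading the output: half the tumour voxels (50.0%) carry systemic
oscillations at the injected systemic frequency (5.56 × 10⁻⁴ Hz = 2.0
cycles h⁻¹), and 7.0% carry tumour-specific oscillations at the injected
cluster frequency (8.34 × 10⁻⁴ Hz = 3.0 cycles h⁻¹) with a higher mean
fluctuation amplitude (temporal s.d. 0.0071 vs 0.0038 ms⁻¹) — matching the
phantom's ground truth, including the 93-voxel cluster and the overlap
voxels that appear in both masks. `tidy(report)` lists the per-component
evidence (O₂sat r and p, peak frequency, cluster sizes, distinctiveness);
`autoplot()` on PCA results, summary maps and ICA fits draws the scree
curve with its shoulder, slice montages and component time-courses;
`write_report()` serialises masks, s.d. maps and a JSON audit trail of
every threshold and seed.

Real acquisitions enter through `load_series()` (4D NIfTI + mask) and
`read_o2sat()` (CSV `time_s,o2sat_pct`), or from the thin CLI in
`inst/cli/hypoxica.R` (`simulate` and `run` subcommands). Multi-echo
gradient-echo magnitudes can be converted to R2\* with `estimate_r2star()`
(log-linear least squares).

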