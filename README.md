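# boutonquant

Quantification of presynaptic potentiation at hippocampal mossy fiber
boutons (hMFBs), for synaptic physiologists working with three imaging
modalities and for anyone who needs the corresponding estimators on
synthetic data with known ground truth:

- **Glutamate transients** from high-speed (1.6 kHz) movies of a
  membrane-bound low-affinity glutamate sensor (Kd = 600 uM): per-pixel
  dF/F (%), the suprathreshold *active area* (pixels with dF/F > 3 x their
  baseline SD), cumulative / mean / maximal amplitudes, paired-pulse ratios
  (PPR = peak2/peak1), monoexponential decay constants, virtual bouton
  diameter `d = 2 sqrt(A/pi)`, correlograms, and longitudinal
  bleaching-normalized tracking.
- **Ordinal-pattern statistics** of 2D dF/F fields: normalized entropy
  `H = -sum(p_i log p_i)/log 24` over 2x2 rank patterns and non-triviality
  `C = H * Q_JS` (Jensen-Shannon disequilibrium), which separate homogeneous
  from anisotropic release patterns.
- **gSTED coupling distances** between Cav2.1 and Munc13-1 clusters:
  Richardson-Lucy deconvolution with a 2D Lorentzian PSF (FWHM 40 nm),
  prominence-gated maxima, Homer1-gated synapse triads, line-profile
  peak-to-peak distances, 20-nm histograms and group comparisons.
- **Serial-section EM morphometry** (70-nm sections): bouton complexity
  (perimeter/area), reconstructed volume, AZ density and area, vesicle
  density, volume-normalized pairwise dispersion (nm/um^3), 2D mean
  nearest-neighbor distance, docked/tethered classification (gap <= 2 nm;
  center <= 60 nm) with per-volume and per-AZ-area densities, and
  mitochondrial volume fraction.
- **Group statistics** reproducing the study-style reporting chain:
  D'Agostino-Pearson normality gate, t test with Welch upgrade on a
  significant F test, exact Mann-Whitney for small samples, two-sample
  Kolmogorov-Smirnov for distributions, paired t for longitudinal data, and
  strict significance stars (* < 0.05 ... **** < 0.0001).

Seeded generators (`simulate_bouton_movie()`, `simulate_sted_field()`,
`simulate_reconstruction()`) emulate all three raw-data kinds with full
ground truth, so every estimator is verifiable at desk scale. Data exchange
uses multi-page TIFF + JSON sidecars (movies, STED fields), a versioned JSON
schema (reconstructions), and tidy CSV (tables). Results are tibbles;
`autoplot()` / `plot_distance_histogram()` give ggplot2 figures; fitted and
comparison objects have `tidy()` / `glance()` methods.

## Worked example

```r
library(boutonquant)

# a paired-pulse movie from one bouton: 4 sites, 50-ms interstimulus interval
sim <- simulate_bouton_movie(bouton_sim_config(seed = 1))
dff <- compute_dff(sim$movie)              # 100-Hz low-pass, 3 x SD threshold
traces <- trace_parameters(dff)
peak_and_ppr(traces)
#> # A tibble: 4 x 5
#>   measure          peak_1  peak_2   ppr ppr_note
#>   <chr>             <dbl>   <dbl> <dbl> <chr>
#> 1 active_area_um2    4.96    5.04  1.02 NA
#> 2 cumulative      2884.   9078.    3.15 NA
#> 3 mean_amp          23.3    72.4   3.11 NA
#> 4 max_amp           45.0   145.    3.22 NA
fit_decay_tau(traces)
#> <bq_decay_fit> tau = 14.9 ms (A = 9.84e+03, c = -163, R2 = 0.997)
```

The active-area peak says ~5 um^2 of the bouton surface turned
suprathreshold after the first pulse; the cumulative amplitude (total
released glutamate signal, % x pixel) facilitates strongly on the second
pulse, and the cumulative transient decays with tau ~= 15 ms. With the
generator's ground truth in `sim$truth` you can check every number.

Coupling distances, end to end:

```r
field <- simulate_sted_field(sted_sim_config(n_triads = 15, seed = 2))
res <- measure_coupling(field$field, prominence = 50)  # deconvolve -> maxima
#   -> Homer-gated triads -> line profiles
aggregate_distances(dplyr::mutate(res, condition = "ctrl",
                                  animal_id = "m1"))
```

Morphometry of a reconstruction:

```r
em <- simulate_reconstruction(em_sim_config(seed = 3))
morphometry(em$rec)   # one tidy row: complexity, densities, dispersion, ...
```

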