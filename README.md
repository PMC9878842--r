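# pcpquant

Quantification of epidermal planar cell polarity (PCP) from fluorescence
microscopy images.

During skin development, hair follicles tilt collectively toward the
anterior and core PCP proteins segregate to anterior–posterior cell
junctions. Testing models of how that asymmetry arises requires turning
images into numbers, and this package implements the four standard
readouts as reusable, tested R functions:

* **Hair-follicle polarity** — segment P-cadherin / Sox9 two-channel
  images, call each follicle polarized (offset Sox9 crescent) or
  non-polarized (concentric "bicycle wheel" ring), compute growth angles,
  and summarize as cumulative percentages and rose plots.
* **Per-cell nematic order** — for a membrane protein and a cell label
  mask, the intensity-weighted second circular moment
  `Q = Σ I·e^{2iφ} / Σ I` over each cell's boundary pixels: `|Q|` is the
  polarity magnitude in [0, 1] and `arg(Q)/2` the axis in [0°, 180°).
* **Junction enrichment (JE)** — background-corrected ratio of mean
  junction-ROI intensity to mean cell-pair-ROI intensity, with two-sample
  Kolmogorov–Smirnov comparison between conditions.
* **FRAP** — reference/background correction, normalization
  `(F_t − F_bleach)/(F_ini − F_bleach)`, one-phase association fitting
  `Y(t) = Y0 + (Plateau − Y0)(1 − e^{−kt})`, and the immobile fraction
  `1 − (Plateau − Y0)/(1 − Y0)`.

Because such measurements are usually validated only by eye, pcpquant
ships a synthetic-data module (`sim_follicle_image()`, `sim_cell_mesh()`,
`sim_cell_pair()`, `sim_frap_traces()`) that generates every input type
with known ground truth; the test suite validates each estimator by
recovering those truths. See the methods vignette
(`vignettes/pcpquant-methods.Rmd`) for the models, parameter defaults,
and design decisions.

All user-facing functions take and return tibbles, so analyses chain with
the pipe; fitted FRAP objects support broom-style `tidy()`, `glance()`
and `augment()`; `plot_rose()`, `plot_polarity_histogram()` and
`plot_frap()` produce the standard figures.

## Worked example

Simulate a backskin with 40 follicles, 70 % of them polarized toward the
anterior (von Mises μ = 0°, κ = 4), then classify and summarize:

```r
library(pcpquant)
library(dplyr)

sim <- sim_follicle_image(image_size = 800, n_follicles = 40,
                          polarized_fraction = 0.7, angle_mean = 0,
                          angle_concentration = 4, seed = 11)
calls <- sim$image |> segment_follicles() |> classify_follicles()
calls
#> # A tibble: 40 × 6
#>   follicle_id polarized angle_deg coverage_deg offset_ratio qc_flag
#>         <int> <lgl>         <dbl>        <dbl>        <dbl> <chr>
#> 1           1 FALSE          NA            360      0.00584 ok
#> 2           2 TRUE          347.           130      0.610   ok
#> 3           3 TRUE           49.5          130      0.601   ok
#> 4           4 TRUE           36.6          130      0.611   ok
#> # ℹ 36 more rows

summarize_calls(calls) |> select(-rose)
#> # A tibble: 1 × 5
#>   n_total n_polarized pct_polarized circular_mean_deg circular_resultant
#>     <int>       <int>         <dbl>             <dbl>              <dbl>
#> 1      40          28            70              359.              0.865
```

Follicle 1 shows a full 360° Sox9 ring concentric with its P-cadherin
core (offset ratio ≈ 0.006) — a non-polarized "bicycle wheel". The other
follicles carry 130°-coverage crescents and get growth angles. The
summary recovers the simulated 70 % polarized fraction exactly and a
circular mean within a degree of anterior (359° ≡ −1°);
`plot_rose(summarize_calls(calls))` draws the rose plot.

A FRAP experiment with 20 noisy traces (mobile fraction 0.6, k = 0.05/s):

```r
frap <- sim_frap_traces(n_traces = 20, mobile_fraction = 0.6,
                        rate_k = 0.05, noise_sd = 18, seed = 11)
norm <- frap$traces |> frap_correct() |> frap_normalize()
frap_summarize(norm)$pooled
#> # A tibble: 1 × 8
#>   condition      Y0 plateau      k r_squared immobile_fraction converged qc_flag
#>   <chr>       <dbl>   <dbl>  <dbl>     <dbl>             <dbl> <lgl>     <chr>
#> 1 all       0.00333   0.606 0.0510     0.998             0.395 TRUE      ok
```

The fit of the averaged trace recovers the plateau (0.606 vs 0.6), the
rate (0.051 vs 0.05/s) and the immobile fraction (0.395 vs the true 0.4)
with r² = 0.998.

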