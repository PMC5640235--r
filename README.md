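# campimetr

Headless engine for **campimetric visual-field examination** — perimetry
performed on an ordinary flat screen instead of a hemispherical perimeter
bowl. It is aimed at vision scientists and tool builders who need the
computational core of a screen-based perimeter (calibration, geometry,
adaptive thresholding, fixation monitoring, dB mapping) as testable,
scriptable code, with a simulated observer standing in for the patient and
display.

## What it computes

* **Luminance calibration** — six photometer measurements at HSB
  brightness 0–100 % are fitted with a least-squares quadratic
  *f*(b) = c₀ + c₁b + c₂b², tabulated at every integer brightness;
  fit quality is a Pearson χ² over the six points with its p-value at
  df = 5 and the residual SD.
* **Decibel sensitivity** — ΔL = 10·log₁₀(L_max/L_T) dB, with exact
  inversion and re-expression against another instrument's maximum
  luminance.
* **Tangent-screen geometry** — field extension 2θ = 2·arctan(y/2x),
  pixels per degree, per-axis sphericity correction D = x·tan β with
  P = D·R/y, matrix stimulus grids, default blind-spot locations.
* **The *Basic* staircase** — a bracketing search over an ascending
  brightness vector of length 5 + 4n, starting mid-vector, stepping one or
  two values per response; per-location threshold or "no response".
* **Session engine** — randomized interleaved scheduling, virtual timing,
  blind-spot / fixation-point-change / both fixation monitoring,
  false-positive response rate FPRR = F/(F+P)·100 and per-technique
  fixation accuracy.
* **Maps** — per-location dB maps (0 dB for no response at maximum
  luminance), aggregation over repeated tests (mean, SD, variance, SEM),
  subtraction comparison, grayscale/color rendering.
* **Storage** — text registries with `P_yyyyMMdd_xxxx`-style ids,
  `.sset` settings templates, self-contained result folders.

## Worked example

Calibrate a scale from noisy photometer readings, run a simulated
examination of a hemianopic observer on the 96-location grid, and map it:

```r
library(campimetr)
set.seed(20)

m <- data.frame(brightness_pct = seq(0, 100, 20),
                luminance = c(0.6, 6.8, 20.1, 43.0, 72.2, 110.9))
sc <- fit_luminance_scale(m, name = "office screen, green")
sc
#> <luminance_scale> S_20260930_LQ3b (office screen, green)
#>   f(b) = 0.6821 + 0.09148 b + 0.01009 b^2  [cd/m2]
#>   range: 0.68 - 110.77 cd/m2
#>   fit: chi2 = 0.035, p = 1.000, residual SD = 0.358 cd/m2

grid <- generate_grid(c(71.73, 44.41), 5.98, 5.52)
grid
#> <stimulus_grid> 12 x 8 = 96 locations, spacing 5.98 x 5.52 deg

cfg <- exam_config(grid, sc, make_brightness_vector(0, 100, 9),
                   fixation = fixation_config("both"))
obs <- observer_hemianopia(grid, 25, blind_side = "right",
                           guess_rate = 0.02, fixation_loss_prob = 0.05)
session <- run_exam(cfg, obs, seed = 42)
session
#> <exam_session> 336 presentations over 96 locations, 484.5 s
#>   positives 100, false positives 6 (FPRR 5.7%)
#>   blindspot fixation accuracy 26/29 (90%)
#>   point-change fixation accuracy 11/12 (92%)

map <- build_map(session)
map
#> <vf_map> left eye, 96 locations, l_max 110.77 cd/m2 (0-5.60 dB scale)
#>   mean 2.68 dB, 50 location(s) at 0 dB
```

Reading the output: the staircase finished all 96 locations in 336
presentations (~8 minutes of virtual exam time). The blind right
half-field (48 locations) maps to 0 dB; two further locations were pushed
to "no response" by the observer's 2 % guess rate corrupting their
staircases — visible downstream in the 5.7 % FPRR, which is exactly the
reliability index an examiner would use to judge such a session. The map
renders with `render_map(map)` and compares across sessions with
`aggregate_maps()` / `subtract_maps()`.

A command-line interface over the same functions ships in
`inst/cli/campimetr.R` (subcommands `calibrate`, `exam`, `map`,
`aggregate`, `compare`, `registry`).

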