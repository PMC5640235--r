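---
title: "Methods: headless flat-screen perimetry with campimetr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: headless flat-screen perimetry with campimetr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(campimetr)
```

campimetr implements the computational core of a campimetric visual-field
examination: a light stimulus is flashed at predefined locations of an
ordinary flat screen, the patient presses a key when they see it, and the
minimum luminance that elicits detection is estimated at every location and
expressed as a decibel sensitivity map. This vignette describes the models
and numerical choices; everything here is computed by the package's
functions and exercised by its test suite.

## Luminance calibration

A consumer screen gives no direct access to physical luminance, so the
brightness channel of the HSB color space is calibrated against a
photometer. Six patches of fixed hue and saturation are measured at
brightness 0, 20, 40, 60, 80 and 100 %, and a second-degree polynomial
$f(b) = c_0 + c_1 b + c_2 b^2$ is fitted by least squares. The fitted
polynomial is tabulated at every integer brightness, giving a 101-element
vector the exam engine indexes directly — a deliberately discrete
representation, since stimuli are specified in whole brightness percent.

Fit quality is summarised three ways:

* a Pearson chi-squared statistic $\chi^2 = \sum_i (o_i - f_i)^2 / f_i$
  over the six calibration points. The exact form of the statistic is a
  package choice; Pearson's is the standard goodness-of-fit statistic for
  this structure.
* its upper-tail p-value on **5 degrees of freedom** (six measurements
  minus one). Five is the unique df under which the reference
  ($\chi^2$, p) pairs used in our acceptance checks — (1.63, 0.898) and
  (2.12, 0.832) — are both reproduced to three decimals.
* the sample (n−1) standard deviation of the residuals, in cd/m².

A concave fit can dip below zero between calibration points at low
brightness; negative entries of the fitted vector are clamped to zero with
a warning, since negative luminance is unphysical. If the fit is negative
*at a calibration point itself* the chi-squared statistic is undefined and
calibration fails loudly rather than silently.

Sensitivity is expressed as attenuation relative to the scale's maximum
stimulus luminance,

$$\Delta L = 10 \log_{10}(L_{max} / L_T)\ \mathrm{dB},$$

so 0 dB means the threshold sits at the maximum (or that the location
never responded), and larger values mean dimmer stimuli were detected.
`convert_db_scale()` re-expresses a dB value against a different
instrument's maximum (e.g. a 318 cd/m² projection perimeter), which is how
thresholds are compared across devices with different dynamic ranges.

## Screen geometry

Distances and sizes are specified in degrees of visual angle. A screen
side of physical length $y$ viewed from distance $x$ subtends
$2\theta = 2\arctan(y/2x)$, and the linear pixels-per-degree factor is
resolution over $2\theta$. For the hardware configuration used throughout
our examples (535 × 300 mm, 1920 × 1080 px, viewed at 370 mm) this gives a
71.73° × 44.14° field at 26.77 px/° horizontally.

On a perimeter bowl all stimuli are equidistant from the eye; on a flat
screen equal visual-angle steps correspond to increasingly large physical
offsets. The optional sphericity correction places a location of per-axis
eccentricity $\beta$ at offset $D = x\tan\beta$ mm from the fixation
point, converted to pixels by $P = DR/y$. The correction is applied per
axis (horizontally and vertically independently). Without correction,
placement is linear at the screen's average pixels-per-degree. The two
placements agree in the small-angle regime (they differ by under 1 % on a
screen subtending a few degrees) but diverge on wide screens, where the
average px/° factor exceeds the tangent mapping's central slope — which is
exactly why the correction exists.

Stimulus locations form an $n_x \times n_y$ matrix centred on the fixation
point with $n = \mathrm{round}(\mathrm{extent}/\mathrm{spacing})$ per
axis. This rule reproduces the 96-location layout (12 × 8) of the
reference configuration (71.73° × 44.41° at 5.98° × 5.52° spacing). The
grid is uniform in degrees; only its on-screen rendering changes with the
sphericity flag.

The assumed blind-spot location defaults to 15° temporal, 3° inferior —
leftward for the left eye, rightward for the right.

## The adaptive staircase

Each location is probed with brightnesses drawn from a single ascending
*brightness vector* of admissible length $5+4n$ (9, 13, 17, …), spread
either arithmetically or geometrically between configured minimum and
maximum percent. The search starts at the middle index and maintains a
candidate interval $[lo, hi]$:

* **not seen** at index $i$: discard everything up to $i$
  ($lo \leftarrow i+1$), jump two brighter (capped at $hi$); if the
  interval empties, the location finishes with *no response*.
* **seen** at $i$: cap the interval ($hi \leftarrow i$), probe one dimmer;
  if no dimmer candidate remains, $i$ is the threshold.

The estimated threshold is therefore the lowest index answered "seen"
whose dimmer neighbour was answered "not seen" or eliminated. For any
deterministic observer whose seen-set is upward-closed (sees everything at
or above some index), this equals the exhaustive-sweep answer — the test
suite verifies the equivalence for *every* such observer at lengths 9 and
13, and that no run ever exceeds one presentation per vector entry.
Responses are taken at face value: an observer who responds to an unseen
stimulus corrupts that location's search, by design — the procedure is
deliberately unaware of such errors, and reliability is judged downstream
from the false-positive rate and fixation accuracy, never by correcting
the data.

## Scheduling and timing

At each step an unfinished location is drawn uniformly at random, so
locations are interleaved rather than tested to completion. The
inter-stimulus interval is drawn uniformly from the configured bounds
(default 1000–1500 ms). Time is virtual — summed display times and
intervals — which makes a full simulated session instantaneous to compute
while preserving the duration bookkeeping a real session would have. The
same interface (present stimulus, await response) would be implemented by
a real display front end; this package ships only the simulation loop.

After every $k$ ordinary stimuli, with $k$ redrawn uniformly from a
configured integer interval (default one check per 5–10 stimuli), a
fixation check is inserted. Checks never touch any staircase.

## Fixation monitoring

Three techniques are provided:

* **Blindspot**: a control stimulus at the assumed optic-disc location;
  a *response* means the eye had moved (the stimulus fell on seeing
  retina).
* **Fixation point change**: a transient change of the fixation mark;
  a *failure to respond* means the eye had moved.
* **Both**: each inserted check draws one of the two uniformly at random,
  and accuracies are tallied separately per technique. Random choice (as
  opposed to strict alternation) was chosen so the patient cannot
  anticipate the check type; either scheme satisfies the same counters.

Because the true optic-disc position varies between subjects, a low
blind-spot accuracy often means the assumed location is wrong rather than
that fixation was poor; the session summary flags blind-spot accuracy
below 75 % as unreliable. The threshold is a tooling choice.

The false-positive response rate is $FPRR = F/(F+P) \times 100$, with $F$
the count of responses arriving with no open response window and $P$ the
positive responses to stimuli. Raw $F$ and $P$ are always carried in the
session counters so that the alternative convention $F/P$ can be
recomputed from the same data.

## The simulated observer

The observer is a fixture generator, but first-class, tested code: it is
what closes the loop. Detection is a step function — the stimulus is
detectable iff the location is not blind and luminance reaches the
location's true threshold — corrupted by a guess rate $\gamma$ (probability
of responding to something undetectable) and lapse rate $\lambda$
(probability of missing something detectable). A step-plus-noise model
rather than a full psychometric sigmoid matches the binary seen/not-seen
model of the procedure itself; a logistic slope would add realism the
staircase cannot resolve at these vector lengths.

$\gamma$ drives two distinct behaviours: in-window guesses (counted as
positives, corrupting the staircase exactly as a real guess would) and one
Bernoulli($\gamma$) spurious-response draw per inter-stimulus interval,
which arrives with no open window and increments $F$. Under this model a
fully sensitive observer produces an expected false fraction
$\gamma/(1+\gamma)$ of all responses, and the 200-exam property test
checks the empirical count against the exact binomial 99 % interval.

Fixation loss is i.i.d. per check with probability $q$ — the simplest
model consistent with per-check accounting; real fixation loss is
temporally correlated, which this fixture does not emulate.

Truth-map presets emulate the canonical clinical pictures: uniform
sensitivity, homonymous hemianopia (one half-field blind), tunnel vision
(periphery blind, as in advanced retinitis pigmentosa) and a scotoma patch
at the blind-spot location. What passing tests show is that the *engine*
recovers whatever ground truth the observer carries (exactly when the
truth lies on a vector luminance, within one vector step otherwise, and
0 dB exactly on blind locations); they do not show anything about human
response variability, fatigue, criterion drift or learning effects, which
real sessions have and this observer does not model.

## Maps, aggregation, comparison

A finished session maps to per-location dB via the scale's maximum fitted
stimulus luminance; *no response at maximum luminance is 0 dB*, which
deliberately conflates "threshold at maximum" with "blind" — both mean the
instrument found no attenuation it could apply.

Repeated maps aggregate per location to the sample mean, SD (n−1),
variance = SD², and SEM = SD/√n. Two results are compared by simple
per-location subtraction, refused unless the settings match (identical
grid, identical maximum luminance, identical vector length) — anything
weaker would silently compare different scales. Rendering draws one cell
per location with no interpolation by default (smoothing is presentation,
not data), a monotone grayscale or color mapping, axes crossing at
fixation with 10° ticks, and an X at the fixation-control location.

## Storage

Registries (`patients.s`, `screenLuminanceScales.s`) are line-per-record
text databases; fields are tab-delimited with backslash escaping, and
appends write-temp-then-swap so a crash cannot corrupt prior lines.
Record ids follow `X_yyyyMMdd_xxxx` (X ∈ {P, S, R}; xxxx four random
alphanumerics) with collision-triggered regeneration. Settings templates
(`.sset`) are a sectioned `key=value` text format storing every parameter,
including the calibration scales as their six raw measurements (refitted
on load, which reproduces the polynomial bit-for-bit). A result folder
(`session.csv`, `map.csv`, `settings.sset`, `scale.csv`, `summary.json`)
contains enough to rebuild its sensitivity map exactly, and the settings
snapshot reruns an identical seeded session.

## Problem sizes and numerical notes

The test suite and the acceptance script run full closed-loop exams on
compact grids (4–8 locations, length-9 vectors) — threshold estimation is
strictly per-location, so small grids exercise the identical code paths as
the 96-location layout while keeping a 200-exam calibration study quick.
The staircase-vs-oracle check is exhaustive over all upward-closed
observers at lengths 9 and 13, and over all 512 response bit-patterns at
length 9. Brightness values are rounded to the nearest whole percent when
indexing the fitted vector (the vector's 12.5-style midpoints follow R's
round-half-to-even); degenerate grids collapse to a single fixation-point
location; `lo`/`hi` index arithmetic is integer throughout.

One geometric note: from the reference screen's 300 mm height at 370 mm
the extension formula yields 44.136°, which we report as 44.14°; grid
construction accepts any stated extent as input, so layouts quoted against
a 44.41° vertical extent are reproduced regardless.

## Limitations

No real display or keyboard backend ships with the package; latencies and
reaction times are not modelled (the log's latency column is NA); there is
no normative database (mean deviation, pattern standard deviation) and no
statistical change detection across visits beyond subtraction — with
test-retest variability, averages of several tests should be compared
rather than two single tests.
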