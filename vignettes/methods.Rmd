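---
title: "Methods: models, parameters and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poleloc)
```

# Scope

`poleloc` quantifies the subcellular position of fluorescent structures in
rod-shaped bacteria from segmented multi-channel fluorescence images: where
along the cell axis a protein cluster sits, whether it shares a pole with a
second structure (a flagellar base), and how concentrated a diffuse
cytoplasmic reporter is once cell volume is accounted for. Because real
microscopy data cannot ship with the package, a synthetic-microscopy
generator with full ground truth is included; every analysis claim the
package makes is validated against planted truth.

# Cell geometry model

Cells are modeled as **spherocylinders**: a cylinder of diameter $d$ capped
by two hemispheres, total tip-to-tip length $L$. The volume is

$$ V = \frac{\pi d^3}{6} + \frac{\pi d^2}{4}(L - d), \qquad L \ge d. $$

We treat the cell as a solid body of cytoplasm for volume normalization;
the membrane is not modeled as a separate shell. From a binary mask,
`fit_axis()` recovers the axis by principal component analysis of the pixel
coordinates; $L$ and $d$ are the projected extents along and across the
first principal axis **plus one pixel** (pixel centers underestimate the
extent of the pixelated region by half a pixel at each end), converted to
micrometers with `pixel_size_um` (default 0.065 µm/px, a typical
100×/sCMOS sampling).

The **axial fraction** $s \in [0, 1]$ of a point is its projection onto the
axis, measured from tip 0 and divided by $L$, clamped to $[0, 1]$. Tip 0 is
the lexicographically smaller tip by (row, col); this makes $s$
deterministic but means $s$ and $1-s$ are equivalent descriptions of the
same position, which is why all zone definitions are symmetric about 0.5.

# Axial zones

Foci are classified by `classify_zone()` into a three-zone partition:

| zone | interval | measure |
|---|---|---|
| `precise_polar` | $s \le 0.10$ or $s \ge 0.90$ | 0.20 |
| `near_polar` | $0.10 < s < 0.25$ or $0.75 < s < 0.90$ | 0.30 |
| `mid_cell` | $0.25 \le s \le 0.75$ | 0.50 |

Boundary ownership is explicit: 0.10 and 0.90 belong to `precise_polar`;
0.25 and 0.75 belong to `mid_cell`. The partition covers $[0,1]$ exactly
once, so under uniform placement the expected zone proportions are
(0.2, 0.3, 0.5) — a property the test suite checks by Monte Carlo.

# Focus detection and the 3×3 intensity rule

Within each cell mask, the candidate focus is the **argmax pixel** of the
channel over the mask (ties broken lexicographically by (row, col) so the
result is deterministic). Its score is the **mean of the 3×3 window**
centered on it, with the window clipped at image edges (so corner pixels
average over 4 values, not 9). The signal-to-background ratio is

$$ \mathrm{SNR} = \frac{\bar{I}_{3\times3}}{\mathrm{median}(I_\text{cell})}. $$

A focus is called **obvious** when both `snr >= 2` and the absolute excess
$\bar{I}_{3\times3} - \mathrm{median}$ exceeds `min_abs` (by default three
times a MAD-based estimate of the noise standard deviation taken from
pixels outside a 3-px dilation of all cells). The dual criterion prevents
false positives in dim cells where a ratio alone is unstable, and in bright
cells where an absolute offset alone would always trigger.

For pre-divisional cells a **second pass** searches the opposite axial half
(relative to the first focus) and keeps a rank-2 focus only if it is
independently obvious. Zone tabulations in `summarize_strains()` count only
rank-1 foci, so per-strain zone counts never exceed the number of
focus-positive cells.

# Colocalization

`colocalize()` reports the Euclidean distance in µm between a cluster focus
and a flagellar focus, calls them colocalized when the distance is at most
`coloc_threshold_um` (default 0.5 µm, a diffraction-scale tolerance), and
separately reports `same_pole` (both foci in the same axial half). When a
cell has foci in both channels, `colocalization_summary()` pairs each
cluster focus with the **nearest** flagellar candidate rather than blindly
pairing rank-1 with rank-1; in bipolar cells the two rank-1 foci can sit at
opposite poles even when each pole is internally matched, and rank-based
pairing would report a spurious full-cell-length distance.

# Diffuse reporter quantification

Background is the **median** of pixels outside a 3-px dilation of all cell
masks (at least 1000 such pixels are required). Per cell,

$$ \text{corrected total} = \sum_{p \in \text{mask}} I_p - n_\text{px}\,b,
\qquad
\text{mean concentration} = \frac{\text{corrected total}}{V}, $$

with $V$ the spherocylinder volume above. Negative corrected totals (noise
in dim cells) are kept but flagged rather than truncated, so population
means stay unbiased. `compare_populations()` reports the percent difference
of population mean concentrations with a seeded bootstrap CI.

# Population statistics

Proportions are summarized with **Wilson score intervals** (better coverage
than Wald at extreme proportions, and never escaping $[0,1]$). Two-group
comparisons use **Fisher's exact test** (two-sided); the label convention
is `***` for $p < 10^{-4}$, `ns` for $p > 0.05$, and `intermediate`
otherwise. A pooled two-proportion z-test is reported alongside for
reference but the label follows the exact test. No multiple-testing
correction is applied across strains — comparisons are treated as
individually planned contrasts against a single reference; users comparing
many strains should apply their own correction. `percent_change()` reports
both conventions explicitly (`absolute_pp`, percentage points, and
`relative_percent`) because "X% drop" is ambiguous between them.

# Synthetic microscopy

`simulate_field()` produces a 3-channel 16-bit field (cluster, flagellum,
reporter), an integer label mask, and a ground-truth table.

* **Lengths** are lognormal with mean 3 µm and SD 0.8 µm, truncated below
  at the width $d$ = 0.8 µm. Cells are placed by rejection sampling with a
  2-px clearance; impossible packings fail with an informative error.
* **Polar sites**: wild-type-like cells draw the cluster site from
  $s \sim U(0, 0.10)$ or its mirror; `flhF_null` draws $s \sim U(0, 1)$
  (delocalized placement); `motor_null` keeps polar clusters but renders no
  flagellar channel signal. The flagellar base is rendered at the
  *identical* pixel as the cluster, so true colocalization distance is 0 by
  construction and any measured distance is attributable to the
  measurement chain.
* **Bipolar cells**: a `p_predivision` fraction of the longest (upper
  length quartile) cells carry a second site at the opposite pole.
* **Optics and noise**: point sources and cytoplasm are blurred with a
  Gaussian PSF ($\sigma$ = 1.3 px), then corrupted with Poisson shot noise,
  a constant background (100 counts), Gaussian read noise (SD 5), and
  quantized to 16-bit with clipping counted and warned about.

Two numerical consequences are deliberate and documented rather than hidden:
16-bit quantization perturbs constant regions by ±0.5 counts, and PSF blur
spills ~10% of a polar point source outside the cell mask. Tests therefore
assert *linearity and ratios* of recovered quantities, not absolute totals,
and mass conservation of the PSF is checked on the pre-quantization signal
via the exported `psf_blur()`.

All randomness flows from `config$seed` (field $k$ of a multi-field run
uses `seed + k - 1`), so simulated TIFF and CSV outputs are byte-identical
across reruns.

# Pipeline and CLI

`run_simulation()` writes TIFF + truth CSV + YAML config to a directory;
`run_analysis()` reads such a directory and writes per-cell, per-focus,
colocalization, reporter, and per-strain summary tables plus a
`summary.json` capturing thresholds and versions. `inst/exec/poleloc` is a
thin command-line wrapper (`simulate`, `analyze`, `compare`) over these
functions; all logic lives in the package so the CLI adds no behavior of
its own.

# Known limitations

* In `flhF_null` cells the two planted sites of a bipolar cell can fall in
  the *same* axial half; the opposite-half second detection pass then
  cannot find the second focus and the affected pair is scored against the
  wrong partner. This depresses the measured colocalization rate of
  delocalized strains by a few percent (tests assert > 0.95 rather than 1).
* Default problem sizes in the examples and acceptance script (50 cells per
  512×512 field, 4–10 fields per condition) are the package's own choices,
  set to give binomial standard errors near 1–2 percentage points while
  keeping runtimes in seconds.
* Segmentation itself is out of scope: the pipeline consumes label masks
  (here, ground-truth masks from the simulator).
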