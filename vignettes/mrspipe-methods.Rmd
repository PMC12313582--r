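---
title: "Processing in vivo MR spectroscopy with mrspipe: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing in vivo MR spectroscopy with mrspipe: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrspipe)
```

mrspipe is a headless, scriptable pipeline engine for single-voxel and
imaging magnetic resonance spectroscopy (MRS/MRSI). Data flow through a
chain of processing *nodes* — coil combination, spectral registration,
eddy-current correction, outlier rejection, apodization, zero filling,
averaging, k-space filtering, automatic phasing — and end up as LCModel
inputs (`.RAW` + control file) or, for imaging data, as CRLB-thresholded
metabolite maps. This vignette documents the models behind each node, the
parameters that matter, the synthetic-data generator the test suite runs
on, and the design choices made where more than one convention is in use.

## Data model and axis conventions

The canonical in-memory object is the `transient_set`: complex
time-domain free induction decays (FIDs) indexed
`[transient, channel, point]` plus the dwell time (s), transmitter
frequency $f_0$ (MHz), nucleus, and the chemical shift assigned to the
carrier (`ref_ppm`). Data stay in the time domain between nodes;
`fid_to_spectrum()` gives the frequency-domain view on demand. Keeping the
time domain canonical avoids repeated transform pairs inside nodes that
act multiplicatively on the FID (apodization, frequency shifts,
eddy-current phase removal) and makes zero filling a pure append.

Axes follow the NMR display convention: the centred DFT grid
$(k - n/2)/(n\,\mathrm{dwell})$, reversed so ppm *decreases* with index,
with $\mathrm{ppm} = \mathrm{Hz}/f_0 + \mathrm{ref_{ppm}}$. The carrier
maps to 4.7 ppm for water-referenced $^1$H and to 0 ppm for X-nuclei; for
even lengths the centre bin sits at $k = n/2$ (half-open convention). The
forward transform is the plain (non-unitary) DFT — only internal
consistency matters, and Parseval's relation
$\sum |X_k|^2 = n \sum |x_j|^2$ is tested on every transform path.

## The synthetic-data generator

All tests and the acceptance script run on synthetic acquisitions from
`sim_config()` / `simulate_transients()`; no scanner data are required.
The generator emulates, per transient $t$ and channel $c$:

$$ s_{t,c}(n) = w_c \Big[ \textstyle\sum_p A_p\, m_{b(t),p}\, g_p(t_n)\,
   e^{i(2\pi (f_p + t\,\delta\!f)\, t_n + \phi_p + \eta_t)} \Big]
   e^{i\phi_e(t_n)} + \epsilon_{t,c}(n) $$

with channel sensitivities $w_c$, linear frequency drift $\delta\!f$,
per-transient phase jitter $\eta_t \sim N(0, \sigma_\phi^2)$, block-design
amplitude multipliers $m_{b,p}$ for functional designs, an eddy-current
phase transient $\phi_e(t) = A_e e^{-t/\tau_e}$, and complex Gaussian
noise. Motion-like outliers multiply single transients by a gain (default
20) and rotate them by a large phase excursion. Lineshapes are calibrated
so that the *spectral* FWHM equals the configured value: Lorentzian decay
$e^{-\pi \Delta\nu_L t}$ and Gaussian decay
$e^{-(\pi \Delta\nu_G t)^2/(4\ln 2)}$. Quality-metric and apodization
tests rely on this calibration being exact.

One global seed expands into per-purpose substreams (noise, jitter,
water-reference noise, CSI noise), so enabling one corruption never
perturbs the draws of another, and identical configs are bit-reproducible.

Default conditions mirror the acquisitions the shipped presets target: a
short-TE 7 T $^1$H brain acquisition (32 transients, 4 kHz bandwidth at
4096 points, $f_0 = 297.2$ MHz, NAA/Cr/Cho-like resonances with 5 Hz
Lorentzian width), a 6 kHz / 2048-point $^{31}$P spectrum (PCr at 0 ppm
with ATP/Pi companions), and a $16 \times 16 \times 8$ $^{31}$P CSI grid
over a $200 \times 200 \times 80$ mm field of view with an ellipsoidal
"brain" support. Where the test suite shrinks problem sizes (e.g. 512-
or 1024-point FIDs in unit tests), that is a deliberate choice of grid
resolution for the property under test; the acceptance checks run at the
full sizes above.

What the generator does *not* emulate: density-matrix metabolite physics
(no J-coupling or multiplet structure — resonances are Voigt singlets),
$B_0$ inhomogeneity across the voxel, frequency-dependent coil
sensitivities, and baseline/macromolecule signals. Passing tests therefore
demonstrate the correctness of the *processing algebra* (registration,
correction, averaging, filtering, I/O), not fitting accuracy on real
brain spectra.

## Processing nodes

**Coil combination** (`coil_combine()`): three standard schemes. `snr2`
weights $w_c \propto \bar S_c^*/\sigma_c^2$ with $\bar S_c$ the first
point of the mean water-reference FID and $\sigma_c$ the channel noise SD
from the last 10% of the FID; `svd` takes the conjugate of the first left
singular vector of the water channel-by-time matrix; `adaptive` maximises
the generalised Rayleigh quotient $w^\dagger R_s w / w^\dagger R_n w$ with
$R_s$ from the leading 5% of samples and $R_n$ from the tail 10%. The
paper trail behind these methods leaves the block sizes open; 5%/10% are
fixed here and exposed nowhere — they are safely inside the signal-
dominated head and noise-dominated tail for any realistic decay. All
methods normalise to unit weight norm and rotate the global phase so the
combined reference first point is real-positive; the same weights are
applied to the water reference so it stays consistent downstream.

**Frequency/phase alignment** (`align_frequency_phase()`): per transient,
bounded nonlinear least squares for $(\Delta f_t, \Delta\phi_t)$
minimising the windowed residual to the pointwise median spectrum (median
of real and imaginary parts separately — "median spectrum" is otherwise
ambiguous). The optimiser is seeded by a coarse scan over frequency with
the analytically optimal phase at each trial (the phase enters the
quadratic objective through a single cross term), then refined with
L-BFGS-B on $[-20, 20]$ Hz $\times$ $[-180°, 180°)$. A solution is
accepted only if it does not increase the objective of the uncorrected
transient; otherwise the transient is left untouched and flagged. The
reference median is computed once from the input ("one-shot"), not
iterated — with a majority of well-behaved transients the median is
already an excellent template, and iteration would make the estimator
data-dependent in a way that is hard to reason about. The default $^1$H
window, 1.6–3.6 ppm, brackets the NAA anchor at 2.02 ppm; X-nuclei
default to the full axis.

**Eddy-current correction** (`eddy_current_correct()`): the Klose scheme,
$s_{corr}(n) = s(n) e^{-i \arg \bar w(n)}$ with $\bar w$ the mean water
FID. Because metabolite and water acquisitions share the eddy-current
phase, the distortion cancels exactly — the test suite checks
cancellation to $10^{-8}$ relative. Water samples below machine precision
carry no phase; the last valid phase is held there.

**Outlier rejection** (`remove_bad_averages()`): transients are scored by
the RMS of their complex difference from the mean transient, in the time
domain, and dropped when the score exceeds
$\mu + k\,\sigma$ ($k = 3$ by default; the source material names no
threshold). A single pass is made — iterating to convergence would let
the threshold chase the shrinking variance and, on clean data, eventually
bite into the noise distribution. Order and content of survivors are
untouched, and the node refuses to empty the set.

**Apodization / zero filling / averaging**: multiplicative Lorentzian or
Gaussian envelopes calibrated as above (so Lorentzian widths add exactly
under convolution); zero filling appends exact zeros and is the
trigonometric interpolation of the spectrum (verified against direct DFT
evaluation); overall, blocked (with cyclic block-type assignment for
rest/active designs) and stride-1 moving averaging. All are linear and
commute with scalar multiplication — tested as properties.

**Quality metrics** (`quality_metrics()`): SNR is the real peak height of
the tallest resonance in the signal window (1.8–2.2 ppm for $^1$H) after
a local zero-order phasing of that peak, over the RMS of the linearly
detrended real part in the noise window (0.2–0.5 ppm). Detrending guards
the noise estimate against baseline tilt from neighbouring resonance
tails. The water linewidth is measured at half maximum with linear
interpolation between bins. One convention had to be fixed here: the
width is read off the *absorption-mode* (zero-order-phased real) profile,
because a noiseless Lorentzian of width $\gamma$ must measure $\gamma$ —
the magnitude profile of the same line is broader by $\sqrt 3$ and would
make the analytic calibration unusable. `measure_fwhm(on = "magnitude")`
retains the magnitude reading.

**3D Hanning filter** (`hanning_filter_3d()`): CSI k-space is multiplied
by the separable window
$H(j) = \tfrac12 (1 + \cos 2\pi (j - c)/(w-1))$, $c = \lfloor w/2
\rfloor$, anchored so the k-space centre sample has weight exactly 1
(integer-centre alignment for even sizes). Window dimensions must equal
the matrix dimensions — the node does not crop or pad, matching how the
filter is used in practice. The price of sidelobe suppression is a wider
spatial point-spread function; `csi_psf()`/`psf_fwhm()` quantify the
broadening (about $2.2\times$ for a $16 \times 16 \times 8$ grid).

**Entropy-minimization phasing** (`entropy_min_phase()`): zero- and
first-order phases minimising the Shannon entropy of the normalised
absolute derivative of the real part, plus a penalty
$\gamma \sum \min(\mathrm{Re}\,S_j, 0)^2$ on negative intensity. The
spectrum is scaled to unit maximum magnitude before the penalty, making
$\gamma$ scale-free; $\gamma = 1000$ is large enough that the penalty
vetoes the inverted (180°-rotated) solution, which has the same
derivative entropy. Optimisation is Nelder-Mead with multi-starts at
$\phi_0 \in \{0°, 90°, 180°, 270°\}$; the first-order pivot is the
carrier. On the synthetic $^{31}$P spectrum the estimator carries a small
(~1°) bias away from perfect absorption — the entropy term trades a sliver
of negative lobe for derivative sparsity — which is well inside the 2°
tolerance the recovery tests use, and identical in the grid-search oracle.

**Manual adjustment** (`manual_adjust()`): frequency offset applied as a
time-domain ramp, then zero/first-order phasing. Every call can append a
timestamped line to the run's adjustment log, so interactive fine-tuning
stays traceable next to the executed pipeline copy.

## Engine, presets and batch mode

Nodes implement a five-part plugin contract (metadata, parameter schema
with types/ranges/defaults, a `process` hook, an optional `plot` hook,
registration) and live in a registry; `load_custom_nodes()` sources
plugin files from one designated folder only — arbitrary script paths are
deliberately not importable. Pipelines serialize to `.pipe` files in
canonical JSON (sorted keys, schema-versioned), so save → load → save is
byte-identical and files diff cleanly under version control. Loading
validates node types and parameter ranges.

The engine executes a validated topological order. Although the graph
type admits DAGs, each node takes exactly one upstream and merge nodes
are rejected: every shipped workflow is a chain, and a merge semantics
(how to zip two payload streams) would be speculative. Averaging nodes
may fan one payload out into several (blocked/moving averaging);
downstream nodes then apply to each. Step mode only adds an inspection
callback — node determinism guarantees bit-identical results in both
modes, which is tested. Inputs are never mutated.

Five presets ship as both constructors and `.pipe` files: single-voxel
$^1$H (adaptive combination → alignment → eddy-current correction →
outlier rejection → averaging), functional MRS (blocked averaging
instead of overall averaging), single-voxel $^{31}$P (alignment →
averaging → entropy phasing), $^{31}$P CSI (3D Hanning + 5 Hz Gaussian
broadening), and GABA-edited MEGA data. MEGA sub-spectra combine by
direct averaging, so they run through the same chain as ordinary
single-voxel $^1$H; a difference-editing (ON−OFF) node is not shipped
and would be a natural custom node.

Batch mode (`make_batch_folder()` / `validate_batch_folder()` /
`run_batch()`) lays out a study tree (study-level control/basis files,
`PARTICIPANT_k/` folders with `_metabolite` and optional
`_water_reference` and tissue-probability files), validates it
report-style rather than failing fast, and applies one pipeline to every
runnable participant. Per-participant failures are caught and recorded as
one JSON line each (participant, node, message) while the rest continue;
a batch entry is bit-identical to the corresponding single run.

## Fitting interface and metabolite maps

LCModel is an external binary and is only *interfaced*: the processed FID
is written as `.RAW` (FORTRAN `(2E15.6)` pairs — scientific notation with
6-digit mantissa, so re-reading is exact to format precision), and the
control file is filled from a template with acquisition-derived keys
(`DELTAT`, `HZPPPM`, `NUNFIL`) and overrides. When no binary is
configured the run degrades gracefully, leaving RAW + control in place
for external fitting. Tissue-probability volumes give voxel fractions and
the water concentration
$\mathrm{WCONC} = 55510 \cdot (0.78 f_{GM} + 0.65 f_{WM} + 0.97
f_{CSF})/(f_{GM}+f_{WM}+f_{CSF})$ mM, following the usual tissue-water
convention. Relaxation attenuation is deliberately excluded — the factors
are field- and sequence-specific, and silently baking in one choice would
be worse than exposing the four constants for override.

`.COORD` outputs are parsed (concentration table with CRLB %SD and
ratios, the FWHM/S-N line, the four curve blocks) targeting the 6.3
layout with free-form column spacing; truncation errors list what was
recovered. Metabolite maps mask voxels at a strict `<` CRLB threshold —
"below the threshold" reads as exclusive, and strictness only matters on
the measure-zero boundary — requiring both the selected and the reference
metabolite to pass when a reference is set. Projection onto an anatomical
slice uses mask-aware bilinear interpolation (normalised convolution):
masked-out voxels are excluded from the support *before* interpolation,
so unreliable concentrations never bleed into displayed pixels, and
interpolated values stay within the input range. Masking after
interpolation would contaminate boundary pixels; if comparison against a
reference rendering ever requires the other order, it is a two-line
change localised in `project_to_anatomy()`.

## Numerical choices and degenerate inputs

* DFT: plain forward/inverse pair, exact to ~1e-15; round-trip tested.
* FWHM: linear interpolation between bins on both flanks; error raised if
  a crossing leaves the spectrum.
* Alignment: coarse grid 81 points over the $\pm 20$ Hz bound, then
  L-BFGS-B (`factr = 1e4`); acceptance is monotone (objective
  non-increase), so a failed refinement can never damage a transient.
* Entropy phasing: `reltol = 1e-10`, 2000 iterations per start, four
  starts; ties between starts resolve to the lowest objective.
* Eddy correction: water magnitudes below `.Machine$double.eps` times the
  maximum hold the last valid phase.
* Outlier scores with zero variance (identical transients) remove
  nothing; a rule that would empty the set is refused with a warning.
* Zero-signal channels combine with weight zero and a warning; an
  all-zero channel set is an error.
* NIfTI-MRS: complex128 on disk; the dwell time is written to `pixdim[4]`
  per the format but also carried in the JSON header extension at full
  double precision (the NIfTI header stores pixdim as float32).

## Known limitations

Vendor raw formats (Siemens `.dat`/`.rda`/`.ima`, Philips `.sdat`) are
not read — convert externally (e.g. spec2nii) to NIfTI-MRS. There is no
$B_0$-map handling, no HSVD water removal, no chemical-shift referencing
to external standards, and no LCModel re-implementation: fit quality is
entirely the external fitter's. The CSI path supports the k-space
filtering / image transform / per-voxel export workflow but not
nonrigid co-registration of maps to anatomy. Multi-echo and spectral
editing beyond direct averaging require custom nodes.
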