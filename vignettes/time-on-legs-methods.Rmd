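---
title: "Detecting time-on-legs from a necklace-worn hybrid sensor: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting time-on-legs from a necklace-worn hybrid sensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tolsense)
```

## The measurement problem

Older adults' daily activity is dominated by postural behaviour — sitting,
standing, short indoor walks, sit/stand transfers — rather than by the
vigorous locomotion that conventional activity monitors count. The
quantity of clinical interest is therefore *time-on-legs* (ToL): the total
time a person spends actively on their legs, comprising standing,
walking/shuffling, and the transfers between sitting and standing.

The instrument modelled here is a hybrid sensor worn as a necklace: a
tri-axial MEMS accelerometer (50 Hz, ±4 g) plus a barometric pressure
sensor (25 Hz). The two modalities are complementary. The accelerometer
carries orientation (gravity direction), movement intensity and gait
rhythm; the barometer sees the small but systematic pressure change when
the trunk rises or falls by roughly a seat height during a transfer
(≈ 0.45 m ≈ 0.053 hPa at the standard 8.43 m/hPa altimetry constant).

## The classification pipeline

### Signal conditioning

All detectors operate on de-noised signals. Low-pass filtering is
Butterworth, order 4, applied forwards and backwards so the output is not
delayed — essential because detector output is compared with annotations
second by second, and a filter group delay would systematically shift
every boundary. Three cut-offs are used (all configurable via
`tol_config()`):

| signal | cut-off | why |
|---|---|---|
| detection band (norm, step peaks) | 5 Hz | upper edge of voluntary trunk movement |
| gravity / orientation estimate | 0.25 Hz | orientation changes over seconds, steps must not leak in |
| barometric pressure | 1 Hz | pressure noise is broadband, transfers last 1.5–3 s |

The forward–backward pass zero-pads internally, which produces severe edge
transients on signals with a large baseline (pressure sits near
1013 hPa). `lowpass()` therefore filters the mean-removed signal with
odd-reflection padding and restores the mean afterwards; constants pass
through exactly and edge transients are reduced to the order of the local
signal variation.

Derived signals: the Euclidean norm of acceleration (≈ 1 g at rest in any
orientation); *intensity*, the moving standard deviation of the norm over
a centred 1 s window (the window mean removal eliminates the locally
constant gravity component, so intensity measures dynamic acceleration
only); *tilt*, the angle between the configured upright device axis and
the low-passed gravity vector (samples with gravity magnitude < 0.2 g are
flagged unreliable); and *relative altitude*,
$h_k = -(p_k - p_1)\cdot 8.43\ \mathrm{m/hPa}$.

### Detectors

**Active periods.** Maximal runs with intensity at or above an
experimental threshold (default 0.04 g), with sub-threshold gaps of up to
2 s merged and bouts shorter than 1 s discarded. The threshold sits about
twice the intensity noise floor of the detection band at the generator's
default noise level, and well below the intensity of walking or a
transfer.

**Sit/stand transfers.** Candidates are proposed where the altitude slope
(centred 1 s difference) exceeds 0.08 m/s, with three gates: the net
altitude change across the ramp must exceed 0.15 m (a seated-height
change, not barometric jitter), must not exceed 2 m (a staircase or
elevator, not a transfer), and the low-passed norm must show a transient
above 0.05 g inside the window (a pressure ramp without trunk
acceleration — lying down, ambient drift — is not a transfer). The
reported event interval is the 10–90 % crossing of the altitude ramp,
which tracks the true transfer duration rather than the smeared slope run.
Each candidate window (3.5 s, centred, shifted — never shrunk — at
recording edges) is summarized by five features: peak normalized
cross-correlation with a canonical 2.5 s biphasic transfer template,
peak–valley time difference, trunk orientation at the midpoint, intensity
in the second before and after the event, and the altitude change. A
linear-kernel SVM (see below) decides sit-to-stand / stand-to-sit / none.
Candidates whose event interval touches the first or last half second of
the recording are discarded: the flanking-intensity features are not
measurable there.

**Walking.** Step peaks in the baseline-removed norm above 0.08 g, grouped
into bouts wherever consecutive peak intervals stay within a plausible
cadence band (0.35–1.4 s); a bout requires at least 2 peaks, mirroring the
definition of walking as a minimum of two steps. The peak threshold was
chosen from two constraints fixed before any end-to-end evaluation: it
must lie below the weakest plausible step of a frail walker with a cane
(trunk step peak ≈ 0.2 g, reduced up to 40 % on the cane side ⇒ ≈ 0.12 g)
and several standard deviations above the detection-band noise floor
(≈ 0.02 g at the default noise level).

**Lying.** Tilt beyond 60° sustained for at least 10 s. The device's true
axis convention when worn as a necklace is unknowable in general, so lying
is defined relative to the *configured* upright axis rather than a
hardware z-axis; the 60°/10 s defaults separate recumbent postures from
bending or reaching, which exceed the angle only briefly.

### Fusion

Detector intervals are placed on a per-second grid by majority coverage
(a second carries a label if the detector's intervals cover at least half
of it). Seconds with multiple labels are corrected by descending priority:
sit/stand transfers, then walking, then lying — a second labeled both
sit-to-stand and walking becomes sit-to-stand. Seconds with only the
active flag remain *active*; empty seconds are *inactive*.

The context rules then relabel each maximal active/inactive run from its
flanks: to **standing** when the run succeeds a sit-to-stand transfer or
walking and precedes a stand-to-sit transfer or walking; to **sitting**
when it succeeds a stand-to-sit transfer and precedes a sit-to-stand
transfer or lying. Runs matching neither rule keep their label, and
un-labeled active runs still count toward ToL. Finally
$\mathrm{ToL} = \{\text{sit-to-stand, stand-to-sit, walking, standing,
active}\}$, and `tol_seconds` is the cardinality of that set in the label
series.

Three boundary conventions deserve note, since the underlying method
description leaves them open:

* *Recording boundaries.* A boundary may stand in for one missing flank
  (so a recording that starts mid-stand before walking, or ends seated
  after a stand-to-sit, is still relabeled), but never for both — an
  entirely unflanked active series stays active. Without the single-sided
  rule, every recording would begin and end with an unlabelable run.
* *Post-lying runs.* The sitting rule admits lying only as the *following*
  flank. A run that follows lying without an intervening transfer matches
  neither rule and stays active/inactive. This is the main category-level
  error source in free-movement simulations (a long sit after a lie-down
  remains "inactive"), and it is deliberate: inventing a post-lying rule
  would go beyond the described method, and the ToL total is unaffected
  because inactive and sitting are both off-legs.
* *Sub-second transfers.* Events are half-open intervals `[start, end)`
  and seconds are labeled by majority coverage with ties to the
  earlier-starting event; a transfer covering less than half of every
  second it touches can thus vanish from the grid. At the modelled
  transfer durations (1.5–3 s) this is rare.

### The transfer classifier

The SVM (linear kernel, cost 1, feature scaling on) is trained at package
run time on features *measured from synthesized snippets*, not drawn from
a parametric cartoon: isolated sit-to-stand and stand-to-sit events in
varying contexts (followed by quiet standing, embedded in walking, rising
from lying), and "none" examples covering quiet rest, walking without
transfers, and — importantly — reclining and sitting up, which change
altitude by a seat height without being sit/stand transfers. Profiles
alternate frail/non-frail and noise levels cycle through 0.01–0.05 g, so
the training distribution brackets what the detector sees. Training is
deterministic (fixed seed, recorded on the model object) and takes a few
seconds; a session cache avoids retraining. A deterministic fallback,
`transfer_threshold_model()` (altitude-change sign gated by template
correlation magnitude), is provided for audits and environments where a
margin classifier is unwanted.

### Validation statistics

Sensitivity, specificity and overall agreement are duration-based: for a
category $c$,
$\mathrm{Se}_c = 100\cdot |\{k: r_k = c \wedge p_k = c\}| / |\{k: r_k = c\}|$,
$\mathrm{Sp}_c = 100\cdot |\{k: r_k \ne c \wedge p_k \ne c\}| / |\{k: r_k \ne c\}|$,
and agreement is the fraction of seconds with identical labels. A metric
whose denominator is empty (category absent from the reference) is
reported as not-applicable — never 0, which would silently distort group
means. Grades follow right-closed cut-offs: ≤ 40 % insufficient, ≤ 60 %
moderate, ≤ 80 % good, > 80 % excellent.

For category-wise comparison both series are collapsed to the
video-annotation vocabulary (sitting, standing, walking, lying), with
transfer seconds assigned to the destination posture. The ToL row is
computed on the *uncollapsed* series, because transfers are on-legs time
by definition on both sides of the comparison; collapsing first would
count every stand-to-sit second as a ToL false positive even for a perfect
detector.

ICC(2,k) — two-way random effects, average measures — is computed directly
from ANOVA mean squares,
$\mathrm{ICC} = (MS_R - MS_E)/(MS_R + (MS_C - MS_E)/n)$ in the
absolute-agreement form. Whether the original reliability analysis used
absolute agreement or consistency is not stated; absolute agreement is the
default here (it penalizes systematic rater offsets, the conservative
choice for duration ratings) and the consistency form is available via
`type = "consistency"`. The group comparison uses the Welch t-test by
default — "independent samples t-test" does not specify the variance
assumption, and unequal variances are the safer default for groups of 7
and 13 — with the pooled form behind a flag.

## What the generator emulates — and what it does not

`make_profile()` draws a subject: GFI score (frail ⇔ GFI ≥ 4), cadence
(1.5–2.0 Hz non-frail, 1.0–1.4 Hz frail), trunk step-peak amplitude
(0.30–0.50 g vs 0.20–0.35 g), lateral sway, transfer duration (1.5–2.2 s
vs 2.2–3.0 s), a 0.45 m seat height, walking-aid use (all frail subjects;
2/13 of non-frail ones) with 20–40 % alternate-step asymmetry, and a
frail slowing factor applied to movement durations. These ranges are
documented fixtures chosen from general gait literature conventions, not
fitted values.

`script_standardized()` realizes the in-home assessment in order: 5 s of
standing, sitting down, timed up-and-go at slow/normal(×3)/fast pace, five
chair rises (modelled as five full up–down cycles ending seated), a single
stand-up, bending to pick something up (modelled as standing — the video
vocabulary has no bending category), bed lying with a turn, an optional
floor lie (non-frail profiles only), and a 10 m aided walk for aid users.
Turning during the up-and-go is modelled as walking. Short seated
instruction rests separate items. `script_free()` produces a semi-Markov
chain over sitting/standing/walking/short lying with dwell times much
longer than the standardized script; every sit↔stand boundary carries an
explicit transfer event, and the scripted time equals the requested
duration exactly (nominal 1800 s).

`synthesize()` turns a script into signals: a per-posture gravity vector
(lying tilts the trunk to 80–95°, with ~1.5 s smoothed re-orientation), a
cadence-locked train of 0.3 s raised-cosine step bumps with aid asymmetry
and sway during walking, the canonical biphasic transfer waveform (negated
for stand-to-sit) plus a transient 20° forward lean during transfers,
white accelerometer noise, and a pressure channel whose baseline follows
necklace height (0 standing, −0.45 m seated, −0.9 m lying, smoothly ramped
through transfers) plus slow drift and noise scaling with the
accelerometer noise level. The ground-truth annotation collapses the
script to the four-category video vocabulary.

The generator is deliberately phenomenological. It does **not** model:
necklace sliding when lying down (a major real-world error source for
short lying bouts), soft-tissue and clothing artefacts, ambient pressure
weather fronts or ventilation gusts, bending or reaching transients,
bicycling, stair climbing (altitude changes beyond 2 m are explicitly
rejected by the transfer detector), or inter-device calibration error.
Passing the simulation-based tests therefore demonstrates the *internal
consistency* of detectors, fusion and metrics under controlled conditions
— not field validity on clinical recordings, which is knowable only with
real video-annotated data.

## Numerical and testing choices

* Intervals are half-open `[start, end)` everywhere; seconds align to
  integer boundaries from recording start; video and sensor clocks are
  assumed to share a zero, with a configurable offset
  (`clock_offset_s`, `read_annotations(offset_s =)`) for known
  desynchronization.
* The moving standard deviation uses cumulative sums with shrinking edge
  windows (length-preserving); negative variances from cancellation are
  clamped at zero.
* Template cross-correlation scans all lags of the 2.5 s template inside
  the 3.5 s window and returns the signed correlation at the lag of
  maximum magnitude; a flat segment (zero variance) contributes 0.
* Degenerate statistics fail loudly or report not-applicable: ICC on a
  constant matrix is an error, t-tests on identical constant groups return
  t = 0, p = 1, metrics with empty denominators return `NA`.
* Problem sizes in the test-suite simulations: 10 zero-noise standardized
  recordings for end-to-end recovery, 20 seeds × 3 noise levels
  (0, 0.05, 0.15 g) for the monotone-degradation check, and 1000 random
  label-series pairs for metric/oracle equivalence. The acceptance script
  simulates the full study layout: 20 subjects (7 frail, 13 non-frail),
  standardized plus 1800 s free-movement sessions at the default 0.05 g
  noise.

## Known limitations

The per-category statistics of a simulated study are upper bounds: the
generator and the detectors share their signal phenomenology (the transfer
template, the step model), which is precisely what makes the pipeline
testable, but real recordings add the unmodelled effects listed above.
The post-lying context gap and the absence of a bending category are
structural, shared with the described method. Walking detection inherits
the fundamental difficulty of frail, aided gait: weak asymmetric step
peaks close to the noise floor, mitigated but not removed by the
peak-threshold choice.
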