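---
title: "Automatic time-shift alignment of chromatographic fingerprints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic time-shift alignment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atsalign)
```

## The problem

Chromatographic fingerprints of nominally identical samples drift along
the retention axis: column ageing, temperature-programme variation and
mobile-phase fluctuations displace peaks by amounts that differ between
runs and, within a run, between elution regions. For quality control of
complex extracts (essential oils, metabolic profiles) the fingerprints
are compared sample-wise — usually by the Pearson correlation of whole
signals — and uncorrected shifts of a fraction of a minute are enough to
push genuinely equivalent samples below conventional similarity
thresholds. `atsalign` implements an automatic time-shift alignment
(ATSA) pipeline for uniformly sampled one-dimensional chromatograms: a
samples-by-channels matrix in, an aligned matrix of identical dimensions
plus per-segment diagnostics out, with `atsa()` as the single fitting
entry point.

The pipeline has three stages.

1. **Baseline correction and peak detection.** Baseline drift is
   estimated from local minimum values (LMVs), robustly filtered, and
   interpolated; peaks are detected by multi-scale Gaussian smoothing
   with ridge-line persistence.
2. **Preliminary alignment.** The reference chromatogram — the sample
   with the highest mean correlation to all others — is partitioned into
   segments of roughly 3 min holding at least three peaks each. Each
   segment is displaced as a rigid block by the integer channel shift
   that maximises the *total peak correlation* (TPC) over candidate
   shifts generated by peak-to-peak matching. Segment shifts are screened
   with a scaled-MAD outlier rule and repaired; boundary gaps/overlaps
   are resolved and each piece is warped back onto the reference grid by
   linear interpolation.
3. **Precise alignment.** The preliminarily aligned signal is cut into
   one sub-segment per peak; each sub-segment is displaced so its apex
   lands exactly on the nearest reference peak apex eluting within the
   test peak's range, unmatched sub-segments borrow the mean shift of
   their matched neighbours, and the two halves of every sub-segment are
   warped independently about the apex.

A classic correlation optimized warping (COW) implementation
(`cow_align()`) is included as a benchmarking baseline, and
`synth_generate()` produces ground-truth synthetic studies for
validation.

## The alignment criterion

For equal-length windows $r$ (reference) and $x$ (test) the Pearson
coefficient is

$$c = \frac{(r-\bar r)^T(x-\bar x)}
          {\sqrt{(r-\bar r)^T(r-\bar r)\,(x-\bar x)^T(x-\bar x)}}.$$

Raw $c$ over a whole segment is dominated by the largest intensities: if
an intense peak is present in only one of the two segments, the
$c$-maximal shift aligns that peak with whatever large feature it can
find and sacrifices every small peak (the package's
`fig_dominant_peak_scenario()` constructs exactly this failure case, and
the acceptance suite shows the misbehaviour across 20 seeds).

ATSA instead scores a candidate segment shift $s$ by the total peak
correlation

$$\mathrm{TPC}(s) = \frac{\sum_{i=1}^{I} w_i\,c_i(s)}{\sum_{i=1}^{I} w_i}
                    \cdot \frac{I}{N},
\qquad w_i = \frac{\mathrm{PeakArea}_i}{\mathrm{PeakLength}_i},$$

where $N$ is the number of reference peaks in the segment and $I$ the
number *matched*: reference peak $i$ is matched when some test-peak apex
lies inside its elution range displaced by $s$. For a matched peak,
$c_i(s)$ is the correlation between the reference peak's window and the
test signal over the same window displaced by $s$, so residual
misalignment inside the segment lowers the score; unmatched peaks are
reported with $c_i = -1$ as a per-peak diagnostic and penalise the score
through the $I/N$ factor only, and $\mathrm{TPC} = -1$ when nothing
matches. Weighting by area-per-channel lets every real peak count while
still trusting well-quantified mass the most.

Candidate shifts are not scanned exhaustively: following the
peak-to-peak strategy, the apex of the segment's largest reference peak
is aligned in turn with each test apex inside the search window, and
candidates that would push the displaced segment outside the window are
discarded (the no-shift fallback 0 is always kept). Ties in TPC go to
the smaller |shift|, then the smaller shift — minimal intervention.

## Robust repair of misaligned segments

With per-segment shifts $s_1,\dots,s_J$, the scale
$\sigma = 1.483\,\mathrm{median}_i\,|s_i - \mathrm{median}_j(s_j)|$ and
scores $d_k = |s_k - \mathrm{median}_j(s_j)|/\sigma$ flag segment $k$ as
misaligned when $d_k > 2.5$ (about the 99% level for normal scatter;
$d_k$ exactly 2.5 is not flagged, and $\sigma = 0$ flags nothing). A
flagged segment is re-aligned by plain correlation: $c$ is evaluated at
every integer shift within $\pm\lceil 2.5\sigma\rceil$ of the median,
and among the *interior* local maxima of that curve the one closest to
the median wins.

Two guards, both this package's own choices where the procedure's source
is silent, matter in practice:

* a window **edge** on a still-rising curve is not a local maximum — it
  points to an optimum outside the window, so the segment keeps its
  original TPC shift when the window holds no interior maximum;
* a repair is accepted only if its correlation is at least that of the
  shift it replaces.

Without them, samples whose shift trends monotonically across the run —
ordinary accumulating drift — have their correctly aligned early
segments flagged (their shifts sit far from the whole-run median) and
dragged tens of channels toward the median, which is precisely the
failure the repair stage exists to prevent.

## Boundaries, warping and bookkeeping

After shifting, neighbouring segments disconnect or overlap. Every
junction is placed at the half-up rounded average of the former
segment's end and the latter segment's start (a disconnection of
14833/14839 resolves to 14836). For overlaps the junction additionally
records which side the rule considers modified: if a test-peak *end*
lies nearer the overlap middle than any peak *start*, the later
segment's start; in the converse case the former segment's end;
otherwise both. Each test piece between junctions is then linearly
interpolated onto the corresponding reference extent with endpoints
fixed, and test peak channels are remapped through the same
piecewise-linear map. Terminal segments whose ideal source extends past
the recorded axis replicate the edge channel rather than stretching the
whole piece, so a shifted first or last segment is translated, not
smeared. The outer warp bounds of the terminal segments are extended to
the axis ends, but the shift search uses the peak-bearing core extent —
otherwise a segment starting at channel 0 could never move left.

The precise stage reuses the same machinery at per-peak granularity:
sub-segment boundaries are the rounded averages of successive peak ends
and starts, displaced junctions are averaged (clamped so every displaced
apex keeps at least one channel on each side), and the left and right
halves of each sub-segment are warped independently so the apex value is
preserved exactly at its new position. Peaks carry stable identifiers
assigned at detection, so original and aligned areas pair unambiguously
in the RD% report.

## Baseline and peak detection choices

The LMV filter compares each interior anchor against the straight line
joining its two surviving neighbours (a leave-one-out residual — the
residual against the interpolant through *all* anchors is identically
zero), removes anchors whose residual exceeds `z_cut = 2.5` robust
standard deviations (`1.483 * MAD`), one-sidedly: only upward-elevated
minima ride on peaks, while downward excursions are legitimate baseline.
Iteration stops when nothing is removed or the MAD collapses. Endpoints
are always anchors so the interpolated baseline covers the axis.

Peak detection smooths at sigmas {1, 2, 3, 5, 8, 12, 16} channels, links
per-scale maxima into ridges (position tolerance = current sigma, one
missing scale tolerated) and keeps ridges spanning at least 3 scales.
The apex SNR is evaluated on the smallest-scale smoothed signal — a real
peak keeps its amplitude there while white-noise excursions are already
attenuated by about half — against the noise level
`1.483 * MAD(diff(signal)) / sqrt(2)`, with `snr_min = 3` by default.
Elution bounds are the flanking minima of the smallest-scale smoothed
signal (every channel of a plateau counts, so bounds hug the peak), and
overlapping bounds of neighbouring peaks are trimmed to the inter-apex
valley. Bounds of well-separated peaks may touch on a flat valley; only
apexes are required to be strictly increasing.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `segment_min` | 3.0 | min | initial segment size; 1–10 min give nearly identical correlations, smaller values make more segments |
| `shift_min` | 0.5 | min | pre-estimated maximal shift; any value at or above the true maximal shift gives identical output, larger values only cost time |
| `z_cut` | 2.5 | robust z | baseline anchor filter |
| `outlier_threshold` | 2.5 | robust d | segment-shift repair trigger |
| `scales` | 1–16 | channels | smoothing sigmas; resolve peaks >= 3 channels wide |
| `min_ridge_len` | 3 | scales | ridge persistence floor |
| `snr_min` | 3 | — | apex signal-to-noise floor |

## The synthetic study generator

`synth_spec()` defaults describe the study scale this package targets:
62 samples of 23,000 channels at 0.01 min/channel, 220 peaks with
log-uniform heights 20–2000 (unit noise, so minimum SNR 20), Gaussian
sigma 0.03–0.08 min, 30% of peaks carrying an exponential tail of 0.02
min, quadratic per-sample baseline drift of 50 units, and
piecewise-constant integer-channel shifts over roughly 3-min regions
following a per-sample random walk (first region sd 15 channels,
increments sd 3, hard bound 0.4 min). Sample 1 is generated with zero
shift as a run-sequence anchor. Design rationale for the choices the
study description leaves open:

* **Shift breakpoints sit in inter-peak gaps.** A physical retention
  shift displaces whole peaks; it cannot tear one apart. Nominal 3-min
  breakpoints are therefore snapped to the nearest midpoint between
  consecutive peaks.
* **Shifts are integer channels and drift slowly.** Instrument drift
  accumulates over a run, so adjacent regions differ by a few channels
  rather than jumping independently; integer shifts reflect that a
  uniformly resampled detector cannot represent sub-channel
  displacement, and they make ground-truth recovery exactly scorable.
* **Peaks are adequately sampled and resolved.** Sigmas of 3–8 channels
  keep at least ~7 channels per FWHM — any practitioner runs the
  detector fast enough for this — and a minimum apex spacing of
  max(0.2 min, 6·sigma_max) keeps neighbouring peaks chromatographically
  resolved, which ground-truth identity scoring requires.

What the generator deliberately does **not** emulate: co-eluting
compounds and shoulder peaks, detector saturation, heteroscedastic
(intensity-dependent) noise, sub-channel shifts, and shift profiles that
change *within* a peak. Passing tests therefore demonstrate correct
behaviour on resolved, well-sampled fingerprints with region-wise rigid
shifts; they do not certify deconvolution of merged peaks or alignment
under saturating detectors.

## Numerical conventions

* Elution channels are 0-based; sample indices are 1-based (R
  convention). Channel `k` elutes at `start_time + k * sampling_interval`
  minutes.
* Peak elution ranges are inclusive, `PeakLength = end - start + 1`.
* Boundary averages round half **up**; imputed shifts round half **away
  from zero**.
* Pearson correlation of a constant window is defined as 0 (flagged);
  COW counts such segments as zero benefit.
* Degenerate sub-segments (no room to anchor an apex) fall back to a
  single-part warp of the piece.
* All stages are deterministic given their inputs; only the synthetic
  generator consumes a seed.

## Validation problem sizes

The unit suite works at 6 samples x 4000 channels (about 35 peaks); the
end-to-end acceptance checks run one full-scale study of 62 samples x
23,000 channels with ~220 peaks (about half a minute for generation plus
alignment on one CPU). On that study the pipeline lifts the median
correlation to the reference from ~0.42 to ~0.999, recovers every
regional shift estimable from at least three matched peaks to within 2
channels, and keeps 100% of peak areas (SNR >= 10) within 7% relative
deviation. Regional shifts carried by fewer than three peaks are not
scored — the same estimability floor the segment partition imposes.

## Known limitations

* Rigid per-segment shifts cannot follow a shift gradient *inside* a
  segment; the precise stage absorbs the per-peak residue, but only for
  detected peaks — unpeaked baseline stretches between junctions are
  interpolated.
* Matching is apex-in-range: two co-eluting test peaks inside one
  displaced reference range resolve to the nearer apex, which can pair
  wrongly for heavily overlapped doublets.
* The outlier rule assumes segment shifts scatter around one centre;
  strongly trending runs rely on the repair guards described above.
* COW is provided at its classic formulation (fixed segment grid,
  per-boundary slack, correlation benefit) without the automatic
  parameter optimisation grids some implementations add.
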