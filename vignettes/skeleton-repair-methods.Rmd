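---
title: "Methods: skeleton repair and REBA scoring for 2D pose sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skeleton repair and REBA scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

A 2D pose detector reports, per video frame, 25 keypoints (BODY_25
numbering) with pixel coordinates and a confidence. During caregiving
tasks two bodies overlap, and the detector produces two failure modes with
different signatures: *missing* keypoints (absent detections, encoded as
confidence 0 and coordinates (0, 0)) and *misidentified* keypoints (a
detection assigned to the wrong person or limb, which violates the
caregiver's skeletal geometry while looking like a confident detection).

The geometric invariant this package exploits is that bone lengths are
constant. Write the 24 tree links of the BODY_25 skeleton as columns of a
2 × 24 link matrix $K$ (column $j$ = child minus parent of link $j$, in a
fixed, versioned order). The Gram matrix $\Psi = K^\top K$ has squared
bone lengths on its diagonal and pairwise bone dot products off it, and is
invariant to any rigid transform of the keypoints. The temporal kinematic
chain

$$\Phi = K_{t+i}^\top K_{t+i} - K_t^\top K_t$$

is therefore zero under rigid motion and, because articulated motion
preserves lengths (though not dot products), its *diagonal* is zero under
any legitimate motion. A nonzero diagonal entry means a bone changed
length — the misidentification signal. A keypoint pulled to the other
person stretches or shrinks its bone: scaling a bone by $1+m$ shifts the
corresponding diagonal entry by $((1+m)^2 - 1)\,\ell^2$, i.e. a relative
change of 1.25 at $m = 0.5$, far above noise.

## Frame discrimination

`classify_sequence()` assigns each frame one of three statuses, with
*missing* taking precedence (any absent keypoint). For non-missing frames
two evidence channels are combined (disjunctively by default; a
conjunctive `policy = "both"` is available):

* **Bone anomaly.** The per-link relative change of squared bone length,
  $\max_j |\Phi_{jj}| / \max(\Psi_{jj}, \text{floor}^2)$, thresholded at
  $\tau = 0.2$ and required to persist for 2 consecutive frames.
* **Action heterogeneity.** An action classifier supplies per-frame label
  weights. Within a ±10-frame window the modal argmax label is *dominant*
  when its share strictly exceeds 60%; a frame whose own label differs
  from an existing dominant label is heterogeneous.

Two numerical choices deserve explanation. First, the *length floor* (50
px): for short bones (facial links ~18 px, shoulder links ~40 px) the
relative statistic is noise-dominated — with σ = 1.5 px of coordinate
noise the squared-length jitter of a 40 px bone is a ~10–20% relative
change, indistinguishable from a real anomaly. Dividing by
$\max(\Psi_{jj}, 50^2)$ converts the test on short bones into an absolute
test at the detection limit, while long bones (trunk 150 px, limbs 70–110
px) keep the pure relative test. Second, the *reference profile*: the
sequence scan compares each frame against the per-link **median** squared
length over the sequence rather than chaining frame-to-frame. Bone
lengths are constant by premise, so the median is the canonical $\Psi$
reference, robust up to ~50% corrupted frames. We first implemented the
frame-chaining variant (each frame against the last anomaly-free frame);
it fails in a characteristic way: a single noise-outlier frame gets
promoted to reference and every subsequent ordinary frame flags against
it, producing false-alarm runs that the persistence filter cannot remove.
The pairwise operation `phi_anomaly()` retains the two-frame definition
exactly.

## Compensation

Missing keypoints are repaired per keypoint: the nearest frames where that
keypoint was actually observed, at most 10 frames away on each side, serve
as anchors $(x_s, y_s)$, $(x_e, y_e)$, and the gap of $n$ frames is filled
by linear interpolation, $x_i = (1-t)x_s + t x_e$ with $t = i/(n+1)$ —
exact when velocity is constant within the gap, which is the modeling
assumption at 50 Hz with a 10-frame span. Only originally observed points
are ever used as anchors; synthesized points carry a sentinel confidence
of 0.5 so downstream consumers can tell measured from inferred
coordinates. Gaps without an anchor on both sides within the span remain
missing and are reported as residual rates; an optional hold-nearest
extrapolation at sequence boundaries was considered and rejected (only
two-sided interpolation has the exactness guarantee).

The spec's two anchor examples are mutually inconsistent (one implies
`n = 2` for anchors 3 and 8, the other `n = end - start - 1`); we follow
the gap-length reading, which the interpolation formula requires.

## Correction and smoothing

A misidentified frame is corrected by *dominant-action replacement*: its
label is rewritten to the window's dominant label, and the keypoints
implicated by the bone anomaly (the flagged links' distal subtrees —a
displaced limb moves rigidly) are re-synthesized by interpolation between
the nearest complete frames of the dominant action. Frames without a
dominant action (≤ 60%) or without same-label anchors are recorded
uncorrectable and left unchanged. How the skeleton is rebuilt after
feature replacement was genuinely open; interpolation between
dominant-action anchors reuses the compensation machinery and is minimally
invasive (untouched keypoints are preserved exactly).

All trajectories are then smoothed by a scalar Kalman filter per
coordinate (predict $x^- = A\hat x + Bu$, $P^- = APA + Q$; gain
$K = P^-C/(CP^-C + R)$; update $\hat x = x^- + K(y - Cx^-)$,
$P = (1-KC)P^-$) with the constant-state model $A = C = 1$, $B = 0$:
adjacent time steps share the same characteristics at 50 Hz, and each
keypoint coordinate is filtered independently. Defaults $Q = 10^{-3}$,
$R = 10^{-2}$ px² give an asymptotic gain ≈ 0.27 (a ~3-frame time
constant): strong enough to remove most of the σ = 1.5 px detector
jitter, short enough that lag error is negligible at caregiving motion
speeds. `x0` defaults to the first measurement so there is no transient.
Absent keypoints are skipped, not interpolated by the filter.

## The action classifier

The pipeline consumes only normalized per-frame weight vectors, so any
producer can stand behind the interface. Two are provided:

* `mock_classify()` — one-hot weights from a scripted label sequence with
  a seeded flip probability; the deterministic plumbing used by most
  tests. Every pipeline stage must work with it alone.
* `stgcn_train()` / `stgcn_classify()` — a miniature spatial-temporal
  graph convolutional network: two spatial graph-convolution blocks with
  residual connections ($\hat A X W$, $\hat A$ the symmetrically
  normalized BODY_25 adjacency with self loops), two spatial–temporal
  blocks (graph conv + temporal conv, kernel 9) chained by dense
  concatenation, mean-pooled over keypoints into a per-frame softmax.
  Hidden width 32, Adam on cross-entropy, manual backpropagation in base
  R. This is the smallest structure exhibiting the stated topology and is
  CPU-trainable in seconds at desk scale. Batch normalization is replaced
  by input standardization (keypoints centered on MidHip, scaled by trunk
  length): stateful normalization layers add no value at this scale.
  Inputs shorter than the receptive field are replicate-edge padded.

## The synthetic world

`generate_sequence()` animates a fixed figure (bone lengths 12–150 px) by
forward kinematics from smooth per-action joint-angle trajectories
(raised-cosine sweeps from a neutral stance: "bend" sweeps the trunk to
55°, "lift" the arms to 85°, etc.) at 50 Hz, then adds Gaussian pixel
noise (default σ = 1.5 px, a typical detector jitter magnitude). Because
poses come from forward kinematics, constant bone length — the premise of
the Φ diagnostic — holds *by construction*, and the noise-free sequence
doubles as ground truth (the role inertial sensors play against real
video).

Corruption is injected with retained truth: `inject_missing()` blanks
whole joint groups in 5-frame bursts placed in disjoint blocks (realized
rate = target up to block rounding); `inject_misidentification()` scales
an arm or thigh bone by $1+m$ *and rotates it* (25°, or 60° in the
second-figure-swap mode), moving the distal subtree rigidly. The rotation
matters: a pure radial stretch leaves every joint angle unchanged (the
subtree translates along the bone line), which would make angle-repair
evaluation vacuous; rotation preserves the $(1+m)^2 - 1$ length signal.

What a green test does **not** establish: the generator has no occlusion
structure correlated with posture, no second articulated person, no
perspective or lens effects, and its noise is i.i.d. Gaussian rather than
detector-structured. Results on it validate the machinery (detection
operating point, exactness and monotonicity properties, end-to-end
improvement), not field performance on real nursing video, which would
require the original recordings and sensor ground truth.

## Defaults

| parameter | default | meaning |
|---|---|---|
| `conf_min` | 0.1 | absence threshold on confidence |
| `tau` | 0.2 | relative squared-bone-length anomaly threshold |
| `persistence` | 2 frames | consecutive anomalies required |
| `len_floor_px` | 50 px | bone-length floor in the anomaly ratio |
| `span` | 10 frames | traversal bound per side (anchors, windows) |
| `dominance` | 0.6 (strict) | dominant-action share |
| `Q`, `R` | 1e-3, 1e-2 px² | Kalman process / measurement noise |
| `conf_sentinel` | 0.5 | confidence of synthesized keypoints |
| fixture | 2000 frames, 2 labels, σ 1.5 px, 10% missing (bursts of 5), 5% misidentification (m = 0.5, 4 frames), confusion 0.02 | default synthetic world |

## Known limitations

* 2D only; flexion/extension are not distinguishable without a facing
  direction, so angle bins use magnitudes (REBA rotation/abduction
  modifiers are manual config flags, as in practice).
* The discriminator assumes constant bone lengths; slow scale drift
  (camera zoom) would need a windowed reference.
* Correction requires a dominant action and same-label anchors inside the
  window; dense label transitions leave frames uncorrectable (recorded,
  not repaired).
* Residual missing: gaps wider than the 10-frame span stay missing by
  design; widening the span trades exactness for coverage.
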