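---
title: "Detecting interictal spike clusters and delineating the irritative zone in MEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting interictal spike clusters and delineating the irritative zone in MEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megspike)
```

## The problem

In medically refractory focal epilepsy, the *irritative zone* (IZ) — the
cortical territory generating interictal epileptiform discharges (spikes and
sharp waves) — is a key landmark for presurgical evaluation.
Magnetoencephalography records these discharges non-invasively over a few
hundred sensors, but the conventional workflow relies on experts visually
scanning tens of minutes of multichannel data, which is slow and biased
towards the most conspicuous events. `megspike` implements a fully automated
two-stage alternative and the geometry needed to validate it against a
surgical resection.

## The model

A repeating interictal discharge from a single cortical patch produces, at
the sensors, a *rank-1 spatiotemporal pattern*: a fixed spatial topography
$u \in \mathbb{R}^{C}$ (how the source projects to the $C$ sensors)
multiplied by a stereotyped waveform $v \in \mathbb{R}^{L}$. Over a
recording, the pattern recurs at sparse times with non-negative amplitudes.
Stage II therefore fits a rank-1 multivariate convolutional dictionary: for
epochs $X^n \in \mathbb{R}^{C \times T}$,

$$
\min_{u_k, v_k, z_k^n}\; \sum_{n=1}^{N} \frac{1}{2}
\Bigl\lVert X^n - \sum_{k=1}^{K} z_k^n * (u_k v_k^\top) \Bigr\rVert_2^2
+ \lambda \sum_{k=1}^{K} \lVert z_k^n \rVert_1,
\qquad
\lVert u_k \rVert_2^2 \le 1,\; \lVert v_k \rVert_2^2 \le 1,\; z_k^n \ge 0,
$$

with $K = 3$ atoms per run, atom duration $0.5$ s and $\lambda = 0.1$.
Each learned atom defines one *cluster* of spikes; its activation vector
$z$ says when and how strongly the pattern occurred.

Because dictionary learning over a full recording is expensive and easily
distracted by artifacts, a cheap Stage I first proposes candidate events:
the 2–90 Hz data (resampled to 200 Hz) are decomposed by FastICA into 20
components; among the 10 components with most explained variance, those
with a "peaky" time course (excess kurtosis in $[1, 10]$) *and* a dipolar
topography (MUSIC goodness of fit at least 0.60 for gradiometers, 0.80 for
magnetometers) are kept, a dipolarity above 0.95 overriding the kurtosis
test. Peaks of the rectified, robustly scaled (median/IQR) 20–90 Hz
component time courses are detected with a threshold that steps down a
fixed grid until at least 300 peaks are found; each peak is re-scored by a
single-dipole MUSIC scan of the $-20$ to $+30$ ms sensor window, and a
greedy sweep keeps only the best-scoring event within any 0.5 s interval.
Stage II runs on 1 s epochs centred on the surviving timestamps — the
sparse coding is used purely as a spatiotemporal clustering device.

The procedure iterates four times: run 1 uses all selected components;
the selected components' absolute, unit-normalized topographies are
k-means clustered into three groups and runs 2–4 restrict peak detection
to one group each, forcing the dictionary to organize around different
event subsets. With 3 atoms per run this yields 12 candidate atoms per
sensor type. Every candidate is scored by the average of three 0–1
features — dipolarity of $u$, mean correlation of $v$ with the assigned
epochs at the dominant channel, and cluster population
$\min(n_{\text{events}}/20, 1)$ — and candidates above the mean + 1 SD of
the pooled score distribution enter the library (an exclusion list can
emulate the visual review step).

Cluster averages are localized by minimum-norm estimation with a diagonal
noise covariance (per-channel variance of the $\pm 0.5$ s averaged
window), at two latencies: the global-field-power peak (PEAK) and the
first sample at or above 50% of the peak GFP on the ascending branch
(SLOPE). Each map is binarized at 50% of its maximum; vertices pointed to
by more than half of the atoms (strict majority) are kept and dilated by
10 mm. Validation converts the resected area to a convex hull and reports
the mean signed Euclidean distance of the IZ vertices to the hull surface,
negative inside.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_ica`, `n_ica_ranked` | 20, 10 | components extracted / eligible |
| `kurtosis_range` | [1, 10] | closed acceptance band, excess kurtosis |
| `gof_threshold_grad/mag` | 0.60 / 0.80 | MUSIC dipolarity thresholds |
| `gof_override` | 0.95 | dipolarity that bypasses kurtosis |
| `peak_band` | 20–90 Hz | band for component peak detection |
| `min_peaks`, `peak_grid` | 300, 8…2 | adaptive threshold schedule |
| `refractory` | 0.5 s | minimum interspike interval |
| `atom_len`, `lambda_reg` | 0.5 s, 0.1 | atom duration, l1 weight |
| `mad_grid`, `min_events` | 7…1.5, 15 | MAD threshold schedule |
| `binarize_frac`, `smooth_mm` | 0.5, 10 mm | map binarization and dilation |
| `resection_margin_mm` | 3 mm | margin when masking the resection |
| `lambda2` | 1/9 | minimum-norm regularization (SNR = 3) |

## Numerical and design choices

Several details are open in the procedure as usually described; the
package fixes them as follows and treats them as its own design choices.

* **Kurtosis** is excess (Fisher) kurtosis; the band $[1, 10]$ is applied
  as a closed interval and values above 10 are rejected as artifactual
  unless the dipolarity override applies.
* **Peak detection** operates on the absolute scaled signal, because the
  sign of an ICA component is arbitrary. The threshold grid is
  $\{8, 7, 6, 5, 4, 3, 2.5, 2\}$ in robust-scaled units; only the
  stopping rule ("at least 300 peaks") is prescribed, the grid is ours.
* **Refractory pruning** processes candidates in descending goodness of
  fit and suppresses any unselected event within 0.5 s of a kept one —
  this realizes "the largest GOF per 0.5 s window" without having to fix
  a window phase, and guarantees all pairwise separations exceed 0.5 s.
* **MUSIC** uses a one-dimensional signal subspace (single-dipole
  assumption) both for topographies and for event windows; with free
  orientations the vertex gain is the orthonormalized span of its three
  leadfield columns, and the goodness of fit is the squared cosine of the
  principal angle.
* **The sparse-coding solver** standardizes the epoch tensor by its
  global standard deviation and interprets $\lambda = 0.1$ as a fraction
  of $\lambda_{\max}$ — the smallest weight that zeroes every activation
  — which is the scale-free convention of convolutional dictionary
  learning; $u$, $v$ and the (MAD-relative) event assignment are
  invariant to both choices. The z-step is per-epoch coordinate descent
  on the non-negative convolutional lasso with a banded Gram (compiled);
  the $(u, v)$-step solves each atom's ball-constrained least-squares
  problem exactly (the $u$ Hessian is proportional to the identity, so
  projection is exact; $v$ uses a trust-region bisection on the Tikhonov
  multiplier). Every block update minimizes a convex subproblem, so the
  objective is non-increasing across outer iterations; we stop after 40
  iterations or a relative change below $10^{-5}$. Atoms are initialized
  from a seeded pool of epochs' best-channel windows, chosen greedily for
  spatially diverse peak-time snapshots so the $K$ atoms do not all start
  on the dominant source, with the window peak placed at a canonical
  position ($L/5$) so early activation latencies stay representable; a
  recentering step keeps the waveform there whenever shifting does not
  hurt the objective (waveform/activation time shifts are a gauge freedom
  of convolutional models). Signs are fixed so the dominant sample of $v$
  is positive.
* **The MAD scale** of an activation vector needs care: $z$ is sparse, so
  the textbook MAD (of all entries, or even of the non-zero pool) can be
  exactly zero on clustered activations. The package uses the MAD
  (constant 1) of the pooled non-zero activations, falls back to their
  mean absolute deviation about the median when that is zero, and treats
  a zero scale as "every positive activation passes". Event timestamps
  are shifted to the activation latency plus the atom's sharp-peak offset
  ($\arg\max |v|$), so assigned events align at the spike peak.
* **SLOPE** is operationalized on the ascending branch of the global
  field power: the first sample at or above 50% of the peak GFP (i.e.
  one past the last strictly-below-half sample). The qualitative
  "distinct focus" reading requires a human; the 50% rule is
  deterministic and testable, and `atom_iz_map()` accepts any explicit
  latency for a diagnostic sweep from take-off to peak.
* **Voting strictness** follows the wording: atom maps require a strict
  majority (count $> n/2$), per-spike visual maps keep vertices in at
  least half (count $\ge n/2$) of the maps.
* **Smoothing** is binary dilation by a 10 mm Euclidean radius on vertex
  coordinates, not geodesic distance along the cortical sheet — adequate
  for point-cloud source spaces; a geodesic variant would need a mesh.
* **The convex hull** is built by an incremental algorithm with outward
  unit normals; signed distance is the minimum over facet triangles
  (projection with barycentric classification, falling back to clamped
  edge distances), negated when every half-space test passes. A
  KKT-case point-to-triangle oracle checks it to $10^{-9}$ in the tests.
* **Wilcoxon comparisons** between estimate types drop zero differences,
  then enumerate the exact signed-rank null over all sign assignments for
  up to 15 informative pairs (average ranks make this valid under ties,
  where the standard exact routine refuses); identical vectors give
  $p = 1$ by convention.

## What the synthetic data emulate — and what they do not

`simulate_forward()` builds a hemispheric source shell (radius 80 mm) and
a sensor cap (110 mm) with smooth tangential-dipole field patterns from
the Biot–Savart leading term; columns of nearby vertices are similar but
distinguishable. `simulate_recording()` plants rank-1 spike sources —
unit-normalized leadfield columns times a skewed biphasic
derivative-of-Gaussian waveform (sharp deflection plus a slower opposite
wave, 70–200 ms) — at Poisson event times thinned to a 0.5 s minimum
separation, on top of per-channel 1/f Gaussian noise. The signal-to-noise
ratio is defined at the single best channel (peak spike amplitude over
noise RMS), because Stage I detects on ICA components dominated by that
channel's pattern. All randomness flows from one integer seed, and the
same seed reproduces the recording bit for bit.

These fixtures exercise every stage of the pipeline, but they are not
patient data: there is no physiological background (alpha rhythm,
cardiac/ocular artifacts), no BEM volume conduction, no spatially
correlated sensor noise, no head movement, and spike morphology within a
cluster is perfectly stereotyped. Passing tests therefore demonstrate
algorithmic correctness and internal consistency — recovery of planted
patterns, invariants, geometry — not clinical performance.

## Problem sizes used in the tests

The default validation suite runs a 3-minute, 64-channel, 200-vertex
fixture for module-level checks; a 2-atom, 10-minute fixture at
signal-to-noise 4 for recovery; a 500-vertex model for localization; and
one 20-minute, 204-channel, 500-vertex fixture with ~450 planted events
(28 events/min before thinning) for the structural acceptance checks —
the full per-sensor-type pipeline (ICA, four runs, three atoms each) on
that fixture completes in well under 15 minutes on one CPU. These sizes
were chosen so the whole suite exercises realistic channel counts and
durations while remaining quick enough to run routinely.

## Known limitations

* FIF files are not read directly; recordings enter as a numeric matrix
  plus a JSON channel manifest (`load_recording()`), the exchange format
  also used by the simulator.
* The sparse-coding objective is the plain squared-error form; the
  alpha-stable heavy-tailed noise extension of the original dictionary
  learning work is out of scope, so unmodelled burst artifacts can
  attract atoms.
* Automatic bad-segment rejection is not attempted: recordings are
  assumed pre-cleaned (the simulator produces none), and an optional
  bad-channel list is honoured.
* Smoothing and distances are Euclidean in head coordinates; geodesic
  cortical distances and mesh-based visualization are not provided.
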