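---
title: "Classifying ECG beats with 1-D inception networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying ECG beats with 1-D inception networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ecgincept)
```

## The problem

Ambulatory ECG monitoring produces long single-lead recordings in which each
heartbeat must be classified into rhythm categories. This package implements
a complete beat-classification pipeline for five classes — normal sinus
rhythm (NSR), left and right bundle branch block (LBBB, RBBB), atrial
premature contraction (APC) and premature ventricular contraction (PVC) —
using small one-dimensional inception convolutional networks. Beats are
located by R-peak annotations (as provided by annotated databases such as
MIT-BIH); the package does not implement a QRS detector.

## Beat windows anchored on R-peaks

A classification unit is a window of signal around a *reference* R-peak.
With segment count $k \in \{3,\dots,7\}$ and reference beat $n$, the window
runs from the midpoint between the R-peaks $k-1$ and $k-2$ positions before
the reference to the midpoint between the first and second R-peaks after it
(midpoints rounded down):

$$
x^{\mathrm{first}}_n = \left\lfloor \tfrac{R_{n-k+1} + R_{n-k+2}}{2} \right\rfloor,
\qquad
x^{\mathrm{end}}_n = \left\lfloor \tfrac{R_{n+1} + R_{n+2}}{2} \right\rfloor .
$$

The window therefore covers about $k$ R–R intervals centred on the reference
beat, and both boundaries fall mid-diastole, where the signal is close to
baseline. A beat whose neighbourhood lacks the required peaks (near the
start or end of a record) is skipped, not an error. Each window is labelled
by its own reference beat's class; context beats contribute signal but not
labels.

Because window duration varies with heart rate, every window is resampled
to a fixed length of $(k-1) \times 100$ samples — 200 for $k=3$ up to 600
for $k=7$. This length is a pure function of the configuration, never of
the sampling rate or the rhythm. One R–R interval less than the covered
count is used because the two boundary half-intervals together contribute
one interval of context.

### Resampling and amplitude normalization

Length normalization uses windowed-sinc band-limited resampling: output
sample $j$ is taken at position $j\,n/m$ on the input grid, with a
Hann-tapered sinc kernel of 10 zero-crossings whose cutoff is lowered to
the output Nyquist rate when decimating (this is the anti-aliasing
low-pass). Kernel rows are renormalized to unit DC gain, which keeps
constants exact. Accuracy, measured against analytic band-limited signals:
interior error (beyond the kernel half-width of ~10 output samples from
either end) is below $10^{-2}$ for content up to 70% of the smaller Nyquist
rate, and typically ~$10^{-4}$ for signals concentrated well below cutoff.
Within the last few samples at the window edges the truncated kernel can
deviate by up to ~0.1 of the local amplitude; beat windows are cut at R–R
midpoints where the ECG is near baseline, so this edge behaviour is
immaterial in use. (The `signal::resample` polyphase implementation was
considered but exhibits an uncompensated fractional delay of about one
output sample, which would shift every beat.)

After resampling each window is z-scored (mean 0, standard deviation 1) to
remove per-record gain and baseline offsets. Constant windows would divide
by a vanishing denominator; they are returned as all zeros instead.

## Network designs

Three declarative designs are supported, all built from the same inception
block — parallel 1-D convolution branches with different kernel sizes plus
a stride-1 max-pooling branch, concatenated along the channel axis:

* **Design I** — one inception module;
* **Design II** — two stacked inception modules;
* **Design III** — a plain convolution layer (15 filters, kernel 5,
  stride 1, no padding, followed by ReLU and max-pooling of size 2,
  stride 2) in front of one inception module.

The basic kernel set is $[1, 3, 5]$. The expanded set $[10, 50, 100]$
reaches across whole R–R intervals (at the normalized rate of 100 samples
per interval, a kernel of 100 spans one full interval) and is only
meaningful on the raw normalized ECG; the spec validator therefore accepts
kernels larger than 5 only in an inception module computed directly on the
input — the first module of designs I and II.

Design choices worth recording:

* The inception block is the *naive* form: no 1×1 reduction convolutions
  before the larger kernels and no projection after pooling — four (or
  however many) independent branches whose outputs are concatenated. The
  channel count out of a block is
  `filters_per_branch × n_conv_branches + input_channels`, since the
  pooling branch passes channels through.
* Convolution branches use same-padding. Branch outputs must share the
  input's temporal length or channel-wise concatenation is impossible;
  zero padding therefore applies inside inception branches, while the
  Design III front convolution is unpadded. For even kernel sizes
  (e.g. 10) the extra padding element goes on the right.
* Activations are ReLU after every convolution and hidden dense layer, and
  a softmax output over the five classes; every design ends in two fully
  connected layers of 100 and 50 neurons. No dropout and no batch
  normalization anywhere.
* Weights are initialized Glorot-uniform from a stored seed; the same spec
  and seed reproduce bit-identical parameters.

The network is implemented directly in R: each convolution is evaluated as
$K$ dense matrix products (one per kernel offset), which keeps the
arithmetic in BLAS; backpropagation was verified against central finite
differences (max relative error ~$3 \times 10^{-9}$) during development,
and the forward pass is unit-tested against naive per-channel
recomputations.

## Training

Optimization is mini-batch Adam with learning rate 0.001, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$ and bias correction, on categorical
cross-entropy, with batches of 100 and 10 epochs by default. Each epoch
reshuffles the training set with the seeded generator, so a (seed, data,
config) triple reproduces training bit-for-bit. The per-epoch loss and
training-accuracy trace is kept on the fitted model (`tidy()`).

Dataset assembly follows per-class count plans (`split_plan()`): the
default counts are the standard five-class MIT-BIH experiment sizes
(train/test: NSR 10,000/5,000; LBBB 6,025/2,000; RBBB 5,728/1,400;
APC 1,870/600; PVC 4,928/1,200). Sampling is without replacement, train
and test are disjoint at the beat level, and a class with fewer beats than
requested is scaled down proportionally with a warning rather than
failing. The split is beat-level, not patient-level, mirroring how the
five-class experiments are conventionally run; patient-aware evaluation is
a separate protocol (below).

## Evaluation

All metrics derive from a confusion matrix with ground truth in rows and
predictions in columns, classes ordered NSR, LBBB, RBBB, APC, PVC.

* **Overall accuracy** = 100 × trace / total.
* **Per-predicted-class misclassification error** is *column-wise*:
  for predicted class $c$, $100 \times (\text{column total} -
  \text{diagonal}) / \text{column total}$, identically $100 -
  \mathrm{PPV}(c)$. A class never predicted yields `NA` ("not
  applicable"), never 0. The column-wise definition reproduces every
  published error cell of the bundled benchmark matrices
  (`benchmark_matrix()`); a row-wise reading does not.
* **Binary metrics** collapse the matrix to 2×2 around a positive
  (abnormal) class set and report Acc = (TP+TN)/(TP+TN+FP+FN),
  Se = TP/(TP+FN), Sp = TN/(TN+FP), PPV = TP/(TP+FP), as percentages;
  zero denominators give `NA`.
* Display rounding is half-up to two decimals (so 13.985 → 13.99);
  computations keep full precision and rounding is applied only for
  reporting.

### Patient-specific normal/abnormal protocol

For per-patient screening every beat is reduced to normal/abnormal. NSR is
always normal; APC and PVC always abnormal. Bundle branch block beats are
abnormal *except* in records whose baseline rhythm is a bundle branch
block — by default the seven MIT-BIH records (109, 111, 118, 124, 207,
214, 232) that contain no NSR beats at all, where LBBB/RBBB *is* that
patient's normal rhythm. The record list is an argument, not a constant.
The published studies sample roughly balanced normal/abnormal subsets for
this protocol; since the exact sampling is under-specified, the package
exposes the relabeling rule and the binary metrics and leaves subset
choice to the caller (seeded `make_split()` covers the common case).

## Synthetic data: what it does and does not emulate

The generator (`synth_config()`, `generate_record()`) exists so the whole
pipeline is exercisable without external data. Each beat is a sum of
Gaussian P/Q/R/S/T waves; classes are caricatures with clearly separated
morphology:

* NSR — reference template (P, Q, R, S, T);
* LBBB — broad slurred R (σ 35 ms), deep wide S, discordant (negative) T;
* RBBB — RSR′ pattern: narrow R, deep S, prominent R′ 70 ms after R;
* APC — premature: the preceding R–R interval is shortened by 25%
  (default), with an earlier, larger P wave;
* PVC — wide bizarre QRS (σ 45 ms), no P wave, discordant T, and a
  compensatory pause: the following interval is stretched ×1.5 (default).

Timing starts from a mean R–R of 0.8 s (75 bpm) with a 5% coefficient of
variation (log of physiological short-term variability, kept small for
clean windows), sampled at 360 Hz; white Gaussian noise of 0.02 mV
emulates measurement noise. The default class mix
(NSR .55 / LBBB .12 / RBBB .11 / APC .10 / PVC .12) keeps every class
frequent enough that a few hundred beats contain usable counts of each.
All draws flow from one seed; records in a dataset get derived seeds.

When an APC directly follows a PVC the compensatory pause and the
prematurity shortening act on the same interval and partially cancel;
the timing signatures (shorter-than-average interval before an APC,
longer after a PVC) hold for all unconflicted premature beats.

What the generator deliberately does **not** model: baseline wander,
electrode motion artefacts, muscle noise, multi-lead morphology,
beat-to-beat morphological variability within a class, fusion beats, or
inter-patient variation. Passing the end-to-end test on this data shows
the pipeline is wired correctly and can learn well-separated morphologies;
it does not certify performance on real MIT-BIH records, where class
overlap (especially APC vs NSR) is the dominant difficulty.

## Problem sizes and numerical choices

The bundled end-to-end check simulates ~2,300 beats (4 records × 580
beats), extracts k = 3 windows, trains Design I (basic kernels, 8 filters
per branch, ~0.5 M parameters) for 10 epochs with batch 100, and evaluates
on a held-out split — about half a minute on one CPU, and comfortably above
its 90% accuracy bar (typically ≈ 97–99%). These sizes were chosen as the
smallest that leave a clear margin between "pipeline works" and "pipeline
broken"; larger runs change the numbers, not the conclusion.

Other numerical details: midpoint boundaries round down; z-scoring guards
denominators below $10^{-12}$; max-pooling resolves ties to the earliest
window position (relevant only for exact duplicates); softmax subtracts
the row maximum before exponentiation; the cross-entropy adds $10^{-12}$
inside the log. Sample indices are 0-based with half-open ranges
throughout, matching the on-disk fixture dialect.

## Known limitations

* R-peak positions come from annotations; there is no QRS detector.
* Only the first/selected channel of a multi-lead WFDB record is used.
* The WFDB reader covers the format-212 single/dual-lead layout and MIT
  annotation streams (including SKIP and AUX words) — the subset the
  five-class experiments need — not the full format family.
* Real-data accuracies reported for this architecture on MIT-BIH are not
  reproduced here, since the database is not bundled; the bundled
  benchmark matrices verify the metric arithmetic instead, and the
  synthetic pipeline verifies the learning machinery.
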