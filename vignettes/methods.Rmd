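---
title: "Synthetic ECG cycles and ensemble user recognition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic ECG cycles and ensemble user recognition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

ECG-based user recognition enrolls a subject with a *registration* template
— here an ordered run of five heartbeat cycles — and later identifies the
subject from *comparison* (probe) data. In practice the probe is often
shorter than the enrollment template: acquisition time is limited, the
subject's state (posture, exercise) has changed, and cycles are discarded by
quality control. `ecgacgan` addresses this data-size inconsistency by
generating the missing cycles with a class-conditional adversarial network,
so a probe of two to four genuine cycles can be completed to the full
five-slot template with subject-specific synthetic cycles rather than by
repeating a real cycle.

## Pipeline overview

1. **Simulation** (`generate_study()`): labelled, noisy, multi-state,
   multi-subject recordings with known R-peak ground truth.
2. **Preprocessing** (`ecg_highpass()`, `ecg_notch()`, `detect_r_peaks()`,
   `segment_cycles()`, `build_cycle_sequences()`): drift and powerline
   removal, Pan–Tompkins QRS detection, R-centred cycle extraction.
3. **Generation** (`train_acgan()`, `generate_cycles()`): auxiliary-
   classifier adversarial training over one-cycle signals.
4. **Validation** (`cosine_similarity()`, `xcorr_euclidean_distance()`,
   `evaluate_generation()`): directional and correlation-shape similarity
   of generated cycles.
5. **Recognition** (`train_ensemble()`, `predict_ensemble()`): a parallel
   ensemble of 1D CNNs, top-3 fusion, retraining, per-scheme evaluation
   (`run_experiment()`).

## The synthetic-data generator

Real multi-state ECG biometric corpora are essentially never public, so the
package ships a generator whose output has exactly the structure the rest of
the pipeline consumes, with ground truth for free.

Each subject is a draw of fifteen numbers: for each wave $w \in \{P, Q, R,
S, T\}$ a phase angle $\theta_w$ (radians, R at 0), an amplitude $a_w$ (mV)
and a Gaussian width $\sigma_w$ (radians), sampled uniformly inside the
ranges of `ecg_wave_ranges()`. A recording is a beat train: R times follow
RR intervals drawn from $\mathcal N(60/\mathrm{hr}, \sigma_{RR})$ truncated
at 0.3 s ($\sigma_{RR}$ scaled from the state's heart-rate SD by the delta
method), every sample gets a phase $\varphi$ relative to its nearest beat,
and the clean signal is

$$x(t) = \sum_w a_w \exp\!\left(-\frac{(\varphi(t) - c\,\theta_w)^2}
{2\sigma_w^2}\right),$$

where the compression factor $c \in (0, 1]$ applies to P and T only and
models the shortening of the PQ and QT intervals at elevated heart rate:
after exercise, P and T move closer to the QRS complex. Additive noise is
baseline drift (0.25 Hz sinusoid, below the 0.5 Hz high-pass corner),
60 Hz powerline interference, and white broadband noise.

State profiles default to lying 62 bpm, sitting before exercise 64 bpm,
standing 72 bpm, and after exercise 130 bpm (kept above 120, with the
strongest P/T compression, 0.7). A study is subjects × four states × three
sessions of one-minute recordings; sessions re-draw RR and noise streams but
never the morphology.

What this emulates: per-subject waveform identity that is stable across
sessions, state-dependent rate and timing changes, and realistic additive
noise. What it does not: ectopic beats and arrhythmia, motion-artifact
transients, electrode-contact changes, multi-lead geometry, or
morphological ageing across sessions. Tests passing on this fixture show the
pipeline's machinery is correct under the stated conditions, not that the
recognition accuracies transfer to clinical data.

A full coupled-oscillator dynamical simulator would add realism (notably
RR-interval autocorrelation and respiratory modulation); the sum-of-
Gaussians model was chosen because it exposes exactly the P/QRS/T structure
the downstream stages consume while keeping ground truth trivially exact.

## Preprocessing choices

* **Filters.** Fourth-order Butterworth high-pass at 0.5 Hz and a
  second-order band-stop of width `notch_freq / notch_q` (default 2 Hz)
  around 60 Hz, both applied forward–backward (zero phase) so R-peak
  latencies are not shifted. Filtering is idempotent in the stop band to
  within 1% RMS.
* **QRS detection** follows the classical Pan–Tompkins stages with the
  original constants: 5–15 Hz band-pass, five-point derivative, squaring,
  150 ms moving-window integration, dual adaptive thresholds with
  search-back at 1.66 × the running RR mean, 200 ms refractory period.
  Candidate peaks are the local maxima of the integrated signal that
  dominate their ±200 ms neighbourhood — integration ripple otherwise
  claims the refractory period ahead of the true QRS. Detections are
  refined to the local maximum of the band-passed signal within ±50 ms.
  Thresholds adapt multiplicatively, so detection is invariant to global
  amplitude scaling.
* **Cycle window.** There is no canonical window for one-cycle extraction,
  so the package uses an R-centred asymmetric window, 0.25 s before to
  0.45 s after the peak — covering P through T at
  rest and after exercise — linearly resampled to 256 samples (a power of
  two convenient for the pooled conv stacks) and normalized to unit maximum
  absolute amplitude so real and generated cycles share scale. Cycles whose
  window overruns the record boundary are dropped, not padded: padding
  would inject artificial morphology into training data.

## The adversarial generator

The generator consumes a noise vector of the same length as the cycle to be
generated, combined element-wise with a learned per-class embedding, and
maps it through **nine** 1D convolutions (kernel 9, leaky-ReLU slope 0.2),
**two** max-pooling stages (after convolutions 3 and 6) and **one** fully
connected output layer with tanh saturation, so generated cycles live in
$[-1, 1]$ like the normalized real ones. This 9/2/1 skeleton is enforced by
`generator_spec()`; deeper generator stacks are prone to divergence on
one-cycle signals, which also motivates the non-finite-loss guard. The discriminator is deliberately shallower — four
convolution + pool blocks — with two heads: a real/fake source score and an
auxiliary class distribution.

Losses follow the standard auxiliary-classifier formulation: the
discriminator minimizes source BCE (real labels smoothed to 0.9) plus class
cross-entropy on both real and generated cycles; the generator minimizes
the fooling BCE plus the class cross-entropy of its own outputs. Both use
Adam ($\beta_1 = 0.5$, lr $2\times10^{-4}$ by default). The class losses
are weighted by `aux_weight` (default 10) relative to the source losses:
with unit weight the shared trunk learns class structure too slowly at this
scale (the 3-class toy run sat near chance for tens of epochs), while the
heavier weight lets the auxiliary task anchor the trunk, speeds
convergence, and pushes generated cycles *away* from neighbouring classes —
important when two subjects' templates are nearly parallel. The trade-off
is deliberate: a larger weight favours between-class separation over raw
waveform fidelity, which is the right priority for class-conditional
generation. Any non-finite epoch loss aborts with an error naming the
epoch rather than silently continuing.

Where the class conditioning enters (element-wise product with the noise,
rather than channel concatenation) and the exact channel schedule are
genuinely open design choices; both are configurable, with defaults
documented in `generator_spec()`.

## Similarity measures

`cosine_similarity(a, b)` is the plain inner-product cosine. Generated
cycles are compared against the class's *mean* real cycle, the most stable
reference.

`cross_correlation(a, b)` is the full normalized cross-correlation (length
$2L-1$, normalized by $\lVert a\rVert \lVert b\rVert$ so an autocorrelation
peaks at exactly 1). `xcorr_euclidean_distance(current, next, synthetic)`
overlays the correlation waveform of (current, synthetic) on that of
(current, next real) and reports their Euclidean distance scaled by
$\sqrt{2L-1}$; it is 0 when the synthetic cycle correlates with the current
cycle exactly as the genuine next cycle does, and is invariant to amplitude
scaling of any argument. The scale factor makes the value length-
independent; absolute distance values are comparable only within one
normalization convention. No lag alignment is applied before subtraction: the
overlay rule gives none, and both correlations share the same `current`
reference, so their lag axes already correspond.

## The recognition ensemble

Each ensemble member is a 1D CNN over the flattened five-cycle input
(5 × 256 samples): convolution (ReLU) and max-pooling alternate (max, not
average, pooling — average pooling down-weights the sparse post-ReLU
activations), then a dense penultimate stage with dropout feeds a softmax
over subjects. Members differ in epochs, batch size, dropout, channel
widths and kernel size. In full-scale mode the hyperparameter grid is
enforced: epochs ∈ {500, 750}, batch ∈ {256, 512}, dropout ∈ [0.5, 0.7],
learning rate 0.001.

After training, members are ranked by validation accuracy (stratified 75/25
split of the registration sequences) and the top three are fused: for every
training input the three penultimate-layer vectors are concatenated.
"Result data" of a member is read as penultimate-layer features — raw
signals would make the members pointless and final softmax scores lose
information. A dense classifier (one hidden stage; fused features have no
spatial order left, so convolution over them would be arbitrary) is
retrained on the fused set; probes pass through the three members, are
fused the same way, and classified. Probes from subjects unseen at
enrollment count as errors with a warning — the task is closed-set
identification.

## The scheme experiment

`combination_schemes()` fixes the seven five-slot probe templates: all-real
(`Real1~5`), synthetic-padded (`Real1~4+Synthetic1`, `Real1~3+Synthetic1~2`,
`Real1~2+Synthetic1~3`) and repetition-padded controls (`Real1~4+Real4`,
`Real1~3+Real3~3`, `Real1~2+Real2~2`). `run_experiment()` executes the whole
pipeline from one configuration and a seed triple (fixture, GAN, ensemble);
registration uses sessions 1–2 across all four states, comparison uses the
held-out session 3 (time-independent probes), and synthetic slots draw from
a per-subject bank generated once with a fixed seed so all schemes share
synthetic material. Probe templates are state-homogeneous (cycles of one
recording); mixing states within one template is not attempted.

## Problem sizes and numerical choices

The desk-scale defaults were chosen so that a full experiment is a
coffee-break computation on one CPU: 5 subjects, 30 s recordings at 500 Hz,
128-sample cycles, GAN for 160 epochs at learning rate $5\times10^{-4}$
(batch 64, at most 100 cycles per class), six members at 50 epochs, ~200
registration sequences. Synthetic scheme slots use discriminator rejection
sampling (`gan_oversample = 8`): candidates are drawn eight-fold and the
ones the auxiliary class head rates most class-typical are kept — a
selection that uses only the trained model, never real data. The
generation-quality evaluation uses the slightly larger 3-subject toy:
256-sample cycles, 200 cycles per class, 300 epochs at the default
learning rate. With
`full_scale = TRUE` the full acquisition-protocol scale (60 s at 2000 Hz,
three sessions, the 500/750-epoch member grid) is enforced instead.

Other numerical choices: He-scaled normal weight initialization; Adam
$\varepsilon = 10^{-8}$; softmax probabilities floored at $10^{-12}$ inside
the cross-entropy; ties in member selection broken toward the lower member
id; all-zero cycles pass through normalization unchanged (the zero vector
has no scale); every random draw flows from an explicit seed through R's
RNG, so every stage is bit-reproducible.

## Known limitations

* Accuracies measured on the simulated fixture are far above what real
  multi-state ECG data yields; only the *orderings* (all-real ≥ heavily
  repetition-padded; synthetic padding ≥ repetition padding) are the
  meaningful observables at this scale.
* The adversarial model is trained per cohort; adding a subject means
  retraining.
* Single-lead, normal-rhythm signals only; no arrhythmia handling.
* Deployments of this kind of system typically augment a few hundred
  recordings per person into tens of thousands of training items; the
  experiment here deliberately uses only the honest counts its simulator
  produces, with no augmentation.
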