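# harkit

Building blocks for recognizing human activities of daily living from
heterogeneous sensors — the computational layer of a smart-home / tele-care
monitoring stack. It is aimed at researchers who need tested, inspectable
reference implementations of four components that usually hide inside such
systems:

* **Body segmentation** from grayscale camera frames: a two-phase level-set
  active contour whose energy couples the Chan–Vese fidelity term with an
  area-scaled Bhattacharyya separation term,

  `E = γ·per(C) + η·A_in + β·F(C) + (1−β)·B(C)·n_pix`,

  with `F(C) = Σ (I−c_in)² H(−φ) + (I−c_out)² H(φ)` and
  `B(C) = Σ_z √(p_in(z)·p_out(z))`. Minimizing within-region variance alone
  fails on inhomogeneous foregrounds (a body whose clothing and skin
  straddle the background intensity); the Bhattacharyya term separates the
  region *histograms* and handles exactly that case.
* **Silhouette-video activity classification**: ICA motion features from
  consecutive-frame differences, k-means vector quantization into a
  codebook, one discrete HMM per activity, forward-likelihood
  classification with an "Unknown" floor.
* **A null-activity-aware semi-Markov CRF** for wearable sensor streams:
  states are labeled segments `s_i = (y_i, b_i, e_i)`, null activities are
  removed so consecutive segments satisfy `b_{i+1} > e_i` and gaps carry
  inactivity observation weights; exact partition function, likelihood,
  fast `O(T·M·(M+D))` forward–backward gradients validated against
  brute-force enumeration, semi-Markov Viterbi decoding, and windowed
  feature extraction (mean / sd / mean-crossing rate over 512-sample,
  50%-overlapped windows).
* **A rule engine** that lifts low-level activity events to reminders,
  device commands and high-level activities (exercise detection, medicine
  reminders, TV/lights control, unknown-movement alerts), with
  knowledge-base gating and precision/recall scoring of event match-making.

Seeded synthetic generators (images, silhouette videos, labeled symbol
corpora, scripted event logs) ship with ground truth so every component is
testable offline. See the vignette
(`vignettes/activity-recognition-methods.Rmd`) for the models, parameter
meanings and numerical choices.

## Worked example

Segment an inhomogeneous body image, with and without the Bhattacharyya
term, then train a semi-Markov CRF on a synthetic wearable corpus:

```r
library(harkit)

fx  <- make_body_image(seed = 1)           # two-tone body on a mid-gray background
res <- segment_body(fx$image)
mask_iou(res$mask, fx$mask)                # 0.922  <- full energy (beta = 0.5)
res_cv <- segment_body(fx$image, params = segmentation_params(beta = 1))
mask_iou(res_cv$mask, fx$mask)             # 0.554  <- variance term only
res
#> level-set segmentation: 600 iterations, converged/stopped, inside area 1106 px
#>   energy 1832 -> 971.5

encode_segments(c("eating", "eating", "cleaning", "cleaning",
                  "having tea", "having tea"), null_labels = "cleaning")
#>        label begin end
#> 1     eating     1   2
#> 2 having tea     5   6

corpus <- make_sensor_corpus(M = 3, emission_sharpness = 0.9, T = 110,
                             n_seqs = 8, seed = 7)
fit  <- train_semicrf(corpus, hyper = list(D = 30, max_iter = 30))
held <- make_sensor_corpus(M = 3, emission_sharpness = 0.9, T = 110,
                           n_seqs = 4, seed = 8)
pred <- lapply(held, function(it) infer(it$x, fit$params, fit$stats, 30))
segment_f1(pred, lapply(held, `[[`, "s"))$f1   # 0.951
```

The IoU pair shows the point of the coupled energy: the variance-only model
(`beta = 1`) barely moves on a bimodal foreground, while the full energy
recovers the body mask. The F1 is segment-level (label equal, overlap IoU
at least 0.5) on held-out sequences: 39 of 42 true segments recovered, one
spurious segment. The `encode_segments()` call shows null-activity
elimination — "cleaning" becomes a gap, so the eating → having-tea
transition stays adjacent in the segment sequence.

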