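# Shared fixtures, built in code at load time.

# random semi-Markov CRF instance (small enough for enumeration oracles)
random_scrf_instance <- function(M = NULL, Tn = NULL, D = NULL, O = NULL,
                                 wsd = 0.5) {
  M <- M %||% sample(1:3, 1)
  Tn <- Tn %||% sample(2:6, 1)
  D <- D %||% sample(1:3, 1)
  O <- O %||% sample(2:4, 1)
  labs <- letters[seq_len(M)]
  w <- semicrf_params(labs, O)
  w$w_tr[] <- rnorm(length(w$w_tr), 0, wsd)
  w$w_d[] <- rnorm(length(w$w_d), 0, wsd)
  w$w_o[] <- rnorm(length(w$w_o), 0, wsd)
  stats <- structure(list(m = setNames(runif(M, 1, 3), labs),
                          s2 = setNames(runif(M, 0.5, 2), labs)),
                     class = "duration_stats")
  x <- sample.int(O, Tn, replace = TRUE)
  list(M = M, Tn = Tn, D = D, O = O, labs = labs, w = w, stats = stats, x = x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force log partition via explicit enumeration (independent oracle)
bf_log_partition <- function(inst) {
  alls <- harkit:::enumerate_segmentations(inst$Tn, inst$labs, inst$D)
  scores <- vapply(alls, harkit:::segmentation_score, numeric(1),
                   x = inst$x, w = inst$w, stats = inst$stats, D = inst$D)
  list(logZ = harkit:::logsumexp(scores), all = alls, scores = scores)
}

# the 3-class silhouette training/test corpus used by the classifier tests;
# built once per test run
video_kinds <- c("wave", "jump", "bend")
make_video_corpus <- function(offset = 0) {
  out <- list()
  for (k in video_kinds) for (i in 1:6)
    out[[length(out) + 1]] <- make_silhouette_video(
      k, n_frames = 16, seed = offset + i * 10 + match(k, video_kinds),
      dim = c(50, 36))
  out
}
video_train <- make_video_corpus()
video_test <- make_video_corpus(offset = 1000)
video_clf <- train_activity_models(video_train, ica_k = 10, K = 16,
                                   n_states = 4, seed = 7)
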