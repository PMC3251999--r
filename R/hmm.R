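# Discrete hidden Markov models over codebook symbols: one ergodic model
# per activity, trained with Baum-Welch; classification takes the
# forward-algorithm log likelihood under each model and returns the argmax
# label, or "Unknown" when even the best per-frame log likelihood falls
# below a floor.

#' Construct a discrete HMM
#'
#' @param initial state initial probabilities (length n).
#' @param transitions n x n row-stochastic transition matrix.
#' @param emissions n x K row-stochastic emission matrix over symbols.
#' @return object of class `discrete_hmm`.
#' @export
discrete_hmm <- function(initial, transitions, emissions) {
  initial <- as.numeric(initial)
  transitions <- as.matrix(transitions); emissions <- as.matrix(emissions)
  n <- length(initial)
  check_that(all(dim(transitions) == n) && nrow(emissions) == n,
             "inconsistent HMM dimensions")
  rows_ok <- function(m) all(abs(rowSums(m) - 1) < 1e-9) && all(m >= 0)
  check_that(abs(sum(initial) - 1) < 1e-9 && all(initial >= 0) &&
               rows_ok(transitions) && rows_ok(emissions),
             "probability rows must be nonnegative and sum to 1")
  structure(list(initial = initial, transitions = transitions,
                 emissions = emissions, n_states = n,
                 n_symbols = ncol(emissions)),
            class = "discrete_hmm")
}

# scaled forward pass; returns log P(x | model)
hmm_forward <- function(x, model) {
  check_that(all(x >= 1 & x <= model$n_symbols),
             "symbol outside the model alphabet")
  Tn <- length(x)
  a <- model$initial * model$emissions[, x[1]]
  ll <- 0
  for (t in seq_len(Tn)) {
    if (t > 1) a <- as.vector(a %*% model$transitions) * model$emissions[, x[t]]
    s <- sum(a)
    if (s == 0) return(-Inf)
    ll <- ll + log(s)
    a <- a / s
  }
  ll
}

#' Train a discrete HMM with Baum-Welch
#'
#' Expectation-maximization from a seeded random positive initialization.
#' Plain EM updates are used during iteration (so the per-iteration training
#' log likelihood is non-decreasing and rows stay positive); Laplace
#' smoothing `smooth` is applied once to the final row estimates.
#'
#' @param sequences list of integer symbol sequences (or a single vector).
#' @param n_states number of hidden states (default 4, ergodic topology).
#' @param n_symbols alphabet size (defaults to the largest symbol seen).
#' @param seed RNG seed for the initialization.
#' @param max_iter,tol EM controls (stop when the total log likelihood
#'   improves by less than `tol`).
#' @param smooth additive smoothing applied to the final rows (default 1e-3).
#' @return `discrete_hmm` with attribute `loglik_trace` (total training log
#'   likelihood per EM iteration).
#' @export
train_hmm <- function(sequences, n_states = 4, n_symbols = NULL, seed = 1,
                      max_iter = 100, tol = 1e-6, smooth = 1e-3) {
  if (!is.list(sequences)) sequences <- list(sequences)
  check_that(length(sequences) >= 1 && all(lengths(sequences) >= 1),
             "empty training corpus")
  syms <- unlist(sequences)
  n_symbols <- n_symbols %||% max(syms)
  check_that(all(syms >= 1 & syms <= n_symbols), "symbols outside alphabet")
  n <- n_states
  rnorm_rows <- function(nr, nc) {
    m <- matrix(runif(nr * nc, 0.5, 1.5), nr, nc)
    m / rowSums(m)
  }
  init <- with_seed(seed, list(
    pi = as.vector(rnorm_rows(1, n)),
    A = rnorm_rows(n, n),
    B = rnorm_rows(n, n_symbols)))
  pi_ <- init$pi; A <- init$A; B <- init$B
  trace <- numeric(0)
  prev_ll <- -Inf
  for (iter in seq_len(max_iter)) {
    acc_pi <- numeric(n)
    acc_A <- matrix(0, n, n)
    acc_B <- matrix(0, n, n_symbols)
    ll <- 0
    for (x in sequences) {
      Tn <- length(x)
      alpha <- matrix(0, Tn, n); beta <- matrix(0, Tn, n)
      cs <- numeric(Tn)
      a <- pi_ * B[, x[1]]
      cs[1] <- sum(a); alpha[1, ] <- a / cs[1]
      if (Tn > 1) for (t in 2:Tn) {
        a <- as.vector(alpha[t - 1, ] %*% A) * B[, x[t]]
        cs[t] <- sum(a); alpha[t, ] <- a / cs[t]
      }
      ll <- ll + sum(log(cs))
      beta[Tn, ] <- 1
      if (Tn > 1) for (t in (Tn - 1):1)
        beta[t, ] <- as.vector(A %*% (B[, x[t + 1]] * beta[t + 1, ])) / cs[t + 1]
      gamma <- alpha * beta
      gamma <- gamma / rowSums(gamma)
      acc_pi <- acc_pi + gamma[1, ]
      if (Tn > 1) for (t in seq_len(Tn - 1)) {
        xi <- (alpha[t, ] %o% (B[, x[t + 1]] * beta[t + 1, ])) * A / cs[t + 1]
        acc_A <- acc_A + xi
      }
      for (t in seq_len(Tn)) acc_B[, x[t]] <- acc_B[, x[t]] + gamma[t, ]
    }
    trace <- c(trace, ll)
    if (is.finite(prev_ll) && ll - prev_ll < tol) break
    prev_ll <- ll
    pi_ <- acc_pi / sum(acc_pi)
    A <- acc_A / pmax(rowSums(acc_A), .Machine$double.xmin)
    B <- acc_B / pmax(rowSums(acc_B), .Machine$double.xmin)
  }
  model <- discrete_hmm((pi_ + smooth) / sum(pi_ + smooth),
                        (A + smooth) / rowSums(A + smooth),
                        (B + smooth) / rowSums(B + smooth))
  attr(model, "loglik_trace") <- trace
  model
}

#' Bundle per-activity HMMs into a model bank
#'
#' @param models named list of `discrete_hmm` (names are activity labels).
#' @param unknown_threshold per-frame log-likelihood floor below which a
#'   sequence is labeled `"Unknown"`. Default `log(1/K) - 2` nats, with `K`
#'   the emission alphabet size.
#' @return object of class `activity_bank`.
#' @export
activity_bank <- function(models, unknown_threshold = NULL) {
  check_that(length(models) >= 1 && !is.null(names(models)) &&
               all(nzchar(names(models))), "models must be a named list")
  K <- models[[1]]$n_symbols
  unknown_threshold <- unknown_threshold %||% (log(1 / K) - 2)
  structure(list(models = models, unknown_threshold = unknown_threshold),
            class = "activity_bank")
}

#' Classify a symbol sequence against an activity model bank
#'
#' Computes the forward log likelihood under each model; returns the argmax
#' label (lexicographic order breaks exact ties) or `"Unknown"` when the
#' best per-frame log likelihood is below the bank's threshold.
#'
#' @param x integer symbol sequence.
#' @param bank `activity_bank`.
#' @return list with `label` and `loglik` (named per-model log likelihoods).
#' @export
classify_activity <- function(x, bank) {
  check_that(inherits(bank, "activity_bank"), "not an activity bank")
  ll <- vapply(bank$models, function(m) hmm_forward(x, m), numeric(1))
  ord <- order(-round(ll, 9), names(ll))   # ties -> lexicographic label order
  best <- ord[1]
  label <- if (ll[best] / length(x) < bank$unknown_threshold) "Unknown"
           else names(ll)[best]
  list(label = label, loglik = ll)
}

#' Train the full silhouette-video activity classifier
#'
#' Convenience wrapper over the pipeline: fit the ICA motion basis on all
#' training sequences, build the k-means codebook from the pooled
#' projections, quantize each sequence and train one HMM per activity label.
#'
#' @param training list of labeled `silhouette_sequence` objects.
#' @param ica_k ICA components (default 10).
#' @param K codebook size (default 16).
#' @param n_states HMM states per activity (default 4).
#' @param seed RNG seed.
#' @param unknown_threshold see [activity_bank()].
#' @return list of class `activity_classifier`: `basis`, `codebook`, `bank`.
#' @export
train_activity_models <- function(training, ica_k = 10, K = 16, n_states = 4,
                                  seed = 1, unknown_threshold = NULL) {
  labs <- vapply(training, function(s) s$label %||% NA_character_, character(1))
  check_that(!any(is.na(labs)), "all training sequences must carry a label")
  basis <- fit_motion_basis(training, k = ica_k, seed = seed)
  feats <- lapply(training, project_features, basis = basis)
  cb <- build_codebook(do.call(rbind, feats), K = K, seed = seed)
  symseqs <- lapply(feats, quantize, codebook = cb)
  models <- lapply(sort(unique(labs)), function(lb)
    train_hmm(symseqs[labs == lb], n_states = n_states, n_symbols = cb$K,
              seed = seed))
  names(models) <- sort(unique(labs))
  structure(list(basis = basis, codebook = cb,
                 bank = activity_bank(models, unknown_threshold)),
            class = "activity_classifier")
}

#' Classify a silhouette sequence with a trained activity classifier
#'
#' @param seq `silhouette_sequence`.
#' @param clf `activity_classifier` from [train_activity_models()].
#' @return as [classify_activity()].
#' @export
classify_sequence <- function(seq, clf) {
  feats <- project_features(seq, clf$basis)
  classify_activity(quantize(feats, clf$codebook), clf$bank)
}
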