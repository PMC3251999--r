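# L2-regularized maximum-likelihood training of the semi-Markov CRF by
# full-batch gradient ascent with backtracking line search. The optimizer is
# deliberately simple: the objective is concave, the corpus sizes this
# package targets are moderate, and every accepted step is guaranteed to
# increase the penalized objective, which the tests check.

flatten_params <- function(w) c(as.vector(w$w_tr), as.vector(w$w_d), as.vector(w$w_o))

unflatten_params <- function(v, proto) {
  M <- length(proto$labels); O <- proto$n_symbols
  n_tr <- (M + 1) * M
  w <- proto
  w$w_tr[] <- v[seq_len(n_tr)]
  w$w_d[] <- v[n_tr + seq_len(M)]
  w$w_o[] <- v[n_tr + M + seq_len((M + 1) * O)]
  w
}

flatten_grad <- function(g) c(as.vector(g$w_tr), as.vector(g$w_d), as.vector(g$w_o))

corpus_objective <- function(corpus, w, stats, D) {
  sum(vapply(corpus, function(it)
    segmentation_score(it$s, it$x, w, stats, D) -
      semicrf_forward(semicrf_tables(it$x, w, stats, D))$logZ, numeric(1)))
}

#' Train a null-activity-aware semi-Markov CRF
#'
#' Maximizes the L2-penalized log likelihood
#' `sum_i L(S_i | x_i) - lambda/2 * ||w||^2` over a corpus of observation
#' sequences with ground-truth segmentations, by full-batch gradient ascent
#' with backtracking line search (accepted steps never decrease the
#' objective). Duration statistics are extracted from the training
#' segmentations first and held fixed.
#'
#' @param corpus list of training items, each a list with `x` (integer
#'   symbol sequence) and `s` (segmentation data frame `label`, `begin`,
#'   `end`).
#' @param hyper list of hyperparameters: `D` (maximum segment duration,
#'   default 256), `lambda` (L2 strength, default 0.1), `max_iter` (default
#'   100), `tol` (gradient sup-norm stop, default 1e-3), `n_symbols`
#'   (defaults to the largest symbol seen), `labels` (defaults to labels
#'   seen in the truths), `verbose`, `seed` (accepted for interface
#'   uniformity; the optimizer is deterministic).
#' @return list with `params` (`semicrf_params`), `stats`
#'   (`duration_stats`), `objective` (trace over accepted iterations), and
#'   `converged`.
#' @export
train_semicrf <- function(corpus, hyper = list()) {
  check_that(length(corpus) >= 1, "empty corpus")
  h <- modifyList(list(D = 256, lambda = 0.1, max_iter = 100, tol = 1e-3,
                       n_symbols = NULL, labels = NULL, verbose = FALSE,
                       seed = NULL), hyper)
  check_that(h$D >= 1 && h$lambda >= 0, "invalid hyperparameters")
  labels <- h$labels %||% sort(unique(unlist(lapply(corpus, function(it)
    as.character(it$s$label)))))
  n_symbols <- h$n_symbols %||% max(unlist(lapply(corpus, function(it) it$x)))
  stats <- duration_stats(lapply(corpus, function(it) it$s), labels = labels)
  for (it in corpus) {
    check_that(length(it$x) >= 1, "empty sequence in corpus")
    validate_segmentation(it$s, length(it$x))
    if (nrow(it$s))
      check_that(max(it$s$end - it$s$begin + 1) <= h$D,
                 "training segment exceeds maximum duration D")
  }
  w <- semicrf_params(labels, n_symbols)
  v <- flatten_params(w)
  obj_at <- function(v) {
    corpus_objective(corpus, unflatten_params(v, w), stats, h$D) -
      h$lambda / 2 * sum(v^2)
  }
  grad_at <- function(v) {
    wv <- unflatten_params(v, w)
    gtot <- numeric(length(v))
    for (it in corpus) {
      g <- gradients_fast(it$x, it$s, wv, stats, h$D)
      gtot <- gtot + flatten_grad(g)
    }
    gtot - h$lambda * v
  }
  obj <- obj_at(v)
  trace <- obj
  converged <- FALSE
  for (iter in seq_len(h$max_iter)) {
    g <- grad_at(v)
    gn <- max(abs(g))
    if (gn < h$tol) { converged <- TRUE; break }
    step <- 1 / max(1, sqrt(sum(g^2)))
    accepted <- FALSE
    for (k in seq_len(40)) {
      v_new <- v + step * g
      obj_new <- obj_at(v_new)
      if (is.finite(obj_new) && obj_new > obj + 1e-4 * step * sum(g^2)) {
        v <- v_new; obj <- obj_new; accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }   # no ascent direction left
    trace <- c(trace, obj)
    if (h$verbose) message(sprintf("iter %3d  obj %.6f  |g| %.3g", iter, obj, gn))
  }
  list(params = unflatten_params(v, w), stats = stats,
       objective = trace, converged = converged)
}
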