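# Gradients of the semi-Markov CRF log likelihood.
#
# dL/dw = observed feature counts along the true segmentation minus
# model-expected counts. Three routes are provided:
#   gradients_fast       one shared forward-backward pass, segment marginals
#                        and running accumulators: O(T M (M + D)) plus O(T M D)
#                        for segment-occupancy accumulation.
#   gradients_naive      a per-weight expectation-semiring forward recursion
#                        in the style of the original segment-CRF training
#                        algorithm: O(T M^2 D) per weight, O(N T M^2 D) total.
#   gradients_bruteforce explicit enumeration of every segmentation (small-T
#                        oracle).
# All three return the same structure and are cross-checked in the tests.

# Feature counts of one segmentation: the sufficient statistics paired with
# each weight block.
feature_counts <- function(s, x, w, stats) {
  T <- length(x); M <- length(w$labels)
  st <- stats_for(stats, w$labels)
  f_tr <- matrix(0, M + 1, M)
  f_d <- rep(0, M)
  f_o <- matrix(0, M + 1, w$n_symbols)
  covered <- rep(FALSE, T)
  prev <- 0L
  if (nrow(s)) for (i in seq_len(nrow(s))) {
    y <- match(s$label[i], w$labels)
    from <- if (i == 1) M + 1 else match(s$label[i - 1], w$labels)
    f_tr[from, y] <- f_tr[from, y] + 1
    d <- s$end[i] - s$begin[i] + 1
    f_d[y] <- f_d[y] + (d - st$m[y])^2 / (2 * st$s2[y])
    for (t in s$begin[i]:s$end[i]) {
      f_o[y, x[t]] <- f_o[y, x[t]] + 1
      covered[t] <- TRUE
    }
  }
  for (t in which(!covered)) f_o[M + 1, x[t]] <- f_o[M + 1, x[t]] + 1
  list(w_tr = f_tr, w_d = f_d, w_o = f_o)
}

grad_shapes_like <- function(w) {
  list(w_tr = w$w_tr * 0, w_d = w$w_d * 0, w_o = w$w_o * 0)
}

#' Fast gradients of the semi-Markov CRF log likelihood
#'
#' Observed minus expected feature counts, with expectations computed from
#' segment posterior marginals obtained by one forward-backward pass with
#' running predecessor accumulators. The returned gradient carries an
#' `"ops"` attribute counting the elementary potential/feature evaluations
#' performed (vectorized operations counted by their length), used by the
#' complexity tests.
#'
#' @inheritParams log_likelihood
#' @return list with gradient blocks `w_tr`, `w_d`, `w_o` (same shapes as in
#'   `semicrf_params`), attributes `ops` and `logZ`.
#' @export
gradients_fast <- function(x, s, w, stats, D) {
  check_params(w); check_obs(x, w)
  obs <- feature_counts(s, x, w, stats)
  # truth must be representable
  if (nrow(s)) check_that(max(s$end - s$begin + 1) <= D,
                          "true segment duration exceeds D")
  tb <- semicrf_tables(x, w, stats, D)
  T <- tb$T; M <- tb$M; Dm <- tb$Deff
  fw <- semicrf_forward(tb)
  bw <- semicrf_backward(tb)
  logZ <- fw$logZ
  ops <- fw$ops + bw$ops
  st <- stats_for(stats, w$labels)
  exp_tr <- matrix(0, M + 1, M)
  exp_d <- rep(0, M)
  occ_diff <- matrix(0, T + 1, M)   # difference array for segment occupancy
  # segment marginals mu(y, b, e) = prefix[b,y] + qd + emit + bwd[e,y] - logZ
  for (e in seq_len(T)) {
    dmax <- min(Dm, e)
    ds <- seq_len(dmax)
    bs <- e - ds + 1L
    for (y in seq_len(M)) {
      emit <- tb$ce[e + 1, y] - tb$ce[bs, y]
      mu <- exp(fw$prefix[bs, y] + tb$qd[ds, y] + emit + bw$bwd[e, y] - logZ)
      ops <- ops + dmax
      exp_d[y] <- exp_d[y] + sum(mu * (ds - st$m[y])^2 / (2 * st$s2[y]))
      occ_diff[cbind(bs, y)] <- occ_diff[cbind(bs, y)] + mu
      occ_diff[e + 1, y] <- occ_diff[e + 1, y] - sum(mu)
    }
  }
  occ <- apply(occ_diff, 2, cumsum)[seq_len(T), , drop = FALSE]  # occ[t, y]
  ops <- ops + T * M
  # transition expectations via the suffix accumulator U from the backward pass
  for (y in seq_len(M)) {
    exp_tr[M + 1, y] <- exp(tb$wtr[M + 1, y] + bw$U[1, y] - logZ)
    for (yp in seq_len(M)) {
      ee <- seq_len(T)
      v <- fw$alpha[, yp] - tb$cia[ee + 1] + bw$U[cbind(ee + 1, y)]
      exp_tr[yp, y] <- exp(tb$wtr[yp, y] - logZ + logsumexp(v))
      ops <- ops + T
    }
  }
  # observation expectations: label occupancy and gap occupancy per symbol
  exp_o <- matrix(0, M + 1, w$n_symbols)
  ia_occ <- pmax(1 - rowSums(occ), 0)
  for (o in seq_len(w$n_symbols)) {
    sel <- x == o
    if (any(sel)) {
      exp_o[seq_len(M), o] <- colSums(occ[sel, , drop = FALSE])
      exp_o[M + 1, o] <- sum(ia_occ[sel])
    }
  }
  ops <- ops + T * (M + 1)
  g <- list(w_tr = obs$w_tr - exp_tr,
            w_d = obs$w_d - exp_d,
            w_o = obs$w_o - exp_o)
  dimnames(g$w_tr) <- dimnames(w$w_tr)
  names(g$w_d) <- names(w$w_d)
  dimnames(g$w_o) <- dimnames(w$w_o)
  attr(g, "ops") <- ops
  attr(g, "logZ") <- logZ
  g
}

#' Brute-force gradients by enumeration (testing oracle)
#'
#' Computes expected feature counts by explicitly enumerating every valid
#' segmentation, scoring each, and averaging feature counts under the
#' resulting Gibbs distribution. Guarded to short sequences.
#'
#' @inheritParams log_likelihood
#' @return same structure as [gradients_fast()], attribute `logZ`.
#' @export
gradients_bruteforce <- function(x, s, w, stats, D) {
  check_params(w); check_obs(x, w)
  T <- length(x)
  check_that(T <= 10, "brute-force gradients guarded to T <= 10")
  obs <- feature_counts(s, x, w, stats)
  all_s <- enumerate_segmentations(T, w$labels, D)
  scores <- vapply(all_s, segmentation_score, numeric(1),
                   x = x, w = w, stats = stats, D = D)
  logZ <- logsumexp(scores)
  p <- exp(scores - logZ)
  exp_f <- grad_shapes_like(w)
  for (i in seq_along(all_s)) {
    f <- feature_counts(all_s[[i]], x, w, stats)
    exp_f$w_tr <- exp_f$w_tr + p[i] * f$w_tr
    exp_f$w_d <- exp_f$w_d + p[i] * f$w_d
    exp_f$w_o <- exp_f$w_o + p[i] * f$w_o
  }
  g <- list(w_tr = obs$w_tr - exp_f$w_tr, w_d = obs$w_d - exp_f$w_d,
            w_o = obs$w_o - exp_f$w_o)
  attr(g, "logZ") <- logZ
  g
}

# ---- naive per-weight gradient (complexity reference) ----------------------

# Enumerates the weight list in a fixed order; each entry names a block and
# an index within it, together with accessor closures for its feature value
# on a (transition, segment) pair.
weight_index <- function(w) {
  M <- length(w$labels); O <- w$n_symbols
  idx <- list()
  for (i in seq_len(M + 1)) for (j in seq_len(M))
    idx[[length(idx) + 1L]] <- list(block = "w_tr", i = i, j = j)
  for (j in seq_len(M))
    idx[[length(idx) + 1L]] <- list(block = "w_d", i = j)
  for (i in seq_len(M + 1)) for (o in seq_len(O))
    idx[[length(idx) + 1L]] <- list(block = "w_o", i = i, j = o)
  idx
}

#' Naive per-weight gradients (original-style training recursion)
#'
#' Computes each weight's expected feature count with its own
#' expectation-semiring forward recursion over (end time, label, duration,
#' previous label), i.e. `O(T M^2 D)` work per weight and `O(N T M^2 D)`
#' total for N weights. Kept as the instrumented reference point for the
#' complexity comparison with [gradients_fast()]; results agree with the
#' fast and brute-force routes. Gap stretches are folded in by a running
#' gap-extension of the forward mass, shared plumbing with the fast route.
#'
#' @inheritParams log_likelihood
#' @return same structure as [gradients_fast()], with attribute `ops`.
#' @export
gradients_naive <- function(x, s, w, stats, D) {
  check_params(w); check_obs(x, w)
  obs <- feature_counts(s, x, w, stats)
  tb <- semicrf_tables(x, w, stats, D)
  T <- tb$T; M <- tb$M; Dm <- tb$Deff
  st <- stats_for(stats, w$labels)
  wIA <- w$w_o[M + 1, ]
  eIA <- exp(wIA[x])                    # per-step gap factor
  widx <- weight_index(w)
  ops <- 0
  g <- grad_shapes_like(w)
  etr <- exp(tb$wtr)                    # (M+1) x M
  # per-symbol cumulative counts for emission features: cnt[o][t+1]
  csym <- lapply(seq_len(w$n_symbols), function(o) c(0L, cumsum(x == o)))
  for (n in seq_along(widx)) {
    wi <- widx[[n]]
    is_ia_w <- wi$block == "w_o" && wi$i == M + 1
    fIA_step <- if (is_ia_w) as.numeric(x == wi$j) else numeric(T)
    # GA[t+1, y]: forward mass of states whose last segment has label y and
    # ended at some e <= t, with e+1..t scored as gap. GH: its
    # feature-weighted companion. a0/h0: the START (no-segment-yet) context.
    GA <- matrix(0, T + 1, M); GH <- matrix(0, T + 1, M)
    a0 <- numeric(T + 1); h0 <- numeric(T + 1)
    a0[1] <- 1
    scale_log <- 0
    for (t in seq_len(T)) {
      # extend gap by one step
      a0[t + 1] <- a0[t] * eIA[t]
      h0[t + 1] <- (h0[t] + a0[t] * fIA_step[t]) * eIA[t]
      GA[t + 1, ] <- GA[t, ] * eIA[t]
      GH[t + 1, ] <- (GH[t, ] + GA[t, ] * fIA_step[t]) * eIA[t]
      dmax <- min(Dm, t)
      ds <- seq_len(dmax)
      bs <- t - ds + 1L                 # segment begins, by duration
      for (y in seq_len(M)) {
        seg_sc <- exp(tb$qd[ds, y] + tb$ce[t + 1, y] - tb$ce[bs, y])
        # common (transition-independent) feature value of the segment itself
        f_seg <- numeric(dmax)
        if (wi$block == "w_d" && wi$i == y)
          f_seg <- (ds - st$m[y])^2 / (2 * st$s2[y])
        if (wi$block == "w_o" && wi$i == y)
          f_seg <- csym[[wi$j]][t + 1] - csym[[wi$j]][bs]
        # START context, lead gap 1..b-1 already accrued in a0/h0
        a_prev <- etr[M + 1, y] * a0[bs]
        h_prev <- etr[M + 1, y] * h0[bs]
        if (wi$block == "w_tr" && wi$i == M + 1 && wi$j == y)
          h_prev <- h_prev + a_prev
        # all previous labels, gap accrued in GA/GH
        a_prev <- a_prev + GA[bs, , drop = FALSE] %*% etr[seq_len(M), y]
        h_prev <- h_prev + GH[bs, , drop = FALSE] %*% etr[seq_len(M), y]
        if (wi$block == "w_tr" && wi$i <= M && wi$j == y)
          h_prev <- h_prev + GA[bs, wi$i] * etr[wi$i, y]
        ops <- ops + dmax * M
        GA[t + 1, y] <- GA[t + 1, y] + sum(a_prev * seg_sc)
        GH[t + 1, y] <- GH[t + 1, y] + sum((h_prev + a_prev * f_seg) * seg_sc)
      }
      mx <- max(max(GA[t + 1, ]), a0[t + 1])
      if (!is.finite(mx))
        stop_degenerate("naive gradient recursion overflowed; potentials too ",
                        "large for linear-space scaling (use gradients_fast)")
      if (mx > 1e150) {                 # rescale to avoid overflow
        GA <- GA / mx; GH <- GH / mx; a0 <- a0 / mx; h0 <- h0 / mx
        scale_log <- scale_log + log(mx)
      }
    }
    z <- a0[T + 1] + sum(GA[T + 1, ])
    num <- h0[T + 1] + sum(GH[T + 1, ])
    eg <- num / z
    if (wi$block == "w_tr") g$w_tr[wi$i, wi$j] <- obs$w_tr[wi$i, wi$j] - eg
    else if (wi$block == "w_d") g$w_d[wi$i] <- obs$w_d[wi$i] - eg
    else g$w_o[wi$i, wi$j] <- obs$w_o[wi$i, wi$j] - eg
  }
  attr(g, "ops") <- ops
  g
}

#' Count weights of a semi-Markov CRF model
#' @param w `semicrf_params`
#' @return number of scalar weights N
#' @export
n_weights <- function(w) {
  length(w$w_tr) + length(w$w_d) + length(w$w_o)
}

#' Analytic operation counts for gradient computation
#'
#' Evaluates the asymptotic operation-count formulas for computing all `N`
#' gradients on a length-`T` sequence with `M` labels and maximum duration
#' `D`: `N*T*M^2*D` for the naive per-weight recursion versus
#' `3*T*M*(M+D) + N*T*D` for the shared forward-backward route.
#'
#' @param N number of weights, `T` sequence length, `M` labels, `D` maximum
#'   duration.
#' @param T,M,D see above.
#' @return list with `naive`, `fast` and their `ratio`.
#' @export
gradient_complexity <- function(N, T, M, D) {
  naive <- N * T * M^2 * D
  fast <- 3 * T * M * (M + D) + N * T * D
  list(naive = naive, fast = fast, ratio = naive / fast)
}
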