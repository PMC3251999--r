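# Null-activity-aware semi-Markov CRF.
#
# A labeling of an observation sequence x[1..T] is an ordered list of
# segments s_i = (y_i, b_i, e_i) with b[i+1] > e[i]; time steps covered by no
# segment ("gaps", including lead and trail) are scored with the inactivity
# (IA) observation weights. The probability of a segmentation S is
#   P(S | x) = exp(sum_i log psi(s_{i-1}, s_i)) / Z_x
# where log psi = Q_tr + Q_d + Q_o (transition, duration, observation
# potentials). The segmentation space includes the empty segmentation, whose
# score is the IA observation total over all T steps. All scoring is in log
# space; the forward/backward recursions use running accumulators over
# predecessor segments so that gap transitions cost O(M) instead of O(TM).

#' Create (zero-initialized) semi-Markov CRF parameters
#'
#' Weight containers for the three potentials: `w_tr` over ordered label
#' pairs (with a distinguished start row `"<s>"`), `w_d` per label, and
#' `w_o` over (label, symbol) pairs for the expected labels and the
#' inactivity label `"IA"`.
#'
#' @param labels character vector of M expected activity labels.
#' @param n_symbols observation alphabet size O (symbols are `1..O`).
#' @return object of class `semicrf_params`.
#' @export
semicrf_params <- function(labels, n_symbols) {
  labels <- as.character(labels)
  check_that(length(labels) >= 1, "need at least one expected label")
  check_that(!any(duplicated(labels)), "labels must be distinct")
  check_that(!"IA" %in% labels, "'IA' is reserved for the inactivity label")
  check_that(n_symbols >= 1, "n_symbols must be >= 1")
  M <- length(labels)
  structure(list(
    labels = labels, n_symbols = as.integer(n_symbols),
    w_tr = matrix(0, M + 1, M, dimnames = list(c(labels, "<s>"), labels)),
    w_d = setNames(rep(0, M), labels),
    w_o = matrix(0, M + 1, n_symbols, dimnames = list(c(labels, "IA"), NULL))
  ), class = "semicrf_params")
}

check_params <- function(w) {
  check_that(inherits(w, "semicrf_params"), "not a semicrf_params object")
  check_that(all(is.finite(w$w_tr)) && all(is.finite(w$w_d)) &&
             all(is.finite(w$w_o)), "weights must be finite")
  invisible(w)
}

check_obs <- function(x, w) {
  check_that(length(x) >= 1, "observation sequence must be non-empty")
  check_that(all(x >= 1 & x <= w$n_symbols & x == as.integer(x)),
             "symbols must be integers in 1..n_symbols")
  invisible(x)
}

stats_for <- function(stats, labels) {
  m <- stats$m[labels]; s2 <- stats$s2[labels]
  check_that(!any(is.na(m)) && !any(is.na(s2)),
             "duration stats missing for some label")
  list(m = unname(m), s2 = unname(s2))
}

q_duration <- function(w_d, d, m, s2) w_d * (d - m)^2 / (2 * s2)

#' Potentials of one semi-Markov transition
#'
#' Evaluates the transition, duration and observation potentials for moving
#' from segment `prev` (or the start of the sequence, `prev = NULL`) to
#' segment `cur`, including the inactivity observation terms for the gap
#' `prev$end + 1 .. cur$begin - 1` (an empty gap contributes 0).
#'
#' @param prev previous segment as list/row with `label`, `begin`, `end`, or
#'   `NULL` for the start of the sequence.
#' @param cur current segment (same form).
#' @param x integer observation sequence.
#' @param w `semicrf_params`.
#' @param stats `duration_stats` for the expected labels.
#' @return list with `Q_tr`, `Q_d`, `Q_o` and their sum `log_psi`.
#' @export
potentials <- function(prev, cur, x, w, stats) {
  check_params(w); check_obs(x, w)
  T <- length(x)
  yi <- match(cur$label, w$labels)
  check_that(!is.na(yi), "unknown label: ", cur$label)
  check_that(cur$begin >= 1 && cur$end <= T && cur$begin <= cur$end,
             "segment outside sequence")
  prev_end <- 0L
  if (!is.null(prev)) {
    check_that(prev$end < cur$begin, "segments must satisfy begin > prev end")
    prev_end <- prev$end
  }
  from <- if (is.null(prev)) nrow(w$w_tr) else match(prev$label, w$labels)
  check_that(!is.na(from), "unknown previous label")
  d <- cur$end - cur$begin + 1
  st <- stats_for(stats, w$labels)
  Q_tr <- w$w_tr[from, yi]
  Q_d <- q_duration(w$w_d[yi], d, st$m[yi], st$s2[yi])
  Q_o <- sum(w$w_o[yi, x[cur$begin:cur$end]])
  if (prev_end + 1 <= cur$begin - 1)
    Q_o <- Q_o + sum(w$w_o[nrow(w$w_o), x[(prev_end + 1):(cur$begin - 1)]])
  list(Q_tr = unname(Q_tr), Q_d = unname(Q_d), Q_o = unname(Q_o),
       log_psi = unname(Q_tr + Q_d + Q_o))
}

# Precomputed per-sequence quantities shared by all DP routines:
#  cia[t+1]  = sum_{u<=t} w_o[IA, x_u]        (gap scores as differences)
#  ce[y, t+1] = sum_{u<=t} w_o[y, x_u]        (segment emission scores)
#  qd[y, d]  = duration potential for duration d (d = 1..D)
semicrf_tables <- function(x, w, stats, D) {
  T <- length(x); M <- length(w$labels)
  st <- stats_for(stats, w$labels)
  wo <- unname(w$w_o)
  cia <- c(0, cumsum(wo[M + 1, x]))
  ce <- rbind(0, apply(matrix(wo[seq_len(M), x], nrow = M), 1, cumsum))
  if (M == 1) ce <- matrix(c(0, cumsum(wo[1, x])), ncol = 1)
  # ce is (T+1) x M: ce[t+1, y]
  Deff <- min(D, T)
  ds <- seq_len(Deff)
  qd <- vapply(seq_len(M), function(y)
    q_duration(w$w_d[y], ds, st$m[y], st$s2[y]), numeric(Deff))
  qd <- matrix(qd, nrow = Deff)  # Deff x M
  list(T = T, M = M, Deff = Deff, cia = cia, ce = ce, qd = qd,
       wtr = w$w_tr)
}

# Forward pass. Returns log alpha[e, y] (score mass of segmentations whose
# last segment ends at e with label y, everything up to e included), the
# prefix table (context mass strictly before each begin b), and log Z.
semicrf_forward <- function(tb) {
  T <- tb$T; M <- tb$M; D <- tb$Deff
  alpha <- matrix(-Inf, T, M)
  prefix <- matrix(-Inf, T, M)
  R <- rep(-Inf, M)           # accumulator over earlier segment ends
  ops <- 0L
  for (t in seq_len(T)) {
    if (t > 1) {
      add <- apply(alpha[t - 1, ] + tb$wtr[seq_len(M), , drop = FALSE], 2, logsumexp)
      R <- logaddexp(R, add - tb$cia[t])
      ops <- ops + M * M
    }
    prefix[t, ] <- logaddexp(tb$wtr[M + 1, ] + tb$cia[t], tb$cia[t] + R)
    dmax <- min(D, t)
    ds <- seq_len(dmax)
    bs <- t - ds + 1L
    for (y in seq_len(M)) {
      emit <- tb$ce[t + 1, y] - tb$ce[bs, y]
      alpha[t, y] <- logsumexp(prefix[bs, y] + tb$qd[ds, y] + emit)
      ops <- ops + dmax
    }
  }
  logZ <- logaddexp(tb$cia[T + 1],
                    logsumexp(alpha + (tb$cia[T + 1] - tb$cia[seq_len(T) + 1])))
  list(alpha = alpha, prefix = prefix, logZ = logZ, ops = ops)
}

# Backward pass. bwd[e, y]: score mass of all completions after a segment
# with label y ending at e (trailing gap included). segpost[b, y]: mass of a
# segment starting at b with label y, its emissions, duration potential and
# everything after it. U[b, y] = logsumexp_{b' >= b} (cia[b'] + segpost[b', y]).
semicrf_backward <- function(tb) {
  T <- tb$T; M <- tb$M; D <- tb$Deff
  bwd <- matrix(-Inf, T, M)
  segpost <- matrix(-Inf, T, M)
  U <- matrix(-Inf, T + 2, M)
  ops <- 0L
  for (e in T:0) {
    b <- e + 1L
    if (b <= T) {
      dmax <- min(D, T - b + 1L)
      ds <- seq_len(dmax)
      es <- b + ds - 1L
      for (y in seq_len(M)) {
        emit <- tb$ce[es + 1, y] - tb$ce[b, y]
        segpost[b, y] <- logsumexp(tb$qd[ds, y] + emit + bwd[cbind(es, y)])
        ops <- ops + dmax
      }
      U[b, ] <- logaddexp(U[b + 1, ], tb$cia[b] + segpost[b, ])
    }
    if (e >= 1) {
      cont <- apply(tb$wtr[seq_len(M), , drop = FALSE] +
                      matrix(U[e + 1, ], M, M, byrow = TRUE), 1, logsumexp)
      ops <- ops + M * M
      bwd[e, ] <- logaddexp(tb$cia[T + 1] - tb$cia[e + 1], cont - tb$cia[e + 1])
    }
  }
  logZ <- logaddexp(tb$cia[T + 1],
                    logsumexp(tb$wtr[M + 1, ] + U[1, ]))
  list(bwd = bwd, segpost = segpost, U = U, logZ = logZ, ops = ops)
}

#' Log partition function of the semi-Markov CRF
#'
#' Log of the sum of exponentiated potential totals over all valid
#' segmentations of `x` (the empty segmentation included, contributing the
#' all-gap inactivity score), computed by a forward recursion over
#' (end time, label, duration) in log space.
#'
#' @param x integer observation sequence (symbols `1..n_symbols`).
#' @param w `semicrf_params`.
#' @param stats `duration_stats`.
#' @param D maximum segment duration.
#' @return `log Z_x` (scalar).
#' @export
log_partition <- function(x, w, stats, D) {
  check_params(w); check_obs(x, w)
  check_that(D >= 1, "D must be >= 1")
  tb <- semicrf_tables(x, w, stats, D)
  semicrf_forward(tb)$logZ
}

# Sum of potentials along a segmentation (numerator of the likelihood),
# including lead/gap/trail IA observation terms.
segmentation_score <- function(s, x, w, stats, D) {
  T <- length(x)
  validate_segmentation(s, T)
  M <- length(w$labels)
  st <- stats_for(stats, w$labels)
  score <- 0
  prev <- NULL
  if (nrow(s)) for (i in seq_len(nrow(s))) {
    cur <- list(label = s$label[i], begin = s$begin[i], end = s$end[i])
    d <- cur$end - cur$begin + 1
    check_that(d <= D, "segment duration ", d, " exceeds maximum duration D = ", D)
    p <- potentials(prev, cur, x, w, stats)
    score <- score + p$log_psi
    prev <- cur
  }
  last_end <- if (nrow(s)) s$end[nrow(s)] else 0L
  if (last_end < T)
    score <- score + sum(w$w_o[M + 1, x[(last_end + 1):T]])
  score
}

#' Log likelihood of a segmentation
#'
#' `L(S|x) = score(S) - log Z_x`, where the score sums the transition,
#' duration and observation potentials along `S` (gap, lead and trail steps
#' scored with the IA observation weights). Always `<= 0`.
#'
#' @inheritParams log_partition
#' @param s a segmentation (data frame `label`, `begin`, `end`). Segment
#'   durations must not exceed `D`.
#' @return scalar log likelihood.
#' @export
log_likelihood <- function(s, x, w, stats, D) {
  check_params(w); check_obs(x, w)
  segmentation_score(s, x, w, stats, D) - log_partition(x, w, stats, D)
}

#' Maximum-probability segmentation (semi-Markov Viterbi)
#'
#' Finds the argmax-score segmentation by dynamic programming over
#' (end time, label, duration) with gap transitions. Exact score ties are
#' broken toward fewer segments, then toward the candidate reached first in
#' the deterministic scan order (end times ascending, durations ascending,
#' labels ascending), which prefers earlier begins and smaller label
#' indices.
#'
#' @inheritParams log_partition
#' @return a `semi_segmentation` with attribute `score` (the potential total
#'   of the decoded segmentation).
#' @export
infer <- function(x, w, stats, D) {
  check_params(w); check_obs(x, w)
  check_that(D >= 1, "D must be >= 1")
  tb <- semicrf_tables(x, w, stats, D)
  T <- tb$T; M <- tb$M; Dm <- tb$Deff
  better <- function(sc, ns, sc0, ns0)  # strict improvement under the tie-break
    sc > sc0 + 1e-12 || (abs(sc - sc0) <= 1e-12 && ns < ns0)
  V <- matrix(-Inf, T, M); Vn <- matrix(0L, T, M)
  # best context before begin b for label y: score, nseg, and backpointer
  pre <- matrix(-Inf, T, M); pre_n <- matrix(0L, T, M)
  pre_e <- matrix(0L, T, M); pre_y <- matrix(0L, T, M)  # 0,0 = START
  Racc <- rep(-Inf, M); Racc_n <- rep(0L, M)
  Racc_e <- rep(0L, M); Racc_y <- rep(0L, M)
  bk_d <- matrix(0L, T, M)
  for (t in seq_len(T)) {
    if (t > 1) {
      for (y in seq_len(M)) {
        cand <- V[t - 1, ] + tb$wtr[seq_len(M), y] - tb$cia[t]
        for (yp in seq_len(M)) {
          if (better(cand[yp], Vn[t - 1, yp] + 0L, Racc[y], Racc_n[y])) {
            Racc[y] <- cand[yp]; Racc_n[y] <- Vn[t - 1, yp]
            Racc_e[y] <- t - 1L; Racc_y[y] <- yp
          }
        }
      }
    }
    for (y in seq_len(M)) {
      s_start <- tb$wtr[M + 1, y] + tb$cia[t]
      s_cont <- tb$cia[t] + Racc[y]
      if (better(s_cont, Racc_n[y], s_start, 0L)) {
        pre[t, y] <- s_cont; pre_n[t, y] <- Racc_n[y]
        pre_e[t, y] <- Racc_e[y]; pre_y[t, y] <- Racc_y[y]
      } else {
        pre[t, y] <- s_start; pre_n[t, y] <- 0L
      }
    }
    dmax <- min(Dm, t)
    for (y in seq_len(M)) {
      for (d in seq_len(dmax)) {
        b <- t - d + 1L
        sc <- pre[b, y] + tb$qd[d, y] + tb$ce[t + 1, y] - tb$ce[b, y]
        if (better(sc, pre_n[b, y] + 1L, V[t, y], Vn[t, y])) {
          V[t, y] <- sc; Vn[t, y] <- pre_n[b, y] + 1L
          bk_d[t, y] <- d
        }
      }
    }
  }
  best_sc <- tb$cia[T + 1]; best_n <- 0L; best_e <- 0L; best_y <- 0L
  for (y in seq_len(M)) for (e in seq_len(T)) {
    sc <- V[e, y] + tb$cia[T + 1] - tb$cia[e + 1]
    if (better(sc, Vn[e, y], best_sc, best_n)) {
      best_sc <- sc; best_n <- Vn[e, y]; best_e <- e; best_y <- y
    }
  }
  segs <- list()
  e <- best_e; y <- best_y
  while (e > 0L) {
    d <- bk_d[e, y]
    b <- e - d + 1L
    segs[[length(segs) + 1L]] <- data.frame(
      label = w$labels[y], begin = b, end = e, stringsAsFactors = FALSE)
    ey <- c(pre_e[b, y], pre_y[b, y])
    e <- ey[1]; y <- ey[2]
  }
  out <- if (length(segs)) do.call(rbind, rev(segs)) else
    data.frame(label = character(), begin = integer(), end = integer(),
               stringsAsFactors = FALSE)
  res <- as_semi_segmentation(out, T)
  attr(res, "score") <- best_sc
  res
}

# Exhaustive enumeration of all valid segmentations (testing oracle and
# brute-force expectation machinery). Returns a list of data frames.
enumerate_segmentations <- function(T, labels, D) {
  check_that(T <= 12, "enumeration guarded to T <= 12")
  M <- length(labels)
  res <- list()
  recurse <- function(t, acc) {
    if (t > T) {
      res[[length(res) + 1L]] <<- acc
      return(invisible(NULL))
    }
    recurse(t + 1L, acc)                     # t is a gap
    for (d in seq_len(min(D, T - t + 1L))) {
      for (y in labels) {
        recurse(t + d, rbind(acc, data.frame(label = y, begin = t,
                                             end = t + d - 1L,
                                             stringsAsFactors = FALSE)))
      }
    }
  }
  empty <- data.frame(label = character(), begin = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  recurse(1L, empty)
  res
}
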