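# Potentials, partition function, likelihood and Viterbi decoding of the
# null-activity-aware semi-Markov CRF.

zero_model <- function(M = 1, O = 2) {
  labs <- letters[seq_len(M)]
  list(w = semicrf_params(labs, O),
       stats = structure(list(m = setNames(rep(1, M), labs),
                              s2 = setNames(rep(1, M), labs)),
                         class = "duration_stats"))
}

test_that("potentials follow the transition/duration/observation forms", {
  zm <- zero_model(2, 2)
  cur <- list(label = "a", begin = 3, end = 4)
  p0 <- potentials(NULL, cur, c(1L, 2L, 1L, 2L), zm$w, zm$stats)
  expect_equal(unlist(p0), c(Q_tr = 0, Q_d = 0, Q_o = 0, log_psi = 0))

  # d = m exactly: duration potential vanishes regardless of its weight
  w <- zm$w; w$w_d["a"] <- 5
  st <- structure(list(m = c(a = 2, b = 1), s2 = c(a = 1, b = 1)),
                  class = "duration_stats")
  expect_equal(potentials(NULL, cur, c(1L, 2L, 1L, 2L), w, st)$Q_d, 0)

  # hand-evaluated 2-label, 2-symbol instance with a gap of length 1:
  # prev = (a,1,2), cur = (b,4,5), x = (1,2,2,1,2)
  w2 <- semicrf_params(c("a", "b"), 2)
  w2$w_tr["a", "b"] <- 0.7
  w2$w_d["b"] <- 2
  w2$w_o["b", 1] <- 0.3; w2$w_o["b", 2] <- -0.1
  w2$w_o["IA", 2] <- 0.4
  st2 <- structure(list(m = c(a = 2, b = 3), s2 = c(a = 1, b = 2)),
                   class = "duration_stats")
  x <- c(1L, 2L, 2L, 1L, 2L)
  p <- potentials(list(label = "a", begin = 1, end = 2),
                  list(label = "b", begin = 4, end = 5), x, w2, st2)
  expect_equal(p$Q_tr, 0.7)
  expect_equal(p$Q_d, 2 * (2 - 3)^2 / (2 * 2))        # d = 2
  expect_equal(p$Q_o, 0.3 - 0.1 + 0.4)                # x4, x5 for b; gap x3 IA
  expect_equal(p$log_psi, p$Q_tr + p$Q_d + p$Q_o)

  expect_error(potentials(list(label = "a", begin = 1, end = 4),
                          list(label = "b", begin = 4, end = 5), x, w2, st2),
               class = "harkit_contract_error")
})

test_that("log partition counts segmentations exactly at zero weights", {
  zm <- zero_model(1, 1)
  # T = 2, M = 1, D = 2: empty, (y,1,1), (y,2,2), (y,1,2), {(y,1,1),(y,2,2)}
  expect_equal(log_partition(c(1L, 1L), zm$w, zm$stats, D = 2), log(5),
               tolerance = 1e-12)
  expect_equal(log_partition(1L, zm$w, zm$stats, D = 1), log(2),
               tolerance = 1e-12)
})

test_that("partition, likelihood and decoding agree with enumeration", {
  set.seed(20)
  for (i in 1:25) {
    inst <- random_scrf_instance()
    bf <- bf_log_partition(inst)
    expect_equal(log_partition(inst$x, inst$w, inst$stats, inst$D), bf$logZ,
                 tolerance = 1e-9)
    # likelihood of a random valid segmentation, and normalization
    s <- bf$all[[sample(length(bf$all), 1)]]
    L <- log_likelihood(s, inst$x, inst$w, inst$stats, inst$D)
    expect_lte(L, 1e-12)
    expect_equal(L, harkit:::segmentation_score(s, inst$x, inst$w, inst$stats,
                                                inst$D) - bf$logZ,
                 tolerance = 1e-9)
    # Viterbi equals the brute-force argmax score
    v <- infer(inst$x, inst$w, inst$stats, inst$D)
    expect_equal(attr(v, "score"), max(bf$scores), tolerance = 1e-9)
  }
})

test_that("exp(log likelihood) sums to one over all segmentations", {
  set.seed(21)
  inst <- random_scrf_instance(M = 2, Tn = 4, D = 2, O = 2)
  bf <- bf_log_partition(inst)
  tot <- sum(vapply(bf$all, function(s)
    exp(log_likelihood(s, inst$x, inst$w, inst$stats, inst$D)), numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-9)
  # zero weights: L = -log(#segmentations)
  zm <- zero_model(1, 1)
  s0 <- data.frame(label = "a", begin = 1L, end = 2L)
  expect_equal(log_likelihood(s0, c(1L, 1L), zm$w, zm$stats, D = 2), -log(5),
               tolerance = 1e-12)
})

test_that("decoding honors dominance and canonical tie-breaks", {
  labs <- c("a", "b")
  w <- semicrf_params(labs, 2)
  st <- structure(list(m = c(a = 3, b = 3), s2 = c(a = 1, b = 1)),
                  class = "duration_stats")
  # strongly favor exactly segment (b, 2, 4)
  w$w_o["b", 1] <- 10; w$w_o["IA", 2] <- 5
  x <- c(2L, 1L, 1L, 1L, 2L)
  v <- infer(x, w, st, D = 3)
  expect_equal(v$label, "b")
  expect_equal(v$begin, 2L)
  expect_equal(v$end, 4L)
  # zero weights: the empty segmentation is the canonical tie-break winner
  zw <- semicrf_params(labs, 2)
  v0 <- infer(x, zw, st, D = 3)
  expect_equal(nrow(v0), 0)
  expect_identical(v0, infer(x, zw, st, D = 3))   # stable across runs
  # truth outside model support
  expect_error(log_likelihood(data.frame(label = "a", begin = 1L, end = 4L),
                              x, zw, st, D = 2),
               class = "harkit_contract_error")
})
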