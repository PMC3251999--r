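# ICA motion features, vector quantization and the per-activity HMM bank.

test_that("motion basis fitting respects rank and retains variance", {
  static <- silhouette_sequence(rep(list(matrix(TRUE, 10, 8)), 5))
  expect_error(fit_motion_basis(list(static), k = 2),
               class = c("harkit_contract_error"))

  wave <- make_silhouette_video("wave", n_frames = 24, seed = 3, dim = c(40, 30))
  basis <- fit_motion_basis(list(wave), k = 6, seed = 1)
  expect_equal(nrow(basis$components), 6)

  # project-then-reconstruct retains >= 80% of the difference variance
  X <- harkit:::frame_differences(wave)
  Xc <- sweep(X, 2, colMeans(X))
  feats <- Xc %*% t(basis$components)
  pinv <- with(svd(basis$components), v %*% diag(1 / d) %*% t(u))
  Xhat <- feats %*% t(pinv)
  expect_gte(sum(Xhat^2) / sum(Xc^2), 0.8)
})

test_that("feature projection is an explicit linear map", {
  wave <- make_silhouette_video("wave", n_frames = 12, seed = 4, dim = c(40, 30))
  basis <- fit_motion_basis(list(wave), k = 4, seed = 1)
  f <- project_features(wave, basis)
  expect_equal(dim(f), c(length(wave$frames) - 1, 4))
  # equals the direct dot-product oracle
  X <- harkit:::frame_differences(wave)
  expect_equal(f, X %*% t(basis$components), tolerance = 1e-12)
  # a static sequence projects to exactly zero
  static <- silhouette_sequence(rep(list(wave$frames[[1]]), 6))
  expect_true(all(project_features(static, basis) == 0))
  # frame-size mismatch
  small <- make_silhouette_video("wave", n_frames = 6, seed = 4, dim = c(20, 16))
  expect_error(project_features(small, basis), class = "harkit_contract_error")
})

test_that("codebook construction is seeded k-means with exact contracts", {
  set.seed(5)
  feats <- matrix(rnorm(60), 20, 3)
  cb1 <- build_codebook(feats, K = 1, seed = 2)
  expect_equal(cb1$centroids, matrix(colMeans(feats), 1), tolerance = 1e-12)

  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  pts <- centers[rep(1:3, each = 30), ] + matrix(rnorm(180, 0, 0.3), 90, 2)
  cb3 <- build_codebook(pts, K = 3, seed = 2)
  ord <- apply(cb3$centroids, 1, function(c_) which.min(colSums((t(centers) - c_)^2)))
  expect_setequal(ord, 1:3)
  expect_lt(max(abs(cb3$centroids - centers[ord, ])), 0.2)

  expect_identical(build_codebook(pts, K = 3, seed = 2)$centroids, cb3$centroids)
  expect_error(build_codebook(matrix(1, 5, 2), K = 2),
               class = "harkit_contract_error")
})

test_that("quantization is nearest-centroid with lowest-index ties", {
  cb <- structure(list(centroids = rbind(c(0, 0), c(4, 0), c(2, 0)), K = 3),
                  class = "codebook")
  expect_equal(as.integer(quantize(rbind(c(4, 0)), cb)), 2L)
  # exact tie between centroids 1 and 3 at x = 1: both at distance 1
  expect_equal(as.integer(quantize(rbind(c(1, 0)), cb)), 1L)
  set.seed(6)
  f <- matrix(rnorm(40), 20, 2)
  q <- as.integer(quantize(f, cb))
  brute <- apply(f, 1, function(v)
    which.min(apply(cb$centroids, 1, function(c_) sum((v - c_)^2))))
  expect_equal(q, brute)
  expect_error(quantize(matrix(1, 2, 3), cb), class = "harkit_contract_error")
})

test_that("Baum-Welch training yields stochastic rows and monotone likelihood", {
  # degenerate corpus: one repeated symbol, one state
  m1 <- train_hmm(list(rep(2L, 30)), n_states = 1, n_symbols = 3, seed = 1)
  expect_gte(m1$emissions[1, 2], 0.99)

  set.seed(7)
  seqs <- replicate(4, sample.int(5, 40, replace = TRUE), simplify = FALSE)
  m <- train_hmm(seqs, n_states = 3, n_symbols = 5, seed = 2)
  expect_equal(rowSums(m$transitions), rep(1, 3), tolerance = 1e-9)
  expect_equal(rowSums(m$emissions), rep(1, 3), tolerance = 1e-9)
  expect_equal(sum(m$initial), 1, tolerance = 1e-9)
  tr <- attr(m, "loglik_trace")
  expect_true(all(diff(tr) >= -1e-8))
  expect_error(train_hmm(list(), n_states = 2), class = "harkit_contract_error")
})

test_that("forward likelihood equals exhaustive path enumeration", {
  m <- discrete_hmm(initial = c(0.6, 0.4),
                    transitions = rbind(c(0.7, 0.3), c(0.2, 0.8)),
                    emissions = rbind(c(0.9, 0.1), c(0.3, 0.7)))
  x <- c(1L, 2L, 2L, 1L, 2L)
  paths <- as.matrix(expand.grid(rep(list(1:2), 5)))
  p_bf <- sum(apply(paths, 1, function(z) {
    p <- m$initial[z[1]] * m$emissions[z[1], x[1]]
    for (t in 2:5) p <- p * m$transitions[z[t - 1], z[t]] * m$emissions[z[t], x[t]]
    p
  }))
  expect_equal(harkit:::hmm_forward(x, m), log(p_bf), tolerance = 1e-10)
  expect_error(harkit:::hmm_forward(c(1L, 3L), m), class = "harkit_contract_error")
})

test_that("the activity bank classifies, breaks ties and flags Unknown", {
  m <- discrete_hmm(1, matrix(1), matrix(c(0.5, 0.5), 1))
  bank1 <- activity_bank(list(walk = m), unknown_threshold = -Inf)
  expect_equal(classify_activity(c(1L, 2L), bank1)$label, "walk")
  # exact tie between two identical models: lexicographic label order
  bank2 <- activity_bank(list(b = m, a = m), unknown_threshold = -Inf)
  expect_equal(classify_activity(c(1L, 2L), bank2)$label, "a")

  # held-out accuracy on the 3-class silhouette corpus
  pred <- vapply(video_test, function(s) classify_sequence(s, video_clf)$label,
                 character(1))
  truth <- vapply(video_test, function(s) s$label, character(1))
  expect_gte(mean(pred == truth), 0.9)

  # a symbol stream cycling through the whole codebook is no one activity
  noise <- rep(seq_len(video_clf$codebook$K), 3)
  expect_equal(classify_activity(noise, video_clf$bank)$label, "Unknown")
})

test_that("quantization is stable under codebook permutation with relabeling", {
  set.seed(8)
  f <- matrix(rnorm(30), 15, 2)
  cb <- build_codebook(f, K = 4, seed = 3)
  q <- as.integer(quantize(f, cb))
  perm <- c(3, 1, 4, 2)
  cb2 <- structure(list(centroids = cb$centroids[perm, ], K = 4),
                   class = "codebook")
  q2 <- as.integer(quantize(f, cb2))
  expect_equal(perm[q2], q)
})
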