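# Motion features for silhouette videos.
#
# A silhouette sequence is a list of binary frames of fixed size. Motion is
# captured by vectorized consecutive-frame differences; an ICA basis
# (FastICA with PCA whitening, symmetric decorrelation, tanh contrast —
# implemented here) extracts k statistically independent motion components,
# whose projections are quantized against a k-means codebook into the
# discrete symbols consumed by the per-activity HMMs.

#' Construct a silhouette sequence
#'
#' @param frames list of logical/0-1 matrices of identical size (>= 2).
#' @param label optional activity label.
#' @return object of class `silhouette_sequence`.
#' @export
silhouette_sequence <- function(frames, label = NULL) {
  check_that(length(frames) >= 2, "need at least 2 frames")
  d <- dim(frames[[1]])
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    check_that(all(dim(f) == d), "all frames must share one size")
    f > 0.5
  })
  structure(list(frames = frames, label = label, dim = d),
            class = "silhouette_sequence")
}

#' Resize a silhouette frame by nearest neighbor and re-binarize
#'
#' @param frame logical/numeric matrix.
#' @param dim target `c(rows, cols)` (default `c(70, 100)`).
#' @return logical matrix of the target size.
#' @export
resize_silhouette <- function(frame, dim = c(70, 100)) {
  r <- pmin(pmax(round(seq(1, nrow(frame), length.out = dim[1])), 1), nrow(frame))
  c_ <- pmin(pmax(round(seq(1, ncol(frame), length.out = dim[2])), 1), ncol(frame))
  frame[r, c_, drop = FALSE] > 0.5
}

frame_differences <- function(seq) {
  fr <- seq$frames
  t(vapply(seq_len(length(fr) - 1), function(i)
    as.vector(fr[[i + 1]]) - as.vector(fr[[i]]),
    numeric(length(fr[[1]]))))
}

#' Fit an ICA motion basis from training silhouette sequences
#'
#' Collects vectorized consecutive-frame differences from all training
#' sequences, centers them, whitens with PCA, and runs FastICA (tanh
#' contrast, symmetric decorrelation) to extract `k` independent motion
#' components. Deterministic given `seed`.
#'
#' @param training list of `silhouette_sequence` objects.
#' @param k number of components (default 10); must not exceed the rank of
#'   the centered difference matrix.
#' @param seed RNG seed for the FastICA initialization.
#' @param max_iter,tol FastICA iteration controls.
#' @return object of class `motion_basis`: `components` (k x p unmixing in
#'   pixel space), `mean` (centering vector), `k`, and the whitening
#'   summary used for variance accounting.
#' @export
fit_motion_basis <- function(training, k = 10, seed = 1,
                             max_iter = 200, tol = 1e-6) {
  if (inherits(training, "silhouette_sequence")) training <- list(training)
  X <- do.call(rbind, lapply(training, frame_differences))
  check_that(nrow(X) >= k + 1, "need at least k+1 difference vectors")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  rank <- sum(sv$d > max(sv$d) * 1e-8)
  if (rank < 1) stop_contract("all frame differences are zero (static video)")
  check_that(k <= rank, "k = ", k, " exceeds data rank ", rank)
  dkeep <- sv$d[seq_len(k)]
  V <- sv$v[, seq_len(k), drop = FALSE]
  # whitening: z = diag(sqrt(n-1)/d) V' (x - mu)
  Kw <- sweep(t(V), 1, sqrt(nrow(X) - 1) / dkeep, `*`)
  Z <- Xc %*% t(Kw)
  W <- with_seed(seed, {
    W0 <- matrix(rnorm(k * k), k, k)
    fastica_symmetric(Z, W0, max_iter, tol)
  })
  comp <- W %*% Kw                       # k x p: sources = comp %*% (x - mu)
  structure(list(components = comp, mean = mu, k = k,
                 sv_d = sv$d, n = nrow(X), rank = rank),
            class = "motion_basis")
}

# FastICA with symmetric decorrelation and tanh contrast on whitened data Z
# (n x k). Returns the k x k rotation W with unit-norm decorrelated rows.
fastica_symmetric <- function(Z, W, max_iter, tol) {
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  n <- nrow(Z)
  for (i in seq_len(max_iter)) {
    U <- Z %*% t(W)                      # n x k source estimates
    G <- tanh(U)
    Gp <- 1 - G^2
    W_new <- t(G) %*% Z / n - diag(colMeans(Gp), nrow = ncol(W)) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tol) break
  }
  W
}

#' Project a silhouette sequence onto a motion basis
#'
#' Features are the raw projections of the frame differences onto the ICA
#' unmixing directions (`X %*% t(components)`); the training mean enters
#' the whitening fit only, so a static sequence (all-zero differences)
#' projects to exactly zero.
#'
#' @param seq `silhouette_sequence` whose frame size matches the basis.
#' @param basis `motion_basis` from [fit_motion_basis()].
#' @return (T-1) x k feature matrix, one row per consecutive frame pair.
#' @export
project_features <- function(seq, basis) {
  X <- frame_differences(seq)
  check_that(ncol(X) == ncol(basis$components),
             "frame size does not match the basis dimensionality")
  X %*% t(basis$components)
}

#' Build a vector-quantization codebook by k-means
#'
#' @param features numeric feature matrix (rows = vectors).
#' @param K codebook size; must not exceed the number of distinct vectors.
#' @param seed RNG seed (k-means is deterministic given the seed).
#' @return object of class `codebook` with `centroids` (K x k) and `K`.
#' @export
build_codebook <- function(features, K = 16, seed = 1) {
  features <- as.matrix(features)
  ndistinct <- nrow(unique(features))
  check_that(K >= 1, "K must be >= 1")
  check_that(K <= ndistinct, "K = ", K, " exceeds ", ndistinct,
             " distinct feature vectors")
  centroids <- if (K == 1) {
    matrix(colMeans(features), 1)
  } else {
    km <- with_seed(seed, kmeans(features, centers = K, nstart = 5,
                                 iter.max = 100))
    km$centers
  }
  rownames(centroids) <- NULL
  structure(list(centroids = centroids, K = K), class = "codebook")
}

#' Quantize feature vectors to codebook symbols
#'
#' Nearest centroid (Euclidean) per row; exact distance ties are broken
#' toward the lowest centroid index.
#'
#' @param features feature matrix (columns must match the codebook).
#' @param codebook `codebook`.
#' @return integer vector of symbols in `1..K` (class `symbol_sequence`).
#' @export
quantize <- function(features, codebook) {
  features <- as.matrix(features)
  check_that(ncol(features) == ncol(codebook$centroids),
             "feature dimensionality does not match the codebook")
  cc <- codebook$centroids
  # squared distances: ||f||^2 - 2 f.c + ||c||^2; which.min takes the first
  # (lowest-index) minimum, giving the documented tie-break
  d2 <- outer(rowSums(features^2), rep(1, nrow(cc))) -
    2 * features %*% t(cc) +
    outer(rep(1, nrow(features)), rowSums(cc^2))
  structure(apply(round(d2, 12), 1, which.min), class = "symbol_sequence")
}
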