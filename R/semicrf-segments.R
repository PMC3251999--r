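# Segment-level encoding of per-sample label sequences.
#
# A semi-Markov state is a labeled segment (y, b, e) with 1-based inclusive
# begin/end times. Null activities (activities present in the data but not
# targeted for recognition) are removed from the encoding, so consecutive
# segments satisfy the relaxed constraint b[i+1] > e[i]: gaps are legal and
# carry the inactivity (IA) observation weight during scoring.

#' Encode a per-sample label sequence as semi-Markov segments
#'
#' Maximal runs of each non-null label become segments `(label, begin, end)`
#' with 1-based inclusive times; runs of null labels become gaps. An
#' all-null sequence encodes to an empty segmentation.
#'
#' @param labels vector (character, factor or integer) of per-sample labels.
#' @param null_labels labels to treat as null activities (dropped from the
#'   encoding, leaving gaps). Default none.
#' @return A `semi_segmentation`: a data frame with columns `label`, `begin`,
#'   `end`, ordered with `begin[i+1] > end[i]`, plus attribute `T` (sequence
#'   length).
#' @examples
#' encode_segments(c(1, 1, 2, 2, 2, 3, 4, 4))
#' encode_segments(c("eating", "eating", "cleaning", "cleaning",
#'                   "having tea", "having tea"), null_labels = "cleaning")
#' @seealso [decode_segments()] for the inverse.
#' @export
encode_segments <- function(labels, null_labels = character()) {
  check_that(length(labels) >= 1, "labels must be non-empty")
  labels <- as.character(labels)
  r <- rle(as.vector(labels))
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  keep <- !(r$values %in% null_labels)
  seg <- data.frame(label = r$values[keep],
                    begin = begins[keep], end = ends[keep],
                    stringsAsFactors = FALSE)
  rownames(seg) <- NULL
  structure(seg, T = length(labels), class = c("semi_segmentation", "data.frame"))
}

#' Expand a semi-Markov segmentation back to a per-sample label sequence
#'
#' Inverse of [encode_segments()]: gap samples (times covered by no segment)
#' receive the inactivity label `ia_label`. `encode_segments(decode_segments(s))`
#' recovers `s` whenever segment labels differ from `ia_label`.
#'
#' @param segments a `semi_segmentation` or data frame with `label`, `begin`,
#'   `end` (1-based inclusive).
#' @param T sequence length; defaults to the segmentation's `T` attribute.
#' @param ia_label label used for gap samples (default `"IA"`).
#' @return vector of length `T` of per-sample labels.
#' @export
decode_segments <- function(segments, T = attr(segments, "T"), ia_label = "IA") {
  check_that(!is.null(T) && T >= 0, "sequence length T required")
  validate_segmentation(segments, T)
  out <- rep(ia_label, T)
  if (nrow(segments)) {
    for (i in seq_len(nrow(segments)))
      out[segments$begin[i]:segments$end[i]] <- segments$label[i]
  }
  if (is.numeric(segments$label) && nrow(segments) && !is.numeric(ia_label))
    out else out
}

validate_segmentation <- function(segments, T) {
  check_that(all(c("label", "begin", "end") %in% names(segments)),
             "segmentation needs columns label, begin, end")
  if (!nrow(segments)) return(invisible(TRUE))
  b <- segments$begin; e <- segments$end
  check_that(all(b >= 1) && all(e <= T), "segment outside [1, T]")
  check_that(all(b <= e), "segment with end < begin")
  if (nrow(segments) > 1)
    check_that(all(b[-1] > e[-nrow(segments)]),
               "segments must be ordered with begin[i+1] > end[i]")
  invisible(TRUE)
}

as_semi_segmentation <- function(df, T) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  validate_segmentation(df, T)
  structure(df, T = T, class = c("semi_segmentation", "data.frame"))
}

#' Per-label duration statistics from training segmentations
#'
#' Sample mean and (population) variance of segment durations
#' `d = end - begin + 1` per label, used by the duration potential. Variances
#' are floored at 0.25 so that labels with constant observed duration do not
#' produce an infinite potential.
#'
#' @param corpus a list of segmentations (each a data frame `label`, `begin`,
#'   `end`), or a single segmentation.
#' @param labels optional label universe; labels never seen in a segment get
#'   the default (`m = 1`, `s2 = 0.25`) with a warning.
#' @return object of class `duration_stats`: list with named numeric vectors
#'   `m` and `s2`.
#' @export
duration_stats <- function(corpus, labels = NULL) {
  if (is.data.frame(corpus)) corpus <- list(corpus)
  lab <- unlist(lapply(corpus, function(s) as.character(s$label)))
  dur <- unlist(lapply(corpus, function(s) s$end - s$begin + 1))
  if (is.null(labels)) labels <- sort(unique(lab))
  labels <- as.character(labels)
  m <- setNames(rep(1, length(labels)), labels)
  s2 <- setNames(rep(0.25, length(labels)), labels)
  for (y in labels) {
    d <- dur[lab == y]
    if (!length(d)) {
      warning("label '", y, "' unseen in training segments; using defaults")
      next
    }
    m[y] <- mean(d)
    s2[y] <- max(mean((d - mean(d))^2), 0.25)  # population convention, floored
  }
  structure(list(m = m, s2 = s2), class = "duration_stats")
}

#' Segment-level F1 between a decoded and a true segmentation
#'
#' Greedy 1-to-1 matching of decoded to true segments with equal label and
#' segment-overlap IoU at least `min_iou` (the usual activity-recognition
#' segment-matching rule); returns precision, recall and F1 over the
#' matched counts. A list of (pred, truth) pairs is pooled.
#'
#' @param pred,truth segmentations (data frames `label`, `begin`, `end`),
#'   or lists of them (pooled).
#' @param min_iou minimum overlap-over-union for a match (default 0.5).
#' @return list with `f1`, `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
segment_f1 <- function(pred, truth, min_iou = 0.5) {
  if (is.data.frame(pred)) { pred <- list(pred); truth <- list(truth) }
  check_that(length(pred) == length(truth), "pred/truth length mismatch")
  tp <- fp <- fn <- 0
  for (k in seq_along(pred)) {
    p <- pred[[k]]; s <- truth[[k]]
    used <- rep(FALSE, nrow(s)); m <- 0
    for (i in seq_len(nrow(p))) {
      for (j in which(!used)) {
        if (p$label[i] == s$label[j]) {
          inter <- max(0, min(p$end[i], s$end[j]) - max(p$begin[i], s$begin[j]) + 1)
          uni <- max(p$end[i], s$end[j]) - min(p$begin[i], s$begin[j]) + 1
          if (inter / uni >= min_iou) { used[j] <- TRUE; m <- m + 1; break }
        }
      }
    }
    tp <- tp + m; fp <- fp + nrow(p) - m; fn <- fn + nrow(s) - m
  }
  list(f1 = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
       precision = if (tp + fp == 0) 1 else tp / (tp + fp),
       recall = if (tp + fn == 0) 1 else tp / (tp + fn),
       tp = tp, fp = fp, fn = fn)
}

# ---- windowed feature extraction for wearable signals ----------------------

#' Effective sampling rate after mean-windowing
#'
#' Averaging a raw signal over non-overlapping windows of `mean_window_s`
#' seconds yields one sample per window, i.e. a rate of `1 / mean_window_s`.
#' A 100 Hz accelerometer averaged over 0.4 s windows becomes a 2.5 Hz
#' stream.
#'
#' @param raw_hz raw sampling rate in Hz (informational; the result depends
#'   only on the window length).
#' @param mean_window_s averaging-window length in seconds.
#' @return effective rate in Hz.
#' @export
effective_sampling_rate <- function(raw_hz, mean_window_s) {
  check_that(mean_window_s > 0, "mean_window_s must be positive")
  check_that(raw_hz * mean_window_s >= 1,
             "window must contain at least one raw sample")
  1 / mean_window_s
}

#' Time span of an n-sample window in minutes
#'
#' @param n window length in samples.
#' @param rate_hz sampling rate in Hz.
#' @return span in minutes (e.g. 512 samples at 2.5 Hz is about 3.41 min).
#' @export
window_span_minutes <- function(n, rate_hz) {
  check_that(n >= 1 && rate_hz > 0, "need n >= 1 and rate_hz > 0")
  n / rate_hz / 60
}

#' Sliding-window features for multi-axis sensor signals
#'
#' Slides a window of `window` samples with fractional `overlap` along each
#' axis and extracts per-axis mean, standard deviation and mean-crossing
#' rate (number of sign changes of the mean-removed window divided by the
#' window length), plus the mid-window time stamp.
#'
#' @param signal numeric vector, matrix or data frame (columns = axes).
#' @param window window length in samples (default 512).
#' @param overlap fraction of overlap between consecutive windows in
#'   `[0, 1)`; default 0.5 (the stride is `window * (1 - overlap)`).
#' @param times optional per-sample time stamps (defaults to 1..T).
#' @return matrix with one row per window: columns `time` (mid-window) and,
#'   per axis, `mean`, `sd`, `mcr`.
#' @export
extract_window_features <- function(signal, window = 512, overlap = 0.5,
                                    times = NULL) {
  if (is.data.frame(signal)) signal <- as.matrix(signal)
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1)
  T <- nrow(signal)
  check_that(T >= window, "signal shorter than one window")
  check_that(overlap >= 0 && overlap < 1, "overlap must be in [0, 1)")
  stride <- max(1L, as.integer(round(window * (1 - overlap))))
  starts <- seq.int(1L, T - window + 1L, by = stride)
  if (is.null(times)) times <- seq_len(T)
  ax <- if (!is.null(colnames(signal))) colnames(signal)
        else paste0("a", seq_len(ncol(signal)))
  out <- matrix(NA_real_, length(starts), 1 + 3 * ncol(signal),
                dimnames = list(NULL, c("time",
                  as.vector(t(outer(ax, c("mean", "sd", "mcr"), paste, sep = "_"))))))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + window - 1L)
    out[i, "time"] <- mean(times[range(idx)])
    for (j in seq_len(ncol(signal))) {
      w <- signal[idx, j]
      mu <- mean(w)
      centered <- w - mu
      s <- sign(centered)
      s <- s[s != 0]
      ncross <- if (length(s) > 1) sum(s[-1] != s[-length(s)]) else 0L
      out[i, 1 + 3 * (j - 1) + 1] <- mu
      out[i, 1 + 3 * (j - 1) + 2] <- sqrt(mean(centered^2) * window / max(window - 1, 1))
      out[i, 1 + 3 * (j - 1) + 3] <- ncross / window
    }
  }
  out
}
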