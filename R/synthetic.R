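# Seeded synthetic fixtures with ground truth, one generator per consumer:
# inhomogeneous body images for the segmenter, periodic silhouette videos
# for the HMM classifier, label-segmented symbol sequences for the
# semi-Markov CRF, and scripted event streams for the rule engine. Identical
# parameters and seed reproduce byte-identical output; no generator touches
# the network or disk.

draw_ellipse <- function(dim, cy, cx, ry, rx) {
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  c_ <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  ((r - cy) / ry)^2 + ((c_ - cx) / rx)^2 <= 1
}

body_mask <- function(dim, scale, cy, cx) {
  torso <- draw_ellipse(dim, cy + 0.12 * dim[1] * scale, cx,
                        0.28 * dim[1] * scale, 0.16 * dim[2] * scale)
  head <- draw_ellipse(dim, cy - 0.22 * dim[1] * scale, cx,
                       0.10 * dim[1] * scale, 0.12 * dim[2] * scale)
  torso | head
}

#' Synthetic inhomogeneous body image with ground truth
#'
#' A body-shaped blob (torso plus head) whose interior mixes two foreground
#' intensities — the upper and lower parts of the body take different
#' values, emulating skin versus clothing — over a constant background,
#' plus i.i.d. Gaussian pixel noise (clamped to `[0, 1]`). The blob is
#' scaled by bisection so the true mask covers `area_frac` of the grid. The
#' default intensities straddle the background, which makes the region
#' means nearly uninformative while the region histograms remain well
#' separated.
#'
#' @param w,h image width and height in pixels.
#' @param fg_intensities the two foreground intensities.
#' @param bg_intensity background intensity (distinct from both).
#' @param noise_sigma Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @param area_frac target foreground area fraction (default 0.25).
#' @return list with `image` (`intensity_image`) and `mask` (logical truth).
#' @export
make_body_image <- function(w = 64, h = 64, fg_intensities = c(0.2, 0.9),
                            bg_intensity = 0.5, noise_sigma = 0.03,
                            seed = 1, area_frac = 0.25) {
  check_that(length(fg_intensities) == 2 &&
               all(abs(fg_intensities - bg_intensity) > 1e-6),
             "foreground intensities must differ from the background")
  check_that(area_frac > 0 && area_frac < 0.9, "area_frac out of range")
  dim <- c(h, w)
  cy <- h / 2; cx <- w / 2
  lo <- 0.1; hi <- 3
  for (i in 1:40) {                       # bisection on the blob scale
    mid <- (lo + hi) / 2
    frac <- mean(body_mask(dim, mid, cy, cx))
    if (frac < area_frac) lo <- mid else hi <- mid
  }
  mask <- body_mask(dim, (lo + hi) / 2, cy, cx)
  img <- matrix(bg_intensity, h, w)
  split_row <- cy - 0.05 * h              # head/shoulders vs torso
  rows <- matrix(seq_len(h), h, w)
  img[mask & rows < split_row] <- fg_intensities[1]
  img[mask & rows >= split_row] <- fg_intensities[2]
  img <- with_seed(seed, img + rnorm(length(img), 0, noise_sigma))
  img <- pmin(pmax(img, 0), 1)
  list(image = intensity_image(matrix(img, h, w)), mask = mask)
}

#' Synthetic silhouette video of a periodic activity
#'
#' Binary frames of a schematic person whose deformation pattern is
#' class-specific: `"wave"` oscillates an arm, `"jump"` translates the body
#' vertically, `"bend"` shears the upper body sideways, `"walk"` translates
#' horizontally with alternating leg spread, `"static"` does not move.
#' Phase and frequency jitter are drawn from the seed, so two sequences of
#' the same kind differ while remaining separable from other kinds.
#'
#' @param activity_kind one of `"wave"`, `"jump"`, `"bend"`, `"walk"`,
#'   `"static"`.
#' @param n_frames number of frames (>= 2).
#' @param seed RNG seed.
#' @param dim frame size `c(rows, cols)`, default `c(100, 70)`.
#' @return labeled `silhouette_sequence`.
#' @export
make_silhouette_video <- function(activity_kind, n_frames = 20, seed = 1,
                                  dim = c(100, 70)) {
  kinds <- c("wave", "jump", "bend", "walk", "static")
  check_that(activity_kind %in% kinds,
             "unknown activity kind: ", activity_kind)
  check_that(n_frames >= 2, "need at least 2 frames")
  with_seed(seed, {
    phase <- runif(1, 0, 2 * pi)
    freq <- runif(1, 0.95, 1.05) * 2 * pi / 10
    frames <- lapply(seq_len(n_frames), function(t) {
      osc <- sin(freq * t + phase)
      cy <- dim[1] * 0.45; cx <- dim[2] * 0.5
      lean <- 0; legs <- 0
      if (activity_kind == "jump") cy <- cy + 0.08 * dim[1] * osc
      if (activity_kind == "walk") {
        cx <- cx + 0.06 * dim[2] * osc
        legs <- abs(osc)
      }
      if (activity_kind == "bend") lean <- 0.25 * osc
      torso <- draw_ellipse(dim, cy + 0.10 * dim[1], cx,
                            0.22 * dim[1], 0.10 * dim[2])
      head <- draw_ellipse(dim, cy - 0.18 * dim[1], cx + lean * 0.3 * dim[2],
                           0.07 * dim[1], 0.08 * dim[2])
      f <- torso | head
      if (lean != 0) {                       # shear the upper half
        top <- seq_len(floor(cy))
        shift <- round(lean * (cy - top))
        for (r in top) {
          row <- f[r, ]
          f[r, ] <- FALSE
          idx <- which(row) + shift[r]
          idx <- idx[idx >= 1 & idx <= dim[2]]
          f[r, idx] <- TRUE
        }
      }
      if (activity_kind == "wave") {         # oscillating arm
        ang <- pi / 3 * osc
        ay <- cy - 0.02 * dim[1]; ax <- cx + 0.11 * dim[2]
        for (s in seq(0, 0.22 * dim[1], by = 0.5)) {
          rr <- round(ay - s * cos(ang)); cc <- round(ax + s * sin(ang) + 2)
          if (rr >= 2 && rr < dim[1] && cc >= 2 && cc < dim[2])
            f[(rr - 1):(rr + 1), (cc - 1):(cc + 1)] <- TRUE
        }
      }
      if (legs > 0) {                        # alternating leg spread
        spread <- 0.06 * dim[2] * legs
        f <- f | draw_ellipse(dim, cy + 0.36 * dim[1], cx - spread,
                              0.12 * dim[1], 0.045 * dim[2])
        f <- f | draw_ellipse(dim, cy + 0.36 * dim[1], cx + spread,
                              0.12 * dim[1], 0.045 * dim[2])
      }
      f
    })
    silhouette_sequence(frames, label = activity_kind)
  })
}

#' Synthetic labeled sensor corpus for the semi-Markov CRF
#'
#' Sequences of discrete symbols with per-sample labels: activity segments
#' draw a duration from a clipped rounded Normal per label and emit symbols
#' from a label-specific categorical distribution (`emission_sharpness`
#' mass on the label's own symbol, the rest uniform); null stretches are
#' interleaved at rate `null_rate` with their own symbol distribution
#' (peaked on symbol `M + 1`).
#'
#' @param M number of expected activity labels (`"act1" .. "actM"`).
#' @param alphabet symbol alphabet size (default `M + 2`, must be >= M).
#' @param emission_sharpness probability of a label's own symbol, in
#'   `(1/alphabet, 1]`.
#' @param duration_means,duration_sds per-label duration parameters
#'   (recycled; defaults 10 and 2).
#' @param null_rate probability of a null stretch between segments, in
#'   `[0, 1]`.
#' @param T sequence length.
#' @param n_seqs number of sequences.
#' @param seed RNG seed.
#' @return list of items, each with `x` (symbols), `labels` (per-sample,
#'   `"null"` for null stretches), and `s` (the true segmentation from
#'   [encode_segments()]); attribute `labels` holds the label universe.
#' @export
make_sensor_corpus <- function(M = 3, alphabet = M + 2,
                               emission_sharpness = 0.8,
                               duration_means = 10, duration_sds = 2,
                               null_rate = 0.3, T = 120, n_seqs = 10,
                               seed = 1) {
  check_that(M >= 2, "M must be >= 2")
  check_that(alphabet >= M, "alphabet must be >= M")
  check_that(null_rate >= 0 && null_rate <= 1, "null_rate must be in [0, 1]")
  check_that(emission_sharpness > 1 / alphabet && emission_sharpness <= 1,
             "emission_sharpness must exceed the uniform rate")
  labels <- paste0("act", seq_len(M))
  dm <- rep_len(duration_means, M); dsd <- rep_len(duration_sds, M)
  null_sym <- if (alphabet > M) M + 1L else NA_integer_
  emit <- function(y, n) {                # y in 1..M, or 0 for null
    own <- if (y == 0) null_sym else y
    if (is.na(own)) return(sample.int(alphabet, n, replace = TRUE))
    p <- rep((1 - emission_sharpness) / (alphabet - 1), alphabet)
    p[own] <- emission_sharpness
    sample.int(alphabet, n, replace = TRUE, prob = p)
  }
  with_seed(seed, {
    corpus <- lapply(seq_len(n_seqs), function(i) {
      lab <- character(0); x <- integer(0)
      prev_y <- 0L
      while (length(x) < T) {
        if (runif(1) < null_rate) {
          d <- max(1L, round(rnorm(1, 5, 2)))
          d <- min(d, T - length(x))
          if (d > 0) { lab <- c(lab, rep("null", d)); x <- c(x, emit(0L, d)) }
          if (length(x) >= T) break
        }
        cands <- setdiff(seq_len(M), prev_y)
        y <- cands[sample.int(length(cands), 1)]
        d <- max(1L, round(rnorm(1, dm[y], dsd[y])))
        d <- min(d, T - length(x))
        if (d > 0) { lab <- c(lab, rep(labels[y], d)); x <- c(x, emit(y, d)) }
        prev_y <- y
      }
      list(x = x, labels = lab,
           s = encode_segments(lab, null_labels = "null"))
    })
    structure(corpus, labels = labels, alphabet = alphabet)
  })
}

#' Scripted activity event log with ground-truth decisions
#'
#' Builds a time-stamped event stream from a script (a data frame with
#' columns `minute`, `name`, and optionally `person`, `location`) or from a
#' named scenario preset, together with the decision list the rules must
#' produce. The `"breakfast"` preset mirrors a morning routine: entering
#' the kitchen (lights on), sitting, watching TV, eating with no prior
#' medicine (reminder), then reading (TV off). The expected decisions for
#' presets are written out by hand, independently of the rule engine.
#'
#' @param script scenario name (`"breakfast"`) or a script data frame; an
#'   empty data frame yields empty outputs. For custom scripts the expected
#'   decisions are `NULL` (no ground truth is invented).
#' @param seed RNG seed (kept for interface uniformity; the generator is
#'   deterministic).
#' @param start start time (POSIXct or string), default 07:00 UTC.
#' @param inject_unknown number of out-of-catalog events to interleave.
#' @return list with `events` (`activity_events`) and `expected` (decision
#'   data frame, or `NULL` for custom scripts).
#' @export
make_event_log <- function(script = "breakfast", seed = 1,
                           start = "2026-01-05 07:00:00",
                           inject_unknown = 0) {
  start <- as.POSIXct(start, tz = "UTC")
  expected <- NULL
  if (is.character(script)) {
    check_that(script == "breakfast", "unknown scenario: ", script)
    script <- data.frame(
      minute = c(0, 2, 5, 10, 30),
      name = c("entering kitchen", "sitting", "watching TV", "eating",
               "reading"),
      person = "p1",
      location = c("kitchen", "kitchen", "kitchen", "kitchen", "bedroom"),
      stringsAsFactors = FALSE)
    expected <- data.frame(
      kind = c("device_command", "reminder", "device_command"),
      payload = c("turnOn(lights)", "take medicine", "turnOff(TV)"),
      minute = c(0, 10, 30),
      stringsAsFactors = FALSE)
    expected$time <- start + expected$minute * 60
  }
  check_that(is.data.frame(script) &&
               all(c("minute", "name") %in% names(script)) || !nrow(script),
             "script needs columns minute, name")
  if (!nrow(script)) {
    ev <- activity_events(character(), character(), as.POSIXct(character()))
    return(list(events = ev, expected = expected %||%
                  data.frame(kind = character(), payload = character(),
                             minute = numeric(), time = as.POSIXct(character()))))
  }
  if (is.null(script$person)) script$person <- "p1"
  if (is.null(script$location)) script$location <- ""
  if (inject_unknown > 0) {
    unk_min <- with_seed(seed,
      sort(round(runif(inject_unknown, min(script$minute), max(script$minute) + 5), 2)))
    script <- rbind(script,
                    data.frame(minute = unk_min,
                               name = paste0("door fiddling ", seq_len(inject_unknown)),
                               person = "p1", location = "",
                               stringsAsFactors = FALSE))
    script <- script[order(script$minute), ]
  }
  ev <- activity_events(id = sprintf("e%03d", seq_len(nrow(script))),
                        name = script$name,
                        time = start + script$minute * 60,
                        person = script$person,
                        location = script$location)
  list(events = ev, expected = expected)
}
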