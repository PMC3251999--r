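# Region-based active-contour segmentation.
#
# The contour is the zero set of a level-set field phi on the image grid;
# the inside region is {phi < 0} (H(-phi) selects it through the smoothed
# Heaviside). The energy couples the two-phase piecewise-constant fidelity
# term (within-region variance) with the Bhattacharyya coefficient between
# the inside and outside intensity histograms, scaled by the image area so
# the two terms are commensurate:
#
#   E = gamma * perimeter + eta * area_in
#       + beta * F(C) + (1 - beta) * B(C) * npix
#   F(C) = sum (I - c_in)^2 H(-phi) + (I - c_out)^2 H(phi)
#   B(C) = sum_bins sqrt(p_in * p_out)
#
# Minimizing F alone merely minimizes within-region variance and fails on
# inhomogeneous (e.g. bimodal) foregrounds; the B term additionally pushes
# the two region histograms apart. Grid convention: matrices indexed
# [row, col], origin at the top-left; file I/O is 0-based row-major.

#' Construct an intensity image
#'
#' @param values numeric matrix of intensities.
#' @param range intensity range (default `c(0, 1)`); all values must lie in
#'   it. Histograms are binned over this range, so shifting both the values
#'   and the range leaves segmentation unchanged.
#' @return matrix of class `intensity_image` with a `range` attribute.
#' @export
intensity_image <- function(values, range = c(0, 1)) {
  values <- as.matrix(values)
  check_that(nrow(values) >= 2 && ncol(values) >= 2, "image must be at least 2x2")
  check_that(all(is.finite(values)), "intensities must be finite")
  check_that(all(values >= range[1] & values <= range[2]),
             "intensities outside the declared range")
  structure(values, range = as.numeric(range),
            class = c("intensity_image", "matrix", "array"))
}

img_range <- function(image) attr(image, "range") %||% c(0, 1)

check_grids <- function(image, field)
  check_that(all(dim(image) == dim(field)), "image and field grids differ")

#' Smoothed Heaviside and Dirac
#'
#' `H_eps(v) = (1 + (2/pi) atan(v / eps)) / 2` and its derivative
#' `delta_eps(v) = eps / (pi (eps^2 + v^2))`.
#'
#' @param v numeric. @param eps smoothing width (default 1).
#' @return numeric of the same shape.
#' @rdname heaviside
#' @export
heaviside_eps <- function(v, eps = 1) 0.5 * (1 + (2 / pi) * atan(v / eps))

#' @rdname heaviside
#' @export
dirac_eps <- function(v, eps = 1) eps / (pi * (eps^2 + v^2))

#' Default segmentation parameters
#'
#' @param beta mixing weight between the fidelity term (`beta`) and the
#'   Bhattacharyya term (`1 - beta`), in `[0, 1]`.
#' @param gamma contour-length penalty (>= 0).
#' @param eta inside-area penalty (>= 0); enters the flow as the constant
#'   speed `V0 = eta`.
#' @param epsilon Heaviside smoothing width (level-set units).
#' @param dt nominal explicit time step; [segment_body()] additionally caps
#'   the per-iteration field increment at `max_step` for stability.
#' @param max_iters iteration budget.
#' @param tol relative-energy convergence threshold (met on 3 consecutive
#'   iterations).
#' @param n_bins histogram bins over the image range.
#' @param reinit_every if positive, rebuild the field as an exact signed
#'   distance to the current contour (zero set preserved) every this many
#'   iterations (off by default).
#' @param max_step per-iteration cap on `max |dphi|` (pixels).
#' @param force_clamp quantile of `|force|` at which [segment_body()]
#'   winsorizes the per-pixel force so isolated outlier pixels cannot
#'   throttle the adaptive step (1 disables; the clamp preserves per-pixel
#'   force signs, hence descent).
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(beta = 0.5, gamma = 0.2, eta = 0,
                                epsilon = 1, dt = 0.1, max_iters = 600,
                                tol = 1e-5, n_bins = 64, reinit_every = 0,
                                max_step = 1.5, force_clamp = 0.8) {
  check_that(beta >= 0 && beta <= 1, "beta must be in [0, 1]")
  check_that(gamma >= 0 && eta >= 0, "gamma and eta must be >= 0")
  check_that(dt > 0, "dt must be positive")
  check_that(n_bins >= 2, "n_bins must be >= 2")
  check_that(force_clamp > 0 && force_clamp <= 1, "force_clamp must be in (0, 1]")
  structure(list(beta = beta, gamma = gamma, eta = eta, epsilon = epsilon,
                 dt = dt, max_iters = max_iters, tol = tol, n_bins = n_bins,
                 reinit_every = reinit_every, max_step = max_step,
                 force_clamp = force_clamp),
            class = "segmentation_params")
}

region_weights <- function(field, eps) {
  list(win = heaviside_eps(-field, eps), wout = heaviside_eps(field, eps))
}

#' Region mean intensities
#'
#' Smoothed-Heaviside-weighted mean intensity inside (`phi < 0`) and
#' outside (`phi > 0`) the contour.
#'
#' @param image `intensity_image` (or plain matrix).
#' @param field level-set matrix on the same grid.
#' @param eps Heaviside smoothing width.
#' @return list with `c_in`, `c_out`, `A_in`, `A_out`.
#' @export
region_means <- function(image, field, eps = 1) {
  check_grids(image, field)
  w <- region_weights(field, eps)
  A_in <- sum(w$win); A_out <- sum(w$wout)
  if (A_in < 1 || A_out < 1)
    stop_degenerate("degenerate region: weight below one pixel-equivalent")
  list(c_in = sum(image * w$win) / A_in, c_out = sum(image * w$wout) / A_out,
       A_in = A_in, A_out = A_out)
}

bin_index <- function(image, n_bins, range) {
  idx <- floor((as.vector(image) - range[1]) / diff(range) * n_bins) + 1L
  pmin(pmax(idx, 1L), as.integer(n_bins))
}

#' Region intensity histograms
#'
#' Heaviside-weighted hard-binned intensity histograms of the inside and
#' outside regions, each normalized by its region weight.
#'
#' @inheritParams region_means
#' @param n_bins number of bins over the image range (>= 2).
#' @return list with `p_in`, `p_out` (each a `region_histogram`: list of
#'   `bin_edges`, `mass`) and region weights `A_in`, `A_out`.
#' @export
region_histograms <- function(image, field, n_bins = 64, eps = 1) {
  check_grids(image, field)
  check_that(n_bins >= 2, "n_bins must be >= 2")
  rng <- img_range(image)
  w <- region_weights(field, eps)
  A_in <- sum(w$win); A_out <- sum(w$wout)
  if (A_in < 1 || A_out < 1)
    stop_degenerate("degenerate region: weight below one pixel-equivalent")
  idx <- bin_index(image, n_bins, rng)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  m_in <- vapply(seq_len(n_bins), function(k) sum(w$win[idx == k]), numeric(1))
  m_out <- vapply(seq_len(n_bins), function(k) sum(w$wout[idx == k]), numeric(1))
  hist_of <- function(mass, total)
    structure(list(bin_edges = edges, mass = mass / total),
              class = "region_histogram")
  list(p_in = hist_of(m_in, A_in), p_out = hist_of(m_out, A_out),
       A_in = A_in, A_out = A_out)
}

#' Bhattacharyya coefficient of two region histograms
#'
#' `B = sum_bins sqrt(p_in * p_out)`, in `[0, 1]`: 1 for identical
#' distributions, 0 for disjoint supports. The result is clamped to `[0, 1]`
#' only against floating-point rounding.
#'
#' @param p_in,p_out `region_histogram` objects on identical bin edges.
#' @return scalar coefficient.
#' @export
bhattacharyya_coefficient <- function(p_in, p_out) {
  check_that(length(p_in$bin_edges) == length(p_out$bin_edges) &&
               all(p_in$bin_edges == p_out$bin_edges),
             "histograms have mismatched bin edges")
  min(max(sum(sqrt(p_in$mass * p_out$mass)), 0), 1)
}

grad_central <- function(f) {
  nr <- nrow(f); nc <- ncol(f)
  pad_r <- f[c(1, seq_len(nr), nr), ]
  pad_c <- f[, c(1, seq_len(nc), nc)]
  gy <- (pad_r[3:(nr + 2), ] - pad_r[1:nr, ]) / 2       # d/drow
  gx <- (pad_c[, 3:(nc + 2)] - pad_c[, 1:nc]) / 2       # d/dcol
  list(gy = gy, gx = gx, mag = sqrt(gx^2 + gy^2))
}

curvature <- function(field) {
  g <- grad_central(field)
  gyy <- grad_central(g$gy)$gy
  gxx <- grad_central(g$gx)$gx
  gxy <- grad_central(g$gx)$gy
  den <- (g$gx^2 + g$gy^2)^1.5 + 1e-8
  (gxx * g$gy^2 - 2 * g$gx * g$gy * gxy + gyy * g$gx^2) / den
}

#' Total segmentation energy
#'
#' `gamma * perimeter + eta * area_in + beta * F + (1 - beta) * B * npix`,
#' with the fidelity `F` the Heaviside-weighted within-region squared
#' deviation from the region means and `B` the Bhattacharyya coefficient of
#' the region histograms (scaled by the pixel count of the grid so the two
#' data terms are commensurate).
#'
#' @inheritParams region_means
#' @param params `segmentation_params`.
#' @return scalar energy.
#' @export
total_energy <- function(image, field, params = segmentation_params()) {
  check_grids(image, field)
  eps <- params$epsilon
  rm_ <- region_means(image, field, eps)
  g <- grad_central(field)
  perim <- sum(dirac_eps(field, eps) * g$mag)
  Fterm <- sum((image - rm_$c_in)^2 * heaviside_eps(-field, eps) +
                 (image - rm_$c_out)^2 * heaviside_eps(field, eps))
  E <- params$gamma * perim + params$eta * rm_$A_in + params$beta * Fterm
  if (params$beta < 1) {
    h <- region_histograms(image, field, params$n_bins, eps)
    B <- bhattacharyya_coefficient(h$p_in, h$p_out)
    E <- E + (1 - params$beta) * B * length(image)
  }
  E
}

# per-pixel force of the flow (shared by evolution_step and segment_body);
# region-histogram masses are floored at 1e-3 inside the ratio terms so the
# flow stays bounded where a bin is (near-)empty on one side
levelset_force <- function(image, field, params, clamp_q = NULL) {
  eps <- params$epsilon
  rm_ <- region_means(image, field, eps)
  I <- unclass(image)
  attributes(I) <- list(dim = dim(I))
  force <- params$gamma * curvature(field) + params$eta +
    params$beta * ((I - rm_$c_in)^2 - (I - rm_$c_out)^2)
  if (params$beta < 1) {
    h <- region_histograms(image, field, params$n_bins, eps)
    B <- bhattacharyya_coefficient(h$p_in, h$p_out)
    pin <- pmax(h$p_in$mass, 1e-3)
    pout <- pmax(h$p_out$mass, 1e-3)
    idx <- bin_index(image, params$n_bins, img_range(image))
    px_term <- 0.5 * (sqrt(pin[idx] / pout[idx]) / h$A_out -
                        sqrt(pout[idx] / pin[idx]) / h$A_in)
    glob <- (B / 2) * (1 / h$A_in - 1 / h$A_out)
    force <- force - (1 - params$beta) * length(image) *
      (glob + matrix(px_term, nrow(image), ncol(image)))
  }
  if (!is.null(clamp_q) && clamp_q < 1) {
    cap <- stats::quantile(abs(force), clamp_q, names = FALSE)
    force <- sign(force) * pmin(abs(force), cap)
  }
  force
}

#' One explicit evolution step of the level-set flow
#'
#' Advances the field by `dt * |grad phi| * force`, where the force is the
#' first variation of the total energy with inside = `{phi < 0}`:
#' curvature and constant-speed regularizers, the piecewise-constant
#' fidelity term, and the Bhattacharyya separation term (its histogram
#' integral evaluated per bin at each pixel's intensity; region masses are
#' floored at 1e-8 in the ratio terms).
#'
#' @inheritParams total_energy
#' @return updated level-set matrix.
#' @export
evolution_step <- function(image, field, params = segmentation_params()) {
  check_grids(image, field)
  g <- grad_central(field)
  field + params$dt * g$mag * levelset_force(image, field, params)
}

# rebuild the field as an exact signed distance to the current interface;
# the sign (and hence the mask) of every pixel is preserved
reinit_field <- function(field) {
  mask <- field < 0
  nr <- nrow(mask); nc <- ncol(mask)
  shift_ne <- function(m, dr, dc) {
    out <- matrix(NA, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  on_boundary <- matrix(FALSE, nr, nc)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- shift_ne(mask, d[1], d[2])
    on_boundary <- on_boundary | (!is.na(nb) & nb != mask)
  }
  if (!any(on_boundary)) return(field)
  bidx <- which(on_boundary, arr.ind = TRUE)
  rr <- matrix(row(mask), ncol = 1); cc <- matrix(col(mask), ncol = 1)
  d2 <- outer(as.vector(row(mask)), bidx[, 1], `-`)^2 +
    outer(as.vector(col(mask)), bidx[, 2], `-`)^2
  d <- sqrt(apply(d2, 1, min)) + 0.5
  matrix(ifelse(as.vector(mask), -d, d), nr, nc)
}

#' Signed-distance circle initialization for the level-set field
#'
#' @param dim image dimensions `c(rows, cols)`.
#' @param center circle center `c(row, col)` (defaults to the grid center).
#' @param radius circle radius (defaults to a third of the smaller side).
#' @return level-set matrix, negative inside the circle.
#' @export
levelset_init <- function(dim, center = NULL, radius = NULL) {
  center <- center %||% (dim / 2)
  radius <- radius %||% (min(dim) / 3)
  r <- matrix(seq_len(dim[1]), dim[1], dim[2])
  c_ <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  sqrt((r - center[1])^2 + (c_ - center[2])^2) - radius
}

#' Segment an image by level-set evolution
#'
#' Iterates [evolution_step()] (with an adaptive per-iteration cap on the
#' maximum field increment for stability) until the relative energy change
#' stays below `tol` for 3 consecutive iterations or `max_iters` is reached.
#' A constant image, or a region collapsing below one pixel-equivalent of
#' weight, sets the `degenerate` flag and returns the last valid state.
#'
#' @inheritParams total_energy
#' @param init initial level-set field (both signs present), e.g. from
#'   [levelset_init()].
#' @return list of class `body_segmentation`: `final_field`, `mask` (logical
#'   matrix, `TRUE` inside = `phi < 0`), `energy_trace`, `iterations`,
#'   `degenerate`.
#' @export
segment_body <- function(image, init = levelset_init(dim(image)),
                         params = segmentation_params()) {
  check_grids(image, init)
  check_that(any(init < 0) && any(init > 0), "init must contain both signs")
  result <- function(field, trace, degenerate) {
    structure(list(final_field = field, mask = field < 0,
                   energy_trace = trace, iterations = length(trace),
                   degenerate = degenerate),
              class = "body_segmentation")
  }
  if (diff(range(image)) == 0)          # nothing to segment
    return(result(init, numeric(0), TRUE))
  field <- init
  trace <- numeric(0)
  E_prev <- total_energy(image, field, params)
  streak <- 0L
  degenerate <- FALSE
  for (it in seq_len(params$max_iters)) {
    g <- grad_central(field)
    force <- tryCatch(levelset_force(image, field, params,
                                     clamp_q = params$force_clamp),
                      harkit_degenerate_error = function(e) NULL)
    if (is.null(force)) { degenerate <- TRUE; break }
    inc <- g$mag * force
    mx <- max(abs(inc))
    dt_eff <- if (mx * params$dt > params$max_step)
      params$max_step / mx else params$dt
    cand <- field + dt_eff * inc
    w <- region_weights(cand, params$epsilon)
    if (sum(w$win) < 1 || sum(w$wout) < 1) { degenerate <- TRUE; break }
    field <- cand
    if (params$reinit_every > 0 && it %% params$reinit_every == 0)
      field <- reinit_field(field)
    E <- total_energy(image, field, params)
    trace <- c(trace, E)
    rel <- abs(E - E_prev) / max(abs(E_prev), 1e-12)
    streak <- if (rel < params$tol) streak + 1L else 0L
    E_prev <- E
    if (streak >= 3L) break
  }
  result(field, trace, degenerate)
}

#' @export
print.body_segmentation <- function(x, ...) {
  cat(sprintf("level-set segmentation: %d iterations, %s, inside area %d px\n",
              x$iterations,
              if (x$degenerate) "degenerate" else "converged/stopped",
              sum(x$mask)))
  if (length(x$energy_trace))
    cat(sprintf("  energy %.4g -> %.4g\n",
                x$energy_trace[1], tail(x$energy_trace, 1)))
  invisible(x)
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b logical matrices of equal size.
#' @return IoU in `[0, 1]` (1 if both masks are empty).
#' @export
mask_iou <- function(a, b) {
  check_that(all(dim(a) == dim(b)), "mask sizes differ")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
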