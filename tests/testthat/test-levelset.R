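# Region terms, Bhattacharyya coupling and the level-set flow.

test_that("region means match direct masked averages", {
  # constant image: both means equal the constant
  img <- intensity_image(matrix(0.5, 4, 4))
  field <- levelset_init(c(4, 4))
  rm_ <- region_means(img, field)
  expect_equal(rm_$c_in, 0.5)
  expect_equal(rm_$c_out, 0.5)

  # sharp-Heaviside limit on an exact partition: rows (0,0) and (1,1)
  img2 <- intensity_image(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE))
  field2 <- matrix(c(1, 1, -1, -1), 2, 2, byrow = TRUE)  # inside = row 2
  rm2 <- region_means(img2, field2, eps = 1e-9)
  expect_equal(rm2$c_in, 1, tolerance = 1e-9)
  expect_equal(rm2$c_out, 0, tolerance = 1e-9)

  # random 8x8 fixture vs independent masked-mean summation at small eps
  set.seed(1)
  v <- matrix(runif(64), 8, 8)
  f <- matrix(rnorm(64), 8, 8)
  rm3 <- region_means(intensity_image(v), f, eps = 1e-12)
  expect_equal(rm3$c_in, sum(v[f < 0]) / sum(f < 0), tolerance = 1e-10)
  expect_equal(rm3$c_out, sum(v[f > 0]) / sum(f > 0), tolerance = 1e-10)

  # strongly one-sided field is degenerate
  expect_error(region_means(img, matrix(100, 4, 4)),
               class = "harkit_degenerate_error")
})

test_that("region histograms normalize and match brute-force binning", {
  # separated intensities concentrate mass in the end bins
  img <- intensity_image(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE))
  field <- matrix(c(1, 1, -1, -1), 2, 2, byrow = TRUE)
  h <- region_histograms(img, field, n_bins = 4, eps = 1e-9)
  expect_equal(h$p_in$mass, c(0, 0, 0, 1), tolerance = 1e-9)
  expect_equal(h$p_out$mass, c(1, 0, 0, 0), tolerance = 1e-9)

  # constant image: identical one-bin histograms
  hc <- region_histograms(intensity_image(matrix(0.4, 4, 4)),
                          levelset_init(c(4, 4)), n_bins = 8)
  expect_equal(hc$p_in$mass, hc$p_out$mass)
  expect_equal(sum(hc$p_in$mass > 0), 1)

  # random fixture vs per-bin weighted count oracle
  set.seed(2)
  v <- matrix(runif(64), 8, 8)
  f <- matrix(rnorm(64), 8, 8)
  nb <- 8
  hr <- region_histograms(intensity_image(v), f, n_bins = nb)
  win <- heaviside_eps(-f); wout <- heaviside_eps(f)
  bins <- pmin(pmax(floor(v * nb) + 1, 1), nb)
  for (k in seq_len(nb)) {
    expect_equal(hr$p_in$mass[k], sum(win[bins == k]) / sum(win), tolerance = 1e-12)
    expect_equal(hr$p_out$mass[k], sum(wout[bins == k]) / sum(wout), tolerance = 1e-12)
  }
  expect_equal(sum(hr$p_in$mass), 1, tolerance = 1e-9)
  expect_equal(sum(hr$p_out$mass), 1, tolerance = 1e-9)
})

test_that("Bhattacharyya coefficient spans [0, 1] with the hand values", {
  hist_of <- function(mass) structure(list(bin_edges = c(0, 0.5, 1),
                                           mass = mass),
                                      class = "region_histogram")
  expect_equal(bhattacharyya_coefficient(hist_of(c(0.3, 0.7)),
                                         hist_of(c(0.3, 0.7))), 1)
  expect_equal(bhattacharyya_coefficient(hist_of(c(1, 0)), hist_of(c(0, 1))), 0)
  expect_equal(bhattacharyya_coefficient(hist_of(c(0.5, 0.5)), hist_of(c(1, 0))),
               sqrt(0.5), tolerance = 1e-9)
  bad <- structure(list(bin_edges = c(0, 1), mass = 1),
                   class = "region_histogram")
  expect_error(bhattacharyya_coefficient(hist_of(c(0.5, 0.5)), bad),
               class = "harkit_contract_error")
})

test_that("total energy reduces to the pure two-phase model at beta = 1", {
  set.seed(3)
  v <- matrix(runif(64), 8, 8)
  img <- intensity_image(v)
  f <- levelset_init(c(8, 8))
  p1 <- segmentation_params(beta = 1, gamma = 0.3, eta = 0.1)
  E <- total_energy(img, f, p1)
  # independent evaluation of fidelity + regularizers
  win <- heaviside_eps(-f); wout <- heaviside_eps(f)
  cin <- sum(v * win) / sum(win); cout <- sum(v * wout) / sum(wout)
  Fterm <- sum((v - cin)^2 * win + (v - cout)^2 * wout)
  g <- harkit:::grad_central(f)
  perim <- sum(dirac_eps(f) * g$mag)
  expect_equal(E, 0.3 * perim + 0.1 * sum(win) + Fterm, tolerance = 1e-10)

  # piecewise-constant image matching the partition, gamma = eta = 0, beta = 1
  img2 <- intensity_image(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE))
  f2 <- matrix(c(5, 5, -5, -5), 2, 2, byrow = TRUE)
  p2 <- segmentation_params(beta = 1, gamma = 0, eta = 0, epsilon = 1e-9)
  expect_equal(total_energy(img2, f2, p2), 0, tolerance = 1e-9)

  # beta = 0 with identical region histograms: B = 1 scaled by image area
  chk <- matrix(c(0, 1, 0, 1,
                  1, 0, 1, 0,
                  0, 1, 0, 1,
                  1, 0, 1, 0), 4, 4, byrow = TRUE)
  f3 <- matrix(rep(c(-1, -1, 1, 1), each = 4), 4, 4)  # split by columns
  p3 <- segmentation_params(beta = 0, gamma = 0, eta = 0, epsilon = 1e-9,
                            n_bins = 2)
  expect_equal(total_energy(intensity_image(chk), f3, p3), 16, tolerance = 1e-6)
})

test_that("evolution step is the printed flow and does not increase energy", {
  # homogeneous input: all data terms vanish
  img <- intensity_image(matrix(0.7, 6, 6))
  f <- levelset_init(c(6, 6))
  p <- segmentation_params(beta = 0.5, gamma = 0, eta = 0)
  expect_equal(evolution_step(img, f, p), f, tolerance = 1e-12)

  # small dt on a random fixture: energy cannot increase beyond slack
  set.seed(4)
  v <- matrix(runif(64), 8, 8)
  img2 <- intensity_image(v)
  f2 <- levelset_init(c(8, 8))
  p2 <- segmentation_params(beta = 0.5, gamma = 0.1, dt = 1e-4)
  E0 <- total_energy(img2, f2, p2)
  E1 <- total_energy(img2, evolution_step(img2, f2, p2), p2)
  expect_lte(E1, E0 + 1e-6)

  # beta = 1, gamma = eta = 0 equals an independently coded two-phase step
  p3 <- segmentation_params(beta = 1, gamma = 0, eta = 0, dt = 0.05)
  stepped <- evolution_step(img2, f2, p3)
  H <- function(z) 0.5 * (1 + (2 / pi) * atan(z))   # oracle's own pieces
  win <- H(-f2); wout <- H(f2)
  cin <- sum(v * win) / sum(win); cout <- sum(v * wout) / sum(wout)
  pad <- function(m) m[c(1, 1:8, 8), c(1, 1:8, 8)]
  pf <- pad(f2)
  gx <- (pf[2:9 + 0, 3:10] - pf[2:9 + 0, 1:8]) / 2
  gy <- (pf[3:10, 2:9 + 0] - pf[1:8, 2:9 + 0]) / 2
  oracle <- f2 + 0.05 * sqrt(gx^2 + gy^2) * ((v - cin)^2 - (v - cout)^2)
  expect_equal(stepped, oracle, tolerance = 1e-12)
})

test_that("segmentation drives the energy down with B within [0, 1] throughout", {
  fx <- make_body_image(w = 48, h = 48, seed = 5)
  p <- segmentation_params(max_iters = 120)
  field <- levelset_init(dim(fx$image))
  for (i in 1:60) {
    h <- region_histograms(fx$image, field, p$n_bins)
    B <- bhattacharyya_coefficient(h$p_in, h$p_out)
    expect_gte(B, 0); expect_lte(B, 1)
    field <- evolution_step(fx$image, field, p)
  }
  res <- segment_body(fx$image, params = p)
  expect_equal(res$iterations, length(res$energy_trace))
  expect_lte(tail(res$energy_trace, 1), res$energy_trace[1])
  expect_identical(res$mask, res$final_field < 0)
})

test_that("degenerate inputs are flagged, not fatal", {
  u <- intensity_image(matrix(0.3, 12, 12))
  res <- segment_body(u)
  expect_true(res$degenerate)
  expect_error(segment_body(u, init = matrix(1, 12, 12)),
               class = "harkit_contract_error")
})

test_that("segmentation is invariant to a global intensity shift", {
  fx <- make_body_image(w = 32, h = 32, seed = 6)
  p <- segmentation_params(max_iters = 60)
  r1 <- segment_body(fx$image, params = p)
  shifted <- intensity_image(unclass(fx$image) + 0.2, range = c(0.2, 1.2))
  r2 <- segment_body(shifted, params = p)
  expect_identical(r1$mask, r2$mask)
  expect_equal(r1$energy_trace, r2$energy_trace, tolerance = 1e-8)
})
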