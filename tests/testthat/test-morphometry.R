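cross_cell <- function(center = c(100, 100), radius = 10, arm_len = 30,
                       width = 3, size = c(200, 200)) {
  generate_microglia_image(
    list(list(center = center, radius = radius,
              arms = data.frame(angle = c(0, pi / 2, pi, 3 * pi / 2),
                                length = arm_len, width = width))),
    size = size)
}

test_that("stack preprocessing smooths then takes the pixelwise maximum", {
  withr::with_seed(70, {
    a <- matrix(runif(100), 10)
    b <- matrix(runif(100), 10)
  })
  # single plane, sigma 0: identity
  expect_equal(preprocess_stack(a, smooth_sigma = 0), a)
  # two planes, sigma 0: elementwise max
  st <- array(c(a, b), dim = c(10, 10, 2))
  expect_equal(preprocess_stack(st, smooth_sigma = 0), pmax(a, b))
  # constant stack stays constant under smoothing
  cst <- array(0.4, dim = c(16, 16, 3))
  expect_equal(preprocess_stack(cst, smooth_sigma = 1),
               matrix(0.4, 16, 16), tolerance = 1e-6)
  expect_error(preprocess_stack(array(0, c(4, 4, 0))), "z-plane")
})

test_that("binarization thresholds correctly for fixed and Otsu methods", {
  img <- matrix(0, 30, 30)
  img[10:20, 10:20] <- 100
  mask <- binarize_image(img, "fixed", level = 50)
  expect_equal(unname(which(mask, arr.ind = TRUE)),
               unname(which(img == 100, arr.ind = TRUE)))

  # bimodal image: Otsu lands strictly between the modes
  withr::with_seed(71, {
    bim <- matrix(rnorm(400, 0.2, 0.02), 20)
    bim[5:15, 5:15] <- rnorm(121, 0.8, 0.02)
  })
  m2 <- binarize_image(bim, "otsu")
  # all bright-mode pixels kept, all dark-mode pixels dropped
  expect_true(all(m2[5:15, 5:15]))
  expect_false(any(m2[1:4, ]))

  expect_error(binarize_image(matrix(1, 5, 5), "otsu"), "constant")
  expect_error(binarize_image(matrix(0:1, 2, 2), "fixed", level = 5),
               "empty mask")
})

test_that("soma detection fits the largest inscribed circle", {
  g <- cross_cell()
  mask <- binarize_image(g$image, "fixed", level = 0.5)
  soma <- detect_soma(mask)
  expect_equal(soma$center, c(100, 100), tolerance = 1)
  expect_equal(soma$radius, 10, tolerance = 1)
  # arms thinner than the disc never displace the soma
  expect_lt(sqrt(sum((soma$center - c(100, 100))^2)), 1.5)

  # radius grows monotonically with the planted disc
  radii <- vapply(c(5, 8, 11, 14), function(r) {
    gg <- generate_microglia_image(
      list(list(center = c(50, 50), radius = r, arms = NULL)),
      size = c(100, 100))
    detect_soma(gg$image > 0.5)$radius
  }, numeric(1))
  expect_true(all(diff(radii) > 0))

  # degenerate 1-px line
  line <- matrix(FALSE, 20, 20); line[10, 5:15] <- TRUE
  expect_lte(detect_soma(line)$radius, 1.5)
  expect_error(detect_soma(matrix(FALSE, 5, 5)), "empty")
})

test_that("skeleton metrics match planted branch counts and lengths", {
  # disc only: no branches, territory = bbox of the disc
  g0 <- generate_microglia_image(
    list(list(center = c(50, 50), radius = 10, arms = NULL)),
    size = c(100, 100))
  m0 <- skeleton_metrics(g0$image > 0.5)
  expect_equal(m0$branch_count, 0L)
  expect_equal(m0$total_length, 0)
  expect_equal(m0$territory, 21 * 21, tolerance = 0.1 * 21 * 21)

  # 4-arm cross: 4 branches, length within 10% of 120, bbox side 81 +/- 2
  g <- cross_cell()
  mask <- binarize_image(g$image, "fixed", level = 0.5)
  m <- skeleton_metrics(mask)
  expect_equal(m$branch_count, 4L)
  expect_gte(m$total_length, 0.9 * 120)
  expect_lte(m$total_length, 1.1 * 120)
  expect_gte(sqrt(m$territory), 79)
  expect_lte(sqrt(m$territory), 83)

  # one arm that bifurcates once: stem + two daughters = 3 branches
  base <- generate_microglia_image(
    list(list(center = c(60, 75), radius = 8,
              arms = data.frame(angle = 0, length = 20, width = 3))),
    size = c(150, 150))
  img2 <- base$image
  tip <- c(60 + 8 + 20, 75)
  for (th in c(pi / 4, -pi / 4)) {
    for (t in seq(0, 20, by = 0.25)) {
      x <- round(tip[1] + t * cos(th)); y <- round(tip[2] + t * sin(th))
      img2[(x - 1):(x + 1), (y - 1):(y + 1)] <- 1
    }
  }
  m2 <- skeleton_metrics(binarize_image(img2, "fixed", level = 0.5))
  expect_equal(m2$branch_count, 3L)
})

test_that("total length scales linearly with planted arm length", {
  lens <- c(10, 20, 30, 40, 50, 60)
  measured <- vapply(lens, function(L) {
    g <- generate_microglia_image(
      list(list(center = c(100, 100), radius = 10,
                arms = data.frame(angle = 0, length = L, width = 3))),
      size = c(220, 220))
    skeleton_metrics(g$image > 0.5)$total_length
  }, numeric(1))
  fit <- stats::lm(measured ~ lens)
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.05)
})

test_that("metrics are invariant under translation and 90-degree rotation", {
  g <- cross_cell(center = c(80, 90))
  mask <- binarize_image(g$image, "fixed", level = 0.5)
  m <- skeleton_metrics(mask)
  # translate by (13, -7)
  shifted <- matrix(FALSE, 200, 200)
  px <- which(mask, arr.ind = TRUE)
  shifted[px + matrix(rep(c(13, -7), each = nrow(px)), ncol = 2)] <- TRUE
  ms <- skeleton_metrics(shifted)
  # rotate 90 degrees
  mr <- skeleton_metrics(t(mask[nrow(mask):1, ]))
  for (col in c("branch_count", "total_length", "territory")) {
    expect_equal(ms[[col]], m[[col]], tolerance = 1e-8)
    expect_equal(mr[[col]], m[[col]], tolerance = 1e-8)
  }
})

test_that("field-level enumeration and per-mouse summaries work end to end", {
  g <- generate_microglia_image(
    list(list(center = c(60, 60), radius = 9,
              arms = data.frame(angle = c(0, pi), length = 20, width = 3)),
         list(center = c(180, 180), radius = 9,
              arms = data.frame(angle = pi / 2, length = 25, width = 3))),
    size = c(240, 240))
  cells <- measure_cells(g$image > 0.5, area_gate = c(50, 5000))
  expect_equal(nrow(cells), 2L)
  expect_setequal(cells$branch_count, c(2L, 1L))

  metrics <- dplyr::bind_cols(
    tibble::tibble(mouse_id = c("m1", "m1")),
    cells[, c("branch_count", "total_length")])
  s <- per_mouse_summary(metrics)
  expect_equal(s$branch_count, mean(cells$branch_count))
  expect_equal(s$n_cells, 2L)
  expect_equal(per_mouse_summary(metrics[1, ])$total_length,
               cells$total_length[1])
  expect_warning(per_mouse_summary(metrics, expected_mice = c("m1", "m2")),
                 "m2")
})

test_that("density by distance respects the uniformity null and its errors", {
  dep <- matrix(FALSE, 300, 300)
  dep[145:155, 145:155] <- TRUE
  # cells on the deposit boundary all land in the first bin
  ring <- tibble::tibble(x = c(144, 156, 150, 150),
                         y = c(150, 150, 144, 156))
  d0 <- density_by_distance(ring, dep, bin_edges = c(0, 10, 20))
  expect_equal(d0$n_cells, c(4L, 0L))

  # uniform random cells: per-bin densities match the global rate
  withr::with_seed(72, {
    cells <- tibble::tibble(x = runif(2000, 1, 300), y = runif(2000, 1, 300))
  })
  d <- density_by_distance(cells, dep, bin_edges = seq(0, 100, 25))
  global <- nrow(cells) / (300 * 300 / 1e6)
  for (b in seq_len(nrow(d))) {
    p_bin <- d$area_mm2[b] / (300 * 300 / 1e6)
    ci <- stats::qbinom(c(0.025, 0.975), nrow(cells), p_bin)
    expect_gte(d$n_cells[b], ci[1])
    expect_lte(d$n_cells[b], ci[2])
  }

  # a bin beyond the field has no area -> NA density with a warning
  expect_warning(
    far <- density_by_distance(ring, dep, bin_edges = c(0, 10, 5000, 6000)),
    "no area")
  expect_true(is.na(far$density[3]))
  expect_error(density_by_distance(ring, matrix(FALSE, 10, 10), c(0, 5)),
               "no deposits")
  expect_error(density_by_distance(ring, dep, c(0, 10, 10)), "increasing")
})
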