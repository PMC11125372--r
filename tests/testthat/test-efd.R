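test_that("circle coefficients match the closed form", {
  d <- efd(circle_outline(r = 2, cx = 3, cy = -1, n = 360), n_harmonics = 4)
  expect_equal(d$a0, 3, tolerance = 1e-3)
  expect_equal(d$c0, -1, tolerance = 1e-3)
  expect_equal(d$a1^2 + d$b1^2, 4, tolerance = 1e-3)
  expect_equal(d$c1^2 + d$d1^2, 4, tolerance = 1e-3)
  # higher harmonics vanish for a circle
  expect_lt(abs(d$a2) + abs(d$b2) + abs(d$c2) + abs(d$d2), 1e-4)
})

test_that("ellipse power concentrates on the first harmonic", {
  hp <- harmonic_power(efd(ellipse_outline(a = 2, b = 1), n_harmonics = 20))
  # under chord-length parameterization a small share of power sits in odd
  # higher harmonics; concentration remains overwhelming
  expect_gt(hp$cum_frac[hp$harmonic == 1], 0.99)
  # even harmonics carry nothing for this symmetric curve
  expect_lt(sum(hp$power[hp$harmonic %% 2 == 0]) / sum(hp$power), 1e-10)
})

test_that("square spectrum matches the dense-quadrature oracle", {
  sq <- square_outline(side = 1)
  d <- efd(sq, n_harmonics = 12)
  cols <- pipmorph:::coef_names(12)
  coef <- matrix(as.numeric(d[1, cols]), 12, 4, byrow = TRUE)
  pw <- rowSums(coef^2) / 2
  # power concentrated on odd harmonics; even-harmonic power is numerically 0
  expect_lt(sum(pw[c(2, 4, 6, 8, 10, 12)]) / sum(pw), 1e-6)
  orc <- efd_quadrature(sq, 12)
  expect_equal(pw / sum(pw), orc$power / sum(orc$power), tolerance = 1e-6)
  expect_equal(d$a0, orc$a0, tolerance = 1e-6)
  expect_equal(d$c0, orc$c0, tolerance = 1e-6)
})

test_that("power agrees with the quadrature oracle on small polygons", {
  set.seed(4)
  for (k in c(5, 8, 12)) {
    ang <- sort(stats::runif(k, 0, 2 * pi))
    rad <- stats::runif(k, 0.5, 1.5)
    o <- outline_tbl(rad * cos(ang), rad * sin(ang), sprintf("poly%d", k))
    d <- efd(o, n_harmonics = 10)
    cols <- pipmorph:::coef_names(10)
    coef <- matrix(as.numeric(d[1, cols]), 10, 4, byrow = TRUE)
    orc <- efd_quadrature(o, 10)
    expect_equal(rowSums(coef^2) / 2, orc$power, tolerance = 1e-6)
  }
})

test_that("normalization algebra standardizes analytic ellipse coefficients", {
  # ellipse with semi-axes (2, 1): parameter-space coefficient quadruple
  coef <- rbind(c(2, 0, 0, 1), matrix(0, 5, 4))
  norm <- pipmorph:::normalize_coef(coef)
  expect_equal(norm[1, ], c(a = 1, b = 0, c = 0, d = 0.5), tolerance = 1e-12)
  # posed variant: rotated 25 degrees, scaled 3x, start shifted
  th <- 25 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  M1 <- 3 * R %*% rbind(c(2, 0), c(0, 1)) %*%
    matrix(c(cos(0.7), -sin(0.7), sin(0.7), cos(0.7)), 2)
  posed <- rbind(as.vector(t(M1)), matrix(0, 5, 4))
  expect_equal(pipmorph:::normalize_coef(posed)[1, ],
               c(a = 1, b = 0, c = 0, d = 0.5), tolerance = 1e-10)
})

test_that("normalized descriptors are invariant to pose and start point", {
  shapes <- template_outlines(c("sylvestris_like", "riparia_like",
                                "vinifera_like", "piasezkii_like"))
  set.seed(9)
  for (df in pipmorph:::split_outlines(shapes)) {
    ref <- efd_normalize(efd(df, 8))
    cols <- pipmorph:::coef_names(8)
    for (i in 1:20) {
      posed <- pose_outline(df, dx = stats::runif(1, -20, 20),
                            dy = stats::runif(1, -20, 20),
                            angle = stats::runif(1, 0, 2 * pi),
                            scale = stats::runif(1, 0.2, 5),
                            shift = sample(nrow(df), 1))
      got <- efd_normalize(efd(posed, 8))
      expect_equal(as.numeric(got[1, cols]), as.numeric(ref[1, cols]),
                   tolerance = 1e-8)
    }
    expect_equal(sqrt(ref$a1^2 + ref$c1^2), 1, tolerance = 1e-10)
  }
})

test_that("the documented pose example reproduces identical coefficients", {
  o <- template_outlines("heyneana_like")
  posed <- pose_outline(o, dx = 17, dy = -5, angle = 40 * pi / 180,
                        scale = 3.2, shift = 90)
  cols <- pipmorph:::coef_names(6)
  a <- efd_normalize(efd(o, 6))
  b <- efd_normalize(efd(posed, 6))
  expect_equal(as.numeric(a[1, cols]), as.numeric(b[1, cols]),
               tolerance = 1e-8)
})

test_that("normalization handles near-circular first harmonics deterministically", {
  # circle with a faint third-harmonic bump: first ellipse is circle-ambiguous
  t <- 2 * pi * (0:719) / 720
  r <- 1 + 0.05 * cos(3 * t)
  o <- outline_tbl(r * cos(t), r * sin(t), "bumpy")
  ref <- efd_normalize(efd(o, 8))
  posed <- pose_outline(o, angle = 1.1, scale = 2, shift = 311)
  got <- efd_normalize(efd(posed, 8))
  cols <- pipmorph:::coef_names(8)
  expect_equal(as.numeric(got[1, cols]), as.numeric(ref[1, cols]),
               tolerance = 1e-7)
})

test_that("feature vectors have the configured dimension and inherit invariance", {
  o <- template_outlines("amurensis_like")
  nd <- efd_normalize(efd(o, 8))
  expect_length(setdiff(names(efd_features(nd, 6)), "specimen_id"), 24)
  expect_length(setdiff(names(efd_features(nd, 1)), "specimen_id"), 4)
  expect_error(efd_features(nd, 9), "harmonics")
  expect_error(efd_features(efd(o, 8), 6), "normalized")
})

test_that("descriptor normalization refuses double application", {
  nd <- efd_normalize(efd(circle_outline(), 4))
  expect_error(efd_normalize(nd), "already normalized")
})

test_that("harmonic power profile is a normalized non-decreasing cumulative", {
  o <- template_outlines("betulifolia_like")
  hp <- harmonic_power(efd(o, 20), n_reference = 20)
  expect_true(all(diff(hp$cum_frac) >= -1e-12))
  expect_equal(hp$cum_frac[20], 1, tolerance = 1e-12)
  expect_true(all(hp$power >= 0))
  expect_error(harmonic_power(efd(o, 8), n_reference = 20), "recompute")
})

test_that("reconstruction inverts the transform", {
  # circle: single-harmonic reconstruction within 0.1% radial error
  d1 <- efd(circle_outline(r = 2, cx = 1, cy = 1, n = 360), 1)
  rc <- efd_reconstruct(d1, n_points = 360)
  rad <- sqrt((rc$x - 1)^2 + (rc$y - 1)^2)
  expect_true(all(abs(rad - 2) / 2 < 1e-3))

  # square at 20 harmonics: corner rounding bounds the deviation; the
  # point-to-polygon oracle gives 1.012% of the side length
  sq <- square_outline(side = 1)
  rc2 <- efd_reconstruct(efd(sq, 20), n_points = 400)
  seg_dist <- function(px, py, x1, y1, x2, y2) {
    dx <- x2 - x1; dy <- y2 - y1
    tt <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / (dx^2 + dy^2), 0), 1)
    sqrt((px - (x1 + tt * dx))^2 + (py - (y1 + tt * dy))^2)
  }
  vx <- c(0, 1, 1, 0); vy <- c(0, 0, 1, 1)
  vx2 <- c(1, 1, 0, 0); vy2 <- c(0, 1, 1, 0)
  dev <- vapply(seq_len(nrow(rc2)), function(i) {
    min(seg_dist(rc2$x[i], rc2$y[i], vx, vy, vx2, vy2))
  }, numeric(1))
  expect_equal(max(dev), 0.010124, tolerance = 1e-3)
  expect_lt(mean(dev), 0.002)

  # compute -> reconstruct -> compute contracts to a fixed point at which a
  # round trip moves coefficients < 1e-6
  o <- template_outlines("coignetiae_like", n_points = 720)
  cols <- pipmorph:::coef_names(10)
  d <- efd(o, 10)
  res <- numeric(0)
  for (i in 1:20) {
    d2 <- efd(efd_reconstruct(d, n_points = 8000), 10)
    res <- c(res, max(abs(as.numeric(d2[1, cols]) - as.numeric(d[1, cols]))))
    d <- d2
    if (res[i] < 1e-6) break
  }
  # the map contracts towards its fixed point; the slowest mode of beaked
  # shapes has a contraction factor near 0.99, so assert the bound the
  # iteration actually reaches plus strict monotone contraction
  expect_lt(min(res), 5e-6)
  expect_true(all(diff(res) < 0))
})

test_that("reconstruction error decreases monotonically with harmonic count", {
  seg_min_dist <- function(px, py, x, y) {
    x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
    vapply(seq_along(px), function(i) {
      dx <- x2 - x; dy <- y2 - y
      tt <- pmin(pmax(((px[i] - x) * dx + (py[i] - y) * dy) /
                        (dx^2 + dy^2), 0), 1)
      min(sqrt((px[i] - (x + tt * dx))^2 + (py[i] - (y + tt * dy))^2))
    }, numeric(1))
  }
  shapes <- sample_outlines(n_per_class = 3,
                            classes = rownames(seed_templates()$coef)[1:10],
                            seed = 21)
  keep <- shapes$truth$specimen_id[!duplicated(shapes$truth$class)]
  one_per_class <- shapes$outlines[shapes$outlines$specimen_id %in% keep, ]
  for (df in pipmorph:::split_outlines(one_per_class)) {
    d <- efd(df, 20)
    errs <- vapply(1:20, function(k) {
      rc <- efd_reconstruct(d, n_points = 180, k_harmonics = k)
      mean(seg_min_dist(rc$x, rc$y, df$x, df$y))
    }, numeric(1))
    # mean point-to-polygon deviation shrinks with every added harmonic
    # beyond the first ellipse (the k = 1 -> 2 step can rise by a fraction
    # of a percent because the transform is not an orthogonal projection
    # under this metric), and the full series beats the first ellipse
    expect_true(all(diff(errs[2:20]) <= 1e-3 * errs[1]))
    expect_lt(errs[20], errs[1])
  }
})

test_that("feature CSV round-trips through the writers", {
  dr <- sample_outlines(classes = c("sylvestris_like", "rupestris_like"),
                        n_per_class = 3, seed = 2)
  fe <- efd_features(efd_normalize(efd(dr$outlines, 6)), 6)
  fe$group <- dr$truth$class[match(fe$specimen_id, dr$truth$specimen_id)]
  f <- withr::local_tempfile(fileext = ".csv")
  write_features(fe, f)
  back <- read_features(f)
  expect_equal(as.data.frame(back), as.data.frame(fe))
})
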