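make_features <- function(X, groups) {
  colnames(X) <- paste0("V", seq_len(ncol(X)))
  dplyr::bind_cols(
    tibble::tibble(specimen_id = sprintf("s%04d", seq_len(nrow(X))),
                   group = groups),
    tibble::as_tibble(as.data.frame(X)))
}

test_that("PCA reproduces closed-form variance splits and the SVD oracle", {
  set.seed(1)
  X <- cbind(stats::rnorm(2000, sd = 2), stats::rnorm(2000, sd = 1))
  p <- pip_pca(make_features(X, "A"))
  expect_equal(p$var_frac, c(0.8, 0.2), tolerance = 0.03)
  expect_equal(sum(p$var_frac), 1, tolerance = 1e-10)

  # scores/loadings match a direct SVD up to the fixed sign convention
  Y <- matrix(stats::rnorm(50 * 24), 50)
  p2 <- pip_pca(make_features(Y, "A"))
  sv <- svd(scale(Y, scale = FALSE))
  for (j in 1:5) {
    lead <- which.max(abs(sv$v[, j]))
    s <- sign(sv$v[lead, j])
    expect_equal(unname(p2$loadings[, j]), s * sv$v[, j], tolerance = 1e-8)
    expect_equal(p2$scores[[paste0("PC", j)]], s * sv$u[, j] * sv$d[j],
                 tolerance = 1e-8)
  }
  # score columns are centred and mutually uncorrelated
  S <- as.matrix(p2$scores[, paste0("PC", 1:10)])
  expect_lt(max(abs(colMeans(S))), 1e-10)
  cc <- stats::cor(S)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-8)
  expect_error(pip_pca(make_features(matrix(1, 10, 3), "A")), "constant")
})

test_that("PCA projection places new specimens in the fitted space", {
  set.seed(2)
  f <- make_features(matrix(stats::rnorm(40 * 6), 40), "A")
  p <- pip_pca(f)
  sc <- predict(p, f)
  expect_equal(as.data.frame(sc[, paste0("PC", 1:6)]),
               as.data.frame(p$scores[, paste0("PC", 1:6)]), tolerance = 1e-10)
})

test_that("stepwise selection finds the informative variable first", {
  set.seed(7)
  n <- 30
  X <- rbind(matrix(stats::rnorm(n * 11), n), matrix(stats::rnorm(n * 11), n))
  X[seq_len(n), 3] <- X[seq_len(n), 3] + 5
  X[n + seq_len(n), 3] <- X[n + seq_len(n), 3] - 5
  f <- make_features(X, rep(c("A", "B"), each = n))
  sel <- stepwise_select(f)
  expect_equal(sel[1], "V3")
  # exhaustive one-variable Wilks scan confirms V3 is the best single entry
  lam <- wilks_scan(X, f$group)
  expect_equal(which.min(lam), 3L)
})

test_that("duplicated informative columns enter only once, lowest index first", {
  set.seed(8)
  n <- 25
  base <- c(stats::rnorm(n, 2), stats::rnorm(n, -2))
  X <- cbind(base, matrix(stats::rnorm(2 * n * 3), 2 * n), base)
  f <- make_features(X, rep(c("A", "B"), each = n))
  sel <- stepwise_select(f)
  expect_true("V1" %in% sel)
  expect_false("V5" %in% sel)
})

test_that("stepwise null entry rate matches the partial-F false-entry oracle", {
  # with p independent pure-noise variables, one-variable partial-F statistics
  # are independent F(g-1, n-g-1) draws, so P(any entry) = 1 - (1 - p0)^p
  set.seed(42)
  n <- 30; p <- 11
  reps <- 1000
  entered <- logical(reps)
  for (r in seq_len(reps)) {
    X <- matrix(stats::rnorm(2 * n * p), 2 * n)
    f <- make_features(X, rep(c("A", "B"), each = n))
    sel <- suppressWarnings(stepwise_select(f))
    entered[r] <- length(sel) > 0
  }
  p0 <- stats::pf(3.84, 1, 2 * n - 2 - 1, lower.tail = FALSE)
  expected <- 1 - (1 - p0)^p
  ci <- binom_ci99(expected, reps)
  expect_gt(mean(entered), ci[1])
  expect_lt(mean(entered), ci[2])
})

test_that("stepwise warns and returns empty when nothing discriminates", {
  set.seed(9)
  X <- matrix(stats::rnorm(40 * 3, sd = 1e-3), 40)
  X[, 2] <- 7  # constant column is never selected
  f <- make_features(X, rep(c("A", "B"), each = 20))
  expect_warning(sel <- stepwise_select(f, f_enter = 1e6), "f_enter")
  expect_length(sel, 0)
})

test_that("the decision boundary of two spherical groups is the bisector", {
  # mirror-symmetric groups about x = 0: posteriors on the plane are 0.5
  set.seed(10)
  A <- cbind(stats::rnorm(40, -3), stats::rnorm(40))
  f <- make_features(rbind(A, cbind(-A[, 1], A[, 2])),
                     rep(c("A", "B"), each = 40))
  m <- pip_lda(f)
  grid <- make_features(cbind(rep(0, 9), seq(-2, 2, length.out = 9)),
                        rep("unknown", 9))
  pr <- predict(m, grid)
  expect_equal(pr$A, rep(0.5, 9), tolerance = 1e-6)

  # a specimen at a far group mean is assigned with near certainty
  at_mean <- make_features(matrix(c(-3, 0), 1), "unknown")
  expect_gt(predict(m, at_mean)$A, 0.999)
})

test_that("classification functions agree with independent oracles", {
  set.seed(11)
  n <- 20
  X <- rbind(matrix(stats::rnorm(n * 4), n),
             matrix(stats::rnorm(n * 4, 1.5), n),
             matrix(stats::rnorm(n * 4, -1), n))
  g <- rep(c("A", "B", "C"), each = n)
  f <- make_features(X, g)
  m <- pip_lda(f)
  new <- matrix(stats::rnorm(40), 10, 4,
                dimnames = list(NULL, paste0("V", 1:4)))
  got <- predict(m, make_features(new, "unknown"))
  # normal-equations oracle assembled in the test helpers
  orc <- lda_oracle_posterior(X, g, new)
  expect_equal(as.matrix(got[, c("A", "B", "C")]), orc, tolerance = 1e-8,
               ignore_attr = TRUE)
  # MASS::lda as an independent published implementation
  skip_if_not_installed("MASS")
  Xn <- X; colnames(Xn) <- paste0("V", 1:4)
  mm <- MASS::lda(Xn, grouping = g, prior = rep(1 / 3, 3))
  pm <- stats::predict(mm, new)$posterior
  expect_equal(as.matrix(got[, c("A", "B", "C")]), pm, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("LDA outputs are invariant to specimen order and feature translation", {
  set.seed(12)
  f <- gaussian_two_group(30, delta = 2, seed = 12)
  cv1 <- loocv_classify(f)
  perm <- sample(nrow(f))
  cv2 <- loocv_classify(f[perm, ])
  expect_equal(cv1$overall, cv2$overall)
  expect_equal(dplyr::arrange(cv1$confusion, true_group),
               dplyr::arrange(cv2$confusion, true_group))
  shifted <- f
  shifted[, -(1:2)] <- shifted[, -(1:2)] + 100
  cv3 <- loocv_classify(shifted)
  expect_equal(cv1$posteriors$predicted, cv3$posteriors$predicted)
  expect_equal(cv1$overall, cv3$overall, tolerance = 1e-9)
})

test_that("LOOCV is at chance for identically distributed groups", {
  f <- gaussian_two_group(100, delta = 0, seed = 13)
  cv <- loocv_classify(f)
  ci <- 100 * binom_ci99(0.5, 200)
  expect_gt(cv$overall, ci[1])
  expect_lt(cv$overall, ci[2])
  # confusion rows are percentages
  expect_equal(cv$confusion$Total, c(100, 100))
  expect_true(all(abs(rowSums(as.matrix(cv$confusion[, c("A", "B")])) - 100) < 0.1))
  # posteriors normalize
  expect_true(all(abs(rowSums(as.matrix(cv$posteriors[, c("A", "B")])) - 1) < 1e-10))
})

test_that("LOOCV refuses groups too small to refit", {
  f <- gaussian_two_group(10, delta = 1, seed = 14)[c(1:2, 11:20), ]
  expect_error(loocv_classify(f), "at least 3")
})

test_that("unknown specimens drawn from a reference class are recovered", {
  set.seed(15)
  d <- 4; delta <- 6
  ref <- gaussian_two_group(50, delta = delta, d = d, seed = 15)
  m <- pip_lda(ref)
  unk <- make_features(matrix(stats::rnorm(60 * d), 60), "unknown")  # class A generator
  al <- classify_unknown(m, unk)
  expect_equal(sum(al$table$percent), 100, tolerance = 1e-9)
  expect_gt(al$table$percent[al$table$group == "A"], 95)
})

test_that("posterior ties and equidistant unknowns split evenly", {
  set.seed(16)
  A <- matrix(stats::rnorm(60 * 2), 60)
  f <- make_features(rbind(sweep(A[1:30, ], 2, c(-2, 0), "+"),
                           sweep(A[31:60, ], 2, c(2, 0), "+")),
                     rep(c("A", "B"), each = 30))
  m <- pip_lda(f)
  # exactly equidistant specimen: posteriors 0.5/0.5
  mid <- make_features(matrix((m$means["A", ] + m$means["B", ]) / 2, 1), "unknown")
  pr <- suppressMessages(predict(m, mid))
  expect_equal(pr$A, 0.5, tolerance = 1e-8)
  expect_equal(pr$B, 0.5, tolerance = 1e-8)
})

test_that("threshold allocation honours the inclusive boundary", {
  post <- tibble::tibble(
    specimen_id = c("u1", "u2", "u3"),
    predicted = c("A", "A", "B"),
    A = c(0.91, 0.89, 0.10),
    B = c(0.09, 0.11, 0.90))
  al <- threshold_allocate(post, p_min = 0.90)
  assigned <- al$posteriors$assigned
  expect_equal(assigned, c("A", "unassigned", "B"))  # 0.90 itself is assigned
  expect_equal(al$table$percent[al$table$group == "unassigned"], 100 / 3,
               tolerance = 1e-9)
  expect_equal(sum(al$table$percent), 100, tolerance = 1e-9)
  expect_error(threshold_allocate(post, p_min = 0), "p_min")
  expect_error(threshold_allocate(post, p_min = 1.2), "p_min")
  bad <- post; bad$A <- bad$A + 0.2
  expect_error(threshold_allocate(bad, p_min = 0.9), "sum to 1")
})

test_that("a vanishing threshold reproduces the argmax allocation", {
  set.seed(17)
  ref <- gaussian_two_group(30, delta = 3, seed = 17)
  m <- pip_lda(ref)
  unk <- make_features(matrix(stats::rnorm(40 * 5, 0.3), 40), "unknown")
  al <- classify_unknown(m, unk)
  th <- threshold_allocate(al, p_min = 1e-12)
  expect_equal(th$table$percent[match(al$table$group, th$table$group)],
               al$table$percent, tolerance = 1e-12)
  expect_equal(th$table$percent[th$table$group == "unassigned"], 0)
})

test_that("proportional priors shift posteriors the Bayes way", {
  set.seed(18)
  X <- rbind(matrix(stats::rnorm(60 * 2), 60), matrix(stats::rnorm(20 * 2, 2), 20))
  f <- make_features(X, c(rep("big", 60), rep("small", 20)))
  m_eq <- pip_lda(f, priors = "equal")
  m_pr <- pip_lda(f, priors = "proportional")
  x0 <- make_features(matrix(c(1, 1), 1), "unknown")
  p_eq <- predict(m_eq, x0); p_pr <- predict(m_pr, x0)
  # the larger group gains posterior mass under proportional priors
  expect_gt(p_pr$big, p_eq$big)
  # and the log-odds shift equals log(n_big / n_small)
  lo <- function(p) log(p$big / p$small)
  expect_equal(lo(p_pr) - lo(p_eq), log(60 / 20), tolerance = 1e-8)
})

test_that("tidy and glance methods return well-formed summaries", {
  f <- gaussian_two_group(20, delta = 3, seed = 19)
  p <- pip_pca(f)
  expect_named(tidy(p), c("variable", "component", "loading"))
  expect_equal(glance(p)$n, 40)
  m <- pip_lda(f)
  td <- tidy(m)
  expect_setequal(unique(td$group), c("A", "B"))
  expect_true("(Intercept)" %in% td$term)
  cv <- loocv_classify(f)
  expect_named(tidy(cv), c("true_group", "predicted", "percent"))
  expect_equal(glance(cv)$overall_correct_pct, cv$overall)
})
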