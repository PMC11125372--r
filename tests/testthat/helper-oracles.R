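# Independent oracles.
#
# efd_quadrature integrates the elliptic Fourier integrals of the
# chord-length-parameterized polygon by dense trapezoid quadrature -- a route
# independent of the package's closed-form per-segment accumulation.
efd_quadrature <- function(outline, n_harmonics, n_steps = 1e5) {
  x <- outline$x; y <- outline$y
  k <- length(x)
  xc <- c(x, x[1]); yc <- c(y, y[1])
  seg <- sqrt(diff(xc)^2 + diff(yc)^2)
  len <- c(0, cumsum(seg))
  total <- len[k + 1]
  t_dense <- seq(0, total, length.out = n_steps + 1)
  xd <- stats::approx(len, xc, xout = t_dense, ties = "ordered")$y
  yd <- stats::approx(len, yc, xout = t_dense, ties = "ordered")$y
  trap <- function(f) {
    # trapezoid rule on the uniform dense grid
    h <- total / n_steps
    h * (sum(f) - (f[1] + f[length(f)]) / 2)
  }
  coef <- t(vapply(seq_len(n_harmonics), function(n) {
    w <- 2 * pi * n * t_dense / total
    c(a = 2 / total * trap(xd * cos(w)),
      b = 2 / total * trap(xd * sin(w)),
      c = 2 / total * trap(yd * cos(w)),
      d = 2 / total * trap(yd * sin(w)))
  }, numeric(4)))
  list(a0 = trap(xd) / total, c0 = trap(yd) / total, coef = coef,
       power = rowSums(coef^2) / 2)
}

# exhaustive one-variable Wilks' lambda scan (oracle for the stepwise entry)
wilks_scan <- function(X, g) {
  g <- factor(g)
  vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    tot <- sum((v - mean(v))^2)
    wit <- sum(unlist(lapply(levels(g), function(l) {
      u <- v[g == l]; (u - mean(u))^2
    })))
    wit / tot
  }, numeric(1))
}

# pooled-covariance linear classification oracle assembled from plain
# normal-equations algebra (independent of the package's fitting code)
lda_oracle_posterior <- function(X, g, newx, priors = NULL) {
  g <- factor(g)
  lev <- levels(g)
  n <- nrow(X); ng <- length(lev)
  mu <- t(vapply(lev, function(l) colMeans(X[g == l, , drop = FALSE]),
                 numeric(ncol(X))))
  W <- matrix(0, ncol(X), ncol(X))
  for (l in lev) {
    Z <- scale(X[g == l, , drop = FALSE], scale = FALSE)
    W <- W + t(Z) %*% Z
  }
  S <- W / (n - ng)
  pri <- priors %||% rep(1 / ng, ng)
  disc <- vapply(seq_along(lev), function(i) {
    dv <- sweep(newx, 2, mu[i, ])
    -0.5 * rowSums((dv %*% solve(S)) * dv) + log(pri[i])
  }, numeric(nrow(newx)))
  disc <- matrix(disc, nrow = nrow(newx))
  p <- exp(disc - apply(disc, 1, max))
  p / rowSums(p)
}

# gaussian two-group feature tibble at a given Mahalanobis separation
gaussian_two_group <- function(n_per_group, delta, d = 5, seed = 1) {
  set.seed(seed)
  shift <- delta / sqrt(d)
  X <- rbind(
    matrix(stats::rnorm(n_per_group * d), n_per_group),
    matrix(stats::rnorm(n_per_group * d, mean = shift), n_per_group))
  colnames(X) <- paste0("V", seq_len(d))
  dplyr::bind_cols(
    tibble::tibble(
      specimen_id = sprintf("s%04d", seq_len(2 * n_per_group)),
      group = rep(c("A", "B"), each = n_per_group)),
    tibble::as_tibble(as.data.frame(X)))
}

binom_ci99 <- function(p, n) {
  se <- sqrt(p * (1 - p) / n)
  c(p - 2.576 * se, p + 2.576 * se)
}
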