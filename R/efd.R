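#' Elliptic Fourier descriptors of closed outlines
#'
#' Computes elliptic Fourier coefficients of each closed outline from the
#' chord-length (piecewise-linear) parameterization of the polygon, using the
#' classical closed-form per-segment accumulation. This is exact for polygons
#' and handles unequally spaced points, unlike an FFT of resampled
#' coordinates.
#'
#' The outline `(x(t), y(t))`, `t` in `[0, T)`, is expanded as
#' \deqn{x(t) = a_0 + \sum_n a_n \cos(2\pi n t/T) + b_n \sin(2\pi n t/T)}
#' and likewise `y(t)` with coefficients `c_n`, `d_n`.
#'
#' @param outlines Outline tibble (`specimen_id`, `x`, `y`).
#' @param n_harmonics Number of harmonics to compute (default 20, enough for
#'   the harmonic-power diagnostic; the feature vector truncates to 6 later).
#' @return A descriptor tibble: one row per specimen with columns
#'   `specimen_id`, `normalized` (FALSE), `a0`, `c0`, then `a1, b1, c1, d1,
#'   ..., a<N>, ..., d<N>`.
#' @seealso [efd_normalize()], [efd_features()], [harmonic_power()],
#'   [efd_reconstruct()]
#' @export
efd <- function(outlines, n_harmonics = 20) {
  if (!is.numeric(n_harmonics) || length(n_harmonics) != 1 || n_harmonics < 1) {
    abort("`n_harmonics` must be a single integer >= 1")
  }
  n_harmonics <- as.integer(n_harmonics)
  purrr::map_dfr(split_outlines(outlines), function(df) {
    co <- efd_core(outline_matrix(df), n_harmonics)
    row <- c(co$a0, co$c0, as.vector(t(co$coef)))
    names(row) <- c("a0", "c0", coef_names(n_harmonics))
    dplyr::bind_cols(
      tibble(specimen_id = df$specimen_id[1], normalized = FALSE),
      as_tibble(as.list(row))
    )
  })
}

# Kuhl-Giardina per-segment closed form on one polygon (k x 2 matrix).
# Returns a0, c0 (curve centroid under chord-length parameterization) and an
# n x 4 coefficient matrix with columns a, b, c, d.
efd_core <- function(xy, n_harmonics) {
  keep <- c(TRUE, rowSums(abs(diff(xy))) > 0)
  xy <- xy[keep, , drop = FALSE]
  k <- nrow(xy)
  if (k < 3) abort("outline must have at least 3 distinct points")
  closed <- rbind(xy, xy[1, ])
  d <- diff(closed)
  dt <- sqrt(rowSums(d^2))
  tc <- cumsum(dt)
  tp <- c(0, tc[-k])
  total <- tc[k]
  if (total <= 0) abort("degenerate outline with zero perimeter")
  h <- seq_len(n_harmonics)
  w <- 2 * pi / total
  # k x n phase matrices
  arg_c <- tc %o% (w * h)
  arg_p <- tp %o% (w * h)
  dcos <- cos(arg_c) - cos(arg_p)
  dsin <- sin(arg_c) - sin(arg_p)
  const <- total / (2 * pi^2 * h^2)
  vx <- d[, 1] / dt
  vy <- d[, 2] / dt
  a <- const * colSums(vx * dcos)
  b <- const * colSums(vx * dsin)
  cc <- const * colSums(vy * dcos)
  dd <- const * colSums(vy * dsin)
  # exact curve centroid of the piecewise-linear parameterization
  a0 <- sum(dt * (closed[1:k, 1] + closed[2:(k + 1), 1]) / 2) / total
  c0 <- sum(dt * (closed[1:k, 2] + closed[2:(k + 1), 2]) / 2) / total
  list(a0 = a0, c0 = c0, coef = cbind(a = a, b = b, c = cc, d = dd),
       perimeter = total)
}

# apply a start-point shift theta and return the n x 4 coefficient matrix
shift_start <- function(coef, theta) {
  n <- nrow(coef)
  h <- seq_len(n)
  cs <- cos(h * theta); sn <- sin(h * theta)
  cbind(
    a = coef[, 1] * cs + coef[, 2] * sn,
    b = -coef[, 1] * sn + coef[, 2] * cs,
    c = coef[, 3] * cs + coef[, 4] * sn,
    d = -coef[, 3] * sn + coef[, 4] * cs
  )
}

# rotate the plane by -psi (align first-harmonic major axis with x)
rotate_plane <- function(coef, psi) {
  cs <- cos(psi); sn <- sin(psi)
  cbind(
    a = cs * coef[, 1] + sn * coef[, 3],
    b = cs * coef[, 2] + sn * coef[, 4],
    c = -sn * coef[, 1] + cs * coef[, 3],
    d = -sn * coef[, 2] + cs * coef[, 4]
  )
}

# full first-ellipse standardization of one coefficient matrix under a given
# start-point angle; returns the normalized matrix (a1 = 1, c1 = b1 = 0,
# d1 > 0)
normalize_at <- function(coef, theta) {
  co <- shift_start(coef, theta)
  psi <- atan2(co[1, 3], co[1, 1])
  co <- rotate_plane(co, psi)
  scale <- co[1, 1]  # = sqrt(a1^2 + c1^2) >= 0 after rotation
  co <- co / scale
  if (co[1, 4] < 0) {
    # clockwise parameter direction: reverse traversal (t -> -t) to make the
    # minor-axis sign convention positive
    co[, 2] <- -co[, 2]
    co[, 4] <- -co[, 4]
  }
  co
}

# Deterministic choice among candidate normalizations (180-degree flip, and
# the 4-fold ambiguity of a near-circular first harmonic). Primary criterion:
# the skewness of x(t), which is positive when the shape's asymmetric
# (beak-bearing) end points along +x and is negated by the joint flip --
# robust to coefficient noise, unlike any single small coefficient. Exactly
# symmetric shapes fall back to a lexicographic comparison of the harmonic-2+
# coefficients.
pick_candidate <- function(cands, tol = 1e-9) {
  if (length(cands) == 1) return(cands[[1]])
  skew <- vapply(cands, function(m) {
    x <- fourier_eval(m, 128)[, 1]
    mean((x - mean(x))^3)
  }, numeric(1))
  alive <- which(skew > max(skew) - tol)
  if (length(alive) == 1) return(cands[[alive]])
  nh <- nrow(cands[[1]])
  if (nh >= 2) {
    flat <- vapply(cands, function(m) as.vector(t(m[-1, , drop = FALSE])),
                   numeric((nh - 1) * 4))
    for (j in seq_len(nrow(flat))) {
      vals <- flat[j, alive]
      best <- max(vals)
      alive <- alive[vals > best - tol]
      if (length(alive) == 1) break
    }
  }
  cands[[alive[1]]]
}

#' Normalize elliptic Fourier descriptors
#'
#' Standardizes raw descriptors for position, size, in-plane rotation and
#' starting point using the first-harmonic ellipse: position terms are
#' zeroed, the parameter origin is shifted so the first point lies on the
#' first ellipse's major axis, the plane is rotated so that axis coincides
#' with x, and all coefficients are divided by the semi-major axis magnitude.
#' After normalization the first-harmonic quadruple is `(1, 0, 0, d1)` with
#' `d1 > 0` (the minor/major axis ratio for an ellipse).
#'
#' The 180-degree start/rotation ambiguity (and the 4-fold ambiguity when the
#' first harmonic is nearly circular, axis ratio > 0.99) is resolved by a
#' deterministic comparison of the harmonic-2 (then 3, ...) coefficients
#' across the candidate orientations, so congruent outlines in any pose map
#' to identical coefficients.
#'
#' @param descriptors Descriptor tibble from [efd()] with `normalized = FALSE`.
#' @return The descriptor tibble with `normalized = TRUE`, `a0 = c0 = 0`.
#' @export
efd_normalize <- function(descriptors) {
  if (any(descriptors$normalized)) {
    abort("descriptors are already normalized")
  }
  nh <- descriptor_harmonics(descriptors)
  cols <- coef_names(nh)
  out <- descriptors
  for (i in seq_len(nrow(descriptors))) {
    coef <- matrix(as.numeric(descriptors[i, cols]), nrow = nh, ncol = 4,
                   byrow = TRUE)
    out[i, cols] <- as.list(as.vector(t(normalize_coef(coef))))
  }
  out$a0 <- 0
  out$c0 <- 0
  out$normalized <- TRUE
  out
}

# normalize one n x 4 coefficient matrix
normalize_coef <- function(coef) {
  a1 <- coef[1, 1]; b1 <- coef[1, 2]; c1 <- coef[1, 3]; d1 <- coef[1, 4]
  if (a1^2 + b1^2 + c1^2 + d1^2 < .Machine$double.eps) {
    abort("first harmonic is degenerate; cannot normalize")
  }
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
  # make phase 0 the major axis
  at <- shift_start(coef[1, , drop = FALSE], theta)
  e_major <- sqrt(at[1, 1]^2 + at[1, 3]^2)
  e_minor <- sqrt(at[1, 2]^2 + at[1, 4]^2)
  if (e_minor > e_major) {
    theta <- theta + pi / 2
    tmp <- e_major; e_major <- e_minor; e_minor <- tmp
  }
  near_circular <- e_major > 0 && e_minor / e_major > 0.99
  if (near_circular && nrow(coef) >= 2) {
    # circle-ambiguous first ellipse: the Jacobi angle is ill-conditioned, so
    # anchor the orientation on harmonic 2 instead -- take the start angles
    # that minimize its off-diagonal energy (continuity of the normalization
    # map), then disambiguate the discrete minima like any other candidates
    thetas <- h2_canonical_angles(coef)
    if (length(thetas) == 0) thetas <- theta + c(0, pi / 2, pi, 3 * pi / 2)
  } else {
    thetas <- theta + c(0, pi)
  }
  cands <- lapply(thetas, function(th) normalize_at(coef, th))
  pick_candidate(cands)
}

# Start angles that diagonalize harmonic 2 after full normalization, used
# when the first harmonic is too circular to define an orientation. The
# off-diagonal energy b2(theta)^2 + c2(theta)^2 is scanned on a fine grid
# and each distinct local minimum is polished with stats::optimize().
h2_canonical_angles <- function(coef, grid = 720) {
  offdiag <- function(th) {
    m <- normalize_at(coef, th)
    m[2, 2]^2 + m[2, 3]^2
  }
  th <- 2 * pi * (seq_len(grid) - 1) / grid
  f <- vapply(th, offdiag, numeric(1))
  if (diff(range(f)) < 1e-12) return(numeric(0))
  is_min <- f <= c(f[-1], f[1]) & f <= c(f[grid], f[-grid]) &
    f < min(f) + 1e-6 * diff(range(f))
  step <- 2 * pi / grid
  vapply(th[is_min], function(t0) {
    stats::optimize(offdiag, interval = c(t0 - step, t0 + step),
                    tol = 1e-12)$minimum
  }, numeric(1))
}

# number of harmonics stored in a descriptor tibble
descriptor_harmonics <- function(descriptors) {
  hcols <- grep("^[abcd][0-9]+$", names(descriptors), value = TRUE)
  hs <- as.integer(sub("^[abcd]", "", hcols))
  hs <- setdiff(hs, 0L)
  if (length(hs) == 0) abort("no harmonic coefficient columns found")
  max(hs)
}

#' Harmonic power profile of descriptors
#'
#' The power of harmonic `n` is `P_n = (a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2`;
#' the cumulative fraction at `k` is the power of harmonics `1..k` relative
#' to the total over the first `n_reference` harmonics. The published
#' truncation criterion ("first six harmonics capture more than 95% of the
#' total harmonic power") is evaluated against this profile.
#'
#' @param descriptors Descriptor tibble from [efd()] (raw or normalized).
#' @param n_reference Reference total for "total power" (default 20).
#' @return Tibble with columns `specimen_id`, `harmonic`, `power`, `cum_frac`.
#' @export
harmonic_power <- function(descriptors, n_reference = 20) {
  nh <- descriptor_harmonics(descriptors)
  if (nh < n_reference) {
    abort(sprintf(
      "descriptors hold %d harmonics but n_reference = %d; recompute efd() with more harmonics",
      nh, n_reference))
  }
  purrr::map_dfr(seq_len(nrow(descriptors)), function(i) {
    pw <- vapply(seq_len(n_reference), function(h) {
      q <- as.numeric(descriptors[i, paste0(c("a", "b", "c", "d"), h)])
      sum(q^2) / 2
    }, numeric(1))
    tibble(
      specimen_id = descriptors$specimen_id[i],
      harmonic = seq_len(n_reference),
      power = pw,
      cum_frac = cumsum(pw) / sum(pw)
    )
  })
}

#' Truncate normalized descriptors to the classification feature vector
#'
#' Concatenates the per-harmonic quadruples of the first `k_harmonics`
#' harmonics, giving `4 * k_harmonics` coefficients per specimen (24 with the
#' default six harmonics). The normalization-fixed coefficients `a1` (= 1)
#' and `b1`, `c1` (= 0) are retained to keep the published feature dimension;
#' downstream stepwise selection ignores constant columns.
#'
#' @param descriptors Normalized descriptor tibble from [efd_normalize()].
#' @param k_harmonics Number of harmonics kept (default 6).
#' @return Feature tibble: `specimen_id` plus `a1 ... d<k>` columns.
#' @export
efd_features <- function(descriptors, k_harmonics = 6) {
  if (!all(descriptors$normalized)) {
    abort("feature vectors require normalized descriptors; call efd_normalize() first")
  }
  nh <- descriptor_harmonics(descriptors)
  if (nh < k_harmonics) {
    abort(sprintf("descriptors hold %d harmonics; %d requested", nh, k_harmonics))
  }
  descriptors[, c("specimen_id", coef_names(k_harmonics))]
}

#' Reconstruct outlines from descriptors
#'
#' Evaluates the truncated Fourier series at `n_points` uniform parameter
#' values. Useful for inspecting how much shape each harmonic carries and for
#' round-trip testing.
#'
#' @param descriptors Descriptor tibble (raw or normalized).
#' @param n_points Points per reconstructed outline.
#' @param k_harmonics Harmonics used (default: all stored).
#' @return Outline tibble (`specimen_id`, `point`, `x`, `y`).
#' @export
efd_reconstruct <- function(descriptors, n_points = 360, k_harmonics = NULL) {
  nh <- descriptor_harmonics(descriptors)
  k <- k_harmonics %||% nh
  if (k > nh) abort("k_harmonics exceeds stored harmonics")
  tt <- (seq_len(n_points) - 1) / n_points
  purrr::map_dfr(seq_len(nrow(descriptors)), function(i) {
    coef <- matrix(as.numeric(descriptors[i, coef_names(nh)]), nrow = nh,
                   ncol = 4, byrow = TRUE)
    x <- rep(descriptors$a0[i], n_points)
    y <- rep(descriptors$c0[i], n_points)
    for (h in seq_len(k)) {
      cs <- cos(2 * pi * h * tt); sn <- sin(2 * pi * h * tt)
      x <- x + coef[h, 1] * cs + coef[h, 2] * sn
      y <- y + coef[h, 3] * cs + coef[h, 4] * sn
    }
    tibble(specimen_id = descriptors$specimen_id[i], point = seq_len(n_points),
           x = x, y = y)
  })
}

#' Write a feature matrix as CSV
#'
#' Columns: `specimen_id`, `group`, then the coefficient columns.
#'
#' @param features Feature tibble (with `group` column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' Read a feature matrix CSV written by [write_features()]
#' @param path CSV path.
#' @return Feature tibble.
#' @export
read_features <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    specimen_id = readr::col_character(),
    group = readr::col_character(),
    .default = readr::col_double()
  ))
}
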