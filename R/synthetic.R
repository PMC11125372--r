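# Synthetic grape-pip cohorts with known class structure.
#
# Templates live in normalized elliptic-Fourier space so that class truth is
# expressed in the same coordinates the analysis uses; specimens are drawn by
# perturbing template coefficients, reconstructed as outlines, posed, and
# (optionally) rasterized and written as silhouette images so the whole
# imaging chain is exercised.

# temporarily set the RNG seed, restoring caller state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# parametric pip silhouette: egg-like body (aspect < 1, egg asymmetry) with a
# beak-like apical extension along +x, traversed counter-clockwise
pip_shape_xy <- function(t, aspect, egg, beak_len, beak_width, flatten) {
  x0 <- cos(t)
  y0 <- aspect * (1 + egg * cos(t) + flatten * cos(2 * t)) * sin(t)
  dt <- pmin(abs(t %% (2 * pi)), 2 * pi - abs(t %% (2 * pi)))
  m <- 1 + beak_len * exp(-dt^2 / (2 * beak_width^2))
  cbind(x = x0 * m, y = y0 * m)
}

template_params <- function() {
  p <- tibble::tribble(
    ~name,               ~continent,        ~aspect, ~egg, ~beak, ~beak_width, ~flatten,
    "sylvestris_like",   "eurasian",        0.60, 0.20, 0.34, 0.28,  0.02,
    "amurensis_like",    "eurasian",        0.62, 0.22, 0.31, 0.27,  0.03,
    "ficifolia_like",    "eurasian",        0.59, 0.18, 0.36, 0.29,  0.00,
    "heyneana_like",     "eurasian",        0.63, 0.17, 0.33, 0.30,  0.04,
    "romanetii_like",    "eurasian",        0.57, 0.23, 0.30, 0.26,  0.01,
    "vinifera_like",     "eurasian",        0.54, 0.26, 0.42, 0.30,  0.02,
    "thunbergii_like",   "eurasian",        0.66, 0.12, 0.26, 0.26,  0.06,
    "yenshanensis_like", "eurasian",        0.68, 0.14, 0.24, 0.28,  0.03,
    "betulifolia_like",  "eurasian",        0.65, 0.20, 0.22, 0.30, -0.02,
    "piasezkii_like",    "eurasian",        0.61, 0.10, 0.28, 0.24,  0.08,
    "coignetiae_like",   "eurasian",        0.70, 0.16, 0.20, 0.28,  0.05,
    "riparia_like",      "north_american",  0.74, 0.08, 0.14, 0.30,  0.02,
    "rupestris_like",    "north_american",  0.78, 0.06, 0.10, 0.32,  0.04,
    "labrusca_like",     "north_american",  0.72, 0.10, 0.16, 0.28, -0.03,
    "aestivalis_like",   "north_american",  0.76, 0.12, 0.12, 0.30,  0.05,
    "cinerea_like",      "north_american",  0.71, 0.07, 0.18, 0.26,  0.06,
    "berlandieri_like",  "north_american",  0.75, 0.05, 0.15, 0.30,  0.00
  )
  p
}

#' Default synthetic seed-class templates
#'
#' Returns 17 named seed-like shape classes (11 Eurasian-style, 6 North
#' American-style) standing in for modern reference accessions. Each template
#' is a normalized elliptic Fourier descriptor (20 harmonics) of a pyriform
#' body with a beak-like apical extension; Eurasian-style templates are more
#' elongate with longer beaks, North American-style ones squatter, which
#' mirrors the real dorsal-view contrast. The `"sylvestris_like"` template is
#' flagged as the wild-grapevine reference; `"amurensis_like"`,
#' `"ficifolia_like"`, `"heyneana_like"` and `"romanetii_like"` are its
#' designated near neighbours. Construction is deterministic (no RNG).
#'
#' @param sd_base Baseline within-class coefficient standard deviation (default
#'   1% of the semi-major axis); the
#'   dispersion of harmonic `h` coefficients is `sd_base / sqrt(h)`, with the
#'   normalization-fixed coefficients `a1`, `b1`, `c1` held at zero
#'   dispersion.
#' @param n_harmonics Harmonics generated per template (>= 20).
#' @return A `pip_templates` object: list with `coef` (templates x
#'   coefficients matrix), `info` (tibble: name, continent, reference flag),
#'   `dispersion` (named vector), `n_harmonics`.
#' @export
seed_templates <- function(sd_base = 0.01, n_harmonics = 20) {
  stopifnot(n_harmonics >= 20)
  params <- template_params()
  tt <- 2 * pi * (seq_len(1024) - 1) / 1024
  coef <- t(vapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    xy <- pip_shape_xy(tt, p$aspect, p$egg, p$beak, p$beak_width, p$flatten)
    co <- efd_core(xy, n_harmonics)
    as.vector(t(normalize_coef(co$coef)))
  }, numeric(4 * n_harmonics)))
  colnames(coef) <- coef_names(n_harmonics)
  rownames(coef) <- params$name
  disp <- rep(sd_base / sqrt(seq_len(n_harmonics)), each = 4)
  names(disp) <- coef_names(n_harmonics)
  disp[c("a1", "b1", "c1")] <- 0  # fixed by normalization; not free to vary
  # within-class variation is modelled in the classification feature space
  # (harmonics 1..6); higher harmonics carry class-specific fine structure
  # deterministically, so the realized feature-space separation equals the
  # nominal one (arc-length re-measurement mixes noise linearly, which
  # preserves full-covariance Mahalanobis distances only when the noise
  # lives in the measured subspace)
  disp[!names(disp) %in% coef_names(6)] <- 0
  structure(list(
    coef = coef,
    info = tibble(name = params$name, continent = params$continent,
                  reference = params$name == "sylvestris_like"),
    dispersion = disp,
    n_harmonics = n_harmonics
  ), class = "pip_templates")
}

#' @export
print.pip_templates <- function(x, ...) {
  cat(sprintf("<pip_templates> %d classes (%s), %d harmonics\n",
              nrow(x$coef),
              paste(sprintf("%d %s", table(x$info$continent),
                            names(table(x$info$continent))), collapse = ", "),
              x$n_harmonics))
  invisible(x)
}

# derive a variant template by nudging shape parameters (used for the
# western/eastern wild-grapevine ecotype split in the demonstration fixture)
template_variant <- function(templates, base, new_name, continent = NULL,
                             d_aspect = 0, d_egg = 0, d_beak = 0) {
  params <- template_params()
  p <- params[params$name == base, ]
  if (nrow(p) != 1) abort(sprintf("unknown base template '%s'", base))
  tt <- 2 * pi * (seq_len(1024) - 1) / 1024
  xy <- pip_shape_xy(tt, p$aspect + d_aspect, p$egg + d_egg, p$beak + d_beak,
                     p$beak_width, p$flatten)
  co <- efd_core(xy, templates$n_harmonics)
  newc <- as.vector(t(normalize_coef(co$coef)))
  templates$coef <- rbind(templates$coef, newc)
  rownames(templates$coef)[nrow(templates$coef)] <- new_name
  templates$info <- dplyr::bind_rows(
    templates$info,
    tibble(name = new_name,
           continent = continent %||% p$continent,
           reference = FALSE))
  templates
}

#' Pairwise class separation implied by the generator
#'
#' Mahalanobis distance between template means under the generator's
#' diagonal dispersion (coefficients with zero dispersion are excluded),
#' scaled by the `separation` multiplier. By default the distance is
#' measured in the classification feature space -- the coefficients of the
#' first `k_harmonics` harmonics -- because that is the separation that
#' governs the Bayes error of downstream classification; harmonics beyond
#' the truncation carry between-class signal that the classifier never sees.
#'
#' @param templates A `pip_templates` object.
#' @param separation Between-class mean multiplier (as in [sample_outlines()]).
#' @param k_harmonics Harmonic truncation of the feature space (default 6,
#'   matching [efd_features()]); `NULL` uses every generated harmonic.
#' @return Tibble: `class_a`, `class_b`, `delta`.
#' @export
template_separation <- function(templates, separation = 1, k_harmonics = 6) {
  free <- templates$dispersion > 0
  if (!is.null(k_harmonics)) {
    free <- free & names(templates$dispersion) %in% coef_names(k_harmonics)
  }
  sd_ <- templates$dispersion[free]
  nm <- rownames(templates$coef)
  grand <- colMeans(templates$coef)
  centers <- grand[col(templates$coef)] +
    separation * (templates$coef - grand[col(templates$coef)])
  pairs <- utils::combn(seq_along(nm), 2)
  tibble(
    class_a = nm[pairs[1, ]],
    class_b = nm[pairs[2, ]],
    delta = apply(pairs, 2, function(ij) {
      sqrt(sum(((centers[ij[1], free] - centers[ij[2], free]) / sd_)^2))
    })
  )
}

#' Realized class separation in the measured feature space
#'
#' [template_separation()] reports the nominal Mahalanobis distance in the
#' generator's coefficient space. What the classifier experiences is the
#' separation after outline reconstruction and arc-length re-measurement,
#' whose (locally linear) map re-mixes the generative noise; the realized
#' distance is systematically smaller. This function estimates it by Monte
#' Carlo: coefficient draws are pushed through reconstruction and normalized
#' re-measurement (no rasterization), and pairwise Mahalanobis distances are
#' computed from the empirical class means and pooled covariance in the
#' truncated feature space. Realized distances scale linearly in
#' `separation`, which is how the cascade fixture calibrates a target
#' minimum separation.
#'
#' @inheritParams template_separation
#' @param classes Classes to include (default: all).
#' @param n_per_class Monte Carlo draws per class.
#' @param seed Optional RNG seed.
#' @return Tibble: `class_a`, `class_b`, `delta`.
#' @export
realized_separation <- function(templates, classes = NULL, separation = 1,
                                n_per_class = 120, k_harmonics = 6,
                                seed = NULL) {
  with_seed(seed, {
    classes <- classes %||% rownames(templates$coef)
    nh <- templates$n_harmonics
    fcols <- which(names(templates$dispersion) %in% coef_names(k_harmonics))
    free <- which(templates$dispersion > 0)
    grand <- colMeans(templates$coef)
    sims <- lapply(classes, function(cl) {
      center <- grand + separation * (templates$coef[cl, ] - grand)
      t(replicate(n_per_class, {
        v <- center
        v[free] <- v[free] + stats::rnorm(length(free), 0,
                                          templates$dispersion[free])
        co <- normalize_coef(efd_core(fourier_eval(
          matrix(v, nh, 4, byrow = TRUE), 512), nh)$coef)
        as.vector(t(co))[fcols]
      }))
    })
    names(sims) <- classes
    n_tot <- length(classes) * n_per_class
    pooled <- Reduce(`+`, lapply(sims, function(s) stats::cov(s) * (nrow(s) - 1))) /
      (n_tot - length(classes))
    sds <- sqrt(diag(pooled))
    keep <- sds > 1e-9 * max(sds)
    pairs <- utils::combn(seq_along(classes), 2)
    tibble(
      class_a = classes[pairs[1, ]],
      class_b = classes[pairs[2, ]],
      delta = apply(pairs, 2, function(ij) {
        g <- colMeans(sims[[ij[1]]])[keep] - colMeans(sims[[ij[2]]])[keep]
        sqrt(sum(g * solve(pooled[keep, keep], g)))
      })
    )
  })
}

# smooth circular moving average used by the roughening model
circular_smooth <- function(x, window) {
  k <- length(x)
  w <- min(window, k)
  pad <- c(x[(k - w + 1):k], x, x[1:w])
  sm <- stats::filter(pad, rep(1 / w, w), sides = 2)
  as.numeric(sm[(w + 1):(w + k)])
}

# evaluate a truncated Fourier series at n uniform parameter values
fourier_eval <- function(coef, n_points) {
  tt <- (seq_len(n_points) - 1) / n_points
  x <- numeric(n_points); y <- numeric(n_points)
  for (h in seq_len(nrow(coef))) {
    cs <- cos(2 * pi * h * tt); sn <- sin(2 * pi * h * tt)
    x <- x + coef[h, 1] * cs + coef[h, 2] * sn
    y <- y + coef[h, 3] * cs + coef[h, 4] * sn
  }
  cbind(x, y)
}

# draw one specimen outline (matrix, mm) from a coefficient center
draw_outline <- function(center, dispersion, n_harmonics, fossil_distortion,
                         n_points, scale_mm, angle, max_tries = 10) {
  disp <- dispersion
  for (try in seq_len(max_tries + 1)) {
    co <- center + stats::rnorm(length(center), 0, disp)
    coef <- matrix(co, nrow = n_harmonics, ncol = 4, byrow = TRUE)
    if (fossil_distortion > 0 && n_harmonics >= 3) {
      # low-frequency warping: amplitude jitter on harmonics 2 and 3
      jit <- 1 + stats::rnorm(8, 0, 0.05 * fossil_distortion)
      coef[2:3, ] <- coef[2:3, ] * matrix(jit, 2, 4)
    }
    xy <- fourier_eval(coef, n_points)
    x <- xy[, 1]; y <- xy[, 2]
    # pose: physical scale then in-plane rotation
    x <- x * scale_mm; y <- y * scale_mm
    xr <- x * cos(angle) - y * sin(angle)
    yr <- x * sin(angle) + y * cos(angle)
    if (fossil_distortion > 0) {
      # boundary roughening: smoothed Gaussian displacement along the
      # outward normal, sigma in mm
      nx <- c(yr[2:n_points], yr[1]) - c(yr[n_points], yr[1:(n_points - 1)])
      ny <- -(c(xr[2:n_points], xr[1]) - c(xr[n_points], xr[1:(n_points - 1)]))
      nl <- sqrt(nx^2 + ny^2)
      nl[nl == 0] <- 1
      disp_mm <- circular_smooth(
        stats::rnorm(n_points, 0, 0.02 * fossil_distortion), 9)
      xr <- xr + disp_mm * nx / nl
      yr <- yr + disp_mm * ny / nl
    }
    if (is_simple_polygon(xr, yr)) return(cbind(xr, yr))
    if (try > max_tries) break
    if (try == max_tries) {
      disp <- disp * 0.5
      inform("self-intersecting draw; shrinking dispersion for this specimen")
    }
  }
  abort("could not draw a simple outline after retries")
}

#' Sample synthetic pip outlines from class templates
#'
#' For each class, coefficient vectors are drawn as template mean plus
#' independent Gaussian perturbations (scaled by the per-coefficient
#' dispersion), reconstructed as 360-point outlines, scaled to a physical
#' seed size, randomly rotated, and optionally degraded by the fossil
#' distortion model (harmonic-2/3 amplitude jitter plus smoothed
#' outline-normal roughening). Self-intersecting draws are resampled up to
#' 10 times, then the dispersion for that draw is halved.
#'
#' @param templates A `pip_templates` object (default [seed_templates()]).
#' @param classes Class names to sample (default: all).
#' @param n_per_class Specimens per class (>= 3 for downstream modelling).
#' @param separation Multiplier applied to between-template mean differences
#'   around the grand mean; 1 keeps the templates as constructed.
#' @param fossil_distortion Non-negative distortion intensity; 0 = pristine.
#' @param n_points Points per outline.
#' @param mean_size_mm Mean semi-major-axis scale in mm (seed length is about
#'   twice this); specimens vary by ~5% around it.
#' @param seed Optional RNG seed (caller state is restored).
#' @param id_prefix Prefix for specimen identifiers.
#' @return List: `outlines` (tibble), `truth` (tibble `specimen_id`, `class`,
#'   `continent`).
#' @export
sample_outlines <- function(templates = seed_templates(), classes = NULL,
                            n_per_class = 30, separation = 1,
                            fossil_distortion = 0, n_points = 360,
                            mean_size_mm = 3, seed = NULL, id_prefix = "") {
  stopifnot(n_per_class >= 3)
  with_seed(seed, {
    classes <- classes %||% rownames(templates$coef)
    grand <- colMeans(templates$coef)
    outlines <- list(); truth <- list()
    for (cl in classes) {
      center <- grand + separation * (templates$coef[cl, ] - grand)
      cont <- templates$info$continent[templates$info$name == cl]
      for (i in seq_len(n_per_class)) {
        id <- sprintf("%s%s_%03d", id_prefix, cl, i)
        xy <- draw_outline(center, templates$dispersion, templates$n_harmonics,
                           fossil_distortion, n_points,
                           scale_mm = max(stats::rnorm(1, mean_size_mm,
                                                       0.05 * mean_size_mm),
                                          mean_size_mm / 2),
                           angle = stats::runif(1, 0, 2 * pi))
        outlines[[id]] <- tibble(specimen_id = id, point = seq_len(n_points),
                                 x = xy[, 1], y = xy[, 2])
        truth[[id]] <- tibble(specimen_id = id, class = cl, continent = cont)
      }
    }
    list(outlines = dplyr::bind_rows(outlines), truth = dplyr::bind_rows(truth))
  })
}

# rasterize one outline (mm) into a logical mask at the given resolution
rasterize_outline <- function(x, y, dpi, margin_mm = 0.8) {
  ppm <- dpi / 25.4
  x0 <- min(x) - margin_mm; y0 <- min(y) - margin_mm
  nx <- ceiling((max(x) - min(x) + 2 * margin_mm) * ppm)
  ny <- ceiling((max(y) - min(y) + 2 * margin_mm) * ppm)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  mask <- matrix(FALSE, ny, nx)
  for (i in seq_len(ny)) {
    yc <- y0 + (i - 0.5) / ppm
    cross <- (y <= yc) != (y2 <= yc)
    if (!any(cross)) next
    xi <- x[cross] + (yc - y[cross]) * (x2[cross] - x[cross]) /
      (y2[cross] - y[cross])
    xi <- sort(xi)
    for (k in seq(1, length(xi) - 1, by = 2)) {
      j1 <- ceiling((xi[k] - x0) * ppm + 0.5)
      j2 <- floor((xi[k + 1] - x0) * ppm + 0.5)
      if (j2 >= j1) mask[i, max(1, j1):min(nx, j2)] <- TRUE
    }
  }
  mask
}

#' Sample a cohort and write it as silhouette images plus manifest
#'
#' Draws outlines with [sample_outlines()], rasterizes each at `dpi` (black
#' seed on white background) and writes PNG silhouettes, a `manifest.csv`
#' with the ingest schema (`specimen_id`, `path`, `group`, `view`, `dpi`)
#' and a `truth.csv` (`specimen_id`, `class`, `continent`). The whole bundle
#' is reproducible bit-for-bit for a fixed seed.
#'
#' @inheritParams sample_outlines
#' @param dir Output directory (created if needed).
#' @param dpi Raster resolution (default 600).
#' @param group Either `"class"` (manifest group = true class) or a single
#'   label such as `"unknown"` for specimens whose truth is withheld from
#'   the analysis.
#' @return List: `manifest`, `truth`, `outlines` (tibbles); files on disk.
#' @export
sample_cohort <- function(dir, templates = seed_templates(), classes = NULL,
                          n_per_class = 30, separation = 1,
                          fossil_distortion = 0, dpi = 600, n_points = 360,
                          mean_size_mm = 3, seed = NULL, id_prefix = "",
                          group = "class") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  draw <- sample_outlines(templates, classes, n_per_class, separation,
                          fossil_distortion, n_points, mean_size_mm, seed,
                          id_prefix)
  rows <- lapply(split_outlines(draw$outlines), function(df) {
    mask <- rasterize_outline(df$x, df$y, dpi)
    img <- matrix(1, nrow(mask), ncol(mask))
    img[mask] <- 0
    path <- file.path(dir, paste0(df$specimen_id[1], ".png"))
    png::writePNG(img, path)
    tibble(specimen_id = df$specimen_id[1], path = path,
           view = "dorsal", dpi = dpi)
  })
  manifest <- dplyr::bind_rows(rows)
  manifest$group <- if (identical(group, "class")) {
    draw$truth$class[match(manifest$specimen_id, draw$truth$specimen_id)]
  } else {
    group
  }
  manifest <- manifest[, c("specimen_id", "path", "group", "view", "dpi")]
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  readr::write_csv(draw$truth, file.path(dir, "truth.csv"))
  list(manifest = manifest, truth = draw$truth, outlines = draw$outlines)
}
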