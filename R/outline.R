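#' Read a grayscale seed scan from disk
#'
#' Reads a PNG or TIFF raster and collapses it to a single grayscale channel
#' in `[0, 1]` (0 = black). Multi-channel images are averaged over the colour
#' channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix (rows = image rows from the top, columns = image
#'   columns), values in `[0, 1]`.
#' @export
read_silhouette <- function(path) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    abort(sprintf("unsupported image format '%s' (use PNG or TIFF): %s", ext, path))
  )
  if (length(dim(img)) == 3) {
    nc <- min(dim(img)[3], 3)  # drop alpha
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  img
}

#' Binarize a grayscale scan into a cleaned seed silhouette
#'
#' Thresholds a grayscale image (dark seed on light background), keeps the
#' largest connected foreground component, discards specks smaller than
#' `min_component_frac` of the largest component, and fills interior holes,
#' so the silhouette is a single simply-connected blob.
#'
#' @param image Numeric matrix in `[0, 1]` (0 = black) as returned by
#'   [read_silhouette()], or values in `[0, 255]` (detected and rescaled).
#' @param threshold `"otsu"` for automatic histogram thresholding, or a fixed
#'   numeric cutoff (on the same scale as the image; values > 1 are
#'   interpreted on the 0--255 scale). Pixels strictly darker than the cutoff
#'   are foreground.
#' @param specimen_id Identifier used in error messages and downstream tables.
#' @param dpi Scan resolution in dots per inch; used later to convert pixel
#'   coordinates to millimetres.
#' @param view Anatomical view of the seed; the workflow analyses `"dorsal"`
#'   silhouettes.
#' @param min_component_frac Foreground components smaller than this fraction
#'   of the largest component are treated as scanner dust and removed.
#' @return An object of class `pip_silhouette`: a list with elements `mask`
#'   (logical matrix, `TRUE` = seed), `dpi`, `specimen_id`, `view`.
#' @export
binarize <- function(image, threshold = "otsu", specimen_id = "specimen",
                     dpi = 600, view = "dorsal", min_component_frac = 0.01) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0) {
    abort("`image` must be a non-empty numeric matrix")
  }
  if (max(image) > 1) image <- image / 255
  if (identical(threshold, "otsu")) {
    # otsu splits the histogram; the seed is the dark class
    thr <- EBImage::otsu(EBImage::Image(image), range = c(0, 1))
  } else {
    assert_scalar_number(threshold, "threshold", lower = 0)
    thr <- if (threshold > 1) threshold / 255 else threshold
  }
  mask <- image < thr
  if (!any(mask)) {
    abort(sprintf("empty silhouette: no foreground pixels for specimen '%s'",
                  specimen_id))
  }
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  areas <- tabulate(as.integer(lab[lab > 0]))
  biggest <- which.max(areas)
  big_enough <- which(areas >= min_component_frac * areas[biggest])
  if (length(big_enough) > 1) {
    warn(sprintf(
      "specimen '%s': %d foreground components above the speck threshold; keeping the largest",
      specimen_id, length(big_enough)))
  }
  mask <- matrix(as.vector(lab) == biggest, nrow(mask), ncol(mask))
  mask <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask), ncol(mask))) > 0
  mask <- matrix(as.vector(mask), nrow(image), ncol(image))
  if (sum(mask) < 50) {
    abort(sprintf("silhouette of specimen '%s' has fewer than 50 foreground pixels",
                  specimen_id))
  }
  structure(
    list(mask = mask, dpi = dpi, specimen_id = specimen_id, view = view),
    class = "pip_silhouette"
  )
}

#' @export
print.pip_silhouette <- function(x, ...) {
  cat(sprintf("<pip_silhouette> %s (%s, %d dpi): %d x %d px, %d foreground px\n",
              x$specimen_id, x$view, x$dpi, nrow(x$mask), ncol(x$mask),
              sum(x$mask)))
  invisible(x)
}

#' Trace the closed outline of a silhouette
#'
#' Extracts the seed boundary as a sub-pixel iso-contour of the binary mask at
#' level 0.5 and converts it to millimetres using the scan resolution
#' (`mm = px * 25.4 / dpi`). The outline is stored counter-clockwise
#' (positive signed area); clockwise traces are reversed on ingest so that
#' Fourier coefficient signs are comparable across specimens.
#'
#' @param sil A `pip_silhouette` from [binarize()].
#' @return A tibble with columns `specimen_id`, `point`, `x`, `y` (mm),
#'   ordered along the boundary; the last point connects back to the first.
#' @export
extract_outline <- function(sil) {
  stopifnot(inherits(sil, "pip_silhouette"))
  m <- sil$mask
  # pad with background so the contour closes inside the grid
  z <- matrix(0, nrow(m) + 2, ncol(m) + 2)
  z[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- as.numeric(m)
  # contourLines' x runs over rows: x_cl = row index, y_cl = column index
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  if (length(cl) == 0) {
    abort(sprintf("no boundary found for specimen '%s'", sil$specimen_id))
  }
  if (length(cl) > 1) {
    abort(sprintf("multiple boundary loops (%d) for specimen '%s' after cleaning",
                  length(cl), sil$specimen_id))
  }
  px_x <- cl[[1]]$y - 1  # image column -> x
  px_y <- cl[[1]]$x - 1  # image row    -> y
  # drop the duplicated closing point if present
  np <- length(px_x)
  if (np > 1 && px_x[1] == px_x[np] && px_y[1] == px_y[np]) {
    px_x <- px_x[-np]; px_y <- px_y[-np]
  }
  keep <- c(TRUE, diff(px_x) != 0 | diff(px_y) != 0)
  px_x <- px_x[keep]; px_y <- px_y[keep]
  if (length(px_x) < 3) {
    abort(sprintf("degenerate outline (<3 points) for specimen '%s'", sil$specimen_id))
  }
  if (signed_area(px_x, px_y) < 0) {
    px_x <- rev(px_x); px_y <- rev(px_y)
  }
  scale <- 25.4 / sil$dpi
  tibble(
    specimen_id = sil$specimen_id,
    point = seq_along(px_x),
    x = px_x * scale,
    y = px_y * scale
  )
}

# equidistant resampling of one closed polygon matrix; returns matrix
resample_polygon <- function(xy, n_points) {
  keep <- c(TRUE, rowSums(abs(diff(xy))) > 0)
  xy <- xy[keep, , drop = FALSE]
  k <- nrow(xy)
  if (k < 3) abort("outline must have at least 3 distinct points")
  closed <- rbind(xy, xy[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  len <- c(0, cumsum(seg))
  total <- len[k + 1]
  if (total <= 0) abort("outline has zero perimeter")
  s <- total * (seq_len(n_points) - 1) / n_points
  xs <- stats::approx(len, closed[, 1], xout = s, ties = "ordered")$y
  ys <- stats::approx(len, closed[, 2], xout = s, ties = "ordered")$y
  cbind(xs, ys)
}

#' Resample outlines to equidistant points along the curvilinear abscissa
#'
#' Each closed outline is re-divided into `n_points` points at uniform
#' arc-length spacing (total perimeter divided by `n_points`), starting at
#' the outline's current first point. Start-point normalization is handled
#' later by the Fourier normalization, not here.
#'
#' @param outlines Tibble with columns `specimen_id`, `x`, `y` (one or more
#'   specimens).
#' @param n_points Number of equidistant points (default 360).
#' @return A tibble with the same columns, `n_points` rows per specimen.
#' @export
resample_outline <- function(outlines, n_points = 360) {
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 3) {
    abort("`n_points` must be a single integer >= 3")
  }
  n_points <- as.integer(n_points)
  purrr::map_dfr(split_outlines(outlines), function(df) {
    xy <- resample_polygon(outline_matrix(df), n_points)
    tibble(specimen_id = df$specimen_id[1], point = seq_len(n_points),
           x = xy[, 1], y = xy[, 2])
  })
}

# split an outline tibble into per-specimen data frames, preserving order
split_outlines <- function(outlines) {
  stopifnot(all(c("specimen_id", "x", "y") %in% names(outlines)))
  split(outlines, factor(outlines$specimen_id, levels = unique(outlines$specimen_id)))
}

#' Read a specimen manifest
#'
#' The manifest is a CSV with columns `specimen_id`, `path`, `group`, `view`,
#' `dpi`; `group` is a reference label or `"unknown"`. Relative image paths
#' are resolved against the manifest's directory.
#'
#' @param path Manifest CSV path.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  man <- readr::read_csv(path, col_types = readr::cols(
    specimen_id = readr::col_character(),
    path = readr::col_character(),
    group = readr::col_character(),
    view = readr::col_character(),
    dpi = readr::col_double()
  ))
  dir <- dirname(path)
  man$path <- ifelse(file.exists(man$path), man$path, file.path(dir, man$path))
  man
}

#' Ingest a cohort of silhouette images into resampled outlines
#'
#' Runs [read_silhouette()], [binarize()], [extract_outline()] and
#' [resample_outline()] for every manifest row.
#'
#' @param manifest Tibble from [read_manifest()] (or with the same columns).
#' @param threshold Threshold policy passed to [binarize()].
#' @param n_points Points per resampled outline (default 360).
#' @return A tibble of outlines (`specimen_id`, `point`, `x`, `y` in mm).
#' @export
outline_cohort <- function(manifest, threshold = "otsu", n_points = 360) {
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    img <- read_silhouette(row$path)
    sil <- binarize(img, threshold = threshold, specimen_id = row$specimen_id,
                    dpi = row$dpi, view = row$view)
    resample_outline(extract_outline(sil), n_points = n_points)
  })
}

#' Write outlines as CSV
#'
#' Columns: `specimen_id`, `point_index`, `x_mm`, `y_mm`.
#'
#' @param outlines Outline tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outlines <- function(outlines, path) {
  out <- tibble(
    specimen_id = outlines$specimen_id,
    point_index = outlines$point,
    x_mm = outlines$x,
    y_mm = outlines$y
  )
  readr::write_csv(out, path)
  invisible(path)
}
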