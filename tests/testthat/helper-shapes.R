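# shape builders used across tests (outline tibbles, mm-scale coordinates)

outline_tbl <- function(x, y, id = "s1") {
  tibble::tibble(specimen_id = id, point = seq_along(x), x = x, y = y)
}

circle_outline <- function(r = 1, cx = 0, cy = 0, n = 360, id = "circle") {
  t <- 2 * pi * (seq_len(n) - 1) / n
  outline_tbl(cx + r * cos(t), cy + r * sin(t), id)
}

ellipse_outline <- function(a = 2, b = 1, n = 720, id = "ellipse") {
  t <- 2 * pi * (seq_len(n) - 1) / n
  outline_tbl(a * cos(t), b * sin(t), id)
}

square_outline <- function(side = 1, id = "square") {
  outline_tbl(c(0, side, side, 0), c(0, 0, side, side), id)
}

# one reconstructed template outline per name
template_outlines <- function(names = NULL, n_points = 360) {
  tp <- seed_templates()
  names <- names %||% rownames(tp$coef)
  desc <- dplyr::bind_cols(
    tibble::tibble(specimen_id = names, normalized = TRUE, a0 = 0, c0 = 0),
    tibble::as_tibble(tp$coef[names, , drop = FALSE]))
  efd_reconstruct(desc, n_points = n_points)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# apply a rigid pose plus start-index shift to an outline tibble
pose_outline <- function(o, dx = 0, dy = 0, angle = 0, scale = 1, shift = 0) {
  x <- o$x * scale; y <- o$y * scale
  xr <- x * cos(angle) - y * sin(angle) + dx
  yr <- x * sin(angle) + y * cos(angle) + dy
  n <- length(xr)
  idx <- ((seq_len(n) - 1 + shift) %% n) + 1
  outline_tbl(xr[idx], yr[idx], o$specimen_id[1])
}

# binary masks as grayscale images (0 = black seed, 1 = white background)
blank_image <- function(nr = 100, nc = 100) matrix(1, nr, nc)

disk_image <- function(radius = 50, nr = 2 * radius + 21, cx = NULL, cy = NULL) {
  cx <- cx %||% (nr / 2); cy <- cy %||% (nr / 2)
  img <- matrix(1, nr, nr)
  rows <- row(img); cols <- col(img)
  img[(rows - cy)^2 + (cols - cx)^2 <= radius^2] <- 0
  img
}

rect_image <- function(w = 20, h = 30, nr = 100, nc = 100, r0 = 30, c0 = 40) {
  img <- matrix(1, nr, nc)
  img[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- 0
  img
}
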