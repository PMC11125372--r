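#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join pull across all_of n
#' @importFrom stats setNames
NULL

# round half away from zero, the convention of the printed report tables
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# shoelace signed area of a closed polygon given as open vertex list
signed_area <- function(x, y) {
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

# TRUE if the closed polygon has no crossing edges (vectorized all-pairs scan)
is_simple_polygon <- function(x, y) {
  k <- length(x)
  if (k < 3) return(FALSE)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  idx <- which(outer(seq_len(k), seq_len(k), function(i, j) j > i + 1 &
                       !(i == 1 & j == k)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  d1 <- (x2[i] - x[i]) * (y[j] - y[i]) - (y2[i] - y[i]) * (x[j] - x[i])
  d2 <- (x2[i] - x[i]) * (y2[j] - y[i]) - (y2[i] - y[i]) * (x2[j] - x[i])
  d3 <- (x2[j] - x[j]) * (y[i] - y[j]) - (y2[j] - y[j]) * (x[i] - x[j])
  d4 <- (x2[j] - x[j]) * (y2[i] - y[j]) - (y2[j] - y[j]) * (x2[i] - x[j])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

# coefficient column names a1, b1, c1, d1, ..., up to harmonic n
coef_names <- function(n_harmonics) {
  as.vector(t(outer(seq_len(n_harmonics), c("a", "b", "c", "d"),
                    function(h, l) paste0(l, h))))
}

# numeric matrix of an outline tibble for one specimen
outline_matrix <- function(df) {
  cbind(df$x, df$y)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
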