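#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy PCA loadings
#' @param x A `pip_pca`.
#' @param ... Unused.
#' @return Tibble: `variable`, `component`, `loading`.
#' @method tidy pip_pca
#' @export
tidy.pip_pca <- function(x, ...) {
  as_tibble(x$loadings, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' One-row PCA summary
#' @param x A `pip_pca`.
#' @param ... Unused.
#' @method glance pip_pca
#' @export
glance.pip_pca <- function(x, ...) {
  tibble(n = nrow(x$scores), n_components = length(x$sdev),
         var_frac_pc1 = x$var_frac[1],
         var_frac_pc12 = sum(x$var_frac[1:2]))
}

#' Tidy linear classification functions
#' @param x A `pip_lda`.
#' @param ... Unused.
#' @return Tibble: `group`, `term` (variable or `"(Intercept)"`), `estimate`.
#' @method tidy pip_lda
#' @export
tidy.pip_lda <- function(x, ...) {
  co <- rbind(x$coef, `(Intercept)` = x$intercept)
  colnames(co) <- x$groups
  as_tibble(co, rownames = "term") |>
    tidyr::pivot_longer(-"term", names_to = "group", values_to = "estimate") |>
    dplyr::arrange(.data$group)
}

#' One-row LDA model summary
#' @param x A `pip_lda`.
#' @param ... Unused.
#' @method glance pip_lda
#' @export
glance.pip_lda <- function(x, ...) {
  tibble(n = x$n, n_groups = length(x$groups),
         n_variables = length(x$variables),
         prior_type = x$prior_type, ridge_used = x$ridge_used)
}

#' Tidy cross-validated confusion matrix
#' @param x A `pip_cv`.
#' @param ... Unused.
#' @return Long tibble: `true_group`, `predicted`, `percent`.
#' @method tidy pip_cv
#' @export
tidy.pip_cv <- function(x, ...) {
  x$confusion |>
    dplyr::select(-"Total") |>
    tidyr::pivot_longer(-"true_group", names_to = "predicted",
                        values_to = "percent")
}

#' One-row cross-validation summary
#' @param x A `pip_cv`.
#' @param ... Unused.
#' @method glance pip_cv
#' @export
glance.pip_cv <- function(x, ...) {
  tibble(n = x$n, n_groups = nrow(x$confusion),
         n_variables = length(x$variables), overall_correct_pct = x$overall)
}

#' Tidy allocation table
#' @param x A `pip_allocation`.
#' @param ... Unused.
#' @method tidy pip_allocation
#' @export
tidy.pip_allocation <- function(x, ...) {
  out <- x$table
  out$p_min <- x$p_min
  out
}

#' One-row allocation summary
#' @param x A `pip_allocation`.
#' @param ... Unused.
#' @method glance pip_allocation
#' @export
glance.pip_allocation <- function(x, ...) {
  un <- x$table$percent[x$table$group == "unassigned"]
  tibble(n_unknown = nrow(x$posteriors), p_min = x$p_min,
         top_group = x$table$group[which.max(x$table$percent)],
         unassigned_pct = if (length(un)) un else 0)
}
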