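#' @importFrom generics tidy glance
NULL

# ---- internal helpers -------------------------------------------------------

# split a feature tibble into matrix + ids + groups; group "unknown" is the
# distinguished non-reference label
feature_parts <- function(features) {
  stopifnot("specimen_id" %in% names(features))
  num_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  X <- as.matrix(features[, num_cols, drop = FALSE])
  if (anyNA(X)) abort("feature matrix contains missing values")
  groups <- if ("group" %in% names(features)) features$group else
    rep(NA_character_, nrow(features))
  list(X = X, ids = features$specimen_id, groups = groups, vars = num_cols)
}

ref_rows <- function(groups) !is.na(groups) & groups != "unknown"

# within-group and total SSCP matrices
sscp <- function(X, g) {
  g <- factor(g)
  Xc <- X - colMeans(X)[col(X)]
  total <- crossprod(Xc)
  within <- matrix(0, ncol(X), ncol(X))
  for (lev in levels(g)) {
    Xg <- X[g == lev, , drop = FALSE]
    Xgc <- Xg - colMeans(Xg)[col(Xg)]
    within <- within + crossprod(Xgc)
  }
  list(within = within, total = total)
}

log_det <- function(m) {
  d <- determinant(m, logarithm = TRUE)
  if (d$sign <= 0) return(NA_real_)
  as.numeric(d$modulus)
}

# ---- PCA --------------------------------------------------------------------

#' Principal component analysis of a feature matrix
#'
#' Thin wrapper around [stats::prcomp()] on the coefficient columns, with a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive). All rows participate, including the `"unknown"`
#' group: PCA is unsupervised and the published workflow ordinates fossil
#' and modern specimens together.
#'
#' @param features Feature tibble (`specimen_id`, optional `group`, numeric
#'   coefficient columns).
#' @param center,scale. Passed to [stats::prcomp()]; the default is covariance
#'   PCA (centred, unscaled), matching coefficients that share a scale.
#' @return A `pip_pca` object: list with `scores` (tibble), `loadings`
#'   (matrix), `sdev`, `var_frac`, `center`, `scale`.
#' @export
pip_pca <- function(features, center = TRUE, scale. = FALSE) {
  parts <- feature_parts(features)
  if (nrow(parts$X) < 2 || ncol(parts$X) < 2) {
    abort("PCA needs at least 2 specimens and 2 variables")
  }
  sds <- apply(parts$X, 2, stats::sd)
  if (all(sds < 1e-12)) abort("feature matrix is constant; PCA is undefined")
  X <- parts$X
  if (scale.) {
    keep <- sds > 1e-12
    X <- X[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = center, scale. = scale.)
  # sign convention: largest |loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- as_tibble(pc$x)
  scores <- dplyr::bind_cols(tibble(specimen_id = parts$ids), scores)
  if ("group" %in% names(features)) scores$group <- features$group
  structure(list(
    scores = scores[, c("specimen_id", intersect("group", names(scores)),
                        colnames(pc$x))],
    loadings = pc$rotation,
    sdev = pc$sdev,
    var_frac = pc$sdev^2 / sum(pc$sdev^2),
    center = pc$center,
    scale = pc$scale
  ), class = "pip_pca")
}

#' @export
print.pip_pca <- function(x, ...) {
  cat(sprintf("<pip_pca> %d specimens, %d components\n",
              nrow(x$scores), length(x$sdev)))
  cat(sprintf("  PC1-PC2 variance: %.1f%%\n", 100 * sum(x$var_frac[1:2])))
  invisible(x)
}

#' Project new specimens onto fitted principal components
#' @param object A `pip_pca`.
#' @param features Feature tibble with the same coefficient columns.
#' @param ... Unused.
#' @return Score tibble for the new specimens.
#' @export
predict.pip_pca <- function(object, features, ...) {
  X <- as.matrix(features[, rownames(object$loadings), drop = FALSE])
  if (is.numeric(object$center)) X <- sweep(X, 2, object$center)
  if (is.numeric(object$scale)) X <- sweep(X, 2, object$scale, "/")
  sc <- X %*% object$loadings
  out <- dplyr::bind_cols(tibble(specimen_id = features$specimen_id),
                          as_tibble(sc))
  if ("group" %in% names(features)) out$group <- features$group
  out[, c("specimen_id", intersect("group", names(out)), colnames(sc))]
}

# ---- stepwise selection -----------------------------------------------------

#' Stepwise variable selection by Wilks' lambda
#'
#' Greedy forward selection with backward elimination: at each step the
#' candidate variable with the largest partial F (from the ratio of Wilks'
#' lambda with and without the variable) enters if it reaches `f_enter`;
#' any included variable whose partial F falls below `f_remove` is then
#' removed. `f_enter > f_remove` guarantees termination. Constant and
#' collinear-with-selected columns are never selected; ties break to the
#' lowest column index. The thresholds default to the classical 3.84 / 2.71
#' (the 5% / 10% chi-square points familiar from legacy stepwise software).
#'
#' Rows labelled `"unknown"` are excluded from selection.
#'
#' @param features Feature tibble with a `group` column.
#' @param f_enter,f_remove Partial-F thresholds.
#' @param max_steps Safety cap on selection steps.
#' @return Character vector of selected column names (possibly empty, with a
#'   warning, in which case callers typically fall back to all non-constant
#'   columns).
#' @export
stepwise_select <- function(features, f_enter = 3.84, f_remove = 2.71,
                            max_steps = 100) {
  if (f_enter <= f_remove) abort("`f_enter` must exceed `f_remove`")
  parts <- feature_parts(features)
  keep <- ref_rows(parts$groups)
  X <- parts$X[keep, , drop = FALSE]
  g <- factor(parts$groups[keep])
  ng <- nlevels(g)
  if (ng < 2) abort("stepwise selection needs at least 2 reference groups")
  n <- nrow(X)
  ss <- sscp(X, g)
  usable <- which(diag(ss$total) > 1e-10 * max(diag(ss$total), 1))
  lw <- function(S) {
    if (length(S) == 0) return(0)  # log Wilks = 0 (lambda = 1)
    ldw <- log_det(ss$within[S, S, drop = FALSE])
    ldt <- log_det(ss$total[S, S, drop = FALSE])
    if (is.na(ldw) || is.na(ldt)) return(NA_real_)
    ldw - ldt
  }
  partial_f <- function(S, v) {
    # F for entering v given S (set size p = |S|)
    p <- length(S)
    if (n - ng - p <= 0) return(-Inf)
    l0 <- lw(S); l1 <- lw(c(S, v))
    if (is.na(l1)) return(-Inf)
    ratio <- exp(l0 - l1)  # Lambda_S / Lambda_{S+v} >= 1
    (n - ng - p) / (ng - 1) * (ratio - 1)
  }
  S <- integer(0)
  for (step in seq_len(max_steps)) {
    cand <- setdiff(usable, S)
    if (length(cand) == 0) break
    fs <- vapply(cand, function(v) partial_f(S, v), numeric(1))
    best <- which.max(fs)  # first max -> lowest index on ties
    if (!is.finite(fs[best]) || fs[best] < f_enter) break
    S <- c(S, cand[best])
    # backward pass
    repeat {
      if (length(S) <= 1) break
      fr <- vapply(seq_along(S), function(j) partial_f(S[-j], S[j]), numeric(1))
      worst <- which.min(fr)
      if (fr[worst] >= f_remove) break
      S <- S[-worst]
    }
  }
  if (length(S) == 0) {
    warn("no variable reached f_enter; returning an empty selection")
    return(character(0))
  }
  parts$vars[S]  # in entry order
}

# ---- LDA --------------------------------------------------------------------

#' Fit a multi-group linear discriminant classifier
#'
#' Classical pooled-covariance LDA: group means and the pooled within-group
#' covariance define linear classification functions; the posterior for
#' specimen `x` and group `g` is proportional to
#' `prior_g * exp(-Mahalanobis^2(x, mean_g) / 2)`. Priors are equal by
#' default (group sizes in reference collections are sampling artifacts), or
#' proportional to group size. If the pooled covariance is numerically
#' singular a ridge of `1e-8 * trace/dim` is added once; if it is still
#' singular the offending variables are reported.
#'
#' @param features Feature tibble with `group`; `"unknown"` rows are ignored.
#' @param variables Columns to use (names or indices); default all
#'   non-constant numeric columns.
#' @param priors `"equal"` or `"proportional"`.
#' @return A `pip_lda` model object.
#' @export
pip_lda <- function(features, variables = NULL, priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  parts <- feature_parts(features)
  keep <- ref_rows(parts$groups)
  X <- parts$X[keep, , drop = FALSE]
  g <- factor(parts$groups[keep])
  if (nlevels(g) < 2) abort("LDA needs at least 2 reference groups")
  if (any(table(g) < 2)) {
    abort(sprintf("groups with fewer than 2 specimens: %s",
                  paste(names(which(table(g) < 2)), collapse = ", ")))
  }
  if (is.null(variables)) {
    sds <- apply(X, 2, stats::sd)
    variables <- parts$vars[sds > 1e-10 * max(sds, 1)]
  } else if (is.numeric(variables)) {
    variables <- parts$vars[variables]
  }
  X <- X[, variables, drop = FALSE]
  fit_lda_core(X, g, priors = priors, variables = variables)
}

fit_lda_core <- function(X, g, priors, variables) {
  g <- droplevels(g)
  ng <- nlevels(g)
  n <- nrow(X)
  d <- ncol(X)
  counts <- as.integer(table(g))
  means <- do.call(rbind, lapply(levels(g), function(lev)
    colMeans(X[g == lev, , drop = FALSE])))
  rownames(means) <- levels(g)
  W <- matrix(0, d, d)
  for (i in seq_len(ng)) {
    Xg <- X[g == levels(g)[i], , drop = FALSE]
    Xgc <- Xg - means[i, ][col(Xg)]
    W <- W + crossprod(Xgc)
  }
  S <- W / (n - ng)
  ridge_used <- FALSE
  inv <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
  if (is.null(inv)) {
    S <- S + diag(1e-8 * sum(diag(S)) / d, d)
    ridge_used <- TRUE
    inv <- tryCatch(chol2inv(chol(S)), error = function(e) NULL)
    if (is.null(inv)) {
      bad <- variables[abs(diag(W)) < 1e-12 * max(diag(W), 1)]
      abort(sprintf("pooled covariance singular even after ridge; offending variables: %s",
                    paste(bad, collapse = ", ")))
    }
  }
  pri <- if (priors == "equal") rep(1 / ng, ng) else counts / n
  names(pri) <- levels(g)
  # linear classification functions: score_g(x) = x' C_g + c0_g
  Cf <- inv %*% t(means)
  c0 <- -0.5 * colSums(t(means) * Cf) + log(pri)
  # canonical axes for plots (eigen of S^-1 B)
  grand <- colSums(means * counts) / n
  B <- crossprod(sqrt(counts) * (means - grand[col(means)]))
  r <- min(ng - 1, d)
  scal <- tryCatch({
    ev <- eigen(inv %*% B)
    Re(ev$vectors[, seq_len(r), drop = FALSE])
  }, error = function(e) NULL)
  structure(list(
    groups = levels(g), counts = setNames(counts, levels(g)),
    means = means, pooled_cov = S, inv_cov = inv,
    coef = Cf, intercept = c0, priors = pri, prior_type = priors,
    variables = variables, scaling = scal, ridge_used = ridge_used,
    n = n
  ), class = "pip_lda")
}

#' @export
print.pip_lda <- function(x, ...) {
  cat(sprintf("<pip_lda> %d groups, %d variables, %d specimens (%s priors%s)\n",
              length(x$groups), length(x$variables), x$n, x$prior_type,
              if (x$ridge_used) ", ridge" else ""))
  invisible(x)
}

# posterior matrix for rows of X (matrix on model variables)
lda_posterior <- function(model, X) {
  scores <- X %*% model$coef + rep(model$intercept, each = nrow(X))
  m <- apply(scores, 1, max)
  p <- exp(scores - m)
  p / rowSums(p)
}

#' Posterior probabilities and classes for new specimens
#'
#' @param object A `pip_lda` model.
#' @param features Feature tibble (or matrix) containing the model variables.
#' @param ... Unused.
#' @return A tibble: `specimen_id`, `predicted`, one posterior column per
#'   group. Ties in the maximum posterior go to the first group in the
#'   model's group order and are reported via a message.
#' @export
predict.pip_lda <- function(object, features, ...) {
  if (is.matrix(features)) {
    X <- features[, object$variables, drop = FALSE]
    ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  } else {
    X <- as.matrix(features[, object$variables, drop = FALSE])
    ids <- features$specimen_id
  }
  post <- lda_posterior(object, X)
  colnames(post) <- object$groups
  best <- max.col(post, ties.method = "first")
  tie <- apply(post, 1, function(p) sum(p >= max(p) - 1e-12) > 1)
  if (any(tie)) inform(sprintf("%d posterior tie(s) resolved to the first group", sum(tie)))
  dplyr::bind_cols(
    tibble(specimen_id = ids, predicted = object$groups[best]),
    as_tibble(post)
  )
}

# ---- LOOCV ------------------------------------------------------------------

#' Leave-one-out cross-validated classification report
#'
#' Each reference specimen is classified by a model refitted on all other
#' reference specimens, using the *same fixed variable set* (variable
#' selection is not re-run per fold, matching the single published model).
#' The report carries the row-percentage confusion matrix, the overall
#' cross-validated correct-classification percentage and per-specimen
#' posteriors.
#'
#' @param features Feature tibble with `group` (`"unknown"` rows ignored).
#' @param variables Variable names/indices (default: all non-constant).
#' @param priors `"equal"` or `"proportional"`.
#' @return A `pip_cv` object: list with `confusion` (row-% tibble), `overall`
#'   (percentage), `posteriors` (tibble), `n`.
#' @export
loocv_classify <- function(features, variables = NULL,
                           priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  parts <- feature_parts(features)
  keep <- ref_rows(parts$groups)
  ids <- parts$ids[keep]
  g <- factor(parts$groups[keep])
  if (any(table(g) < 3)) {
    abort("leave-one-out needs at least 3 specimens per fitted group")
  }
  X <- parts$X[keep, , drop = FALSE]
  if (is.null(variables)) {
    sds <- apply(X, 2, stats::sd)
    variables <- parts$vars[sds > 1e-10 * max(sds, 1)]
  } else if (is.numeric(variables)) {
    variables <- parts$vars[variables]
  }
  X <- X[, variables, drop = FALSE]
  n <- nrow(X)
  post <- matrix(NA_real_, n, nlevels(g), dimnames = list(NULL, levels(g)))
  for (i in seq_len(n)) {
    m <- fit_lda_core(X[-i, , drop = FALSE], g[-i], priors = priors,
                      variables = variables)
    post[i, m$groups] <- lda_posterior(m, X[i, , drop = FALSE])
  }
  predicted <- levels(g)[max.col(post, ties.method = "first")]
  cv_report(ids, as.character(g), predicted, post, variables)
}

cv_report <- function(ids, true, predicted, post, variables) {
  groups <- colnames(post)
  conf_counts <- table(factor(true, levels = groups),
                       factor(predicted, levels = groups))
  conf_pct <- 100 * prop.table(conf_counts, 1)
  confusion <- as_tibble(as.data.frame.matrix(conf_pct), rownames = "true_group")
  confusion$Total <- as.numeric(rowSums(conf_pct))
  overall <- 100 * mean(true == predicted)
  posteriors <- dplyr::bind_cols(
    tibble(specimen_id = ids, true_group = true, predicted = predicted),
    as_tibble(post)
  )
  structure(list(confusion = confusion, overall = overall,
                 posteriors = posteriors, n = length(ids),
                 variables = variables),
            class = "pip_cv")
}

#' @export
print.pip_cv <- function(x, ...) {
  cat(sprintf("<pip_cv> %d specimens, %d groups\n", x$n, nrow(x$confusion)))
  cat(sprintf("  %.1f%% of cross-validated grouped cases correctly classified\n",
              round_half_away(x$overall, 1)))
  invisible(x)
}

# ---- unknown-group allocation ----------------------------------------------

#' Classify an unknown group and tabulate its allocation
#'
#' Computes posterior probabilities for every `"unknown"` specimen (or every
#' row if no `group` column is present) under a fitted model and tabulates
#' the percentage of unknowns whose maximum-posterior group is each
#' reference group.
#'
#' @param model A `pip_lda` model.
#' @param features Feature tibble holding the unknown specimens.
#' @return A `pip_allocation` object: list with `table` (tibble `group`,
#'   `percent`), `posteriors` (tibble), `p_min` (`NA`: no threshold applied).
#' @export
classify_unknown <- function(model, features) {
  if ("group" %in% names(features) && any(features$group == "unknown")) {
    features <- features[features$group == "unknown", , drop = FALSE]
  }
  if (nrow(features) == 0) abort("no unknown specimens to classify")
  pred <- predict(model, features)
  tab <- tibble(
    group = model$groups,
    percent = 100 * as.numeric(table(factor(pred$predicted,
                                            levels = model$groups))) / nrow(pred)
  )
  structure(list(table = tab, posteriors = pred, p_min = NA_real_),
            class = "pip_allocation")
}

#' Threshold-based allocation of unknown specimens
#'
#' A specimen is assigned to its maximum-posterior group only if that
#' posterior reaches `p_min` (boundary inclusive, so `p = p_min` is
#' assigned); otherwise it is counted `"unassigned"`. Percentages are over
#' all unknown specimens and always include the unassigned category.
#'
#' @param posteriors Posterior tibble from [classify_unknown()] /
#'   [predict.pip_lda()] (columns: `specimen_id`, `predicted`, one numeric
#'   column per group), or a `pip_allocation`.
#' @param p_min Minimum posterior in `(0, 1]` (default 0.90).
#' @return A `pip_allocation` with an `"unassigned"` row and `p_min` recorded.
#' @export
threshold_allocate <- function(posteriors, p_min = 0.90) {
  if (!is.numeric(p_min) || length(p_min) != 1 || p_min <= 0 || p_min > 1) {
    abort("`p_min` must be a single number in (0, 1]")
  }
  if (inherits(posteriors, "pip_allocation")) posteriors <- posteriors$posteriors
  groups <- setdiff(names(posteriors)[vapply(posteriors, is.numeric, logical(1))],
                    c("point"))
  P <- as.matrix(posteriors[, groups, drop = FALSE])
  if (any(abs(rowSums(P) - 1) > 1e-6)) {
    abort("posterior rows must sum to 1")
  }
  best <- max.col(P, ties.method = "first")
  pmax_ <- P[cbind(seq_len(nrow(P)), best)]
  assigned <- ifelse(pmax_ >= p_min, groups[best], "unassigned")
  tab <- tibble(
    group = c(groups, "unassigned"),
    percent = 100 * as.numeric(table(factor(assigned,
                                            levels = c(groups, "unassigned")))) / nrow(P)
  )
  out <- posteriors
  out$assigned <- assigned
  structure(list(table = tab, posteriors = out, p_min = p_min),
            class = "pip_allocation")
}

#' @export
print.pip_allocation <- function(x, ...) {
  thr <- if (is.na(x$p_min)) "no threshold" else sprintf("p >= %.2f", x$p_min)
  cat(sprintf("<pip_allocation> %d unknown specimens (%s)\n",
              nrow(x$posteriors), thr))
  tab <- x$table
  tab$percent <- round_half_away(tab$percent, 1)
  print(tab, n = nrow(tab))
  invisible(x)
}
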