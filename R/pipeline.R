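ANALYSIS_NAMES <- c("assemblage_pca", "continental_lda", "eurasian11_lda",
                    "eurasian5_lda", "threshold_allocation", "ecotype_lda")

#' Configuration for a named analysis
#'
#' The classification cascade is data-driven: the six analyses share one
#' engine and differ only in group mappings and thresholds. Every default
#' that influences a run is recorded here and echoed into the run log.
#'
#' @param name One of `"assemblage_pca"` (ordination of the unknown
#'   assemblages only), `"continental_lda"`, `"eurasian11_lda"`,
#'   `"eurasian5_lda"`, `"threshold_allocation"` (the 5-species posteriors
#'   under a minimum-posterior rule) or `"ecotype_lda"`.
#' @param group_map Optional tibble with columns `class`, `group` mapping
#'   specimen labels to analysis groups; unmapped classes are dropped,
#'   `"unknown"` is passed through.
#' @param n_points,k_harmonics Outline sampling and harmonic truncation used
#'   upstream (echoed for provenance).
#' @param p_min Posterior threshold for `threshold_allocation`.
#' @param f_enter,f_remove Stepwise partial-F thresholds.
#' @param priors `"equal"` or `"proportional"` group priors.
#' @param pca_var When `lda_input = "pca"`, components are retained up to
#'   this cumulative explained-variance fraction.
#' @param lda_input `"pca"` (stepwise LDA on uncorrelated principal
#'   component scores, the default order of operations) or `"raw"`
#'   (coefficients directly).
#' @param seed Seed echoed into the config (the engine itself is
#'   deterministic).
#' @return A `pip_config` list.
#' @export
analysis_config <- function(name = ANALYSIS_NAMES, group_map = NULL,
                            n_points = 360, k_harmonics = 6, p_min = 0.90,
                            f_enter = 3.84, f_remove = 2.71,
                            priors = c("equal", "proportional"),
                            pca_var = 0.99, lda_input = c("pca", "raw"),
                            seed = NULL) {
  name <- match.arg(name)
  priors <- match.arg(priors)
  lda_input <- match.arg(lda_input)
  assert_scalar_number(n_points, "n_points", 3)
  assert_scalar_number(k_harmonics, "k_harmonics", 1)
  assert_scalar_number(p_min, "p_min", 1e-12, 1)
  assert_scalar_number(f_enter, "f_enter", 0)
  assert_scalar_number(f_remove, "f_remove", 0)
  assert_scalar_number(pca_var, "pca_var", 1e-6, 1)
  if (!is.null(group_map)) {
    stopifnot(all(c("class", "group") %in% names(group_map)))
  }
  structure(list(
    name = name, group_map = group_map, n_points = n_points,
    k_harmonics = k_harmonics, p_min = p_min, f_enter = f_enter,
    f_remove = f_remove, priors = priors, pca_var = pca_var,
    lda_input = lda_input, seed = seed
  ), class = "pip_config")
}

apply_group_map <- function(features, group_map) {
  if (is.null(group_map)) return(features)
  idx <- match(features$group, group_map$class)
  mapped <- group_map$group[idx]
  mapped[features$group == "unknown"] <- "unknown"
  features$group <- mapped
  features[!is.na(features$group), , drop = FALSE]
}

config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$group_map <- if (is.null(cfg$group_map)) NULL else
    as.list(setNames(cfg$group_map$group, cfg$group_map$class))
  cfg
}

log_line <- function(event, ...) {
  jsonlite::toJSON(c(list(event = event), list(...)), auto_unbox = TRUE,
                   digits = NA, null = "null")
}

#' Run one named analysis over a feature matrix
#'
#' Executes the stage sequence for the configured analysis:
#' `assemblage_pca` ordinates the specimens as given (typically the unknown
#' assemblages co-plotted); the LDA analyses run PCA (component scores
#' retained to the configured cumulative variance), Wilks-lambda stepwise
#' selection, pooled-covariance LDA with leave-one-out cross-validation, and
#' allocate the unknown group by maximum posterior;
#' `threshold_allocation` additionally applies the minimum-posterior rule.
#'
#' @param features Feature tibble (`specimen_id`, `group`, coefficient
#'   columns); `group == "unknown"` marks the unknown set.
#' @param config A `pip_config` from [analysis_config()].
#' @return A `pip_run` bundle: list with the resolved `config`, stage
#'   outputs (`pca`, `scores`, `variables`, `model`, `cv`, `allocation`,
#'   `threshold`, `overlap`) and a JSON-lines `log`.
#' @export
run_analysis <- function(features, config) {
  stopifnot(inherits(config, "pip_config"))
  features <- apply_group_map(features, config$group_map)
  logs <- c(log_line("config", config = config_echo(config)))
  if (config$name == "assemblage_pca") {
    # ordination of the (usually unknown) assemblages; group = assemblage
    if (nrow(features) < 3) abort("assemblage PCA needs at least 3 specimens")
    pca <- pip_pca(features)
    overlap <- assemblage_overlap(pca$scores)
    logs <- c(logs, log_line("pca", n = nrow(features),
                             var_pc12 = sum(pca$var_frac[1:2])))
    return(structure(list(name = config$name, config = config, pca = pca,
                          scores = pca$scores, overlap = overlap, log = logs),
                     class = "pip_run"))
  }
  ref <- features[ref_rows(features$group), , drop = FALSE]
  unk <- features[features$group == "unknown", , drop = FALSE]
  if (length(unique(ref$group)) < 2) {
    abort(sprintf("analysis '%s': fewer than 2 reference groups after mapping",
                  config$name))
  }
  if (config$name == "threshold_allocation" && nrow(unk) == 0) {
    abort("threshold_allocation requires unknown specimens")
  }
  if (config$lda_input == "pca") {
    pca <- pip_pca(ref)
    ncomp <- max(2, which(cumsum(pca$var_frac) >= config$pca_var)[1])
    comps <- colnames(pca$loadings)[seq_len(ncomp)]
    ref_data <- pca$scores[, c("specimen_id", "group", comps)]
    unk_data <- if (nrow(unk)) predict(pca, unk)[, c("specimen_id", "group", comps)]
    logs <- c(logs, log_line("pca", n_components = ncomp,
                             cum_var = sum(pca$var_frac[seq_len(ncomp)])))
  } else {
    pca <- NULL
    ref_data <- ref
    unk_data <- if (nrow(unk)) unk
  }
  vars <- withCallingHandlers(
    stepwise_select(ref_data, f_enter = config$f_enter,
                    f_remove = config$f_remove),
    warning = function(w) {
      logs <<- c(logs, log_line("stepwise_empty", message = conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  if (length(vars) == 0) {
    # fall back to all non-constant variables
    parts <- feature_parts(ref_data)
    sds <- apply(parts$X, 2, stats::sd)
    vars <- parts$vars[sds > 1e-10 * max(sds, 1)]
  }
  logs <- c(logs, log_line("stepwise", selected = vars))
  model <- pip_lda(ref_data, variables = vars, priors = config$priors)
  cv <- loocv_classify(ref_data, variables = vars, priors = config$priors)
  logs <- c(logs, log_line("loocv", overall = cv$overall, n = cv$n))
  allocation <- NULL; threshold <- NULL
  if (!is.null(unk_data) && nrow(unk_data)) {
    allocation <- classify_unknown(model, unk_data)
    logs <- c(logs, log_line("allocation",
                             table = setNames(allocation$table$percent,
                                              allocation$table$group)))
    if (config$name == "threshold_allocation") {
      threshold <- threshold_allocate(allocation, p_min = config$p_min)
      logs <- c(logs, log_line("threshold",
                               p_min = config$p_min,
                               table = setNames(threshold$table$percent,
                                                threshold$table$group)))
    }
  }
  structure(list(
    name = config$name, config = config, pca = pca,
    scores = if (!is.null(pca)) dplyr::bind_rows(ref_data, unk_data),
    variables = vars, model = model, cv = cv,
    allocation = allocation, threshold = threshold, log = logs
  ), class = "pip_run")
}

# centroid distance between assemblages relative to pooled within-assemblage
# spread on the first two components
assemblage_overlap <- function(scores) {
  if (!"group" %in% names(scores) || length(unique(scores$group)) < 2) {
    return(NULL)
  }
  sc <- scores[, c("group", "PC1", "PC2")]
  cent <- sc |> group_by(.data$group) |>
    summarise(PC1 = mean(.data$PC1), PC2 = mean(.data$PC2), .groups = "drop")
  d <- as.matrix(stats::dist(cent[, c("PC1", "PC2")]))
  within_sd <- sc |> group_by(.data$group) |>
    summarise(s = sqrt(mean((.data$PC1 - mean(.data$PC1))^2 +
                              (.data$PC2 - mean(.data$PC2))^2)),
              .groups = "drop")
  tibble(centroid_distance = max(d),
         pooled_within_sd = sqrt(mean(within_sd$s^2)))
}

#' @export
print.pip_run <- function(x, ...) {
  cat(sprintf("<pip_run> %s\n", x$name))
  if (!is.null(x$cv)) {
    cat(sprintf("  %.1f%% of cross-validated grouped cases correctly classified (n = %d)\n",
                round_half_away(x$cv$overall, 1), x$cv$n))
  }
  if (!is.null(x$threshold)) {
    un <- x$threshold$table$percent[x$threshold$table$group == "unassigned"]
    cat(sprintf("  threshold p >= %.2f: %.1f%% unassigned\n",
                x$threshold$p_min, round_half_away(un, 1)))
  } else if (!is.null(x$allocation)) {
    top <- x$allocation$table[which.max(x$allocation$table$percent), ]
    cat(sprintf("  unknown plurality: %s (%.1f%%)\n", top$group,
                round_half_away(top$percent, 1)))
  }
  if (!is.null(x$overlap)) {
    cat(sprintf("  assemblage centroid distance %.3f vs pooled within-SD %.3f\n",
                x$overlap$centroid_distance, x$overlap$pooled_within_sd))
  }
  invisible(x)
}

# ---- report writing ---------------------------------------------------------

fmt10 <- function(x) sprintf("%.10g", x)
fmt1 <- function(x) sprintf("%.1f", round_half_away(x, 1))

# deterministic CSV writer: numbers pre-formatted, LF line endings
write_table_csv <- function(df, path, digits = c("full", "one")) {
  digits <- match.arg(digits)
  fmt <- if (digits == "one") fmt1 else fmt10
  cols <- lapply(df, function(col) if (is.numeric(col)) fmt(col) else as.character(col))
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

confusion_text <- function(cv) {
  conf <- cv$confusion
  body <- conf
  for (j in 2:ncol(body)) body[[j]] <- fmt1(body[[j]])
  widths <- pmax(nchar(names(body)),
                 vapply(body, function(c) max(nchar(c)), numeric(1)))
  pad <- function(v, w) formatC(v, width = w)
  header <- paste(mapply(pad, names(body), widths), collapse = "  ")
  rows <- vapply(seq_len(nrow(body)), function(i) {
    paste(mapply(function(col, w) pad(body[[col]][i], w), names(body), widths),
          collapse = "  ")
  }, character(1))
  c(header, rows, "",
    sprintf("%s%% of cross-validated grouped cases correctly classified.",
            fmt1(cv$overall)))
}

#' Write the report files of a run bundle
#'
#' Writes, per analysis: the echoed configuration (JSON), the JSON-lines run
#' log, PCA scores and per-specimen posteriors (full precision CSV), and the
#' row-percentage confusion matrix and allocation tables (CSV and aligned
#' text, one decimal, half away from zero, with the overall cross-validated
#' percentage as a footnote). Output is byte-deterministic for identical
#' bundles.
#'
#' @param bundle A `pip_run` from [run_analysis()].
#' @param outdir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_reports <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "pip_run"))
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(sprintf("cannot create output directory %s", outdir))
  p <- function(suffix) file.path(outdir, paste0(bundle$name, "_", suffix))
  files <- character(0)
  writeLines(jsonlite::toJSON(config_echo(bundle$config), auto_unbox = TRUE,
                              pretty = TRUE, digits = NA, null = "null"),
             p("config.json"), sep = "\n")
  files <- c(files, p("config.json"))
  writeLines(unlist(bundle$log), p("log.jsonl"), sep = "\n")
  files <- c(files, p("log.jsonl"))
  if (!is.null(bundle$scores)) {
    write_table_csv(bundle$scores, p("scores.csv"), "full")
    files <- c(files, p("scores.csv"))
  }
  if (!is.null(bundle$cv)) {
    write_table_csv(bundle$cv$confusion, p("confusion.csv"), "one")
    writeLines(confusion_text(bundle$cv), p("confusion.txt"), sep = "\n")
    write_table_csv(bundle$cv$posteriors, p("cv_posteriors.csv"), "full")
    files <- c(files, p("confusion.csv"), p("confusion.txt"),
               p("cv_posteriors.csv"))
  }
  alloc <- bundle$threshold %||% bundle$allocation
  if (!is.null(alloc)) {
    write_table_csv(alloc$table, p("allocation.csv"), "one")
    write_table_csv(alloc$posteriors, p("unknown_posteriors.csv"), "full")
    files <- c(files, p("allocation.csv"), p("unknown_posteriors.csv"))
  }
  if (!is.null(bundle$overlap)) {
    write_table_csv(bundle$overlap, p("overlap.csv"), "full")
    files <- c(files, p("overlap.csv"))
  }
  invisible(files)
}
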