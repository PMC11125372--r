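#' End-to-end demonstration fixture: synthetic cohorts through the full cascade
#'
#' Builds a complete paper-shaped study from the synthetic generator and runs
#' the six-analysis cascade on it. The reference cohort covers all 17 class
#' templates plus an eastern ecotype variant of the wild-grapevine class
#' (so the western/eastern comparison has two populations); the unknown
#' cohort plays the role of the fossil assemblages: specimens drawn from the
#' `"sylvestris_like"` template, degraded by the fossil-distortion model and
#' split into two "assemblages" of 60 and 10. All images are written to disk
#' and re-ingested through the imaging chain, so the whole pipeline (not
#' just the math core) is exercised.
#'
#' The between-class `separation` multiplier is scaled, if necessary, so the
#' designated unknown-source class sits at least `min_separation` Mahalanobis
#' units from its nearest neighbour among the five-species subset.
#'
#' @param seed Integer seed controlling every random draw.
#' @param dir Directory for images, manifests and reports (default: a
#'   session temporary directory).
#' @param n_per_class Reference specimens per class (default 30, so the
#'   reference cohort is 540 specimens across 18 classes).
#' @param n_unknown Sizes of the two unknown assemblages (default 60 and 10).
#' @param fossil_distortion Distortion intensity applied to the unknown
#'   cohort (default 1).
#' @param min_separation Minimum Mahalanobis distance from the unknown-source
#'   class to its nearest five-species neighbour (default 4).
#' @param dpi Raster resolution (default 600).
#' @param p_min Posterior threshold for the allocation analysis.
#' @param raster If `FALSE`, skip rasterization and feed reconstructed
#'   outlines straight to the descriptor stage (used for quick checks).
#' @param write_report_files If `TRUE`, write all report files under
#'   `file.path(dir, "reports")`.
#' @return A list: `runs` (named list of `pip_run` bundles), `features`,
#'   `truth`, `templates`, `separation`, `dir`.
#' @export
cascade_fixture <- function(seed, dir = file.path(tempdir(), "pip_cascade"),
                            n_per_class = 30, n_unknown = c(60, 10),
                            fossil_distortion = 1, min_separation = 4,
                            dpi = 600, p_min = 0.90, raster = TRUE,
                            write_report_files = FALSE) {
  stopifnot(length(n_unknown) == 2)
  templates <- seed_templates()
  templates <- template_variant(templates, "sylvestris_like",
                                "sylvestris_like_east",
                                d_aspect = 0.010, d_egg = -0.012,
                                d_beak = -0.012)
  five <- c("sylvestris_like", "amurensis_like", "ficifolia_like",
            "heyneana_like", "romanetii_like")
  # calibrate the separation multiplier on the *realized* feature-space
  # distances (realized distance scales linearly in the multiplier)
  sep_tab <- realized_separation(templates, classes = five,
                                 n_per_class = 100, seed = seed + 7919L)
  neigh <- sep_tab[sep_tab$class_a == "sylvestris_like" |
                     sep_tab$class_b == "sylvestris_like", ]
  base_delta <- min(neigh$delta)
  separation <- max(1, min_separation / base_delta)

  ref_classes <- rownames(templates$coef)
  if (raster) {
    ref <- sample_cohort(file.path(dir, "reference"), templates,
                         classes = ref_classes, n_per_class = n_per_class,
                         separation = separation, fossil_distortion = 0,
                         dpi = dpi, seed = seed, group = "class")
    unk <- sample_cohort(file.path(dir, "unknown"), templates,
                         classes = "sylvestris_like",
                         n_per_class = sum(n_unknown),
                         separation = separation,
                         fossil_distortion = fossil_distortion,
                         dpi = dpi, seed = seed + 1L, id_prefix = "fossil_",
                         group = "unknown")
    manifest <- dplyr::bind_rows(ref$manifest, unk$manifest)
    outlines <- outline_cohort(manifest, n_points = 360)
  } else {
    ref <- sample_outlines(templates, classes = ref_classes,
                           n_per_class = n_per_class, separation = separation,
                           fossil_distortion = 0, seed = seed)
    unk <- sample_outlines(templates, classes = "sylvestris_like",
                           n_per_class = sum(n_unknown),
                           separation = separation,
                           fossil_distortion = fossil_distortion,
                           seed = seed + 1L, id_prefix = "fossil_")
    manifest <- dplyr::bind_rows(
      tibble(specimen_id = ref$truth$specimen_id, group = ref$truth$class),
      tibble(specimen_id = unk$truth$specimen_id, group = "unknown"))
    outlines <- dplyr::bind_rows(ref$outlines, unk$outlines)
  }
  truth <- dplyr::bind_rows(ref$truth, unk$truth)
  # the two fossil "assemblages": first 60 specimens vs the remaining 10
  unk_ids <- unk$truth$specimen_id
  site <- tibble(
    specimen_id = unk_ids,
    site = rep(c("assemblage_A", "assemblage_B"), times = n_unknown)
  )

  desc <- efd_normalize(efd(outlines, n_harmonics = 20))
  feats <- efd_features(desc, k_harmonics = 6)
  feats$group <- manifest$group[match(feats$specimen_id, manifest$specimen_id)]
  feats <- feats[, c("specimen_id", "group", coef_names(6))]

  info <- templates$info
  merge_sylvestris <- function(x) ifelse(x == "sylvestris_like_east",
                                         "sylvestris_like", x)
  maps <- list(
    continental_lda = tibble(class = info$name, group = info$continent),
    eurasian11_lda = {
      eur <- info$name[info$continent == "eurasian"]
      tibble(class = eur, group = merge_sylvestris(eur))
    },
    eurasian5_lda = {
      cls <- c(five, "sylvestris_like_east")
      tibble(class = cls, group = merge_sylvestris(cls))
    },
    ecotype_lda = tibble(
      class = c("sylvestris_like", "sylvestris_like_east"),
      group = c("western_sylvestris", "eastern_sylvestris"))
  )
  maps$threshold_allocation <- maps$eurasian5_lda

  runs <- list()
  fossil_feats <- feats[feats$group == "unknown", , drop = FALSE]
  fossil_feats$group <- site$site[match(fossil_feats$specimen_id,
                                        site$specimen_id)]
  runs$assemblage_pca <- run_analysis(
    fossil_feats, analysis_config("assemblage_pca", seed = seed))
  for (nm in c("continental_lda", "eurasian11_lda", "eurasian5_lda",
               "threshold_allocation", "ecotype_lda")) {
    runs[[nm]] <- run_analysis(
      feats, analysis_config(nm, group_map = maps[[nm]], p_min = p_min,
                             seed = seed))
  }
  if (write_report_files) {
    for (r in runs) write_reports(r, file.path(dir, "reports"))
  }
  list(runs = runs, features = feats, truth = truth, site = site,
       templates = templates, separation = separation, dir = dir)
}
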