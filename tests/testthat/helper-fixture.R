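# cascade fixtures are expensive; build each configuration once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached_cascade <- function(distortion = 1, seed = 101, full = TRUE) {
  key <- sprintf("cascade_d%s_s%d_%s", distortion, seed, full)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  fx <- if (full) {
    cascade_fixture(seed = seed, fossil_distortion = distortion,
                    dir = file.path(tempdir(), key))
  } else {
    cascade_fixture(seed = seed, fossil_distortion = distortion,
                    n_per_class = 12, n_unknown = c(10, 5), raster = FALSE,
                    dir = file.path(tempdir(), key))
  }
  .fixture_cache[[key]] <- fx
  fx
}
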