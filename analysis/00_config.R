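# Shared settings for the analysis scripts. Each numbered script sources
# this file and regenerates the synthetic trajectory deterministically from
# the seed, so no step depends on a previous step's bulky intermediate
# files.

library(memdrug)

ANALYSIS_SEED <- 20260922L
OUT_DIR <- "results"

# 200 ns sampled every 0.1 ns on the default bilayer (100 lipids +
# cholesterol per leaflet, one drug molecule).
analysis_synthetic_config <- function() {
  synthetic_config(seed = ANALYSIS_SEED, n_frames = 2000L, dt = 0.1)
}

analysis_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_synthetic(analysis_synthetic_config())
    cache
  }
})

dir.create(OUT_DIR, recursive = TRUE, showWarnings = FALSE)
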