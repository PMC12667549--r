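# Memoised end-to-end runs of the reference layered-tissue preset, shared by
# the acceptance tests so each (seed, effect-size) combination is computed
# once per session.

.pipeline_cache <- new.env(parent = emptyenv())

preset_run <- function(seed, markerLog2fc = 1.5, keepEmbeddings = FALSE) {
  key <- sprintf("s%d_fc%g_e%d", seed, markerLog2fc, keepEmbeddings)
  if (!is.null(.pipeline_cache[[key]])) return(.pipeline_cache[[key]])
  ds <- generateSynth(synthConfig(markerLog2fc = markerLog2fc, seed = seed))
  X <- preprocessExpression(ds@expression)
  res <- suppressWarnings(
    runMcist(X, ds@coords, nDomains = 5, seed = seed,
             returnEmbeddings = keepEmbeddings))
  out <- list(result = res, truth = ds@truth,
              recovery = evaluateRecovery(res, ds@truth))
  if (keepEmbeddings) out$aligned <- attr(res, "alignedEmbeddings")
  .pipeline_cache[[key]] <- out
  out
}

# small, fast synthetic dataset for unit tests
small_synth <- function(seed = 1, ...) {
  generateSynth(synthConfig(grid = c(10, 20), nGenes = 100,
                            nMarkersPerDomain = 12, seed = seed, ...))
}
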