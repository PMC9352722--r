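# One full pipeline run on the default toy genome, shared across test files
# (the run is deterministic given the seed).
.run_cache <- new.env(parent = emptyenv())
sharedRun <- function() {
  if (is.null(.run_cache$res)) {
    .run_cache$dir <- file.path(tempdir(), "rloopscape-shared-run")
    .run_cache$res <- runPipeline(.run_cache$dir, seed = 1L)
  }
  .run_cache$res
}
sharedRunDir <- function() {
  sharedRun()
  .run_cache$dir
}
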