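# Shared scaled-down synthetic cohort, emitted once per test session.
# The coordinate frame is the 16-chromosome genome at 5% physical scale
# with proportionally scaled depth windows; mutation structure, strain
# layout and effect sizes are the generator defaults.

.supscan_test_cache <- new.env(parent = emptyenv())

test_genome <- function() default_genome(scale = 0.05)

test_depth_spec <- function() depth_track_spec(window_size = 1500L)

cached_cohort <- function() {
  if (is.null(.supscan_test_cache$cohort)) {
    td <- file.path(tempdir(), "supscan-test-cohort")
    .supscan_test_cache$cohort <- emit_cohort(
      td, genome = test_genome(), seed = 42,
      depth_spec = test_depth_spec(), n_colonies = 40L)
  }
  .supscan_test_cache$cohort
}

cached_pipeline <- function() {
  if (is.null(.supscan_test_cache$pipeline)) {
    co <- cached_cohort()
    .supscan_test_cache$pipeline <- run_end_to_end(co$dir)
  }
  .supscan_test_cache$pipeline
}

read_tsv_manifest <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# md5 of every file under a directory, keyed by relative path
dir_md5 <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  setNames(as.character(tools::md5sum(file.path(dir, files))), files)
}
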