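# Shared test helpers: tiny records, a toy model spec, and a motif-free
# backbone for liability ground-truth construction.

tiny_records <- function(n = 5, len = 30, seed = 1, germline = NA) {
  withr::with_seed(seed, {
    nano_records(sprintf("t%03d", seq_len(n)),
                 vapply(seq_len(n), function(i) {
                   paste(sample(AA20, len, replace = TRUE), collapse = "")
                 }, character(1)),
                 germline)
  })
}

tiny_spec <- function(germlines = c("G1", "G2"), r = 2L) {
  lora_spec(germlines, d_model = 16L, n_layers = 2L, n_heads = 2L,
            d_ff = 24L, r = r)
}

# a sequence with no PTM liability motifs under the default table's
# high-risk rows (no N/D followed by G/S/T, no DP, no sequon, <=2 C)
motif_free_seq <- function(len = 80) {
  paste(rep(c("A", "E", "L", "K", "G"), length.out = len), collapse = "")
}

ref_fixtures <- function() nano_references()

# Two demo pipeline runs with identical configs, computed once per suite
# (the pipeline tests and the determinism acceptance check share them).
demo_run_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg1 <- demo_pipeline_config(file.path(tempdir(), "demo_run_a"))
      cfg2 <- demo_pipeline_config(file.path(tempdir(), "demo_run_b"))
      man1 <- suppressWarnings(run_pipeline(cfg1))
      man2 <- suppressWarnings(run_pipeline(cfg2))
      cache <<- list(cfg1 = cfg1, man1 = man1, cfg2 = cfg2, man2 = man2)
    }
    cache
  }
})

expect_tiles <- function(ann) {
  expect_equal(ann$spans$start[1], 1L)
  expect_equal(ann$spans$end[nrow(ann$spans)], nchar(ann$seq))
  expect_true(all(ann$spans$start[-1] == head(ann$spans$end, -1) + 1L))
}
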