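test_that("global alignment handles identity and single-gap cases", {
  a <- align_global("ACD", "ACD")
  expect_equal(a$pattern, "ACD")
  expect_equal(a$subject, "ACD")
  expect_equal(percent_identity(a), 1.0)
  b <- align_global("ACD", "AD")
  expect_equal(nchar(b$pattern), nchar(b$subject))
  gaps <- sum(strsplit(b$subject, "")[[1]] == "-")
  expect_equal(gaps, 1L)
  expect_error(align_global("", "ACD"), "empty")
})

test_that("self-alignment score equals the BLOSUM62 diagonal sum", {
  fw1 <- nano_framework("IGHV3-3*01")$seq
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  chars <- strsplit(fw1, "")[[1]]
  expected <- sum(e$BLOSUM62[cbind(chars, chars)])
  expect_equal(align_global(fw1, fw1)$score, expected)
})

test_that("percent identity counts matches over reference columns", {
  # gapless mismatch: 4/5
  a <- align_global("ACDEF", "ACDEG")
  expect_equal(percent_identity(a), 0.8)
  # 10 substitutions on a 100-residue reference, gapless -> 0.90
  ref <- paste(rep(c("A", "E", "K", "L", "G"), 20), collapse = "")
  chars <- strsplit(ref, "")[[1]]
  at <- seq(5, 95, by = 10)
  chars[at] <- ifelse(chars[at] == "W", "Y", "W")
  mut <- paste(chars, collapse = "")
  expect_equal(percent_identity(align_global(mut, ref)), 0.90)
  # symmetry for gapless equal-length pairs
  expect_equal(percent_identity(align_global(ref, mut)), 0.90)
})

test_that("fast gapped-string reconstruction matches the Biostrings oracle", {
  refs <- ref_fixtures()
  sim <- simulate_repertoire(repertoire_config("IGHV3-3*01", 15, seed = 44))
  cases <- c(sim$records$seq,
             substr(refs[[1]]$seq, 1, 60),              # truncated query
             paste0("GGGGG", refs[[2]]$seq, "GGGGG"))   # overhanging query
  for (ref in refs) {
    fast <- nanolibkit:::.align_global_many(cases, ref$seq)
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    oracle <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(cases), Biostrings::AAString(ref$seq),
      type = "global", substitutionMatrix = e$BLOSUM62,
      gapOpening = 11, gapExtension = 1)
    op <- as.character(Biostrings::alignedPattern(oracle))
    os <- as.character(Biostrings::alignedSubject(oracle))
    for (i in seq_along(cases)) {
      expect_identical(fast[[i]]$pattern, unname(op[i]))
      expect_identical(fast[[i]]$subject, unname(os[i]))
    }
  }
})

test_that("the printed frameworks are assigned to their own germlines", {
  refs <- ref_fixtures()
  a1 <- assign_germline(nano_framework("IGHV3-3*01"), refs)
  expect_equal(a1$best_germline, "IGHV3-3*01")
  a2 <- assign_germline(nano_framework("IGHV3S53*01"), refs)
  expect_equal(a2$best_germline, "IGHV3S53*01")
  expect_gte(a1$identity, a1$runner_up_identity)
  # a reference queried against the set containing it matches itself exactly
  self <- assign_germline(list(id = "r", seq = refs[[1]]$seq), refs)
  expect_equal(self$identity, 1.0)
  expect_equal(self$best_germline, refs[[1]]$name)
  expect_error(assign_germline(nano_framework("IGHV3-3*01"), list()),
               "reference")
})

test_that("curation deduplicates, filters and splits reproducibly", {
  refs <- ref_fixtures()
  fw <- nano_framework("IGHV3-3*01")
  dup <- nano_records(sprintf("d%02d", 1:10), rep(fw$seq, 10))
  cur <- curate_dataset(dup, refs, seed = 3)
  expect_equal(nrow(cur$train) + nrow(cur$test), 1L)
  expect_equal(sum(cur$rejected$reason == "duplicate"), 9L)

  # a mutant at ~80% identity to its best reference is rejected as identity
  chars <- strsplit(refs[[1]]$seq, "")[[1]]
  at <- round(seq(3, length(chars) - 2, length.out = 20))
  chars[at] <- vapply(chars[at], function(c) setdiff(AA20, c)[1], "")
  low <- paste(chars, collapse = "")
  expect_lte(percent_identity(align_global(low, refs[[1]]$seq)), 0.85)
  recs <- rbind(fw, nano_records("low", low))
  class(recs) <- c("nano_records", "data.frame")
  cur2 <- curate_dataset(recs, refs)
  expect_true("low" %in% cur2$rejected$id)
  expect_equal(cur2$rejected$reason[cur2$rejected$id == "low"], "identity")

  # length filter
  cur3 <- curate_dataset(rbind(fw, nano_records("short", "EVQLV")), refs)
  expect_equal(cur3$rejected$reason, "length")

  # all-rejected input errors with the dominant reason
  expect_error(curate_dataset(nano_records("s", "EVQLV"), refs), "length")
})

test_that("an 80/20 split is exact and disjoint on simulated repertoires", {
  refs <- ref_fixtures()
  sim <- simulate_repertoire(repertoire_config("IGHV3-3*01", 100, seed = 5))
  cur <- curate_dataset(sim$records, refs, seed = 9)
  n <- nrow(cur$train) + nrow(cur$test)
  expect_lte(abs(nrow(cur$train) - 0.8 * n), 1)
  expect_length(intersect(cur$train$id, cur$test$id), 0)
  expect_true(all(cur$train$germline == "IGHV3-3*01"))
  # same seed reproduces the split; different seed changes it
  cur_b <- curate_dataset(sim$records, refs, seed = 9)
  expect_identical(cur_b$train$id, cur$train$id)
})

test_that("curation is idempotent on a curated train set", {
  refs <- ref_fixtures()
  sim <- simulate_repertoire(repertoire_config("IGHV3S53*01", 60, seed = 8))
  cur <- curate_dataset(sim$records, refs, seed = 2)
  again <- curate_dataset(cur$train, refs, seed = 2)
  expect_equal(nrow(again$rejected), 0L)
  expect_setequal(c(again$train$id, again$test$id), cur$train$id)
})

test_that("germline assignment recovers the source germline on simdata", {
  refs <- ref_fixtures()
  hits <- 0L
  n <- 0L
  for (g in nano_germlines()) {
    sim <- simulate_repertoire(repertoire_config(g, 100, seed = 13))
    asg <- assign_germline_batch(sim$records, refs)
    hits <- hits + sum(asg$best_germline == g)
    n <- n + nrow(sim$records)
  }
  expect_gte(hits / n, 0.99)
})
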