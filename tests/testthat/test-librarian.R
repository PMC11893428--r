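test_that("PFMs from one or two sequences behave as point masses / splits", {
  refs <- ref_fixtures()
  fw <- nano_framework("IGHV3-3*01")
  ann <- annotate_sequence(fw, refs)
  pfm1 <- compute_pfm(list(ann), "IGHV3-3*01", "CDR3", nchar(ann$cdr3))
  expect_equal(pfm1$support, 1L)
  expect_true(all(apply(pfm1$matrix, 2, max) == 1))
  # two sequences differing at one CDR3 column
  mut <- fw
  at <- ann$spans$start[ann$spans$region == "CDR3"] + 2L
  substr(mut$seq, at, at) <- if (substr(mut$seq, at, at) == "G") "S" else "G"
  mut$id <- "mut"
  ann2 <- annotate_sequence(mut, refs)
  pfm2 <- compute_pfm(list(ann, ann2), "IGHV3-3*01", "CDR3",
                      nchar(ann$cdr3))
  mx <- apply(pfm2$matrix, 2, max)
  expect_equal(sum(mx == 0.5), 1L)
  expect_equal(sum(mx == 1), ncol(pfm2$matrix) - 1L)
  expect_true(all(abs(colSums(pfm2$matrix) - 1) < 1e-9))
  expect_error(compute_pfm(list(ann), "IGHV3-3*01", "CDR3", 99L),
               "empty stratum")
})

test_that("CDR3 stratification keeps only lengths inside the range", {
  refs <- ref_fixtures()
  sim <- simulate_repertoire(repertoire_config("IGHV3-3*01", 80, seed = 3))
  anns <- annotate_repertoire(sim$records, refs)
  strata <- stratify_cdr3(anns, "IGHV3-3*01", c(15L, 19L))
  expect_true(all(as.integer(names(strata)) %in% 15:19))
  # counts match the simulator's draw log exactly
  truth_counts <- table(nchar(sim$truth$cdr3))
  for (L in names(strata)) {
    expect_equal(length(strata[[L]]), unname(truth_counts[L]), info = L)
  }
  # a narrow range filters
  narrow <- stratify_cdr3(anns, "IGHV3-3*01", c(17L, 17L))
  expect_true(all(as.integer(names(narrow)) == 17L))
})

test_that("logo export writes information content and round-trips", {
  refs <- ref_fixtures()
  sim <- simulate_repertoire(repertoire_config("IGHV3S53*01", 40, seed = 9))
  anns <- annotate_repertoire(sim$records, refs)
  pfm <- compute_pfm(anns, "IGHV3S53*01", "CDR1", 8L)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_logo_matrix(pfm, path)
  back <- read_logo_matrix(path)
  expect_equal(back, pfm$matrix, tolerance = 1e-6)
  tab <- utils::read.delim(path, na.strings = character(0))
  # information bounds: 0 (uniform) .. log2(20) (point mass)
  expect_true(all(tab$information >= 0 & tab$information <= log2(20) + 1e-9))
  # a point-mass column carries log2(20) bits, a uniform column 0
  pm <- pfm
  pm$matrix[, 1] <- 0; pm$matrix["A", 1] <- 1
  pm$matrix[, 2] <- 1 / 20
  export_logo_matrix(pm, path)
  tab2 <- utils::read.delim(path, na.strings = character(0))
  expect_equal(tab2$information[1], log2(20), tolerance = 1e-9)
  expect_equal(tab2$information[2], 0, tolerance = 1e-9)
})

test_that("point-mass PFMs give a single-member library; members stay on-germline", {
  refs <- ref_fixtures()
  fw <- nano_framework("IGHV3-3*01")
  ann <- annotate_sequence(fw, refs)
  point <- function(region) {
    compute_pfm(list(ann), "IGHV3-3*01", region, nchar(ann[[tolower(region)]]))
  }
  des <- library_design("IGHV3-3*01", cdr1_pfm = point("CDR1"),
                        cdr2_pfm = point("CDR2"),
                        cdr3_pfms = list(point("CDR3")))
  expect_warning(lib <- synthesize_library(des, 10, seed = 1), "diversity")
  expect_equal(nrow(lib), 1L)
  expect_equal(lib$seq[1], fw$seq)

  # a diverse design: all members valid, unique, annotatable, on-germline
  sim <- simulate_repertoire(repertoire_config("IGHV3-3*01", 100, seed = 23))
  anns <- annotate_repertoire(sim$records, refs)
  des2 <- design_from_annotations(anns, "IGHV3-3*01")
  lib2 <- synthesize_library(des2, 150, seed = 2)
  expect_equal(nrow(lib2), 150L)
  expect_false(any(duplicated(lib2$seq)))
  asg <- assign_germline_batch(lib2, refs)
  expect_true(all(asg$best_germline == "IGHV3-3*01"))
  some <- annotate_repertoire(lib2[1:10, ], refs)
  for (a in some) expect_tiles(a)
  # mismatched slot lengths are refused
  expect_error(library_design("IGHV3S53*01", cdr1_pfm = point("CDR1"),
                              cdr2_pfm = point("CDR2"),
                              cdr3_pfms = list(point("CDR3"))),
               "CDR")
})

test_that("library frequencies recover the design PFMs as n grows", {
  refs <- ref_fixtures()
  sim <- simulate_repertoire(repertoire_config("IGHV3S53*01", 150, seed = 31))
  anns <- annotate_repertoire(sim$records, refs)
  des <- design_from_annotations(anns, "IGHV3S53*01")
  err_at <- function(n) {
    lib <- synthesize_library(des, n, seed = 7)
    anns_lib <- annotate_repertoire(lib, refs)
    rec <- compute_pfm(anns_lib, "IGHV3S53*01", "CDR1", des$cdr1_pfm$length)
    mean(abs(rec$matrix - des$cdr1_pfm$matrix))
  }
  e_small <- err_at(50)
  e_big <- err_at(400)
  expect_lt(e_big, e_small)
})

test_that("germline_accuracy is exact on constructed mixtures", {
  refs <- ref_fixtures()
  r1 <- nano_records("a", refs[["IGHV3-3*01"]]$seq)
  expect_equal(germline_accuracy(r1, "IGHV3-3*01", refs), 1.0)
  half <- rbind(nano_framework("IGHV3-3*01"), nano_framework("IGHV3S53*01"))
  class(half) <- c("nano_records", "data.frame")
  expect_equal(germline_accuracy(half, "IGHV3-3*01", refs), 0.5)
})
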