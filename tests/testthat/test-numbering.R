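test_that("numbering a reference against itself reproduces its IMGT map", {
  for (ref in ref_fixtures()) {
    num <- number_sequence(list(id = ref$name, seq = ref$seq), ref)
    expect_identical(as.integer(num$table$label), ref$imgt_positions)
  }
})

test_that("the printed frameworks carry cysteines at IMGT 23 and 104", {
  for (g in nano_germlines()) {
    num <- number_sequence(nano_framework(g), nano_references(g))
    cys <- num$table[num$table$residue == "C", ]
    expect_equal(cys$label, c("23", "104"), info = g)
    chk <- check_conserved_cysteines(num)
    expect_true(chk$conserved_pair_present, info = g)
  }
})

test_that("a C23 substitution is detected by the cysteine check", {
  fw <- nano_framework("IGHV3-3*01")
  num <- number_sequence(fw, nano_references("IGHV3-3*01"))
  at <- num$table$index[num$table$label == "23"]
  substr(fw$seq, at, at) <- "S"
  num2 <- number_sequence(fw, nano_references("IGHV3-3*01"))
  chk <- check_conserved_cysteines(num2)
  expect_false(chk$has_c23)
  expect_true(chk$has_c104)
  expect_false(chk$conserved_pair_present)
})

test_that("region spans tile the sequence and match the framework anatomy", {
  ann1 <- framework_annotation("IGHV3-3*01")
  expect_tiles(ann1)
  expect_equal(ann1$spans$region,
               c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"))
  expect_equal(ann1$cdr1, "GRTFSYNP")
  expect_equal(ann1$cdr2, "ISRTGGST")
  expect_equal(ann1$cdr3, "AAAGVRAEDGRVRTLPSEYTF")
  ann2 <- framework_annotation("IGHV3S53*01")
  expect_tiles(ann2)
  expect_equal(ann2$cdr3, "GLLKGNRVVSPSVAY")
  # concatenating the seven regions reproduces the input
  segs <- vapply(seq_len(7), function(i) {
    substr(ann2$seq, ann2$spans$start[i], ann2$spans$end[i])
  }, character(1))
  expect_equal(paste(segs, collapse = ""), nano_framework("IGHV3S53*01")$seq)
})

test_that("an insertion inside CDR3 shifts no labels outside CDR3", {
  fw <- nano_framework("IGHV3-3*01")
  ref <- nano_references("IGHV3-3*01")
  base <- number_sequence(fw, ref)
  ann <- extract_regions(base)
  at <- ann$spans$start[ann$spans$region == "CDR3"] + 3L
  ins <- fw
  ins$seq <- paste0(substr(fw$seq, 1, at), "G",
                    substr(fw$seq, at + 1L, nchar(fw$seq)))
  num <- number_sequence(ins, ref)
  ann_ins <- extract_regions(num)
  # one more CDR3 residue, all other regions unchanged
  expect_equal(nchar(ann_ins$cdr3), nchar(ann$cdr3) + 1L)
  expect_equal(ann_ins$cdr1, ann$cdr1)
  expect_equal(ann_ins$cdr2, ann$cdr2)
  outside <- function(a) a$numbering$table$label[
    c(seq_len(a$spans$end[5]),
      seq(a$spans$start[7], nrow(a$numbering$table)))]
  expect_identical(outside(ann_ins), outside(ann))
  # insertion codes appear on 111/112 for a long loop
  expect_true(any(grepl("^11[12]\\.", num$table$label)))
})

test_that("truncation before CDR3 is a region error and low identity is unnumberable", {
  ref <- nano_references("IGHV3-3*01")
  fw <- nano_framework("IGHV3-3*01")
  trunc <- list(id = "t", seq = substr(fw$seq, 1, 96))  # ends at C104
  num <- number_sequence(trunc, ref)
  expect_error(extract_regions(num), "CDR3")
  scramble <- tiny_records(1, len = 120, seed = 42)
  expect_error(number_sequence(scramble, ref), "unnumberable")
})

test_that("numbering keys are non-decreasing and junction codes ordered", {
  jl <- nanolibkit:::.cdr3_junction_labels(21L)
  expect_equal(nrow(jl), 21L)
  expect_false(is.unsorted(jl$key))
  expect_equal(jl$label[1], "105")
  expect_equal(jl$label[21], "117")
  expect_true("111.4" %in% jl$label)
  # short loop: gap sits in the middle (IMGT 111 first to go)
  jl12 <- nanolibkit:::.cdr3_junction_labels(12L)
  expect_false("111" %in% jl12$label)
  expect_true(all(c("110", "112") %in% jl12$label))
})

test_that("numbering exports one TSV row per residue", {
  num <- number_sequence(nano_framework("IGHV3-3*01"),
                         nano_references("IGHV3-3*01"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_numbering_tsv(num, path)
  tab <- utils::read.delim(path, colClasses = "character")
  expect_equal(nrow(tab), 128L)
  expect_equal(tab$imgt_label[tab$residue == "C"], c("23", "104"))
})

test_that("simulated sequences always keep the conserved cysteine pair", {
  ref <- nano_references("IGHV3S53*01")
  sim <- simulate_repertoire(repertoire_config("IGHV3S53*01", 150, seed = 4))
  ok <- vapply(seq_len(150), function(i) {
    check_conserved_cysteines(
      number_sequence(sim$records[i, ], ref))$conserved_pair_present
  }, logical(1))
  expect_equal(mean(ok), 1.0)
})

test_that("extract_regions recovers the exact CDR strings the simulator planted", {
  refs <- ref_fixtures()
  for (g in nano_germlines()) {
    sim <- simulate_repertoire(repertoire_config(g, 50, seed = 17))
    anns <- annotate_repertoire(sim$records, refs)
    expect_equal(vapply(anns, `[[`, "", "cdr3"), sim$truth$cdr3, info = g)
    expect_equal(vapply(anns, `[[`, "", "cdr1"), sim$truth$cdr1, info = g)
    expect_equal(vapply(anns, `[[`, "", "cdr2"), sim$truth$cdr2, info = g)
  }
})
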