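test_that("zero-initialized adapters leave the model function-identical", {
  m <- attach_lora(tiny_spec(), seed = 7)
  recs <- nano_records(c("a", "b"), c("ACDEFGHIK", "ACDFWYHIK"),
                       c("G1", "G2"))
  ids <- do.call(rbind, nanolibkit:::.tokenize_records(m, recs))
  with_ad <- nanolibkit:::.model_pass(m, ids, backward = FALSE)
  m0 <- m
  m0$adapters <- replicate(m$spec$n_layers, list(), simplify = FALSE)
  without <- nanolibkit:::.model_pass(m0, ids, backward = FALSE)
  expect_identical(with_ad$loss, without$loss)
})

test_that("rank constraints and trainable parameter counts are exact", {
  expect_error(lora_spec("G1", d_model = 8L, n_heads = 2L, d_ff = 16L,
                         r = 8L), "rank")
  # r = 1, d = k = 8: 16 trainable parameters per adapted square matrix
  sp <- lora_spec("G1", d_model = 8L, n_layers = 1L, n_heads = 2L,
                  d_ff = 16L, r = 1L, adapted_targets = "wq")
  m <- attach_lora(sp)
  expect_equal(length(m$adapters[[1]]$wq$A) + length(m$adapters[[1]]$wq$B),
               16L)
  # closed-form fraction for the full target set
  sp2 <- tiny_spec(r = 2L)
  m2 <- attach_lora(sp2)
  d <- sp2$d_model; dff <- sp2$d_ff; r <- sp2$r; L <- sp2$n_layers
  ad <- L * (4 * (d * r + r * d) + 2 * (d * r + r * dff) + (dff * r + r * d))
  base <- length(sp2$vocab) * d + L * (4 * d * d + 2 * d * dff + dff * d)
  expect_equal(trainable_fraction(m2), ad / (base + ad))
  # linear in r: doubling r doubles the adapter count
  m4 <- attach_lora(tiny_spec(r = 4L))
  count <- function(m) sum(unlist(lapply(m$adapters, function(l) {
    lapply(l, function(ab) length(ab$A) + length(ab$B))
  })))
  expect_equal(count(m4), 2L * count(m2))
  # no adapters -> 0
  m2$adapters <- list()
  expect_equal(trainable_fraction(m2), 0)
})

test_that("adapter gradients match numerical differentiation", {
  m <- attach_lora(tiny_spec(), seed = 3)
  withr::with_seed(5, {
    for (l in seq_along(m$adapters)) {
      for (t in names(m$adapters[[l]])) {
        m$adapters[[l]][[t]]$B <-
          matrix(rnorm(length(m$adapters[[l]][[t]]$B), sd = 0.1),
                 nrow = m$spec$r)
      }
    }
  })
  recs <- nano_records(c("a", "b"), c("ACDEFGHIK", "MNPQRSTVW"),
                       c("G1", "G2"))
  ids <- do.call(rbind, nanolibkit:::.tokenize_records(m, recs))
  out <- nanolibkit:::.model_pass(m, ids, backward = TRUE)
  eps <- 1e-5
  probes <- list(c(1, "wq", "B"), c(1, "wo", "A"), c(2, "wgate", "B"),
                 c(2, "wdown", "A"), c(1, "wk", "A"), c(2, "wv", "B"),
                 c(1, "wup", "B"))
  for (p in probes) {
    l <- as.integer(p[1]); t <- p[2]; w <- p[3]
    mp <- m; mp$adapters[[l]][[t]][[w]][1, 2] <-
      mp$adapters[[l]][[t]][[w]][1, 2] + eps
    mm <- m; mm$adapters[[l]][[t]][[w]][1, 2] <-
      mm$adapters[[l]][[t]][[w]][1, 2] - eps
    num <- (nanolibkit:::.model_pass(mp, ids, backward = FALSE)$loss -
              nanolibkit:::.model_pass(mm, ids, backward = FALSE)$loss) /
      (2 * eps)
    expect_equal(out$grads[[l]][[t]][[w]][1, 2], num, tolerance = 1e-5,
                 info = paste(p, collapse = "/"))
  }
})

test_that("training reduces held-out NLL, freezes the base, and is reproducible", {
  sim1 <- simulate_repertoire(repertoire_config("IGHV3-3*01", 30, seed = 1))
  sim2 <- simulate_repertoire(repertoire_config("IGHV3S53*01", 30, seed = 2))
  recs <- rbind(sim1$records, sim2$records)
  class(recs) <- c("nano_records", "data.frame")
  held <- recs[seq(1, 60, by = 6), ]
  train <- recs[setdiff(1:60, seq(1, 60, by = 6)), ]
  m <- attach_lora(lora_spec(nano_germlines(), d_model = 32L, n_layers = 2L,
                             n_heads = 2L, d_ff = 64L, r = 4L), seed = 9)
  nll0 <- sequence_nll(m, held)
  mt <- train_generator(m, train, epochs = 3, lr = 3e-3, batch_size = 8,
                        seed = 21)
  expect_lt(sequence_nll(mt, held), nll0)
  # freeze contract
  expect_identical(mt$base_checksum$before, mt$base_checksum$after)
  expect_identical(mt$base, m$base)
  # loss broadly non-increasing over epochs
  expect_lte(mt$training_log[3], mt$training_log[1])
  # determinism: same seed, same adapters
  mt2 <- train_generator(m, train, epochs = 3, lr = 3e-3, batch_size = 8,
                         seed = 21)
  expect_identical(mt$adapters, mt2$adapters)
  # unlabeled records are refused
  bad <- train
  bad$germline[1] <- NA
  expect_error(train_generator(m, bad), "unlabeled")
})

test_that("generation respects n = 0, determinism, and the germline label", {
  m <- attach_lora(lora_spec(nano_germlines(), d_model = 32L, n_layers = 1L,
                             n_heads = 2L, d_ff = 64L, r = 4L), seed = 9)
  expect_equal(nrow(generate_sequences(m, "IGHV3-3*01", 0)), 0L)
  expect_error(generate_sequences(m, "IGHV9-9*99", 5), "unknown germline")
  # an untrained model emits garbage: the filter should leave few survivors
  # and warn when the attempt cap is hit
  expect_warning(
    g <- generate_sequences(m, "IGHV3-3*01", 30, seed = 1,
                            attempt_cap = 40L),
    "attempt cap")
  # unfiltered generation is deterministic given the seed
  g1 <- generate_sequences(m, "IGHV3-3*01", 10, seed = 5, filter = FALSE)
  g2 <- generate_sequences(m, "IGHV3-3*01", 10, seed = 5, filter = FALSE)
  expect_identical(g1, g2)
  expect_true(all(g1$germline == "IGHV3-3*01"))
  expect_false(any(duplicated(g1$seq)))
})

test_that("the PSSM baseline fits, samples validly, and round-trips frequencies", {
  refs <- ref_fixtures()
  sim <- simulate_repertoire(repertoire_config("IGHV3S53*01", 120, seed = 6))
  anns <- annotate_repertoire(sim$records, refs)
  pssm <- fit_pssm(anns, "IGHV3S53*01")
  # every column is a proper smoothed distribution
  for (tab in pssm$tables$cdr3) {
    expect_true(all(abs(colSums(tab$matrix) - 1) < 1e-9))
    expect_true(all(tab$matrix > 0))
  }
  # fitting a single sequence gives near-point-mass columns: the observed
  # residue holds all non-pseudocount mass, 1.01/1.20 with n = 1
  p1 <- fit_pssm(anns[1], "IGHV3S53*01")
  expect_equal(max(p1$tables$cdr1[[1]]$matrix[, 1]), 1.01 / 1.2,
               tolerance = 1e-9)
  samp <- sample_pssm(pssm, 50, seed = 31)
  expect_equal(nrow(samp), 50L)
  expect_true(all(vapply(samp$seq, function(s) validate_sequence(s)$ok,
                         logical(1))))
  # sampled sequences keep the conserved cysteines (framework grafting)
  chk <- check_conserved_cysteines(
    number_sequence(samp[1, ], nano_references("IGHV3S53*01")))
  expect_true(chk$conserved_pair_present)
})
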