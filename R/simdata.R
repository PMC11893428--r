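# Synthetic germline-derived repertoires with controlled divergence.
#
# Each simulated sequence is derived from the bundled framework of its
# germline: framework columns are substituted at a low per-residue rate,
# CDR1/CDR2 columns at a higher rate, and CDR3 is resampled wholesale from a
# germline-specific seed PFM at a length drawn from the configured
# distribution. Substitutions are uniform over the 19 alternative residues
# (the simplest null for recovery tests). The simulator's CDR3 alphabet
# excludes C and W, keeping the conserved-cysteine count and the FR4 WGQG
# anchor unambiguous by construction.

#' Configure a synthetic repertoire
#'
#' @param germline One of [nano_germlines()].
#' @param n Number of sequences.
#' @param framework_mutation_rate Per-residue substitution probability in
#'   framework columns (default 0.03).
#' @param cdr_mutation_rate Per-residue substitution probability in
#'   CDR1/CDR2 columns (default 0.15, reflecting their higher variability).
#' @param cdr3_length_distribution Named numeric vector of probabilities
#'   over CDR3 lengths; defaults to uniform over 15-19 for IGHV3-3*01 and
#'   12-16 for IGHV3S53*01 (the length strata with the most data).
#' @param anchor_protection Never mutate the conserved IMGT 23/104 cysteines
#'   or the FR4 WGQG anchor (default TRUE).
#' @param seed Integer seed.
#' @return A list of class `repertoire_config`.
#' @export
repertoire_config <- function(germline = nano_germlines(), n,
                              framework_mutation_rate = 0.03,
                              cdr_mutation_rate = 0.15,
                              cdr3_length_distribution = NULL,
                              anchor_protection = TRUE, seed = 1L) {
  germline <- match.arg(germline)
  stopifnot(n >= 0,
            framework_mutation_rate >= 0, framework_mutation_rate <= 1,
            cdr_mutation_rate >= 0, cdr_mutation_rate <= 1)
  if (is.null(cdr3_length_distribution)) {
    lens <- if (germline == "IGHV3-3*01") 15:19 else 12:16
    cdr3_length_distribution <- stats::setNames(rep(1 / length(lens),
                                                    length(lens)), lens)
  }
  if (abs(sum(cdr3_length_distribution) - 1) > 1e-9) {
    stop("cdr3_length_distribution must sum to 1")
  }
  structure(list(germline = germline, n = as.integer(n),
                 framework_mutation_rate = framework_mutation_rate,
                 cdr_mutation_rate = cdr_mutation_rate,
                 cdr3_length_distribution = cdr3_length_distribution,
                 anchor_protection = anchor_protection,
                 seed = as.integer(seed)),
            class = "repertoire_config")
}

#' Seed PFM for simulated CDR3 loops
#'
#' A deterministic, germline-specific position frequency matrix over CDR3
#' columns: each column puts mass 0.55 on a consensus residue derived from
#' the bundled framework's own CDR3 (junction-style trimmed or middle-padded
#' to the requested length) and spreads the rest uniformly over the other
#' residues of an 18-letter alphabet (no C, no W).
#'
#' @param germline One of [nano_germlines()].
#' @param length CDR3 length in residues.
#' @return A 20 x `length` column-stochastic matrix (rows named by [AA20]).
#' @export
cdr3_seed_pfm <- function(germline = nano_germlines(), length) {
  germline <- match.arg(germline)
  pool <- setdiff(AA20, c("C", "W"))
  fw_cdr3 <- strsplit(framework_annotation(germline)$cdr3, "", fixed = TRUE)[[1]]
  L <- as.integer(length)
  if (L <= length(fw_cdr3)) {
    front <- ceiling(L / 2)
    cons <- c(fw_cdr3[seq_len(front)],
              if (L > front) utils::tail(fw_cdr3, L - front) else character(0))
  } else {
    extra <- L - length(fw_cdr3)
    mid <- ceiling(length(fw_cdr3) / 2)
    cons <- c(fw_cdr3[seq_len(mid)],
              rep(c("G", "S"), length.out = extra),
              fw_cdr3[(mid + 1):length(fw_cdr3)])
  }
  cons[!(cons %in% pool)] <- "G"
  m <- matrix(0, 20L, L, dimnames = list(AA20, NULL))
  for (j in seq_len(L)) {
    m[pool, j] <- 0.45 / (length(pool) - 1)
    m[cons[j], j] <- 0.55
  }
  m
}

#' Simulate a germline-derived repertoire
#'
#' @param config A `repertoire_config`.
#' @return A list of class `sim_repertoire` with `records` (a
#'   `nano_records` data frame, germline-labeled) and `truth`, a data frame
#'   logging each sequence's germline, true CDR strings and mutated
#'   framework/CDR positions (comma-separated indices into the source
#'   framework).
#' @export
simulate_repertoire <- function(config) {
  stopifnot(inherits(config, "repertoire_config"))
  ann <- framework_annotation(config$germline)
  fw <- strsplit(ann$seq, "", fixed = TRUE)[[1]]
  sp <- ann$spans
  span_idx <- function(nm) {
    i <- which(sp$region == nm)
    sp$start[i]:sp$end[i]
  }
  fr_idx <- sort(unlist(lapply(c("FR1", "FR2", "FR3", "FR4"), span_idx)))
  cdr12_idx <- sort(unlist(lapply(c("CDR1", "CDR2"), span_idx)))
  if (config$anchor_protection) {
    lab <- ann$numbering$table$label
    cys <- which(lab %in% c("23", "104"))
    fr4 <- span_idx("FR4")
    anchor <- c(cys, fr4[1:4])   # C23, C104 and the WGQG J anchor
    fr_idx <- setdiff(fr_idx, anchor)
  }
  lens <- as.integer(names(config$cdr3_length_distribution))
  pfms <- lapply(lens, function(L) cdr3_seed_pfm(config$germline, L))
  names(pfms) <- lens
  cdr3_span <- span_idx("CDR3")
  pre <- fw[seq_len(min(cdr3_span) - 1L)]
  post <- fw[seq(max(cdr3_span) + 1L, length(fw))]

  out <- withr::with_seed(config$seed, {
    recs <- vector("list", config$n)
    truth <- vector("list", config$n)
    for (i in seq_len(config$n)) {
      s <- fw
      mut <- integer(0)
      for (set in list(list(idx = fr_idx, p = config$framework_mutation_rate),
                       list(idx = cdr12_idx, p = config$cdr_mutation_rate))) {
        hit <- set$idx[stats::runif(length(set$idx)) < set$p]
        for (j in hit) s[j] <- sample(setdiff(AA20, s[j]), 1L)
        mut <- c(mut, hit)
      }
      L <- lens[sample.int(length(lens), 1L,
                           prob = config$cdr3_length_distribution)]
      pf <- pfms[[as.character(L)]]
      cdr3 <- vapply(seq_len(L),
                     function(j) sample(AA20, 1L, prob = pf[, j]),
                     character(1))
      full <- c(s[seq_along(pre)], cdr3, s[seq(length(fw) - length(post) + 1L,
                                               length(fw))])
      id <- sprintf("sim_%s_%05d", gsub("[^A-Za-z0-9]", "", config$germline),
                    i)
      recs[[i]] <- data.frame(id = id, seq = paste(full, collapse = ""),
                              germline = config$germline,
                              stringsAsFactors = FALSE)
      sp_c1 <- span_idx("CDR1")
      sp_c2 <- span_idx("CDR2")
      truth[[i]] <- data.frame(
        id = id, germline = config$germline,
        cdr1 = paste(s[sp_c1], collapse = ""),
        cdr2 = paste(s[sp_c2], collapse = ""),
        cdr3 = paste(cdr3, collapse = ""),
        mutated_positions = paste(sort(mut), collapse = ","),
        stringsAsFactors = FALSE)
    }
    list(records = do.call(rbind, recs), truth = do.call(rbind, truth))
  })
  records <- out$records
  class(records) <- c("nano_records", "data.frame")
  structure(list(records = records, truth = out$truth,
                 config = config),
            class = "sim_repertoire")
}

#' Plant a motif into a sequence
#'
#' Replaces the substring starting at `position` with `motif`; used to
#' construct ground truth for the liability scan.
#'
#' @param rec Single-row `nano_records` data frame.
#' @param motif Replacement string (canonical residues).
#' @param position 1-based start position;
#'   `position + nchar(motif) - 1` must not exceed the sequence length.
#' @return The modified single-row `nano_records` data frame.
#' @export
plant_motif <- function(rec, motif, position) {
  seq <- rec$seq[1]
  if (position < 1L || position + nchar(motif) - 1L > nchar(seq)) {
    stop("motif does not fit at position ", position)
  }
  substr(seq, position, position + nchar(motif) - 1L) <- motif
  rec$seq[1] <- seq
  rec
}
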