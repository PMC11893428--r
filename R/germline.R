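# Germline V-gene references, best-germline assignment, dataset curation.

#' Construct a germline V-gene reference
#'
#' A named germline protein sequence (the V region, through the conserved
#' second cysteine at IMGT 104) together with its IMGT position map. The map
#' anchors the numbering transfer performed by [number_sequence()].
#'
#' @param name Germline identifier, e.g. `"IGHV3-3*01"`.
#' @param seq Amino-acid sequence of the V region.
#' @param imgt_positions Integer vector, one IMGT position per residue of
#'   `seq`, strictly increasing. Positions 23 and 104, when present, must
#'   carry a cysteine.
#' @return An object of class `germline_reference`.
#' @export
germline_reference <- function(name, seq, imgt_positions) {
  v <- validate_sequence(seq)
  if (!v$ok) stop("invalid reference sequence for ", name)
  n <- nchar(seq)
  imgt_positions <- as.integer(imgt_positions)
  if (length(imgt_positions) != n) {
    stop("imgt map must cover every residue exactly once (", name, ")")
  }
  if (any(diff(imgt_positions) <= 0L)) {
    stop("imgt positions must be strictly increasing (", name, ")")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (cys in c(23L, 104L)) {
    at <- which(imgt_positions == cys)
    if (length(at) == 1L && chars[at] != "C") {
      stop("reference ", name, " lacks the conserved cysteine at IMGT ", cys)
    }
  }
  structure(list(name = name, seq = seq, imgt_positions = imgt_positions),
            class = "germline_reference")
}

#' @export
print.germline_reference <- function(x, ...) {
  cat("<germline_reference>", x$name, "-", nchar(x$seq), "aa, IMGT",
      x$imgt_positions[1], "..", x$imgt_positions[length(x$imgt_positions)],
      "\n")
  invisible(x)
}

#' Assign the best-matching germline to a sequence
#'
#' Aligns the query to every reference and reports the reference with the
#' highest [percent_identity()]; ties break deterministically by reference
#' name order.
#'
#' @param rec A single-row `nano_records` data frame, or a list with `id` and
#'   `seq`.
#' @param refs A list of `germline_reference` objects.
#' @return A list of class `germline_assignment` with `query_id`,
#'   `best_germline`, `identity` and `runner_up_identity`.
#' @export
assign_germline <- function(rec, refs) {
  if (length(refs) == 0L) stop("need at least one germline reference")
  out <- assign_germline_batch(nano_records(rec$id[1], rec$seq[1]), refs)
  structure(list(query_id = out$query_id[1],
                 best_germline = out$best_germline[1],
                 identity = out$identity[1],
                 runner_up_identity = out$runner_up_identity[1]),
            class = "germline_assignment")
}

#' Assign germlines to many sequences at once
#'
#' Vectorized counterpart of [assign_germline()] (one alignment C call per
#' reference), used by curation, generation filtering and accuracy scoring.
#'
#' @param records A `nano_records` data frame.
#' @param refs A list of `germline_reference` objects.
#' @return A data frame with one row per record: `query_id`, `best_germline`,
#'   `identity`, `runner_up_identity`.
#' @export
assign_germline_batch <- function(records, refs) {
  if (length(refs) == 0L) stop("need at least one germline reference")
  nm <- vapply(refs, function(r) r$name, character(1))
  refs <- refs[order(nm)]
  nm <- sort(nm)
  ids <- matrix(0, nrow = nrow(records), ncol = length(refs))
  for (j in seq_along(refs)) {
    ids[, j] <- .identity_to_ref(records$seq, refs[[j]]$seq)
  }
  best <- max.col(ids, ties.method = "first")
  identity <- ids[cbind(seq_len(nrow(ids)), best)]
  runner <- if (length(refs) == 1L) {
    rep(0, nrow(ids))
  } else {
    vapply(seq_len(nrow(ids)),
           function(i) max(ids[i, -best[i]]), numeric(1))
  }
  data.frame(query_id = records$id, best_germline = nm[best],
             identity = identity, runner_up_identity = runner,
             stringsAsFactors = FALSE)
}

#' Curate a repertoire for training
#'
#' Applies, in order: exact-sequence deduplication (first occurrence kept),
#' a length filter, and the germline-consistency filter (identity to the
#' best-matching reference must exceed `min_identity`, strictly). Retained
#' records are labeled with their assigned germline and split at random into
#' train and test sets, reproducibly from `seed`. Every rejection is recorded
#' with a reason tag (`duplicate`, `length` or `identity`).
#'
#' @param records A `nano_records` data frame.
#' @param refs List of `germline_reference` objects.
#' @param min_identity Identity threshold; retained records satisfy
#'   identity > `min_identity` (default 0.85).
#' @param length_bounds Inclusive length bounds, default `c(90, 160)` —
#'   generous bounds around the 110-130 aa bulk of VHH domains.
#' @param split Training fraction (default 0.8).
#' @param seed Integer seed for the split.
#' @return A list of class `curated_dataset`: `train`, `test` (both
#'   `nano_records`), `rejected` (data frame of `id`, `reason`) and `params`.
#' @export
curate_dataset <- function(records, refs, min_identity = 0.85,
                           length_bounds = c(90L, 160L), split = 0.8,
                           seed = 1L) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  rejected <- data.frame(id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  reject <- function(ids, reason) {
    if (length(ids) == 0L) return(rejected)
    rbind(rejected, data.frame(id = ids, reason = reason,
                               stringsAsFactors = FALSE))
  }

  dup <- duplicated(records$seq)
  rejected <- reject(records$id[dup], "duplicate")
  records <- records[!dup, , drop = FALSE]

  len <- nchar(records$seq)
  badlen <- len < length_bounds[1] | len > length_bounds[2]
  rejected <- reject(records$id[badlen], "length")
  records <- records[!badlen, , drop = FALSE]

  if (nrow(records) > 0L) {
    asg <- assign_germline_batch(records, refs)
    low <- asg$identity <= min_identity
    rejected <- reject(records$id[low], "identity")
    records <- records[!low, , drop = FALSE]
    records$germline <- asg$best_germline[!low]
  }

  if (nrow(records) == 0L) {
    dominant <- names(sort(table(rejected$reason), decreasing = TRUE))[1]
    stop("all ", nrow(rejected), " records rejected (dominant reason: ",
         dominant, ")")
  }

  n <- nrow(records)
  perm <- withr::with_seed(seed, sample.int(n))
  n_train <- round(split * n)
  train <- records[sort(perm[seq_len(n_train)]), , drop = FALSE]
  test <- records[sort(perm[setdiff(seq_len(n), seq_len(n_train))]), ,
                  drop = FALSE]
  rownames(train) <- NULL
  rownames(test) <- NULL
  class(train) <- class(test) <- c("nano_records", "data.frame")
  structure(list(train = train, test = test, rejected = rejected,
                 params = list(min_identity = min_identity,
                               length_bounds = length_bounds,
                               split = split, seed = seed)),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat("<curated_dataset> train:", nrow(x$train), "test:", nrow(x$test),
      "rejected:", nrow(x$rejected), "\n")
  invisible(x)
}

#' Fraction of generated sequences assigned to the requested germline
#'
#' The germline-generation accuracy measure: the fraction of records whose
#' best-identity germline assignment equals the requested conditioning tag.
#'
#' @param generated A non-empty `nano_records` data frame.
#' @param requested Germline name the sequences were conditioned on.
#' @param refs List of `germline_reference` objects.
#' @return A fraction in \[0, 1\].
#' @export
germline_accuracy <- function(generated, requested, refs) {
  stopifnot(nrow(generated) > 0L)
  asg <- assign_germline_batch(generated, refs)
  mean(asg$best_germline == requested)
}
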