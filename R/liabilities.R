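# Post-translational-modification liability scanning.
#
# The motif table encodes standard antibody developability practice:
# high risk  - N-glycosylation sequons N[^P][ST]; deamidation NG/NS/NT;
#              isomerization DG/DS/DT; acid hydrolysis DP; and any cysteine
#              outside the conserved IMGT 23/104 pair (unpaired cysteine).
# medium     - methionine and tryptophan oxidation; weaker deamidation
#              contexts NN/NA.
# The table ships as a TSV data file so alternative counting conventions can
# be reproduced by swapping the file, not the code.

#' Load a PTM liability motif table
#'
#' @param path Path to a TSV with columns `motif_regex`, `liability_class`,
#'   `risk_tier`; defaults to the bundled table.
#' @return A data frame.
#' @export
load_motif_table <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("ptm_motifs.tsv")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = character(0))
  need <- c("motif_regex", "liability_class", "risk_tier")
  if (!all(need %in% names(tab))) {
    stop("motif table must have columns: ", paste(need, collapse = ", "))
  }
  tab
}

#' Scan a sequence for PTM liability motifs
#'
#' Deterministic left-to-right scan of the sequence against a motif table;
#' overlapping matches are all reported (a lookahead regex is used so that
#' e.g. `NGS` yields both the `NG` deamidation site and the `NGS`
#' glycosylation sequon). When a `region_annotation` is supplied, each site
#' is tagged with its FR/CDR region, and cysteines outside the conserved
#' IMGT 23/104 pair are additionally reported as high-risk
#' `unpaired_cysteine` sites (one site per residue); without an annotation
#' the cysteine rule is skipped, since pairing is defined by IMGT position.
#'
#' @param rec Single-row `nano_records` data frame (or list with `id`,
#'   `seq`).
#' @param annotation Optional `region_annotation` for `rec`.
#' @param motifs Motif table from [load_motif_table()].
#' @return A data frame of sites ordered by position: `query_id`, `position`
#'   (1-based), `motif`, `liability_class`, `risk_tier`, `region` (`NA`
#'   without annotation).
#' @export
scan_ptm <- function(rec, annotation = NULL, motifs = load_motif_table()) {
  seq <- rec$seq[1]
  v <- validate_sequence(seq)
  if (!v$ok) stop("invalid sequence: ", rec$id[1])
  sites <- list()
  for (i in seq_len(nrow(motifs))) {
    rx <- paste0("(?=(", motifs$motif_regex[i], "))")
    m <- gregexpr(rx, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    lens <- attr(m, "capture.length")[, 1]
    sites[[length(sites) + 1L]] <- data.frame(
      position = as.integer(m),
      motif = substring(seq, as.integer(m), as.integer(m) + lens - 1L),
      liability_class = motifs$liability_class[i],
      risk_tier = motifs$risk_tier[i],
      stringsAsFactors = FALSE)
  }
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "region_annotation"))
    if (annotation$seq != seq) {
      stop("annotation does not match the record sequence")
    }
    lab <- annotation$numbering$table$label
    cyspos <- which(strsplit(seq, "", fixed = TRUE)[[1]] == "C" &
                      !(lab %in% c("23", "104")))
    if (length(cyspos) > 0L) {
      sites[[length(sites) + 1L]] <- data.frame(
        position = cyspos, motif = "C",
        liability_class = "unpaired_cysteine", risk_tier = "high",
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(sites) == 0L) {
    data.frame(position = integer(0), motif = character(0),
               liability_class = character(0), risk_tier = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, sites)
  }
  out <- cbind(query_id = rep(rec$id[1], nrow(out)), out,
               stringsAsFactors = FALSE)
  out$region <- rep(NA_character_, nrow(out))
  if (!is.null(annotation) && nrow(out) > 0L) {
    sp <- annotation$spans
    for (j in seq_len(nrow(sp))) {
      inside <- out$position >= sp$start[j] & out$position <= sp$end[j]
      out$region[inside] <- sp$region[j]
    }
  }
  out <- out[order(out$position, out$liability_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count high-risk liability sites
#'
#' @param sites A site table from [scan_ptm()].
#' @return Integer count of sites with `risk_tier == "high"`.
#' @export
count_high_risk <- function(sites) {
  sum(sites$risk_tier == "high")
}

#' Scan a repertoire and write a liability report
#'
#' @param records A `nano_records` data frame.
#' @param path Output TSV path.
#' @param refs Optional references; when given, records are annotated so
#'   sites carry region tags and unpaired cysteines are detected.
#' @param motifs Motif table.
#' @return Invisibly, the combined site data frame.
#' @export
write_ptm_report <- function(records, path, refs = NULL,
                             motifs = load_motif_table()) {
  anns <- if (is.null(refs)) NULL else annotate_repertoire(records, refs)
  all <- lapply(seq_len(nrow(records)), function(i) {
    scan_ptm(records[i, , drop = FALSE],
             annotation = if (is.null(anns)) NULL else anns[[i]],
             motifs = motifs)
  })
  out <- do.call(rbind, all)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
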