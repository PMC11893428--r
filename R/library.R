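# Framework-grafted synthetic library construction: a fixed donor framework
# with CDR1/CDR2/CDR3 slots refilled by independent per-column sampling from
# position frequency matrices (CDR3 over weighted length strata).

#' Specify a synthetic library design
#'
#' @param germline Germline name.
#' @param framework Single-row `nano_records` framework (default the bundled
#'   framework for `germline`); must be annotatable against the bundled
#'   references.
#' @param cdr1_pfm,cdr2_pfm `nano_pfm` objects for CDR1 and CDR2; their
#'   lengths must match the framework's CDR slot lengths.
#' @param cdr3_pfms List of `nano_pfm` objects, one per CDR3 length stratum.
#' @param cdr3_weights Stratum weights; default proportional to each PFM's
#'   support (`"uniform"` gives equal weights).
#' @param size_target Intended library size (informational).
#' @return A list of class `library_design`.
#' @export
library_design <- function(germline, framework = NULL, cdr1_pfm, cdr2_pfm,
                           cdr3_pfms, cdr3_weights = NULL,
                           size_target = NULL) {
  if (is.null(framework)) framework <- nano_framework(germline)
  ann <- annotate_sequence(framework, nano_references())
  if (ncol(cdr1_pfm$matrix) != nchar(ann$cdr1)) {
    stop("CDR1 PFM length ", ncol(cdr1_pfm$matrix),
         " does not match the framework CDR1 slot (", nchar(ann$cdr1), ")")
  }
  if (ncol(cdr2_pfm$matrix) != nchar(ann$cdr2)) {
    stop("CDR2 PFM length ", ncol(cdr2_pfm$matrix),
         " does not match the framework CDR2 slot (", nchar(ann$cdr2), ")")
  }
  if (is.null(cdr3_weights)) {
    cdr3_weights <- vapply(cdr3_pfms, function(p) p$support, numeric(1))
  } else if (identical(cdr3_weights, "uniform")) {
    cdr3_weights <- rep(1, length(cdr3_pfms))
  }
  stopifnot(length(cdr3_weights) == length(cdr3_pfms), all(cdr3_weights >= 0))
  cdr3_weights <- cdr3_weights / sum(cdr3_weights)
  structure(list(germline = germline, framework = framework,
                 annotation = ann, cdr1_pfm = cdr1_pfm, cdr2_pfm = cdr2_pfm,
                 cdr3_pfms = cdr3_pfms, cdr3_weights = cdr3_weights,
                 size_target = size_target),
            class = "library_design")
}

#' Synthesize a framework-grafted library
#'
#' Each member is built by sampling CDR1 and CDR2 independently from their
#' PFMs, choosing a CDR3 length stratum by weight and sampling its columns,
#' and grafting the three loops into the fixed framework. Duplicates are
#' dropped; every member passes [validate_sequence()] and retains the
#' conserved C23/C104 pair by construction (the framework contributes the
#' cysteines). Reproducible from `seed`.
#'
#' @param design A `library_design`.
#' @param n Number of unique members requested.
#' @param seed Integer seed.
#' @param max_rounds Resampling rounds before giving up on reaching `n`
#'   unique members (a partial library is returned with a warning, e.g.
#'   when the design's attainable diversity is below `n`).
#' @return A `nano_records` data frame labeled with the design germline.
#' @export
synthesize_library <- function(design, n, seed = 1L, max_rounds = 25L) {
  stopifnot(inherits(design, "library_design"), n >= 0)
  if (n == 0L) return(nano_records(character(0), character(0)))
  ann <- design$annotation
  sp <- ann$spans
  seg <- function(nm) {
    i <- which(sp$region == nm)
    substr(ann$seq, sp$start[i], sp$end[i])
  }
  fr1 <- seg("FR1"); fr2 <- seg("FR2"); fr3 <- seg("FR3"); fr4 <- seg("FR4")
  seqs <- character(0)
  withr::with_seed(seed, {
    for (round in seq_len(max_rounds)) {
      need <- n - length(seqs)
      if (need <= 0L) break
      draw <- max(need, ceiling(need * 1.2))
      c1 <- .sample_pfm_strings(design$cdr1_pfm$matrix, draw)
      c2 <- .sample_pfm_strings(design$cdr2_pfm$matrix, draw)
      stratum <- sample.int(length(design$cdr3_pfms), draw, replace = TRUE,
                            prob = design$cdr3_weights)
      c3 <- character(draw)
      for (s in unique(stratum)) {
        at <- which(stratum == s)
        c3[at] <- .sample_pfm_strings(design$cdr3_pfms[[s]]$matrix,
                                      length(at))
      }
      cand <- paste0(fr1, c1, fr2, c2, fr3, c3, fr4)
      seqs <- c(seqs, setdiff(unique(cand), seqs))
      if (length(seqs) >= n) break
    }
  })
  if (length(seqs) < n) {
    warning("attainable diversity below request: returning ", length(seqs),
            " of ", n, " members")
  }
  seqs <- utils::head(seqs, n)
  nano_records(sprintf("lib_%s_%06d", gsub("[^A-Za-z0-9]", "",
                                           design$germline),
                       seq_along(seqs)),
               seqs, design$germline)
}

#' Build a default library design from annotated sequences
#'
#' Convenience constructor mirroring the statistical-library recipe: compute
#' CDR1/CDR2 PFMs at the framework slot lengths and CDR3 PFMs over every
#' length stratum inside `cdr3_length_range`, weighted by stratum counts.
#'
#' @param annotations List of `region_annotation` objects (germline-labeled).
#' @param germline Germline name.
#' @param cdr3_length_range Inclusive CDR3 length interval; defaults to
#'   15-19 for IGHV3-3*01 and 12-16 for IGHV3S53*01.
#' @param size_target Intended library size (informational).
#' @return A `library_design`.
#' @export
design_from_annotations <- function(annotations, germline,
                                    cdr3_length_range = NULL,
                                    size_target = NULL) {
  if (is.null(cdr3_length_range)) {
    cdr3_length_range <- if (germline == "IGHV3-3*01") c(15L, 19L)
    else c(12L, 16L)
  }
  ann_fw <- framework_annotation(germline)
  cdr1 <- compute_pfm(annotations, germline, "CDR1", nchar(ann_fw$cdr1))
  cdr2 <- compute_pfm(annotations, germline, "CDR2", nchar(ann_fw$cdr2))
  strata <- stratify_cdr3(annotations, germline, cdr3_length_range)
  if (length(strata) == 0L) {
    stop("no CDR3 strata inside length range ",
         paste(cdr3_length_range, collapse = "-"), " for ", germline)
  }
  cdr3 <- lapply(names(strata), function(L) {
    compute_pfm(strata[[L]], germline, "CDR3", as.integer(L))
  })
  library_design(germline, cdr1_pfm = cdr1, cdr2_pfm = cdr2,
                 cdr3_pfms = cdr3, size_target = size_target)
}
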