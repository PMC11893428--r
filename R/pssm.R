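# PSSM baseline sampler: a purely statistical germline-conditional
# generator (smoothed per-region position frequencies plus an empirical
# CDR3 length distribution grafted onto the bundled framework). Serves as a
# simple reference point for the LoRA language model.

#' Fit a germline PSSM from annotated sequences
#'
#' Per-region, per-length position frequency tables with additive smoothing
#' (pseudo-count 0.01 per residue), plus the empirical CDR3 length
#' distribution. Strata with no observations are excluded (and never
#' sampled).
#'
#' @param annotations List of `region_annotation` objects.
#' @param germline Germline name.
#' @param pseudocount Additive smoothing constant (default 0.01).
#' @return An object of class `germline_pssm`.
#' @export
fit_pssm <- function(annotations, germline, pseudocount = 0.01) {
  keep <- Filter(function(a) identical(a$germline, germline), annotations)
  if (length(keep) == 0L) stop("no annotations for germline ", germline)
  regions <- c("cdr1", "cdr2", "cdr3")
  tables <- lapply(regions, function(rg) {
    strs <- vapply(keep, function(a) a[[rg]], character(1))
    out <- lapply(split(strs, nchar(strs)), function(grp) {
      chars <- do.call(rbind, strsplit(grp, "", fixed = TRUE))
      m <- vapply(seq_len(ncol(chars)), function(j) {
        cnt <- table(factor(chars[, j], levels = AA20))
        (as.numeric(cnt) + pseudocount) /
          (length(grp) + 20 * pseudocount)
      }, numeric(20L))
      m <- matrix(m, nrow = 20L, dimnames = list(AA20, NULL))
      list(matrix = m, support = length(grp))
    })
    out
  })
  names(tables) <- regions
  cdr3_lens <- vapply(keep, function(a) nchar(a$cdr3), integer(1))
  len_tab <- table(cdr3_lens) / length(cdr3_lens)
  structure(list(germline = germline, tables = tables,
                 cdr3_length_distribution =
                   stats::setNames(as.numeric(len_tab), names(len_tab)),
                 pseudocount = pseudocount, n_fit = length(keep)),
            class = "germline_pssm")
}

#' @export
print.germline_pssm <- function(x, ...) {
  cat("<germline_pssm>", x$germline, "fit on", x$n_fit, "sequences; CDR3 lengths:",
      paste(names(x$cdr3_length_distribution), collapse = ","), "\n")
  invisible(x)
}

#' Sample sequences from a germline PSSM
#'
#' Draws a CDR3 length from the empirical distribution, samples each CDR
#' column independently, and grafts the loops into the germline's bundled
#' framework. All samples pass [validate_sequence()] by construction.
#'
#' @param pssm A `germline_pssm`.
#' @param n Number of sequences.
#' @param seed Integer seed.
#' @return A `nano_records` data frame labeled with the germline.
#' @export
sample_pssm <- function(pssm, n, seed = 1L) {
  stopifnot(inherits(pssm, "germline_pssm"), n >= 0)
  if (n == 0L) return(nano_records(character(0), character(0)))
  ann <- framework_annotation(pssm$germline)
  sp <- ann$spans
  seg <- function(nm) {
    i <- which(sp$region == nm)
    substr(ann$seq, sp$start[i], sp$end[i])
  }
  draw_region <- function(tabs, n) {
    lens <- names(tabs)
    supp <- vapply(tabs, function(t) t$support, numeric(1))
    pick <- sample(lens, n, replace = TRUE, prob = supp / sum(supp))
    out <- character(n)
    for (L in unique(pick)) {
      at <- which(pick == L)
      out[at] <- .sample_pfm_strings(tabs[[L]]$matrix, length(at))
    }
    out
  }
  seqs <- withr::with_seed(seed, {
    c1 <- draw_region(pssm$tables$cdr1, n)
    c2 <- draw_region(pssm$tables$cdr2, n)
    lens <- names(pssm$cdr3_length_distribution)
    pickL <- sample(lens, n, replace = TRUE,
                    prob = pssm$cdr3_length_distribution)
    c3 <- character(n)
    for (L in unique(pickL)) {
      at <- which(pickL == L)
      c3[at] <- .sample_pfm_strings(pssm$tables$cdr3[[L]]$matrix, length(at))
    }
    paste0(seg("FR1"), c1, seg("FR2"), c2, seg("FR3"), c3, seg("FR4"))
  })
  nano_records(sprintf("pssm_%s_%05d", gsub("[^A-Za-z0-9]", "",
                                            pssm$germline),
                       seq_len(n)),
               seqs, pssm$germline)
}
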