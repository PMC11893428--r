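# Positional amino-acid frequency matrices over CDR regions, length
# stratification, and sequence-logo export.

#' Compute a position frequency matrix for one CDR stratum
#'
#' Raw per-column residue frequencies (no smoothing — logos display raw
#' frequencies) over all annotations of the given germline whose region
#' string has exactly `length_stratum` residues.
#'
#' @param annotations List of `region_annotation` objects.
#' @param germline Germline name to restrict to.
#' @param region One of `"CDR1"`, `"CDR2"`, `"CDR3"`.
#' @param length_stratum Region length in residues defining the stratum.
#' @return An object of class `nano_pfm`: `germline`, `region`, `length`,
#'   `support` (number of sequences) and `matrix`, a 20 x length
#'   column-stochastic matrix with rows named by [AA20].
#' @export
compute_pfm <- function(annotations, germline, region = c("CDR1", "CDR2", "CDR3"),
                        length_stratum) {
  region <- match.arg(region)
  field <- tolower(region)
  strs <- vapply(annotations, function(a) {
    if (!is.null(a$germline) && identical(a$germline, germline)) {
      a[[field]]
    } else NA_character_
  }, character(1))
  strs <- strs[!is.na(strs) & nchar(strs) == length_stratum]
  if (length(strs) == 0L) {
    stop("empty stratum: ", germline, " / ", region, " / length ",
         length_stratum)
  }
  chars <- do.call(rbind, strsplit(strs, "", fixed = TRUE))
  m <- vapply(seq_len(length_stratum), function(j) {
    tab <- table(factor(chars[, j], levels = AA20))
    as.numeric(tab) / length(strs)
  }, numeric(20L))
  m <- matrix(m, nrow = 20L, dimnames = list(AA20, NULL))
  structure(list(germline = germline, region = region,
                 length = as.integer(length_stratum),
                 support = length(strs), matrix = m),
            class = "nano_pfm")
}

#' @export
print.nano_pfm <- function(x, ...) {
  cat("<nano_pfm>", x$germline, x$region, "length", x$length,
      "support", x$support, "\n")
  invisible(x)
}

#' Stratify annotations by CDR3 length
#'
#' @param annotations List of `region_annotation` objects.
#' @param germline Germline name to restrict to.
#' @param length_range Inclusive CDR3 length interval, e.g. `c(15, 19)`.
#' @return A named list mapping each kept length to its annotation subset,
#'   with per-length counts in the `counts` attribute.
#' @export
stratify_cdr3 <- function(annotations, germline, length_range) {
  keep <- vapply(annotations, function(a) {
    identical(a$germline, germline) &&
      nchar(a$cdr3) >= length_range[1] && nchar(a$cdr3) <= length_range[2]
  }, logical(1))
  kept <- annotations[keep]
  lens <- vapply(kept, function(a) nchar(a$cdr3), integer(1))
  out <- split(kept, lens)
  attr(out, "counts") <- vapply(out, length, integer(1))
  out
}

# Shannon information content per column, in bits: log2(20) - H(column).
.column_information <- function(m) {
  apply(m, 2, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
}

#' Export a PFM as a logo matrix TSV
#'
#' One row per column: `position`, the 20 residue frequencies (alphabetical),
#' and the column information content in bits (`log2(20)` minus the Shannon
#' entropy), the quantity that scales letter heights in a sequence logo.
#'
#' @param pfm A `nano_pfm`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
export_logo_matrix <- function(pfm, path) {
  stopifnot(inherits(pfm, "nano_pfm"))
  df <- as.data.frame(t(pfm$matrix))
  names(df) <- AA20
  df <- cbind(position = seq_len(ncol(pfm$matrix)), df,
              information = .column_information(pfm$matrix))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a logo matrix TSV back into a PFM matrix
#'
#' @param path TSV written by [export_logo_matrix()].
#' @return A 20 x L matrix with rows named by [AA20].
#' @export
read_logo_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character(0))
  m <- t(as.matrix(df[, AA20]))
  rownames(m) <- AA20
  m
}

# Sample n strings of the PFM's length, columns independent.
.sample_pfm_strings <- function(m, n) {
  L <- ncol(m)
  cols <- vapply(seq_len(L),
                 function(j) sample(AA20, n, replace = TRUE, prob = m[, j]),
                 character(n))
  if (n == 1L) cols <- matrix(cols, nrow = 1L)
  apply(cols, 1, paste, collapse = "")
}
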