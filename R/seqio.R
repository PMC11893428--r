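#' The 20 canonical amino-acid letters
#'
#' Alphabetically ordered one-letter codes of the 20 proteinogenic amino
#' acids. This is the only residue alphabet the package accepts: ambiguity
#' codes (X, B, Z, J) and stops (*) are rejected rather than masked, because
#' they would contaminate positional frequency statistics downstream.
#'
#' @format Character vector of length 20.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a table of sequence records
#'
#' The package's core record collection: a data frame with columns `id`,
#' `seq` and `germline` (an optional germline label such as "IGHV3-3*01",
#' `NA` when unassigned).
#'
#' @param id Character vector of unique identifiers.
#' @param seq Character vector of amino-acid sequences (uppercase, 20-letter
#'   alphabet).
#' @param germline Optional character vector of germline labels.
#' @return A data frame of class `nano_records`.
#' @export
nano_records <- function(id, seq, germline = NA_character_) {
  stopifnot(length(id) == length(seq))
  if (anyDuplicated(id)) {
    stop("record ids must be unique; duplicated: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  out <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                    germline = rep_len(as.character(germline), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("nano_records", "data.frame")
  out
}

#' Validate an amino-acid sequence
#'
#' Checks a sequence against the canonical 20-letter alphabet. Validation
#' never throws: the result lists every offending character with its
#' (1-based) position.
#'
#' @param seq A single character string.
#' @return A list with elements `ok` (logical) and `violations`, a data frame
#'   with columns `position` and `char` (empty when `ok`).
#' @examples
#' validate_sequence("EVQLV")$ok
#' validate_sequence("EVX*LV")$violations
#' @export
validate_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% AA20))
  if (nchar(seq) == 0L) {
    return(list(ok = FALSE,
                violations = data.frame(position = 0L, char = "",
                                        stringsAsFactors = FALSE)))
  }
  list(ok = length(bad) == 0L,
       violations = data.frame(position = bad, char = chars[bad],
                               stringsAsFactors = FALSE))
}

#' Read protein sequences from a FASTA file
#'
#' One record per FASTA entry, order preserved. The first whitespace-separated
#' token of the header is the record id; a `germline=<name>` key in the
#' header description, as written by [write_fasta()], is parsed back into the
#' `germline` column. Sequences are uppercased; duplicate ids are
#' disambiguated by suffixing `_2`, `_3`, ...
#'
#' @param path Path to a FASTA file.
#' @return A `nano_records` data frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(nano_records(character(0), character(0)))
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA at line ", first,
         ": expected a '>' header, got: ", trimws(lines[first]))
  }
  bad <- nonblank[!startsWith(trimws(lines[nonblank]), ">") &
                    grepl("[^A-Za-z*.-]", gsub("\\s", "", lines[nonblank]))]
  if (length(bad) > 0L) {
    stop("malformed FASTA at line ", bad[1],
         ": not a valid sequence line: ", trimws(lines[bad[1]]))
  }
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  germ <- rep(NA_character_, length(headers))
  hit <- regmatches(headers, regexpr("germline=[^\\s]+", headers, perl = TRUE))
  has <- grepl("germline=", headers, fixed = TRUE)
  germ[has] <- sub("^germline=", "", hit)
  if (anyDuplicated(ids)) {
    for (dup in unique(ids[duplicated(ids)])) {
      at <- which(ids == dup)
      ids[at[-1]] <- paste0(dup, "_", seq_along(at[-1]) + 1L)
    }
  }
  nano_records(ids, toupper(as.character(aas)), germ)
}

#' Write sequence records to a FASTA file
#'
#' Round-trip safe with [read_fasta()]: ids and sequences are reproduced
#' exactly, and non-`NA` germline labels are carried in the header as
#' `germline=<name>`. Sequence lines are wrapped at 60 columns.
#'
#' @param records A `nano_records` data frame (all sequences must validate).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records))
  ok <- vapply(records$seq, function(s) validate_sequence(s)$ok, logical(1))
  if (!all(ok)) {
    stop("invalid sequence(s): ",
         paste(records$id[!ok], collapse = ", "))
  }
  headers <- records$id
  withg <- !is.na(records$germline)
  headers[withg] <- paste0(headers[withg], " germline=", records$germline[withg])
  aas <- Biostrings::AAStringSet(stats::setNames(records$seq, headers))
  Biostrings::writeXStringSet(aas, filepath = path, width = 60L)
  invisible(path)
}
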