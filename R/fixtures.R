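# Bundled fixtures: the two donor framework sequences and the matching
# synthetic germline V-gene references with hand-assigned IMGT maps.
# The references are germline-consistent backbones derived from the
# frameworks' V regions (through IMGT 104); they emulate the alpaca IMGT
# alleles IGHV3-3*01 and IGHV3S53*01 and are not copies of IMGT records.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "nanolibkit")
  if (!nzchar(path)) {
    # during in-source development (pkgload) fall back to inst/
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("missing bundled fixture: ", file)
  path
}

#' Names of the bundled germlines
#'
#' @return Character vector of germline names with bundled framework and
#'   reference fixtures.
#' @export
nano_germlines <- function() c("IGHV3-3*01", "IGHV3S53*01")

#' A bundled donor framework sequence
#'
#' The full-length (FR1..FR4) framework chosen for the given germline:
#' highly humanized donors with few liability motifs, used as grafting
#' scaffolds for library synthesis and as simulation backbones.
#'
#' @param germline One of [nano_germlines()].
#' @return A single-row `nano_records` data frame.
#' @export
nano_framework <- function(germline = nano_germlines()) {
  germline <- match.arg(germline)
  recs <- read_fasta(.extdata("frameworks.fasta"))
  out <- recs[recs$germline == germline, , drop = FALSE]
  if (nrow(out) != 1L) stop("no bundled framework for ", germline)
  rownames(out) <- NULL
  class(out) <- c("nano_records", "data.frame")
  out
}

#' The bundled germline V-gene references
#'
#' @param germline Optionally, a single germline name; by default all
#'   bundled references are returned.
#' @return A list of `germline_reference` objects (or a single one when
#'   `germline` is given).
#' @export
nano_references <- function(germline = NULL) {
  recs <- read_fasta(.extdata("germline_refs.fasta"))
  map <- utils::read.delim(.extdata("germline_refs_imgt.tsv"),
                           stringsAsFactors = FALSE)
  refs <- lapply(seq_len(nrow(recs)), function(i) {
    m <- map[map$name == recs$id[i], , drop = FALSE]
    m <- m[order(m$residue_index), , drop = FALSE]
    germline_reference(recs$id[i], recs$seq[i], m$imgt_position)
  })
  names(refs) <- recs$id
  if (!is.null(germline)) {
    if (!germline %in% names(refs)) stop("no bundled reference for ", germline)
    return(refs[[germline]])
  }
  refs
}

#' Region annotation of a bundled framework
#'
#' The framework numbered against its own germline reference and delimited
#' into FR/CDR regions; used as the grafting template by the simulator and
#' the library synthesizer.
#'
#' @param germline One of [nano_germlines()].
#' @return A `region_annotation`.
#' @export
framework_annotation <- function(germline = nano_germlines()) {
  germline <- match.arg(germline)
  fw <- nano_framework(germline)
  extract_regions(number_sequence(fw, nano_references(germline)))
}
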