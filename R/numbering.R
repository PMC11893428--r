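# IMGT anchor-transfer numbering and FR/CDR delimitation.
#
# Queries are numbered by global alignment to an assigned germline reference
# whose IMGT map is known: reference-aligned residues inherit the reference's
# IMGT number, insertions receive insertion codes, and the tail beyond the
# V gene (CDR3 + FR4) is numbered by the IMGT junction convention with FR4
# right-anchored on the J-region WGQG motif. This is sufficient for the
# regime the pipeline operates in (sequences >= 85% identical to a known
# reference); it is not a general HMM-based numberer.

#' IMGT region boundary constants
#'
#' IMGT unique-numbering delimitations used throughout the package:
#' CDR1 = positions 27-38, CDR2 = 56-65, CDR3 = 105-117 (insertion codes on
#' 111/112 included), FR4 from 118; the conserved cysteines sit at 23 and 104.
#'
#' @format Named integer vector.
#' @export
IMGT_BOUNDS <- c(cdr1_start = 27L, cdr1_end = 38L,
                 cdr2_start = 56L, cdr2_end = 65L,
                 cdr3_start = 105L, cdr3_end = 117L,
                 fr4_start = 118L, cys1 = 23L, cys2 = 104L)

# IMGT middle-gapping: place L residues into IMGT positions from..to,
# filling contiguously from both ends with the gap at the top of the loop
# (front half rounds up). Returns the occupied positions in order.
.imgt_fill <- function(from, to, L) {
  width <- to - from + 1L
  if (L > width) stop("segment of ", L, " residues exceeds IMGT range ",
                      from, "-", to)
  front <- ceiling(L / 2)
  back <- L - front
  c(seq_len(front) + from - 1L,
    if (back > 0) seq(to - back + 1L, to) else integer(0))
}

#' Build an IMGT position map for a V region from its segment lengths
#'
#' Assigns IMGT positions 1-104 to a V-region sequence given the lengths of
#' its FR1, CDR1, FR2, CDR2 and FR3 segments, using the standard IMGT
#' conventions: FR1 occupies 1-26 (gap at position 10 when 25 residues),
#' CDR1 fills 27-38 and CDR2 fills 56-65 from both ends with the gap in the
#' middle, FR2 is exactly 39-55 (17 residues), and FR3 occupies 66-104 (gap
#' at position 73 when 38 residues).
#'
#' @param fr1,cdr1,fr2,cdr2,fr3 Segment lengths in residues.
#' @return Integer vector of IMGT positions, one per residue.
#' @export
imgt_v_map <- function(fr1, cdr1, fr2, cdr2, fr3) {
  if (fr2 != 17L) stop("FR2 must be 17 residues (IMGT 39-55), got ", fr2)
  if (fr1 > 26L || fr1 < 9L) stop("FR1 length out of range: ", fr1)
  if (fr3 > 39L) stop("FR3 length out of range: ", fr3)
  fr1_pos <- c(1:9, seq(26L - (fr1 - 9L) + 1L, 26L))
  fr3_pos <- c(66:72, seq(104L - (fr3 - 7L) + 1L, 104L))
  c(fr1_pos,
    .imgt_fill(27L, 38L, cdr1),
    39:55,
    .imgt_fill(56L, 65L, cdr2),
    fr3_pos)
}

# IMGT junction numbering for n CDR3 residues (IMGT 105-117 plus insertion
# codes on 111/112). Returns data.frame(label, key): `key` is a numeric sort
# key consistent with the IMGT order 111 < 111.1 < ... < 112.2 < 112.1 < 112.
.cdr3_junction_labels <- function(n) {
  if (n == 0L) return(data.frame(label = character(0), key = numeric(0)))
  if (n <= 13L) {
    front <- ceiling(n / 2)
    back <- n - front
    pos <- c(seq_len(front) + 104L,
             if (back > 0) seq(117L - back + 1L, 117L) else integer(0))
    return(data.frame(label = as.character(pos), key = as.numeric(pos),
                      stringsAsFactors = FALSE))
  }
  extra <- n - 13L
  a <- ceiling(extra / 2)
  b <- extra - a
  lab <- c(as.character(105:111),
           paste0("111.", seq_len(a)),
           if (b > 0) paste0("112.", rev(seq_len(b))) else character(0),
           as.character(112:117))
  key <- c(105:111,
           111 + seq_len(a) / 100,
           if (b > 0) 112 - rev(seq_len(b)) / 100 else numeric(0),
           112:117)
  data.frame(label = lab, key = key, stringsAsFactors = FALSE)
}

#' Transfer IMGT numbering from a germline reference onto a query
#'
#' Globally aligns the query to the reference; residues aligned to a
#' reference residue inherit its IMGT number, insertions relative to the
#' reference receive insertion codes (`62.1`, `62.2`, ...) on the preceding
#' number, and the tail beyond the last reference-aligned residue is split
#' into CDR3 (IMGT junction numbering, 105-117 with 111.x/112.x insertion
#' codes) and FR4 (118 onward), right-anchored on the last `WGQG` motif in
#' the tail. When no `WGQG` is present the first 13 tail residues are
#' numbered as CDR3 and the remainder as FR4.
#'
#' @param rec Single-row `nano_records` data frame (or list with `id`,
#'   `seq`).
#' @param ref A `germline_reference`.
#' @param min_identity Numbering floor: below this identity to the reference
#'   the query is considered unnumberable (default 0.5).
#' @return An object of class `imgt_numbering`: `query_id`, `germline`, and
#'   `table`, a data frame with one row per query residue (`index`,
#'   `residue`, `label`, `key`) in sequence order; `key` is a numeric sort
#'   key consistent with IMGT label order.
#' @export
number_sequence <- function(rec, ref, min_identity = 0.5) {
  stopifnot(inherits(ref, "germline_reference"))
  seq <- rec$seq[1]
  v <- validate_sequence(seq)
  if (!v$ok) stop("invalid query sequence")
  aln <- align_global(seq, ref$seq)
  .number_from_alignment(aln, rec$id[1], ref, min_identity)
}

# Numbering walk over a precomputed alignment; shared by number_sequence
# and the batched paths (annotate_repertoire, the generation filter).
.number_from_alignment <- function(aln, query_id, ref, min_identity = 0.5) {
  pid <- percent_identity(aln)
  if (pid < min_identity) {
    stop("unnumberable: identity ", sprintf("%.2f", pid), " to ", ref$name,
         " is below the ", min_identity, " floor")
  }
  p <- strsplit(aln$pattern, "", fixed = TRUE)[[1]]
  s <- strsplit(aln$subject, "", fixed = TRUE)[[1]]
  last_ref_col <- max(which(s != "-"))
  n_res <- sum(p != "-")

  residue <- character(n_res)
  label <- character(n_res)
  key <- numeric(n_res)
  idx <- 0L   # query residue counter
  ri <- 0L    # reference residue counter
  ins_count <- 0L
  last_label <- NA_integer_
  for (col in seq_len(last_ref_col)) {
    if (s[col] != "-") {
      ri <- ri + 1L
      ins_count <- 0L
      last_label <- ref$imgt_positions[ri]
      if (p[col] != "-") {
        idx <- idx + 1L
        residue[idx] <- p[col]
        label[idx] <- as.character(last_label)
        key[idx] <- last_label
      }
    } else if (p[col] != "-") {
      # insertion relative to the reference
      idx <- idx + 1L
      ins_count <- ins_count + 1L
      if (is.na(last_label)) stop("insertion before the first reference position")
      residue[idx] <- p[col]
      label[idx] <- paste0(last_label, ".", ins_count)
      key[idx] <- last_label + ins_count / 100
    }
  }

  # tail: query residues beyond the last reference-aligned column
  tail_chars <- p[seq_len(length(p)) > last_ref_col]
  tail_chars <- tail_chars[tail_chars != "-"]
  n_tail <- length(tail_chars)
  if (n_tail > 0L) {
    tail_str <- paste(tail_chars, collapse = "")
    hits <- gregexpr("WGQG", tail_str, fixed = TRUE)[[1]]
    if (hits[1] != -1L) {
      n_cdr3 <- hits[length(hits)] - 1L
    } else {
      n_cdr3 <- min(13L, n_tail)
    }
    jl <- .cdr3_junction_labels(n_cdr3)
    at <- idx + seq_len(n_tail)
    residue[at] <- tail_chars
    label[at] <- c(jl$label, as.character(117L + seq_len(n_tail - n_cdr3)))
    key[at] <- c(jl$key, 117 + seq_len(n_tail - n_cdr3))
    idx <- idx + n_tail
  }

  stopifnot(idx == n_res, !is.unsorted(key))
  tab <- data.frame(index = seq_len(n_res), residue = residue,
                    label = label, key = key, stringsAsFactors = FALSE)
  structure(list(query_id = query_id, germline = ref$name, table = tab),
            class = "imgt_numbering")
}

#' Delimit FR and CDR regions from an IMGT numbering
#'
#' Applies the IMGT delimitation (CDR1 27-38, CDR2 56-65, CDR3 105-117 with
#' insertion codes; FR1-FR4 the complements) to a numbered query. The seven
#' spans are contiguous, non-overlapping, and tile the sequence.
#'
#' @param numbering An `imgt_numbering` from [number_sequence()].
#' @return An object of class `region_annotation`: `query_id`, `germline`,
#'   `seq`, `spans` (data frame of `region`, `start`, `end`, inclusive
#'   1-based residue indices), the extracted `cdr1`/`cdr2`/`cdr3` strings,
#'   and the `numbering` it was derived from.
#' @export
extract_regions <- function(numbering) {
  stopifnot(inherits(numbering, "imgt_numbering"))
  tab <- numbering$table
  b <- IMGT_BOUNDS
  region <- cut(tab$key,
                breaks = c(-Inf, b["cdr1_start"] - 0.5, b["cdr1_end"] + 0.5,
                           b["cdr2_start"] - 0.5, b["cdr2_end"] + 0.5,
                           b["cdr3_start"] - 0.5, b["cdr3_end"] + 0.5, Inf),
                labels = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"))
  missing <- setdiff(c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
                     as.character(unique(region)))
  if (length(missing) > 0L) {
    stop("region error: no residues for ", paste(missing, collapse = ", "),
         " (query ", numbering$query_id, ")")
  }
  r <- rle(as.character(region))
  if (length(r$values) != 7L) {
    stop("region error: regions are not contiguous for ", numbering$query_id)
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  spans <- data.frame(region = r$values, start = starts, end = ends,
                      stringsAsFactors = FALSE)
  seq <- paste(tab$residue, collapse = "")
  sub_region <- function(nm) {
    i <- which(spans$region == nm)
    substr(seq, spans$start[i], spans$end[i])
  }
  structure(list(query_id = numbering$query_id, germline = numbering$germline,
                 seq = seq, spans = spans,
                 cdr1 = sub_region("CDR1"), cdr2 = sub_region("CDR2"),
                 cdr3 = sub_region("CDR3"), numbering = numbering),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat("<region_annotation>", x$query_id, "germline:", x$germline, "\n")
  cat("  CDR1:", x$cdr1, " CDR2:", x$cdr2, " CDR3:", x$cdr3, "\n")
  invisible(x)
}

#' Check the conserved C23/C104 cysteine pair
#'
#' Reports whether the residues numbered IMGT 23 and 104 exist and are
#' cysteines — the sequence-level signature of the conserved FR1-FR3
#' disulfide bond that stabilizes the VHH fold.
#'
#' @param numbering An `imgt_numbering`.
#' @return A list of class `disulfide_check` with `query_id`, `has_c23`,
#'   `has_c104` and `conserved_pair_present` (the conjunction).
#' @export
check_conserved_cysteines <- function(numbering) {
  stopifnot(inherits(numbering, "imgt_numbering"))
  tab <- numbering$table
  has_c23 <- any(tab$label == "23" & tab$residue == "C")
  has_c104 <- any(tab$label == "104" & tab$residue == "C")
  structure(list(query_id = numbering$query_id, has_c23 = has_c23,
                 has_c104 = has_c104,
                 conserved_pair_present = has_c23 && has_c104),
            class = "disulfide_check")
}

#' Assign, number and annotate a sequence in one step
#'
#' Convenience wrapper: assigns the best germline, transfers its numbering,
#' and extracts the region annotation.
#'
#' @param rec Single-row `nano_records` data frame.
#' @param refs List of `germline_reference` objects.
#' @return A `region_annotation`.
#' @export
annotate_sequence <- function(rec, refs) {
  asg <- assign_germline(rec, refs)
  ref <- refs[[which(vapply(refs, function(r) r$name, character(1)) ==
                       asg$best_germline)]]
  extract_regions(number_sequence(rec, ref))
}

#' Annotate every record of a repertoire
#'
#' @param records A `nano_records` data frame.
#' @param refs List of `germline_reference` objects.
#' @param on_error `"stop"` (default) propagates the first numbering or
#'   region error; `"skip"` returns `NULL` for records that cannot be
#'   annotated (e.g. unnumberable or missing a region).
#' @return A list of `region_annotation` objects, one per record (`NULL`
#'   entries for skipped records under `on_error = "skip"`).
#' @export
annotate_repertoire <- function(records, refs, on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  asg <- assign_germline_batch(records, refs)
  byname <- stats::setNames(refs, vapply(refs, function(r) r$name,
                                         character(1)))
  out <- vector("list", nrow(records))
  for (g in unique(asg$best_germline)) {
    at <- which(asg$best_germline == g)
    alns <- .align_global_many(records$seq[at], byname[[g]]$seq)
    out[at] <- lapply(seq_along(at), function(k) {
      annotate1 <- function() {
        extract_regions(.number_from_alignment(alns[[k]],
                                               records$id[at[k]],
                                               byname[[g]]))
      }
      if (on_error == "skip") {
        tryCatch(annotate1(), error = function(e) NULL)
      } else {
        annotate1()
      }
    })
  }
  out
}

#' Export an IMGT numbering as a TSV table
#'
#' Writes one row per residue: `query_id`, `residue_index`, `residue`,
#' `imgt_label`.
#'
#' @param numbering An `imgt_numbering`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_numbering_tsv <- function(numbering, path) {
  tab <- numbering$table
  out <- data.frame(query_id = numbering$query_id, residue_index = tab$index,
                    residue = tab$residue, imgt_label = tab$label,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
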