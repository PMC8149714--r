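## Breakpoint characterization: the analysis this package exists for.
## A deletion between two copies of a direct repeat can be placed anywhere
## the repeat slides, so coordinates are normalized to the leftmost
## (canonical) placement, the maximal exact repeat at the junction is the
## microhomology, and the junction is re-enacted and verified against the
## rearranged assembly. N never matches anything, including itself, so
## assembly gaps cannot inflate microhomology.

## match helper honouring the N-never-matches rule (codes: A..T = 0..3, N = NA)
.codes_eq <- function(a, b) !is.na(a) & !is.na(b) & a == b

#' Characterize a deletion breakpoint
#'
#' Given a raw deletion interval on the reference, computes the canonical
#' (leftmost) placement by sliding the interval left while the base before
#' the start equals the base before the end, the maximal exact direct repeat
#' shared by the two breakpoint flanks (the microhomology), the full range
#' of equivalent placements, and the deleted-segment length (invariant under
#' sliding).
#'
#' @param ref A \code{genome_element}.
#' @param start,end Internal 0-based half-open deletion interval
#'   \code{[start, end)} on \code{ref} (use \code{\link{interval_from_1based}}
#'   to convert printed coordinates).
#' @return A \code{deletion_call}: list with \code{element}, canonical
#'   \code{start}/\code{end} (0-based half-open), \code{repeat_seq},
#'   \code{mh_length}, \code{slide_window} (leftmost and rightmost equivalent
#'   canonical starts, 0-based), \code{deleted_segment_length} and
#'   \code{degenerate} flag.
#' @export
characterize_breakpoint <- function(ref, start, end) {
  stopifnot(inherits(ref, "genome_element"))
  stopifnot(start >= 0L, end >= start, end <= ref$length)
  x <- seq_to_codes(ref$seq)   # x[i] is the base at 0-based position i-1
  s <- as.integer(start); e <- as.integer(end)
  if (s == e) {
    return(structure(list(element = ref$id, start = s, end = e,
                          repeat_seq = "", mh_length = 0L,
                          slide_window = c(s, s),
                          deleted_segment_length = 0L, degenerate = TRUE),
                     class = "deletion_call"))
  }
  # canonical leftmost placement: slide while base before start == base before end
  while (s > 0L && .codes_eq(x[s], x[e])) { s <- s - 1L; e <- e - 1L }
  # rightmost equivalent placement
  s2 <- s; e2 <- e
  while (e2 < ref$length && .codes_eq(x[s2 + 1L], x[e2 + 1L])) {
    s2 <- s2 + 1L; e2 <- e2 + 1L
  }
  # microhomology: longest common prefix of the suffixes at s and e
  mh <- 0L
  while (e + mh < ref$length && .codes_eq(x[s + mh + 1L], x[e + mh + 1L]))
    mh <- mh + 1L
  structure(list(element = ref$id, start = s, end = e,
                 repeat_seq = substr(ref$seq, s + 1L, s + mh),
                 mh_length = mh,
                 slide_window = c(s, s2),
                 deleted_segment_length = e - s,
                 degenerate = FALSE),
            class = "deletion_call")
}

#' @export
print.deletion_call <- function(x, ...) {
  cat(sprintf(
    "<deletion_call> %s:%d-%d (1-based), %s bp deleted, repeat '%s' (%d bp), slide [%d, %d]\n",
    x$element, x$start + 1L, x$end, format(x$deleted_segment_length, big.mark = ","),
    x$repeat_seq, x$mh_length, x$slide_window[1] + 1L, x$slide_window[2] + 1L))
  invisible(x)
}

#' Re-enact a deletion in silico
#'
#' Excises \code{[start, end)} from the reference, exactly one repeat copy
#' surviving at the junction — the operation expected of repair between two
#' direct repeats.
#'
#' @param ref A \code{genome_element}.
#' @param call A \code{deletion_call} (or any list with \code{start},
#'   \code{end} internal coordinates).
#' @return A \code{genome_element} of length
#'   \code{ref$length - (end - start)}, id suffixed \code{"_del"}.
#' @export
reenact_deletion <- function(ref, call) {
  stopifnot(inherits(ref, "genome_element"))
  s <- call$start; e <- call$end
  stopifnot(s >= 0L, e >= s, e <= ref$length)
  derived <- paste0(substr(ref$seq, 1L, s), substr(ref$seq, e + 1L, ref$length))
  genome_element(paste0(ref$id, "_del"), derived, topology = ref$topology)
}

#' Reconstruct the expected junction sequence
#'
#' Returns the sequence expected to surround the surviving repeat copy in
#' the rearranged genome: \code{flank} bases upstream of the canonical start,
#' the repeat itself, and \code{flank} bases downstream of the second repeat
#' copy, truncated at element ends.
#'
#' @param ref A \code{genome_element}.
#' @param call A \code{deletion_call}.
#' @param flank Flank width in bp (default 60).
#' @return Junction string of length \code{<= flank + mh_length + flank}.
#' @export
reconstruct_junction <- function(ref, call, flank = 60L) {
  stopifnot(flank >= 0L)
  s <- call$start; e <- call$end; mh <- call$mh_length
  left <- substr(ref$seq, max(1L, s - flank + 1L), s)
  right <- substr(ref$seq, e + mh + 1L, min(ref$length, e + mh + flank))
  paste0(left, call$repeat_seq, right)
}

#' Verify a reconstructed junction in the rearranged genome
#'
#' Exact (overlap-aware) substring search of the junction in the derived
#' element.
#'
#' @param derived A \code{genome_element} (the rearranged assembly).
#' @param junction Non-empty junction string.
#' @return One of \code{"verified"} (exactly one occurrence),
#'   \code{"not_found"}, or \code{"multiple"}.
#' @export
verify_junction <- function(derived, junction) {
  stopifnot(inherits(derived, "genome_element"),
            is.character(junction), nzchar(junction))
  n <- Biostrings::countPattern(junction,
                                Biostrings::DNAString(derived$seq),
                                fixed = TRUE)
  if (n == 1L) "verified" else if (n == 0L) "not_found" else "multiple"
}

#' Classify the compatible repair mechanism of a junction
#'
#' Pure rule table over the junction features. An inexact junction or one
#' with inserted bases is the signature of non-homologous end-joining
#' (NHEJ), which typically uses 0-4 bp homology and adds or loses bases.
#' An exact junction at 2-20 bp of microhomology is compatible with
#' alternative end-joining (A-EJ/MMEJ); at >= 25 bp with single-strand
#' annealing (SSA). The 21-24 bp band between the two published thresholds
#' is reported as ambiguous, and exact junctions with 0-1 bp homology are
#' unclassified.
#'
#' @param mh_length Microhomology length in bp.
#' @param junction_exact Logical; junction matches the reference-predicted
#'   sequence exactly.
#' @param inserted_bases Bases added at the junction (bp).
#' @return A \code{mechanism_call}: list with \code{label} in
#'   \code{NHEJ-like}, \code{AEJ-compatible}, \code{SSA-compatible},
#'   \code{ambiguous}, \code{unclassified}, and the triggering
#'   \code{features}.
#' @export
classify_mechanism <- function(mh_length, junction_exact, inserted_bases = 0L) {
  if (mh_length < 0L || inserted_bases < 0L)
    stop("mh_length and inserted_bases must be non-negative")
  stopifnot(is.logical(junction_exact), length(junction_exact) == 1L)
  label <-
    if (inserted_bases > 0L || !junction_exact) "NHEJ-like"
    else if (mh_length >= 25L) "SSA-compatible"
    else if (mh_length >= 21L) "ambiguous"
    else if (mh_length >= 2L) "AEJ-compatible"
    else "unclassified"
  structure(list(label = label,
                 features = list(mh_length = as.integer(mh_length),
                                 junction_exact = junction_exact,
                                 inserted_bases = as.integer(inserted_bases))),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  f <- x$features
  cat(sprintf("<mechanism_call> %s (mh %d bp, %s junction, %d inserted)\n",
              x$label, f$mh_length,
              if (f$junction_exact) "exact" else "inexact", f$inserted_bases))
  invisible(x)
}
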