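#' @importFrom stats setNames
#' @importFrom utils read.delim write.table
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Create a genome element
#'
#' A genome element is one replicon (chromosome or plasmid): an id, an
#' upper-case nucleotide sequence over \code{A,C,G,T,N}, and a topology.
#' Bacterial replicons are physically circular, but deletions that do not
#' span the origin are analyzed on the linearized sequence, so topology
#' defaults to \code{"linear"}.
#'
#' @param id Character label for the replicon.
#' @param seq Nucleotide sequence (single string); lower case is accepted and
#'   upper-cased on ingest.
#' @param topology Either \code{"linear"} or \code{"circular"}.
#' @return An object of class \code{genome_element} with fields \code{id},
#'   \code{seq}, \code{topology} and \code{length}.
#' @export
genome_element <- function(id, seq, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  bad <- gregexpr("[^ACGTN]", seq)[[1L]]
  if (bad[1L] != -1L) {
    stop(sprintf("element '%s': invalid character '%s' at position %d",
                 id, substr(seq, bad[1L], bad[1L]), bad[1L]))
  }
  structure(list(id = id, seq = seq, topology = topology,
                 length = nchar(seq)),
            class = "genome_element")
}

#' @export
print.genome_element <- function(x, ...) {
  cat(sprintf("<genome_element> %s  %s  %s bp\n", x$id, x$topology,
              format(x$length, big.mark = ",")))
  invisible(x)
}

#' Read a multi-record FASTA file into a genome
#'
#' Parsing is delegated to \code{Biostrings::readDNAStringSet}; each record
#' becomes one \code{\link{genome_element}}. A header carrying the token
#' \code{circular=true} (or \code{topology=circular}) marks that element
#' circular; otherwise elements are linear unless \code{circular = TRUE}
#' forces all of them.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical; treat every element as circular.
#' @return A named list of \code{genome_element} objects (class
#'   \code{genome}), in file order.
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) stop("FASTA file is empty: ", path)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[[`, character(1L), 1L)
  circ <- circular | grepl("circular=true|topology=circular", headers,
                           ignore.case = TRUE)
  els <- lapply(seq_along(set), function(i) {
    genome_element(ids[i], as.character(set[[i]]),
                   topology = if (circ[i]) "circular" else "linear")
  })
  as_genome(els)
}

#' Assemble genome elements into a genome object
#'
#' @param elements List of \code{genome_element} objects.
#' @return Named list of class \code{genome}.
#' @export
as_genome <- function(elements) {
  if (inherits(elements, "genome_element")) elements <- list(elements)
  stopifnot(all(vapply(elements, inherits, logical(1L), "genome_element")))
  ids <- vapply(elements, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) stop("duplicate element ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(setNames(elements, ids), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d element(s), %s bp total\n", length(x),
              format(sum(vapply(x, `[[`, numeric(1L), "length")),
                     big.mark = ",")))
  for (el in x) print(el)
  invisible(x)
}

#' Write a genome to FASTA
#'
#' Sequences are wrapped at 70 columns. Circular elements carry a
#' \code{circular=true} token in the header so topology round-trips.
#'
#' @param genome A \code{genome} or single \code{genome_element}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (inherits(genome, "genome_element")) genome <- as_genome(list(genome))
  set <- Biostrings::DNAStringSet(vapply(genome, `[[`, character(1L), "seq"))
  names(set) <- vapply(genome, function(el) {
    if (el$topology == "circular") paste0(el$id, " circular=true") else el$id
  }, character(1L))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

## ---- intervals ------------------------------------------------------------
## Internal convention: 0-based half-open [start, end). All user-facing I/O is
## 1-based inclusive (GenBank style). Conversions live here and nowhere else.

#' Build an internal interval from 1-based inclusive coordinates
#'
#' @param element Element id.
#' @param start1,end1 1-based inclusive coordinates as printed in GenBank-style
#'   tables. A zero-length interval is represented as \code{end1 == start1 - 1}
#'   or flagged via \code{read_deletion_table}.
#' @return A one-row data.frame with internal 0-based half-open
#'   \code{start}/\code{end}.
#' @export
interval_from_1based <- function(element, start1, end1) {
  data.frame(element = element, start = start1 - 1L, end = end1,
             stringsAsFactors = FALSE)
}

#' Render internal intervals as 1-based inclusive coordinates
#'
#' @param intervals Data.frame with internal \code{start}/\code{end} columns.
#' @return The same data.frame with \code{start_1based}/\code{end_1based}
#'   replacing the internal columns.
#' @export
interval_to_1based <- function(intervals) {
  out <- intervals
  out$start_1based <- intervals$start + 1L
  out$end_1based <- intervals$end
  out$start <- NULL
  out$end <- NULL
  out
}

#' Read a deletion-coordinate table
#'
#' Expects a TSV with header columns \code{isolate}, \code{element},
#' \code{start}, \code{end}: 1-based repeat-anchored deletion coordinates in
#' the convention of GenBank-style published tables, where \code{start} and
#' \code{end} are the positions at which the two breakpoint-repeat copies
#' begin. The excised interval is therefore internally
#' \code{[start - 1, end - 1)} (0-based half-open) and the deleted-segment
#' length is \code{end - start} exactly as printed. An optional
#' \code{printed_length} column carries a published deletion length; when it
#' disagrees with \code{end - start} the row is kept and a warning surfaces
#' both values — published tables are never silently reconciled. Optional
#' extra columns (e.g. \code{repeat_seq}) are preserved.
#'
#' @param path TSV path.
#' @param genome Optional \code{genome} used to bounds-check coordinates.
#' @return Data.frame with columns \code{isolate}, \code{element}, internal
#'   \code{start}/\code{end} (0-based half-open excision bounds),
#'   \code{deleted_segment_length} (= end - start), \code{degenerate} flag,
#'   plus any extra input columns.
#' @export
read_deletion_table <- function(path, genome = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("isolate", "element", "start", "end")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("deletion table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(tab$end < tab$start))
    stop("deletion table: end < start on a linear element")
  out <- tab
  out$start <- tab$start - 1L   # internal 0-based half-open excision bounds
  out$end <- tab$end - 1L
  out$deleted_segment_length <- out$end - out$start
  out$degenerate <- out$deleted_segment_length == 0L
  if (any(out$degenerate))
    warning("zero-length interval(s) for isolate(s): ",
            paste(out$isolate[out$degenerate], collapse = ", "))
  if (!is.null(genome)) {
    for (i in seq_len(nrow(out))) {
      el <- genome[[out$element[i]]]
      if (is.null(el)) stop("unknown element '", out$element[i], "' in row ", i)
      if (out$start[i] < 0L || out$end[i] > el$length)
        stop(sprintf("row %d (%s): coordinates exceed element '%s' length %d",
                     i, out$isolate[i], el$id, el$length))
    }
  }
  if ("printed_length" %in% names(tab)) {
    bad <- which(!is.na(tab$printed_length) &
                   tab$printed_length != out$deleted_segment_length)
    if (length(bad))
      warning("printed deletion length disagrees with end - start for: ",
              paste(sprintf("%s (printed %d vs computed %d)",
                            out$isolate[bad], tab$printed_length[bad],
                            out$deleted_segment_length[bad]),
                    collapse = "; "),
              call. = FALSE)
  }
  out
}

#' Read a gene table
#'
#' TSV with columns \code{gene_id}, \code{element}, \code{start}, \code{end}
#' (1-based inclusive), \code{strand} (\code{+}, \code{-}, or \code{.} when
#' unknown), \code{product}, \code{cog} (concatenated single-letter COG
#' classes, possibly empty or \code{-}).
#'
#' @param path TSV path.
#' @param complete_cds Logical; require interval lengths to be multiples of 3.
#' @return Data.frame with internal 0-based half-open \code{start}/\code{end}.
#' @export
read_gene_table <- function(path, complete_cds = FALSE) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("gene_id", "element", "start", "end", "strand", "product", "cog")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(tab$end < tab$start)) stop("gene table: end < start")
  tab$start <- tab$start - 1L
  len <- tab$end - tab$start
  if (complete_cds && any(len %% 3L != 0L))
    stop("complete CDS record(s) with length not a multiple of 3: ",
         paste(tab$gene_id[len %% 3L != 0L], collapse = ", "))
  tab$cog[is.na(tab$cog) | tab$cog == "-"] <- ""
  tab
}

## internal: sequence <-> integer codes (A=0 C=1 G=2 T=3, N=NA)
.BASE_CODE <- local({
  v <- rep(NA_integer_, 128L)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("T")] <- 3L
  v
})

seq_to_codes <- function(seq) .BASE_CODE[utf8ToInt(seq)]

codes_to_seq <- function(codes) {
  map <- utf8ToInt("ACGTN")
  idx <- ifelse(is.na(codes), 5L, codes + 1L)
  intToUtf8(map[idx])
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
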