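## End-to-end orchestration: call (or load) deletions, characterize each
## breakpoint, re-enact and verify junctions, classify mechanisms, and emit
## the supporting genome statistics. All outputs are plain data.frames with
## 1-based printed coordinates and fixed float formatting, so a run is
## byte-reproducible from its configuration and inputs.

#' Characterize a table of deletions end to end
#'
#' For each deletion interval: canonical placement and microhomology, the
#' reconstructed junction, verification against the derived assembly (or
#' \code{"skipped"} when no derived genome is supplied), and the
#' repair-mechanism classification. Junction verification failing does not
#' stop the run; it is reported per row.
#'
#' @param reference A \code{genome}.
#' @param deletions Data.frame with \code{isolate}, \code{element}, internal
#'   \code{start}/\code{end} (as from \code{\link{read_deletion_table}} or
#'   \code{\link{call_deletions}}).
#' @param derived Optional named list mapping isolate to its derived
#'   \code{genome} (or a single \code{genome} used for all isolates).
#' @param flank Junction flank width (default 60 bp).
#' @return Data.frame, one row per deletion: 1-based canonical coordinates,
#'   deleted-segment length, repeat, microhomology length, slide window,
#'   junction string, verification status and mechanism label.
#' @export
characterize_deletions <- function(reference, deletions, derived = NULL,
                                   flank = 60L) {
  stopifnot(inherits(reference, "genome"))
  rows <- lapply(seq_len(nrow(deletions)), function(i) {
    el <- reference[[deletions$element[i]]]
    if (is.null(el)) stop("unknown element: ", deletions$element[i])
    call <- characterize_breakpoint(el, deletions$start[i], deletions$end[i])
    junction <- reconstruct_junction(el, call, flank)
    der_genome <- if (is.null(derived)) NULL
      else if (inherits(derived, "genome")) derived
      else derived[[deletions$isolate[i]]]
    status <- if (is.null(der_genome)) "skipped" else {
      der_el <- der_genome[[sub("_del$", "", el$id)]]
      if (is.null(der_el)) der_el <- der_genome[[1L]]
      verify_junction(der_el, junction)
    }
    mech <- classify_mechanism(call$mh_length,
                               junction_exact = !identical(status, "not_found"),
                               inserted_bases = 0L)
    data.frame(isolate = if ("isolate" %in% names(deletions))
                 deletions$isolate[i] else paste0("call", i),
               element = el$id,
               start_1based = call$start + 1L,
               end_1based = call$end + 1L,   # repeat-anchored: second repeat start
               deleted_segment_length = call$deleted_segment_length,
               repeat_seq = call$repeat_seq,
               mh_length = call$mh_length,
               slide_leftmost_1based = call$slide_window[1L] + 1L,
               slide_rightmost_1based = call$slide_window[2L] + 1L,
               junction = junction,
               junction_verified = status,
               mechanism = mech$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full breakpoint-characterization pipeline
#'
#' Stages: (1) load or accept the reference genome; (2) take deletion calls
#' from a table, or call them against the derived genome; (3) characterize
#' every breakpoint, verify junctions, classify mechanisms; (4) repeat-pair
#' coverage at the requested lengths; (5) region statistics for the common
#' deleted region versus its whole element (when genes are given); (6)
#' terminus flags under replichore balance.
#'
#' @param reference A \code{genome} (or FASTA path).
#' @param derived Optional derived \code{genome} (or FASTA path), one
#'   rearranged assembly.
#' @param deletions Optional deletion table (data.frame with internal
#'   coordinates or TSV path); when absent, deletions are called from
#'   \code{derived}.
#' @param genes Optional gene table (data.frame or TSV path).
#' @param flank Junction flank width (default 60).
#' @param k,min_len Caller parameters (defaults 31, 1000).
#' @param coverage_L Integer vector of repeat lengths for coverage (default
#'   11), or NULL to skip.
#' @param coverage_revcomp Count inverted repeats in coverage (default
#'   FALSE).
#' @param ori Named vector of 1-based origin positions per element (default:
#'   position 1 for every element).
#' @return List of class \code{deljunct_run}: \code{deletions} (the
#'   characterized table), \code{repeat_coverage}, \code{region_stats},
#'   \code{terminus}, \code{log} (data.frame of stage decisions).
#' @export
run_pipeline <- function(reference, derived = NULL, deletions = NULL,
                         genes = NULL, flank = 60L, k = 31L,
                         min_len = 1000L, coverage_L = 11L,
                         coverage_revcomp = FALSE, ori = NULL) {
  log <- list()
  note <- function(stage, event, detail = "")
    log[[length(log) + 1L]] <<- data.frame(stage = stage, event = event,
                                           detail = detail)
  if (is.character(reference)) reference <- read_genome_fasta(reference)
  if (is.character(derived)) derived <- read_genome_fasta(derived)
  if (is.character(deletions))
    deletions <- read_deletion_table(deletions, genome = reference)
  if (is.character(genes)) genes <- read_gene_table(genes)

  if (is.null(deletions)) {
    if (is.null(derived))
      stop("run_pipeline: need either a deletion table or a derived genome")
    calls <- list()
    for (id in names(reference)) {
      der_el <- derived[[id]]
      if (is.null(der_el)) next
      cl <- call_deletions(reference[[id]], der_el, k = k, min_len = min_len)
      if (nrow(cl)) {
        cl$element <- id
        calls[[length(calls) + 1L]] <- cl
      }
      note("call", "element_done",
           sprintf("%s: %d call(s)", id, nrow(cl)))
    }
    deletions <- if (length(calls)) {
      d <- do.call(rbind, calls)
      data.frame(isolate = paste0("call", seq_len(nrow(d))),
                 element = d$element, start = d$ref_start, end = d$ref_end,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(isolate = character(0L), element = character(0L),
                 start = integer(0L), end = integer(0L))
    }
  }

  characterized <- if (nrow(deletions))
    characterize_deletions(reference, deletions, derived, flank)
  else NULL
  if (!is.null(characterized)) {
    slid <- characterized$start_1based != deletions$start + 1L
    for (i in which(slid))
      note("characterize", "canonicalization_slide",
           sprintf("%s: start %d -> %d", characterized$isolate[i],
                   deletions$start[i] + 1L, characterized$start_1based[i]))
  }

  coverage <- NULL
  if (!is.null(coverage_L)) {
    coverage <- do.call(rbind, lapply(coverage_L, function(L) {
      rc <- repeat_coverage(reference, L, include_revcomp = coverage_revcomp)
      data.frame(L = L, covered = rc$covered_positions,
                 total = rc$total_positions,
                 percent = round(rc$percent, 1L))
    }))
  }

  region_stats <- NULL
  terminus <- NULL
  if (!is.null(characterized) && nrow(characterized)) {
    by_el <- split(characterized, characterized$element)
    terminus <- do.call(rbind, lapply(names(by_el), function(id) {
      el <- reference[[id]]
      ori_pos <- if (!is.null(ori) && id %in% names(ori)) ori[[id]] else 1L
      ter <- predict_terminus(ori_pos, el$length)
      tab <- by_el[[id]]
      data.frame(isolate = tab$isolate, element = id,
                 ter_pos = ter, ter_rounded = round_coord(ter),
                 spans_terminus = vapply(seq_len(nrow(tab)), function(i)
                   spans_terminus(tab$start_1based[i] - 1L,
                                  tab$end_1based[i] - 1L, ter), logical(1L)))
    }))
    for (id in names(by_el)) {
      tab <- by_el[[id]]
      if (nrow(tab) < 2L) next
      cr <- common_region(data.frame(start = tab$start_1based - 1L,
                                     end = tab$end_1based - 1L))
      if (nrow(cr)) {
        note("overlap", "common_region",
             sprintf("%s:%d-%d (repeat-anchored, 1-based), %d kb", id,
                     cr$start + 1L, cr$end + 1L,
                     (cr$end - cr$start) %/% 1000L))
        if (!is.null(genes)) {
          region_stats <- list(
            common_region = region_report(reference[[id]], genes,
                                          cr$start, cr$end),
            whole_element = region_report(reference[[id]], genes))
        }
      }
    }
  }

  structure(list(deletions = characterized, repeat_coverage = coverage,
                 region_stats = region_stats, terminus = terminus,
                 log = if (length(log)) do.call(rbind, log) else NULL),
            class = "deljunct_run")
}

#' Write the pipeline report bundle as TSV files
#'
#' Fixed column order and float formatting (percent: 1 decimal, SCUO: 4
#' decimals) keep reports byte-identical across runs.
#'
#' @param run A \code{deljunct_run}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_run_report <- function(run, dir) {
  stopifnot(inherits(run, "deljunct_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name) {
    if (is.null(df)) return()
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  emit(run$deletions, "deletions.tsv")
  emit(run$repeat_coverage, "repeat_coverage.tsv")
  emit(run$terminus, "terminus.tsv")
  emit(run$log, "log.tsv")
  if (!is.null(run$region_stats)) {
    fmt <- function(r) data.frame(
      region = sprintf("%s:%d-%d", r$element, r$start_1based, r$end_1based),
      gc_percent = sprintf("%.1f", r$gc_percent),
      gene_count = r$gene_count,
      median_scuo = ifelse(is.na(r$median_scuo), "NA",
                           sprintf("%.4f", r$median_scuo)),
      gc3s_percent = ifelse(is.na(r$gc3s_percent), "NA",
                            sprintf("%.1f", r$gc3s_percent)))
    emit(rbind(fmt(run$region_stats$common_region),
               fmt(run$region_stats$whole_element)), "region_stats.tsv")
  }
  invisible(dir)
}
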