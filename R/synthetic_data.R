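## Synthetic genomes with planted repeats and deletion events. The simulator
## emulates the composition regime of a GC-rich multi-replicon bacterial
## genome (defaults: the four replicon lengths of the D. radiodurans wt-1999
## assembly at 67% GC) and plants deletion events under three repair models:
## A-EJ (2-20 bp exact microhomology), SSA (>= 25 bp repeats) and NHEJ
## (0-4 bp homology, junctional indels). Planted truth is exact: flank bases
## at each repeat copy are fixed by rejection so the maximal exact repeat at
## the junction equals the requested microhomology exactly, and the planted
## leftmost placement is canonical.

#' Default element lengths for the emulation profile
#'
#' The four replicon lengths (chromosome I, chromosome II, megaplasmid MP1,
#' plasmid CP1) of the wt-1999 *D. radiodurans* assembly, 3,284,156 bp total.
#' @export
WT1999_ELEMENT_LENGTHS <- c(chrI = 2648638L, chrII = 412348L,
                            MP1 = 177466L, CP1 = 45704L)

#' Simulation configuration
#'
#' @param element_lengths Named or unnamed positive integer vector of replicon
#'   lengths (bp). Defaults to the wt-1999 emulation profile.
#' @param gc Genome GC fraction in \[0, 1\] (default 0.67).
#' @param seed Integer seed; fully determines the simulator output.
#' @param markov_order 0 for iid bases, 1 for a first-order chain.
#' @param persistence For \code{markov_order = 1}: probability that a base
#'   copies its predecessor instead of an independent draw (a simple way to
#'   obtain short-range autocorrelation with the stationary composition kept
#'   at \code{gc}).
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(element_lengths = WT1999_ELEMENT_LENGTHS,
                       gc = 0.67, seed = 1L, markov_order = 0L,
                       persistence = 0.0) {
  stopifnot(length(element_lengths) >= 1L, all(element_lengths > 0L),
            gc >= 0, gc <= 1, markov_order %in% c(0L, 1L),
            persistence >= 0, persistence < 1)
  if (is.null(names(element_lengths)))
    names(element_lengths) <- paste0("elem", seq_along(element_lengths))
  structure(list(element_lengths = element_lengths, gc = gc,
                 seed = as.integer(seed), markov_order = as.integer(markov_order),
                 persistence = persistence),
            class = "sim_config")
}

## base probabilities (A, C, G, T) for a GC fraction
.base_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

## draw n base codes (0..3) from the current RNG stream
.draw_codes <- function(n, gc, markov_order = 0L, persistence = 0) {
  p <- .base_probs(gc)
  iid <- sample.int(4L, n, replace = TRUE, prob = p) - 1L
  if (markov_order == 0L || persistence == 0) return(iid)
  fresh <- stats::runif(n) >= persistence
  fresh[1L] <- TRUE
  src <- cummax(ifelse(fresh, seq_len(n), 0L))
  iid[src]
}

#' Generate a random genome
#'
#' Elements are generated in configuration order from a single RNG stream
#' seeded with \code{config$seed}, so output is reproducible.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{genome}.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  els <- lapply(seq_along(config$element_lengths), function(i) {
    codes <- .draw_codes(config$element_lengths[[i]], config$gc,
                         config$markov_order, config$persistence)
    genome_element(names(config$element_lengths)[i], codes_to_seq(codes))
  })
  as_genome(els)
}

#' Specify a deletion event
#'
#' @param mechanism One of \code{"AEJ"}, \code{"SSA"}, \code{"NHEJ"}.
#' @param mh_length Exact microhomology at the junction (bp): 2-20 for AEJ,
#'   >= 25 for SSA, 0-4 for NHEJ.
#' @param deletion_length Distance between the two repeat starts (bp); the
#'   number of reference bases removed, ignoring any junctional indel.
#' @param junction_indel NHEJ only: bases inserted at the junction (> 0) or
#'   additionally lost beyond the deletion interval (< 0). Must be 0 for
#'   AEJ/SSA, whose junctions carry no sequence change besides the deletion.
#' @return An \code{event_spec} list.
#' @export
event_spec <- function(mechanism = c("AEJ", "SSA", "NHEJ"),
                       mh_length, deletion_length, junction_indel = 0L) {
  mechanism <- match.arg(mechanism)
  mh_length <- as.integer(mh_length)
  deletion_length <- as.integer(deletion_length)
  junction_indel <- as.integer(junction_indel)
  ok <- switch(mechanism,
               AEJ = mh_length >= 2L && mh_length <= 20L && junction_indel == 0L,
               SSA = mh_length >= 25L && junction_indel == 0L,
               NHEJ = mh_length >= 0L && mh_length <= 4L)
  if (!ok) stop("invalid event_spec for mechanism ", mechanism,
                ": mh_length ", mh_length, ", junction_indel ", junction_indel)
  if (deletion_length < mh_length)
    stop("deletion_length must be >= mh_length")
  structure(list(mechanism = mechanism, mh_length = mh_length,
                 deletion_length = deletion_length,
                 junction_indel = junction_indel),
            class = "event_spec")
}

## resample the base at 0-based position `pos` so it differs from `other`
## (both codes); draws from the base distribution restricted to the other
## three bases, so no rejection loop is needed
.force_differ <- function(codes, pos, other, gc) {
  p <- .base_probs(gc)
  choices <- setdiff(0:3, other)
  codes[pos + 1L] <- sample(choices, 1L, prob = p[choices + 1L])
  codes
}

## write one event into a reference code vector at 0-based start s.
## Returns list(codes, truth row fields).
.plant_into_codes <- function(codes, spec, s, gc) {
  mh <- spec$mh_length
  d <- spec$deletion_length
  e <- s + d
  len <- length(codes)
  if (s < 1L || e + mh + 1L > len)
    stop("event does not fit: start ", s, ", needs ", d + mh + 1L, " bp")
  if (mh > 0L) {
    rep_codes <- .draw_codes(mh, gc)
    codes[(s + 1L):(s + mh)] <- rep_codes
    codes[(e + 1L):(e + mh)] <- rep_codes
  }
  # pin the planted placement as canonical and the repeat as maximal:
  # base before each copy must differ, base after each copy must differ
  if (s > 0L && !is.na(codes[s]) && identical(codes[s], codes[e]))
    codes <- .force_differ(codes, s - 1L, codes[e], gc)
  if (e + mh < len && identical(codes[s + mh + 1L], codes[e + mh + 1L]))
    codes <- .force_differ(codes, e + mh, codes[s + mh + 1L], gc)
  repeat_seq <- if (mh > 0L) codes_to_seq(codes[(s + 1L):(s + mh)]) else ""
  list(codes = codes, start = s, end = e, repeat_seq = repeat_seq)
}

## excise the planted events (plus NHEJ indels) from a reference code vector
.apply_events <- function(codes, truth, gc) {
  ord <- order(-truth$start)
  for (i in ord) {
    s <- truth$start[i]; e <- truth$end[i]
    indel <- truth$junction_indel[i]
    if (indel < 0L) e <- e - indel          # extra bases lost at the junction
    ins <- if (indel > 0L) .draw_codes(indel, gc) else integer(0L)
    keep_right <- if (e < length(codes)) codes[(e + 1L):length(codes)]
                  else integer(0L)
    codes <- c(codes[seq_len(s)], ins, keep_right)
  }
  codes
}

#' Plant one deletion event into a reference element
#'
#' For AEJ/SSA, writes an exact repeat of the requested microhomology at two
#' sites \code{deletion_length} apart and fixes the four flanking bases so
#' the repeat can be extended in neither direction (rejection-free
#' resampling); the derived element is the reference with
#' \code{[start, start + deletion_length)} excised. For NHEJ, the junction
#' agreement is exactly \code{mh_length} and \code{junction_indel} bases are
#' inserted (or additionally lost).
#'
#' Because flank fixing edits the reference, the (possibly modified)
#' reference is part of the return value; truth is stated with respect to it.
#'
#' @param ref A \code{genome_element}.
#' @param spec An \code{\link{event_spec}}.
#' @param pos Optional 0-based planted start; random when \code{NULL}.
#' @param seed Optional seed (\code{set.seed} is called when given);
#'   otherwise the current RNG stream is consumed.
#' @param gc GC fraction used for repeat/flank/insert draws (default 0.67).
#' @return List with \code{reference}, \code{derived} (both
#'   \code{genome_element}) and \code{truth} (one-row data.frame: mechanism,
#'   0-based \code{start}/\code{end}, \code{mh_length}, \code{repeat_seq},
#'   \code{junction_indel}).
#' @export
plant_deletion <- function(ref, spec, pos = NULL, seed = NULL, gc = 0.67) {
  stopifnot(inherits(ref, "genome_element"), inherits(spec, "event_spec"))
  if (!is.null(seed)) set.seed(seed)
  codes <- seq_to_codes(ref$seq)
  if (is.null(pos)) {
    lo <- 1L
    hi <- ref$length - spec$deletion_length - spec$mh_length - 1L
    if (hi < lo) stop("element too short for event")
    pos <- sample.int(hi - lo + 1L, 1L) + lo - 1L
  }
  planted <- .plant_into_codes(codes, spec, as.integer(pos), gc)
  truth <- data.frame(element = ref$id, mechanism = spec$mechanism,
                      start = planted$start, end = planted$end,
                      mh_length = spec$mh_length,
                      repeat_seq = planted$repeat_seq,
                      junction_indel = spec$junction_indel,
                      stringsAsFactors = FALSE)
  ref2 <- genome_element(ref$id, codes_to_seq(planted$codes), ref$topology)
  der_codes <- .apply_events(planted$codes, truth, gc)
  der <- genome_element(ref$id, codes_to_seq(der_codes), ref$topology)
  list(reference = ref2, derived = der, truth = truth)
}

#' Simulate a full dataset with planted truth
#'
#' Generates a genome from \code{config}, plants the given events at
#' non-colliding random positions (retrying up to \code{max_tries} per
#' event), and derives the rearranged genome. All randomness comes from one
#' stream seeded with \code{config$seed}, consumed in a fixed order
#' (elements, then events in list order), so the dataset is reproducible.
#'
#' @param config A \code{\link{sim_config}}.
#' @param events List of \code{\link{event_spec}}; each may carry an
#'   \code{element} attribute naming its target element (default: the first
#'   element long enough).
#' @param margin Minimum distance (bp) kept between planted features.
#' @param max_tries Placement attempts per event before erroring.
#' @param out_dir Optional directory; when given, writes
#'   \code{reference.fasta}, \code{derived.fasta} and \code{truth.json}
#'   (1-based coordinates).
#' @return List with \code{reference} and \code{derived} genomes and the
#'   \code{truth} data.frame (0-based internal coordinates on the reference).
#' @export
simulate_dataset <- function(config, events, margin = 200L, max_tries = 100L,
                             out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genome <- generate_genome(config)   # seeds the stream
  codes <- lapply(genome, function(el) seq_to_codes(el$seq))
  occupied <- lapply(genome, function(el) integer(0L))  # planted footprints
  rows <- list()
  for (ev in events) {
    stopifnot(inherits(ev, "event_spec"))
    target <- attr(ev, "element")
    if (is.null(target)) {
      fits <- vapply(genome, function(el)
        el$length > ev$deletion_length + ev$mh_length + 2L * margin, logical(1L))
      if (!any(fits)) stop("no element long enough for event")
      target <- names(genome)[which(fits)[1L]]
    }
    n <- genome[[target]]$length
    span <- ev$deletion_length + ev$mh_length
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(n - span - 2L * margin, 1L) + margin
      foot <- c(s - margin, s + span + margin)
      occ <- occupied[[target]]
      clash <- length(occ) &&
        any(foot[1L] <= occ[seq(2L, length(occ), 2L)] &
              occ[seq(1L, length(occ), 2L)] <= foot[2L])
      if (clash) next
      planted <- .plant_into_codes(codes[[target]], ev, s, config$gc)
      codes[[target]] <- planted$codes
      occupied[[target]] <- c(occ, foot)
      rows[[length(rows) + 1L]] <-
        data.frame(element = target, mechanism = ev$mechanism,
                   start = planted$start, end = planted$end,
                   mh_length = ev$mh_length, repeat_seq = planted$repeat_seq,
                   junction_indel = ev$junction_indel, stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place event after ", max_tries, " tries")
  }
  truth <- do.call(rbind, rows)
  reference <- as_genome(lapply(names(genome), function(id)
    genome_element(id, codes_to_seq(codes[[id]]), genome[[id]]$topology)))
  derived <- as_genome(lapply(names(genome), function(id) {
    t_el <- truth[truth$element == id, , drop = FALSE]
    der <- if (nrow(t_el)) .apply_events(codes[[id]], t_el, config$gc)
           else codes[[id]]
    genome_element(id, codes_to_seq(der), genome[[id]]$topology)
  }))
  out <- list(reference = reference, derived = derived, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genome_fasta(reference, file.path(out_dir, "reference.fasta"))
    write_genome_fasta(derived, file.path(out_dir, "derived.fasta"))
    tj <- truth
    tj$start_1based <- tj$start + 1L
    tj$end_1based <- tj$end
    tj$start <- NULL; tj$end <- NULL
    jsonlite::write_json(tj, file.path(out_dir, "truth.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  out
}
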