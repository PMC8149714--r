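## Assembly-to-assembly deletion calling by unique k-mer anchor chaining.
## k-mers unique in both sequences are matched by content, the longest
## collinear (strictly increasing in both coordinates) chain is kept, and
## each chain gap where the reference advances by at least min_len more than
## the derived sequence is refined to base pair resolution by exact outward
## extension from the bounding anchors. Forward strand only: the deletions
## this targets are collinear events, not inversions or translocations.

#' Find unique k-mer anchors between two elements
#'
#' An anchor is a k-mer that occurs exactly once in the reference and exactly
#' once in the derived sequence, matched by content. Windows containing N are
#' never anchors.
#'
#' @param ref,der \code{genome_element}s.
#' @param k Anchor length in bp (default 31; unique in a random megabase-scale
#'   genome with overwhelming probability, and long enough not to be confused
#'   by short repeat families).
#' @return Data.frame with 0-based \code{ref_pos}, \code{der_pos} and
#'   \code{k}, sorted by \code{ref_pos}. Errors with "unalignable" when no
#'   anchor exists.
#' @export
find_anchors <- function(ref, der, k = 31L) {
  stopifnot(inherits(ref, "genome_element"), inherits(der, "genome_element"))
  k <- as.integer(k)
  stopifnot(k >= 2L)
  if (ref$length < k || der$length < k)
    stop("unalignable: sequence shorter than k")
  rc <- encode_windows(seq_to_codes(ref$seq), k)
  dc <- encode_windows(seq_to_codes(der$seq), k)
  runiq <- !(duplicated(rc) | duplicated(rc, fromLast = TRUE)) & !is.na(rc)
  duniq <- !(duplicated(dc) | duplicated(dc, fromLast = TRUE)) & !is.na(dc)
  rpos <- which(runiq)
  m <- match(rc[rpos], dc[which(duniq)])
  hit <- !is.na(m)
  if (!any(hit)) stop("unalignable: no shared unique ", k, "-mers")
  out <- data.frame(ref_pos = rpos[hit] - 1L,
                    der_pos = which(duniq)[m[hit]] - 1L,
                    k = k)
  out[order(out$ref_pos), , drop = FALSE]
}

## maximal exact forward agreement of ref from r0 and der from d0 (0-based),
## vectorized comparison on code vectors; N never matches
.extend_right <- function(xr, xd, r0, d0) {
  n <- min(length(xr) - r0, length(xd) - d0)
  if (n <= 0L) return(0L)
  a <- xr[(r0 + 1L):(r0 + n)]
  b <- xd[(d0 + 1L):(d0 + n)]
  neq <- which(is.na(a) | is.na(b) | a != b)
  if (length(neq)) neq[1L] - 1L else n
}

## maximal exact backward agreement of ref ending at r1 and der ending at d1
## (0-based, exclusive ends)
.extend_left <- function(xr, xd, r1, d1) {
  n <- min(r1, d1)
  if (n <= 0L) return(0L)
  a <- xr[(r1 - n + 1L):r1]
  b <- xd[(d1 - n + 1L):d1]
  neq <- which(is.na(a) | is.na(b) | a != b)
  if (length(neq)) n - neq[length(neq)] else n
}

#' Call large deletions between a reference and a derived element
#'
#' Chains unique k-mer anchors (longest strictly collinear chain), then
#' refines every chain gap where the reference coordinate advances at least
#' \code{min_len} bp more than the derived coordinate: matching bases are
#' extended rightward from the left bounding anchor and leftward from the
#' right bounding anchor; the leftmost junction consistent with both
#' extensions places the deletion. Gaps where the derived sequence advances
#' more (insertions) are skipped with a message. Every emitted call is
#' checked: excising it from the reference must reproduce the derived
#' sequence over the spanned region, otherwise the gap is reported as
#' unresolved (e.g. a substitution adjacent to the junction) and dropped
#' with a warning.
#'
#' @param ref,der \code{genome_element}s.
#' @param k Anchor k-mer length (default 31).
#' @param min_len Minimum deletion length to report (default 1000 bp;
#'   smaller events are the business of an SNP/indel caller, not this one).
#' @return Data.frame with 0-based half-open \code{ref_start}, \code{ref_end}
#'   and \code{der_breakpoint}; zero rows when the sequences are collinear
#'   without large deletions.
#' @export
call_deletions <- function(ref, der, k = 31L, min_len = 1000L) {
  anchors <- find_anchors(ref, der, k)
  chain_idx <- lis_indices(anchors$der_pos)
  if (isTRUE(attr(chain_idx, "ambiguous")))
    warning("multiple maximal collinear chains; kept the leftmost-ending one")
  chain <- anchors[chain_idx, , drop = FALSE]
  xr <- seq_to_codes(ref$seq)
  xd <- seq_to_codes(der$seq)
  calls <- list()
  if (nrow(chain) >= 2L) {
    for (i in seq_len(nrow(chain) - 1L)) {
      r1 <- chain$ref_pos[i];      d1 <- chain$der_pos[i]
      r2 <- chain$ref_pos[i + 1L]; d2 <- chain$der_pos[i + 1L]
      gap <- (r2 - r1) - (d2 - d1)
      if (gap < min_len) {
        if (-gap >= min_len)
          message("insertion of ", -gap, " bp near ref ", r1 + k,
                  " skipped (not a deletion)")
        next
      }
      fwd <- .extend_right(xr, xd, r1, d1)       # >= k by anchor identity
      bwd <- .extend_left(xr, xd, r2 + k, d2 + k)
      j_min <- (d2 + k) - bwd                    # leftmost consistent junction
      j_max <- d1 + fwd
      if (j_min > j_max) {
        warning("gap near ref ", r1 + k, " not resolvable by exact extension",
                "; dropped")
        next
      }
      shift_l <- r1 - d1
      shift_r <- r2 - d2
      calls[[length(calls) + 1L]] <-
        data.frame(ref_start = shift_l + j_min, ref_end = shift_r + j_min,
                   der_breakpoint = j_min)
    }
  }
  if (!length(calls))
    return(data.frame(ref_start = integer(0L), ref_end = integer(0L),
                      der_breakpoint = integer(0L)))
  out <- do.call(rbind, calls)
  out <- out[order(out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  # soundness assertion on every call: the excision reproduces the derived
  # sequence across the junction neighbourhood
  for (i in seq_len(nrow(out))) {
    s <- out$ref_start[i]; e <- out$ref_end[i]; j <- out$der_breakpoint[i]
    w <- 200L
    lo <- max(0L, j - w, j - s)
    hi <- min(der$length, j + w, j + ref$length - e)
    der_win <- substr(der$seq, lo + 1L, hi)
    rec_win <- paste0(substr(ref$seq, lo + (s - j) + 1L, s),
                      substr(ref$seq, e + 1L, e + (hi - j)))
    if (!identical(der_win, rec_win))
      stop("internal error: call ", i, " fails excision soundness check")
  }
  out
}
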