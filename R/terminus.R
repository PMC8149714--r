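## Replichore-balance terminus prediction and deletion-overlap analysis.
## With bidirectional replication from a known origin, the terminus is
## assumed antipodal on the circular replicon.

#' Predict the replication terminus under replichore balance
#'
#' The terminus is placed half the replicon length downstream of the origin,
#' modulo the (circular) length.
#'
#' @param ori_pos Origin position, 1-based.
#' @param length Replicon length in bp.
#' @return 1-based terminus coordinate:
#'   \code{((ori_pos - 1 + floor(length/2)) mod length) + 1}.
#' @export
predict_terminus <- function(ori_pos, length) {
  stopifnot(ori_pos >= 1L, ori_pos <= length)
  ((ori_pos - 1L + length %/% 2L) %% length) + 1L
}

#' Round a coordinate for human-readable reporting
#'
#' @param pos Coordinate in bp.
#' @param to Rounding grain (default 1000 bp).
#' @return \code{pos} rounded to the nearest multiple of \code{to}.
#' @export
round_coord <- function(pos, to = 1000L) as.integer(round(pos / to) * to)

#' Intersection of deletion intervals
#'
#' @param intervals Data.frame with internal 0-based half-open
#'   \code{start}/\code{end} columns (one element).
#' @return One-row data.frame \code{start}/\code{end} (internal), or a
#'   zero-row frame when the intersection is empty.
#' @export
common_region <- function(intervals) {
  stopifnot(nrow(intervals) >= 1L)
  if ("element" %in% names(intervals) &&
      length(unique(intervals$element)) > 1L)
    stop("common_region expects intervals on a single element")
  s <- max(intervals$start)
  e <- min(intervals$end)
  if (e <= s) return(data.frame(start = integer(0L), end = integer(0L)))
  data.frame(start = s, end = e)
}

#' Does an interval contain the replication terminus?
#'
#' @param start,end Internal 0-based half-open interval.
#' @param ter_pos 1-based terminus coordinate.
#' @param length Replicon length (only needed for \code{circular}).
#' @param circular Treat the interval as possibly wrapping the origin
#'   (\code{start > end} means it spans position 1).
#' @return Logical.
#' @export
spans_terminus <- function(start, end, ter_pos, length = NULL,
                           circular = FALSE) {
  t0 <- ter_pos - 1L   # 0-based position of the terminus base
  if (!circular || start <= end) return(t0 >= start && t0 < end)
  stopifnot(!is.null(length))
  t0 >= start || t0 < end
}
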