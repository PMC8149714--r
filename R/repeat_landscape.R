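## Genome coverage by exact repeat pairs of a given length: the fraction of
## genomic positions lying inside at least one L-bp window whose sequence
## occurs at two or more distinct start positions anywhere in the genome
## (all elements pooled). This is the abundance statistic that quantifies
## how much of a genome is, at a given repeat length, a potential substrate
## for repeat-mediated deletion.

#' Genome coverage of exact repeat pairs of length L
#'
#' An L-bp window is "repeated" when its sequence occurs at two or more
#' distinct start positions across the pooled genome; a position is covered
#' when it lies inside at least one repeated window. Windows containing N
#' are excluded from both sides of the ratio (an ambiguous window cannot
#' attest a repeat pair), so the denominator is the number of positions
#' lying in at least one N-free window. Circular elements contribute
#' wrap-around windows. With \code{include_revcomp}, occurrences of a
#' window's reverse complement also count toward its multiplicity (a
#' self-reverse-complementary window at a single position still counts
#' once) — the convention of repeat finders that detect both direct and
#' inverted repeat pairs.
#'
#' @param genome A \code{genome} or single \code{genome_element}.
#' @param L Repeat length in bp (>= 1).
#' @param include_revcomp Count inverted-repeat occurrences (default FALSE:
#'   direct repeats only).
#' @param per_element Also return a per-element breakdown.
#' @return A \code{repeat_coverage}: list with \code{L},
#'   \code{covered_positions}, \code{total_positions}, \code{percent}, and
#'   optionally \code{per_element} (data.frame).
#' @export
repeat_coverage <- function(genome, L, include_revcomp = FALSE,
                            per_element = FALSE) {
  if (inherits(genome, "genome_element")) genome <- as_genome(list(genome))
  L <- as.integer(L)
  stopifnot(L >= 1L)
  if (include_revcomp && L > 26L)
    stop("include_revcomp supported for L <= 26")
  lens <- vapply(genome, `[[`, numeric(1L), "length")
  if (all(lens < L)) stop("L = ", L, " exceeds every element length")
  codes <- lapply(genome, function(el) {
    x <- seq_to_codes(el$seq)
    if (el$topology == "circular" && el$length >= L)
      x <- c(x, x[seq_len(L - 1L)])   # wrap-around windows
    x
  })
  wins <- lapply(codes, encode_windows, k = L)
  all_w <- unlist(wins, use.names = FALSE)
  u <- unique(all_w[!is.na(all_w)])
  idx <- match(all_w, u)
  cnt <- tabulate(idx, nbins = length(u))
  mult <- cnt[idx]
  if (include_revcomp) {
    rc <- unlist(lapply(codes, encode_windows_rc, k = L), use.names = FALSE)
    rc_idx <- match(rc, u)
    extra <- ifelse(!is.na(rc_idx) & rc != all_w, cnt[rc_idx], 0L)
    extra[is.na(extra)] <- 0L
    mult <- mult + extra
  }
  repeated <- !is.na(all_w) & mult >= 2L
  valid <- !is.na(all_w)

  cover_count <- function(mask, el_len, nwin) {
    # positions covered by >= 1 flagged window, window i covering
    # 0-based [i-1, i-1+L), modulo el_len for wrap-around windows
    starts <- which(mask)
    if (!length(starts)) return(0L)
    d <- tabulate(starts, nbins = el_len) -
      tabulate(pmin(starts + L, el_len + 1L), nbins = el_len)
    cov <- cumsum(d) > 0L
    wrap <- starts[starts + L - 1L > el_len]    # circular overhang
    for (s in wrap) {
      over <- (s + L - 1L) - el_len
      cov[seq_len(over)] <- TRUE
    }
    sum(cov)
  }

  off <- 0L
  per <- lapply(seq_along(genome), function(i) {
    nw <- length(wins[[i]])
    el_len <- genome[[i]]$length
    if (nw == 0L)
      return(data.frame(element = names(genome)[i], covered = 0L, total = 0L))
    sel <- (off + 1L):(off + nw)
    covered <- cover_count(repeated[sel], el_len, nw)
    total <- cover_count(valid[sel], el_len, nw)
    off <<- off + nw
    data.frame(element = names(genome)[i], covered = covered, total = total)
  })
  per <- do.call(rbind, per)
  covered <- sum(per$covered)
  total <- sum(per$total)
  out <- structure(list(L = L, covered_positions = covered,
                        total_positions = total,
                        percent = 100 * covered / total),
                   class = "repeat_coverage")
  if (per_element) {
    per$percent <- ifelse(per$total > 0L, 100 * per$covered / per$total, NA_real_)
    out$per_element <- per
  }
  out
}

#' @export
print.repeat_coverage <- function(x, ...) {
  cat(sprintf("<repeat_coverage> L = %d: %s / %s positions = %.2f%%\n",
              x$L, format(x$covered_positions, big.mark = ","),
              format(x$total_positions, big.mark = ","), x$percent))
  invisible(x)
}
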