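## k-mer window encoding shared by the deletion caller and the repeat
## landscape. Windows are packed into numerics: one double for k <= 26
## (4^26 < 2^53, exact), a complex pair of half-codes for larger k. Windows
## containing N encode as NA, so ambiguity never attests a repeat or anchors
## an alignment.

encode_windows_half <- function(codes, k) {
  n <- length(codes) - k + 1L
  if (n < 1L) return(numeric(0L))
  v <- numeric(n)
  for (j in 0:(k - 1L)) v <- v * 4 + codes[(1L + j):(n + j)]
  v
}

#' @keywords internal
encode_windows <- function(codes, k) {
  stopifnot(k >= 1L)
  if (length(codes) < k) {
    return(if (k <= 26L) numeric(0L) else complex(0L))
  }
  if (k <= 26L) return(encode_windows_half(codes, k))
  k1 <- ceiling(k / 2)
  if (k1 > 26L) stop("k too large: ", k)
  n <- length(codes) - k + 1L
  a <- encode_windows_half(codes, k1)[seq_len(n)]
  b <- encode_windows_half(codes[-seq_len(k1)], k - k1)[seq_len(n)]
  complex(real = a, imaginary = b)
}

## reverse-complement window codes (same coordinates: code of revcomp of the
## window starting at each position), k <= 26 only
encode_windows_rc <- function(codes, k) {
  xc <- 3L - codes
  n <- length(codes) - k + 1L
  if (n < 1L) return(numeric(0L))
  v <- numeric(n)
  for (j in (k - 1L):0) v <- v * 4 + xc[(1L + j):(n + j)]
  v
}

## longest strictly-increasing subsequence of a numeric vector, O(n log n);
## returns indices. Ties resolved so the earliest attainable elements win,
## which keeps chain selection deterministic.
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer(0L))
  if (n == 1L || all(diff(x) > 0)) {
    # already strictly increasing: the whole sequence is the unique LIS
    out <- seq_len(n)
    attr(out, "ambiguous") <- FALSE
    return(out)
  }
  tails <- numeric(n)      # smallest tail value of an increasing run of each length
  tails_idx <- integer(n)  # index in x achieving that tail
  prev <- integer(n)       # predecessor links for reconstruction
  writes <- integer(n)
  len <- 0L
  for (i in seq_len(n)) {
    # strict increase: place x[i] at the first run length whose tail >= x[i]
    # (manual binary search; tails[1:len] is strictly increasing)
    xi <- x[i]
    lo <- 1L; hi <- len + 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (tails[mid] < xi) lo <- mid + 1L else hi <- mid
    }
    pos <- lo
    tails[pos] <- xi
    tails_idx[pos] <- i
    writes[pos] <- writes[pos] + 1L
    prev[i] <- if (pos > 1L) tails_idx[pos - 1L] else 0L
    if (pos > len) len <- pos
  }
  out <- integer(len)
  j <- tails_idx[len]
  for (p in len:1) { out[p] <- j; j <- prev[j] }
  # more than one write at the maximal length means at least two maximal
  # chains existed; the earliest-ending one was kept
  attr(out, "ambiguous") <- writes[len] > 1L
  out
}
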