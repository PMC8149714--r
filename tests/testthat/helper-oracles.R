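# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check: plain substring scans and exhaustive
# enumeration, feasible only at toy scale.

# all start positions (0-based) of `pat` in `s`, overlap-aware
oracle_occurrences <- function(s, pat) {
  L <- nchar(pat)
  n <- nchar(s)
  if (L == 0L || L > n) return(integer(0L))
  starts <- which(vapply(1:(n - L + 1L), function(i)
    substr(s, i, i + L - 1L) == pat, logical(1L)))
  starts - 1L
}

# exhaustive breakpoint characterization: every equivalent placement of a
# deletion of the same length producing the same derived sequence
oracle_breakpoint <- function(seq, s, e) {
  n <- nchar(seq)
  d <- e - s
  excise <- function(a, b) paste0(substr(seq, 1L, a), substr(seq, b + 1L, n))
  target <- excise(s, e)
  placements <- Filter(function(a) excise(a, a + d) == target, 0:(n - d))
  canon <- min(placements)
  # maximal exact common prefix of the suffixes at the canonical bounds
  mh <- 0L
  while (canon + d + mh < n &&
         substr(seq, canon + mh + 1L, canon + mh + 1L) ==
         substr(seq, canon + d + mh + 1L, canon + d + mh + 1L) &&
         substr(seq, canon + mh + 1L, canon + mh + 1L) != "N")
    mh <- mh + 1L
  list(canonical_start = canon, placements = sort(placements),
       mh_length = mh,
       repeat_seq = substr(seq, canon + 1L, canon + mh))
}

# quadratic repeat-pair coverage: a position is covered iff some window
# containing it has a second occurrence somewhere in the pooled sequences
oracle_repeat_coverage <- function(seqs, L, include_revcomp = FALSE) {
  wins <- list()
  for (si in seq_along(seqs)) {
    s <- seqs[[si]]
    n <- nchar(s)
    if (n < L) next
    for (i in 1:(n - L + 1L))
      wins[[length(wins) + 1L]] <- list(el = si, start = i - 1L,
                                        seq = substr(s, i, i + L - 1L))
  }
  strs <- vapply(wins, `[[`, character(1L), "seq")
  valid <- !grepl("N", strs, fixed = TRUE)
  rc <- vapply(strs, function(w)
    paste(rev(strsplit(chartr("ACGT", "TGCA", w), "")[[1L]]), collapse = ""),
    character(1L), USE.NAMES = FALSE)
  counts <- table(strs[valid])
  mult <- ifelse(valid, as.integer(counts[strs]), 0L)
  if (include_revcomp) {
    rc_cnt <- ifelse(is.na(counts[rc]), 0L, as.integer(counts[rc]))
    mult <- mult + ifelse(valid & strs != rc, rc_cnt, 0L)
  }
  covered <- 0L; total <- 0L
  for (si in seq_along(seqs)) {
    n <- nchar(seqs[[si]])
    cov_mask <- logical(n); val_mask <- logical(n)
    for (wi in seq_along(wins)) {
      w <- wins[[wi]]
      if (w$el != si) next
      span <- (w$start + 1L):(w$start + L)
      if (valid[wi]) val_mask[span] <- TRUE
      if (valid[wi] && mult[wi] >= 2L) cov_mask[span] <- TRUE
    }
    covered <- covered + sum(cov_mask)
    total <- total + sum(val_mask)
  }
  list(covered = covered, total = total,
       percent = if (total) 100 * covered / total else NaN)
}

# every (s, e) whose excision turns ref into der, for tiny sequences
oracle_deletions <- function(ref, der) {
  n <- nchar(ref)
  m <- nchar(der)
  d <- n - m
  if (d <= 0L) return(data.frame(start = integer(0L), end = integer(0L)))
  hits <- Filter(function(s)
    paste0(substr(ref, 1L, s), substr(ref, s + d + 1L, n)) == der, 0:m)
  data.frame(start = unlist(hits), end = unlist(hits) + d)
}

# random nucleotide string, iid at a given GC
random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random in-frame CDS of n_codons codons (no stops), returned with its counts
random_cds <- function(n_codons) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  cods <- sample(sense, n_codons, replace = TRUE)
  list(seq = paste(cods, collapse = ""),
       counts = table(factor(cods, levels = names(Biostrings::GENETIC_CODE))))
}
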