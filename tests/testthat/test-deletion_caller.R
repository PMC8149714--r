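test_that("anchors are unique k-mers matched by content", {
  # identity: all 5-mers unique -> the full diagonal
  set.seed(41)
  s <- random_seq(60)
  el <- genome_element("r", s)
  a <- find_anchors(el, el, k = 31L)
  expect_equal(a$ref_pos, 0:(60 - 31))
  expect_equal(a$der_pos, a$ref_pos)

  # hand-enumerated toy: ACGT occurs twice in ref, so it can never anchor
  ref <- genome_element("r", "TTACGTCCCCACGTGG")
  der <- genome_element("d", "TTACGTGG")
  a <- find_anchors(ref, der, k = 4L)
  expect_equal(a$ref_pos, c(0L, 1L, 11L, 12L))
  expect_equal(a$der_pos, c(0L, 1L, 3L, 4L))

  # reverse-complemented derived shares no forward anchors
  rc <- genome_element("rc", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))))
  expect_error(find_anchors(el, rc, k = 31L), "unalignable")
})

test_that("a planted deletion is called at exactly the planted interval", {
  cfg <- sim_config(element_lengths = c(chr = 200000L), gc = 0.67, seed = 42L)
  g <- generate_genome(cfg)
  set.seed(43)
  p <- plant_deletion(g[["chr"]], event_spec("AEJ", 6, 50000), gc = 0.67)
  calls <- call_deletions(p$reference, p$derived, k = 31L, min_len = 1000L)
  expect_equal(nrow(calls), 1L)
  cl <- characterize_breakpoint(p$reference, calls$ref_start, calls$ref_end)
  expect_equal(cl$start, p$truth$start)
  expect_equal(cl$end, p$truth$end)
  expect_equal(cl$mh_length, 6L)
  # soundness: excision reproduces the derived sequence byte for byte
  r <- p$reference$seq
  expect_identical(paste0(substr(r, 1L, calls$ref_start),
                          substr(r, calls$ref_end + 1L, nchar(r))),
                   p$derived$seq)
})

test_that("identical sequences yield no calls; insertions are skipped", {
  set.seed(44)
  el <- genome_element("c", random_seq(50000, gc = 0.67))
  expect_equal(nrow(call_deletions(el, el)), 0L)
  # derived longer than reference in one gap -> insertion, not a deletion
  ins <- genome_element("c", paste0(substr(el$seq, 1, 25000),
                                    random_seq(5000, gc = 0.67),
                                    substr(el$seq, 25001, 50000)))
  expect_message(calls <- call_deletions(el, ins, min_len = 1000L),
                 "insertion")
  expect_equal(nrow(calls), 0L)
})

test_that("two distant planted deletions are both recovered", {
  cfg <- sim_config(element_lengths = c(chr = 400000L), gc = 0.67, seed = 45L)
  evs <- list(event_spec("AEJ", 9, 30000), event_spec("SSA", 27, 60000))
  d <- simulate_dataset(cfg, evs, margin = 5000L)
  calls <- call_deletions(d$reference[["chr"]], d$derived[["chr"]])
  expect_equal(nrow(calls), 2L)
  truth <- d$truth[order(d$truth$start), ]
  for (i in 1:2) {
    cl <- characterize_breakpoint(d$reference[["chr"]],
                                  calls$ref_start[i], calls$ref_end[i])
    expect_equal(cl$start, truth$start[i])
    expect_equal(cl$end, truth$end[i])
    expect_equal(cl$mh_length, truth$mh_length[i])
  }
})

test_that("caller agrees with the exhaustive oracle on tiny instances", {
  set.seed(46)
  n_ok <- 0L
  for (i in 1:30) {
    ref_seq <- random_seq(180, gc = 0.5)
    s <- sample(30:90, 1L)
    d <- sample(40:60, 1L)
    der_seq <- paste0(substr(ref_seq, 1, s), substr(ref_seq, s + d + 1, 180))
    ref <- genome_element("r", ref_seq)
    der <- genome_element("d", der_seq)
    calls <- call_deletions(ref, der, k = 11L, min_len = 10L)
    oracle <- oracle_deletions(ref_seq, der_seq)
    expect_equal(nrow(calls), 1L)
    # the call must be one of the oracle's equivalent placements, and its
    # canonical form must be the oracle's leftmost placement
    expect_true(any(oracle$start == calls$ref_start &
                      oracle$end == calls$ref_end))
    cl <- characterize_breakpoint(ref, calls$ref_start, calls$ref_end)
    expect_equal(cl$start, min(oracle$start))
    n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, 30L)
})

test_that("round trip: planted events are recovered across scales", {
  # 200 AEJ/SSA events (mh 2-30 within the mechanism bands, deletions up to
  # 90 kb) planted on 100-500 kb genomes, 4 per genome
  set.seed(47)
  n_events <- 0L
  n_exact <- 0L
  for (rep in 1:50) {
    len <- sample(100000:500000, 1L)
    cfg <- sim_config(element_lengths = c(chr = len), gc = 0.67,
                      seed = 1000L + rep)
    max_del <- min(90000L, (len - 10000L) %/% 5L)
    evs <- lapply(1:4, function(i) {
      mh <- sample(c(2:20, 25:30), 1L)
      event_spec(if (mh >= 25L) "SSA" else "AEJ", mh,
                 sample(1000:max_del, 1L))
    })
    d <- simulate_dataset(cfg, evs, margin = 1000L)
    calls <- call_deletions(d$reference[["chr"]], d$derived[["chr"]],
                            k = 21L, min_len = 500L)
    truth <- d$truth[order(d$truth$start), ]
    n_events <- n_events + nrow(truth)
    if (nrow(calls) != nrow(truth)) next
    ok <- vapply(seq_len(nrow(truth)), function(i) {
      cl <- characterize_breakpoint(d$reference[["chr"]],
                                    calls$ref_start[i], calls$ref_end[i])
      cl$start == truth$start[i] && cl$end == truth$end[i] &&
        cl$mh_length == truth$mh_length[i]
    }, logical(1L))
    n_exact <- n_exact + sum(ok)
  }
  expect_equal(n_events, 200L)
  expect_gte(n_exact / n_events, 0.95)
})

test_that("chain selection equals a quadratic longest-chain oracle", {
  # O(n^2) DP for the length of the longest strictly increasing subsequence
  lis_len_oracle <- function(x) {
    n <- length(x)
    if (!n) return(0L)
    best <- rep(1L, n)
    for (i in seq_len(n))
      for (j in seq_len(i - 1L))
        if (x[j] < x[i]) best[i] <- max(best[i], best[j] + 1L)
    max(best)
  }
  set.seed(48)
  for (i in 1:30) {
    x <- sample.int(40L, sample(1:25, 1L), replace = TRUE)
    got <- deljunct:::lis_indices(x)
    expect_equal(length(got), lis_len_oracle(x))
    expect_true(all(diff(x[got]) > 0) || length(got) <= 1L)
  }
  # monotone fast path agrees with the general algorithm
  expect_equal(as.integer(deljunct:::lis_indices(c(1, 5, 9))), 1:3)
})
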