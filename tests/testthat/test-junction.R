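test_that("breakpoint characterization matches exhaustive enumeration on toys", {
  el <- genome_element("x", "TTACGTCCCCACGTGG")
  call <- characterize_breakpoint(el, 2L, 10L)
  expect_equal(call$repeat_seq, "ACGT")
  expect_equal(call$mh_length, 4L)
  expect_equal(call$start, 2L)
  expect_equal(call$deleted_segment_length, 8L)
  expect_equal(substr(el$seq, call$start + 1L, call$end), "ACGTCCCC")

  # homopolymer slide: canonical placement is leftmost
  hp <- genome_element("y", "CAAAG")
  c2 <- characterize_breakpoint(hp, 2L, 3L)
  expect_equal(c2$start, 1L)
  expect_equal(c2$repeat_seq, "AA")
  expect_equal(c2$slide_window, c(1L, 3L))

  # agreement with the brute-force oracle on random raw intervals
  set.seed(31)
  for (i in 1:40) {
    s <- random_seq(60, gc = sample(c(0.3, 0.5, 0.7), 1L))
    el <- genome_element("r", s)
    a <- sample(0:40, 1L)
    b <- a + sample(1:15, 1L)
    got <- characterize_breakpoint(el, a, b)
    want <- oracle_breakpoint(s, a, b)
    expect_equal(got$start, want$canonical_start)
    expect_equal(got$mh_length, want$mh_length)
    expect_equal(got$repeat_seq, want$repeat_seq)
    expect_equal(got$slide_window[1L], min(want$placements))
    expect_equal(got$slide_window[2L], max(want$placements))
  }
})

test_that("every placement in the slide window excises to the same sequence", {
  set.seed(32)
  for (i in 1:20) {
    el <- genome_element("r", random_seq(80, gc = 0.6))
    a <- sample(0:50, 1L); b <- a + sample(2:20, 1L)
    call <- characterize_breakpoint(el, a, b)
    d <- call$deleted_segment_length
    derived <- vapply(call$slide_window[1L]:call$slide_window[2L], function(s)
      paste0(substr(el$seq, 1L, s), substr(el$seq, s + d + 1L, el$length)),
      character(1L))
    expect_length(unique(derived), 1L)
    expect_identical(derived[[1L]], reenact_deletion(el, call)$seq)
  }
})

test_that("N never matches, so microhomology cannot cross ambiguity", {
  el <- genome_element("n", "TTNCGTCCCCNCGTGG")
  call <- characterize_breakpoint(el, 2L, 10L)
  expect_equal(call$mh_length, 0L)   # would be 4 without the N rule
  el2 <- genome_element("n2", "GANNTCCCNNTC")
  expect_equal(characterize_breakpoint(el2, 2L, 8L)$mh_length, 0L)
})

test_that("degenerate zero-length interval yields a flagged empty call", {
  el <- genome_element("x", "ACGTACGT")
  call <- characterize_breakpoint(el, 3L, 3L)
  expect_true(call$degenerate)
  expect_equal(call$repeat_seq, "")
  expect_identical(reenact_deletion(el, call)$seq, el$seq)
})

test_that("re-enactment excises exactly the deleted segment", {
  el <- genome_element("x", "TTACGTCCCCACGTGG")
  call <- characterize_breakpoint(el, 2L, 10L)
  expect_identical(reenact_deletion(el, call)$seq, "TTACGTGG")
  expect_equal(reenact_deletion(el, call)$length,
               el$length - call$deleted_segment_length)
})

test_that("junction reconstruction honours flank width and element ends", {
  el <- genome_element("x", "TTACGTCCCCACGTGG")
  call <- characterize_breakpoint(el, 2L, 10L)
  expect_identical(reconstruct_junction(el, call, flank = 2L), "TTACGTGG")
  expect_identical(reconstruct_junction(el, call, flank = 0L), "ACGT")
  # wide flanks truncate at the element boundaries
  expect_identical(reconstruct_junction(el, call, flank = 60L), "TTACGTGG")
  # interior junctions are flank + mh + flank long
  set.seed(33)
  ref <- genome_element("c", random_seq(2000, gc = 0.67))
  p <- plant_deletion(ref, event_spec("AEJ", 7, 500), pos = 300L, gc = 0.67)
  cl <- characterize_breakpoint(p$reference, p$truth$start, p$truth$end)
  expect_equal(nchar(reconstruct_junction(p$reference, cl, 60L)), 60L + 7L + 60L)
})

test_that("junction verification distinguishes unique, absent, multiple", {
  el <- genome_element("x", "TTACGTCCCCACGTGG")
  call <- characterize_breakpoint(el, 2L, 10L)
  der <- reenact_deletion(el, call)
  j <- reconstruct_junction(el, call, 2L)
  expect_equal(verify_junction(der, j), "verified")
  mut <- paste0("A", substr(j, 2L, nchar(j)))
  expect_equal(verify_junction(der, mut), "not_found")
  twice <- genome_element("t", paste0("AA", j, "CC", j, "AA"))
  expect_equal(verify_junction(twice, j), "multiple")
  # overlap-aware: "AAA" in "AAAA" occurs twice
  expect_equal(verify_junction(genome_element("o", "AAAA"), "AAA"), "multiple")
})

test_that("mechanism rule table covers all bands and rejects bad input", {
  expect_equal(classify_mechanism(11, TRUE, 0)$label, "AEJ-compatible")
  expect_equal(classify_mechanism(2, TRUE, 0)$label, "AEJ-compatible")
  expect_equal(classify_mechanism(20, TRUE, 0)$label, "AEJ-compatible")
  expect_equal(classify_mechanism(438, TRUE, 0)$label, "SSA-compatible")
  expect_equal(classify_mechanism(25, TRUE, 0)$label, "SSA-compatible")
  expect_equal(classify_mechanism(22, TRUE, 0)$label, "ambiguous")
  expect_equal(classify_mechanism(3, FALSE, 2)$label, "NHEJ-like")
  expect_equal(classify_mechanism(3, TRUE, 2)$label, "NHEJ-like")
  expect_equal(classify_mechanism(0, TRUE, 0)$label, "unclassified")
  expect_equal(classify_mechanism(1, TRUE, 0)$label, "unclassified")
  expect_error(classify_mechanism(-1, TRUE, 0), "non-negative")
  expect_error(classify_mechanism(3, TRUE, -2), "non-negative")
})

test_that("re-enactment/verification closure holds on planted fixtures", {
  set.seed(34)
  for (i in 1:25) {
    ref <- genome_element("c", random_seq(4000, gc = 0.67))
    mh <- sample(2:20, 1L)
    p <- plant_deletion(ref, event_spec("AEJ", mh, sample(500:2000, 1L)),
                        gc = 0.67)
    cl <- characterize_breakpoint(p$reference, p$truth$start, p$truth$end)
    der <- reenact_deletion(p$reference, cl)
    expect_identical(der$seq, p$derived$seq)
    j <- reconstruct_junction(p$reference, cl, 60L)
    expect_equal(verify_junction(der, j), "verified")
  }
})
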