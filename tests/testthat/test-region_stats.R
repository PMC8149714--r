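test_that("GC percent counts only unambiguous bases", {
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("ACGT"), 50)
  expect_equal(round(gc_percent("ACGGTC"), 1), 66.7)   # 4 of 6
  expect_equal(round(gc_percent("ACGGGC"), 1), 83.3)   # 5 of 6
  expect_equal(gc_percent("GCNNNN"), 100)   # N out of the denominator
  expect_error(gc_percent("NNNN"), "no unambiguous")
})

test_that("SCUO attains its closed-form limits and the hand-computed value", {
  code <- Biostrings::GENETIC_CODE
  zero <- setNames(integer(64), names(code))
  # uniform usage of every synonymous codon of every amino acid -> 0
  uniform <- zero
  for (a in setdiff(unique(code), "*")) uniform[code == a] <- 6L
  expect_equal(scuo(uniform), 0)
  # a single codon per amino acid -> 1
  single <- zero
  for (a in setdiff(unique(code), "*")) single[which(code == a)[1L]] <- 5L
  expect_equal(scuo(single), 1)
  # {GCA:3, GCC:1}, Ala only: H = 0.8113, O = (2 - 0.8113)/2
  ala <- zero; ala["GCA"] <- 3L; ala["GCC"] <- 1L
  h <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(scuo(ala), (2 - h) / 2, tolerance = 1e-12)
  # Met/Trp-only genes are undefined
  mw <- zero; mw["ATG"] <- 3L; mw["TGG"] <- 2L
  expect_error(scuo(mw), "undefined")
})

test_that("SCUO stays in [0,1] on random codon tables", {
  set.seed(61)
  for (i in 1:50) {
    cds <- random_cds(sample(30:200, 1L))
    v <- scuo(cds$counts)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("GC3s uses exactly the eight fourfold boxes", {
  expect_equal(gc3s(c(GTG = 5L)), 100)
  expect_equal(gc3s(c(ACA = 1L, ACG = 1L)), 50)
  # ATG is not in a fourfold box: 2 of 3 third sites are G/C
  expect_equal(round(gc3s(c(GCC = 2L, GCT = 1L, ATG = 7L)), 1), 66.7)
  # AAA/TTT (Lys/Phe, twofold) contribute nothing
  expect_error(gc3s(c(AAA = 5L, TTT = 5L, ATG = 1L)), "undefined")
})

test_that("codon profiles are strand invariant", {
  set.seed(62)
  cds <- random_cds(80)
  flank <- random_seq(30)
  el_plus <- genome_element("p", paste0(flank, cds$seq, flank))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(el_plus$seq)))
  el_minus <- genome_element("m", rc)
  s <- 30L; e <- 30L + 80L * 3L
  prof_p <- codon_profile(el_plus, s, e, "+")
  prof_m <- codon_profile(el_minus, el_minus$length - e,
                          el_minus$length - s, "-")
  expect_identical(prof_p$counts, prof_m$counts)
  expect_equal(prof_p$scuo, prof_m$scuo)
  expect_equal(sum(prof_p$counts) * 3L, e - s)
})

test_that("region reports aggregate contained genes with the lower median", {
  set.seed(63)
  n_genes <- 10L
  gap <- function() random_seq(21)
  cds <- replicate(n_genes, random_cds(sample(40:90, 1L)), simplify = FALSE)
  seq <- gap()
  rows <- list()
  for (i in seq_len(n_genes)) {
    start <- nchar(seq)                      # 0-based
    seq <- paste0(seq, cds[[i]]$seq)
    rows[[i]] <- data.frame(gene_id = sprintf("g%02d", i), element = "chr",
                            start = start, end = nchar(seq), strand = "+",
                            product = "synthetic", cog = sample(c("T", "Q", "IQ", ""), 1L))
    seq <- paste0(seq, gap())
  }
  genes <- do.call(rbind, rows)
  el <- genome_element("chr", seq)
  rep_all <- region_report(el, genes)
  expect_equal(rep_all$gene_count, n_genes)
  per_gene <- vapply(cds, function(x) scuo(x$counts), numeric(1L))
  expect_equal(unname(rep_all$gene_scuo), per_gene)
  sorted <- sort(per_gene)
  expect_equal(rep_all$median_scuo, sorted[n_genes / 2L])   # lower median
  pooled <- Reduce(`+`, lapply(cds, function(x)
    as.integer(x$counts)))
  names(pooled) <- names(Biostrings::GENETIC_CODE)
  expect_equal(rep_all$gc3s_percent, gc3s(pooled))
  # permutation invariance of the median
  perm <- genes[sample(n_genes), ]
  expect_equal(region_report(el, perm)$median_scuo, rep_all$median_scuo)

  # a window straddling gene 3 contains it but only overlaps genes 2 and 4
  g3 <- genes[3L, ]
  rep_win <- region_report(el, genes, g3$start - 10L, g3$end + 10L)
  expect_equal(rep_win$gene_count, 1L)
  expect_setequal(rep_win$overlapping_gene_ids, character(0L))
  rep_tight <- region_report(el, genes, g3$start + 3L, g3$end + 10L)
  expect_equal(rep_tight$gene_count, 0L)
  expect_equal(rep_tight$overlapping_gene_ids, "g03")
  # an interval with no genes still reports GC
  empty <- region_report(el, genes, 0L, 10L)
  expect_equal(empty$gene_count, 0L)
  expect_true(is.na(empty$median_scuo))
  expect_false(is.na(empty$gc_percent))
})

test_that("COG histograms split multi-class annotations into letters", {
  genes <- deleted_region_genes()
  set.seed(64)
  hist <- region_report(genome_element("chrII", random_seq(500)),
                        genes[0, ])$cog_histogram
  expect_length(hist, 0L)
  # hand counts from the bundled annotation table
  cogs <- unlist(strsplit(genes$cog[nzchar(genes$cog)], ""))
  expect_equal(sum(cogs == "T"), 3L)
  expect_equal(sum(cogs == "Q"), 4L)
  expect_equal(sum(cogs == "I"), 4L)
  expect_equal(sum(cogs == "G"), 3L)
  expect_equal(sum(cogs == "L"), 2L)
})
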