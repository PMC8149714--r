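## Published coordinate tables for D. radiodurans bundled as plain TSV in
## inst/extdata: the deletion coordinates of the five sequenced recA
## isolates on the reference-wt chromosome II (repeat-anchored, 1-based),
## and the gene annotations of the chromosome II region deleted in all
## isolates (wt-1999 coordinates). Published lengths that disagree with
## end - start are surfaced as warnings by the reader, never reconciled.

#' Published replicon lengths
#'
#' Lengths (bp) of the reference-wt assembly replicons and, separately, the
#' wt-1999 replicons (see \code{\link{WT1999_ELEMENT_LENGTHS}}).
#' @export
REFWT_ELEMENT_LENGTHS <- c(chrI = 2644543L, chrII = 412189L,
                           MP1 = 177363L, CP1 = 45503L)

#' Bundled deletion coordinates of the five recA isolates
#'
#' Chromosome II deletion intervals of isolates S1, S2, R1, R2 and R6 on the
#' reference wt, anchored at the beginning of the breakpoint repeat, with
#' the published deletion length and repeat string, plus the corresponding
#' wt-1999 coordinates. Reading emits warnings where the published length
#' disagrees with \code{end - start} (it does for S2, R1, R2 and R6).
#'
#' @param quiet Suppress the published-vs-computed length warnings.
#' @return Data.frame as from \code{\link{read_deletion_table}}.
#' @export
recA_deletions <- function(quiet = FALSE) {
  path <- system.file("extdata", "recA_deletions.tsv", package = "deljunct",
                      mustWork = TRUE)
  if (quiet) suppressWarnings(read_deletion_table(path))
  else read_deletion_table(path)
}

#' Bundled gene annotations of the commonly deleted chromosome II region
#'
#' Genes of the wt-1999 chromosome II region deleted in all five recA
#' isolates, with products and COG classes. Strand is not part of the
#' published table and is recorded as unknown (\code{.}).
#'
#' @return Data.frame as from \code{\link{read_gene_table}}.
#' @export
deleted_region_genes <- function() {
  read_gene_table(system.file("extdata", "chrII_deleted_region_genes.tsv",
                              package = "deljunct", mustWork = TRUE))
}
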