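## Region dispensability statistics: GC%, GC3s (GC at third positions of
## fourfold-degenerate codon boxes), per-gene SCUO (synonymous codon usage
## order, an entropy-based codon bias statistic in [0,1]) and COG category
## tabulation. Used to compare a deleted region against its whole replicon.

#' GC content of a sequence, in percent
#'
#' N bases are excluded from the denominator.
#'
#' @param seq Nucleotide string.
#' @return (G+C)/(A+C+G+T) x 100.
#' @export
gc_percent <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  x <- seq_to_codes(toupper(seq))
  n_valid <- sum(!is.na(x))
  if (n_valid == 0L) stop("sequence contains no unambiguous bases")
  100 * sum(x == 1L | x == 2L, na.rm = TRUE) / n_valid
}

## quartet codon boxes of the bacterial genetic code (translation table 11,
## whose amino acid assignments match the standard code): the eight amino
## acids with a fully fourfold-degenerate box. Ser/Leu/Arg sextets
## contribute only their quartet boxes (TCN, CTN, CGN).
.FOURFOLD_PREFIXES <- c("GC", "CG", "GG", "CT", "CC", "TC", "AC", "GT")

.ALL_CODONS <- names(Biostrings::GENETIC_CODE)

#' Count codons of a CDS
#'
#' @param seq In-frame coding sequence (length a multiple of 3), already on
#'   the coding strand. Codons containing N are dropped.
#' @return Named integer vector over the 64 codons.
#' @export
codon_counts <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0L || n %% 3L != 0L)
    stop("CDS length must be a positive multiple of 3, got ", n)
  cods <- substring(seq, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  cods <- cods[cods %in% .ALL_CODONS]
  tab <- table(factor(cods, levels = .ALL_CODONS))
  setNames(as.integer(tab), .ALL_CODONS)
}

#' Synonymous codon usage order (SCUO)
#'
#' Entropy-based codon bias in \[0, 1\]: 0 when every used amino acid
#' employs its synonymous codons uniformly, 1 when each uses a single codon.
#' For each amino acid \eqn{a} with degeneracy \eqn{n_a \ge 2} present in
#' the gene, the normalized entropy deficit
#' \eqn{O_a = (\log_2 n_a - H_a)/\log_2 n_a} is averaged with weights
#' \eqn{F_a}, the amino acid's share of the counted codons. Met, Trp and
#' stop codons are excluded; absent amino acids do not contribute.
#'
#' @param counts Named codon count vector (as from \code{\link{codon_counts}}).
#' @return SCUO value in \[0, 1\].
#' @export
scuo <- function(counts) {
  counts <- counts[intersect(names(counts), .ALL_CODONS)]
  aa <- Biostrings::GENETIC_CODE[names(counts)]
  deg <- table(Biostrings::GENETIC_CODE)   # degeneracy class per amino acid
  keep <- aa != "*" & deg[aa] >= 2L
  counts <- counts[keep]; aa <- aa[keep]
  totals <- tapply(counts, aa, sum)
  totals <- totals[totals > 0L]
  if (length(totals) == 0L)
    stop("SCUO undefined: no amino acid with synonymous codons present")
  grand <- sum(totals)
  o <- vapply(names(totals), function(a) {
    p <- counts[aa == a]
    p <- p[p > 0L] / sum(p)
    h <- -sum(p * log2(p))
    hmax <- log2(deg[[a]])
    (hmax - h) / hmax
  }, numeric(1L))
  sum((totals / grand) * o)
}

#' GC at third positions of fourfold-degenerate codon boxes (GC3s)
#'
#' Over codons belonging to the eight quartet boxes of the bacterial code
#' (GCN, CGN, GGN, CTN, CCN, TCN, ACN, GTN), the percent of third positions
#' that are G or C.
#'
#' @param counts Named codon count vector.
#' @return Percent in \[0, 100\].
#' @export
gc3s <- function(counts) {
  counts <- counts[intersect(names(counts), .ALL_CODONS)]
  in_box <- substr(names(counts), 1L, 2L) %in% .FOURFOLD_PREFIXES
  counts <- counts[in_box]
  tot <- sum(counts)
  if (tot == 0L) stop("GC3s undefined: no fourfold-box codons present")
  gc3 <- substr(names(counts), 3L, 3L) %in% c("G", "C")
  100 * sum(counts[gc3]) / tot
}

#' Per-gene codon profile
#'
#' Extracts the coding sequence of a gene from its element (minus-strand
#' genes are reverse-complemented first) and computes codon counts, SCUO and
#' GC3s. Genes whose SCUO or GC3s is undefined get \code{NA} there.
#'
#' @param element A \code{genome_element}.
#' @param start,end Internal 0-based half-open CDS interval.
#' @param strand \code{"+"}, \code{"-"}, or \code{"."} (unknown, treated as
#'   plus).
#' @return List with \code{counts}, \code{scuo}, \code{gc3s}.
#' @export
codon_profile <- function(element, start, end, strand = "+") {
  stopifnot(inherits(element, "genome_element"),
            start >= 0L, end > start, end <= element$length)
  cds <- substr(element$seq, start + 1L, end)
  if (identical(strand, "-")) cds <- revcomp(cds)
  cnt <- codon_counts(cds)
  list(counts = cnt,
       scuo = tryCatch(scuo(cnt), error = function(e) NA_real_),
       gc3s = tryCatch(gc3s(cnt), error = function(e) NA_real_))
}

## lower median: for even n the smaller of the two central order statistics;
## deterministic and exactly attained by one observation
median_lower <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  x[[ceiling(n / 2)]]
}

#' Region report: GC, codon bias, and COG composition
#'
#' Aggregates \code{\link{gc_percent}} over the region sequence and, over
#' the genes fully contained in the region (or merely overlapping it, per
#' \code{rule}), the lower-median per-gene SCUO, pooled GC3s, and a COG
#' class histogram. Genes overlapping but not contained are listed
#' separately so boundary genes are never silently dropped.
#'
#' @param element A \code{genome_element}.
#' @param genes Gene table as from \code{\link{read_gene_table}} (internal
#'   coordinates), or NULL.
#' @param start,end Internal 0-based half-open region interval; defaults to
#'   the whole element.
#' @param rule \code{"contained"} (default) or \code{"overlapping"}.
#' @return A \code{region_report} list: \code{element}, 1-based
#'   \code{start_1based}/\code{end_1based}, \code{gc_percent},
#'   \code{gene_count}, \code{median_scuo}, \code{gc3s_percent},
#'   \code{cog_histogram}, \code{gene_scuo} (named per-gene values) and
#'   \code{overlapping_gene_ids}.
#' @export
region_report <- function(element, genes = NULL, start = 0L,
                          end = element$length,
                          rule = c("contained", "overlapping")) {
  rule <- match.arg(rule)
  stopifnot(inherits(element, "genome_element"),
            start >= 0L, end >= start, end <= element$length)
  out <- list(element = element$id, start_1based = start + 1L,
              end_1based = end,
              gc_percent = gc_percent(substr(element$seq, start + 1L, end)),
              gene_count = 0L, median_scuo = NA_real_,
              gc3s_percent = NA_real_, cog_histogram = integer(0L),
              gene_scuo = numeric(0L), overlapping_gene_ids = character(0L))
  if (is.null(genes) || nrow(genes) == 0L) {
    class(out) <- "region_report"
    return(out)
  }
  g <- genes[genes$element == element$id, , drop = FALSE]
  contained <- g$start >= start & g$end <= end
  overlapping <- g$start < end & g$end > start
  sel <- if (rule == "contained") contained else overlapping
  out$overlapping_gene_ids <- g$gene_id[overlapping & !contained]
  gsel <- g[sel, , drop = FALSE]
  out$gene_count <- nrow(gsel)
  if (nrow(gsel)) {
    profs <- lapply(seq_len(nrow(gsel)), function(i)
      codon_profile(element, gsel$start[i], gsel$end[i], gsel$strand[i]))
    sc <- vapply(profs, `[[`, numeric(1L), "scuo")
    names(sc) <- gsel$gene_id
    out$gene_scuo <- sc
    out$median_scuo <- median_lower(sc[!is.na(sc)])
    pooled <- Reduce(`+`, lapply(profs, `[[`, "counts"))
    out$gc3s_percent <- tryCatch(gc3s(pooled), error = function(e) NA_real_)
  }
  cogs <- unlist(strsplit(gsel$cog[nzchar(gsel$cog)], ""))
  out$cog_histogram <- if (length(cogs)) table(cogs) else integer(0L)
  class(out) <- "region_report"
  out
}

#' @export
print.region_report <- function(x, ...) {
  cat(sprintf("<region_report> %s:%d-%d  GC %.1f%%  genes %d  median SCUO %s  GC3s %s\n",
              x$element, x$start_1based, x$end_1based, x$gc_percent,
              x$gene_count,
              ifelse(is.na(x$median_scuo), "NA", sprintf("%.4f", x$median_scuo)),
              ifelse(is.na(x$gc3s_percent), "NA", sprintf("%.1f%%", x$gc3s_percent))))
  invisible(x)
}
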