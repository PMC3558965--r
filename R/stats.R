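#' Round to 2 decimal places, halves away from zero
#'
#' The rounding convention of the genome summary tables (e.g. 93.959 prints
#' as 93.96 and 40.738 as 40.74); differs from R's banker's rounding on
#' exact halves.
#'
#' @param x Numeric vector.
#' @return `x` rounded to 2 dp with ties away from zero.
#' @export
round2 <- function(x) {
  sign(x) * floor(abs(x) * 100 + 0.5 + 1e-9) / 100
}

#' GC content of a DNA sequence, in percent
#'
#' `100 * (#G + #C) / (#A + #C + #G + #T)`, rounded half away from zero to
#' 2 decimal places. `N` bases are excluded from both numerator and
#' denominator; an all-N sequence is an error.
#'
#' @param seq DNA string or [seq_record()].
#' @return Percent GC (2 dp).
#' @examples
#' gc_percent("GCGC")  # 100
#' @export
gc_percent <- function(seq) {
  if (inherits(seq, "seq_record")) seq <- seq$seq
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  fr <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                    letters = c("A", "C", "G", "T"))
  denom <- sum(fr)
  if (denom == 0) stop("all-N sequence: GC content undefined")
  round2(100 * (fr[["C"]] + fr[["G"]]) / denom)
}

#' Percentage of a count within a total
#'
#' `round2(100 * count / total)` -- the convention used for every
#' percent-of-total column of the genome summary report.
#'
#' @param count,total Non-negative counts with `count <= total`, `total > 0`.
#' @return Percent (2 dp).
#' @examples
#' category_percent(2800, 2980)  # 93.96
#' @export
category_percent <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(count < 0 | count > total)) stop("require 0 <= count <= total")
  round2(100 * count / total)
}

#' Difference in ORF counts between two genomes
#'
#' @param count_a,count_b Non-negative ORF counts.
#' @return `count_a - count_b`.
#' @examples
#' orf_count_difference(2835, 2299)  # 536
#' @export
orf_count_difference <- function(count_a, count_b) {
  stopifnot(count_a >= 0, count_b >= 0)
  as.integer(count_a) - as.integer(count_b)
}

#' Coding fraction of a genome
#'
#' The coding region is the union of all protein-coding and RNA gene
#' intervals (overlaps merged once, never double-counted); wrapping
#' intervals on circular genomes are split at the origin before merging.
#'
#' @param annotations Data frame of gene annotations with columns `start`,
#'   `end` and `category` (`protein_coding`, `rna` or `pseudogene`;
#'   pseudogenes are not coding).
#' @param genome_len Genome length in bp.
#' @param circular Genome topology; wrapping intervals are only legal on
#'   circular genomes.
#' @return List with `coding_bp` and `percent` (2 dp).
#' @export
coding_percent <- function(annotations, genome_len, circular = TRUE) {
  genome_len <- as.integer(genome_len)
  if (is.null(annotations) || nrow(annotations) == 0)
    return(list(coding_bp = 0L, percent = 0))
  g <- annotations[annotations$category %in% c("protein_coding", "rna"), ,
                   drop = FALSE]
  if (nrow(g) == 0) return(list(coding_bp = 0L, percent = 0))
  if (any(g$end > genome_len | g$start > genome_len))
    stop("annotation interval beyond genome length")
  wrap <- g$start > g$end
  if (any(wrap) && !circular)
    stop("wrapping interval on a linear genome: coordinate error")
  starts <- c(g$start[!wrap], g$start[wrap], rep(1L, sum(wrap)))
  ends <- c(g$end[!wrap], rep(genome_len, sum(wrap)), g$end[wrap])
  merged <- IRanges::reduce(IRanges::IRanges(start = starts, end = ends))
  bp <- sum(IRanges::width(merged))
  list(coding_bp = bp, percent = round2(100 * bp / genome_len))
}

#' Build a genome summary report
#'
#' Assembles the standard genome-property rows -- size, coding bp, GC bp,
#' gene counts by category -- each with its percent-of-total (genome size
#' for bp rows, total genes for gene rows), plus optional extra category
#' counts and an inversion table (name, start, end, length, frequency) when
#' calls are supplied.
#'
#' @param genome A [seq_record()].
#' @param annotations Optional gene annotation data frame (`gene_id`,
#'   `start`, `end`, `category`, optionally `subcategory`).
#' @param extra_counts Optional named integer vector of additional gene
#'   category counts (e.g. genes assigned to orthologous-group clusters),
#'   reported as percent of total genes.
#' @param inversions Optional [call_inversions()] result (or any data frame
#'   with `name`, `start`, `end`, `length`, `frequency`).
#' @return Object of class `genome_stats_report`: `rows` (data frame
#'   `attribute`, `value`, `percent`) and `inversions`.
#' @export
build_report <- function(genome, annotations = NULL, extra_counts = NULL,
                         inversions = NULL) {
  stopifnot(inherits(genome, "seq_record"))
  L <- genome$length
  fr <- Biostrings::letterFrequency(Biostrings::DNAString(genome$seq),
                                    letters = c("C", "G"))
  gc_bp <- sum(fr)
  cp <- coding_percent(annotations, L, genome$circular)
  rows <- data.frame(
    attribute = c("Genome size (bp)", "DNA Coding region (bp)",
                  "DNA G+C content (bp)"),
    value = c(L, cp$coding_bp, gc_bp),
    percent = c(100, cp$percent, round2(100 * gc_bp / L)),
    stringsAsFactors = FALSE)
  if (!is.null(annotations) && nrow(annotations) > 0) {
    total <- nrow(annotations)
    n_rna <- sum(annotations$category == "rna")
    n_cds <- sum(annotations$category == "protein_coding")
    n_pseudo <- sum(annotations$category == "pseudogene")
    grow <- data.frame(
      attribute = c("Total genes", "RNA genes", "Protein-coding genes",
                    "Pseudogenes"),
      value = c(total, n_rna, n_cds, n_pseudo),
      percent = c(100, category_percent(n_rna, total),
                  category_percent(n_cds, total),
                  category_percent(n_pseudo, total)),
      stringsAsFactors = FALSE)
    rows <- rbind(rows, grow)
    if (!is.null(extra_counts)) {
      rows <- rbind(rows, data.frame(
        attribute = names(extra_counts),
        value = as.integer(extra_counts),
        percent = category_percent(as.integer(extra_counts), total),
        stringsAsFactors = FALSE))
    }
  }
  inv <- NULL
  if (!is.null(inversions) && nrow(inversions) > 0) {
    inv <- data.frame(name = inversions$name, start = inversions$start,
                      end = inversions$end, length = inversions$length,
                      frequency = inversions$frequency,
                      stringsAsFactors = FALSE)
  }
  structure(list(rows = rows, inversions = inv,
                 genome_id = genome$id,
                 topology = if (genome$circular) "circular" else "linear"),
            class = "genome_stats_report")
}

#' @export
print.genome_stats_report <- function(x, ...) {
  cat(sprintf("Genome summary: %s (%s)\n", x$genome_id, x$topology))
  print.data.frame(x$rows, row.names = FALSE)
  if (!is.null(x$inversions)) {
    cat("\nPopulation inversions:\n")
    print.data.frame(x$inversions, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
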