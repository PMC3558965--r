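#' Read and write FASTA with a circularity token
#'
#' Sequences are written wrapped at 70 columns; circular topology is
#' recorded as a `[topology=circular]` token in the header and recovered on
#' reading.
#'
#' @param path File path.
#' @return `read_fasta`: a named list of [seq_record()]s.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  recs <- lapply(seq_along(ss), function(i) {
    hdr <- names(ss)[i]
    circ <- grepl("[topology=circular]", hdr, fixed = TRUE)
    id <- sub("\\s.*$", "", hdr)
    seq_record(id, as.character(ss[[i]]), circular = circ)
  })
  setNames(recs, vapply(recs, `[[`, "", "id"))
}

#' @rdname read_fasta
#' @param records A [seq_record()] or list of them.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  ss <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "seq"))
  names(ss) <- vapply(records, function(r)
    paste0(r$id, if (r$circular) " [topology=circular]" else ""), "")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write intervals as 6-column BED
#'
#' Converts 1-based closed intervals to the 0-based half-open BED
#' convention. Input is a data frame with `start`, `end` and optionally
#' `seq_id`/`chrom`, `name`, `score`, `strand`.
#'
#' @param x Data frame of intervals (1-based closed), e.g. inversion calls.
#' @param path Output path.
#' @param chrom Chromosome name used when `x` carries none.
#' @export
write_bed <- function(x, path, chrom = "chr") {
  chroms <- if (!is.null(x$seq_id)) x$seq_id else
    if (!is.null(x$chrom)) x$chrom else rep(chrom, nrow(x))
  bed <- data.frame(chrom = chroms,
                    start = x$start - 1L, end = x$end,
                    name = if (!is.null(x$name)) x$name else ".",
                    score = if (!is.null(x$score)) x$score else 0L,
                    strand = if (!is.null(x$strand)) x$strand else "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data frame as TSV
#'
#' Plain tab-separated output with a header line; used for truth tables,
#' alignments, From::To tables and inversion calls.
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations
#'
#' Accepts either a 4+ column TSV (`gene_id`, `start`, `end`, `category`,
#' optional `subcategory`) or GFF3 (via \pkg{rtracklayer}; feature types
#' containing "RNA" map to category `rna`, `pseudogene` to `pseudogene`,
#' everything else to `protein_coding`).
#'
#' @param path File path.
#' @param format `"tsv"` or `"gff3"` (default guessed from the extension).
#' @return Annotation data frame (`gene_id`, `start`, `end`, `category`,
#'   `subcategory`).
#' @export
read_annotations <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "tsv") {
    x <- read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "start", "end", "category") %in% names(x)))
    if (is.null(x$subcategory)) x$subcategory <- NA_character_
    return(x[, c("gene_id", "start", "end", "category", "subcategory")])
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  category <- ifelse(grepl("RNA", type), "rna",
              ifelse(type == "pseudogene", "pseudogene", "protein_coding"))
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    sprintf("gene%04d", seq_along(gr))
  data.frame(gene_id = ids, start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr), category = category,
             subcategory = type, stringsAsFactors = FALSE)
}

#' Write a scaffold as AGP v2.1
#'
#' One object line per contig component plus gap lines between consecutive
#' contigs carrying `scaffold` linkage evidence (`paired-ends`). Gap lengths
#' come from [estimate_gaps()]; junctions without spanning pairs use
#' `default_gap`.
#'
#' @param scaffold A [build_scaffold()] result.
#' @param contig_lengths Named integer vector.
#' @param gaps Optional [estimate_gaps()] result.
#' @param path Output path.
#' @param object_name Scaffold object name.
#' @param default_gap Gap length used when unknown (AGP requires >= 1).
#' @export
write_agp <- function(scaffold, contig_lengths, gaps = NULL, path,
                      object_name = "scaffold", default_gap = 100L) {
  lines <- character(0)
  lines <- c(lines, "##agp-version\t2.1")
  for (si in seq_along(scaffold$scaffolds)) {
    sc <- scaffold$scaffolds[[si]]
    obj <- if (length(scaffold$scaffolds) == 1L) object_name else
      sprintf("%s_%d", object_name, si)
    pos <- 1L; part <- 1L
    m <- nrow(sc$order)
    for (i in seq_len(m)) {
      cid <- sc$order$contig_id[i]
      len <- contig_lengths[[cid]]
      lines <- c(lines, paste(obj, pos, pos + len - 1L, part, "W", cid, 1L,
                              len, sc$order$strand[i], sep = "\t"))
      pos <- pos + len; part <- part + 1L
      has_next <- i < m || sc$circular
      if (has_next && !(sc$circular && m == 1L)) {
        g <- default_gap
        if (!is.null(gaps)) {
          i2 <- if (i == m) 1L else i + 1L
          hit <- gaps$contig_a == cid & gaps$contig_b == sc$order$contig_id[i2]
          if (any(hit) && is.finite(gaps$gap_est[hit][1]))
            g <- max(1L, as.integer(round(gaps$gap_est[hit][1])))
        }
        if (i < m) {  # AGP is linear: the closing circular gap is not emitted
          lines <- c(lines, paste(obj, pos, pos + g - 1L, part, "N", g,
                                  "scaffold", "yes", "paired-ends", sep = "\t"))
          pos <- pos + g; part <- part + 1L
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Emit the scaffolded sequence as FASTA
#'
#' Concatenates the oriented contigs with N-runs at each junction (estimated
#' gap length where available and positive, otherwise `default_gap`).
#'
#' @param scaffold A [build_scaffold()] result.
#' @param contigs Named list of [seq_record()]s.
#' @param gaps Optional [estimate_gaps()] result.
#' @param default_gap N-run length when a gap is unknown or non-positive.
#' @return A list of [seq_record()]s, one per scaffold.
#' @export
scaffold_sequence <- function(scaffold, contigs, gaps = NULL,
                              default_gap = 100L) {
  out <- list()
  for (si in seq_along(scaffold$scaffolds)) {
    sc <- scaffold$scaffolds[[si]]
    m <- nrow(sc$order)
    parts <- character(0)
    for (i in seq_len(m)) {
      cid <- sc$order$contig_id[i]
      s <- contigs[[cid]]$seq
      if (sc$order$strand[i] == "-") s <- revcomp(s)
      parts <- c(parts, s)
      if (i < m) {
        g <- default_gap
        if (!is.null(gaps)) {
          hit <- gaps$contig_a == cid &
                 gaps$contig_b == sc$order$contig_id[i + 1L]
          if (any(hit) && is.finite(gaps$gap_est[hit][1]) &&
              gaps$gap_est[hit][1] >= 1)
            g <- as.integer(round(gaps$gap_est[hit][1]))
        }
        if (g > 0L) parts <- c(parts, strrep("N", g))
      }
    }
    out[[si]] <- seq_record(sprintf("scaffold_%d", si),
                            paste0(parts, collapse = ""),
                            circular = sc$circular)
  }
  out
}

#' Write alignments as a minimal SAM file
#'
#' Emits `@HD`/`@SQ` headers and one record per uniquely-mapped read with
#' FLAG bits for pairing (0x1), strand (0x10) and first/last of pair
#' (0x40/0x80); CIGAR is full-length match.
#'
#' @param paired Paired alignments ([map_pairs()]`$pairs`).
#' @param index The [build_index()] used for mapping (for `@SQ` lines and
#'   read length).
#' @param path Output path.
#' @export
write_sam <- function(paired, index, path) {
  k <- index$k
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", index$ids, index$lengths))
  rec <- function(id, seq, pos, strand, first) {
    flag <- 1L + 2L + (if (strand == "-") 16L else 0L) +
      (if (first) 64L else 128L)
    paste(id, flag, seq, pos, 60L, paste0(k, "M"), "*", 0L, 0L, "*", "*",
          sep = "\t")
  }
  body <- character(2L * nrow(paired))
  for (i in seq_len(nrow(paired))) {
    body[2L * i - 1L] <- rec(paired$pair_id[i], paired$seq1[i],
                             paired$pos1[i], paired$strand1[i], TRUE)
    body[2L * i] <- rec(paired$pair_id[i], paired$seq2[i],
                        paired$pos2[i], paired$strand2[i], FALSE)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write simulated reads as interleaved FASTA or FASTQ
#'
#' @param pairs Data frame from [simulate_mate_pairs()]`$pairs`.
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"` (constant qualities; the package
#'   ignores qualities on input).
#' @export
write_reads <- function(pairs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  n <- nrow(pairs)
  if (format == "fasta") {
    lines <- character(4L * n)
    lines[seq(1L, by = 4L, length.out = n)] <- paste0(">", pairs$pair_id, "/1")
    lines[seq(2L, by = 4L, length.out = n)] <- pairs$read1
    lines[seq(3L, by = 4L, length.out = n)] <- paste0(">", pairs$pair_id, "/2")
    lines[seq(4L, by = 4L, length.out = n)] <- pairs$read2
  } else {
    q <- strrep("I", nchar(pairs$read1[1]))
    lines <- character(8L * n)
    lines[seq(1L, by = 8L, length.out = n)] <- paste0("@", pairs$pair_id, "/1")
    lines[seq(2L, by = 8L, length.out = n)] <- pairs$read1
    lines[seq(3L, by = 8L, length.out = n)] <- "+"
    lines[seq(4L, by = 8L, length.out = n)] <- q
    lines[seq(5L, by = 8L, length.out = n)] <- paste0("@", pairs$pair_id, "/2")
    lines[seq(6L, by = 8L, length.out = n)] <- pairs$read2
    lines[seq(7L, by = 8L, length.out = n)] <- "+"
    lines[seq(8L, by = 8L, length.out = n)] <- q
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read mate pairs from an interleaved FASTA or FASTQ file
#'
#' Consecutive records are taken as read 1 and read 2 of a pair; `/1`
#' and `/2` suffixes are stripped from identifiers. Qualities are ignored.
#'
#' @param path File path.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return Data frame `pair_id`, `read1`, `read2`.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "@")) "fastq" else "fasta"
  }
  ss <- if (format == "fastq") Biostrings::readDNAStringSet(path, format = "fastq")
        else Biostrings::readDNAStringSet(path)
  n <- length(ss)
  if (n %% 2L != 0L) stop("interleaved file must contain an even number of reads")
  i1 <- seq(1L, n, by = 2L)
  ids <- sub("/[12]$", "", sub("\\s.*$", "", names(ss)[i1]))
  data.frame(pair_id = ids,
             read1 = as.character(ss[i1]),
             read2 = as.character(ss[i1 + 1L]),
             stringsAsFactors = FALSE)
}

#' Write a genome summary report
#'
#' @param report A [build_report()] result.
#' @param path Output path (without extension for `"both"`).
#' @param format `"tsv"` or `"markdown"`.
#' @export
write_report <- function(report, path, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "genome_stats_report"))
  if (format == "tsv") {
    write_tsv(report$rows, path)
    if (!is.null(report$inversions))
      write_tsv(report$inversions, sub("(\\.tsv)?$", ".inversions.tsv", path))
  } else {
    lines <- c(sprintf("# Genome summary: %s (%s)", report$genome_id,
                       report$topology), "",
               "| Attribute | Value | % of total |", "| --- | --- | --- |",
               sprintf("| %s | %s | %.2f |", report$rows$attribute,
                       format(report$rows$value, big.mark = ","),
                       report$rows$percent))
    if (!is.null(report$inversions)) {
      lines <- c(lines, "", "## Population inversions", "",
                 "| Name | Start | End | Length | Frequency |",
                 "| --- | --- | --- | --- | --- |",
                 sprintf("| %s | %d | %d | %d | %.2f |",
                         report$inversions$name, report$inversions$start,
                         report$inversions$end, report$inversions$length,
                         report$inversions$frequency))
    }
    writeLines(lines, path)
  }
  invisible(path)
}
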