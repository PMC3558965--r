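#' scaffinv: mate-pair scaffolding and population inversion analysis
#'
#' Tools to close draft assemblies of circular microbial genomes with
#' mate-pair libraries and to detect and quantify genomic inversions that
#' segregate within a heterogeneous (not-quite-clonal) cell population.
#' The package covers the full desk-scale workflow: seeded simulation of a
#' circular chromosome with inverted-repeat-flanked inversion loci, exact
#' unique mapping of short mate-pair reads, accumulation of the contig-pair
#' orientation-count ("From::To") table, greedy scaffold closure, inversion
#' calling from inverted-orientation discordant pairs with Wilson confidence
#' intervals on population frequencies, and genome summary statistics.
#'
#' @keywords internal
#' @importFrom stats rbinom runif setNames
#' @importFrom utils head read.delim write.table
"_PACKAGE"

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a sequence record
#'
#' A sequence record is the package's unit of reference sequence: an
#' identifier, an uppercase DNA string over `{A,C,G,T,N}`, and a topology
#' flag. Circular records permit intervals and simulated fragments that wrap
#' past the end coordinate.
#'
#' @param id Character identifier.
#' @param seq DNA string (coerced to uppercase).
#' @param circular Logical topology flag.
#' @return An object of class `seq_record` with fields `id`, `seq`,
#'   `circular` and `length`.
#' @examples
#' rec <- seq_record("chr", "ACGTACGT", circular = TRUE)
#' rec$length
#' @export
seq_record <- function(id, seq, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L,
            is.logical(circular), length(circular) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < 1L) stop("sequence must have length >= 1")
  if (grepl("[^ACGTN]", seq)) stop("sequence contains characters outside {A,C,G,T,N}")
  structure(list(id = id, seq = seq, circular = circular, length = nchar(seq)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Construct a genomic interval
#'
#' Intervals are 1-based and closed (both endpoints included), the
#' convention used throughout the package for chromosome coordinates.
#' On circular sequences a wrapping interval is represented canonically
#' with `start > end`.
#'
#' @param seq_id Identifier of the sequence the interval lives on.
#' @param start,end Integer coordinates, 1-based, inclusive.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genome_interval`.
#' @examples
#' iv <- interval("chr", 50930, 223540)
#' interval_length(iv)
#' @export
interval <- function(seq_id, start, end, strand = "+") {
  stopifnot(length(start) == 1L, length(end) == 1L,
            start >= 1L, end >= 1L, strand %in% c("+", "-"))
  structure(list(seq_id = seq_id, start = as.integer(start),
                 end = as.integer(end), strand = strand),
            class = "genome_interval")
}

#' @export
print.genome_interval <- function(x, ...) {
  cat(sprintf("<interval> %s:%d-%d(%s)\n", x$seq_id, x$start, x$end, x$strand))
  invisible(x)
}

#' Length of a 1-based closed interval
#'
#' For a non-wrapping interval the length is `end - start + 1`. A wrapping
#' interval (`start > end`) is only legal on a circular sequence and its
#' length is `(seq_len - start + 1) + end`.
#'
#' @param iv A `genome_interval`, or an integer start coordinate.
#' @param end End coordinate when `iv` is given as a start coordinate.
#' @param seq_len Sequence length; required for wrapping intervals.
#' @param circular Whether the underlying sequence is circular.
#' @return Integer length in bp.
#' @examples
#' interval_length(50930, 223540)   # 172611
#' @export
interval_length <- function(iv, end = NULL, seq_len = NULL, circular = FALSE) {
  if (inherits(iv, "genome_interval")) {
    start <- iv$start; stop_ <- iv$end
  } else {
    start <- as.integer(iv); stop_ <- as.integer(end)
  }
  if (start <= stop_) return(stop_ - start + 1L)
  if (!circular)
    stop("start > end on a non-circular sequence: coordinate error")
  if (is.null(seq_len))
    stop("seq_len is required to measure a wrapping interval")
  (as.integer(seq_len) - start + 1L) + stop_
}

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; `N` is complemented to `N`. `revcomp` is an
#' involution: `revcomp(revcomp(x)) == x`.
#'
#' @param x Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AAAC")  # "GTTT"
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  if (any(grepl("[^ACGTN]", x)))
    stop("illegal character: revcomp is defined over {A,C,G,T,N}")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between 1-based closed and BED (0-based half-open) coordinates
#'
#' `to_bed` maps a non-wrapping interval to the BED convention
#' `(chrom, start - 1, end)`; `from_bed` is its inverse. The two form a
#' bijection on valid non-wrapping intervals.
#'
#' @param iv A `genome_interval` (non-wrapping).
#' @return `to_bed`: a list with `chrom`, `start`, `end`, `strand` in BED
#'   convention. `from_bed`: a `genome_interval`.
#' @examples
#' to_bed(interval("chr", 1, 10))
#' @export
to_bed <- function(iv) {
  stopifnot(inherits(iv, "genome_interval"))
  if (iv$start > iv$end)
    stop("wrapping interval: split into two BED records before export")
  list(chrom = iv$seq_id, start = iv$start - 1L, end = iv$end, strand = iv$strand)
}

#' @rdname to_bed
#' @param chrom,start,end,strand BED fields (0-based half-open).
#' @export
from_bed <- function(chrom, start, end, strand = "+") {
  interval(chrom, as.integer(start) + 1L, as.integer(end), strand)
}

#' Mate-pair library specification
#'
#' Describes the sequencing library: fragment ("insert") length bounds, read
#' length, and the expected relative strand of the two reads of a pair.
#' Mate-pair chemistry places both reads on the same strand of the fragment
#' (`expected_relative_strand = "same"`), which makes inversion evidence
#' visible as opposite-strand mappings; paired-end chemistry would use
#' `"opposite"`.
#'
#' @param insert_min,insert_max Fragment length bounds in bp.
#' @param read_length Read length in bp.
#' @param expected_relative_strand `"same"` (mate-pair) or `"opposite"`
#'   (paired-end).
#' @return An object of class `library_spec`.
#' @examples
#' library_spec()  # the 1000-3500 bp / 25 bp mate-pair design
#' @export
library_spec <- function(insert_min = 1000L, insert_max = 3500L,
                         read_length = 25L,
                         expected_relative_strand = c("same", "opposite")) {
  expected_relative_strand <- match.arg(expected_relative_strand)
  insert_min <- as.integer(insert_min); insert_max <- as.integer(insert_max)
  read_length <- as.integer(read_length)
  if (!(read_length > 0L && read_length < insert_min && insert_min <= insert_max))
    stop("require 0 < read_length < insert_min <= insert_max")
  structure(list(insert_min = insert_min, insert_max = insert_max,
                 read_length = read_length,
                 expected_relative_strand = expected_relative_strand),
            class = "library_spec")
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf("<library_spec> inserts %d-%d bp, reads %d bp, relative strand: %s\n",
              x$insert_min, x$insert_max, x$read_length, x$expected_relative_strand))
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream (no global RNG state leaks out of simulation functions).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Substring on a circular sequence: positions are taken modulo the sequence
# length, `start` in 1..len, total extraction <= len assumed by callers.
circ_substr <- function(seq2x, start, width) {
  # seq2x is the sequence concatenated with its own prefix (>= max width - 1)
  substring(seq2x, start, start + width - 1L)
}
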