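#' Build an exact-match read index over a set of targets
#'
#' Indexes every k-mer of both strands of every target for exact matching of
#' fixed-length reads. Circular targets contribute wrap-around k-mers (a
#' circular target of length L exposes exactly L forward k-mer start
#' positions). Matching itself is delegated to the Aho-Corasick machinery of
#' `Biostrings::matchPDict`.
#'
#' @param targets A list of [seq_record()]s (or a single one).
#' @param k Read length in bp.
#' @return An object of class `read_index`.
#' @export
build_index <- function(targets, k) {
  if (inherits(targets, "seq_record")) targets <- list(targets)
  stopifnot(length(targets) > 0, all(vapply(targets, inherits, TRUE, "seq_record")))
  k <- as.integer(k)
  lens <- vapply(targets, `[[`, 1L, "length")
  if (k > min(lens))
    stop("k exceeds the shortest target (configuration error)")
  circ <- vapply(targets, `[[`, TRUE, "circular")
  ids <- vapply(targets, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate target ids")
  ext <- Biostrings::DNAStringSet(vapply(seq_along(targets), function(i) {
    s <- targets[[i]]$seq
    if (circ[i]) paste0(s, substring(s, 1L, k - 1L)) else s
  }, ""))
  names(ext) <- ids
  structure(list(ext = ext, ids = ids, lengths = lens, circular = circ, k = k),
            class = "read_index")
}

#' @export
print.read_index <- function(x, ...) {
  cat(sprintf("<read_index> %d target(s), k = %d\n", length(x$ids), x$k))
  invisible(x)
}

#' Map fixed-length reads exactly and classify by uniqueness
#'
#' Each read is matched exactly against both strands of every indexed
#' target. A read with exactly one hit across all targets and strands is
#' `unique` (position and strand reported); more than one hit is
#' `ambiguous`; no hit is `unmapped`. Reads containing `N` are rejected
#' outright (`rejected_n`) and never matched. Minus-strand positions are the
#' 1-based leftmost coordinate of the match of the read's reverse complement
#' on the forward strand (SAM convention).
#'
#' @param index A [build_index()] result.
#' @param reads Character vector of reads, all of length `index$k`.
#' @param read_ids Optional read identifiers (default `read1..readN`).
#' @return Data frame with columns `read_id`, `seq_id`, `pos`, `strand`,
#'   `status`; `seq_id`/`pos`/`strand` are `NA` unless `status == "unique"`.
#' @export
map_reads <- function(index, reads, read_ids = NULL) {
  stopifnot(inherits(index, "read_index"))
  n <- length(reads)
  if (is.null(read_ids)) read_ids <- sprintf("read%d", seq_len(n))
  out <- data.frame(read_id = read_ids, seq_id = NA_character_,
                    pos = NA_integer_, strand = NA_character_,
                    status = rep("unmapped", n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  if (any(nchar(reads) != index$k))
    stop("all reads must have length k = ", index$k)
  has_n <- grepl("N", reads, fixed = TRUE)
  out$status[has_n] <- "rejected_n"
  valid <- which(!has_n)
  if (length(valid) == 0L) return(out)

  rs <- Biostrings::DNAStringSet(reads[valid])
  pd_f <- Biostrings::PDict(rs)
  pd_r <- Biostrings::PDict(Biostrings::reverseComplement(rs))
  ntarg <- length(index$ids)
  ncol_ <- 2L * ntarg
  cnt <- matrix(0L, nrow = length(valid), ncol = ncol_)
  si <- vector("list", ncol_)
  for (j in seq_len(ntarg)) {
    subj <- index$ext[[j]]
    mi_f <- Biostrings::matchPDict(pd_f, subj)
    mi_r <- Biostrings::matchPDict(pd_r, subj)
    si[[2L * j - 1L]] <- Biostrings::startIndex(mi_f)
    si[[2L * j]] <- Biostrings::startIndex(mi_r)
    cnt[, 2L * j - 1L] <- S4Vectors::elementNROWS(si[[2L * j - 1L]])
    cnt[, 2L * j] <- S4Vectors::elementNROWS(si[[2L * j]])
  }
  total <- rowSums(cnt)
  st <- ifelse(total == 0L, "unmapped", ifelse(total == 1L, "unique", "ambiguous"))
  out$status[valid] <- st
  uniq <- which(st == "unique")
  if (length(uniq) > 0L) {
    col <- max.col(cnt[uniq, , drop = FALSE])
    for (cc in unique(col)) {
      rows <- uniq[col == cc]                    # rows within `valid`
      pos <- unlist(si[[cc]][rows], use.names = FALSE)
      gi <- valid[rows]                          # rows in `out`
      tj <- (cc + 1L) %/% 2L
      out$seq_id[gi] <- index$ids[tj]
      out$pos[gi] <- pos
      out$strand[gi] <- if (cc %% 2L == 1L) "+" else "-"
    }
  }
  out
}

#' Map a single read
#'
#' Convenience wrapper around [map_reads()] for one read.
#'
#' @inheritParams map_reads
#' @param read A single read string.
#' @param read_id Identifier.
#' @return One-row data frame as in [map_reads()].
#' @export
map_read <- function(index, read, read_id = "read1") {
  map_reads(index, read, read_id)
}

#' Map mate pairs and retain those with both reads uniquely mapped
#'
#' Maps both reads of every pair with [map_reads()] and keeps only pairs in
#' which both reads map uniquely -- the uniqueness requirement under which
#' orientation-count evidence is accumulated. The summary partitions all
#' pairs into `both_unique`, `any_ambiguous` (at least one read ambiguous)
#' and `any_unmapped` (no ambiguous read, at least one unmapped or
#' N-containing read); the three counts sum to the input pair count.
#'
#' @param index A [build_index()] result.
#' @param pairs Data frame with columns `pair_id`, `read1`, `read2` (as
#'   produced by [simulate_mate_pairs()]).
#' @return List with `pairs` (data frame of paired alignments: `pair_id`,
#'   `seq1`, `pos1`, `strand1`, `seq2`, `pos2`, `strand2`) and `summary`
#'   (named list of category counts, including `n_rejected_n` reads counted
#'   separately).
#' @export
map_pairs <- function(index, pairs) {
  stopifnot(all(c("pair_id", "read1", "read2") %in% names(pairs)))
  a1 <- map_reads(index, pairs$read1, pairs$pair_id)
  a2 <- map_reads(index, pairs$read2, pairs$pair_id)
  both_unique <- a1$status == "unique" & a2$status == "unique"
  any_amb <- !both_unique & (a1$status == "ambiguous" | a2$status == "ambiguous")
  any_unm <- !both_unique & !any_amb
  keep <- which(both_unique)
  list(pairs = data.frame(pair_id = pairs$pair_id[keep],
                          seq1 = a1$seq_id[keep], pos1 = a1$pos[keep],
                          strand1 = a1$strand[keep],
                          seq2 = a2$seq_id[keep], pos2 = a2$pos[keep],
                          strand2 = a2$strand[keep],
                          stringsAsFactors = FALSE),
       summary = list(total = nrow(pairs),
                      both_unique = sum(both_unique),
                      any_ambiguous = sum(any_amb),
                      any_unmapped = sum(any_unm),
                      n_rejected_n = sum(a1$status == "rejected_n") +
                                     sum(a2$status == "rejected_n")))
}
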